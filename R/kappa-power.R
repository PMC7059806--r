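#' Describe a kappa sample-size scenario
#'
#' Bundles the planning inputs of a two-rater agreement study: anticipated
#' marginal category probabilities for each rater, the kappa to rule out
#' (`k0`), the kappa expected if the protocol works as hoped (`k1`), the
#' test's type-I error and target power, and its sidedness.
#'
#' @param marginalsA,marginalsB probability vectors over the rating
#'   categories (default: the same vector for both raters).
#' @param k0 null-hypothesis kappa.
#' @param k1 alternative (true) kappa, `> k0`.
#' @param alpha type-I error (default 0.05).
#' @param power target power (default 0.8).
#' @param sided `"one_sided"` (default) or `"two_sided"`.
#' @return A [KappaPowerScenario-class].
#' @examples
#' kappaPowerScenario(c(0.30, 0.35, 0.35), k0 = 0.5, k1 = 0.72)
#' @export
kappaPowerScenario <- function(marginalsA, marginalsB = marginalsA,
                               k0, k1, alpha = 0.05, power = 0.8,
                               sided = c("one_sided", "two_sided")) {
  new("KappaPowerScenario", marginalsA = as.numeric(marginalsA),
      marginalsB = as.numeric(marginalsB), k0 = as.numeric(k0),
      k1 = as.numeric(k1), alpha = alpha, power = power,
      sided = match.arg(sided))
}

setMethod("show", "KappaPowerScenario", function(object) {
  cat(sprintf("KappaPowerScenario: k0 = %g vs k1 = %g, alpha = %g (%s), power = %g\n",
              object@k0, object@k1, object@alpha, object@sided, object@power))
  cat("  marginals A:", paste(signif(object@marginalsA, 3), collapse = " "), "\n")
  cat("  marginals B:", paste(signif(object@marginalsB, 3), collapse = " "), "\n")
  invisible(object)
})

# LP data shared by extremalJoint / kappaVariance: FCE variance numerator is
# linear in the joint cell probabilities once the margins and kappa (hence
# p_e, p_o) are fixed.
kappaLP <- function(pa, pb, kappa) {
  k <- length(pa)
  pe <- sum(pa * pb)
  if (1 - pe < 1e-12)
    stop("degenerate margins: expected agreement is 1", call. = FALSE)
  po <- kappa * (1 - pe) + pe
  if (po < -1e-12 || po > 1 + 1e-12)
    stop(sprintf("kappa = %g is unattainable for these margins (implied agreement %.3f)",
                 kappa, po), call. = FALSE)
  cc <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cc[i, j] <- if (i == j) (1 - (pa[i] + pb[i]) * (1 - kappa))^2
                else (1 - kappa)^2 * (pb[i] + pa[j])^2
  }
  A <- matrix(0, 2L * k + 1L, k * k)
  b <- c(pa, pb, po)
  for (i in seq_len(k)) A[i, (seq_len(k) - 1L) * k + i] <- 1       # row sums
  for (j in seq_len(k)) A[k + j, (j - 1L) * k + seq_len(k)] <- 1   # col sums
  A[2L * k + 1L, (seq_len(k) - 1L) * k + seq_len(k)] <- 1          # trace
  list(k = k, pe = pe, po = po, coef = cc, A = A, b = b)
}

#' Extremal joint distribution for the kappa variance bound
#'
#' Among all joint rating distributions with the given margins and the given
#' kappa, finds the one maximizing the large-sample variance of the kappa
#' estimator (Fleiss-Cohen-Everitt variance; the maximization is a linear
#' program over the joint simplex, following the conservative planning
#' approach of Flack, Afifi, Lachenbruch and Schouten 1988).
#'
#' @param marginalsA,marginalsB marginal probability vectors.
#' @param kappa the fixed kappa value.
#' @return k x k joint probability matrix (rows = rater A).
#' @export
extremalJoint <- function(marginalsA, marginalsB = marginalsA, kappa) {
  lp <- kappaLP(marginalsA, marginalsB, kappa)
  sol <- simplexMax(as.vector(lp$coef), lp$A, lp$b)
  if (!sol$feasible)
    stop(sprintf("kappa = %g is unattainable for these margins (no joint distribution exists)",
                 kappa), call. = FALSE)
  matrix(sol$x, lp$k, lp$k)
}

#' Worst-case variance factor of the kappa estimator
#'
#' The large-sample variance multiplier Q such that Var(kappa-hat) = Q / n,
#' evaluated at the extremal (variance-maximizing) joint distribution
#' consistent with the margins and the given kappa. Strictly positive
#' except at the degenerate perfect-agreement boundary (kappa = 1 with
#' equal margins), where it is 0.
#'
#' @inheritParams extremalJoint
#' @return Non-negative scalar variance factor.
#' @examples
#' kappaVariance(c(0.30, 0.35, 0.35), kappa = 0.72)
#' @export
kappaVariance <- function(marginalsA, marginalsB = marginalsA, kappa) {
  lp <- kappaLP(marginalsA, marginalsB, kappa)
  sol <- simplexMax(as.vector(lp$coef), lp$A, lp$b)
  if (!sol$feasible)
    stop(sprintf("kappa = %g is unattainable for these margins (no joint distribution exists)",
                 kappa), call. = FALSE)
  q <- (sol$value - (kappa - lp$pe * (1 - kappa))^2) / (1 - lp$pe)^2
  max(q, 0)
}

zAlphaOf <- function(scenario)
  stats::qnorm(1 - scenario@alpha /
                 (if (scenario@sided == "two_sided") 2 else 1))

#' Minimum sample size to detect a kappa improvement
#'
#' Smallest integer N for which the normal-approximation test of
#' H0: kappa = k0 against the alternative kappa = k1 reaches the target
#' power, using the worst-case variance factors at k0 and k1
#' ([kappaVariance()]):
#' N = ceiling( ( (z_alpha sqrt(Q0) + z_power sqrt(Q1)) / (k1 - k0) )^2 ).
#'
#' @param scenario a [KappaPowerScenario-class].
#' @return Integer sample size (number of items rated by both raters).
#' @examples
#' sc <- kappaPowerScenario(c(0.30, 0.35, 0.35), k0 = 0.5, k1 = 0.72)
#' minSampleSize(sc)
#' @export
minSampleSize <- function(scenario) {
  stopifnot(is(scenario, "KappaPowerScenario"))
  q0 <- kappaVariance(scenario@marginalsA, scenario@marginalsB, scenario@k0)
  q1 <- kappaVariance(scenario@marginalsA, scenario@marginalsB, scenario@k1)
  za <- zAlphaOf(scenario)
  zb <- stats::qnorm(scenario@power)
  rawN <- ((za * sqrt(q0) + zb * sqrt(q1)) / (scenario@k1 - scenario@k0))^2
  as.integer(ceiling(rawN - 1e-9))
}

# unweighted kappa estimate from a k x k count table; NA when p_e-hat = 1
kappaHat <- function(counts) {
  n <- sum(counts)
  P <- counts / n
  po <- sum(diag(P))
  pe <- sum(rowSums(P) * colSums(P))
  if (1 - pe < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Monte-Carlo power of the kappa test at a given sample size
#'
#' Simulates paired rating sets of size `n` from the extremal joint
#' distribution with the scenario margins and kappa = k1, applies the
#' planning test of H0: kappa = k0 (reject when kappa-hat exceeds
#' k0 + z_alpha sqrt(Q0 / n), with Q0 the worst-case variance factor at k0
#' that the sample-size formula itself uses), and returns the rejection
#' fraction.
#'
#' @param scenario a [KappaPowerScenario-class].
#' @param n sample size per replicate (`>= 2`).
#' @param reps number of Monte-Carlo replicates (default 2000).
#' @param seed integer seed.
#' @return Numeric power estimate in [0, 1] with attribute `se` (binomial
#'   standard error) and `reps`.
#' @export
empiricalPower <- function(scenario, n, reps = 2000L, seed = 1L) {
  stopifnot(is(scenario, "KappaPowerScenario"), n >= 2, reps >= 1)
  q0 <- kappaVariance(scenario@marginalsA, scenario@marginalsB, scenario@k0)
  J1 <- extremalJoint(scenario@marginalsA, scenario@marginalsB, scenario@k1)
  k <- nrow(J1)
  za <- zAlphaOf(scenario)
  crit <- scenario@k0 + za * sqrt(q0 / n)
  draws <- withSeed(seed, stats::rmultinom(reps, n, as.vector(J1)))
  rej <- vapply(seq_len(reps), function(r) {
    kh <- kappaHat(matrix(draws[, r], k, k))
    isTRUE(kh > crit)
  }, logical(1))
  p <- mean(rej)
  structure(p, se = sqrt(max(p * (1 - p), 1e-12) / reps), reps = reps)
}
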