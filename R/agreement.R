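kappaWeights <- function(weights = c("linear", "quadratic", "unweighted"),
                         k = length(ratingLevels())) {
  weights <- match.arg(weights)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  switch(weights,
         linear = 1 - d,
         quadratic = 1 - d^2,
         unweighted = (d == 0) * 1)
}

# shared pairing rule: restrict to positions rated by both
pairComplete <- function(a, b) {
  if (!is.factor(a)) a <- asRating(a)
  if (!is.factor(b)) b <- asRating(b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) {
    stop("rating vectors differ in length and carry no image names",
         call. = FALSE)
  }
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

#' Weighted Cohen's kappa for two raters
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), where p_o and
#' p_e are observed and expected agreement computed as weighted sums over
#' the 3x3 contingency table. With the default linear weights
#' `w_ij = 1 - |i - j| / 2`, an OK-vs-Maybe or Maybe-vs-Fail disagreement
#' counts as half a disagreement and OK-vs-Fail as a full one, matching the
#' protocol's reading of adjacent categories as partial disagreement.
#'
#' When both vectors carry image names, the comparison is restricted to the
#' commonly rated images (pairwise-complete analysis). When both raters are
#' constant and identical, `p_e = 1` and kappa is undefined: the function
#' returns `NA` flagged with `attr(, "undefined")` rather than a value.
#'
#' @param a,b rating vectors (ordered factors from [asRating()], or
#'   character), optionally named by image id.
#' @param weights `"linear"` (default), `"quadratic"` or `"unweighted"`.
#' @return Numeric scalar in [-1, 1], or `NA` with attribute
#'   `undefined = TRUE` when `p_e = 1`.
#' @examples
#' a <- asRating(c("OK", "OK", "Maybe", "Fail"))
#' b <- asRating(c("OK", "Maybe", "Maybe", "Fail"))
#' weightedKappa(a, b)
#' @export
weightedKappa <- function(a, b, weights = c("linear", "quadratic", "unweighted")) {
  p <- pairComplete(a, b)
  if (length(p$a) < 2L)
    stop("fewer than 2 commonly rated images; kappa needs at least 2",
         call. = FALSE)
  counts <- table(p$a, p$b)
  weightedKappaFromTable(unclass(counts), weights)
}

#' @rdname weightedKappa
#' @param counts k x k contingency matrix of joint rating counts (rows =
#'   rater A, columns = rater B), category order worst to best.
#' @export
weightedKappaFromTable <- function(counts,
                                   weights = c("linear", "quadratic", "unweighted")) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  stopifnot(ncol(counts) == k, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  w <- kappaWeights(weights, k)
  P <- counts / n
  po <- sum(w * P)
  pe <- as.numeric(rowSums(P) %*% w %*% colSums(P))
  if (1 - pe < 1e-12)
    return(structure(NA_real_, undefined = TRUE))
  (po - pe) / (1 - pe)
}

#' Per-category Sorensen-Dice agreement
#'
#' For one rating category, the Dice coefficient 2|X n Y| / (|X| + |Y|)
#' between the sets of images each rater assigned to that category: the
#' number of images both raters put in the category, divided by the average
#' number either put there. Undefined (flagged `NA`) when neither rater
#' used the category.
#'
#' @param a,b rating vectors as in [weightedKappa()].
#' @param category the rating level (`"OK"`, `"Maybe"` or `"Fail"`).
#' @return Numeric scalar in [0, 1], or flagged `NA` when both sets are
#'   empty.
#' @export
categoryDice <- function(a, b, category) {
  category <- as.character(asRating(category))
  p <- pairComplete(a, b)
  if (length(p$a) < 2L)
    stop("fewer than 2 commonly rated images", call. = FALSE)
  x <- p$a == category; y <- p$b == category
  denom <- sum(x) + sum(y)
  if (denom == 0) return(structure(NA_real_, undefined = TRUE))
  2 * sum(x & y) / denom
}

#' Landis-Koch interpretation band of an agreement value
#'
#' Conventional qualitative labels for kappa (and, by the protocol's usage,
#' Dice): poor (<= 0), slight (0, 0.20], fair (0.20, 0.40], moderate
#' (0.40, 0.60], substantial (0.60, 0.80], almost perfect (0.80, 1].
#' Intervals are upper-closed, which covers the gap the printed ranges
#' leave between 0 and 0.01.
#'
#' @param value numeric in [-1, 1] (vectorized).
#' @return Character vector of band labels.
#' @examples
#' interpretStrength(c(0, 0.54, 0.80, 0.95))
#' @export
interpretStrength <- function(value) {
  if (any(!is.na(value) & (value < -1 | value > 1)))
    stop("agreement values must lie in [-1, 1]", call. = FALSE)
  cut(value, breaks = c(-1.000001, 0, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"),
      right = TRUE) |> as.character()
}

#' Pairwise agreement report for raters and consensus panels
#'
#' Computes all pairwise weighted kappas and per-category Dice coefficients
#' between the requested units over commonly rated images, with the
#' Landis-Koch band and the shared-image count for every pair. A unit is a
#' single rater id or a named panel (character vector of rater ids), in
#' which case the panel is first collapsed with [panelConsensus()]. Pairs
#' with fewer than 2 common images are reported as `NA` rather than
#' failing.
#'
#' @param table a [RatingTable-class].
#' @param units character vector of rater ids, or a named list mixing rater
#'   ids and panels; default: every rater in the table.
#' @param weights kappa weighting scheme.
#' @return An [AgreementReport-class].
#' @export
pairwiseReport <- function(table, units = NULL,
                           weights = c("linear", "quadratic", "unweighted")) {
  stopifnot(is(table, "RatingTable"))
  weights <- match.arg(weights)
  if (is.null(units)) units <- table@raterIds
  if (!is.list(units)) units <- stats::setNames(as.list(units), units)
  if (is.null(names(units)) || any(names(units) == ""))
    stop("units must be named", call. = FALSE)
  if (length(units) < 2L) stop("need at least 2 units", call. = FALSE)
  vecs <- lapply(units, function(u) {
    if (length(u) == 1L) raterVector(table, u)
    else suppressWarnings(panelConsensus(table, u))
  })
  nm <- names(units); nu <- length(units)
  kp <- matrix(NA_real_, nu, nu, dimnames = list(nm, nm))
  nc <- matrix(0L, nu, nu, dimnames = list(nm, nm))
  dice <- stats::setNames(lapply(ratingLevels(), function(l) kp), ratingLevels())
  diag(kp) <- 1
  for (i in seq_len(nu)) {
    nc[i, i] <- length(vecs[[i]])
    for (l in ratingLevels()) dice[[l]][i, i] <- 1
  }
  for (i in seq_len(nu - 1L)) for (j in (i + 1L):nu) {
    common <- intersect(names(vecs[[i]]), names(vecs[[j]]))
    nc[i, j] <- nc[j, i] <- length(common)
    if (length(common) < 2L) next
    kp[i, j] <- kp[j, i] <- as.numeric(weightedKappa(vecs[[i]], vecs[[j]],
                                                     weights = weights))
    for (l in ratingLevels())
      dice[[l]][i, j] <- dice[[l]][j, i] <-
        as.numeric(categoryDice(vecs[[i]], vecs[[j]], l))
  }
  bands <- matrix(interpretStrength(pmax(pmin(kp, 1), -1)), nu, nu,
                  dimnames = list(nm, nm))
  new("AgreementReport", units = nm, kappa = kp, dice = dice, bands = bands,
      nCommon = nc, weights = weights)
}

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport (%s weights): %d units\n", object@weights,
              length(object@units)))
  off <- object@kappa[upper.tri(object@kappa)]
  if (length(off) && any(!is.na(off)))
    cat(sprintf("  pairwise kappa: mean %.3f, range [%.3f, %.3f]\n",
                mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
                max(off, na.rm = TRUE)))
  invisible(object)
})

#' Write an agreement report to CSV matrices plus a JSON summary
#'
#' @param report an [AgreementReport-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeAgreementReport <- function(report, dir) {
  stopifnot(is(report, "AgreementReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report@kappa, file.path(dir, "kappa.csv"))
  for (l in names(report@dice))
    utils::write.csv(report@dice[[l]], file.path(dir, sprintf("dice_%s.csv", l)))
  utils::write.csv(report@nCommon, file.path(dir, "n_common.csv"))
  jsonlite::write_json(
    list(weights = report@weights, units = report@units,
         kappa = report@kappa, bands = report@bands,
         dice = report@dice, n_common = report@nCommon),
    file.path(dir, "agreement.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(dir)
}
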