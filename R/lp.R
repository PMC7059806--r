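# Dense two-phase primal simplex for small linear programs
#   maximize c'x  subject to  A x = b,  x >= 0
# Bland's rule throughout (anti-cycling). Written for the tiny LPs of the
# kappa variance bound (k^2 variables, 2k+1 equality rows), where a dense
# tableau is simplest and exact enough.

simplexPivot <- function(Tab, basis, cvec, tol = 1e-10, maxIter = 10000L) {
  m <- nrow(Tab); n <- ncol(Tab) - 1L
  for (it in seq_len(maxIter)) {
    cB <- cvec[basis]
    red <- cvec - as.numeric(cB %*% Tab[, seq_len(n), drop = FALSE])
    red[basis] <- 0
    enter <- which(red > tol)
    if (!length(enter)) return(list(Tab = Tab, basis = basis, status = "optimal"))
    j <- min(enter)  # Bland
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tab = Tab, basis = basis, status = "unbounded"))
    ratio <- Tab[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    i <- cand[which.min(basis[cand])]  # Bland tie-break
    piv <- Tab[i, j]
    Tab[i, ] <- Tab[i, ] / piv
    for (r in seq_len(m)) if (r != i && abs(Tab[r, j]) > 0)
      Tab[r, ] <- Tab[r, ] - Tab[r, j] * Tab[i, ]
    basis[i] <- j
  }
  list(Tab = Tab, basis = basis, status = "maxiter")
}

# returns list(feasible, x, value)
simplexMax <- function(cvec, A, b, tol = 1e-9) {
  A <- as.matrix(A); m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]; b[flip] <- -b[flip]
  # phase 1
  Tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- simplexPivot(Tab, basis, c1, tol = tol)
  if (p1$status != "optimal") return(list(feasible = FALSE))
  art <- sum(p1$Tab[match(n + seq_len(m), p1$basis, nomatch = 0L)[
    match(n + seq_len(m), p1$basis, nomatch = 0L) > 0L], n + m + 1L])
  val1 <- sum(c1[p1$basis] * p1$Tab[, n + m + 1L])
  if (val1 < -1e-7) return(list(feasible = FALSE))
  Tab <- p1$Tab; basis <- p1$basis
  # pivot remaining artificials out of the basis (degenerate rows)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      j <- which(abs(Tab[i, seq_len(n)]) > tol)
      if (length(j)) {
        j <- min(j)
        piv <- Tab[i, j]
        Tab[i, ] <- Tab[i, ] / piv
        for (r in seq_len(m)) if (r != i && abs(Tab[r, j]) > 0)
          Tab[r, ] <- Tab[r, ] - Tab[r, j] * Tab[i, ]
        basis[i] <- j
      } else keep[i] <- FALSE  # redundant constraint row
    }
  }
  Tab <- Tab[keep, c(seq_len(n), n + m + 1L), drop = FALSE]
  basis <- basis[keep]
  # phase 2
  p2 <- simplexPivot(Tab, basis, cvec, tol = tol)
  if (p2$status == "unbounded") return(list(feasible = TRUE, unbounded = TRUE))
  x <- numeric(n)
  x[p2$basis] <- p2$Tab[, ncol(p2$Tab)]
  list(feasible = TRUE, unbounded = FALSE, x = x,
       value = sum(cvec * x))
}
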