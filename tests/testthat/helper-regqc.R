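# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive enumeration (explicit loops, ball structuring elements, direct
# formula evaluation) so they share no code path with the implementation.

# --- volumes -----------------------------------------------------------

centredAffine <- function(n, voxel = c(1, 1, 1)) {
  a <- diag(c(voxel, 1))
  a[1:3, 4] <- -(n - 1) / 2 * voxel
  a
}

coordGrids <- function(n, voxel = c(1, 1, 1)) {
  if (length(n) == 1L) n <- rep(n, 3L)
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  ax <- lapply(1:3, function(a) ((seq_len(n[a]) - 1) - (n[a] - 1) / 2) * voxel[a])
  list(X = array(rep(ax[[1]], times = n[2] * n[3]), n),
       Y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), n),
       Z = array(rep(ax[[3]], each = n[1] * n[2]), n))
}

makeSphereVolume <- function(radius, n, voxel = 1) {
  g <- coordGrids(n, voxel)
  r <- sqrt(g$X^2 + g$Y^2 + g$Z^2)
  vol <- BrainVolume(array(as.numeric(r <= radius), dim(r)),
                     centredAffine(rep(n, 3L)[1:3], rep(voxel, 3L)))
  list(vol = vol, r = r)
}

# random smooth blob mask (threshold of a few cosine modes)
makeBlobMask <- function(seed, n = 24L, voxel = c(1, 1, 1)) {
  g <- coordGrids(n, voxel)
  set.seed(seed)
  f <- 0
  for (m in 1:5) {
    k <- runif(3, -0.25, 0.25); ph <- runif(1, 0, 2 * pi)
    f <- f + rnorm(1) * cos(k[1] * g$X + k[2] * g$Y + k[3] * g$Z + ph)
  }
  ext <- (n - 1) / 2 * voxel
  rim <- (g$X / ext[1])^2 + (g$Y / ext[2])^2 + (g$Z / ext[3])^2
  m <- array(as.numeric(f > 0 & rim < 0.7), dim(f))
  BrainVolume(m, centredAffine(rep(n, 3L), voxel))
}

# --- morphology oracle: explicit ball structuring element --------------

ballOffsets <- function(radiusMm, voxel) {
  reach <- floor(radiusMm / voxel)
  off <- as.matrix(expand.grid(i = -reach[1]:reach[1],
                               j = -reach[2]:reach[2],
                               k = -reach[3]:reach[3]))
  d2 <- (off[, 1] * voxel[1])^2 + (off[, 2] * voxel[2])^2 + (off[, 3] * voxel[3])^2
  off[d2 <= radiusMm^2 + 1e-9, , drop = FALSE]
}

bruteDilate <- function(maskArr, radiusMm, voxel = c(1, 1, 1)) {
  off <- ballOffsets(radiusMm, voxel)
  dm <- dim(maskArr)
  out <- array(0, dm)
  src <- which(maskArr != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(src))) {
    tgt <- sweep(off, 2, src[r, ], "+")
    ok <- tgt[, 1] >= 1 & tgt[, 1] <= dm[1] & tgt[, 2] >= 1 &
      tgt[, 2] <= dm[2] & tgt[, 3] >= 1 & tgt[, 3] <= dm[3]
    out[tgt[ok, , drop = FALSE]] <- 1
  }
  out
}

bruteErode <- function(maskArr, radiusMm, voxel = c(1, 1, 1)) {
  # closed-ball convention: keep voxels with distance > r to background,
  # i.e. no background voxel within the closed ball
  bg <- 1 - maskArr
  dil <- bruteDilate(bg, radiusMm, voxel)
  array(as.numeric(maskArr != 0 & dil == 0), dim(maskArr))
}

# --- agreement oracle: scalar-loop weighted kappa ----------------------

oracleKappa <- function(counts, weights = "linear") {
  k <- nrow(counts); n <- sum(counts)
  wfun <- function(i, j) {
    d <- abs(i - j) / (k - 1)
    switch(weights, linear = 1 - d, quadratic = 1 - d^2,
           unweighted = as.numeric(i == j))
  }
  po <- 0
  for (i in 1:k) for (j in 1:k) po <- po + wfun(i, j) * counts[i, j] / n
  ra <- rowSums(counts) / n; rb <- colSums(counts) / n
  pe <- 0
  for (i in 1:k) for (j in 1:k) pe <- pe + wfun(i, j) * ra[i] * rb[j]
  if (1 - pe < 1e-14) return(NA_real_)
  (po - pe) / (1 - pe)
}

# --- kappa variance oracle: vertex enumeration of the joint polytope ---

jointPolytopeVertices <- function(pa, pb, kappa) {
  k <- length(pa)
  pe <- sum(pa * pb)
  po <- kappa * (1 - pe) + pe
  A <- matrix(0, 2L * k + 1L, k * k)
  for (i in seq_len(k)) A[i, (seq_len(k) - 1L) * k + i] <- 1
  for (j in seq_len(k)) A[k + j, (j - 1L) * k + seq_len(k)] <- 1
  A[2L * k + 1L, (seq_len(k) - 1L) * k + seq_len(k)] <- 1
  b <- c(pa, pb, po)
  verts <- list()
  for (sz in c(2L * k, 2L * k + 1L)) {
    for (cols in utils::combn(k * k, sz, simplify = FALSE)) {
      As <- A[, cols, drop = FALSE]
      x <- tryCatch(qr.solve(As, b, tol = 1e-10), error = function(e) NULL)
      if (is.null(x)) {
        x <- qr.coef(qr(As), b)
        x[is.na(x)] <- 0
      }
      if (any(!is.finite(x))) next
      if (max(abs(As %*% x - b)) > 1e-9) next
      if (any(x < -1e-9)) next
      full <- numeric(k * k); full[cols] <- pmax(x, 0)
      key <- paste(round(full, 9), collapse = ",")
      verts[[key]] <- matrix(full, k, k)
    }
  }
  verts
}

oracleMaxKappaVariance <- function(pa, pb, kappa) {
  pe <- sum(pa * pb)
  po <- kappa * (1 - pe) + pe
  verts <- jointPolytopeVertices(pa, pb, kappa)
  if (!length(verts)) return(NULL)
  qOf <- function(P) {
    k <- nrow(P); s <- 0
    for (i in 1:k) for (j in 1:k) {
      s <- s + P[i, j] * if (i == j) (1 - (pa[i] + pb[i]) * (1 - kappa))^2
                         else (1 - kappa)^2 * (pb[i] + pa[j])^2
    }
    (s - (kappa - pe * (1 - kappa))^2) / (1 - pe)^2
  }
  max(vapply(verts, qOf, 1))
}

# --- misc --------------------------------------------------------------

randomTagCloud <- function(seed, n, extent = 40) {
  set.seed(seed)
  matrix(runif(3 * n, -extent, extent), ncol = 3)
}

honestPool <- function(n, seed = 1L, diagWeight = 0.7) {
  base <- matrix((1 - diagWeight) / 2, 3, 3)
  diag(base) <- diagWeight
  jitterProfiles(base, sprintf("R%02d", seq_len(n)), concentration = 60,
                 seed = seed)
}

# single 6-connected component check via flood fill
isConnectedMask <- function(maskArr) {
  dm <- dim(maskArr)
  idx <- which(maskArr != 0)
  if (!length(idx)) return(FALSE)
  lab <- array(FALSE, dm)
  queue <- idx[1]
  lab[queue] <- TRUE
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    k0 <- (v - 1) %/% (dm[1] * dm[2])
    j0 <- ((v - 1) %% (dm[1] * dm[2])) %/% dm[1]
    i0 <- (v - 1) %% dm[1]
    for (t in 1:6) {
      i <- i0 + nb[t, 1]; j <- j0 + nb[t, 2]; k <- k0 + nb[t, 3]
      if (i < 0 || i >= dm[1] || j < 0 || j >= dm[2] || k < 0 || k >= dm[3]) next
      w <- i + j * dm[1] + k * dm[1] * dm[2] + 1
      if (maskArr[w] != 0 && !lab[w]) {
        lab[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  sum(lab) == length(idx)
}
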