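# Exact Euclidean distance transforms for binary 3-D masks, with per-axis
# voxel spacing in mm. Separable lower-envelope (parabola) algorithm; the
# squared distance map is exact for anisotropic grids, which is what makes
# millimetre-calibrated morphology independent of voxel size.

# 1-D squared-distance transform of f at positions i*s (lower envelope of
# parabolas). f may contain Inf.
edt1d <- function(f, s) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)      # parabola sites
  z <- numeric(n + 1L) # boundaries
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  s2 <- s * s
  for (q in 2:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      if (!is.finite(f[p])) { # drop placeholder parabola at +Inf
        k <- k - 1L
        if (k == 0L) break
        next
      }
      sx <- ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2 * s2 * (q - p))
      if (sx > z[k]) break
      k <- k - 1L
      if (k == 0L) break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else sx
    z[k + 1L] <- Inf
  }
  if (!is.finite(f[v[1L]]) && k == 1L) return(rep(Inf, n))
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- s2 * (q - p)^2 + f[p]
  }
  d
}

# squared EDT of a 3-D logical array: distance (mm^2) from every voxel to
# the nearest TRUE voxel. voxel = length-3 spacing in mm.
squaredEDT <- function(feature, voxel) {
  dm <- dim(feature)
  f <- array(ifelse(feature, 0, Inf), dm)
  # pass along axis 1
  for (k in seq_len(dm[3]))
    for (j in seq_len(dm[2]))
      f[, j, k] <- edt1d(f[, j, k], voxel[1])
  for (k in seq_len(dm[3]))
    for (i in seq_len(dm[1]))
      f[i, , k] <- edt1d(f[i, , k], voxel[2])
  for (j in seq_len(dm[2]))
    for (i in seq_len(dm[1]))
      f[i, j, ] <- edt1d(f[i, j, ], voxel[3])
  f
}

#' Millimetre-calibrated morphology on binary volumes
#'
#' Dilation and erosion of a binary mask by a Euclidean ball of radius
#' `radiusMm` (closed-ball convention both ways): dilation keeps voxels whose
#' distance to the mask is `<= r`; erosion keeps mask voxels whose distance
#' to the background is `> r`. Radii are in world mm and converted per axis
#' from the affine's voxel sizes, so a "4 mm" operation means 4 mm whatever
#' the grid resolution. Implemented by thresholding the exact Euclidean
#' distance transform.
#'
#' @param mask a binary [BrainVolume-class].
#' @param radiusMm ball radius in mm (`>= 0`).
#' @return A binary `BrainVolume` on the same grid.
#' @seealso [buildOutlineShell()]
#' @export
dilateMask <- function(mask, radiusMm) {
  checkBinaryVolume(mask)
  stopifnot(is.finite(radiusMm), radiusMm >= 0)
  m <- mask@data != 0
  if (radiusMm == 0 || !any(m)) return(BrainVolume(array(as.numeric(m), dim(m)),
                                                   mask@affine, mask@space))
  d2 <- squaredEDT(m, voxelSize(mask))
  BrainVolume(array(as.numeric(d2 <= radiusMm^2), dim(m)), mask@affine, mask@space)
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, radiusMm) {
  checkBinaryVolume(mask)
  stopifnot(is.finite(radiusMm), radiusMm >= 0)
  m <- mask@data != 0
  if (radiusMm == 0 || !any(m)) return(BrainVolume(array(as.numeric(m), dim(m)),
                                                   mask@affine, mask@space))
  d2 <- squaredEDT(!m, voxelSize(mask))
  BrainVolume(array(as.numeric(m & d2 > radiusMm^2), dim(m)), mask@affine, mask@space)
}

checkBinaryVolume <- function(mask) {
  if (!is(mask, "BrainVolume"))
    stop("expected a BrainVolume mask", call. = FALSE)
  if (!isBinaryArray(mask@data))
    stop("mask is not binary (values other than 0/1 present)", call. = FALSE)
  invisible(TRUE)
}
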