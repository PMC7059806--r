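#' Build the brain-outline landmark shell
#'
#' The registration "confidence interval" of the QC protocol: the brain
#' outline is turned into a thick shell by subtracting an eroded copy of the
#' template brain mask from a dilated copy. With the protocol defaults of
#' 4 mm dilation and 4 mm erosion the shell is roughly 8 mm thick and
#' centred on the brain outline; a structure that stays inside the shell is
#' considered acceptably registered.
#'
#' @param brainMask binary [BrainVolume-class] of the template brain.
#' @param dilateMm dilation radius in mm (default 4).
#' @param erodeMm erosion radius in mm (default 4).
#' @return A [LandmarkMask-class] with provenance `"computed_shell"`,
#'   grid-compatible with `brainMask`.
#' @examples
#' m <- array(0, c(24, 24, 24))
#' m[8:16, 8:16, 8:16] <- 1
#' shell <- buildOutlineShell(BrainVolume(m), dilateMm = 2, erodeMm = 2)
#' sum(volumeData(shell))
#' @export
buildOutlineShell <- function(brainMask, dilateMm = 4, erodeMm = 4) {
  checkBinaryVolume(brainMask)
  if (!is.finite(dilateMm) || !is.finite(erodeMm) || dilateMm < 0 || erodeMm < 0)
    stop("dilation/erosion radii must be finite and >= 0", call. = FALSE)
  dil <- dilateMask(brainMask, dilateMm)
  ero <- erodeMask(brainMask, erodeMm)
  shell <- array(as.numeric(dil@data != 0 & ero@data == 0), dim(brainMask@data))
  new("LandmarkMask",
      BrainVolume(shell, brainMask@affine, brainMask@space),
      provenance = "computed_shell")
}

#' Merge landmark masks into one overlay
#'
#' Voxelwise union of the computed outline shell with any number of
#' user-supplied interior landmark masks (ventricles, central sulcus, ...),
#' which the protocol treats as hand-drawn inputs rather than computed
#' objects. All masks must be grid-compatible.
#'
#' @param shell a [LandmarkMask-class].
#' @param interiors list of further `LandmarkMask` objects (may be empty).
#' @return A `LandmarkMask` with provenance `"merged"` (or `shell` unchanged
#'   when `interiors` is empty).
#' @export
mergeLandmarkMasks <- function(shell, interiors = list()) {
  stopifnot(is(shell, "LandmarkMask"))
  if (length(interiors) == 0L) return(shell)
  acc <- shell@data != 0
  for (m in interiors) {
    if (!is(m, "LandmarkMask"))
      stop("interior landmarks must be LandmarkMask objects", call. = FALSE)
    if (!gridCompatible(shell, m))
      stop("landmark masks are not grid-compatible", call. = FALSE)
    acc <- acc | (m@data != 0)
  }
  new("LandmarkMask",
      BrainVolume(array(as.numeric(acc), dim(acc)), shell@affine, shell@space),
      provenance = "merged")
}

#' Validate a landmark mask against a template
#'
#' Report-only checks: grid compatibility with the template, binarity, voxel
#' count, and the fraction of mask voxels that fall inside the template's
#' brain bounding box (voxels where the template is positive). Never
#' modifies its inputs.
#'
#' @param mask a [LandmarkMask-class] (or binary `BrainVolume`).
#' @param template the template [BrainVolume-class].
#' @return A list with elements `ok`, `reasons` (character), `gridCompatible`,
#'   `binary`, `voxelCount`, `fractionInBoundingBox`.
#' @export
validateLandmarkMask <- function(mask, template) {
  stopifnot(is(mask, "BrainVolume"), is(template, "BrainVolume"))
  reasons <- character()
  gridOk <- gridCompatible(mask, template)
  if (!gridOk) reasons <- c(reasons, "grid mismatch")
  binary <- isBinaryArray(mask@data)
  if (!binary) reasons <- c(reasons, "non-binary")
  nvox <- sum(mask@data != 0)
  frac <- NA_real_
  if (gridOk && nvox > 0L) {
    pos <- which(template@data > 0, arr.ind = TRUE)
    if (nrow(pos) > 0L) {
      lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
      idx <- which(mask@data != 0, arr.ind = TRUE)
      inside <- idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
                idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
                idx[, 3] >= lo[3] & idx[, 3] <= hi[3]
      frac <- mean(inside)
    } else frac <- 0
  }
  list(ok = length(reasons) == 0L, reasons = reasons,
       gridCompatible = gridOk, binary = binary,
       voxelCount = nvox, fractionInBoundingBox = frac)
}

#' @rdname LandmarkMask-class
#' @param x a `LandmarkMask`.
#' @export
setMethod("provenance", "LandmarkMask", function(x) x@provenance)
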