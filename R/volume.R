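#' Construct a BrainVolume
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, mm). The
#'   default identity affine puts voxel (1,1,1) at the world origin with
#'   1 mm isotropic spacing.
#' @param space stereotaxic-space tag.
#' @return A [BrainVolume-class] object.
#' @examples
#' v <- BrainVolume(array(0, c(4, 4, 4)))
#' dim(v)
#' @export
BrainVolume <- function(data, affine = diag(4), space = "unknown") {
  storage.mode(affine) <- "double"
  new("BrainVolume", data = data, affine = affine, space = space)
}

#' @rdname BrainVolume-class
#' @param x a `BrainVolume`.
#' @export
setMethod("volumeData", "BrainVolume", function(x) x@data)

#' @rdname BrainVolume-class
#' @export
setMethod("affineMatrix", "BrainVolume", function(x) x@affine)

#' @rdname BrainVolume-class
#' @export
setMethod("spaceTag", "BrainVolume", function(x) x@space)

#' @export
setMethod("dim", "BrainVolume", function(x) dim(x@data))

#' Voxel sizes in mm
#'
#' Per-axis voxel spacing derived from the affine (Euclidean norm of its
#' columns), in mm.
#'
#' @param x a `BrainVolume`.
#' @return Numeric length-3 vector of voxel sizes.
#' @export
#' @rdname voxelSize
setMethod("voxelSize", "BrainVolume", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' Convert between world mm and voxel indices
#'
#' `worldToVoxel` maps world-mm points to (fractional) 1-based voxel indices
#' through the inverse affine; `voxelToWorld` is its inverse. Points are rows
#' of a 3-column matrix.
#'
#' @param x a `BrainVolume`.
#' @param xyz,ijk numeric matrix (n x 3) or length-3 vector.
#' @return n x 3 numeric matrix.
#' @rdname worldToVoxel
#' @export
setMethod("worldToVoxel", "BrainVolume", function(x, xyz) {
  xyz <- rbind3(xyz)
  h <- cbind(xyz, 1) %*% t(solve(x@affine))
  h[, 1:3, drop = FALSE] + 1  # affine is 0-based; R arrays are 1-based
})

#' @rdname worldToVoxel
#' @export
setMethod("voxelToWorld", "BrainVolume", function(x, ijk) {
  ijk <- rbind3(ijk)
  h <- cbind(ijk - 1, 1) %*% t(x@affine)
  h[, 1:3, drop = FALSE]
})

rbind3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' Grid compatibility of two volumes
#'
#' Two volumes are grid-compatible when their array dimensions are identical
#' and their affines agree within `tol` mm. Most pairwise operations
#' (overlays, mask unions, mosaic pairs) require it.
#'
#' @param x,y `BrainVolume` objects.
#' @param tol affine tolerance in mm (default 1e-6).
#' @return `TRUE` or `FALSE`.
#' @rdname gridCompatible
#' @export
setMethod("gridCompatible", signature("BrainVolume", "BrainVolume"),
  function(x, y, tol = 1e-6) {
    identical(dim(x@data), dim(y@data)) &&
      all(abs(x@affine - y@affine) < tol)
  })

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@data)
  vs <- voxelSize(object)
  cat(sprintf("%s: %d x %d x %d voxels, %.3g x %.3g x %.3g mm [%s]\n",
              class(object), d[1], d[2], d[3], vs[1], vs[2], vs[3],
              object@space))
  invisible(object)
})

setMethod("show", "LandmarkMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LandmarkMask (%s): %d x %d x %d voxels, %d set\n",
              object@provenance, d[1], d[2], d[3], sum(object@data != 0)))
  invisible(object)
})

isBinaryArray <- function(a) all(a == 0 | a == 1)

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. `readVolume` returns a
#' [BrainVolume-class]; `readLandmarkMask` additionally checks binarity and
#' tags provenance `"user_supplied"`. Masks are written as unsigned 8-bit,
#' other volumes in their native type.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param space stereotaxic-space tag to record.
#' @return `readVolume`: a `BrainVolume`; `writeVolume`: the path, invisibly.
#' @export
readVolume <- function(path, space = "unknown") {
  img <- RNifti::readNifti(path)
  a <- unclass(RNifti::xform(img))
  dm <- dim(img)
  d <- array(as.numeric(img), dm)
  if (length(dm) > 3L) d <- array(d, dm[1:3])
  BrainVolume(d, affine = matrix(as.numeric(a), 4, 4), space = space)
}

#' @rdname readVolume
#' @param vol a `BrainVolume` (or `LandmarkMask`).
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  dat <- vol@data
  dt <- if (is(vol, "LandmarkMask") || isBinaryArray(dat)) "uint8" else "float"
  img <- RNifti::asNifti(dat, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' @rdname readVolume
#' @export
readLandmarkMask <- function(path, space = "unknown") {
  v <- readVolume(path, space = space)
  if (!isBinaryArray(v@data))
    stop("mask file is not binary: ", path, call. = FALSE)
  new("LandmarkMask", v, provenance = "user_supplied")
}
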