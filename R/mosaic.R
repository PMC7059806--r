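AXES <- c(sagittal_x = 1L, coronal_y = 2L, axial_z = 3L)

normAxis <- function(axis) {
  axis <- match.arg(axis, c(names(AXES), "sagittal", "coronal", "axial"))
  switch(axis, sagittal = "sagittal_x", coronal = "coronal_y",
         axial = "axial_z", axis)
}

#' The protocol's nine-slice specification
#'
#' The standard QC view is a mosaic of nine slices at fixed template-space
#' coordinates: sagittal x in \{-50, -8, 30\}, coronal y in \{-65, -20, 54\},
#' axial z in \{-6, 13, 58\} mm. `scale` shrinks or stretches the coordinates
#' proportionally, which keeps the protocol usable on phantoms smaller than
#' a human head.
#'
#' @param scale multiplicative factor applied to all coordinates (default 1).
#' @return A data.frame with columns `axis` (one of `"axial_z"`,
#'   `"sagittal_x"`, `"coronal_y"`) and `mm`, ordered as displayed: axial
#'   row first, then sagittal, then coronal.
#' @examples
#' sliceProtocol()
#' @export
sliceProtocol <- function(scale = 1) {
  stopifnot(is.finite(scale), scale > 0)
  data.frame(
    axis = rep(c("axial_z", "sagittal_x", "coronal_y"), each = 3L),
    mm = scale * c(-6, 13, 58, -50, -8, 30, -65, -20, 54),
    stringsAsFactors = FALSE)
}

# world axis k must map to exactly one voxel axis (axis-aligned affine)
voxelAxisFor <- function(affine, worldAxis, tol = 1e-6) {
  row <- affine[worldAxis, 1:3]
  ax <- which(abs(row) > tol)
  if (length(ax) != 1L)
    stop("affine is oblique; slice extraction needs an axis-aligned grid",
         call. = FALSE)
  ax
}

#' Extract one slice plane at a world coordinate
#'
#' Returns the in-plane intensity lattice nearest (by voxel index) to the
#' requested world-mm coordinate. Sampling is nearest-voxel on purpose: QC
#' views the registered data as stored, and interpolation could smooth away
#' the very artefacts the protocol looks for.
#'
#' @param volume a [BrainVolume-class] on an axis-aligned grid.
#' @param axis `"sagittal_x"`, `"coronal_y"` or `"axial_z"` (short forms
#'   `"sagittal"` etc. accepted).
#' @param mm world coordinate of the plane in mm.
#' @return Numeric matrix over the two remaining voxel axes (ascending voxel
#'   index), with attributes `axis`, `mm` and `index` (the voxel index of
#'   the plane).
#' @export
extractSlicePlane <- function(volume, axis, mm) {
  stopifnot(is(volume, "BrainVolume"), is.finite(mm))
  axis <- normAxis(axis)
  w <- AXES[[axis]]
  vax <- voxelAxisFor(volume@affine, w)
  idx0 <- (mm - volume@affine[w, 4]) / volume@affine[w, vax]
  idx <- as.integer(round(idx0)) + 1L
  n <- dim(volume@data)[vax]
  if (idx < 1L || idx > n)
    stop(sprintf("slice coordinate out of bounds: %s = %g mm (valid voxel range 1..%d, got %d)",
                 axis, mm, n, idx), call. = FALSE)
  pl <- switch(vax,
               volume@data[idx, , , drop = TRUE],
               volume@data[, idx, , drop = TRUE],
               volume@data[, , idx, drop = TRUE])
  structure(as.matrix(pl), axis = axis, mm = mm, index = idx)
}

# orient a raw plane matrix for display: superior/anterior up, neurological
# left-on-left (assumes a RAS-oriented, axis-aligned affine)
orientPlane <- function(plane, axis) {
  o <- switch(axis,
    axial_z    = t(plane)[rev(seq_len(ncol(plane))), , drop = FALSE], # rows y desc, cols x
    sagittal_x = t(plane)[rev(seq_len(ncol(plane))), , drop = FALSE], # rows z desc, cols y
    coronal_y  = t(plane)[rev(seq_len(ncol(plane))), , drop = FALSE]) # rows z desc, cols x
  o
}

#' Build a QC mosaic image
#'
#' Renders the requested slices as a 3x3 grid of panels (the default
#' protocol: axial, sagittal and coronal rows top to bottom). Intensities
#' are window-normalized per volume at the 1st-99th percentiles and mapped
#' linearly to gray; voxels of the landmark overlay that fall on a selected
#' plane are tinted pure red with fixed alpha 0.4. Rendering is fully
#' deterministic: identical inputs give identical pixels.
#'
#' @param volume a [BrainVolume-class].
#' @param specs data.frame of slice specs as from [sliceProtocol()].
#' @param overlay optional [LandmarkMask-class], grid-compatible with
#'   `volume`.
#' @param alpha overlay opacity in [0, 1] (default 0.4).
#' @param window intensity percentile window (default `c(0.01, 0.99)`).
#' @param pad inter-panel padding in pixels (default 2).
#' @param volumeId identifier recorded in the mosaic metadata.
#' @return A [MosaicImage-class].
#' @export
buildMosaic <- function(volume, specs = sliceProtocol(), overlay = NULL,
                        alpha = 0.4, window = c(0.01, 0.99), pad = 2L,
                        volumeId = "volume") {
  stopifnot(is(volume, "BrainVolume"), nrow(specs) >= 1L,
            all(c("axis", "mm") %in% names(specs)))
  if (!is.null(overlay)) {
    stopifnot(is(overlay, "BrainVolume"))
    if (!gridCompatible(volume, overlay))
      stop("overlay is not grid-compatible with the volume", call. = FALSE)
  }
  qs <- stats::quantile(volume@data, window, names = FALSE, type = 7)
  rng <- qs[2] - qs[1]
  toGray <- function(p) {
    if (rng <= 0) return(array(0, dim(p)))
    pmin(pmax((p - qs[1]) / rng, 0), 1)
  }
  panels <- vector("list", nrow(specs))
  masks <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    ax <- normAxis(specs$axis[i])
    pl <- extractSlicePlane(volume, ax, specs$mm[i])
    panels[[i]] <- orientPlane(toGray(pl), ax)
    masks[[i]] <- if (is.null(overlay)) {
      array(FALSE, dim(panels[[i]]))
    } else {
      om <- extractSlicePlane(overlay, ax, specs$mm[i])
      orientPlane(om, ax) != 0
    }
  }
  ph <- max(vapply(panels, nrow, 1L)); pw <- max(vapply(panels, ncol, 1L))
  ncol_g <- 3L; nrow_g <- ceiling(length(panels) / ncol_g)
  H <- nrow_g * ph + (nrow_g + 1L) * pad
  W <- ncol_g * pw + (ncol_g + 1L) * pad
  px <- array(0, c(H, W, 3L))
  layout <- data.frame(panel = seq_along(panels),
                       axis = vapply(seq_len(nrow(specs)),
                                     function(i) normAxis(specs$axis[i]), ""),
                       mm = specs$mm, row = NA_integer_, col = NA_integer_,
                       y0 = NA_integer_, x0 = NA_integer_)
  for (i in seq_along(panels)) {
    r <- (i - 1L) %/% ncol_g; cl <- (i - 1L) %% ncol_g
    y0 <- pad + r * (ph + pad); x0 <- pad + cl * (pw + pad)
    p <- panels[[i]]; m <- masks[[i]]
    ys <- y0 + seq_len(nrow(p)); xs <- x0 + seq_len(ncol(p))
    g <- p
    px[ys, xs, 1] <- g + m * alpha * (1 - g)     # red channel raised
    px[ys, xs, 2] <- g - m * alpha * g           # green/blue damped
    px[ys, xs, 3] <- g - m * alpha * g
    layout$row[i] <- r + 1L; layout$col[i] <- cl + 1L
    layout$y0[i] <- y0; layout$x0[i] <- x0
  }
  new("MosaicImage", pixels = px, layout = layout, volumeId = volumeId)
}

#' Render the flippable template/individual mosaic pair
#'
#' Produces two mosaics with identical geometry (panel sizes, positions and
#' overlay) that differ only in the underlying intensities, so a viewer can
#' flip between them pixel-for-pixel — the template shows where each
#' structure should be, the individual shows where it is.
#'
#' @param individual registered individual [BrainVolume-class].
#' @param template template `BrainVolume` on the same grid.
#' @param overlay optional [LandmarkMask-class] (red tint on both mosaics).
#' @param ... further arguments passed to [buildMosaic()].
#' @return List with elements `individual` and `template`, both
#'   [MosaicImage-class].
#' @export
renderPair <- function(individual, template, overlay = NULL, ...) {
  stopifnot(is(individual, "BrainVolume"), is(template, "BrainVolume"))
  if (!gridCompatible(individual, template))
    stop("individual and template are not grid-compatible", call. = FALSE)
  list(individual = buildMosaic(individual, overlay = overlay,
                                volumeId = "individual", ...),
       template = buildMosaic(template, overlay = overlay,
                              volumeId = "template", ...))
}

#' Write a mosaic as PNG
#'
#' @param mosaic a [MosaicImage-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMosaicPNG <- function(mosaic, path) {
  stopifnot(is(mosaic, "MosaicImage"))
  png::writePNG(mosaic@pixels, path)
  invisible(path)
}

setMethod("show", "MosaicImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MosaicImage '%s': %d x %d px, %d panels\n", object@volumeId,
              d[1], d[2], nrow(object@layout)))
  invisible(object)
})
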