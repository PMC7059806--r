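#' Construct a TagSet
#'
#' @param imageId,raterId identifiers.
#' @param tags numeric n x 3 matrix (or length-3 vector, or NULL) of tag
#'   centres in world mm.
#' @param artifact image-wide quality failure flag.
#' @param radiusMm tag-sphere radius in mm; the standard protocol uses 4.
#' @return A [TagSet-class].
#' @examples
#' ts <- TagSet("img1", "R1", rbind(c(0, 0, 0), c(10, 0, 0)))
#' rateFromTags(ts)
#' @export
TagSet <- function(imageId, raterId, tags = NULL, artifact = FALSE,
                   radiusMm = 4) {
  if (is.null(tags)) tags <- matrix(numeric(), 0L, 3L)
  if (is.null(dim(tags))) tags <- matrix(tags, ncol = 3L, byrow = TRUE)
  storage.mode(tags) <- "double"
  colnames(tags) <- c("x", "y", "z")
  new("TagSet", imageId = as.character(imageId),
      raterId = as.character(raterId), tags = tags,
      artifact = isTRUE(artifact), radiusMm = radiusMm)
}

#' @rdname TagSet-class
#' @param x a `TagSet`.
#' @export
setMethod("tagCoords", "TagSet", function(x) x@tags)

#' @rdname TagSet-class
#' @export
setMethod("hasArtifact", "TagSet", function(x) x@artifact)

setMethod("show", "TagSet", function(object) {
  cat(sprintf("TagSet %s / %s: %d tag(s)%s\n", object@imageId, object@raterId,
              nrow(object@tags), if (object@artifact) ", artifact" else ""))
  invisible(object)
})

#' Pairwise distances between tags, in mm
#'
#' Euclidean world-mm distances between all tag centres; distances are
#' always computed in world coordinates, never voxels, because the
#' tag-sphere radius is an anatomical quantity.
#'
#' @param tags a [TagSet-class] or an n x 3 coordinate matrix.
#' @return Symmetric n x n matrix of distances (0 x 0 when there are no
#'   tags).
#' @export
pairwiseTagDistances <- function(tags) {
  p <- if (is(tags, "TagSet")) tags@tags else rbind3(tags)
  n <- nrow(p)
  if (n == 0L) return(matrix(numeric(), 0L, 0L))
  as.matrix(stats::dist(p))
}

#' Convert a rater's tags into the protocol's three-level rating
#'
#' The protocol's decision rule: an image with no tags is `OK`; tagged but
#' with no two tag spheres overlapping is `Maybe`; two overlapping tag
#' spheres (centres strictly closer than `overlapMm`, i.e. 8 mm for 4-mm
#' spheres) mean an extensive misregistration and the image is `Fail`. A
#' raised artifact flag (motion, ringing, excessive blur) forces `Fail`
#' regardless of tags. Exactly touching spheres (distance equal to
#' `overlapMm`) do not overlap: their interiors are disjoint, so the rating
#' stays `Maybe`.
#'
#' @param tagset a [TagSet-class].
#' @param overlapMm centre distance below which two tag spheres overlap
#'   (default 8, twice the 4-mm tag radius).
#' @return Length-1 ordered factor (`Fail < Maybe < OK`).
#' @examples
#' rateFromTags(TagSet("i", "r"))                         # OK
#' rateFromTags(TagSet("i", "r", c(0, 0, 0), artifact = TRUE)) # Fail
#' @export
rateFromTags <- function(tagset, overlapMm = 8) {
  stopifnot(is(tagset, "TagSet"))
  if (!is.numeric(overlapMm) || length(overlapMm) != 1L || overlapMm <= 0)
    stop("'overlapMm' must be a positive length in mm", call. = FALSE)
  lab <- if (tagset@artifact) {
    "Fail"
  } else if (nrow(tagset@tags) == 0L) {
    "OK"
  } else {
    d <- pairwiseTagDistances(tagset)
    if (any(d[upper.tri(d)] < overlapMm)) "Fail" else "Maybe"
  }
  asRating(lab)
}

#' Validate a TagSet against the landmark mask
#'
#' Report-only plausibility checks: tags whose centres fall outside the
#' landmark mask (raters are asked to tag within the landmarks, so outside
#' tags are suspicious but never change the rating) and exactly duplicated
#' tag points (distance-0 pairs, which force a `Fail` under the overlap
#' rule and usually indicate a double click).
#'
#' @param tagset a [TagSet-class].
#' @param landmarks optional [LandmarkMask-class] in the same world space.
#' @return List with `ok`, `warnings` (character), `outsideMask` (indices of
#'   tags outside the mask, if a mask was given) and `duplicates` (indices
#'   of tags duplicating an earlier tag).
#' @export
validateTagSet <- function(tagset, landmarks = NULL) {
  stopifnot(is(tagset, "TagSet"))
  warn <- character(); outside <- integer(); dups <- integer()
  n <- nrow(tagset@tags)
  if (n > 0L) {
    dups <- unname(which(duplicated(unname(round(tagset@tags, 9)))))
    if (length(dups))
      warn <- c(warn, sprintf("duplicate tag point(s) at row(s) %s",
                              paste(dups, collapse = ", ")))
    if (!is.null(landmarks)) {
      stopifnot(is(landmarks, "BrainVolume"))
      ijk <- round(worldToVoxel(landmarks, tagset@tags))
      dm <- dim(landmarks@data)
      for (i in seq_len(n)) {
        v <- ijk[i, ]
        inGrid <- all(v >= 1) && all(v <= dm)
        if (!inGrid || landmarks@data[v[1], v[2], v[3]] == 0)
          outside <- c(outside, i)
      }
      if (length(outside))
        warn <- c(warn, sprintf("tag(s) outside landmark mask: %s",
                                paste(apply(tagset@tags[outside, , drop = FALSE],
                                            1, function(p)
                                              sprintf("(%g, %g, %g)", p[1], p[2], p[3])),
                                      collapse = "; ")))
    }
  }
  list(ok = length(warn) == 0L, warnings = warn,
       outsideMask = outside, duplicates = dups)
}
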