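#' BrainVolume: a 3-D intensity lattice in world (mm) coordinates
#'
#' The basic spatial unit of the package: a 3-D array of scalar intensities
#' together with a 4x4 voxel-index-to-world affine (in mm) and a free-text
#' tag naming the stereotaxic space. Templates, registered individual T1
#' volumes and binary masks are all `BrainVolume` objects. Voxel indices are
#' 1-based on the R side; the affine maps 0-based indices to world mm, the
#' convention of the NIfTI format.
#'
#' @slot data 3-D numeric array of intensities.
#' @slot affine 4x4 numeric matrix, invertible, mapping 0-based voxel indices
#'   (homogeneous coordinates) to world mm.
#' @slot space character scalar identifying the stereotaxic space.
#' @export
setClass("BrainVolume",
  representation(data = "array", affine = "matrix", space = "character"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("'data' must be a 3-D array")
    if (any(dim(d) < 1L)) return("'data' must have positive extent on all axes")
    a <- object@affine
    if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)))
      return("'affine' must be a numeric 4x4 matrix")
    if (!all(is.finite(a))) return("'affine' must be finite")
    if (abs(det(a)) < 1e-12) return("'affine' must be invertible")
    if (length(object@space) != 1L) return("'space' must be a single string")
    TRUE
  })

#' LandmarkMask: a binary mask of QC landmark regions
#'
#' A binary `BrainVolume` marking the protocol's landmark "confidence
#' interval" regions in template space, with a provenance tag recording how
#' it was produced: `"computed_shell"` for the brain-outline shell,
#' `"user_supplied"` for hand-drawn interior landmarks read from file, and
#' `"merged"` for unions.
#'
#' @slot provenance one of `"computed_shell"`, `"user_supplied"`, `"merged"`.
#' @export
setClass("LandmarkMask", contains = "BrainVolume",
  representation(provenance = "character"),
  validity = function(object) {
    if (!object@provenance %in% c("computed_shell", "user_supplied", "merged"))
      return("unknown provenance")
    v <- unique(as.vector(object@data))
    if (!all(v %in% c(0, 1))) return("mask values must all be 0 or 1")
    TRUE
  })

#' TagSet: one rater's tags on one image
#'
#' The marks a rater places on misregistered structures for a single image:
#' a list of world-mm points, each representing a sphere of fixed radius
#' (4 mm in the standard protocol), plus a global artifact flag raised when
#' the whole image is unusable (motion, ringing, excessive blur).
#'
#' @slot imageId character id of the rated image.
#' @slot raterId character id of the rater.
#' @slot tags numeric matrix with 3 columns (x, y, z in world mm), one row
#'   per tag; may have zero rows.
#' @slot artifact logical; image-wide quality failure.
#' @slot radiusMm tag-sphere radius in mm (protocol default 4).
#' @export
setClass("TagSet",
  representation(imageId = "character", raterId = "character",
                 tags = "matrix", artifact = "logical", radiusMm = "numeric"),
  validity = function(object) {
    if (length(object@imageId) != 1L || length(object@raterId) != 1L)
      return("imageId and raterId must be single strings")
    tg <- object@tags
    if (!is.numeric(tg) || ncol(tg) != 3L)
      return("'tags' must be a numeric matrix with 3 columns")
    if (nrow(tg) > 0L && !all(is.finite(tg)))
      return("tag coordinates must be finite")
    if (length(object@artifact) != 1L || is.na(object@artifact))
      return("'artifact' must be TRUE or FALSE")
    if (length(object@radiusMm) != 1L || !is.finite(object@radiusMm) ||
        object@radiusMm <= 0)
      return("'radiusMm' must be a positive length")
    TRUE
  })

#' RatingTable: sparse images x raters table of ordinal ratings
#'
#' Long-format storage of at most one rating per (image, rater) pair, with
#' ordered id lists. Ratings are the protocol's three-level ordinal scale
#' (`Fail < Maybe < OK`); missing pairs are simply absent.
#'
#' @slot entries data.frame with columns `image_id`, `rater_id` (character)
#'   and `rating` (ordered factor `Fail < Maybe < OK`).
#' @slot imageIds ordered character vector of all image ids.
#' @slot raterIds ordered character vector of all rater ids.
#' @export
setClass("RatingTable",
  representation(entries = "data.frame", imageIds = "character",
                 raterIds = "character"),
  validity = function(object) {
    e <- object@entries
    need <- c("image_id", "rater_id", "rating")
    if (!all(need %in% names(e)))
      return("entries must have columns image_id, rater_id, rating")
    if (!is.ordered(e$rating) || !identical(levels(e$rating), ratingLevels()))
      return("rating must be an ordered factor Fail < Maybe < OK")
    if (anyDuplicated(e[c("image_id", "rater_id")]))
      return("duplicate (image_id, rater_id) entries")
    if (!all(e$image_id %in% object@imageIds))
      return("entries reference image ids missing from imageIds")
    if (!all(e$rater_id %in% object@raterIds))
      return("entries reference rater ids missing from raterIds")
    TRUE
  })

#' AgreementReport: pairwise agreement statistics for raters or panels
#'
#' Holds the symmetric matrix of pairwise weighted kappas, one Dice matrix
#' per rating category, the Landis-Koch interpretation band of each kappa
#' cell, and the number of commonly rated images behind each pair.
#'
#' @slot units character vector of unit (rater or panel) names.
#' @slot kappa units x units numeric matrix of weighted kappas.
#' @slot dice named list of three units x units matrices (OK, Maybe, Fail).
#' @slot bands units x units character matrix of interpretation bands.
#' @slot nCommon units x units integer matrix of shared-image counts.
#' @slot weights weighting scheme used for the kappas.
#' @export
setClass("AgreementReport",
  representation(units = "character", kappa = "matrix", dice = "list",
                 bands = "matrix", nCommon = "matrix", weights = "character"),
  validity = function(object) {
    n <- length(object@units)
    if (!identical(dim(object@kappa), c(n, n))) return("kappa has wrong size")
    if (!isTRUE(all.equal(object@kappa, t(object@kappa), tolerance = 1e-8,
                          check.attributes = FALSE)))
      return("kappa matrix must be symmetric")
    if (!identical(sort(names(object@dice)), sort(ratingLevels())))
      return("dice must hold one matrix per rating category")
    TRUE
  })

#' KappaPowerScenario: inputs of the kappa sample-size analysis
#'
#' Describes a planned two-rater agreement study on the three-category scale:
#' the marginal category probabilities of each rater, the kappa under the
#' null hypothesis (`k0`), the anticipated true kappa (`k1 > k0`), the type-I
#' error and target power, and the sidedness of the test.
#'
#' @slot marginalsA,marginalsB probability vectors over the categories.
#' @slot k0,k1 null and alternative kappa, `-1 < k0 < k1 <= 1`.
#' @slot alpha type-I error in (0, 1).
#' @slot power target power in (0, 1).
#' @slot sided `"one_sided"` or `"two_sided"`.
#' @export
setClass("KappaPowerScenario",
  representation(marginalsA = "numeric", marginalsB = "numeric",
                 k0 = "numeric", k1 = "numeric", alpha = "numeric",
                 power = "numeric", sided = "character"),
  validity = function(object) {
    a <- object@marginalsA; b <- object@marginalsB
    if (length(a) < 2L || length(a) != length(b))
      return("marginals must be two vectors of equal length >= 2")
    if (any(a < 0) || any(b < 0)) return("marginals must be non-negative")
    if (abs(sum(a) - 1) > 1e-9 || abs(sum(b) - 1) > 1e-9)
      return("each marginal vector must sum to 1")
    if (object@k0 <= -1 || object@k0 >= object@k1 || object@k1 > 1)
      return("need -1 < k0 < k1 <= 1")
    if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
    if (object@power <= 0 || object@power >= 1) return("power must be in (0,1)")
    if (!object@sided %in% c("one_sided", "two_sided"))
      return("sided must be 'one_sided' or 'two_sided'")
    TRUE
  })

#' RaterProfile: confusion-matrix model of one simulated rater
#'
#' A statistical stand-in for a human rater: given an image's true class,
#' the rater reports a class drawn from the corresponding row of a 3x3
#' row-stochastic confusion matrix (rows and columns ordered Fail, Maybe,
#' OK).
#'
#' @slot raterId character id.
#' @slot confusion 3x3 row-stochastic matrix; rows = true class,
#'   columns = reported class, both ordered `Fail, Maybe, OK`.
#' @export
setClass("RaterProfile",
  representation(raterId = "character", confusion = "matrix"),
  validity = function(object) {
    cm <- object@confusion
    k <- length(ratingLevels())
    if (!is.numeric(cm) || !identical(dim(cm), c(k, k)))
      return("confusion must be a numeric 3x3 matrix")
    if (any(cm < 0)) return("confusion entries must be non-negative")
    if (any(abs(rowSums(cm) - 1) > 1e-9)) return("confusion rows must sum to 1")
    TRUE
  })

#' MosaicImage: a rendered 3x3 QC mosaic
#'
#' Deterministic RGB rendering of nine brain slices (3 axial, 3 sagittal,
#' 3 coronal) from one registered volume, optionally tinted red where a
#' landmark overlay intersects the slice planes.
#'
#' @slot pixels numeric array height x width x 3 with values in [0, 1].
#' @slot layout data.frame describing each panel (row, col, axis, mm, and
#'   pixel offsets).
#' @slot volumeId character id of the source volume.
#' @export
setClass("MosaicImage",
  representation(pixels = "array", layout = "data.frame", volumeId = "character"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("pixels must be a height x width x 3 array")
    if (any(p < 0 | p > 1)) return("pixel values must lie in [0, 1]")
    TRUE
  })
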