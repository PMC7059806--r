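#' @rdname gridCompatible
#' @export
setGeneric("gridCompatible", function(x, y, tol = 1e-6) standardGeneric("gridCompatible"))

#' @rdname voxelSize
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname worldToVoxel
#' @export
setGeneric("worldToVoxel", function(x, xyz) standardGeneric("worldToVoxel"))

#' @rdname worldToVoxel
#' @export
setGeneric("voxelToWorld", function(x, ijk) standardGeneric("voxelToWorld"))

#' @rdname BrainVolume-class
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname BrainVolume-class
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname BrainVolume-class
#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))

#' @rdname LandmarkMask-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TagSet-class
#' @export
setGeneric("tagCoords", function(x) standardGeneric("tagCoords"))

#' @rdname TagSet-class
#' @export
setGeneric("hasArtifact", function(x) standardGeneric("hasArtifact"))

#' @rdname RatingTable-class
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname RatingTable-class
#' @export
setGeneric("raterIds", function(x) standardGeneric("raterIds"))

#' @rdname RatingTable-class
#' @export
setGeneric("ratingEntries", function(x) standardGeneric("ratingEntries"))
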