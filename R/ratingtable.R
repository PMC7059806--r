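#' Construct a RatingTable
#'
#' @param imageId,raterId character vectors (recycled to common length).
#' @param rating ratings coercible via [asRating()].
#' @param imageIds,raterIds optional full ordered id lists; defaults to the
#'   ids observed, in order of first appearance.
#' @return A [RatingTable-class].
#' @examples
#' RatingTable(c("i1", "i1", "i2"), c("A", "B", "A"), c("OK", "Maybe", "Fail"))
#' @export
RatingTable <- function(imageId = character(), raterId = character(),
                        rating = character(),
                        imageIds = NULL, raterIds = NULL) {
  e <- data.frame(image_id = as.character(imageId),
                  rater_id = as.character(raterId),
                  rating = asRating(rating),
                  stringsAsFactors = FALSE)
  if (is.null(imageIds)) imageIds <- unique(e$image_id)
  if (is.null(raterIds)) raterIds <- unique(e$rater_id)
  new("RatingTable", entries = e, imageIds = as.character(imageIds),
      raterIds = as.character(raterIds))
}

#' @rdname RatingTable-class
#' @param x a `RatingTable`.
#' @export
setMethod("imageIds", "RatingTable", function(x) x@imageIds)

#' @rdname RatingTable-class
#' @export
setMethod("raterIds", "RatingTable", function(x) x@raterIds)

#' @rdname RatingTable-class
#' @export
setMethod("ratingEntries", "RatingTable", function(x) x@entries)

setMethod("show", "RatingTable", function(object) {
  cat(sprintf("RatingTable: %d rating(s), %d image(s), %d rater(s)\n",
              nrow(object@entries), length(object@imageIds),
              length(object@raterIds)))
  tb <- table(object@entries$rating)
  cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "), "\n")
  invisible(object)
})

#' One rater's ratings as a named vector over images
#'
#' @param table a [RatingTable-class].
#' @param rater a rater id present in the table.
#' @return Named ordered factor, names = image ids rated by this rater.
#' @export
raterVector <- function(table, rater) {
  stopifnot(is(table, "RatingTable"))
  if (!rater %in% table@raterIds)
    stop("unknown rater id: ", rater, call. = FALSE)
  e <- table@entries[table@entries$rater_id == rater, ]
  stats::setNames(e$rating, e$image_id)
}

#' Read / write rating tables as CSV
#'
#' The interchange format is a plain CSV with header
#' `image_id,rater_id,rating`, rating in `OK` / `Maybe` / `Fail`
#' (case-insensitive on read, canonical case on write). Round-trips are
#' lossless; malformed ratings and duplicate (image, rater) pairs are
#' rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return `readRatingTable`: a [RatingTable-class]; `writeRatingTable`:
#'   the path, invisibly.
#' @export
readRatingTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("image_id", "rater_id", "rating")
  if (!all(need %in% names(df)))
    stop("rating CSV must have columns image_id, rater_id, rating: ", path,
         call. = FALSE)
  lv <- tolower(c(ratingLevels(), "failed"))
  bad <- which(!tolower(df$rating) %in% lv)
  if (length(bad))
    stop(sprintf("unparseable rating %-1s at line %d of %s",
                 dQuote(df$rating[bad[1]]), bad[1] + 1L, path), call. = FALSE)
  dup <- which(duplicated(df[c("image_id", "rater_id")]))
  if (length(dup))
    stop(sprintf("duplicate (image_id, rater_id) at line %d of %s",
                 dup[1] + 1L, path), call. = FALSE)
  RatingTable(df$image_id, df$rater_id, df$rating)
}

#' @rdname readRatingTable
#' @param table a [RatingTable-class].
#' @export
writeRatingTable <- function(table, path) {
  stopifnot(is(table, "RatingTable"))
  e <- table@entries
  utils::write.csv(data.frame(image_id = e$image_id, rater_id = e$rater_id,
                              rating = as.character(e$rating)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write tag sets as JSON
#'
#' One record per (image, rater): `{"image_id": ..., "rater_id": ...,
#' "tags": [[x, y, z], ...], "artifact": false}`. Coordinates are preserved
#' to full double precision; a missing or non-numeric field is a schema
#' error.
#'
#' @param path JSON file path.
#' @return `readTagSets`: list of [TagSet-class]; `writeTagSets`: the path,
#'   invisibly.
#' @export
readTagSets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(js), function(i) {
    r <- js[[i]]
    for (f in c("image_id", "rater_id", "tags", "artifact"))
      if (is.null(r[[f]]))
        stop(sprintf("tag record %d lacks field '%s' in %s", i, f, path),
             call. = FALSE)
    tg <- r$tags
    if (length(tg)) {
      coords <- vapply(tg, function(p) {
        if (length(p) != 3L || !all(vapply(p, is.numeric, TRUE)))
          stop(sprintf("tag record %d has a malformed coordinate in %s", i, path),
               call. = FALSE)
        as.numeric(p)
      }, numeric(3))
      tg <- t(coords)
    } else tg <- NULL
    radius <- if (!is.null(r$radius_mm)) as.numeric(r$radius_mm) else 4
    TagSet(r$image_id, r$rater_id, tg, isTRUE(r$artifact), radiusMm = radius)
  })
}

#' @rdname readTagSets
#' @param tagsets list of [TagSet-class] objects.
#' @export
writeTagSets <- function(tagsets, path) {
  if (is(tagsets, "TagSet")) tagsets <- list(tagsets)
  recs <- lapply(tagsets, function(ts) {
    stopifnot(is(ts, "TagSet"))
    list(image_id = ts@imageId, rater_id = ts@raterId,
         tags = unname(apply(ts@tags, 1, as.numeric, simplify = FALSE)),
         artifact = ts@artifact, radius_mm = ts@radiusMm)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
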