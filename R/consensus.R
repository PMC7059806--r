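#' Consensus of a vote count by plurality with worst-category tie-break
#'
#' The panel rule of the protocol: the category with the most votes wins;
#' when two or three categories tie at the maximum, the worst of the tied
#' categories is selected (`Fail < Maybe < OK`), reflecting a
#' better-safe-than-sorry stance on data quality.
#'
#' @param nOk,nMaybe,nFail non-negative integer vote counts. Alternatively
#'   `nOk` may be a length-3 vector named with rating levels.
#' @return Length-1 ordered factor (`Fail < Maybe < OK`).
#' @examples
#' consensusVote(nOk = 4, nMaybe = 4, nFail = 2)  # Maybe (tie OK/Maybe)
#' consensusVote(nOk = 3, nMaybe = 3, nFail = 3)  # Fail  (three-way tie)
#' @export
consensusVote <- function(nOk, nMaybe = NULL, nFail = NULL) {
  if (is.null(nMaybe) && is.null(nFail) && length(nOk) == 3L) {
    v <- nOk
    if (is.null(names(v))) names(v) <- c("OK", "Maybe", "Fail")
    nMaybe <- v[["Maybe"]]; nFail <- v[["Fail"]]; nOk <- v[["OK"]]
  }
  counts <- c(Fail = nFail, Maybe = nMaybe, OK = nOk)  # worst-first order
  if (any(counts < 0) || any(counts != round(counts)))
    stop("vote counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("cannot form a consensus from an empty panel (zero votes)",
         call. = FALSE)
  asRating(names(counts)[which.max(counts)])  # first max = worst tied category
}

#' Panel consensus over a rating table
#'
#' Collapses the votes of a rater panel into one consensus rating per image
#' using [consensusVote()]. Only observed votes count (no imputation);
#' images the panel never rated are omitted with a warning.
#'
#' @param table a [RatingTable-class].
#' @param panel character vector of rater ids (must all be in the table).
#' @return Named ordered factor of consensus ratings, names = image ids.
#' @export
panelConsensus <- function(table, panel) {
  stopifnot(is(table, "RatingTable"))
  if (length(panel) == 0L) stop("empty panel", call. = FALSE)
  if (!all(panel %in% table@raterIds))
    stop("panel contains unknown rater id(s): ",
         paste(setdiff(panel, table@raterIds), collapse = ", "), call. = FALSE)
  e <- table@entries[table@entries$rater_id %in% panel, ]
  covered <- unique(e$image_id)
  missed <- setdiff(table@imageIds, covered)
  if (length(missed))
    warning(sprintf("%d image(s) without any panel rating omitted: %s",
                    length(missed),
                    paste(utils::head(missed, 5), collapse = ", ")),
            call. = FALSE)
  imgs <- table@imageIds[table@imageIds %in% covered]
  out <- vapply(imgs, function(im) {
    r <- e$rating[e$image_id == im]
    as.character(consensusVote(nOk = sum(r == "OK"), nMaybe = sum(r == "Maybe"),
                               nFail = sum(r == "Fail")))
  }, character(1))
  asRating(stats::setNames(out, imgs))
}

#' Split raters into disjoint panels by a seeded shuffle
#'
#' The protocol's panels are arbitrary (not optimized) splits of the rater
#' pool; this helper makes them reproducible. Raters are shuffled under the
#' seed and dealt into consecutive blocks of the requested sizes.
#'
#' @param raterIds character vector of rater ids.
#' @param sizes integer vector of panel sizes; `sum(sizes)` must not exceed
#'   the pool.
#' @param seed integer seed for the shuffle.
#' @return List of character vectors (disjoint panels).
#' @examples
#' partitionRaters(paste0("R", 1:9), c(3, 3, 3), seed = 1)
#' @export
partitionRaters <- function(raterIds, sizes, seed) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("panel sizes must be positive", call. = FALSE)
  if (sum(sizes) > length(raterIds))
    stop(sprintf("requested %d raters but only %d available", sum(sizes),
                 length(raterIds)), call. = FALSE)
  shuffled <- withSeed(seed, sample(raterIds))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(i) shuffled[starts[i]:ends[i]])
}
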