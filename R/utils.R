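#' @keywords internal
#' @import methods
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded helpers do not disturb the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Ordered rating levels of the QC protocol
#'
#' The protocol rates each registered image on a three-level ordinal scale,
#' ordered from worst to best: `Fail < Maybe < OK`. Ordinal codes used
#' throughout the package are Fail = 0, Maybe = 1, OK = 2.
#'
#' @return Character vector `c("Fail", "Maybe", "OK")` (worst to best).
#' @examples
#' ratingLevels()
#' @export
ratingLevels <- function() c("Fail", "Maybe", "OK")

#' Turn free-text ratings into the protocol's ordered factor
#'
#' Parsing is case-insensitive; "Failed" is accepted as an alias of "Fail"
#' (the protocol's original wording).
#'
#' @param x character vector (or factor) of rating labels.
#' @return Ordered factor with levels `Fail < Maybe < OK`.
#' @examples
#' asRating(c("ok", "MAYBE", "Failed"))
#' @export
asRating <- function(x) {
  nms <- names(x)
  x <- tolower(as.character(x))
  x[x == "failed"] <- "fail"
  lv <- tolower(ratingLevels())
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad))
    stop("unknown rating label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  out <- factor(ratingLevels()[match(x, lv)], levels = ratingLevels(),
                ordered = TRUE)
  names(out) <- nms
  out
}

# integer ordinal codes Fail=0, Maybe=1, OK=2
ratingCode <- function(x) {
  if (!is.factor(x)) x <- asRating(x)
  as.integer(x) - 1L
}
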