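#' The standard QC protocol configuration
#'
#' All protocol parameters with their standard values: the nine slice
#' coordinates, the 4 mm / 4 mm outline-shell morphology, the 4 mm tag
#' radius with the 8 mm overlap rule, and linear kappa weights. Functions
#' across the package default to these values; `defaultProtocol()` collects
#' them in one place so a pipeline (or the command-line interface) can be
#' configured, serialized and audited as a unit.
#'
#' @param overrides named list of values replacing individual defaults.
#' @return Named list with elements `slices` (data.frame from
#'   [sliceProtocol()]), `dilateMm`, `erodeMm`, `tagRadiusMm`, `overlapMm`,
#'   `weights`, `overlayAlpha`, `window`.
#' @examples
#' defaultProtocol()$overlapMm
#' @export
defaultProtocol <- function(overrides = list()) {
  cfg <- list(
    slices = sliceProtocol(),
    dilateMm = 4,
    erodeMm = 4,
    tagRadiusMm = 4,
    overlapMm = 8,
    weights = "linear",
    overlayAlpha = 0.4,
    window = c(0.01, 0.99))
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown protocol field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  cfg
}
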