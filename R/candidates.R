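#' Enumerate candidate mature-miRNA windows
#'
#' Slides a fixed-length window 1 nt at a time across the hairpin, producing
#' every possible mature start: `L - window_len + 1` candidates.
#'
#' @param h A [hairpin()] object.
#' @param window_len Window length in nt (default 22, the typical mature
#'   miRNA length; sensible range 18-28).
#' @return Data frame with columns `hairpin_id`, `start`, `window_len`.
#' @export
generate_windows <- function(h, window_len = 22L) {
  stopifnot(inherits(h, "hairpin"))
  L <- nchar(h$sequence)
  window_len <- as.integer(window_len)
  if (window_len > L)
    stop("window_len ", window_len, " exceeds hairpin length ", L,
         " for '", h$id, "'")
  starts <- seq_len(L - window_len + 1L)
  data.frame(hairpin_id = h$id, start = starts, window_len = window_len,
             stringsAsFactors = FALSE)
}

#' Label candidate windows against the annotated mature start
#'
#' The single window whose start coincides with the annotated mature start
#' is the positive example (+1); every other window is a negative (-1). If
#' the annotated start is outside the enumerable range the hairpin
#' contributes negatives only, with a warning.
#'
#' @param windows Data frame from [generate_windows()].
#' @param mature_start Annotated 1-based mature start.
#' @return `windows` with an added integer `label` column (+1/-1).
#' @export
label_windows <- function(windows, mature_start) {
  stopifnot(is.data.frame(windows), nrow(windows) > 0L)
  mature_start <- as.integer(mature_start)
  lab <- ifelse(windows$start == mature_start, 1L, -1L)
  if (!any(lab == 1L))
    warning("mature start ", mature_start,
            " is not an enumerable window start for '",
            windows$hairpin_id[1], "'; hairpin contributes negatives only")
  windows$label <- lab
  windows
}

#' Position deviation between predicted and true start
#'
#' Absolute distance in nucleotides, symmetric in direction: a prediction
#' 3 nt upstream or 3 nt downstream of the truth both score 3.
#'
#' @param pred_start,true_start 1-based positions (vectorized).
#' @return Non-negative integer deviations.
#' @export
position_deviation <- function(pred_start, true_start) {
  stopifnot(all(pred_start >= 1L), all(true_start >= 1L))
  abs(as.integer(pred_start) - as.integer(true_start))
}
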