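## Relative ATP binding from gel-band intensities.

#' Normalize ATP-analog band intensity by expressed receptor
#'
#' Per-replicate ratio of the fluorescent ATP-analog band to the labeled
#' receptor band (the amount of receptor produced), reported as the mean
#' ratio with its standard error over biological replicates. The ratio is
#' invariant to common exposure scaling of both channels.
#'
#' @param atto647N ATP-analog band intensities, one per replicate, `> 0`.
#' @param ss488 receptor band intensities, paired with `atto647N`, `> 0`.
#' @param condition optional condition label.
#' @return List (`BandQuantification`): `condition`, `ratios`, `ratio`
#'   (mean), `sem` (`NA` for a single replicate), `n`.
#' @export
normalizeAtpBinding <- function(atto647N, ss488, condition = NA_character_) {
  if (length(atto647N) != length(ss488))
    stop("unpaired replicates: ", length(atto647N), " vs ", length(ss488))
  stopifnot2(length(atto647N) >= 1, "need at least one replicate")
  if (any(atto647N <= 0) || any(ss488 <= 0))
    stop("band intensities must be > 0")
  ratios <- atto647N / ss488
  n <- length(ratios)
  list(condition = condition, ratios = ratios, ratio = mean(ratios),
       sem = if (n > 1) stats::sd(ratios) / sqrt(n) else NA_real_, n = n)
}
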