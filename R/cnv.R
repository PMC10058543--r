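#' Contingent negative variation at Cz
#'
#' The CNV is analysed on cue-locked epochs at the vertex electrode Cz with
#' its own baseline (900-1000 ms post-cue, i.e. before the ramp build-up
#' used here), extracting the 1000-2900 ms segment that brackets the go
#' stimulus at 2000 ms. Two summaries are taken: the mean value over a late
#' pre-go window (default 1500-2000 ms) — the quantity correlated with
#' reaction time — and the ordinary least-squares slope over a fit window
#' (default 1200-2000 ms), the preparation index compared between
#' conditions and performance groups.
#'
#' @name cnv
NULL

#' Extract the CNV waveform at Cz
#'
#' Trials matching the selector are averaged, the 900-1000 ms mean is
#' subtracted as baseline, and the 1000-2900 ms segment is returned.
#'
#' @param epochs cue-locked `epoch_set` covering 0.9-2.9 s post-cue.
#' @param selector condition selector (default `"all"`).
#' @param channel electrode to analyse (default `"Cz"`).
#' @param baseline_s baseline window, seconds post-cue.
#' @param range_s extracted range, seconds post-cue.
#' @return list of class `cnv_measure`: `waveform` (uV), `times` (s),
#'   `condition`, `n_trials`, `channel`.
#' @export
extract_cnv <- function(epochs, selector = "all", channel = "Cz",
                        baseline_s = c(0.9, 1.0), range_s = c(1.0, 2.9)) {
  if (!channel %in% epochs$montage$name)
    stop("channel ", channel, " not present in montage")
  if (min(epochs$times) > baseline_s[1] ||
      max(epochs$times) < range_s[2] - 1 / epochs$sfreq)
    stop("epochs do not cover the CNV analysis range [", baseline_s[1], ", ",
         range_s[2], "] s")
  erp <- average_erp(epochs, selector)
  v <- erp$data[match(channel, epochs$montage$name), ]
  bsel <- epochs$times >= baseline_s[1] & epochs$times < baseline_s[2]
  v <- v - mean(v[bsel])
  rsel <- epochs$times >= range_s[1] & epochs$times < range_s[2]
  structure(
    list(waveform = v[rsel], times = epochs$times[rsel],
         condition = erp$condition, n_trials = erp$n_trials,
         channel = channel, baseline_s = baseline_s, range_s = range_s),
    class = "cnv_measure"
  )
}

#' @export
print.cnv_measure <- function(x, ...) {
  cat(sprintf("<cnv_measure> %s at %s, %d trials, %.1f-%.1f s\n",
              x$condition, x$channel, x$n_trials, min(x$times), max(x$times)))
  invisible(x)
}

#' Mean CNV value
#'
#' Arithmetic mean of the extracted waveform over a window (default the
#' late pre-go 1500-2000 ms).
#'
#' @param measure a `cnv_measure`.
#' @param window_ms window in ms post-cue, inside the extracted range.
#' @return mean value, uV.
#' @export
cnv_mean <- function(measure, window_ms = c(1500, 2000)) {
  w <- window_ms / 1000
  sel <- measure$times >= w[1] & measure$times < w[2]
  if (!any(sel))
    stop("mean window [", window_ms[1], ", ", window_ms[2],
         "] ms contains no samples of the extracted CNV range")
  mean(measure$waveform[sel])
}

#' CNV slope
#'
#' Ordinary least-squares slope of voltage against time over the fit window
#' (default 1200-2000 ms); invariant to constant offsets.
#'
#' @param measure a `cnv_measure`.
#' @param fit_window_ms fit window in ms post-cue.
#' @return slope, uV/s.
#' @export
cnv_slope <- function(measure, fit_window_ms = c(1200, 2000)) {
  w <- fit_window_ms / 1000
  sel <- measure$times >= w[1] & measure$times < w[2]
  if (sum(sel) < 2L)
    stop("slope fit window [", fit_window_ms[1], ", ", fit_window_ms[2],
         "] ms contains fewer than two samples")
  tt <- measure$times[sel]
  vv <- measure$waveform[sel]
  unname(stats::coef(stats::lm(vv ~ tt))[2])
}
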