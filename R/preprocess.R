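#' Preprocessing
#'
#' Resampling (spectral method with ideal anti-aliasing), zero-phase FIR
#' band-pass filtering, epoching, peak-to-peak artifact rejection and
#' baseline correction. The stage order used by the pipeline is resample ->
#' filter -> epoch -> reject -> baseline.
#'
#' @name preprocess
NULL

#' FFT-based resampling of a single signal
#'
#' Fourier-domain truncation/zero-padding (the approach of MATLAB's
#' `interpft` and scipy's `resample`): downsampling discards all content
#' above the new Nyquist frequency, i.e. applies an ideal anti-alias filter.
#'
#' @param x numeric vector.
#' @param n_out output length.
#' @return numeric vector of length `n_out` spanning the same duration.
#' @export
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  N <- min(n_in, n_out)
  nyq <- N %/% 2L
  Y <- complex(n_out)
  Y[1:(nyq + 1L)] <- X[1:(nyq + 1L)]
  nneg <- N - nyq - 1L
  if (nneg > 0L)
    Y[n_out - seq_len(nneg) + 1L] <- X[n_in - seq_len(nneg) + 1L]
  if (N %% 2L == 0L)  # shared Nyquist bin: keep it real
    Y[nyq + 1L] <- complex(real = Re(Y[nyq + 1L]))
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Resample a recording
#'
#' @param recording a `continuous_recording`.
#' @param target_hz new sampling rate, Hz.
#' @return a `continuous_recording` at `target_hz`; duration is preserved to
#'   within one sample and event onsets expressed in seconds remain valid.
#' @export
resample_recording <- function(recording, target_hz) {
  if (!is.numeric(target_hz) || target_hz <= 0)
    stop("target_hz must be positive")
  if (abs(target_hz - recording$sfreq) < 1e-12) return(recording)
  n_in <- ncol(recording$data)
  n_out <- round(n_in * target_hz / recording$sfreq)
  out <- matrix(0, nrow(recording$data), n_out)
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- fft_resample(recording$data[ch, ], n_out)
  continuous_recording(out, sfreq = target_hz, montage = recording$montage,
                       start = recording$start)
}

#' Design a linear-phase band-pass FIR filter
#'
#' Hamming-window design via [signal::fir1()]; the order is set by the
#' narrower transition band (3.3 / normalized width, rounded up to even).
#'
#' @param sfreq sampling rate, Hz.
#' @param low_hz,high_hz pass-band corner frequencies.
#' @param trans_low_hz,trans_high_hz transition band widths at each edge.
#' @return numeric coefficient vector (odd length).
#' @keywords internal
design_bandpass <- function(sfreq, low_hz, high_hz,
                            trans_low_hz = 0.2, trans_high_hz = 7.5) {
  nyq <- sfreq / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (",
         low_hz, ", ", high_hz, " at sfreq ", sfreq, ")")
  tb <- min(trans_low_hz, trans_high_hz)
  ord <- ceiling(3.3 * sfreq / tb)
  if (ord %% 2L == 1L) ord <- ord + 1L
  signal::fir1(ord, c(low_hz, high_hz) / nyq, type = "pass")
}

.filtfilt_fir <- function(b, x) {
  # zero-phase forward-backward FIR via FFT convolution; linear-phase group
  # delay (L-1)/2 is removed on each pass and edges are zero padded
  L <- length(b)
  d <- (L - 1L) %/% 2L
  xp <- c(rep(0, L), x, rep(0, L))
  one_pass <- function(v) {
    y <- signal::fftfilt(b, c(v, rep(0, L)))
    y[d + seq_along(v)]
  }
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[L + seq_along(x)]
}

#' Zero-phase FIR band-pass filter
#'
#' A linear-phase FIR (Hamming design) applied forward and backward, so the
#' net filter has exactly zero phase and the pass-band gain stays ~1 (the
#' magnitude response is squared).
#'
#' @param recording a `continuous_recording`.
#' @param low_hz,high_hz pass-band corners in Hz (defaults 0.2 and 30).
#' @param trans_low_hz,trans_high_hz transition widths in Hz.
#' @return filtered `continuous_recording`.
#' @export
bandpass_fir <- function(recording, low_hz = 0.2, high_hz = 30,
                         trans_low_hz = 0.2, trans_high_hz = 7.5) {
  b <- design_bandpass(recording$sfreq, low_hz, high_hz,
                       trans_low_hz, trans_high_hz)
  if (length(b) > ncol(recording$data))
    stop("FIR filter length (", length(b), ") exceeds signal length (",
         ncol(recording$data), "); provide a longer recording or wider ",
         "transition bands")
  out <- recording$data
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- .filtfilt_fir(b, out[ch, ])
  continuous_recording(out, sfreq = recording$sfreq,
                       montage = recording$montage, start = recording$start)
}

#' Extract epochs around events
#'
#' Windows are half-open `[tmin, tmax)` with `round((tmax - tmin) * sfreq)`
#' samples; time 0 is the locking event onset. Epochs whose window falls
#' outside the recording are dropped with a warning. For go-locked epochs
#' the condition label of the preceding cue is attached.
#'
#' @param recording a `continuous_recording`.
#' @param events an `eeg_events` table.
#' @param lock `"cue"` (any S1..S5 event) or `"go"`.
#' @param tmin_s,tmax_s window limits in seconds relative to the event.
#' @return an `epoch_set`.
#' @export
extract_epochs <- function(recording, events, lock = c("cue", "go"),
                           tmin_s = -1.5, tmax_s = 3.5) {
  lock <- match.arg(lock)
  if (tmin_s >= tmax_s) stop("tmin_s must be smaller than tmax_s")
  sf <- recording$sfreq
  nsamp <- round((tmax_s - tmin_s) * sf)
  times <- tmin_s + (seq_len(nsamp) - 1L) / sf

  cue_rows <- which(events$trial_type %in% CUE_LABELS)
  go_rows <- which(events$trial_type == "go")
  if (lock == "cue") {
    onsets <- events$onset[cue_rows]
    cond <- events$trial_type[cue_rows]
    # RT of the first go event following each cue
    rt <- vapply(events$onset[cue_rows], function(o) {
      nxt <- go_rows[events$onset[go_rows] > o]
      if (length(nxt)) events$response_time[nxt[1]] else NA_real_
    }, numeric(1))
  } else {
    onsets <- events$onset[go_rows]
    rt <- events$response_time[go_rows]
    cond <- vapply(events$onset[go_rows], function(o) {
      prv <- cue_rows[events$onset[cue_rows] < o]
      if (length(prv)) events$trial_type[prv[length(prv)]] else NA_character_
    }, character(1))
  }
  i0 <- round((onsets - recording$start + tmin_s) * sf)
  ok <- i0 >= 0L & (i0 + nsamp) <= ncol(recording$data)
  if (!any(ok)) stop("no epochs fall fully inside the recording")
  if (any(!ok))
    warning(sum(!ok), " epoch(s) extended beyond the recording and were dropped")
  keep <- which(ok)
  arr <- array(0, c(length(keep), nrow(recording$data), nsamp))
  for (k in seq_along(keep))
    arr[k, , ] <- recording$data[, i0[keep[k]] + seq_len(nsamp)]
  epoch_set(arr, times, cond[keep], rt[keep], sf, recording$montage,
            lock = lock)
}

#' Peak-to-peak artifact rejection
#'
#' An epoch is removed when any channel's peak-to-peak amplitude exceeds the
#' threshold. If any condition retains fewer than `min_per_condition` epochs
#' a warning (not an error) is raised, mirroring the design guard that at
#' least 60 epochs per stimulus type should survive cleaning.
#'
#' @param epochs an `epoch_set`.
#' @param p2p_threshold_uv rejection threshold, uV (default 100).
#' @param min_per_condition minimum surviving epochs per condition.
#' @return list with `epochs` (retained trials) and `report` (counts per
#'   condition, threshold, rejected trial indices).
#' @export
reject_artifacts <- function(epochs, p2p_threshold_uv = 100,
                             min_per_condition = 60) {
  if (!is.numeric(p2p_threshold_uv) || p2p_threshold_uv <= 0)
    stop("p2p_threshold_uv must be positive")
  d <- dim(epochs$data)
  p2p <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  bad <- apply(p2p > p2p_threshold_uv, 1, any)
  kept <- select_trials(epochs, !bad)
  before <- table(factor(epochs$condition, levels = CUE_LABELS))
  after <- table(factor(kept$condition, levels = CUE_LABELS))
  low <- names(after)[after < min_per_condition & before > 0]
  if (length(low))
    warning("condition(s) ", paste(low, collapse = ", "), " retain fewer ",
            "than ", min_per_condition, " epochs after rejection")
  report <- list(threshold_uv = p2p_threshold_uv,
                 n_before = as.list(before), n_after = as.list(after),
                 n_rejected = sum(bad), rejected_trials = which(bad),
                 min_per_condition = min_per_condition,
                 below_minimum = low,
                 rule = "peak-to-peak threshold per channel")
  list(epochs = kept, report = report)
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (half-open `[t0, t1)`); applying it twice is a no-op.
#'
#' @param epochs an `epoch_set`.
#' @param window two-element numeric, seconds, inside the epoch time axis
#'   (default `c(-0.1, 0)`, the 100 ms before stimulus onset).
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-0.1, 0)) {
  sel <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(sel))
    stop("baseline window [", window[1], ", ", window[2],
         ") contains no samples of the epoch time axis")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs$data - as.vector(base)  # recycles over the time dimension
  epoch_set(out, epochs$times, epochs$condition, epochs$rt_ms, epochs$sfreq,
            epochs$montage, lock = epochs$lock)
}
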