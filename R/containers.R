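#' Core data containers
#'
#' `continuous_recording`: voltages (microvolts) as a channels x samples
#' matrix with a sampling rate and montage. `event_table`: BIDS-style events
#' (onset in seconds, duration, trial_type, response_time in ms).
#' `epoch_set`: a trials x channels x samples array time-locked to an event,
#' with per-trial condition labels and reaction times.
#'
#' All invariants are enforced at construction.
#'
#' @name containers
NULL

CUE_LABELS <- c("S1", "S2", "S3", "S4", "S5")
DS_LABELS <- c("S1", "S2", "S3", "S4")
NDS_LABELS <- "S5"

#' Construct a continuous recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param montage an `eeg_montage` whose rows match the rows of `data`.
#' @param start recording start time in seconds (default 0).
#' @return object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sfreq, montage, start = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0)
    stop("sfreq must be a positive scalar (Hz)")
  if (nrow(data) != nrow(montage))
    stop("recording has ", nrow(data), " rows but montage has ",
         nrow(montage), " electrodes")
  structure(
    list(data = data, sfreq = sfreq, montage = montage, start = start),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$sfreq, " Hz (", round(ncol(x$data) / x$sfreq, 2),
      " s)\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `continuous_recording`.
#' @export
recording_duration <- function(recording) ncol(recording$data) / recording$sfreq

#' Construct an event table
#'
#' @param onset event onsets in seconds, strictly increasing.
#' @param trial_type `"S1"`..`"S5"` for cues, `"go"` for imperative stimuli.
#' @param duration event durations in seconds (default 0).
#' @param response_time reaction time in ms for go events, `NA` otherwise.
#' @return data frame of class `eeg_events`.
#' @export
event_table <- function(onset, trial_type, duration = 0,
                        response_time = NA_real_) {
  df <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   response_time = as.numeric(response_time),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$trial_type), c(CUE_LABELS, "go"))
  if (length(bad))
    stop("invalid trial_type value(s): ", paste(bad, collapse = ", "),
         " (allowed: S1..S5, go)")
  if (any(diff(df$onset) <= 0))
    stop("event onsets must be strictly increasing")
  class(df) <- c("eeg_events", "data.frame")
  df
}

#' Construct an epoch set
#'
#' @param data numeric array trials x channels x samples (microvolts).
#' @param times time axis in seconds relative to the locking event
#'   (0 = stimulus onset), uniform and strictly increasing.
#' @param condition per-trial condition label (`"S1"`..`"S5"`).
#' @param rt_ms per-trial reaction time in ms (`NA` when none).
#' @param sfreq sampling rate in Hz.
#' @param montage an `eeg_montage` matching the channel dimension.
#' @param lock which event the epochs are locked to (`"cue"` or `"go"`).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, condition, rt_ms, sfreq, montage,
                      lock = "cue") {
  d <- dim(data)
  if (length(d) != 3L) stop("epoch data must be a 3D array")
  if (d[2] != nrow(montage))
    stop("channel dimension (", d[2], ") does not match montage (",
         nrow(montage), ")")
  if (d[3] != length(times)) stop("time axis length does not match data")
  if (length(condition) != d[1] || length(rt_ms) != d[1])
    stop("per-trial metadata length does not match trial count")
  dt <- diff(times)
  if (any(dt <= 0) || (length(dt) > 1 && diff(range(dt)) > 1e-9))
    stop("time axis must be strictly increasing and uniform")
  bad <- setdiff(unique(condition), CUE_LABELS)
  if (length(bad))
    stop("invalid condition label(s): ", paste(bad, collapse = ", "))
  structure(
    list(data = data, times = times, condition = as.character(condition),
         rt_ms = as.numeric(rt_ms), sfreq = sfreq, montage = montage,
         lock = lock),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " ch x ", d[3],
      " samples, ", x$lock, "-locked [", round(min(x$times), 3), ", ",
      round(max(x$times) + 1 / x$sfreq, 3), ") s @ ", x$sfreq, " Hz\n",
      sep = "")
  cat("  conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                     table(x$condition)), collapse = " "), "\n")
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset epochs by channel
#'
#' Returns the epochs restricted to the named electrodes, in the requested
#' order; trial metadata is unchanged.
#'
#' @param epochs an `epoch_set`.
#' @param names electrode labels to keep.
#' @export
select_channels <- function(epochs, names) {
  idx <- match(names, epochs$montage$name)
  if (anyNA(idx))
    stop("unknown electrode(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  mon <- epochs$montage[idx, , drop = FALSE]
  class(mon) <- class(epochs$montage)
  epoch_set(epochs$data[, idx, , drop = FALSE], epochs$times,
            epochs$condition, epochs$rt_ms, epochs$sfreq, mon,
            lock = epochs$lock)
}

#' Subset epochs by trial
#' @param epochs an `epoch_set`.
#' @param idx trial indices (or logical mask) to keep.
#' @export
select_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times,
            epochs$condition[idx], epochs$rt_ms[idx], epochs$sfreq,
            epochs$montage, lock = epochs$lock)
}

#' Expand a condition selector
#'
#' `"DS"` pools the four directional cues S1-S4, `"nDS"` is S5, `"all"` is
#' every cue; otherwise the selector is taken as a vector of S-labels.
#'
#' @param selector condition selector.
#' @return character vector of S-labels.
#' @export
expand_conditions <- function(selector) {
  if (length(selector) == 1L) {
    if (selector == "DS") return(DS_LABELS)
    if (selector == "nDS") return(NDS_LABELS)
    if (selector == "all") return(CUE_LABELS)
  }
  bad <- setdiff(selector, CUE_LABELS)
  if (length(bad))
    stop("unknown condition selector: ", paste(bad, collapse = ", "))
  selector
}
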