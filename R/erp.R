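#' ERP averaging and component measurement
#'
#' Condition-wise averaging of epochs into ERP waveforms, peak-based
#' measurement of component amplitude and latency on predefined channel
#' groups, and grand averaging across subjects.
#'
#' The measurement convention: a component's latency is fixed on the mean
#' time course of its channel group (argmax for positive, argmin for
#' negative polarity within the search window); the group amplitude is that
#' extremum; per-electrode amplitudes are then read for every montage
#' electrode as the mean voltage in latency +/- 20 ms, giving a full scalp
#' amplitude vector at a single component latency.
#'
#' @name erp_components
NULL

#' Default component definitions
#'
#' Search windows bracket the nominal latencies (P100 70-140, P150 140-190,
#' N200 180-280, P300 250-450, P400 400-600 ms). Channel groups follow the
#' standard selections for this paradigm: parietal/occipital electrodes for
#' the early sensory components, a central/parietal set for P300, and
#' Cz/CPz for P400.
#'
#' @return named list of definitions (name, polarity, window_ms, channels).
#' @export
component_definitions <- function() {
  early <- c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
             "PO3", "PO4", "PO7", "PO8", "O1", "O2", "Pz", "POz", "Oz")
  p300 <- c("C1", "C2", "C3", "C4", "C5", "C6",
            "CP1", "CP2", "CP3", "CP4", "CP5", "CP6",
            "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
            "Cz", "CPz", "Pz")
  list(
    P100 = list(name = "P100", polarity = "positive",
                window_ms = c(70, 140), channels = early),
    P150 = list(name = "P150", polarity = "positive",
                window_ms = c(140, 190), channels = early),
    N200 = list(name = "N200", polarity = "negative",
                window_ms = c(180, 280), channels = early),
    P300 = list(name = "P300", polarity = "positive",
                window_ms = c(250, 450), channels = p300),
    P400 = list(name = "P400", polarity = "positive",
                window_ms = c(400, 600), channels = c("Cz", "CPz"))
  )
}

#' Average epochs into an ERP waveform
#'
#' @param epochs an `epoch_set`.
#' @param selector condition selector (`"DS"`, `"nDS"`, `"all"` or a vector
#'   of S-labels); see [expand_conditions()].
#' @return object of class `erp_waveform`: channels x samples mean, time
#'   axis, montage, the selector, the number of trials averaged and the lock.
#' @export
average_erp <- function(epochs, selector = "all") {
  labels <- expand_conditions(selector)
  idx <- which(epochs$condition %in% labels)
  if (!length(idx))
    stop("no trials match condition selector: ",
         paste(selector, collapse = ","))
  avg <- colMeans(epochs$data[idx, , , drop = FALSE], dims = 1)
  structure(
    list(data = avg, times = epochs$times, sfreq = epochs$sfreq,
         montage = epochs$montage,
         condition = paste(selector, collapse = ","),
         n_trials = length(idx), lock = epochs$lock),
    class = "erp_waveform"
  )
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat("<erp_waveform> ", x$condition, " (", x$lock, "-locked), ",
      x$n_trials, " trials, ", nrow(x$data), " ch\n", sep = "")
  invisible(x)
}

#' Measure a component on an ERP waveform
#'
#' @param erp an `erp_waveform`.
#' @param def a component definition (see [component_definitions()]).
#' @param halfwin_ms half width of the per-electrode averaging window around
#'   the measured latency (default 20 ms).
#' @return list of class `component_measure`: `component`, `condition`,
#'   `lock`, `amplitude_uv` (group-peak), `latency_ms`, `electrodes` (named
#'   per-electrode amplitude vector over the whole montage) and
#'   `low_prominence` (TRUE when the group time course is flat in the
#'   window, in which case the first window sample is reported).
#' @export
measure_component <- function(erp, def, halfwin_ms = 20) {
  ch_idx <- match(def$channels, erp$montage$name)
  if (anyNA(ch_idx))
    stop("component channel(s) not in montage: ",
         paste(def$channels[is.na(ch_idx)], collapse = ", "))
  t_ms <- erp$times * 1000
  wsel <- which(t_ms >= def$window_ms[1] & t_ms <= def$window_ms[2])
  if (!length(wsel))
    stop("search window [", def$window_ms[1], ", ", def$window_ms[2],
         "] ms lies outside the epoch time axis")
  g <- colMeans(erp$data[ch_idx, wsel, drop = FALSE])
  flat <- diff(range(g)) < 1e-12
  i <- if (def$polarity == "negative") which.min(g) else which.max(g)
  if (flat) i <- 1L
  lat <- t_ms[wsel[i]]
  amp <- g[i]
  esel <- which(abs(t_ms - lat) <= halfwin_ms)
  elec <- rowMeans(erp$data[, esel, drop = FALSE])
  names(elec) <- erp$montage$name
  structure(
    list(component = def$name, condition = erp$condition, lock = erp$lock,
         amplitude_uv = unname(amp), latency_ms = unname(lat),
         electrodes = elec, n_trials = erp$n_trials,
         low_prominence = flat),
    class = "component_measure"
  )
}

#' @export
print.component_measure <- function(x, ...) {
  cat(sprintf("<component_measure> %s %s (%s): %.2f uV @ %.0f ms%s\n",
              x$component, x$condition, x$lock, x$amplitude_uv,
              x$latency_ms, if (x$low_prominence) " [low prominence]" else ""))
  invisible(x)
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject ERP waveforms sharing a time axis and
#' montage.
#'
#' @param waveforms list of `erp_waveform`s, one per subject.
#' @return an `erp_waveform` whose `n_subjects` attribute records the count.
#' @export
grand_average <- function(waveforms) {
  if (!length(waveforms)) stop("no waveforms to average")
  t0 <- waveforms[[1]]$times
  for (w in waveforms)
    if (length(w$times) != length(t0) || max(abs(w$times - t0)) > 1e-9)
      stop("waveforms have mixed time axes")
  acc <- Reduce(`+`, lapply(waveforms, `[[`, "data")) / length(waveforms)
  out <- waveforms[[1]]
  out$data <- acc
  out$n_subjects <- length(waveforms)
  out$n_trials <- sum(vapply(waveforms, `[[`, numeric(1), "n_trials"))
  out
}

#' Tidy a set of component measures
#'
#' Flattens `component_measure` objects into one row each, with electrode
#' amplitudes as columns — the export scheme used for the measures TSV.
#'
#' @param measures list of `component_measure`s.
#' @param subject optional subject ids (recycled).
#' @return data frame.
#' @export
tidy_measures <- function(measures, subject = NA) {
  subject <- rep_len(subject, length(measures))
  rows <- lapply(seq_along(measures), function(i) {
    m <- measures[[i]]
    cbind(data.frame(subject = subject[i], lock = m$lock,
                     condition = m$condition, component = m$component,
                     amplitude_uv = m$amplitude_uv,
                     latency_ms = m$latency_ms,
                     n_trials = m$n_trials,
                     low_prominence = m$low_prominence,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m$electrodes), check.names = FALSE))
  })
  do.call(rbind, rows)
}
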