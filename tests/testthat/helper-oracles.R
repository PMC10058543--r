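# Independent oracles used across the suite. These deliberately re-derive
# results by exhaustive enumeration or closed form, not by calling the
# implementation under test.

# exhaustive peak scan: walk every sample of the group-mean time course in
# the window, tracking the extremum
oracle_peak <- function(data, ch_idx, times_ms, window_ms, polarity) {
  best_v <- NULL
  best_t <- NULL
  for (i in seq_along(times_ms)) {
    if (times_ms[i] < window_ms[1] || times_ms[i] > window_ms[2]) next
    v <- mean(data[ch_idx, i])
    better <- is.null(best_v) ||
      (polarity == "positive" && v > best_v) ||
      (polarity == "negative" && v < best_v)
    if (better) {
      best_v <- v
      best_t <- times_ms[i]
    }
  }
  list(amplitude = best_v, latency = best_t)
}

# Benjamini-Hochberg by direct enumeration of the step-up definition
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  thr <- NA_real_
  for (k in m:1) {
    if (ps[k] <= k * alpha / m) {
      thr <- ps[k]
      break
    }
  }
  rejected <- if (is.na(thr)) integer(0) else which(p <= thr)
  list(threshold = thr, rejected = rejected)
}

# Pearson r and two-tailed p from the covariance/SD closed form
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# small montage containing every electrode of the default component groups
# plus the CNV channel; used where a full 64-channel run would be wasteful
test_montage <- function() {
  make_montage(c(
    "Cz", "CPz", "Pz", "POz", "Oz", "O1", "O2",
    "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
    "PO3", "PO4", "PO7", "PO8",
    "C1", "C2", "C3", "C4", "C5", "C6",
    "CP1", "CP2", "CP3", "CP4", "CP5", "CP6"
  ))
}

# fast small-scale simulation settings (structure preserved, sizes reduced)
test_sim_config <- function(...) {
  args <- list(n_trials = 20, ds_nds_ratio = 0.8, montage = test_montage(),
               sfreq_hz = 250)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
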