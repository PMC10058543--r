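#' Synthetic cue-go EEG generator
#'
#' Generates ground-truth-known multichannel EEG for a cued visuomotor task:
#' 400 pseudorandomised cues (320 directional arrows S1-S4 in four equal
#' classes, 80 non-directional squares S5) each followed by an imperative go
#' stimulus 2000 ms later. Each cue and go inserts Gaussian-windowed ERP
#' deflections (P100/P150/N200/P300/P400) with electrode-specific spatial
#' profiles and condition-dependent scaling; a linear negative CNV ramp runs
#' from 500 ms post-cue to go onset, with a per-trial slope whose implied
#' mean CNV value drives the trial's reaction time. Background activity is
#' white plus 1/f ("pink") noise.
#'
#' @name synthetic_data
NULL

#' Default ERP component specifications
#'
#' Widths are Gaussian standard deviations in ms, chosen so neighbouring
#' deflections remain resolvable at 512 Hz (analytic cross-component
#' contamination at each peak below 0.5 uV). The N200 carries the only
#' condition-dependent scaling: more negative for directional cues, with a
#' posterior spatial profile.
#'
#' @return list of component specs (name, polarity, latency_ms, width_ms,
#'   amplitude_uv, center, profile_sigma, condition_scaling).
#' @export
default_component_specs <- function() {
  sc1 <- c(S1 = 1, S2 = 1, S3 = 1, S4 = 1, S5 = 1)
  list(
    list(name = "P100", polarity = "positive", latency_ms = 100,
         width_ms = 15, amplitude_uv = 5, center = "POz",
         profile_sigma = 0.4, condition_scaling = sc1),
    list(name = "P150", polarity = "positive", latency_ms = 150,
         width_ms = 15, amplitude_uv = 4, center = "POz",
         profile_sigma = 0.4, condition_scaling = sc1),
    list(name = "N200", polarity = "negative", latency_ms = 200,
         width_ms = 20, amplitude_uv = 6, center = "POz",
         profile_sigma = 0.4,
         condition_scaling = c(S1 = 1.25, S2 = 1.25, S3 = 1.25,
                               S4 = 1.25, S5 = 0.75)),
    list(name = "P300", polarity = "positive", latency_ms = 300,
         width_ms = 35, amplitude_uv = 7, center = "CPz",
         profile_sigma = 0.4, condition_scaling = sc1),
    list(name = "P400", polarity = "positive", latency_ms = 480,
         width_ms = 40, amplitude_uv = 5, center = "Cz",
         profile_sigma = 0.3, condition_scaling = sc1)
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the task and recording design the analysis assumes:
#' 400 trials (80% directional), 64 channels at 1000 Hz, 2000 ms cue-go
#' interval, CNV slope ~ N(-4, 1.5^2) uV/s starting 500 ms post-cue, and an
#' RT model RT = rt_base + rt_coupling x (mean CNV value implied by the
#' slope) + Gaussian noise, clipped at `rt_floor_ms`. With the default
#' coupling of 20 ms/uV and 50 ms RT noise the population correlation
#' between mean CNV value and RT is 0.6.
#'
#' @param n_trials number of cue-go trials.
#' @param ds_nds_ratio proportion of directional cues.
#' @param montage electrode montage (defaults to the 64-channel standard set).
#' @param sfreq_hz sampling rate, Hz.
#' @param cue_go_interval_ms cue to go-stimulus interval, ms.
#' @param fixation_ms inter-trial fixation period, ms.
#' @param go_window_ms response window after go onset, ms.
#' @param component_specs list of component specs
#'   (see [default_component_specs()]).
#' @param cnv_slope_mean_uv_per_s,cnv_slope_sd mean (negative) and SD of the
#'   per-trial CNV slope, uV/s.
#' @param cnv_ramp_start_ms CNV onset after the cue, ms.
#' @param cnv_resolve_ms time for the CNV to return to baseline after go, ms.
#' @param cnv_center,cnv_profile_sigma spatial profile of the CNV
#'   (Gaussian around `cnv_center` on the 2D layout).
#' @param cnv_mean_window_ms window (post-cue, ms) over which the "mean CNV
#'   value" entering the RT model is defined.
#' @param rt_base_ms,rt_coupling_ms_per_uv,rt_noise_sd_ms,rt_floor_ms
#'   reaction-time model parameters.
#' @param noise_white_sd_uv,noise_pink_sd_uv background noise SDs, uV.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 400, ds_nds_ratio = 0.8,
                       montage = standard_montage(), sfreq_hz = 1000,
                       cue_go_interval_ms = 2000, fixation_ms = 2000,
                       go_window_ms = 2000,
                       component_specs = default_component_specs(),
                       cnv_slope_mean_uv_per_s = -4, cnv_slope_sd = 1.5,
                       cnv_ramp_start_ms = 500, cnv_resolve_ms = 300,
                       cnv_center = "Cz", cnv_profile_sigma = 0.4,
                       cnv_mean_window_ms = c(1500, 2000),
                       rt_base_ms = 450, rt_coupling_ms_per_uv = 20,
                       rt_noise_sd_ms = 50, rt_floor_ms = 150,
                       noise_white_sd_uv = 6, noise_pink_sd_uv = 8,
                       seed = 1L) {
  cfg <- list(
    n_trials = n_trials, ds_nds_ratio = ds_nds_ratio, montage = montage,
    n_channels = nrow(montage), sfreq_hz = sfreq_hz,
    cue_go_interval_ms = cue_go_interval_ms, fixation_ms = fixation_ms,
    go_window_ms = go_window_ms, component_specs = component_specs,
    cnv_slope_mean_uv_per_s = cnv_slope_mean_uv_per_s,
    cnv_slope_sd = cnv_slope_sd, cnv_ramp_start_ms = cnv_ramp_start_ms,
    cnv_resolve_ms = cnv_resolve_ms, cnv_center = cnv_center,
    cnv_profile_sigma = cnv_profile_sigma,
    cnv_mean_window_ms = cnv_mean_window_ms, rt_base_ms = rt_base_ms,
    rt_coupling_ms_per_uv = rt_coupling_ms_per_uv,
    rt_noise_sd_ms = rt_noise_sd_ms, rt_floor_ms = rt_floor_ms,
    noise_white_sd_uv = noise_white_sd_uv,
    noise_pink_sd_uv = noise_pink_sd_uv, seed = as.integer(seed)
  )
  if (cfg$n_trials <= 0) stop("n_trials must be positive")
  if (cfg$ds_nds_ratio < 0 || cfg$ds_nds_ratio > 1)
    stop("ds_nds_ratio must be a proportion in [0, 1]")
  if (cfg$sfreq_hz <= 0) stop("sfreq_hz must be positive")
  if (cfg$cue_go_interval_ms <= 0) stop("cue_go_interval_ms must be positive")
  for (sp in cfg$component_specs) {
    if (sp$width_ms <= 0) stop("component width_ms must be positive: ", sp$name)
    if (!sp$polarity %in% c("positive", "negative"))
      stop("component polarity must be positive/negative: ", sp$name)
    if (!setequal(names(sp$condition_scaling), CUE_LABELS))
      stop("condition_scaling must name exactly S1..S5: ", sp$name)
    if (!is.null(sp[["profile"]]) && length(sp[["profile"]]) != cfg$n_channels)
      stop("spatial profile length (", length(sp[["profile"]]),
           ") does not match channel count (", cfg$n_channels, "): ", sp$name)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Gaussian spatial profile over a montage
#'
#' @param montage an `eeg_montage`.
#' @param center electrode label at which the profile peaks (value 1).
#' @param sigma Gaussian width in 2D layout units (unit-disc scale).
#' @return numeric vector, one weight per electrode.
#' @export
gaussian_profile <- function(montage, center, sigma) {
  i <- match(center, montage$name)
  if (is.na(i)) stop("profile center electrode not in montage: ", center)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  exp(-d2 / (2 * sigma^2))
}

.component_profile <- function(spec, montage) {
  if (!is.null(spec[["profile"]])) return(spec[["profile"]])
  gaussian_profile(montage, spec$center, spec$profile_sigma)
}

.signed_amp <- function(spec) {
  spec$amplitude_uv * if (spec$polarity == "negative") -1 else 1
}

#' Generate the pseudorandomised task event sequence
#'
#' Directional trials are split equally over S1-S4; the order is a seeded
#' permutation. Each cue is followed by exactly one go event
#' `cue_go_interval_ms` later, and trials are separated by the fixation
#' period.
#'
#' @param config a `sim_config`.
#' @return an `eeg_events` table (go events have `response_time = NA` until
#'   reaction times are generated).
#' @export
generate_task_sequence <- function(config) {
  n_ds <- config$n_trials * config$ds_nds_ratio
  if (abs(n_ds - round(n_ds)) > 1e-9 || round(n_ds) %% 4L != 0L)
    stop("n_trials x ds_nds_ratio must give a directional count divisible ",
         "by 4 (got ", n_ds, " directional trials from ", config$n_trials,
         " x ", config$ds_nds_ratio, ")")
  n_ds <- as.integer(round(n_ds))
  n_nds <- config$n_trials - n_ds
  labels <- c(rep(DS_LABELS, each = n_ds / 4L), rep("S5", n_nds))
  set.seed(config$seed)
  labels <- labels[sample.int(length(labels))]
  slot_s <- (config$fixation_ms + config$cue_go_interval_ms +
               config$go_window_ms) / 1000
  cue_on <- config$fixation_ms / 1000 + (seq_len(config$n_trials) - 1L) * slot_s
  go_on <- cue_on + config$cue_go_interval_ms / 1000
  ord <- order(c(cue_on, go_on))
  event_table(
    onset = c(cue_on, go_on)[ord],
    trial_type = c(labels, rep("go", config$n_trials))[ord],
    duration = c(rep(config$cue_go_interval_ms / 1000, config$n_trials),
                 rep(config$go_window_ms / 1000, config$n_trials))[ord],
    response_time = NA_real_
  )
}

#' Mean CNV value implied by a ramp slope
#'
#' For a linear ramp starting at `cnv_ramp_start_ms`, the mean voltage over
#' the configured mean-CNV window is `slope x (window midpoint - ramp
#' start)` in seconds.
#'
#' @param config a `sim_config`.
#' @param slopes ramp slopes, uV/s.
#' @return mean CNV values, uV.
#' @export
implied_cnv_mean <- function(config, slopes) {
  slopes * (mean(config$cnv_mean_window_ms) - config$cnv_ramp_start_ms) / 1000
}

#' Generate reaction times from CNV slopes
#'
#' RT = `rt_base_ms` + `rt_coupling_ms_per_uv` x (mean CNV value implied by
#' the slope) + Gaussian noise, clipped below at `rt_floor_ms`. Because the
#' mean CNV value is negative and the coupling positive, steeper (more
#' negative) ramps yield shorter RTs and the correlation between mean CNV
#' value and RT is positive.
#'
#' @param config a `sim_config` (`rt_noise_sd_ms` must be non-negative).
#' @param true_cnv_slopes per-trial ramp slopes, uV/s.
#' @return list with `rt_ms` and a ground-truth data frame
#'   (`cnv_slope`, `cnv_mean_true`, `rt_true` pre-noise, `rt_ms`).
#' @export
generate_rts <- function(config, true_cnv_slopes) {
  if (config$rt_noise_sd_ms < 0) stop("rt_noise_sd_ms must be non-negative")
  m <- implied_cnv_mean(config, true_cnv_slopes)
  rt_true <- config$rt_base_ms + config$rt_coupling_ms_per_uv * m
  set.seed(config$seed + 1L)
  rt <- rt_true + stats::rnorm(length(rt_true), 0, config$rt_noise_sd_ms)
  rt <- pmax(rt, config$rt_floor_ms)
  list(rt_ms = rt,
       truth = data.frame(cnv_slope = true_cnv_slopes, cnv_mean_true = m,
                          rt_true = rt_true, rt_ms = rt))
}

#' 1/f ("pink") noise by FFT amplitude shaping
#'
#' White Gaussian noise is transformed to the frequency domain, scaled by
#' 1/sqrt(f) (DC removed), transformed back and normalised to the requested
#' standard deviation.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1) {
  x <- stats::rnorm(n)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f)                 # two-sided frequency axis
  w <- ifelse(f > 0, 1 / sqrt(f), 0)
  y <- Re(stats::fft(stats::fft(x) * w, inverse = TRUE)) / n
  y <- y - mean(y)
  y * sd / stats::sd(y)
}

#' Synthesize a continuous recording for an event sequence
#'
#' Each cue and each go event inserts every configured component as a
#' Gaussian bump (signed by polarity, scaled per electrode by the spatial
#' profile and per condition by `condition_scaling`). A linear CNV ramp with
#' a per-trial slope drawn from N(mean, sd) runs from `cnv_ramp_start_ms`
#' post-cue to go onset, then resolves linearly over `cnv_resolve_ms`.
#' White and 1/f noise are added per channel.
#'
#' @param config a `sim_config`.
#' @param events the event table from [generate_task_sequence()].
#' @return list with `recording` (a `continuous_recording`) and `truth`
#'   (per-trial condition, true component peak amplitudes/latencies and CNV
#'   slope).
#' @export
synthesize_recording <- function(config, events) {
  sf <- config$sfreq_hz
  mon <- config$montage
  nch <- nrow(mon)
  cues <- events[events$trial_type %in% CUE_LABELS, , drop = FALSE]
  ntr <- nrow(cues)
  dur <- max(events$onset) + (config$go_window_ms + config$fixation_ms) / 1000
  # pad to a 2/3/5-smooth sample count: the FFTs used for 1/f noise and
  # downstream spectral resampling are then fast regardless of duration
  n <- stats::nextn(ceiling(dur * sf), c(2, 3, 5))
  if (max(events$onset) * sf >= n)
    stop("events do not fit within the generated recording duration")

  set.seed(config$seed + 2L)
  slopes <- stats::rnorm(ntr, config$cnv_slope_mean_uv_per_s,
                         config$cnv_slope_sd)

  # per-channel noise generation keeps the peak memory footprint at one
  # channels x samples matrix plus one channel-length temporary
  x <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    v <- numeric(n)
    if (config$noise_white_sd_uv > 0)
      v <- stats::rnorm(n, 0, config$noise_white_sd_uv)
    if (config$noise_pink_sd_uv > 0)
      v <- v + pink_noise(n, config$noise_pink_sd_uv)
    x[ch, ] <- v
  }

  # precompute per-component bump and profile
  comps <- lapply(config$component_specs, function(sp) {
    sig_s <- sp$width_ms / 1000
    tt <- seq(-4 * sig_s, 4 * sig_s, by = 1 / sf)
    list(spec = sp, bump = exp(-tt^2 / (2 * sig_s^2)),
         offset = round((sp$latency_ms / 1000 - 4 * sig_s) * sf),
         profile = .component_profile(sp, mon))
  })
  cnv_prof <- gaussian_profile(mon, config$cnv_center,
                               config$cnv_profile_sigma)
  ramp0_s <- config$cnv_ramp_start_ms / 1000
  iv_s <- config$cue_go_interval_ms / 1000
  ramp_len <- round((iv_s - ramp0_s) * sf)
  dec_len <- round(config$cnv_resolve_ms / 1000 * sf)
  ramp_t <- (seq_len(ramp_len) - 1L) / sf

  truth <- data.frame(trial = seq_len(ntr), condition = cues$trial_type,
                      cue_onset_s = cues$onset, cnv_slope = slopes,
                      stringsAsFactors = FALSE)
  for (cp in comps) {
    sc <- cp$spec$condition_scaling[cues$trial_type]
    truth[[paste0(cp$spec$name, "_amp_uv")]] <- .signed_amp(cp$spec) * sc
    truth[[paste0(cp$spec$name, "_latency_ms")]] <- cp$spec$latency_ms
  }

  add_block <- function(i0, block) {
    idx <- i0 + seq_len(ncol(block))
    keep <- idx >= 1L & idx <= n
    if (any(keep)) x[, idx[keep]] <<- x[, idx[keep]] + block[, keep, drop = FALSE]
  }
  for (i in seq_len(ntr)) {
    cue_i <- round(cues$onset[i] * sf)
    for (lock_off in c(0L, round(iv_s * sf))) {
      for (cp in comps) {
        amp <- .signed_amp(cp$spec) *
          cp$spec$condition_scaling[[cues$trial_type[i]]]
        add_block(cue_i + lock_off + cp$offset,
                  outer(cp$profile * amp, cp$bump))
      }
    }
    ramp <- slopes[i] * ramp_t
    endv <- slopes[i] * (iv_s - ramp0_s)
    dec <- endv * (1 - seq_len(dec_len) / dec_len)
    add_block(cue_i + round(ramp0_s * sf), outer(cnv_prof, c(ramp, dec)))
  }

  list(recording = continuous_recording(x, sfreq = sf, montage = mon),
       truth = truth)
}

#' Ground-truth group-mean component amplitude
#'
#' The noise-free value a channel-group peak measurement should recover:
#' signed peak amplitude x condition scaling x mean spatial-profile weight
#' over the measurement channel group. Used for parameter-recovery checks.
#'
#' @param config a `sim_config`.
#' @param component component name (must exist in `component_specs`).
#' @param channels measurement channel group (electrode labels).
#' @param condition a single condition label S1..S5, or `"DS"`/`"nDS"`
#'   (scaling averaged over the pooled labels).
#' @return expected group-mean peak amplitude, uV (signed).
#' @export
predict_group_amplitude <- function(config, component, channels,
                                    condition = "DS") {
  sp <- NULL
  for (s in config$component_specs) if (s$name == component) sp <- s
  if (is.null(sp)) stop("unknown component: ", component)
  prof <- .component_profile(sp, config$montage)
  idx <- match(channels, config$montage$name)
  if (anyNA(idx))
    stop("channel(s) not in montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  sc <- mean(sp$condition_scaling[expand_conditions(condition)])
  .signed_amp(sp) * sc * mean(prof[idx])
}

#' Simulate one subject end to end
#'
#' Generates the event sequence, the continuous recording with ground truth,
#' and reaction times coupled to the per-trial CNV slopes; go events in the
#' returned table carry the generated RTs.
#'
#' @param config a `sim_config`.
#' @return list with `recording`, `events`, `truth` and `config`.
#' @export
simulate_subject <- function(config = sim_config()) {
  events <- generate_task_sequence(config)
  syn <- synthesize_recording(config, events)
  rts <- generate_rts(config, syn$truth$cnv_slope)
  events$response_time[events$trial_type == "go"] <- rts$rt_ms
  truth <- cbind(syn$truth, rts$truth[c("cnv_mean_true", "rt_true", "rt_ms")])
  list(recording = syn$recording, events = events, truth = truth,
       config = config)
}

#' Simulate per-subject mean CNV values and reaction times
#'
#' A subject-level view of the CNV-RT coupling model: each subject's mean
#' CNV slope is drawn from the configured slope distribution and the mean RT
#' follows the same affine-plus-noise model used per trial. Used to study
#' the correlation between mean CNV value and RT across a cohort without
#' synthesising full recordings.
#'
#' @param n_subjects cohort size.
#' @param config a `sim_config` (its `seed` drives the draw).
#' @return data frame with `subject`, `cnv_slope`, `cnv_mean_uv`, `rt_ms`.
#' @export
simulate_cnv_rt_cohort <- function(n_subjects, config = sim_config()) {
  set.seed(config$seed + 3L)
  slopes <- stats::rnorm(n_subjects, config$cnv_slope_mean_uv_per_s,
                         config$cnv_slope_sd)
  rts <- generate_rts(config, slopes)
  data.frame(subject = seq_len(n_subjects), cnv_slope = slopes,
             cnv_mean_uv = rts$truth$cnv_mean_true, rt_ms = rts$rt_ms)
}

#' Simulate per-subject per-electrode component amplitudes
#'
#' Measurement-level generator for statistical-map studies: condition `a` is
#' pure between-subject noise, condition `b` adds `effect_uv` times the
#' spatial `profile`. Returns subjects x electrodes matrices suitable for
#' [paired_t_map()] / [unpaired_t_map()].
#'
#' @param n_subjects number of subjects.
#' @param montage an `eeg_montage`.
#' @param effect_uv effect size at the profile peak, uV (0 = global null).
#' @param profile per-electrode effect profile (defaults to all zero).
#' @param noise_sd between-subject noise SD, uV.
#' @param seed integer seed.
#' @return list with matrices `a` and `b` (dimnames = electrode names).
#' @export
simulate_component_amplitudes <- function(n_subjects, montage,
                                          effect_uv = 0, profile = NULL,
                                          noise_sd = 1, seed = 1L) {
  nel <- nrow(montage)
  if (is.null(profile)) profile <- rep(0, nel)
  if (length(profile) != nel)
    stop("profile length does not match montage size")
  set.seed(seed)
  a <- matrix(stats::rnorm(n_subjects * nel, 0, noise_sd), n_subjects, nel)
  b <- matrix(stats::rnorm(n_subjects * nel, 0, noise_sd), n_subjects, nel) +
    matrix(effect_uv * profile, n_subjects, nel, byrow = TRUE)
  dimnames(a) <- dimnames(b) <- list(NULL, montage$name)
  list(a = a, b = b)
}
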