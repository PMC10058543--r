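#' Pipeline orchestration
#'
#' `run_pipeline()` ties the stages together for a whole cohort: simulate
#' (or load) each subject's recording, preprocess, measure components and
#' CNV, split performance, and run the four group analyses — directional vs
#' non-directional cues, fast vs slow subjects, fast vs slow trials, and the
#' CNV-RT correlation — writing tidy TSV/JSON outputs and a run manifest.
#'
#' @name cli_pipeline
NULL

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: preprocessing follows the
#' recording design (resample to 512 Hz, 0.2-30 Hz zero-phase FIR, 5 s cue
#' epochs, 1100 ms component segments with a 100 ms pre-stimulus baseline,
#' 100 uV peak-to-peak rejection with a 60-epoch-per-condition guard), the
#' component and CNV windows are the package defaults, and the simulated
#' cohort has 19 subjects.
#'
#' @return nested list of pipeline settings.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_subjects = 19L),
    input = list(raw = NULL, events = NULL),
    preprocess = list(target_hz = 512, low_hz = 0.2, high_hz = 30,
                      trans_low_hz = 0.2, trans_high_hz = 7.5,
                      cue_window_s = c(-1.5, 3.5),
                      seg_window_s = c(-0.1, 1.0),
                      baseline_s = c(-0.1, 0),
                      p2p_threshold_uv = 100, min_per_condition = 60),
    cnv = list(baseline_s = c(0.9, 1.0), range_s = c(1.0, 2.9),
               mean_window_ms = c(1500, 2000),
               fit_window_ms = c(1200, 2000), channel = "Cz"),
    splits = list(sd_mult = 0.5, min_group = 10, trial_selector = "DS"),
    stats = list(alpha = 0.05, var_equal = TRUE)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (if given) and merges it over the defaults; explicit
#' `overrides` win over both. A configuration naming both an input dataset
#' and an enabled simulation is rejected.
#'
#' @param path optional YAML file.
#' @param overrides optional nested list of settings.
#' @return validated configuration list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- .merge_config(cfg, overrides)
  has_input <- !is.null(cfg$input$raw)
  if (has_input && isTRUE(cfg$simulate$enabled))
    stop("configure either input paths or simulation, not both")
  if (!has_input && !isTRUE(cfg$simulate$enabled))
    stop("no data source: provide input paths or enable simulation")
  cfg
}

#' Preprocess and measure a single subject
#'
#' Resamples and band-pass filters the recording, extracts 5 s cue-locked
#' epochs (for the CNV) and 1100 ms cue- and go-locked segments (for the
#' components), rejects high-amplitude epochs, baseline-corrects the
#' segments, and measures every component for the DS and nDS conditions at
#' both locks plus the within-subject fast/slow trial contrast. The CNV is
#' extracted at Cz with its dedicated 900-1000 ms baseline.
#'
#' @param recording a `continuous_recording` (as recorded, e.g. 1000 Hz).
#' @param events the subject's `eeg_events`.
#' @param cfg a pipeline configuration (see [default_pipeline_config()]).
#' @param comps component definitions.
#' @param subject subject identifier attached to the outputs.
#' @return list with `measures` (tidy data frame incl. electrode columns),
#'   `cnv` (per-condition mean/slope), `rt` (per-condition mean RT),
#'   `trial_split`, `warnings` and epoch counts.
#' @export
analyze_subject <- function(recording, events,
                            cfg = default_pipeline_config(),
                            comps = component_definitions(),
                            subject = "sub1") {
  pp <- cfg$preprocess
  warnings <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  rec <- resample_recording(recording, pp$target_hz)
  rec <- bandpass_fir(rec, pp$low_hz, pp$high_hz,
                      pp$trans_low_hz, pp$trans_high_hz)

  cue_long <- extract_epochs(rec, events, "cue",
                             pp$cue_window_s[1], pp$cue_window_s[2])
  cue_long <- wcollect(reject_artifacts(cue_long, pp$p2p_threshold_uv,
                                        pp$min_per_condition))$epochs

  segs <- list()
  for (lk in c("cue", "go")) {
    ep <- extract_epochs(rec, events, lk,
                         pp$seg_window_s[1], pp$seg_window_s[2])
    ep <- wcollect(reject_artifacts(ep, pp$p2p_threshold_uv,
                                    pp$min_per_condition))$epochs
    segs[[lk]] <- baseline_correct(ep, pp$baseline_s)
  }

  measures <- list()
  for (lk in c("cue", "go"))
    for (cond in c("DS", "nDS")) {
      erp <- average_erp(segs[[lk]], cond)
      for (cd in comps)
        measures[[length(measures) + 1L]] <- measure_component(erp, cd)
    }

  # within-subject fast/slow trial contrast on the go segments
  tsplit <- tryCatch(
    wcollect(trial_sd_split(segs$go$rt_ms, segs$go$condition,
                            cfg$splits$trial_selector,
                            cfg$splits$sd_mult, cfg$splits$min_group)),
    error = function(e) NULL)
  trial_measures <- list()
  if (!is.null(tsplit)) {
    for (grp in c("F", "S")) {
      idx <- which(tsplit$membership == grp)
      if (length(idx) >= 2L) {
        sub <- select_trials(segs$go, idx)
        erp <- average_erp(sub, "all")
        erp$condition <- paste0("trial", grp)
        for (cd in comps)
          trial_measures[[length(trial_measures) + 1L]] <-
            measure_component(erp, cd)
      }
    }
  }

  cnv_rows <- list()
  cnv_waveforms <- list()
  for (cond in c("DS", "nDS", "all")) {
    cm <- extract_cnv(cue_long, cond, channel = cfg$cnv$channel,
                      baseline_s = cfg$cnv$baseline_s,
                      range_s = cfg$cnv$range_s)
    cnv_waveforms[[cond]] <- cm
    cnv_rows[[cond]] <- data.frame(
      subject = subject, condition = cond, n_trials = cm$n_trials,
      mean_uv = cnv_mean(cm, cfg$cnv$mean_window_ms),
      slope_uv_per_s = cnv_slope(cm, cfg$cnv$fit_window_ms),
      stringsAsFactors = FALSE)
  }

  go_rt <- events$response_time[events$trial_type == "go"]
  cue_lab <- events$trial_type[events$trial_type %in% CUE_LABELS]
  rt <- do.call(rbind, lapply(c("DS", "nDS", "all"), function(cond) {
    m <- mean_rt(go_rt, cue_lab, cond)
    data.frame(subject = subject, condition = cond, mean_rt_ms = m$mean_ms,
               n = m$n, n_missing = m$n_missing, stringsAsFactors = FALSE)
  }))

  list(
    subject = subject,
    measures = tidy_measures(c(measures, trial_measures), subject),
    cnv = do.call(rbind, cnv_rows),
    cnv_waveforms = cnv_waveforms,
    rt = rt,
    trial_split = tsplit,
    warnings = warnings,
    n_epochs = list(cue_long = n_trials(cue_long),
                    cue_seg = n_trials(segs$cue),
                    go_seg = n_trials(segs$go))
  )
}

.electrode_matrix <- function(measures, montage, lock, cond, comp) {
  rows <- measures[measures$lock == lock & measures$condition == cond &
                     measures$component == comp, , drop = FALSE]
  as.matrix(rows[, montage$name, drop = FALSE])
}

#' Run the full cohort pipeline
#'
#' Deterministic given `cfg$seed`: per-subject seeds are derived from it.
#' Writes, under `out_dir`: `measures.tsv`, `cnv.tsv`, `rt.tsv`, stat-map
#' tables for the DS-vs-nDS, fast/slow-subject and fast/slow-trial
#' contrasts, `splits/*.json`, `correlation.json` and `manifest.json`.
#'
#' @param cfg pipeline configuration (see [pipeline_config()]).
#' @param sim a `sim_config` used as the per-subject simulation template
#'   (its seed is overridden per subject).
#' @param out_dir output directory (created); `NULL` returns results only.
#' @return list with per-subject results, group-level stat maps, split
#'   results, latency tests and the CNV-RT correlation.
#' @export
run_pipeline <- function(cfg = pipeline_config(), sim = sim_config(),
                         out_dir = NULL) {
  if (!isTRUE(cfg$simulate$enabled))
    stop("run_pipeline currently drives the simulated cohort; preprocess ",
         "recorded data via analyze_subject()")
  nsub <- cfg$simulate$n_subjects
  comps <- component_definitions()
  montage <- sim$montage

  subjects <- vector("list", nsub)
  for (s in seq_len(nsub)) {
    sim_s <- sim
    sim_s$seed <- as.integer(cfg$seed * 1000L + s * 7L) %% .Machine$integer.max
    dat <- simulate_subject(sim_s)
    subjects[[s]] <- analyze_subject(dat$recording, dat$events, cfg, comps,
                                     subject = sprintf("sub%02d", s))
    subjects[[s]]$truth <- dat$truth
  }

  measures <- do.call(rbind, lapply(subjects, `[[`, "measures"))
  cnv <- do.call(rbind, lapply(subjects, `[[`, "cnv"))
  rt <- do.call(rbind, lapply(subjects, `[[`, "rt"))
  alpha <- cfg$stats$alpha

  # analysis 1: DS vs nDS, paired over subjects, per lock x component
  ds_nds <- list()
  latency_tests <- list()
  for (lk in c("cue", "go")) {
    maps <- list()
    for (cp in names(comps)) {
      a <- .electrode_matrix(measures, montage, lk, "DS", cp)
      b <- .electrode_matrix(measures, montage, lk, "nDS", cp)
      maps[[cp]] <- paired_t_map(a, b, contrast = paste0(lk, ":DS-nDS:", cp),
                                 alpha = alpha)
      la <- measures$latency_ms[measures$lock == lk &
                                  measures$condition == "DS" &
                                  measures$component == cp]
      lb <- measures$latency_ms[measures$lock == lk &
                                  measures$condition == "nDS" &
                                  measures$component == cp]
      latency_tests[[paste(lk, cp, sep = ":")]] <- c(
        list(lock = lk, component = cp),
        anova = latency_anova(list(la, lb))["p"],
        latency_homogeneity(la, lb))
    }
    ds_nds[[lk]] <- maps
  }

  # analysis 2: fast vs slow subjects (median split of DS / nDS mean RTs)
  subj_splits <- list()
  fs_subject <- list()
  for (cond in c("DS", "nDS")) {
    mr <- rt$mean_rt_ms[rt$condition == cond]
    names(mr) <- rt$subject[rt$condition == cond]
    sp <- subject_median_split(mr)
    subj_splits[[cond]] <- sp
    fsub <- names(sp$membership)[sp$membership == "F"]
    ssub <- names(sp$membership)[sp$membership == "S"]
    maps <- list()
    if (length(fsub) >= 2L && length(ssub) >= 2L) {
      for (cp in names(comps)) {
        gmat <- .electrode_matrix(measures, montage, "go", cond, cp)
        rownames(gmat) <- measures$subject[measures$lock == "go" &
                                             measures$condition == cond &
                                             measures$component == cp]
        maps[[cp]] <- unpaired_t_map(
          gmat[fsub, , drop = FALSE], gmat[ssub, , drop = FALSE],
          contrast = paste0("go:", cond, ":F-S:", cp), alpha = alpha,
          var_equal = cfg$stats$var_equal)
      }
    }
    fs_subject[[cond]] <- maps
  }

  # analysis 3: fast vs slow trials, paired over subjects
  fs_trial <- list()
  for (cp in names(comps)) {
    fa <- .electrode_matrix(measures, montage, "go", "trialF", cp)
    sa <- .electrode_matrix(measures, montage, "go", "trialS", cp)
    if (nrow(fa) == nrow(sa) && nrow(fa) >= 2L)
      fs_trial[[cp]] <- paired_t_map(fa, sa,
                                     contrast = paste0("go:trialF-S:", cp),
                                     alpha = alpha)
  }

  # analysis 4: CNV-RT correlation, all subjects together
  cnv_all <- cnv[cnv$condition == "all", ]
  rt_all <- rt[rt$condition == "all", ]
  corr <- pearson_corr(cnv_all$mean_uv[match(rt_all$subject,
                                             cnv_all$subject)],
                       rt_all$mean_rt_ms)

  res <- list(cfg = cfg, sim = sim, subjects = subjects,
              measures = measures, cnv = cnv, rt = rt,
              ds_nds = ds_nds, latency_tests = latency_tests,
              subject_splits = subj_splits, fs_subject = fs_subject,
              fs_trial = fs_trial, correlation = corr)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "splits"), showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(res$measures, "measures.tsv")
  tsv(res$cnv, "cnv.tsv")
  tsv(res$rt, "rt.tsv")
  for (lk in names(res$ds_nds))
    stat_table(res$ds_nds[[lk]],
               file.path(out_dir, paste0("stats_ds_nds_", lk, ".tsv")))
  for (cond in names(res$fs_subject))
    if (length(res$fs_subject[[cond]]))
      stat_table(res$fs_subject[[cond]],
                 file.path(out_dir, paste0("stats_fs_subjects_", cond, ".tsv")))
  if (length(res$fs_trial))
    stat_table(res$fs_trial, file.path(out_dir, "stats_fs_trials.tsv"))
  for (cond in names(res$subject_splits))
    write_split(res$subject_splits[[cond]],
                file.path(out_dir, "splits",
                          paste0("subject_split_", cond, ".json")))
  jsonlite::write_json(res$correlation,
                       file.path(out_dir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(res$cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("erpcnv")),
    r_version = R.version.string,
    seed = res$cfg$seed,
    n_subjects = length(res$subjects),
    config_md5 = unname(tools::md5sum(cfg_path)),
    warnings = unlist(lapply(res$subjects, `[[`, "warnings")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Plot CNV waveforms
#'
#' Line plot of one or more extracted CNV waveforms on a shared axis, with
#' the go stimulus marked at 2000 ms.
#'
#' @param measures named list of `cnv_measure`s.
#' @param path optional PNG output path.
#' @export
plot_cnv <- function(measures, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  rng <- range(unlist(lapply(measures, `[[`, "waveform")))
  graphics::plot(NULL, xlim = range(measures[[1]]$times), ylim = rng,
                 xlab = "time after cue (s)", ylab = "amplitude (uV)",
                 main = paste("CNV at", measures[[1]]$channel))
  cols <- seq_along(measures) + 1L
  for (i in seq_along(measures))
    graphics::lines(measures[[i]]$times, measures[[i]]$waveform,
                    col = cols[i], lwd = 2)
  graphics::abline(v = 2, lty = 2)
  graphics::legend("bottomleft", legend = names(measures), col = cols,
                   lwd = 2, bty = "n")
  invisible(NULL)
}

#' Plot an interpolated scalp map
#'
#' @param grid output of [interpolate_topography()].
#' @param montage optional montage whose electrode positions are overdrawn.
#' @param main plot title.
#' @param path optional PNG output path.
#' @export
plot_topography <- function(grid, montage = NULL, main = "", path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::image(grid$x, grid$y, t(grid$z), asp = 1, axes = FALSE,
                  xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  if (!is.null(montage))
    graphics::points(montage$x, montage$y, pch = 20, cex = 0.5)
  invisible(NULL)
}
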