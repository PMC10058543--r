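test_that("default task sequence emits the printed trial budget", {
  ev <- generate_task_sequence(sim_config(seed = 5))
  cues <- ev$trial_type[ev$trial_type != "go"]
  expect_equal(length(cues), 400L)
  expect_equal(sum(cues %in% c("S1", "S2", "S3", "S4")), 320L)
  expect_equal(sum(cues == "S5"), 80L)
  # equal split over the four directions
  expect_equal(unname(table(cues)[c("S1", "S2", "S3", "S4")]),
               rep(80L, 4), ignore_attr = TRUE)
  # every cue followed by exactly one go at the configured interval
  cue_on <- ev$onset[ev$trial_type != "go"]
  go_on <- ev$onset[ev$trial_type == "go"]
  expect_equal(go_on, cue_on + 2, tolerance = 1e-9)
})

test_that("task sequence is seed-deterministic and guards divisibility", {
  cfg <- test_sim_config(seed = 9)
  expect_identical(generate_task_sequence(cfg), generate_task_sequence(cfg))
  cfg2 <- test_sim_config(seed = 10)
  expect_false(identical(generate_task_sequence(cfg)$trial_type,
                         generate_task_sequence(cfg2)$trial_type))
  expect_error(sim_config(n_trials = 8, ds_nds_ratio = 0.8) |>
                 generate_task_sequence(), "divisible")
})

test_that("reaction-time generation follows the coupling model", {
  cfg <- test_sim_config(seed = 2)
  slopes <- rnorm(400, -4, 1.5)

  # decoupled: correlation vanishes within Monte-Carlo error
  cfg0 <- test_sim_config(rt_coupling_ms_per_uv = 0, seed = 2)
  r0 <- cor(slopes, generate_rts(cfg0, slopes)$rt_ms)
  expect_lt(abs(r0), 0.15)

  # noise-free limit: deterministic affine map, |r| = 1
  cfgd <- test_sim_config(rt_noise_sd_ms = 0, seed = 2)
  res <- generate_rts(cfgd, slopes)
  expect_equal(res$rt_ms, res$truth$rt_true)
  expect_equal(abs(cor(slopes, res$rt_ms)), 1, tolerance = 1e-12)

  # coupling recovery: regression of RT on true mean CNV value within 10%
  res2 <- generate_rts(cfg, slopes)
  beta <- coef(lm(res2$rt_ms ~ res2$truth$cnv_mean_true))[2]
  expect_lt(abs(beta - cfg$rt_coupling_ms_per_uv) /
              cfg$rt_coupling_ms_per_uv, 0.1)

  expect_error(generate_rts(test_sim_config(rt_noise_sd_ms = -1), slopes),
               "non-negative")
  # floor clips implausibly fast responses
  cfgf <- test_sim_config(rt_base_ms = 100, rt_noise_sd_ms = 0, seed = 2)
  expect_true(all(generate_rts(cfgf, slopes)$rt_ms >= cfgf$rt_floor_ms))
})

test_that("noise-free synthesis places components and the CNV ramp exactly", {
  mon <- test_montage()
  spec <- list(name = "P300", polarity = "positive", latency_ms = 300,
               width_ms = 30, amplitude_uv = 5, center = "CPz",
               profile_sigma = 0.4,
               condition_scaling = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1, S5 = 1))
  cfg <- sim_config(n_trials = 8, ds_nds_ratio = 0.5, montage = mon,
                    sfreq_hz = 500, component_specs = list(spec),
                    cnv_slope_mean_uv_per_s = -4, cnv_slope_sd = 0,
                    noise_white_sd_uv = 0, noise_pink_sd_uv = 0,
                    rt_noise_sd_ms = 0, seed = 4)
  sub <- simulate_subject(cfg)
  sf <- cfg$sfreq_hz
  ich <- match("CPz", mon$name)
  cues <- sub$events$onset[sub$events$trial_type != "go"]
  i300 <- round((cues[1] + 0.3) * sf) + 1L
  expect_equal(sub$recording$data[ich, i300], 5, tolerance = 1e-9)

  # linear ramp identity at Cz: go-onset value minus ramp-start value
  icz <- match("Cz", mon$name)
  i_start <- round((cues[1] + 0.5) * sf) + 1L
  i_go <- round((cues[1] + 2.0) * sf) + 1L
  drop_uv <- sub$recording$data[icz, i_go] - sub$recording$data[icz, i_start]
  expect_equal(drop_uv, -4 * 1.5, tolerance = 0.02)

  # linearity: doubling amplitude_uv doubles the noise-free peak
  spec2 <- spec
  spec2$amplitude_uv <- 10
  cfg2 <- cfg
  cfg2$component_specs <- list(spec2)
  sub2 <- simulate_subject(cfg2)
  expect_equal(sub2$recording$data[ich, i300], 10, tolerance = 1e-9)

  # seeded reproducibility is bit-exact
  sub3 <- simulate_subject(cfg)
  expect_identical(sub3$recording$data, sub$recording$data)
  expect_identical(sub3$truth, sub$truth)
})

test_that("spatial profile length mismatches are rejected", {
  spec <- list(name = "P300", polarity = "positive", latency_ms = 300,
               width_ms = 30, amplitude_uv = 5, profile = c(1, 0),
               condition_scaling = c(S1 = 1, S2 = 1, S3 = 1, S4 = 1, S5 = 1))
  expect_error(sim_config(montage = test_montage(),
                          component_specs = list(spec)), "profile length")
})

test_that("background noise reaches the configured white+pink level", {
  mon <- make_montage(c("Cz", "Pz", "Oz", "Fz"))
  cfg <- sim_config(n_trials = 8, ds_nds_ratio = 0.5, montage = mon,
                    sfreq_hz = 250, fixation_ms = 100000,
                    component_specs = list(), cnv_center = "Cz",
                    noise_white_sd_uv = 6, noise_pink_sd_uv = 8, seed = 6)
  sub <- simulate_subject(cfg)
  # the first fixation period is stimulus-free
  base <- sub$recording$data[, seq_len(95 * 250)]
  target <- sqrt(6^2 + 8^2)
  for (ch in seq_len(nrow(base)))
    expect_lt(abs(sd(base[ch, ]) - target) / target, 0.1)
})

test_that("subject-level CNV-RT cohorts reflect the configured coupling", {
  co <- simulate_cnv_rt_cohort(200, test_sim_config(seed = 12))
  expect_equal(nrow(co), 200L)
  r <- cor(co$cnv_mean_uv, co$rt_ms)
  expect_gt(r, 0.4)
  expect_lt(r, 0.8)
  # steeper (more negative) CNV goes with faster responses
  expect_gt(cor(co$cnv_slope, co$rt_ms), 0)
})
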