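one_ch_rec <- function(x, sfreq) {
  continuous_recording(matrix(x, nrow = 1), sfreq, make_montage("Cz"))
}

fft_amp <- function(x, sfreq, freq) {
  n <- length(x)
  sp <- abs(fft(x)) / n * 2
  sp[round(freq * n / sfreq) + 1]
}

test_that("resampling preserves duration, sample counts and amplitudes", {
  t <- seq(0, 10 - 1 / 1000, by = 1 / 1000)
  rec <- one_ch_rec(sin(2 * pi * 5 * t), 1000)
  out <- resample_recording(rec, 512)
  expect_equal(ncol(out$data), 5120L)
  expect_equal(out$sfreq, 512)
  expect_equal(recording_duration(out), recording_duration(rec),
               tolerance = 1 / 512)
  expect_equal(fft_amp(out$data[1, ], 512, 5), 1, tolerance = 0.01)
  # identity when target equals source
  expect_identical(resample_recording(rec, 1000)$data, rec$data)
  expect_error(resample_recording(rec, -5), "positive")
})

test_that("downsampling removes content above the new Nyquist", {
  set.seed(1)
  t <- seq(0, 4 - 1 / 1000, by = 1 / 1000)
  # 300 Hz tone would alias at 512 Hz (Nyquist 256); it must vanish
  rec <- one_ch_rec(sin(2 * pi * 300 * t), 1000)
  out <- resample_recording(rec, 512)
  expect_lt(sd(out$data[1, ]), 0.01)
})

test_that("zero-phase band-pass attenuates DC and stopband, passes passband", {
  sf <- 512
  t <- seq(0, 60 - 1 / sf, by = 1 / sf)
  x <- 10 + sin(2 * pi * 10 * t) + sin(2 * pi * 45 * t)
  out <- bandpass_fir(one_ch_rec(x, sf), 0.2, 30)
  mid <- out$data[1, (10 * sf):(50 * sf)]
  expect_lt(abs(mean(mid)), 0.5)                           # DC removed
  a10 <- fft_amp(out$data[1, ], sf, 10)
  expect_gt(a10, 0.95)
  expect_lt(a10, 1.05)                                      # passband ~ 1
  a45 <- fft_amp(out$data[1, ], sf, 45)
  expect_lt(a45, 0.1)                                       # >= 20 dB down
  # no phase shift: filtered 10 Hz tone stays aligned with the original
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_fir(one_ch_rec(x10, sf), 0.2, 30)$data[1, ]
  mid_idx <- (10 * sf):(50 * sf)
  expect_gt(cor(x10[mid_idx], y10[mid_idx]), 0.999)
})

test_that("filter length exceeding the signal raises a helpful error", {
  rec <- one_ch_rec(rnorm(1000), 512)  # ~2 s, far below the 0.2 Hz design
  expect_error(bandpass_fir(rec, 0.2, 30), "longer")
  expect_error(bandpass_fir(one_ch_rec(rnorm(30720), 512), 40, 30),
               "Nyquist|edges")
})

test_that("epoch extraction gives round((tmax-tmin)*sfreq) samples", {
  cfg <- test_sim_config(n_trials = 5, seed = 8, sfreq_hz = 512,
                         noise_white_sd_uv = 1, noise_pink_sd_uv = 0)
  sub <- simulate_subject(cfg)
  ep <- extract_epochs(sub$recording, sub$events, "cue", -1.5, 3.5)
  expect_equal(dim(ep$data)[3], 2560L)
  expect_equal(n_trials(ep), 5L)
  expect_equal(ep$times[1], -1.5)
  seg <- extract_epochs(sub$recording, sub$events, "cue", -0.1, 1.0)
  expect_equal(dim(seg$data)[3], round(1.1 * 512))
  # go-locked epochs inherit the cue condition and the response time
  go <- extract_epochs(sub$recording, sub$events, "go", -0.1, 1.0)
  expect_equal(go$condition, ep$condition)
  expect_false(anyNA(go$rt_ms))

  # an event too close to the recording start is dropped with a warning
  ev2 <- sub$events
  ev2$onset <- ev2$onset - ev2$onset[1] + 0.1
  expect_warning(ep2 <- extract_epochs(sub$recording, ev2, "cue", -1.5, 3.5),
                 "dropped")
  expect_equal(n_trials(ep2), 4L)
  expect_error(extract_epochs(sub$recording, sub$events, "cue", 1, 1))
})

test_that("peak-to-peak rejection removes exactly the contaminated epochs", {
  cfg <- test_sim_config(n_trials = 10, seed = 3,
                         noise_white_sd_uv = 2, noise_pink_sd_uv = 0)
  sub <- simulate_subject(cfg)
  ep <- extract_epochs(sub$recording, sub$events, "cue", -0.1, 1.0)
  clean <- suppressWarnings(reject_artifacts(ep, 100))
  expect_equal(n_trials(clean$epochs), 10L)

  spiked <- ep
  spiked$data[4, 2, 10] <- 500
  res <- suppressWarnings(reject_artifacts(spiked, 100))
  expect_equal(res$report$rejected_trials, 4L)
  expect_equal(n_trials(res$epochs), 9L)
  # few epochs per condition triggers the minimum-count guard
  expect_warning(reject_artifacts(ep, 100, min_per_condition = 60),
                 "fewer|minimum|60")
  expect_error(reject_artifacts(ep, -10), "positive")
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  mon <- test_montage()
  arr <- array(rnorm(6 * nrow(mon) * 55), c(6, nrow(mon), 55))
  ep <- epoch_set(arr, -0.1 + (0:54) / 100, rep("S1", 6), rep(NA_real_, 6),
                  100, mon)
  bc <- baseline_correct(ep, c(-0.1, 0))
  sel <- bc$times >= -0.1 & bc$times < 0
  expect_lt(max(abs(apply(bc$data[, , sel], c(1, 2), mean))), 1e-9)
  twice <- baseline_correct(bc, c(-0.1, 0))
  expect_equal(twice$data, bc$data, tolerance = 1e-12)
  # constant epochs become identically zero
  const <- epoch_set(array(7, c(2, nrow(mon), 55)), ep$times, rep("S1", 2),
                     rep(NA_real_, 2), 100, mon)
  expect_equal(max(abs(baseline_correct(const)$data)), 0)
  expect_error(baseline_correct(ep, c(5, 6)), "baseline")
})

test_that("rejection is deterministic and invariant to trial order", {
  cfg <- test_sim_config(n_trials = 10, seed = 17,
                         noise_white_sd_uv = 2, noise_pink_sd_uv = 0)
  sub <- simulate_subject(cfg)
  ep <- extract_epochs(sub$recording, sub$events, "cue", -0.1, 1.0)
  ep$data[3, 1, 5] <- 400
  ep$data[8, 4, 2] <- -400
  r1 <- suppressWarnings(reject_artifacts(ep, 100))
  r2 <- suppressWarnings(reject_artifacts(ep, 100))
  expect_identical(r1$report$rejected_trials, r2$report$rejected_trials)
  perm <- c(10:1)
  epp <- select_trials(ep, perm)
  rp <- suppressWarnings(reject_artifacts(epp, 100))
  expect_setequal(perm[rp$report$rejected_trials], r1$report$rejected_trials)
})
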