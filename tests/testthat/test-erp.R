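random_waveform <- function(mon, nsamp = 120, sfreq = 200) {
  structure(
    list(data = matrix(rnorm(nrow(mon) * nsamp), nrow(mon), nsamp),
         times = -0.1 + (seq_len(nsamp) - 1) / sfreq, sfreq = sfreq,
         montage = mon, condition = "DS", n_trials = 1L, lock = "cue"),
    class = "erp_waveform")
}

test_that("averaging pools the selected trials and keeps the bookkeeping", {
  mon <- test_montage()
  nsamp <- 40
  arr <- array(0, c(10, nrow(mon), nsamp))
  for (i in 1:10) arr[i, , ] <- i
  ep <- epoch_set(arr, (0:39) / 100, rep(c("S1", "S5"), 5),
                  rep(NA_real_, 10), 100, mon)
  # identical epochs average to any one of them
  same <- ep
  for (i in 1:10) same$data[i, , ] <- 3.5
  expect_equal(average_erp(same, "all")$data,
               matrix(3.5, nrow(mon), nsamp), ignore_attr = TRUE)
  # DS selector counts exactly the S1-S4 trials
  avg <- average_erp(ep, "DS")
  expect_equal(avg$n_trials, 5L)
  expect_equal(unique(as.vector(avg$data)), mean(c(1, 3, 5, 7, 9)))
  expect_error(average_erp(ep, "S3"), "S3")
})

test_that("averaging suppresses noise as 1/sqrt(n)", {
  mon <- make_montage(c("Cz", "Pz"))
  sfreq <- 100
  nsamp <- 100
  signal <- sin(2 * pi * 3 * (0:(nsamp - 1)) / sfreq)
  sigma <- 2
  set.seed(21)
  arr <- array(rnorm(100 * 2 * nsamp, sd = sigma), c(100, 2, nsamp))
  for (i in 1:100) arr[i, , ] <- arr[i, , ] + rep(signal, each = 2)
  ep <- epoch_set(arr, (0:(nsamp - 1)) / sfreq, rep("S1", 100),
                  rep(NA_real_, 100), sfreq, mon)
  resid <- average_erp(ep, "all")$data[1, ] - signal
  expect_lt(abs(sd(resid) - sigma / 10) / (sigma / 10), 0.2)
})

test_that("peak measurement equals the exhaustive scan oracle", {
  mon <- test_montage()
  defs <- component_definitions()
  set.seed(33)
  for (i in 1:200) {
    w <- random_waveform(mon)
    def <- defs[[sample(length(defs), 1)]]
    m <- measure_component(w, def)
    o <- oracle_peak(w$data, match(def$channels, mon$name), w$times * 1000,
                     def$window_ms, def$polarity)
    expect_equal(m$amplitude_uv, o$amplitude, tolerance = 1e-12)
    expect_equal(m$latency_ms, o$latency, tolerance = 1e-9)
  }
})

test_that("polarity symmetry and degenerate input behave as documented", {
  mon <- test_montage()
  sfreq <- 500
  times <- seq(-0.1, 0.999, by = 1 / sfreq)
  bump <- 5 * exp(-((times - 0.3)^2) / (2 * 0.03^2))
  w <- structure(list(data = matrix(rep(bump, each = nrow(mon)), nrow(mon)),
                      times = times, sfreq = sfreq, montage = mon,
                      condition = "DS", n_trials = 10L, lock = "cue"),
                 class = "erp_waveform")
  defs <- component_definitions()
  mp <- measure_component(w, defs$P300)
  expect_equal(mp$amplitude_uv, 5, tolerance = 1e-6)
  expect_equal(mp$latency_ms, 300, tolerance = 1000 / sfreq)
  wn <- w
  wn$data <- -w$data * 6 / 5
  # a negated bump inside the N200 window read with negative polarity
  defN <- defs$N200
  defN$window_ms <- c(250, 450)
  mn <- measure_component(wn, defN)
  expect_equal(mn$amplitude_uv, -6, tolerance = 1e-6)
  expect_equal(mn$latency_ms, mp$latency_ms)

  flat <- w
  flat$data[] <- 0
  mf <- measure_component(flat, defs$P300)
  expect_equal(mf$amplitude_uv, 0)
  expect_true(mf$low_prominence)
  expect_equal(mf$latency_ms, flat$times[which(flat$times * 1000 >= 250)[1]] * 1000)

  bad <- defs$P300
  bad$window_ms <- c(5000, 6000)
  expect_error(measure_component(w, bad), "window")
  bad2 <- defs$P300
  bad2$channels <- c("Cz", "QQ7")
  expect_error(measure_component(w, bad2), "QQ7")
})

test_that("raising an embedded amplitude never lowers the measured peak", {
  mon <- test_montage()
  base <- test_sim_config(n_trials = 5, noise_white_sd_uv = 0,
                          noise_pink_sd_uv = 0, cnv_slope_sd = 0,
                          rt_noise_sd_ms = 0, seed = 19)
  amps <- c(2, 4, 6, 8)
  got <- vapply(amps, function(a) {
    cfg <- base
    cfg$component_specs <- lapply(cfg$component_specs, function(sp) {
      if (sp$name == "P300") sp$amplitude_uv <- a
      sp
    })
    sub <- simulate_subject(cfg)
    ep <- baseline_correct(extract_epochs(sub$recording, sub$events,
                                          "cue", -0.1, 1.0))
    measure_component(average_erp(ep, "DS"),
                      component_definitions()$P300)$amplitude_uv
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("grand averaging is an unweighted mean invariant to subject order", {
  mon <- test_montage()
  set.seed(41)
  a <- random_waveform(mon)
  b <- random_waveform(mon)
  expect_equal(grand_average(list(a))$data, a$data)
  g <- grand_average(list(a, b))
  expect_equal(g$data, (a$data + b$data) / 2)
  expect_equal(g$n_subjects, 2L)
  expect_equal(grand_average(list(b, a))$data, g$data)
  mixed <- b
  mixed$times <- b$times + 0.01
  expect_error(grand_average(list(a, mixed)), "time axes")
})
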