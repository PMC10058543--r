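test_that("paired t maps detect shifts and honour the zero-variance rule", {
  mon <- test_montage()
  sim <- simulate_component_amplitudes(15, mon, noise_sd = 0.01, seed = 51)
  b <- sim$a + 5 + matrix(rnorm(length(sim$a), sd = 0.01), nrow(sim$a))
  m <- paired_t_map(sim$a, b)
  expect_equal(m$electrodes, mon$name)
  expect_true(all(m$p < 1e-6))
  expect_true(all(m$mask))
  expect_true(all(m$statistic < 0))

  same <- paired_t_map(sim$a, sim$a)
  expect_true(all(same$p == 1))
  expect_false(any(same$mask))
  expect_error(paired_t_map(sim$a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "two subjects")
})

test_that("unpaired t maps are antisymmetric and control the null rate", {
  mon <- test_montage()
  g <- simulate_component_amplitudes(20, mon, seed = 53)
  m1 <- unpaired_t_map(g$a[1:10, ], g$a[11:20, ])
  m2 <- unpaired_t_map(g$a[11:20, ], g$a[1:10, ])
  expect_equal(m1$statistic, -m2$statistic, tolerance = 1e-12)
  expect_equal(m1$p, m2$p, tolerance = 1e-12)

  # raw p < .05 fraction under the null across replicate maps
  ps <- unlist(lapply(1:120, function(i) {
    g <- simulate_component_amplitudes(12, mon, seed = 1000 + i)
    unpaired_t_map(g$a[1:6, ], g$a[7:12, ])$p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)

  # strong separation: 3 pooled SDs apart at n = 10 + 10
  hits <- vapply(1:100, function(i) {
    g <- simulate_component_amplitudes(20, mon, seed = 2000 + i)
    m <- unpaired_t_map(g$a[1:10, , drop = FALSE] + 3,
                        g$a[11:20, , drop = FALSE])
    mean(m$p < 0.01)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)

  expect_error(unpaired_t_map(g$a[1, , drop = FALSE], g$a[2:4, ]),
               "two subjects")
})

test_that("the BH step-up threshold matches hand enumeration", {
  # hand-worked example: thresholds k*alpha/m = .0125 .025 .0375 .05
  r <- fdr_threshold(c(0.001, 0.02, 0.03, 0.2), 0.05)
  expect_equal(r$adjusted_threshold, 0.03)
  expect_equal(sort(r$rejected), 1:3)

  r2 <- fdr_threshold(rep(0.5, 8))
  expect_true(is.na(r2$adjusted_threshold))
  expect_equal(r2$n_rejected, 0L)

  r3 <- fdr_threshold(0.01)
  expect_equal(r3$adjusted_threshold, 0.01)
  expect_equal(r3$rejected, 1L)

  expect_error(fdr_threshold(numeric(0)), "empty")
  expect_error(fdr_threshold(c(0.2, 1.2)), "0, 1")
})

test_that("BH-FDR equals the enumeration oracle and p.adjust on random input", {
  set.seed(57)
  for (i in 1:300) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)  # occasionally enriched near zero
    got <- fdr_threshold(p, 0.05)
    ora <- oracle_bh(p, 0.05)
    expect_identical(is.na(got$adjusted_threshold), is.na(ora$threshold))
    if (!is.na(ora$threshold))
      expect_equal(got$adjusted_threshold, ora$threshold)
    expect_equal(sort(got$rejected), sort(ora$rejected))
    # cross-check against the adjusted-p formulation
    expect_equal(sort(got$rejected),
                 which(p.adjust(p, "BH") <= 0.05 + 1e-12))
  }
})

test_that("latency ANOVA reduces to t^2 for two groups and scales up", {
  set.seed(59)
  a <- rnorm(12, 300, 20)
  b <- rnorm(12, 310, 20)
  res <- latency_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$F, unname(tt^2), tolerance = 1e-9)

  same <- latency_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  big <- latency_anova(list(rnorm(200, 300, 10), rnorm(200, 300, 10),
                            rnorm(200, 306, 10)))
  expect_lt(big$p, 0.01)
  expect_error(latency_anova(list(a)), "two groups")
  expect_error(latency_anova(list(a, 300)), "observations")
})

test_that("latency homogeneity flags incomparable conditions", {
  same <- latency_homogeneity(c(300, 305, 310), c(300, 305, 310))
  expect_equal(same$p, 1)
  expect_false(same$flag)
  set.seed(61)
  far <- latency_homogeneity(rnorm(10, 300, 5), rnorm(10, 400, 5))
  expect_lt(far$p, 1e-4)
  expect_true(far$flag)
  mild <- latency_homogeneity(c(1, 2, 3, 4), c(1.1, 2.1, 3.1, 4.1),
                              flag_level = 1e-6)
  expect_false(mild$flag)
})

test_that("pearson_corr matches the closed form and rejects degenerates", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  got <- pearson_corr(x, c(2, 1, 4, 3))
  ora <- oracle_pearson(x, c(2, 1, 4, 3))
  expect_equal(got$r, ora$r, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-9)
  set.seed(63)
  for (i in 1:25) {
    xx <- rnorm(10 + i)
    yy <- rnorm(10 + i) + 0.3 * xx
    g <- pearson_corr(xx, yy)
    o <- oracle_pearson(xx, yy)
    expect_equal(g$r, o$r, tolerance = 1e-12)
    expect_equal(g$p, o$p, tolerance = 1e-9)
  }
  expect_error(pearson_corr(x, rep(1, 4)), "variance")
  expect_error(pearson_corr(1:2, 1:2), "three")
  expect_error(pearson_corr(1:4, 1:5), "equal length")
})

test_that("significant electrodes concentrate on the embedded profile", {
  mon <- standard_montage()
  prof <- gaussian_profile(mon, "POz", 0.4)
  support <- prof > 0.25
  frac <- vapply(1:100, function(i) {
    g <- simulate_component_amplitudes(19, mon, effect_uv = 3,
                                       profile = prof, noise_sd = 1.5,
                                       seed = 3000 + i)
    m <- paired_t_map(g$b, g$a)
    if (!any(m$mask)) return(NA_real_)
    mean(support[m$mask])
  }, numeric(1))
  frac <- frac[!is.na(frac)]
  expect_gt(length(frac), 90)
  expect_gte(mean(frac), 0.8)
})

test_that("topographic interpolation is exact, masked and symmetric", {
  mon <- test_montage()
  vals <- stats::setNames(rep(2.5, nrow(mon)), mon$name)
  g <- interpolate_topography(vals, mon, grid_n = 41)
  inside <- !is.na(g$z)
  expect_true(all(abs(g$z[inside] - 2.5) < 1e-9))
  expect_true(any(!inside))  # corners are outside the disc

  one <- stats::setNames(rep(0, nrow(mon)), mon$name)
  one["O1"] <- 10
  g2 <- interpolate_topography(one, mon, grid_n = 61)
  peak <- which(g2$z == max(g2$z, na.rm = TRUE), arr.ind = TRUE)
  io1 <- match("O1", mon$name)
  expect_lt(abs(g2$x[peak[2]] - mon$x[io1]), 2 / 60)
  expect_lt(abs(g2$y[peak[1]] - mon$y[io1]), 2 / 60)

  # left-right mirrored input gives a mirrored map
  vals_lr <- stats::setNames(mon$x, mon$name)
  ga <- interpolate_topography(vals_lr, mon, grid_n = 41)
  gb <- interpolate_topography(unname(-vals_lr), mon, grid_n = 41)
  expect_equal(gb$z[, rev(seq_len(41))], ga$z, tolerance = 1e-9)

  expect_error(interpolate_topography(c(a = 1, b = 2), mon[1:2, ]), "three")
  dup <- mon
  dup$x[2] <- dup$x[1]; dup$y[2] <- dup$y[1]
  expect_error(interpolate_topography(vals, dup), "coincident")
})
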