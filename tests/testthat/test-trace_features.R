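test_that("normalize_trace divides by the pre-stimulus baseline", {
  t <- seq(0, 60, by = 0.5)
  # constant trace: response identically 0
  tr <- calcium_trace(t, rep(50, length(t)), stimulus_time = 10)
  nt <- normalize_trace(tr)
  expect_equal(nt$baseline_f0, 50)
  expect_true(all(abs(nt$response) < 1e-12))
  # doubling from baseline: peak response 1.0
  f <- rep(30, length(t)); f[t >= 20 & t <= 25] <- 60
  nt2 <- normalize_trace(calcium_trace(t, f, stimulus_time = 10))
  expect_equal(peak_amplitude(nt2), 1.0)
  # baseline 40, peak 100 -> amplitude 1.5
  f3 <- rep(40, length(t)); f3[t == 30] <- 100
  nt3 <- normalize_trace(calcium_trace(t, f3, stimulus_time = 10))
  expect_equal(peak_amplitude(nt3), 1.5)
})

test_that("trace construction and normalization validate their inputs", {
  t <- seq(0, 60, by = 0.5)
  expect_error(calcium_trace(t, rep(-1, length(t)), 10),
               class = "p2e_data_error")
  expect_error(calcium_trace(t[1:10], rep(1, 9), 5), class = "p2e_data_error")
  expect_error(calcium_trace(c(0, 1, 1, 2), rep(1, 4), 1.5),
               class = "p2e_data_error")
  tr <- calcium_trace(t, rep(50, length(t)), stimulus_time = 10)
  expect_error(normalize_trace(tr, baseline_window = 0.2),
               class = "p2e_data_error")
})

test_that("peak_amplitude takes the post-stimulus global maximum", {
  t <- seq(0, 60, by = 0.5)
  y <- rep(0, length(t))
  y[t >= 15 & t <= 20] <- 0.5
  y[t >= 35 & t <= 40] <- 0.9
  nt <- structure(list(time = t, response = y, baseline_f0 = 50,
                       stimulus_time = 10), class = "normalized_trace")
  expect_equal(peak_amplitude(nt), 0.9)
  nt$response <- rep(0, length(t))
  expect_equal(peak_amplitude(nt), 0)
})

test_that("width_at_half_max matches closed forms", {
  # symmetric triangle, base 20 s, peak 1.0 -> FWHM 10 s
  tri <- normalize_trace(make_triangle_trace(amp = 1, base_s = 20))
  w <- width_at_half_max(tri)
  expect_equal(w$duration, 10, tolerance = 1e-9)
  expect_false(w$truncated)
  # Gaussian pulse sigma = 4 -> FWHM 2 sqrt(2 ln 2) sigma = 9.4187 s
  g <- normalize_trace(make_gaussian_trace(sigma = 4))
  wg <- width_at_half_max(g)
  expect_equal(wg$duration, 2 * sqrt(2 * log(2)) * 4, tolerance = 0.01)
  # plateau that never decays: width to trace end, truncated
  t <- seq(0, 60, by = 0.5)
  f <- rep(40, length(t)); f[t >= 20] <- 80
  pl <- normalize_trace(calcium_trace(t, f, stimulus_time = 10))
  wp <- width_at_half_max(pl)
  expect_true(wp$truncated)
  expect_equal(wp$duration, 60 - 19.75, tolerance = 1e-9)
  # zero peak -> undefined width
  flat <- normalize_trace(calcium_trace(t, rep(50, length(t)), 10))
  expect_error(width_at_half_max(flat), class = "p2e_data_error")
})

test_that("area_under_curve is the trapezoidal integral after stimulus", {
  t <- seq(0, 70, by = 0.5)
  # flat -> 0
  flat <- normalize_trace(calcium_trace(t, rep(50, length(t)), 10))
  expect_equal(area_under_curve(flat), 0, tolerance = 1e-12)
  # rectangle height 1.0 spanning 60 s (ramp edges contribute half a
  # sample each); closed form 60 within 0.5%
  f <- rep(30, length(t)); f[t >= 10 & t <= 70] <- 60
  rect <- normalize_trace(calcium_trace(t, f, stimulus_time = 10))
  expect_equal(area_under_curve(rect), 60, tolerance = 0.005)
  # triangle height 1.0, base 20 s -> area 10 (exact for piecewise-linear)
  tri <- normalize_trace(make_triangle_trace(amp = 1, base_s = 20))
  expect_equal(area_under_curve(tri), 10, tolerance = 1e-9)
  # negative excursions are included, not clipped
  f2 <- rep(50, length(t)); f2[t >= 20 & t < 30] <- 25
  dip <- normalize_trace(calcium_trace(t, f2, stimulus_time = 10))
  expect_lt(area_under_curve(dip), 0)
})

test_that("features are invariant to fluorescence scale and sampling", {
  tr <- make_gaussian_trace(amp = 1.2, sigma = 5)
  f1 <- trace_features(tr)
  for (c_scale in c(0.1, 3, 40)) {
    tr2 <- calcium_trace(tr$time, tr$fluorescence * c_scale,
                         tr$stimulus_time, concentration = tr$concentration)
    f2 <- trace_features(tr2)
    expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-10)
    expect_equal(f2$duration_s, f1$duration_s, tolerance = 1e-10)
    expect_equal(f2$auc, f1$auc, tolerance = 1e-10)
  }
  # resampling a smooth trace at 0.25 vs 0.5 s changes FWHM and AUC < 2%
  mk <- function(dt) {
    t <- seq(0, 60, by = dt)
    f <- 50 * (1 + exp(-(t - 30)^2 / (2 * 4^2)))
    trace_features(calcium_trace(t, f, stimulus_time = 10))
  }
  fa <- mk(0.5); fb <- mk(0.25)
  expect_lt(abs(fa$duration_s - fb$duration_s) / fb$duration_s, 0.02)
  expect_lt(abs(fa$auc - fb$auc) / abs(fb$auc), 0.02)
})

test_that("remove_outliers implements a single mean +/- 2 SD pass", {
  # spec fixture: brute-force oracle shows 100 is INSIDE the 2 SD band
  # (mean 20.8, sd 44.27, upper bound 109.3), so nothing is removed
  r <- remove_outliers(c(1, 1, 1, 1, 100))
  expect_identical(r$removed, oracle_outliers(c(1, 1, 1, 1, 100)))
  expect_length(r$removed, 0L)
  # identical values: SD 0, all at mean, none removed
  expect_length(remove_outliers(rep(2, 5))$removed, 0L)
  # symmetric small set: all within 2 SD
  expect_length(remove_outliers(c(-1, 0, 1))$removed, 0L)
  # too few values: no-op with warning flag
  r2 <- remove_outliers(c(1, 2))
  expect_true(r2$warning)
  expect_identical(r2$kept, c(1, 2))
  # oracle equivalence on 1000 random sets
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    v <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
    if (runif(1) < 0.3) v[sample(n, 1)] <- v[1] + 20
    r <- remove_outliers(v)
    expect_identical(r$removed, oracle_outliers(v))
    expect_identical(r$kept, v[setdiff(seq_len(n), r$removed)])
  }
})

test_that("summarize_condition normalizes per experiment per metric", {
  mk <- function(eid, conc, amps) {
    data.frame(experiment_id = eid, cell_id = paste0(eid, seq_along(amps)),
               concentration_M = conc, amplitude = amps,
               duration_s = amps * 10, auc = amps * 5)
  }
  feats <- rbind(mk("e1", 1e-8, c(2, 2, 2)), mk("e1", 1e-7, c(4, 4, 4)),
                 mk("e1", 1e-6, c(8, 8, 8)), mk("e2", 1e-8, c(1, 1, 1)),
                 mk("e2", 1e-7, c(5, 5, 5)))
  s <- summarize_condition(feats, normalize_within_experiment = TRUE)
  a1 <- s[s$experiment_id == "e1" & s$metric == "amplitude", ]
  expect_equal(a1$mean[order(a1$concentration_M)], c(0.25, 0.5, 1.0))
  # every experiment x metric has exactly max 1
  for (e in c("e1", "e2")) {
    for (m in unique(s$metric)) {
      expect_equal(max(s$mean[s$experiment_id == e & s$metric == m]), 1)
    }
  }
  # flag off: unscaled means
  s0 <- summarize_condition(feats, normalize_within_experiment = FALSE)
  expect_equal(max(s0$mean[s0$experiment_id == "e1" &
                             s0$metric == "amplitude"]), 8)
  # sem = sd / sqrt(n)
  expect_equal(s0$sem, s0$sd / sqrt(s0$n))
})

test_that("outlier removal happens before normalization in summaries", {
  feats <- data.frame(
    experiment_id = "e1",
    cell_id = paste0("c", 1:22),
    concentration_M = rep(c(1e-8, 1e-6), each = 11),
    amplitude = c(rep(1, 10), 30, rep(2, 11)),  # one far outlier at 1e-8
    duration_s = 10, auc = 5)
  s <- summarize_condition(feats, normalize_within_experiment = FALSE)
  a <- s[s$metric == "amplitude" & s$concentration_M == 1e-8, ]
  expect_equal(a$n_outliers_removed, 1L)
  expect_equal(a$mean, 1)  # the 30 was dropped before averaging
})

test_that("amplitude_duration_relation fits r and the exponential law", {
  # perfectly anti-correlated linear data
  amp <- seq(0.1, 2, length.out = 20)
  f <- data.frame(amplitude = amp, duration_s = 50 - 20 * amp)
  expect_equal(amplitude_duration_relation(f)$r, -1, tolerance = 1e-12)
  # exact exponential recovery: duration = 30 exp(-2 amplitude)
  f2 <- data.frame(amplitude = amp, duration_s = 30 * exp(-2 * amp))
  rel <- amplitude_duration_relation(f2)
  expect_equal(rel$a, 30, tolerance = 1e-6)
  expect_equal(rel$b, -2, tolerance = 1e-6)
  # independent data: |r| small at n = 500
  set.seed(3)
  f3 <- data.frame(amplitude = runif(500, 0.1, 2),
                   duration_s = runif(500, 5, 50))
  expect_lt(abs(amplitude_duration_relation(f3)$r), 0.15)
  # degenerate variance
  f4 <- data.frame(amplitude = rep(1, 5), duration_s = 1:5)
  expect_error(amplitude_duration_relation(f4), class = "p2e_data_error")
})
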