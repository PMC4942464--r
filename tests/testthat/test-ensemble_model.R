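test_that("ensemble_response reduces to its parts", {
  b1 <- basis_set("P2Y1", "rodent")
  m1 <- ensemble_model(b1, 1)
  L <- 10^seq(-9, -3, length.out = 13)
  expect_equal(ensemble_response(L, m1),
               hill_response(L, b1$k_half_M, b1$hill), tolerance = 1e-12)
  # all-zero coefficients with an offset: constant
  b3 <- basis_set(c("P2Y1", "P2Y4", "P2X7"), "rodent")
  m0 <- ensemble_model(b3, c(0, 0, 0), offset = 0.3)
  expect_equal(ensemble_response(L, m0), rep(0.3, length(L)))
  # signed three-receptor combination at 1e-2 M (closed-form oracle)
  m <- ensemble_model(b3, c(1.8, -1.4, 0.6))
  want <- 1.8 * oracle_hill(1e-2, 3e-7, 0.5) -
    1.4 * oracle_hill(1e-2, 1.2e-6, 1.0) +
    0.6 * oracle_hill(1e-2, 1.3e-4, 2.2)
  expect_equal(ensemble_response(1e-2, m), want, tolerance = 1e-12)
  expect_equal(ensemble_response(1e-2, m), 1.0, tolerance = 0.02)
})

test_that("superposition: concatenated bases add their responses", {
  L <- 10^seq(-8, -3, length.out = 9)
  ba <- basis_set(c("P2Y1", "P2Y2"), "rodent")
  bb <- basis_set(c("P2X7"), "rodent")
  bab <- basis_set(c("P2Y1", "P2Y2", "P2X7"), "rodent")
  ra <- ensemble_response(L, ensemble_model(ba, c(1.1, -0.4)))
  rb <- ensemble_response(L, ensemble_model(bb, 0.7))
  rab <- ensemble_response(L, ensemble_model(bab, c(1.1, -0.4, 0.7)))
  expect_equal(rab, ra + rb, tolerance = 1e-12)
})

test_that("fit_linear_combination solves least squares with signed weights", {
  bs <- basis_set(c("P2Y1", "P2Y4"), "rodent")
  L <- 10^seq(-9, -7, length.out = 7)
  truth <- c(7, -25)
  pts <- data.frame(concentration = L,
                    response = drop(evaluate_basis(bs, L) %*% truth))
  fit <- fit_linear_combination(pts, bs)
  expect_equal(unname(fit$coefficients), truth, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # single-receptor data on its own basis: a = 1, R^2 = 1
  b1 <- basis_set("P2Y1", "rodent")
  pts1 <- data.frame(concentration = L,
                     response = hill_response(L, b1$k_half_M, b1$hill))
  f1 <- fit_linear_combination(pts1, b1)
  expect_equal(unname(f1$coefficients), 1, tolerance = 1e-10)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
})

test_that("rank-deficient and underdetermined designs raise typed errors", {
  bs <- basis_set(c("P2Y1", "P2Y4"), "rodent")
  # identical columns via two concentrations equal at machine level:
  # duplicate members are already blocked upstream, so emulate collinearity
  # with more parameters than points
  one <- data.frame(concentration = 1e-7, response = 0.5)
  expect_error(fit_linear_combination(one, bs), class = "p2e_data_error")
  # duplicated basis members are blocked at construction; forcing two
  # identical rows past the constructor must hit the rank check
  dup <- bs[c(1L, 1L), ]
  class(dup) <- c("basis_set", "data.frame")
  pts <- data.frame(concentration = 10^seq(-9, -6, length.out = 6),
                    response = rnorm(6))
  err <- tryCatch(fit_linear_combination(pts, dup), error = identity)
  expect_s3_class(err, "p2e_collinear_error")
  expect_match(conditionMessage(err), "collinear")
  # repeated concentrations can also exhaust the design's rank
  pts2 <- data.frame(concentration = c(1e-7, 1e-7, 1e-5, 1e-5, 1e-7),
                     response = rnorm(5))
  err2 <- tryCatch(
    fit_linear_combination(pts2, basis_set(c("P2Y1", "P2Y4", "P2X7"),
                                           "rodent")),
    error = identity)
  expect_s3_class(err2, "p2e_collinear_error")
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(21)
  pool <- c("P2Y1", "P2Y2", "P2Y4", "P2X2", "P2X5", "P2X7")
  for (i in 1:20) {
    k <- sample(2:4, 1)
    bs <- basis_set(sample(pool, k), "rodent")
    L <- 10^seq(runif(1, -9.5, -8.5), runif(1, -3.5, -2.5),
                length.out = sample(8:14, 1))
    X <- evaluate_basis(bs, L)
    if (kappa(crossprod(X)) > 1e6) next
    y <- rnorm(length(L))
    fit <- fit_linear_combination(data.frame(concentration = L, response = y),
                                  bs)
    expect_equal(unname(fit$coefficients), oracle_normal_equations(X, y),
                 tolerance = 1e-10)
  }
})

test_that("drop_top_concentration excludes the highest dose", {
  bs <- basis_set(c("P2Y1", "P2Y4"), "rodent")
  L <- 10^seq(-9, -2, length.out = 8)
  y <- drop(evaluate_basis(bs, L) %*% c(2, -1))
  y[8] <- y[8] - 0.5  # corrupt the top dose
  pts <- data.frame(concentration = L, response = y)
  fit <- fit_linear_combination(pts, bs, drop_top_concentration = TRUE)
  expect_equal(fit$n_points, 7L)
  expect_equal(unname(fit$coefficients), c(2, -1), tolerance = 1e-9)
})

test_that("compare_models ranks by R^2 and tolerates failures", {
  bs2 <- basis_set(c("P2Y1", "P2Y4"), "rodent")
  bs1 <- basis_set("P2Y1", "rodent")
  L <- 10^seq(-9, -7, length.out = 7)
  set.seed(5)
  pts <- generate_dose_response(ensemble_model(bs2, c(7, -25)), L,
                                noise_sd = 0.05, seed = 17)
  cmp <- compare_models(pts, list(two = bs2, one_off = bs1),
                        include_offset = c(FALSE, TRUE))
  expect_identical(cmp$ranking$label[1], "two")
  expect_true(all(diff(cmp$ranking$r_squared) <= 0))
  # single candidate comes back as rank 1
  cmp1 <- compare_models(pts, list(bs1), include_offset = TRUE)
  expect_equal(cmp1$ranking$rank, 1L)
  # per-candidate failure recorded, not fatal
  few <- pts[1:2, ]
  cmp2 <- compare_models(few, list(big = basis_set(c("P2Y1", "P2Y2", "P2Y4"),
                                                   "rodent"), one = bs1))
  expect_true(any(!is.na(cmp2$ranking$error)))
  expect_true(any(is.na(cmp2$ranking$error)))
})

test_that("find_landmarks labels peaks, troughs and flanks", {
  x <- 10^c(-8, -7, -6, -5, -4)
  lms <- find_landmarks(data.frame(concentration = x,
                                   response = c(0.2, 0.8, 0.3, 0.9, 0.4)))
  expect_equal(lms$n_peaks, 2L)
  expect_equal(lms$landmarks$first_peak$concentration, 1e-7)
  expect_equal(lms$landmarks$trough$concentration, 1e-6)
  expect_equal(lms$landmarks$second_peak$concentration, 1e-5)
  expect_equal(lms$landmarks$initial_low$amplitude, 0.2)
  expect_equal(lms$landmarks$post_trough$amplitude, 0.4)
  # strictly increasing curve: no-peak result, not an error
  mono <- find_landmarks(data.frame(concentration = x,
                                    response = c(0.1, 0.2, 0.4, 0.7, 0.9)))
  expect_equal(mono$n_peaks, 0L)
  # one-peak variant
  one <- find_landmarks(data.frame(concentration = x,
                                   response = c(0.1, 0.3, 0.9, 0.5, 0.2)))
  expect_equal(one$n_peaks, 1L)
  expect_named(one$landmarks, c("initial_low", "first_peak", "post_trough"))
  # vehicle rows are ignored; input order does not matter
  shuf <- data.frame(concentration = c(0, x), response = c(9, 0.2, 0.8, 0.3, 0.9, 0.4))
  shuf <- shuf[sample(nrow(shuf)), ]
  lms2 <- find_landmarks(shuf)
  expect_equal(lms2$landmarks, lms$landmarks)
})

test_that("find_landmarks treats plateaus as one peak at their start", {
  x <- 10^seq(-8, -2, length.out = 7)
  y <- c(0.1, 0.6, 0.6, 0.2, 0.8, 0.3, 0.1)
  lms <- find_landmarks(data.frame(concentration = x, response = y))
  expect_equal(lms$n_peaks, 2L)
  expect_equal(lms$landmarks$first_peak$concentration, x[2])
})

test_that("the default two-peak generating model is detected on the grid", {
  amp <- two_peak_amplitude_model()
  grid <- 10^seq(-9, -2, length.out = 11)
  lms <- find_landmarks(data.frame(concentration = grid,
                                   response = amp(grid)))
  expect_equal(lms$n_peaks, 2L)
  expect_lt(lms$landmarks$first_peak$concentration, 1e-6)
  expect_gt(lms$landmarks$second_peak$concentration, 1e-4)
  expect_false(lms$post_trough_at_end)
})

test_that("ensemble model JSON serialization round-trips the essentials", {
  bs <- basis_set(c("P2Y1", "P2Y4"), "rodent")
  L <- 10^seq(-9, -7, length.out = 7)
  pts <- data.frame(concentration = L,
                    response = drop(evaluate_basis(bs, L) %*% c(7, -25)))
  fit <- fit_linear_combination(pts, bs)
  path <- withr::local_tempfile(fileext = ".json")
  ensemble_model_json(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$coefficients$P2Y1, 7, tolerance = 1e-9)
  expect_equal(back$coefficients$P2Y4, -25, tolerance = 1e-9)
  expect_equal(back$r_squared, 1, tolerance = 1e-12)
})
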