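# Independent oracles and shared fixtures, built in code at test time.

# brute-force mean +/- 2 SD outlier rule, deliberately naive
oracle_outliers <- function(values) {
  m <- sum(values) / length(values)
  s <- sqrt(sum((values - m)^2) / (length(values) - 1))
  removed <- integer(0)
  for (i in seq_along(values)) {
    if (values[i] < m - 2 * s || values[i] > m + 2 * s) {
      removed <- c(removed, i)
    }
  }
  removed
}

# closed-form normal-equations least squares
oracle_normal_equations <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# direct evaluation of the Hill closed form (no shared code path with
# hill_response, which works via exp/log)
oracle_hill <- function(L, K, h) ifelse(L == 0, 0, L^h / (K^h + L^h))

# flat-baseline trace with a Gaussian-shaped calcium transient
make_gaussian_trace <- function(amp = 1, sigma = 4, center = 30, f0 = 50,
                                stim = 10, dt = 0.5, t_end = 60) {
  t <- seq(0, t_end, by = dt)
  f <- f0 * (1 + amp * exp(-(t - center)^2 / (2 * sigma^2)))
  calcium_trace(t, f, stimulus_time = stim, concentration = 1e-6)
}

# triangular pulse trace: linear rise/fall, peak `amp`, base width `base_s`
make_triangle_trace <- function(amp = 1, base_s = 20, start = 10, f0 = 40,
                                stim = 10, dt = 0.5, t_end = 60) {
  t <- seq(0, t_end, by = dt)
  half <- base_s / 2
  y <- pmax(0, 1 - abs(t - (start + half)) / half) * amp
  calcium_trace(t, f0 * (1 + y), stimulus_time = stim,
                concentration = 1e-6)
}

# small shared synthetic dataset for module-level pipeline tests (the
# full-size default config is exercised in test-acceptance.R)
small_sim_config <- function(seed = 11L, ...) {
  simulation_config(seed = seed, n_experiments = 2L,
                    cells_per_condition = c(8L, 12L),
                    trace_duration = 120, ...)
}

.shared_env <- new.env(parent = emptyenv())

shared_small_dataset <- function() {
  if (is.null(.shared_env$ds)) {
    .shared_env$ds <- generate_experiment_set(small_sim_config())
  }
  .shared_env$ds
}
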