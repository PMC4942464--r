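#' Construct a single-cell calcium trace
#'
#' One cell's raw fluo-4 fluorescence time series with stimulus metadata.
#' Time must be uniformly sampled (default acquisition every 0.5 s) and at
#' least two samples must precede the stimulus so a baseline exists.
#'
#' @param time numeric vector of seconds, strictly increasing, uniform step.
#' @param fluorescence raw fluorescence (FU), positive, same length as `time`.
#' @param stimulus_time agonist application time (s).
#' @param cell_id,experiment_id identifiers.
#' @param concentration ATP concentration (molar; 0 for vehicle).
#' @return an object of class `calcium_trace`.
#' @export
calcium_trace <- function(time, fluorescence, stimulus_time,
                          cell_id = "cell1", experiment_id = "exp1",
                          concentration = 0) {
  if (length(time) != length(fluorescence) || length(time) < 4L) {
    abort_data("time and fluorescence must have equal length >= 4")
  }
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort_data("time must be strictly increasing with uniform step")
  }
  if (sum(time < stimulus_time) < 2L) {
    abort_data("need >= 2 samples before stimulus_time")
  }
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0)) {
    abort_data("fluorescence must be finite and > 0")
  }
  structure(list(time = time, fluorescence = fluorescence,
                 stimulus_time = stimulus_time, cell_id = cell_id,
                 experiment_id = experiment_id,
                 concentration = concentration),
            class = "calcium_trace")
}

#' Baseline-normalize a calcium trace
#'
#' Computes the baseline F0 as the mean fluorescence over the
#' `baseline_window` seconds preceding the stimulus and returns the
#' normalized response (F/F0) - 1, which is ~0 over the baseline and
#' dimensionless thereafter (so any multiplicative scale on F cancels).
#'
#' @param trace a `calcium_trace`.
#' @param baseline_window seconds before `stimulus_time` used for F0
#'   (default 5 s); must contain >= 2 samples.
#' @return an object of class `normalized_trace` with fields `time`,
#'   `response`, `baseline_f0`, `stimulus_time` and the trace metadata.
#' @export
normalize_trace <- function(trace, baseline_window = 5) {
  stopifnot(inherits(trace, "calcium_trace"))
  in_win <- trace$time < trace$stimulus_time &
    trace$time >= trace$stimulus_time - baseline_window
  if (sum(in_win) < 2L) {
    abort_data("baseline window must contain >= 2 pre-stimulus samples")
  }
  f0 <- mean(trace$fluorescence[in_win])
  if (!is.finite(f0) || f0 <= 0) abort_data("baseline F0 must be > 0")
  structure(list(time = trace$time,
                 response = trace$fluorescence / f0 - 1,
                 baseline_f0 = f0,
                 stimulus_time = trace$stimulus_time,
                 cell_id = trace$cell_id,
                 experiment_id = trace$experiment_id,
                 concentration = trace$concentration),
            class = "normalized_trace")
}

#' Peak amplitude of a normalized trace
#'
#' The maximal rise, max of (F/F0) - 1 over the post-stimulus interval.
#'
#' @param trace a `normalized_trace`.
#' @return scalar amplitude (dimensionless).
#' @export
peak_amplitude <- function(trace) {
  stopifnot(inherits(trace, "normalized_trace"))
  post <- trace$time >= trace$stimulus_time
  if (!any(post)) abort_data("no post-stimulus samples")
  max(trace$response[post])
}

#' Width at half maximum (response duration)
#'
#' Duration of the calcium response: the time between the first upward
#' crossing of half the peak before the peak and the first downward crossing
#' after it, each located by linear interpolation between adjacent samples.
#' If the response never falls back below half-max (e.g. prolonged
#' P2X7-type responses), the width runs to the end of the trace and
#' `truncated = TRUE`.
#'
#' @param trace a `normalized_trace` with positive peak.
#' @return list with `duration` (s) and `truncated` (logical).
#' @export
width_at_half_max <- function(trace) {
  stopifnot(inherits(trace, "normalized_trace"))
  post <- which(trace$time >= trace$stimulus_time)
  if (!length(post)) abort_data("no post-stimulus samples")
  t <- trace$time[post]
  y <- trace$response[post]
  ipk <- which.max(y)
  peak <- y[ipk]
  if (peak <= 0) abort_data("width undefined: peak amplitude is not positive")
  half <- peak / 2

  cross_at <- function(i, j) {
    # linear interpolation of the time where y crosses `half` between i and j
    t[i] + (half - y[i]) * (t[j] - t[i]) / (y[j] - y[i])
  }
  # first upward crossing before the peak
  t_up <- t[1L]
  if (y[1L] < half) {
    ups <- which(y[seq_len(ipk - 1L)] < half & y[2:ipk] >= half)
    i <- ups[1L]
    t_up <- cross_at(i, i + 1L)
  }
  # first downward crossing after the peak
  n <- length(y)
  truncated <- TRUE
  t_down <- t[n]
  if (ipk < n) {
    downs <- which(y[ipk:(n - 1L)] >= half & y[(ipk + 1L):n] < half)
    if (length(downs)) {
      i <- ipk + downs[1L] - 1L
      t_down <- cross_at(i, i + 1L)
      truncated <- FALSE
    }
  }
  list(duration = t_down - t_up, truncated = truncated)
}

#' Area under the normalized response curve
#'
#' Trapezoidal integral of (F/F0) - 1 from the stimulus time to the end of
#' the trace; negative excursions are included, not clipped. A proxy for the
#' total calcium released over time.
#'
#' @param trace a `normalized_trace`.
#' @return scalar area (dimensionless x seconds).
#' @export
area_under_curve <- function(trace) {
  stopifnot(inherits(trace, "normalized_trace"))
  post <- trace$time >= trace$stimulus_time
  if (!any(post)) abort_data("no post-stimulus samples")
  t <- trace$time[post]
  y <- trace$response[post]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Extract amplitude, duration and AUC features from one trace
#'
#' @param trace a `calcium_trace` or `normalized_trace`.
#' @param baseline_window passed to [normalize_trace()] for raw traces.
#' @return one-row data frame: `experiment_id`, `cell_id`,
#'   `concentration_M`, `amplitude`, `duration_s`, `auc`, `truncated`.
#'   Duration is `NA` (truncated `NA`) when the peak is not positive.
#' @export
trace_features <- function(trace, baseline_window = 5) {
  if (inherits(trace, "calcium_trace")) {
    trace <- normalize_trace(trace, baseline_window)
  }
  stopifnot(inherits(trace, "normalized_trace"))
  amp <- peak_amplitude(trace)
  if (amp > 0) {
    w <- width_at_half_max(trace)
    dur <- w$duration; trunc <- w$truncated
  } else {
    dur <- NA_real_; trunc <- NA
  }
  data.frame(experiment_id = trace$experiment_id,
             cell_id = trace$cell_id,
             concentration_M = trace$concentration,
             amplitude = amp,
             duration_s = dur,
             auc = area_under_curve(trace),
             truncated = trunc,
             stringsAsFactors = FALSE)
}

#' Remove outliers by the mean +/- 2 SD rule
#'
#' Single deterministic pass: values strictly outside
#' \[mean - 2 SD, mean + 2 SD\] of the whole input are dropped. With fewer
#' than 3 values the rule is a no-op (flagged by a warning attribute).
#'
#' @param values numeric vector.
#' @return list with `kept` (values retained), `removed` (integer indices of
#'   dropped values) and `warning` (TRUE when the input was too small to
#'   apply the rule).
#' @export
remove_outliers <- function(values) {
  if (!is.numeric(values)) abort_data("`values` must be numeric")
  if (length(values) < 3L) {
    return(list(kept = values, removed = integer(0), warning = TRUE))
  }
  m <- mean(values)
  s <- stats::sd(values)
  out <- which(values < m - 2 * s | values > m + 2 * s)
  list(kept = values[setdiff(seq_along(values), out)],
       removed = out, warning = FALSE)
}

#' Summarize features per (experiment, concentration) condition
#'
#' For each metric (amplitude, duration, AUC), outliers are removed per
#' (experiment, concentration) group by the mean +/- 2 SD rule, then mean,
#' SD, SEM and n are computed. With `normalize_within_experiment = TRUE`
#' each metric's summaries are divided, within each experiment, by the
#' maximum of that metric's per-condition means (so each experiment has one
#' condition at exactly 1 per metric) — accounting for biological and
#' experimental variability between experiments.
#'
#' @param features data frame as returned by [trace_features()] (row-bound
#'   over cells).
#' @param normalize_within_experiment logical flag.
#' @param metrics which feature columns to summarize.
#' @return long-form data frame: `experiment_id`, `concentration_M`,
#'   `metric`, `mean`, `sd`, `sem`, `n`, `n_outliers_removed`.
#' @export
summarize_condition <- function(features,
                                normalize_within_experiment = FALSE,
                                metrics = c("amplitude", "duration_s", "auc")) {
  if (!is.data.frame(features) || nrow(features) == 0L) {
    abort_data("`features` must be a non-empty data frame")
  }
  need <- c("experiment_id", "concentration_M", metrics)
  if (!all(need %in% names(features))) {
    abort_data(sprintf("`features` must have columns: %s",
                       paste(need, collapse = ", ")))
  }
  key <- interaction(features$experiment_id, features$concentration_M,
                     drop = TRUE)
  groups <- split(seq_len(nrow(features)), key)
  rows <- list()
  for (g in groups) {
    eid <- features$experiment_id[g[1L]]
    conc <- features$concentration_M[g[1L]]
    for (metric in metrics) {
      v <- features[[metric]][g]
      v <- v[is.finite(v)]
      if (!length(v)) next
      ro <- remove_outliers(v)
      v <- ro$kept
      n <- length(v)
      s <- if (n > 1L) stats::sd(v) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = eid, concentration_M = conc, metric = metric,
        mean = mean(v), sd = s, sem = if (n > 1L) s / sqrt(n) else NA_real_,
        n = n, n_outliers_removed = length(ro$removed),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$experiment_id, out$metric, out$concentration_M), ]
  rownames(out) <- NULL
  if (normalize_within_experiment) {
    key2 <- interaction(out$experiment_id, out$metric, drop = TRUE)
    for (g in split(seq_len(nrow(out)), key2)) {
      mx <- max(out$mean[g])
      if (is.finite(mx) && mx != 0) {
        out$mean[g] <- out$mean[g] / mx
        out$sd[g] <- out$sd[g] / mx
        out$sem[g] <- out$sem[g] / mx
      }
    }
  }
  out
}

#' Amplitude-duration relation across cells
#'
#' Pearson correlation between per-cell peak amplitude and response
#' duration, plus a least-squares exponential regression
#' `duration = a * exp(b * amplitude)` (initialized by the log-linear fit and
#' polished by Gauss-Newton on the original scale). The negative correlation
#' at low ATP reflects the coupling between how high and how long a
#' transient rises.
#'
#' @param features data frame with `amplitude` and `duration_s` columns (one
#'   row per cell); rows with undefined duration are dropped.
#' @return list: `r`, `p_value`, `a`, `b`, `n`.
#' @export
amplitude_duration_relation <- function(features) {
  ok <- is.finite(features$amplitude) & is.finite(features$duration_s)
  amp <- features$amplitude[ok]
  dur <- features$duration_s[ok]
  if (length(amp) < 3L) abort_data("need >= 3 cells with defined duration")
  if (stats::sd(amp) == 0 || stats::sd(dur) == 0) {
    abort_data("correlation undefined: zero variance in amplitude or duration")
  }
  ct <- stats::cor.test(amp, dur)
  if (any(dur <= 0)) abort_data("durations must be positive")
  lin <- stats::lm.fit(cbind(1, amp), log(dur))
  p <- c(a = exp(lin$coefficients[[1L]]), b = lin$coefficients[[2L]])
  # Gauss-Newton polish of sum (dur - a exp(b amp))^2
  for (it in 1:50) {
    f <- p[["a"]] * exp(p[["b"]] * amp)
    r <- dur - f
    J <- cbind(a = f / p[["a"]], b = f * amp)
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    p_new <- p + drop(step)
    f_new <- p_new[["a"]] * exp(p_new[["b"]] * amp)
    halve <- 0L
    while (sum((dur - f_new)^2) > sum(r^2) && halve < 20L) {
      halve <- halve + 1L
      p_new <- p + drop(step) / 2^halve
      f_new <- p_new[["a"]] * exp(p_new[["b"]] * amp)
    }
    delta <- max(abs(p_new - p) / pmax(abs(p), 1e-12))
    p <- p_new
    if (delta < 1e-12) break
  }
  list(r = unname(ct$estimate), p_value = ct$p.value,
       a = p[["a"]], b = p[["b"]], n = length(amp))
}
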