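#' Hill equation response
#'
#' Fraction of activated receptors at ligand concentration `L`:
#' \deqn{\theta = \frac{L^h}{K_{1/2}^h + L^h}}
#' where `k_half` is the ligand concentration at half-maximal response and
#' `hill_coeff` (h) describes cooperativity. Evaluated stably on the log
#' scale; `theta(0) = 0` by definition.
#'
#' @param concentration numeric vector of ligand concentrations (molar, >= 0).
#' @param k_half half-maximal concentration (molar, > 0), scalar.
#' @param hill_coeff Hill coefficient (> 0), scalar.
#' @return numeric vector of responses in \[0, 1).
#' @examples
#' hill_response(3e-7, k_half = 3e-7, hill_coeff = 0.9) # 0.5 at L = K
#' @export
hill_response <- function(concentration, k_half, hill_coeff) {
  if (!is.numeric(k_half) || length(k_half) != 1L || !is.finite(k_half) ||
      k_half <= 0) {
    abort_param("`k_half` must be a single finite positive number")
  }
  if (!is.numeric(hill_coeff) || length(hill_coeff) != 1L ||
      !is.finite(hill_coeff) || hill_coeff <= 0) {
    abort_param("`hill_coeff` must be a single finite positive number")
  }
  if (!is.numeric(concentration) || any(concentration < 0, na.rm = TRUE)) {
    abort_param("`concentration` must be numeric and non-negative")
  }
  out <- numeric(length(concentration))
  pos <- is.finite(concentration) & concentration > 0
  # 1 / (1 + (K/L)^h) computed via exp/log for numerical stability
  out[pos] <- 1 / (1 + exp(hill_coeff * (log(k_half) - log(concentration[pos]))))
  out[!is.finite(concentration)] <- NA_real_
  out[is.finite(concentration) & concentration == 0] <- 0
  out
}

#' Hill equation with a constant offset
#'
#' `hill_response()` shifted by a constant `offset` (beta), used when an
#' extraneous concentration-independent contribution (e.g. mechanical
#' perturbation on bath application) is modeled.
#'
#' @inheritParams hill_response
#' @param offset finite constant added to the response.
#' @return numeric vector of responses.
#' @export
hill_response_offset <- function(concentration, k_half, hill_coeff, offset) {
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset)) {
    abort_param("`offset` must be a single finite number")
  }
  hill_response(concentration, k_half, hill_coeff) + offset
}

#' Coefficient of determination
#'
#' R^2 = 1 - SSres/SStot with SStot about the mean of `observed`. Errors if
#' the observations have zero variance (SStot = 0), where R^2 is undefined.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return scalar in (-Inf, 1].
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    abort_data("`observed` and `predicted` must have equal length >= 2")
  }
  if (anyNA(observed) || anyNA(predicted)) {
    abort_data("missing values in `observed`/`predicted`")
  }
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) {
    abort_data("R-squared undefined: observations have zero variance (SStot = 0)")
  }
  1 - sum((observed - predicted)^2) / sstot
}

# -- internal machinery -------------------------------------------------------

# model and Jacobian on internal parameterization p = (log10 K, h [, beta]).
# Returns list(fitted, J) for concentrations L (may include zeros).
.hill_model <- function(p, L, include_offset) {
  lk <- p[[1L]]; h <- p[[2L]]
  beta <- if (include_offset) p[[3L]] else 0
  K <- 10^lk
  theta <- hill_response(L, K, h)
  d <- theta * (1 - theta)               # common factor; 0 at L = 0
  llr <- ifelse(L > 0, log(L) - log(K), 0)
  J <- cbind(
    log10K = -d * h * log(10),
    h      = d * llr
  )
  if (include_offset) J <- cbind(J, offset = 1)
  list(fitted = theta + beta, J = J)
}

.hill_bounds <- function(include_offset) {
  lower <- c(log10K = -12, h = 0.1)
  upper <- c(log10K = -1, h = 10)
  if (include_offset) {
    lower <- c(lower, offset = -1)
    upper <- c(upper, offset = 2)
  }
  list(lower = lower, upper = upper)
}

# initial K: concentration where the linearly interpolated response first
# crosses halfway between baseline and max; fallback geometric mean.
.hill_init <- function(L, y, include_offset) {
  pos <- L > 0
  Lp <- L[pos]; yp <- y[pos]
  o <- order(Lp); Lp <- Lp[o]; yp <- yp[o]
  b0 <- if (include_offset) min(y) else 0
  half <- b0 + (max(y) - b0) / 2
  k0 <- NA_real_
  above <- yp >= half
  idx <- which(above)[1L]
  if (!is.na(idx) && idx > 1L) {
    y1 <- yp[idx - 1L]; y2 <- yp[idx]
    f <- if (y2 != y1) (half - y1) / (y2 - y1) else 0.5
    k0 <- exp(log(Lp[idx - 1L]) + f * (log(Lp[idx]) - log(Lp[idx - 1L])))
  } else if (!is.na(idx)) {
    k0 <- Lp[1L]
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- exp(mean(log(Lp)))
  p0 <- c(log10K = log10(k0), h = 1)
  if (include_offset) p0 <- c(p0, offset = b0)
  bb <- .hill_bounds(include_offset)
  pmin(pmax(p0, bb$lower), bb$upper)
}

# Gauss-Newton polish with Levenberg damping and box projection; refines an
# optim() solution to (near) machine precision, which matters for noiseless
# self-consistency recovery.
.gn_polish <- function(p, L, y, w, include_offset, max_iter = 50L) {
  bb <- .hill_bounds(include_offset)
  m <- .hill_model(p, L, include_offset)
  ss <- sum(w * (y - m$fitted)^2)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    r <- y - m$fitted
    Jw <- m$J * w
    A <- crossprod(m$J, Jw)
    g <- crossprod(Jw, r)
    step <- tryCatch(
      solve(A + lambda * diag(diag(A) + 1e-300), g),
      error = function(e) NULL
    )
    if (is.null(step)) { lambda <- max(lambda * 10, 1e-8); next }
    p_new <- pmin(pmax(p + drop(step), bb$lower), bb$upper)
    m_new <- .hill_model(p_new, L, include_offset)
    ss_new <- sum(w * (y - m_new$fitted)^2)
    halved <- 0L
    while (!is.finite(ss_new) || ss_new > ss) {
      halved <- halved + 1L
      if (halved > 25L) break
      p_new <- pmin(pmax(p + drop(step) / 2^halved, bb$lower), bb$upper)
      m_new <- .hill_model(p_new, L, include_offset)
      ss_new <- sum(w * (y - m_new$fitted)^2)
    }
    if (!is.finite(ss_new) || ss_new > ss) break
    delta <- max(abs(p_new - p) / pmax(abs(p), 1e-8))
    p <- p_new; m <- m_new
    improved <- ss - ss_new
    ss <- ss_new
    if (delta < 1e-13 || (improved < 1e-18 * max(ss, 1e-30) && it > 2L)) break
  }
  list(par = p, ss = ss, fitted = m$fitted, J = m$J)
}

#' Fit the Hill equation by nonlinear least squares
#'
#' Minimizes the (optionally weighted) sum of squared residuals over
#' `(K_half, h)` — plus a constant offset beta when `include_offset = TRUE` —
#' with `K_half` optimized on the log10 scale for conditioning
#' (concentrations typically span many decades). Bounds:
#' K half in \[1e-12, 1e-1\] M, h in \[0.1, 10\], beta in \[-1, 2\].
#' 95% confidence intervals come from the linearized covariance at the
#' optimum scaled by the t quantile on `n - p` degrees of freedom, matching
#' the usual "best fit value +/- 95% confidence interval" reporting.
#'
#' @param points a data frame with columns `concentration` (or
#'   `concentration_M`) and `response`, optionally `dispersion`; one row per
#'   dose-response observation. Zero-concentration points are allowed
#'   (theta(0) = 0 is defined) and included in the residual.
#' @param include_offset fit an additive constant beta as a third parameter.
#' @param weights `NULL` (ordinary least squares, the default) or
#'   `"dispersion"` to weight by 1/dispersion^2.
#' @param n_starts number of additional coarse multistart initializations of
#'   log10(K half) to guard against local minima.
#' @return an object of class `hill_fit`: a list with `k_half`, `hill_coeff`,
#'   `offset` (NA when not fitted), `ci` (named 95% CI half-widths),
#'   `r_squared` (NA with `degenerate = TRUE` when SStot = 0), `n_points`,
#'   `df`, `sigma`, `converged`, `fitted`, `residuals`, `data`.
#' @export
fit_hill <- function(points, include_offset = FALSE, weights = NULL,
                     n_starts = 2L) {
  pts <- as_dose_response(points)
  L <- pts$concentration
  y <- pts$response
  n <- length(y)
  p_free <- 2L + as.integer(include_offset)
  if (n < p_free + 1L) {
    abort_data(sprintf(
      "need at least %d points to fit %d parameters", p_free + 1L, p_free))
  }
  if (length(unique(L[L > 0])) < 2L) {
    abort_data("need at least 2 distinct positive concentrations")
  }
  if (!all(is.finite(y))) abort_data("responses must be finite")
  w <- rep(1, n)
  if (identical(weights, "dispersion")) {
    if (is.null(pts$dispersion) || !all(is.finite(pts$dispersion)) ||
        any(pts$dispersion <= 0)) {
      abort_data("`weights = \"dispersion\"` needs finite positive dispersions")
    }
    w <- 1 / pts$dispersion^2
  }

  bb <- .hill_bounds(include_offset)
  obj <- function(p) {
    f <- .hill_model(p, L, include_offset)$fitted
    sum(w * (y - f)^2)
  }
  grad <- function(p) {
    m <- .hill_model(p, L, include_offset)
    drop(-2 * crossprod(m$J, w * (y - m$fitted)))
  }
  starts <- list(.hill_init(L, y, include_offset))
  if (n_starts > 0L) {
    lks <- seq(log10(min(L[L > 0])), log10(max(L)), length.out = n_starts + 2L)
    lks <- lks[c(-1L, -(n_starts + 2L))]
    for (lk in lks) {
      s <- starts[[1L]]; s[["log10K"]] <- lk
      starts <- c(starts, list(s))
    }
  }
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0, obj, grad, method = "L-BFGS-B",
                   lower = bb$lower, upper = bb$upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort_fit("Hill fit failed: optimizer did not produce a finite objective")
  }
  pol <- .gn_polish(best$par, L, y, w, include_offset)
  if (!is.finite(pol$ss)) {
    abort_fit("Hill fit failed: non-finite residual sum of squares")
  }
  p_hat <- pol$par
  k_half <- 10^p_hat[["log10K"]]
  h_hat <- p_hat[["h"]]
  beta_hat <- if (include_offset) p_hat[["offset"]] else NA_real_

  df <- n - p_free
  sigma2 <- if (df > 0) pol$ss / df else NA_real_
  # Jacobian on the reporting scale (linear K half)
  J_rep <- pol$J
  J_rep[, "log10K"] <- J_rep[, "log10K"] / (k_half * log(10))
  colnames(J_rep)[1L] <- "k_half"
  colnames(J_rep)[2L] <- "hill_coeff"
  ci <- rep(NA_real_, p_free)
  names(ci) <- colnames(J_rep)
  if (df > 0 && is.finite(sigma2)) {
    A <- crossprod(J_rep, J_rep * w)
    covm <- tryCatch(solve(A) * sigma2, error = function(e) NULL)
    if (!is.null(covm)) {
      se <- sqrt(pmax(diag(covm), 0))
      ci <- stats::qt(0.975, df) * se
      names(ci) <- colnames(J_rep)
    }
  }
  sstot <- sum((y - mean(y))^2)
  degenerate <- sstot == 0
  r2 <- if (degenerate) NA_real_ else 1 - pol$ss / sstot
  if (degenerate) {
    warning("observations have zero variance (SStot = 0); R-squared undefined",
            call. = FALSE)
  }
  structure(list(
    k_half = unname(k_half),
    hill_coeff = unname(h_hat),
    offset = unname(beta_hat),
    include_offset = include_offset,
    ci = ci,
    r_squared = r2,
    degenerate = degenerate,
    n_points = n,
    df = df,
    sigma = if (is.finite(sigma2)) sqrt(sigma2) else NA_real_,
    ss_res = pol$ss,
    converged = TRUE,
    weighted = identical(weights, "dispersion"),
    fitted = pol$fitted,
    residuals = y - pol$fitted,
    data = pts
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  K1/2 = %.4g M (95%% CI +/- %.2g)\n", x$k_half,
              x$ci[["k_half"]]))
  cat(sprintf("  h    = %.3g (95%% CI +/- %.2g)\n", x$hill_coeff,
              x$ci[["hill_coeff"]]))
  if (x$include_offset) {
    cat(sprintf("  beta = %.3g (95%% CI +/- %.2g)\n", x$offset,
                x$ci[["offset"]]))
  }
  cat(sprintf("  R^2  = %s\n",
              if (is.na(x$r_squared)) "NA (degenerate)" else
                format(x$r_squared, digits = 4)))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, concentration, ...) {
  beta <- if (object$include_offset) object$offset else 0
  hill_response(concentration, object$k_half, object$hill_coeff) + beta
}

#' Coerce to a dose-response table
#'
#' Normalizes a data frame to the internal dose-response representation:
#' columns `concentration` (molar, >= 0) and `response`, with optional
#' `dispersion` and `n`. Accepts `concentration_M` as a column alias (the CSV
#' dialect header).
#'
#' @param x a data frame of dose-response observations.
#' @return a `data.frame` with validated columns.
#' @export
as_dose_response <- function(x) {
  if (!is.data.frame(x)) abort_data("dose-response input must be a data frame")
  nm <- names(x)
  if ("concentration_M" %in% nm && !("concentration" %in% nm)) {
    x$concentration <- x$concentration_M
  }
  if (!all(c("concentration", "response") %in% names(x))) {
    abort_data("dose-response table needs columns `concentration` (or `concentration_M`) and `response`")
  }
  if (nrow(x) == 0L) abort_data("dose-response table is empty")
  if (!is.numeric(x$concentration) || anyNA(x$concentration) ||
      any(x$concentration < 0)) {
    abort_data("concentrations must be numeric and >= 0")
  }
  if (!is.numeric(x$response)) abort_data("responses must be numeric")
  keep <- intersect(c("concentration", "response", "dispersion", "n"), names(x))
  out <- x[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a Hill fit to JSON
#'
#' Writes (or returns) the fit report JSON:
#' `{k_half, hill_coeff, offset?, ci: {...}, r_squared, n_points, converged}`.
#'
#' @param fit a `hill_fit` object.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to `path`.
#' @export
hill_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "hill_fit"))
  rec <- list(
    k_half = fit$k_half,
    hill_coeff = fit$hill_coeff,
    ci = as.list(fit$ci),
    r_squared = fit$r_squared,
    n_points = fit$n_points,
    converged = fit$converged
  )
  if (fit$include_offset) rec$offset <- fit$offset
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
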