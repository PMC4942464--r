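#' Construct an ensemble dose-response model
#'
#' An ensemble model represents a complex ATP dose dependence as a signed
#' linear combination of fixed per-receptor Hill basis functions:
#' `f(x) = a1 f1(x) + ... + an fn(x) + beta`, where `fi` are the catalog
#' Hill curves and negative coefficients represent inhibitory contributions
#' (phenomenological heterologous desensitization).
#'
#' @param basis a `basis_set`.
#' @param coefficients numeric weights, one per basis member (signed).
#' @param offset optional constant beta (`NULL` to omit).
#' @param ci optional named 95% CI half-widths per coefficient.
#' @param r_squared optional fit diagnostic.
#' @param n_points optional number of fitted points.
#' @return an object of class `ensemble_model`.
#' @export
ensemble_model <- function(basis, coefficients, offset = NULL, ci = NULL,
                           r_squared = NA_real_, n_points = NA_integer_) {
  stopifnot(inherits(basis, "basis_set"))
  if (length(coefficients) != nrow(basis)) {
    abort_param("need exactly one coefficient per basis member")
  }
  if (!all(is.finite(coefficients))) abort_param("coefficients must be finite")
  if (!is.null(offset) && (!is.numeric(offset) || !is.finite(offset))) {
    abort_param("offset must be a finite number or NULL")
  }
  names(coefficients) <- basis$receptor
  structure(list(basis = basis, coefficients = coefficients, offset = offset,
                 ci = ci, r_squared = r_squared, n_points = n_points),
            class = "ensemble_model")
}

#' Evaluate an ensemble model
#'
#' @param concentrations numeric molar concentrations (>= 0).
#' @param model an `ensemble_model`.
#' @return numeric response vector, one value per concentration.
#' @export
ensemble_response <- function(concentrations, model) {
  stopifnot(inherits(model, "ensemble_model"))
  X <- evaluate_basis(model$basis, concentrations)
  out <- drop(X %*% model$coefficients)
  if (!is.null(model$offset)) out <- out + model$offset
  if (length(concentrations) == 0L) numeric(0) else out
}

#' Fit a signed linear combination of receptor basis functions
#'
#' Ordinary linear least squares of the responses on the basis Hill curves
#' evaluated at the observed concentrations (plus a constant column when
#' `include_offset = TRUE`). Coefficients are unconstrained in sign —
#' negative weights are the model's representation of inhibitory receptor
#' contributions. 95% CIs come from the standard linear-model covariance
#' (t quantile on n - p df).
#'
#' @param points dose-response data frame (see [as_dose_response()]).
#' @param basis a `basis_set`.
#' @param include_offset add a fitted constant beta.
#' @param drop_top_concentration drop the highest concentration before
#'   fitting (mirrors excluding a top dose with suspected non-specific
#'   effects).
#' @return an `ensemble_model` with coefficients, `offset` (if requested),
#'   `ci`, `r_squared`, `n_points`, plus `sigma`, `fitted`, `residuals`,
#'   `data`.
#' @export
fit_linear_combination <- function(points, basis, include_offset = FALSE,
                                   drop_top_concentration = FALSE) {
  stopifnot(inherits(basis, "basis_set"))
  pts <- as_dose_response(points)
  if (drop_top_concentration) {
    pts <- pts[pts$concentration < max(pts$concentration), , drop = FALSE]
    if (nrow(pts) == 0L) abort_data("no points left after dropping top concentration")
  }
  y <- pts$response
  X <- evaluate_basis(basis, pts$concentration)
  if (include_offset) X <- cbind(X, `(offset)` = 1)
  p <- ncol(X)
  n <- nrow(X)
  if (n < p) {
    abort_data(sprintf(
      "underdetermined: %d points for %d free parameters", n, p))
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    abort_collinear(sprintf(
      "basis design matrix is rank deficient; collinear column(s): %s",
      paste(bad, collapse = ", ")))
  }
  coef <- qr.coef(qrx, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  df <- n - p
  sigma2 <- if (df > 0) sum(resid^2) / df else NA_real_
  ci <- rep(NA_real_, p)
  names(ci) <- colnames(X)
  if (df > 0 && is.finite(sigma2)) {
    covm <- chol2inv(qr.R(qrx)) * sigma2
    se <- sqrt(pmax(diag(covm), 0))
    # chol2inv of qr.R is in pivoted order; map back
    se[qrx$pivot] <- se
    ci <- stats::qt(0.975, df) * se
    names(ci) <- colnames(X)
  }
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(resid^2) / sstot else NA_real_
  k <- nrow(basis)
  m <- ensemble_model(basis, unname(coef[seq_len(k)]),
                      offset = if (include_offset) unname(coef[[p]]) else NULL,
                      ci = ci, r_squared = r2, n_points = n)
  m$sigma <- if (is.finite(sigma2)) sqrt(sigma2) else NA_real_
  m$df <- df
  m$fitted <- fitted
  m$residuals <- resid
  m$data <- pts
  m
}

#' Fit and rank candidate basis sets
#'
#' Fits every candidate basis by [fit_linear_combination()] and ranks by
#' R-squared descending; ties broken by fewer parameters, then input order.
#' Per-candidate failures are recorded, not fatal.
#'
#' @param points dose-response data frame.
#' @param candidate_bases list of `basis_set` objects (optionally named).
#' @param include_offset logical, recycled over candidates.
#' @param drop_top_concentration passed to [fit_linear_combination()].
#' @return a list with `fits` (one `ensemble_model` or error message per
#'   candidate, ranked order) and `ranking` (data frame: candidate, label,
#'   n_parameters, r_squared, rank, error).
#' @export
compare_models <- function(points, candidate_bases, include_offset = FALSE,
                           drop_top_concentration = FALSE) {
  if (!length(candidate_bases)) abort_param("no candidate bases given")
  include_offset <- rep_len(include_offset, length(candidate_bases))
  labels <- names(candidate_bases)
  if (is.null(labels)) labels <- rep("", length(candidate_bases))
  fits <- vector("list", length(candidate_bases))
  info <- vector("list", length(candidate_bases))
  for (i in seq_along(candidate_bases)) {
    b <- candidate_bases[[i]]
    lab <- if (nzchar(labels[i])) labels[i] else
      paste0(paste(b$receptor, collapse = "+"),
             if (include_offset[i]) "+offset" else "")
    res <- tryCatch(
      fit_linear_combination(points, b, include_offset = include_offset[i],
                             drop_top_concentration = drop_top_concentration),
      error = function(e) e)
    failed <- inherits(res, "error")
    fits[[i]] <- res
    info[[i]] <- data.frame(
      candidate = i, label = lab,
      n_parameters = nrow(b) + as.integer(include_offset[i]),
      r_squared = if (failed) NA_real_ else res$r_squared,
      error = if (failed) conditionMessage(res) else NA_character_,
      stringsAsFactors = FALSE)
  }
  ranking <- do.call(rbind, info)
  ord <- order(-replace(ranking$r_squared, is.na(ranking$r_squared), -Inf),
               ranking$n_parameters, ranking$candidate)
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(fits = fits[ord], ranking = ranking)
}

#' Landmark analysis of a dose-response curve
#'
#' Identifies the labeled landmark points of a (possibly two-peak) amplitude
#' dose dependence: the initial low response, the first peak, the lowest
#' value between the peaks, the second peak, and the lowest value after the
#' second peak. Peaks are interior points strictly greater than both
#' neighbors (plateau runs count once, located at their lowest
#' concentration); with more than two peaks the two largest are kept,
#' ordered by concentration. A curve with a single peak yields the one-peak
#' variant; a monotone curve yields a no-peak result, not an error.
#'
#' @param points dose-response data frame; concentrations must be unique.
#'   Vehicle (0 M) rows are excluded before analysis.
#' @return an object of class `landmark_set`: list with `n_peaks`,
#'   `landmarks` (named list of `(concentration, amplitude)` pairs among
#'   `initial_low`, `first_peak`, `trough`, `second_peak`, `post_trough`)
#'   and `post_trough_at_end` (TRUE when the final point had to serve as the
#'   post-peak minimum).
#' @export
find_landmarks <- function(points) {
  pts <- as_dose_response(points)
  pts <- pts[pts$concentration > 0, , drop = FALSE]
  pts <- pts[order(pts$concentration), , drop = FALSE]
  if (anyDuplicated(pts$concentration)) {
    abort_data("concentrations must be unique for landmark analysis")
  }
  if (nrow(pts) < 5L) abort_data("need >= 5 points for landmark analysis")
  x <- pts$concentration
  y <- pts$response
  n <- length(y)

  # collapse plateau runs; representative index = run start (lowest conc)
  runs <- rle(y)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ry <- runs$values
  m <- length(ry)
  peak_idx <- integer(0)
  if (m >= 3L) {
    interior <- 2:(m - 1L)
    is_pk <- ry[interior] > ry[interior - 1L] & ry[interior] > ry[interior + 1L]
    peak_idx <- starts[interior[is_pk]]
  }
  lm_pt <- function(i) list(concentration = x[i], amplitude = y[i])
  at_end <- FALSE
  if (length(peak_idx) == 0L) {
    out <- list(n_peaks = 0L, landmarks = list(), post_trough_at_end = FALSE)
  } else if (length(peak_idx) == 1L) {
    pk <- peak_idx
    before <- 1:(pk - 1L)
    after <- (pk + 1L):n
    imin_after <- after[which.min(y[after])]
    at_end <- imin_after == n && y[n] >= y[n - 1L]
    out <- list(
      n_peaks = 1L,
      landmarks = list(
        initial_low = lm_pt(before[which.min(y[before])]),
        first_peak = lm_pt(pk),
        post_trough = lm_pt(imin_after)),
      post_trough_at_end = at_end)
  } else {
    if (length(peak_idx) > 2L) {
      keep <- order(y[peak_idx], decreasing = TRUE)[1:2]
      peak_idx <- sort(peak_idx[keep])
    }
    p1 <- peak_idx[1L]; p2 <- peak_idx[2L]
    before <- 1:(p1 - 1L)
    between <- (p1 + 1L):(p2 - 1L)
    after <- (p2 + 1L):n
    imin_after <- after[which.min(y[after])]
    at_end <- imin_after == n && y[n] >= y[n - 1L]
    out <- list(
      n_peaks = 2L,
      landmarks = list(
        initial_low = lm_pt(before[which.min(y[before])]),
        first_peak = lm_pt(p1),
        trough = lm_pt(between[which.min(y[between])]),
        second_peak = lm_pt(p2),
        post_trough = lm_pt(imin_after)),
      post_trough_at_end = at_end)
  }
  class(out) <- "landmark_set"
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Ensemble P2 receptor model (", nrow(x$basis), " basis functions)\n",
      sep = "")
  for (i in seq_along(x$coefficients)) {
    cat(sprintf("  %-6s a = %+.4g", names(x$coefficients)[i],
                x$coefficients[i]))
    if (!is.null(x$ci) && is.finite(x$ci[i])) {
      cat(sprintf("  (95%% CI +/- %.2g)", x$ci[i]))
    }
    cat("\n")
  }
  if (!is.null(x$offset)) cat(sprintf("  offset beta = %+.4g\n", x$offset))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set:", x$n_peaks, "peak(s)\n")
  for (nm in names(x$landmarks)) {
    p <- x$landmarks[[nm]]
    cat(sprintf("  %-12s %.3g M, amplitude %.3g\n", nm, p$concentration,
                p$amplitude))
  }
  invisible(x)
}

#' Serialize an ensemble model to JSON
#'
#' @param model an `ensemble_model`.
#' @param path optional output path.
#' @param excluded_concentrations concentrations dropped before the fit, for
#'   provenance.
#' @return JSON string (invisibly when written to `path`).
#' @export
ensemble_model_json <- function(model, path = NULL,
                                excluded_concentrations = numeric(0)) {
  stopifnot(inherits(model, "ensemble_model"))
  rec <- list(
    basis = data.frame(receptor = model$basis$receptor,
                       species = model$basis$species,
                       stringsAsFactors = FALSE),
    coefficients = as.list(model$coefficients),
    ci = if (is.null(model$ci)) NULL else as.list(model$ci),
    r_squared = model$r_squared,
    n_points = model$n_points,
    excluded_concentrations = excluded_concentrations
  )
  if (!is.null(model$offset)) rec$offset <- model$offset
  js <- jsonlite::toJSON(rec, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
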