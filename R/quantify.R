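#' z-transform a vector
#'
#' Centres to mean 0 and scales to sample (n - 1) standard deviation 1.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return The z-scores.
#' @export
z_transform <- function(values) {
  if (length(values) < 2L) stop("z_transform needs at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("z_transform: constant vector")
  (values - mean(values)) / s
}

.regression_result <- function(intercept, slope, r_squared, delta, sigma,
                               log_likelihood, n, slope_se) {
  t <- slope / slope_se
  structure(list(intercept = intercept, slope = slope,
                 r_squared = r_squared, delta = delta, sigma = sigma,
                 log_likelihood = log_likelihood, n = n,
                 slope_se = slope_se, t_slope = t,
                 p_slope = 2 * pt(abs(t), df = n - 2, lower.tail = FALSE)),
            class = "ms_regression")
}

#' @export
print.ms_regression <- function(x, ...) {
  cat(sprintf("y ~ %.4g + %.4g x  (n = %d)\n", x$intercept, x$slope, x$n))
  if (!is.na(x$delta))
    cat(sprintf("  varExp delta = %.4g, sigma = %.4g\n", x$delta, x$sigma))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  cat(sprintf("  slope p = %.3g, logLik = %.4g\n", x$p_slope,
              x$log_likelihood))
  invisible(x)
}

#' Ordinary least squares fit
#'
#' Closed-form simple linear regression with `R^2 = 1 - SSE/SST` and the
#' usual t-test on the slope.
#'
#' @param x,y numeric vectors of equal length (n >= 3; x non-constant).
#' @return An `ms_regression` with `delta = NA` (homoscedastic model).
#' @export
ols_fit <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need n >= 3 paired observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate design: x is constant")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / n  # ML scale, consistent with gls_varexp_fit
  ll <- -n / 2 * log(2 * pi * sigma2) - n / 2
  se <- sqrt(sse / (n - 2) / sxx)
  .regression_result(intercept, slope,
                     r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
                     delta = NA_real_, sigma = sqrt(sigma2),
                     log_likelihood = ll, n = n, slope_se = se)
}

# weighted least squares at fixed delta; returns ML profile pieces
.wls_at_delta <- function(x, y, delta) {
  w <- exp(-2 * delta * x)
  sw <- sum(w)
  xw <- sum(w * x) / sw
  yw <- sum(w * y) / sw
  sxx <- sum(w * (x - xw)^2)
  slope <- sum(w * (x - xw) * (y - yw)) / sxx
  intercept <- yw - slope * xw
  res <- y - intercept - slope * x
  n <- length(x)
  sigma2 <- sum(w * res^2) / n
  ll <- -n / 2 * log(2 * pi * sigma2) - sum(delta * x) - n / 2
  list(intercept = intercept, slope = slope, sigma2 = sigma2,
       log_likelihood = ll, sxx = sxx)
}

#' Generalised least squares with an exponential variance function
#'
#' Fits `y_i = a + b x_i + e_i` with `sd(e_i) = sigma * exp(delta * x_i)`
#' by maximum likelihood: for fixed `delta` the weighted least squares
#' solution (weights `exp(-2 delta x_i)`) is closed-form, and the resulting
#' one-dimensional profile likelihood is maximised over `delta` by bounded
#' scalar optimisation. This is the variance model used to absorb the
#' heteroscedasticity of biomass-read regressions, where residual spread
#' grows with frequency.
#'
#' @param x,y numeric vectors of equal length (n >= 5).
#' @param delta optional fixed value of the variance coefficient; when
#'   supplied (e.g. `delta = 0`) no optimisation is performed and the fit
#'   reduces exactly to (weighted) least squares.
#' @param delta_range search interval for `delta`; default `c(-10, 10)`.
#' @param tol convergence tolerance of the scalar optimiser; default 1e-8.
#' @return An `ms_regression` with `delta`, `sigma` and the maximised
#'   log-likelihood. The slope standard error comes from the weighted
#'   information matrix at the optimum.
#' @export
gls_varexp_fit <- function(x, y, delta = NULL, delta_range = c(-10, 10),
                           tol = 1e-8) {
  n <- length(x)
  if (n < 5L || length(y) != n) stop("need n >= 5 paired observations")
  if (is.null(delta)) {
    opt <- optimize(function(d) .wls_at_delta(x, y, d)$log_likelihood,
                    interval = delta_range, maximum = TRUE, tol = tol)
    delta <- opt$maximum
    # keep delta = 0 exactly when it is at least as likely (optimize never
    # returns an exact interior 0)
    if (.wls_at_delta(x, y, 0)$log_likelihood >=
        .wls_at_delta(x, y, delta)$log_likelihood)
      delta <- 0
  }
  fit <- .wls_at_delta(x, y, delta)
  se <- sqrt(fit$sigma2 * n / (n - 2) / fit$sxx)
  .regression_result(fit$intercept, fit$slope, r_squared = NA_real_,
                     delta = delta, sigma = sqrt(fit$sigma2),
                     log_likelihood = fit$log_likelihood, n = n,
                     slope_se = se)
}

#' Convert read frequencies to estimated species counts
#'
#' A sample's total biomass can be weighed before DNA extraction; read
#' frequencies then estimate per-species biomasses, which divide by
#' species-typical per-individual biomass to give (real-valued) count
#' estimates. Rounding is left to the caller.
#'
#' @param read_freqs named per-species frequencies summing to 1.
#' @param total_sample_biomass total biomass of the sample (same units as
#'   `biomass_per_individual`).
#' @param biomass_per_individual named per-species biomass of one
#'   individual, > 0.
#' @return Data frame with `species_id`, `estimated_biomass`,
#'   `estimated_count`; estimated biomasses sum to the sample total.
#' @export
biomass_to_counts <- function(read_freqs, total_sample_biomass,
                              biomass_per_individual) {
  if (abs(sum(read_freqs) - 1) > 1e-6)
    stop("read_freqs must sum to 1")
  bpi <- biomass_per_individual[names(read_freqs)]
  if (any(is.na(bpi)) || any(bpi <= 0))
    stop("biomass_per_individual must be positive for every species")
  est_b <- unname(read_freqs) * total_sample_biomass
  data.frame(species_id = names(read_freqs),
             estimated_biomass = est_b,
             estimated_count = est_b / unname(bpi),
             stringsAsFactors = FALSE)
}

#' Biomass-frequency versus read-frequency regression
#'
#' Builds the paired (biomass frequency, read frequency) points - one per
#' species x sample cell where the species occurs in the morphological truth
#' or is detected in the reads - z-transforms each side, and fits both an
#' OLS and an exponential-variance GLS regression of read on biomass.
#' Frequencies are computed per sample over the full reference library;
#' z-transformation is within sample across the cell set by default (the
#' transform that corrects for different sample sizes), with a global
#' alternative.
#'
#' @param profile a `profile_table`.
#' @param truth_biomass species x samples biomass matrix (morphological
#'   truth).
#' @param variant which read counts to use: `"corrected"` (length +
#'   mitonuclear, default), `"normalized"` (length only) or `"raw"`.
#' @param scope z-transform within `"sample"` (default) or over the
#'   `"global"` point set.
#' @param zscore z-transform the frequencies (default TRUE) or regress the
#'   raw frequencies.
#' @return List with elements `ols` and `gls` (`ms_regression` objects) and
#'   `points` (the assembled data frame).
#' @export
biomass_read_regression <- function(profile, truth_biomass,
                                    variant = c("corrected", "normalized",
                                                "raw"),
                                    scope = c("sample", "global"),
                                    zscore = TRUE) {
  variant <- match.arg(variant)
  scope <- match.arg(scope)
  value <- switch(variant, corrected = "corrected_reads",
                  normalized = "normalized_reads", raw = "raw_reads")
  rf <- read_frequencies(profile, value = value)
  common_sp <- intersect(rownames(rf), rownames(truth_biomass))
  common_sa <- intersect(colnames(rf), colnames(truth_biomass))
  rf <- rf[common_sp, common_sa, drop = FALSE]
  tb <- truth_biomass[common_sp, common_sa, drop = FALSE]
  bf <- sweep(tb, 2L, colSums(tb), "/")
  pres <- presence_matrix(profile)[common_sp, common_sa, drop = FALSE]
  pts <- do.call(rbind, lapply(common_sa, function(sa) {
    keep <- which(tb[, sa] > 0 | pres[, sa])
    if (length(keep) < 2L) return(NULL)
    x <- bf[keep, sa]
    y <- rf[keep, sa]
    if (zscore && scope == "sample") {
      if (sd(x) == 0 || sd(y) == 0) return(NULL)
      x <- z_transform(x)
      y <- z_transform(y)
    }
    data.frame(species_id = common_sp[keep], sample_id = sa,
               biomass_freq = x, read_freq = y, stringsAsFactors = FALSE)
  }))
  if (is.null(pts) || nrow(pts) < 5L)
    stop("too few (species, sample) points for regression")
  if (zscore && scope == "global") {
    pts$biomass_freq <- z_transform(pts$biomass_freq)
    pts$read_freq <- z_transform(pts$read_freq)
  }
  list(ols = ols_fit(pts$biomass_freq, pts$read_freq),
       gls = gls_varexp_fit(pts$biomass_freq, pts$read_freq),
       points = pts)
}
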