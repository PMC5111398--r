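#' Jaccard dissimilarities between samples
#'
#' Binary mode gives the classic Jaccard distance
#' `1 - |A intersect B| / |A union B|` over presence sets; quantitative mode
#' gives the Ruzicka form `2B / (1 + B)` over the Bray-Curtis ratio
#' `B = sum|x - y| / sum(x + y)` (the documented behaviour of
#' `vegan::vegdist(method = "jaccard")`, which does the computation here).
#' The two coincide on 0/1 data.
#'
#' @param matrix species x samples matrix of non-negative values
#'   (frequencies, biomasses or presence).
#' @param binary use presence/absence (`TRUE`) or quantitative (`FALSE`)
#'   dissimilarity.
#' @return A `dist` object over samples, values in `[0, 1]`.
#' @export
jaccard <- function(matrix, binary = TRUE) {
  if (ncol(matrix) < 2L) stop("need at least 2 samples")
  if (any(matrix < 0)) stop("values must be non-negative")
  zero <- colSums(matrix) == 0
  if (any(zero))
    stop("sample(s) with all-zero composition: ",
         paste(colnames(matrix)[zero], collapse = ", "))
  vegan::vegdist(t(matrix), method = "jaccard", binary = binary)
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 by iterative descent with monotone (isotonic)
#' regression, best of `n_restarts` random starts plus a metric start
#' (`vegan::metaMDS` engine). The returned configuration is centred.
#'
#' With `n_restarts = 0` the descent starts from the metric (PCoA)
#' configuration only, with no random restarts; this deterministic variant
#' gives reproducible, start-independent configurations, which matters when
#' two ordinations of nearly identical dissimilarities are to be compared
#' (random restarts can land near-degenerate stress surfaces in different
#' basins).
#'
#' @param dissimilarity a `dist` object (e.g. from [jaccard()]).
#' @param k embedding dimension; default 2.
#' @param n_restarts maximum random restarts; 0 for the deterministic
#'   PCoA-start descent; default 20.
#' @param max_iter iteration cap per run; default 500.
#' @param seed integer seed for the restarts.
#' @return List of class `ms_ordination`: `configuration` (samples x k),
#'   `stress` (Kruskal stress-1 in [0, 1]), `converged`, `n_restarts_used`.
#' @export
nmds <- function(dissimilarity, k = 2, n_restarts = 20, max_iter = 500,
                 seed = 1) {
  stopifnot(inherits(dissimilarity, "dist"))
  n <- attr(dissimilarity, "Size")
  if (n < k + 1) stop("need at least k + 1 samples")
  fit <- if (n_restarts == 0) {
    start <- stats::cmdscale(dissimilarity, k = k)
    vegan::monoMDS(dissimilarity, y = start, k = k, maxit = max_iter,
                   sratmax = 0.9999999, sfgrmin = 1e-9)
  } else with_seed(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(dissimilarity, k = k, trymax = n_restarts, trace = 0,
                   maxit = max_iter, sratmax = 0.9999999, sfgrmin = 1e-9,
                   autotransform = FALSE, wascores = FALSE)
  )))
  cfg <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(cfg, "scaled:center") <- NULL
  conv <- if (n_restarts == 0) !is.null(fit$icause) && fit$icause %in% c(3, 4)
  else isTRUE(fit$converged) ||
    (is.numeric(fit$converged) && fit$converged > 0)
  structure(list(configuration = cfg, stress = fit$stress,
                 converged = conv,
                 n_restarts_used = if (n_restarts == 0) 0L
                 else fit$tries %||% n_restarts),
            class = "ms_ordination")
}

#' @export
print.ms_ordination <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dims, stress = %.4g (%s)\n",
              nrow(x$configuration), ncol(x$configuration), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Symmetric Procrustes comparison with permutation test
#'
#' Centres and unit-scales both configurations, finds the optimal rotation,
#' and reports `m^2` (the symmetric Procrustes sum of squares), the
#' correlation `r = sqrt(1 - m^2)`, and a permutation p-value computed with
#' the add-one rule `(count + 1) / (B + 1)` by permuting the row order of
#' the second configuration (`vegan::protest(symmetric = TRUE)` does the
#' work).
#'
#' @param X,Y sample x axis configuration matrices with matching rows (e.g.
#'   `$configuration` of two [nmds()] results).
#' @param n_permutations number of permutations; default 9999.
#' @param seed integer seed for the permutations.
#' @return List of class `ms_procrustes`: `m_squared`, `correlation_r`,
#'   `p_value`, `n_permutations`.
#' @export
procrustes_protest <- function(X, Y, n_permutations = 9999, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (ncol(X) > nrow(X) || ncol(Y) > nrow(Y))
    stop("more axes than observations")
  if (qr(scale(X, scale = FALSE))$rank < ncol(X) ||
      qr(scale(Y, scale = FALSE))$rank < ncol(Y))
    stop("rank-deficient configuration")
  res <- with_seed(seed,
                   vegan::protest(X, Y, symmetric = TRUE,
                                  permutations = n_permutations))
  structure(list(m_squared = unname(res$ss),
                 correlation_r = unname(res$t0),
                 p_value = unname(res$signif),
                 n_permutations = length(res$t)),
            class = "ms_procrustes")
}

#' @export
print.ms_procrustes <- function(x, ...) {
  cat(sprintf("Procrustes: r = %.4g (m^2 = %.4g), p = %.4g (%d permutations)\n",
              x$correlation_r, x$m_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Bias-corrected Chao2 incidence-based richness estimate
#'
#' With `q1` uniques (species in exactly one sample), `q2` duplicates, `m`
#' samples and `A = (m - 1) / m`:
#' `chao2 = s_obs + A * q1 (q1 - 1) / (2 (q2 + 1))`, with standard error
#' from the matching incidence variance
#' `var = A q1(q1-1)/(2(q2+1)) + A^2 q1(2q1-1)^2/(4(q2+1)^2) +
#'  A^2 q1^2 q2 (q1-1)^2 / (4 (q2+1)^4)`.
#'
#' The classic (legacy) estimator `s_obs + A q1^2 / (2 q2)` with the
#' matching variance `q2 (A^2 G^4 / 4 + A^2 G^3 + A G^2 / 2)`, `G = q1/q2`,
#' is available behind `bias_corrected = FALSE` (it falls back to the
#' bias-corrected form when `q2 = 0`, where the classic formula is
#' undefined).
#'
#' @param incidence_matrix binary (or logical) species x samples matrix,
#'   m >= 2 samples.
#' @param bias_corrected use the small-sample bias-corrected form (default
#'   `TRUE`) or the classic estimator.
#' @return List of class `richness_estimate`: `s_obs`, `q1`, `q2`, `m`,
#'   `chao2`, `se`.
#' @export
chao2 <- function(incidence_matrix, bias_corrected = TRUE) {
  m <- ncol(incidence_matrix)
  if (m < 2L) stop("need at least 2 samples")
  inc <- rowSums(incidence_matrix > 0)
  s_obs <- sum(inc > 0)
  q1 <- sum(inc == 1)
  q2 <- sum(inc == 2)
  A <- (m - 1) / m
  if (bias_corrected || q2 == 0) {
    est <- s_obs + A * q1 * (q1 - 1) / (2 * (q2 + 1))
    v <- A * q1 * (q1 - 1) / (2 * (q2 + 1)) +
      A^2 * q1 * (2 * q1 - 1)^2 / (4 * (q2 + 1)^2) +
      A^2 * q1^2 * q2 * (q1 - 1)^2 / (4 * (q2 + 1)^4)
  } else {
    G <- q1 / q2
    est <- s_obs + A * q1^2 / (2 * q2)
    v <- q2 * (A^2 * G^4 / 4 + A^2 * G^3 + A * G^2 / 2)
  }
  structure(list(s_obs = s_obs, q1 = q1, q2 = q2, m = m,
                 chao2 = est, se = sqrt(v)),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("Chao2 = %.1f +/- %.1f SE (S_obs = %d, Q1 = %d, Q2 = %d, m = %d)\n",
              x$chao2, x$se, x$s_obs, x$q1, x$q2, x$m))
  invisible(x)
}

#' Welch's t-test from richness estimates and standard errors
#'
#' Compares two extrapolated richness estimates given their standard errors
#' and the number of samples behind each:
#' `t = (est1 - est2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite
#' degrees of freedom
#' `df = (se1^2 + se2^2)^2 / (se1^4 / (m1 - 1) + se2^4 / (m2 - 1))` and a
#' two-sided Student-t p-value.
#'
#' @param est1,est2 the two estimates.
#' @param se1,se2 their standard errors (> 0).
#' @param m1,m2 number of samples behind each estimate (>= 2).
#' @return List of class `ms_welch`: `t`, `df`, `p`.
#' @export
welch_from_estimates <- function(est1, se1, m1, est2, se2, m2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  if (m1 < 2 || m2 < 2) stop("need m >= 2 per group")
  v <- se1^2 + se2^2
  t <- (est1 - est2) / sqrt(v)
  df <- v^2 / (se1^4 / (m1 - 1) + se2^4 / (m2 - 1))
  structure(list(t = t, df = df,
                 p = 2 * pt(abs(t), df = df, lower.tail = FALSE)),
            class = "ms_welch")
}

#' @export
print.ms_welch <- function(x, ...) {
  cat(sprintf("Welch t(df = %.1f) = %.2f, p = %.2f\n", x$df, x$t, x$p))
  invisible(x)
}
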