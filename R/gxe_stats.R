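#' Additive genetic variance at an environmental gradient value
#'
#' `sigma2_a(f) = sigma2_a0 + sigma2_a1 f^2 + 2 sigma_a01 f`: the variance
#' of `a0 + a1 f` under the fitted 2x2 covariance of intercept and slope.
#'
#' @param f Environmental gradient value(s) (herd-effect units).
#' @param genetic 2x2 genetic covariance matrix (or an `rnm_fit`).
#' @return Variance at each `f` (vectorised).
#' @export
genetic_variance_at <- function(f, genetic) {
  g <- genetic_block(genetic)
  g[1, 1] + g[2, 2] * f^2 + 2 * g[1, 2] * f
}

genetic_block <- function(genetic) {
  if (inherits(genetic, "rnm_fit")) genetic$genetic
  else if (is.matrix(genetic)) genetic
  else stop("need a 2x2 genetic covariance matrix or an rnm_fit")
}

#' Heritability at an environmental gradient value
#'
#' `h2(f) = sigma2_a(f) / (sigma2_a(f) + sigma2_pe + sigma2_e / w)`, where
#' `w` is the residual weight of the herd group that `f` belongs to.
#' Herd-year variance is not part of the denominator.
#'
#' @param f Environmental gradient value(s).
#' @param w Residual weight(s) of the group(s) of `f` (recycled).
#' @param genetic 2x2 genetic covariance matrix or `rnm_fit`.
#' @param sigma2_pe,sigma2_e Permanent environmental and residual variance
#'   (taken from the fit when `genetic` is an `rnm_fit` and these are
#'   missing).
#' @return Heritability in \[0, 1\] at each `f`.
#' @export
heritability_at <- function(f, w = 1, genetic, sigma2_pe = NULL,
                            sigma2_e = NULL) {
  if (inherits(genetic, "rnm_fit")) {
    if (is.null(sigma2_pe)) sigma2_pe <- genetic$sigma2_pe
    if (is.null(sigma2_e)) sigma2_e <- genetic$sigma2_e
  }
  va <- genetic_variance_at(f, genetic)
  va / (va + sigma2_pe + sigma2_e / w)
}

#' Genetic correlation between two environmental gradient values
#'
#' The linear reaction norm implies
#' `cov(f1, f2) = sigma2_a0 + sigma_a01 (f1 + f2) + sigma2_a1 f1 f2`,
#' normalised by the genetic standard deviations at `f1` and `f2`.
#'
#' @param f1,f2 Environmental gradient values (vectorised in `f1`).
#' @param genetic 2x2 genetic covariance matrix or `rnm_fit`.
#' @return Correlation(s) in \[-1, 1\].
#' @export
genetic_correlation <- function(f1, f2, genetic) {
  g <- genetic_block(genetic)
  v1 <- genetic_variance_at(f1, g)
  v2 <- genetic_variance_at(f2, g)
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("zero or negative genetic variance at an evaluation point")
  cv <- g[1, 1] + g[1, 2] * (f1 + f2) + g[2, 2] * f1 * f2
  pmin(1, pmax(-1, cv / sqrt(v1 * v2)))
}

#' Correlation between reaction norm intercept and slope
#'
#' `sigma_a01 / sqrt(sigma2_a0 * sigma2_a1)`.
#'
#' @param genetic 2x2 genetic covariance matrix or `rnm_fit`.
#' @return The correlation.
#' @export
intercept_slope_correlation <- function(genetic) {
  g <- genetic_block(genetic)
  if (g[1, 1] <= 0 || g[2, 2] <= 0)
    stop("zero intercept or slope variance")
  g[1, 2] / sqrt(g[1, 1] * g[2, 2])
}

#' Likelihood-ratio test of the reaction norm against the reduced model
#'
#' `D = 2 (logL_RNM - logL_RM)`, clipped at zero with a warning if
#' numerically negative. Because the slope variance sits on the boundary of
#' the parameter space under the null, the p-value uses the 50:50 mixture
#' `p = 0.5 P[chisq_1 >= D] + 0.5 P[chisq_2 >= D]`.
#'
#' @param logL_rm,logL_rnm REML log-likelihoods of the reduced and reaction
#'   norm models (same data and residual weights).
#' @return List with the statistic `D` and `p_value`.
#' @export
lrt_rnm_vs_rm <- function(logL_rm, logL_rnm) {
  D <- 2 * (logL_rnm - logL_rm)
  if (D < 0) {
    if (D < -1e-4)
      warning("negative LRT statistic (", format(D),
              "); models may not be nested or not converged; clipping at 0")
    D <- 0
  }
  p <- 0.5 * stats::pchisq(D, df = 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(D, df = 2, lower.tail = FALSE)
  list(D = D, p_value = p)
}

#' Environmental gradient values at record-weighted quantiles
#'
#' Empirical quantiles of the estimated herd effects, weighting each herd
#' by its record count, used to evaluate genetic correlations between
#' environments (e.g. the 1 vs 99% extremes).
#'
#' @param f Named herd-effect vector.
#' @param record_herds Herd of each record (defines the weights).
#' @param quantiles Quantiles in (0, 100).
#' @return Named vector of gradient values.
#' @export
quantile_eg_values <- function(f, record_herds,
                               quantiles = c(1, 5, 10, 20, 80, 90, 95, 99)) {
  if (any(quantiles <= 0 | quantiles >= 100))
    stop("quantiles must lie strictly between 0 and 100")
  per_rec <- unname(f[as.character(record_herds)])
  if (anyNA(per_rec)) stop("records in herds without a herd effect")
  stats::setNames(stats::quantile(per_rec, probs = quantiles / 100,
                                  names = FALSE, type = 7),
                  paste0("q", quantiles))
}

#' Evaluation grid along the environmental gradient
#'
#' Points spanning mean +/- `span` standard deviations of the estimated
#' herd effects, with the group and weight each point falls in (for
#' heritability profiles with group-wise residual variances).
#'
#' @param f Named herd-effect vector.
#' @param groups Optional `residual_groups`.
#' @param n Number of points.
#' @param span Half-width in SD units.
#' @return `data.frame` with `f`, `normalized`, `group`, `w`.
#' @export
eg_grid <- function(f, groups = NULL, n = 101L, span = 2.5) {
  mu <- mean(f); sdv <- stats::sd(f)
  pts <- seq(mu - span * sdv, mu + span * sdv, length.out = n)
  if (is.null(groups)) {
    grp <- rep(1L, n); w <- rep(1, n)
  } else {
    ## a grid point belongs to the group of the nearest herd
    hvals <- f[names(groups$herd_group)]
    nearest <- vapply(pts, function(x) which.min(abs(hvals - x)), integer(1))
    grp <- unname(groups$herd_group[nearest])
    w <- groups$weights[grp]
  }
  data.frame(f = pts, normalized = (pts - mu) / sdv, group = grp, w = w)
}

#' G x E summary of a reaction norm fit
#'
#' Intercept-slope correlation, the likelihood-ratio test, and genetic
#' correlations between extreme environmental quantile pairs.
#'
#' @param fit An `rnm_fit`.
#' @param data The phenotype data used (for record weights per herd).
#' @param pairs List of quantile pairs (percent).
#' @return A list with `r_a0a1`, `lrt`, and a `data.frame` `correlations`.
#' @export
gxe_summary <- function(fit, data,
                        pairs = list(c(1, 99), c(5, 95), c(10, 90),
                                     c(20, 80))) {
  qs <- sort(unique(unlist(pairs)))
  eg <- quantile_eg_values(fit$f, data$herd, qs)
  cors <- vapply(pairs, function(pr)
    genetic_correlation(eg[paste0("q", pr[1])], eg[paste0("q", pr[2])],
                        fit), numeric(1))
  data.frame(low = vapply(pairs, `[`, numeric(1), 1),
             high = vapply(pairs, `[`, numeric(1), 2),
             correlation = cors) -> ctab
  list(r_a0a1 = intercept_slope_correlation(fit),
       lrt = lrt_rnm_vs_rm(fit$logLik_rm, fit$logLik_rnm),
       correlations = ctab)
}
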