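#' Fit a log-linear Poisson model by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a Poisson regression with log link on a
#' user-supplied design matrix (an intercept column is added).  The fit is
#' the standard IRLS iteration, run to a tight coefficient tolerance
#' (`1e-10` relative deviance change, at most 100 iterations).  Returns the
#' coefficient vector, its asymptotic covariance (inverse Fisher
#' information), the log-likelihood and AIC.
#'
#' @param counts non-negative integer response, or a [stratum_counts()].
#' @param X design matrix (without intercept); must be full rank.
#' @return list with `coef`, `vcov`, `loglik`, `aic`, `fitted`,
#'   `converged`, `n`, `k`.
#' @export
fit_poisson_loglinear <- function(counts, X) {
  y <- if (inherits(counts, "stratum_counts")) counts$count else counts
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  Xf <- cbind("(Intercept)" = 1, X)
  stopifnot(nrow(Xf) == length(y))
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- glm.fit(Xf, y, family = poisson(),
                 control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge within 100 iterations (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  mu <- fit$fitted.values
  # Fisher information for the log link: X' diag(mu) X
  info <- crossprod(Xf * sqrt(mu))
  vcov <- solve(info)
  ll <- sum(dpois(y, mu, log = TRUE))
  k <- ncol(Xf)
  list(coef = fit$coefficients, vcov = vcov, loglik = ll,
       aic = -2 * ll + 2 * k, fitted = mu, converged = fit$converged,
       n = length(y), k = k)
}

#' Select the calendar-time spline df by AIC
#'
#' Fits the base model (natural spline of time + day-of-week, no
#' pollutant) for each candidate df and returns the AIC-minimising df,
#' ties going to the smaller df.  Residual partial autocorrelations of the
#' chosen model (Pearson residuals, lags 1..14) are returned as a
#' diagnostic for remaining serial structure.
#'
#' @param counts a [stratum_counts()].
#' @param candidate_dfs integer vector of spline df values to compare.
#' @return list with `df`, `aic_table` (data.frame df/aic) and `pacf`
#'   (numeric, lags 1..14).
#' @export
select_df_aic <- function(counts, candidate_dfs) {
  stopifnot(inherits(counts, "stratum_counts"), length(candidate_dfs) >= 1)
  candidate_dfs <- as.integer(candidate_dfs)
  t_num <- as.numeric(counts$date - counts$date[1]) + 1
  dow <- dow_design(counts$date)
  fits <- lapply(candidate_dfs, function(df) {
    B <- natural_spline_basis(t_num, df)$design
    colnames(B) <- paste0("ns", seq_len(df))
    fit_poisson_loglinear(counts, cbind(B, dow))
  })
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  # ties -> smallest df: order by (aic, df)
  best <- order(aics, candidate_dfs)[1]
  chosen <- fits[[best]]
  resid_p <- (counts$count - chosen$fitted) / sqrt(chosen$fitted)
  pac <- as.numeric(pacf(resid_p, lag.max = 14, plot = FALSE)$acf)
  list(df = candidate_dfs[best],
       aic_table = data.frame(df = candidate_dfs, aic = aics),
       pacf = pac)
}
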