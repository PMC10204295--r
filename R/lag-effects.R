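# 97.5th percentile of the standard normal, used for all Wald intervals
Z975 <- 1.959964

#' Relative risk per exposure increment from a log-linear coefficient
#'
#' Converts a log-relative-rate coefficient (per ug/m3) and its standard
#' error into the relative risk per `increment` ug/m3 with a 95% Wald
#' confidence interval on the log scale:
#' `rr = exp(increment * beta)`,
#' `ci = exp(increment * (beta +/- 1.959964 * se))`.
#'
#' @param beta log-relative-rate per ug/m3.
#' @param se standard error of `beta`, >= 0.
#' @param increment exposure increment in ug/m3 (default 10).
#' @return list with `rr`, `ci_low`, `ci_high`.
#' @export
rr_from_beta <- function(beta, se, increment = 10) {
  stopifnot(se >= 0)
  list(rr = exp(increment * beta),
       ci_low = exp(increment * (beta - Z975 * se)),
       ci_high = exp(increment * (beta + Z975 * se)))
}

# shared worker: fit counts ~ ozone lag column(s) + ns(time, df) + DOW
# on days where the counts and all required lagged exposures are valid
fit_lagged_model <- function(counts, exposure, lags, df) {
  stopifnot(inherits(counts, "stratum_counts"),
            inherits(exposure, "daily_series"))
  expo_val <- exposure$value
  expo_val[!exposure$valid] <- NA_real_
  lag_cols <- sapply(lags, function(l) {
    expo_val[match(counts$date - l, exposure$date)]
  })
  lag_cols <- matrix(lag_cols, nrow = nrow(counts))
  colnames(lag_cols) <- paste0("ozone_lag", lags)
  keep <- complete.cases(lag_cols)
  n_use <- sum(keep)
  min_n <- 10 * (df + 8)
  if (n_use < min_n) {
    stop("insufficient usable days after lag alignment: ", n_use,
         " < ", min_n, call. = FALSE)
  }
  dts <- counts$date[keep]
  # a nearly constant exposure cannot identify the lag coefficients
  if (any(apply(lag_cols[keep, , drop = FALSE], 2, sd) < 1e-12)) {
    stop("exposure nearly constant; lag coefficients not identifiable",
         call. = FALSE)
  }
  t_num <- as.numeric(dts - dts[1]) + 1
  B <- natural_spline_basis(t_num, df)$design
  colnames(B) <- paste0("ns", seq_len(df))
  X <- cbind(lag_cols[keep, , drop = FALSE], B, dow_design(dts))
  fit <- fit_poisson_loglinear(counts$count[keep], X)
  fit$lag_names <- colnames(lag_cols)
  fit$n_used <- n_use
  fit
}

#' Single-day lag effect of exposure on admissions
#'
#' Fits `log E(Y_t) = alpha + beta1 * Ozone_{t-lag} + ns(Time, df) +
#' beta2 * DOW` on the days where both series are usable after the lag
#' shift, and reports the relative risk per 10 ug/m3 with its 95% CI and
#' two-sided Wald p-value.
#'
#' @param counts a [stratum_counts()].
#' @param exposure a [daily_series()] of daily-mean ozone.
#' @param lag lag in days, 0..14 by convention (any non-negative value is
#'   accepted).
#' @param df spline df for the calendar-time trend (default 7).
#' @return object of class `lag_effect`: list with `lag`, `beta`, `se`,
#'   `rr10`, `ci_low`, `ci_high`, `p`, `n_used`.
#' @export
fit_single_lag <- function(counts, exposure, lag, df = 7) {
  stopifnot(lag >= 0)
  fit <- fit_lagged_model(counts, exposure, lags = lag, df = df)
  beta <- unname(fit$coef[fit$lag_names])
  se <- sqrt(fit$vcov[fit$lag_names, fit$lag_names])
  rr <- rr_from_beta(beta, se)
  structure(list(lag = lag, beta = beta, se = se, rr10 = rr$rr,
                 ci_low = rr$ci_low, ci_high = rr$ci_high,
                 p = 2 * pnorm(-abs(beta / se)), n_used = fit$n_used),
            class = "lag_effect")
}

#' Cumulative (distributed-lag) effect over lags 0..max_lag
#'
#' Fits one unconstrained distributed-lag model containing the exposure at
#' every lag 0..`max_lag` simultaneously; the cumulative effect is the sum
#' of the lag coefficients with its standard error taken from the full
#' coefficient covariance (`sqrt(1' V 1)`).  A moving-average exposure
#' (mean over the lag window as a single term) is available behind
#' `moving_average = TRUE`.
#'
#' @inheritParams fit_single_lag
#' @param max_lag largest lag in the window (default 5, the "lag05"
#'   cumulative window).
#' @param moving_average if `TRUE`, use the lag-window mean exposure as a
#'   single regressor instead of the unconstrained distributed lag.
#' @return object of class `cumulative_lag_effect`: list with `max_lag`,
#'   `beta_sum`, `se_sum`, `rr10`, `ci_low`, `ci_high`, `p`, `significant`.
#' @export
fit_cumulative_lag <- function(counts, exposure, max_lag = 5, df = 7,
                               moving_average = FALSE) {
  stopifnot(max_lag >= 1)
  if (moving_average) {
    expo_val <- exposure$value
    expo_val[!exposure$valid] <- NA_real_
    # window mean per day, aligned on the exposure's own dates
    ma <- sapply(0:max_lag, function(l)
      expo_val[match(exposure$date - l, exposure$date)])
    mavg <- rowMeans(matrix(ma, nrow = nrow(exposure)))
    expo_ma <- daily_series(exposure$date, pmax(mavg, 0), !is.na(mavg))
    fit <- fit_lagged_model(counts, expo_ma, lags = 0, df = df)
    beta_sum <- unname(fit$coef[fit$lag_names])
    se_sum <- sqrt(fit$vcov[fit$lag_names, fit$lag_names])
  } else {
    fit <- fit_lagged_model(counts, exposure, lags = 0:max_lag, df = df)
    idx <- fit$lag_names
    beta_sum <- sum(fit$coef[idx])
    ones <- rep(1, length(idx))
    se_sum <- sqrt(drop(t(ones) %*% fit$vcov[idx, idx] %*% ones))
  }
  rr <- rr_from_beta(beta_sum, se_sum)
  structure(list(max_lag = max_lag, beta_sum = beta_sum, se_sum = se_sum,
                 rr10 = rr$rr, ci_low = rr$ci_low, ci_high = rr$ci_high,
                 p = 2 * pnorm(-abs(beta_sum / se_sum)),
                 significant = rr$ci_low > 1 || rr$ci_high < 1,
                 n_used = fit$n_used),
            class = "cumulative_lag_effect")
}

#' Z-test for the difference between two group coefficients
#'
#' Compares a coefficient estimated in two independent strata (e.g. male
#' vs female) with `z = (delta1 - delta2) / sqrt(se1^2 + se2^2)` and a
#' two-sided normal p-value.  Swapping the groups negates z and leaves p
#' unchanged.
#'
#' @param delta1,delta2 group coefficients.
#' @param se1,se2 their standard errors (not both zero).
#' @return list with `delta1`, `delta2`, `se1`, `se2`, `z`, `p`.
#' @examples
#' compare_groups_z(0.003, 0.001, 0.001, 0.001)
#' @export
compare_groups_z <- function(delta1, se1, delta2, se2) {
  stopifnot(se1 >= 0, se2 >= 0)
  if (se1 == 0 && se2 == 0) {
    stop("both standard errors are zero", call. = FALSE)
  }
  z <- (delta1 - delta2) / sqrt(se1^2 + se2^2)
  list(delta1 = delta1, delta2 = delta2, se1 = se1, se2 = se2,
       z = z, p = 2 * (1 - pnorm(abs(z))))
}

#' Descriptive Pearson correlation between admissions and exposure
#'
#' Plain Pearson correlation over the overlapping valid days; a
#' descriptive statistic only — lagged regression and cross mapping are
#' the inferential tools.
#'
#' @param counts a [stratum_counts()] (or numeric vector).
#' @param exposure a [daily_series()] (or numeric vector).
#' @return the correlation coefficient.
#' @export
pearson_descriptive <- function(counts, exposure) {
  if (inherits(counts, "stratum_counts") && inherits(exposure, "daily_series")) {
    idx <- match(counts$date, exposure$date)
    ok <- !is.na(idx) & exposure$valid[idx] & !is.na(exposure$value[idx])
    x <- counts$count[ok]
    y <- exposure$value[idx[ok]]
  } else {
    x <- as.numeric(counts)
    y <- as.numeric(exposure)
    ok <- complete.cases(x, y)
    x <- x[ok]
    y <- y[ok]
  }
  if (length(x) < 3) stop("need at least 3 overlapping valid days", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in one of the series", call. = FALSE)
  }
  cor(x, y)
}

#' Lag-effect table across strata in the reporting layout
#'
#' Builds the standard reporting table: rows Lag0..Lag`max_lag` plus the
#' cumulative Lag0`max_lag` row, one column per stratum, cells formatted
#' `rr (ci_low, ci_high)`, together with a long-format machine-readable
#' data.frame (`beta`, `se`, `p` per lag and stratum).
#'
#' @param strata_list named list of [stratum_counts()].
#' @param exposure a [daily_series()].
#' @param max_lag largest single-day lag (default 5).
#' @param df spline df (default 7).
#' @return list with `wide` (formatted data.frame) and `long` (data.frame
#'   with stratum, lag, beta, se, rr10, ci_low, ci_high, p).
#' @export
lag_effect_table <- function(strata_list, exposure, max_lag = 5, df = 7) {
  rows <- c(paste0("Lag", 0:max_lag), paste0("Lag0", max_lag))
  wide <- data.frame(LAG = rows)
  long <- NULL
  for (nm in names(strata_list)) {
    cnt <- strata_list[[nm]]
    effs <- lapply(0:max_lag, function(l)
      fit_single_lag(cnt, exposure, lag = l, df = df))
    cum <- fit_cumulative_lag(cnt, exposure, max_lag = max_lag, df = df)
    fmt <- function(e) sprintf("%.3f(%.3f,%.3f)", e$rr10, e$ci_low, e$ci_high)
    wide[[nm]] <- c(vapply(effs, fmt, character(1)), fmt(cum))
    long <- rbind(long, data.frame(
      stratum = nm,
      lag = c(as.character(0:max_lag), paste0("0-", max_lag)),
      beta = c(vapply(effs, function(e) e$beta, numeric(1)), cum$beta_sum),
      se = c(vapply(effs, function(e) e$se, numeric(1)), cum$se_sum),
      rr10 = c(vapply(effs, function(e) e$rr10, numeric(1)), cum$rr10),
      ci_low = c(vapply(effs, function(e) e$ci_low, numeric(1)), cum$ci_low),
      ci_high = c(vapply(effs, function(e) e$ci_high, numeric(1)), cum$ci_high),
      p = c(vapply(effs, function(e) e$p, numeric(1)), cum$p)))
  }
  list(wide = wide, long = long)
}
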