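#' Simulate a seasonal daily exposure series
#'
#' Emulates the annual cycle of daily-mean ground-level ozone as a sinusoid
#' with a 365-day period plus AR(1) noise, clipped at zero.  This
#' reproduces the warm-season peak structure of urban ozone without any
#' atmospheric-chemistry modelling.
#'
#' @param n_days series length (days), >= 1.
#' @param mean_level long-run mean concentration (ug/m3), > 0.
#' @param seasonal_amplitude half peak-to-trough amplitude of the annual
#'   sinusoid (ug/m3).
#' @param ar_coef AR(1) coefficient of the noise, |ar_coef| < 1.
#' @param noise_sd innovation standard deviation of the AR(1) noise (ug/m3).
#' @param seed RNG seed.
#' @param start_date first calendar day (`Date` or ISO string).
#' @param phase phase offset of the sinusoid in days (peak at
#'   `phase + 365/4` days after start when 0).
#' @return a [daily_series()] with all days valid.
#' @examples
#' oz <- simulate_exposure(365, mean_level = 70, seasonal_amplitude = 40,
#'                         ar_coef = 0.7, noise_sd = 10, seed = 1)
#' @export
simulate_exposure <- function(n_days, mean_level = 70,
                              seasonal_amplitude = 40, ar_coef = 0.7,
                              noise_sd = 10, seed = 1L,
                              start_date = "2013-01-01", phase = 0) {
  stopifnot(n_days >= 1, mean_level > 0, abs(ar_coef) < 1, noise_sd >= 0)
  set.seed(seed)
  t <- seq_len(n_days)
  seasonal <- seasonal_amplitude * sin(2 * pi * (t - phase) / 365)
  if (noise_sd > 0) {
    e <- numeric(n_days)
    e[1] <- rnorm(1, 0, noise_sd / sqrt(1 - ar_coef^2))
    if (n_days > 1) {
      innov <- rnorm(n_days - 1, 0, noise_sd)
      for (i in 2:n_days) e[i] <- ar_coef * e[i - 1] + innov[i - 1]
    }
  } else {
    e <- numeric(n_days)
  }
  vals <- pmax(mean_level + seasonal + e, 0)
  daily_series(seq(as.Date(start_date), by = "day", length.out = n_days), vals)
}

#' Configuration for the admission-count simulator
#'
#' Holds the parameters of the log-linear Poisson model generating daily
#' admission counts: intercept, per-lag exposure effects, a smooth
#' calendar-time trend expressed on a natural-cubic-spline basis, and
#' additive day-of-week effects.
#'
#' @param n_days number of count days to generate.
#' @param alpha intercept on the log scale (log expected count at baseline).
#' @param beta1 numeric vector of exposure effects on the log-relative-rate
#'   scale, one entry per lag starting at lag 0 (per ug/m3).
#' @param trend_coefs coefficients applied to a natural-spline basis of
#'   calendar time with `df = length(trend_coefs)`; use `numeric(0)` for no
#'   trend.
#' @param dow_effects exactly 7 additive log-scale day-of-week effects,
#'   ordered Monday..Sunday.
#' @param seed RNG seed for the Poisson draws.
#' @return an object of class `health_sim_config`.
#' @export
health_sim_config <- function(n_days, alpha = log(100), beta1 = 0,
                              trend_coefs = numeric(0),
                              dow_effects = rep(0, 7), seed = 1L) {
  stopifnot(n_days > length(beta1) - 1L)
  if (length(dow_effects) != 7L) {
    stop("dow_effects must have exactly 7 entries (Monday..Sunday)",
         call. = FALSE)
  }
  structure(list(n_days = as.integer(n_days), alpha = alpha,
                 beta1 = as.numeric(beta1),
                 trend_coefs = as.numeric(trend_coefs),
                 dow_effects = as.numeric(dow_effects),
                 seed = as.integer(seed)),
            class = "health_sim_config")
}

#' Simulate daily admission counts from the log-linear Poisson model
#'
#' Counts are drawn Poisson with log-mean
#' `alpha + sum_l beta1[l] * exposure[t - l] + trend(t) + dow(t)`.
#' The calendar-time trend is evaluated through the same natural-spline
#' basis constructor used by the regression module
#' ([natural_spline_basis()]), so a fitted model with the generating `df`
#' is correctly specified.
#'
#' The first `length(beta1) - 1` exposure days serve as lag lead-in: the
#' returned counts start on exposure day `length(beta1)` and are aligned
#' with the exposure dates.
#'
#' @param exposure a [daily_series()]; must have at least
#'   `cfg$n_days + length(cfg$beta1) - 1` days.
#' @param cfg a [health_sim_config()].
#' @return a [stratum_counts()] series of `cfg$n_days` days.
#' @export
simulate_counts <- function(exposure, cfg) {
  stopifnot(inherits(exposure, "daily_series"),
            inherits(cfg, "health_sim_config"))
  max_lag <- length(cfg$beta1) - 1L
  need <- cfg$n_days + max_lag
  if (nrow(exposure) < need) {
    stop("exposure too short: need at least ", need, " days, got ",
         nrow(exposure), call. = FALSE)
  }
  t_out <- (max_lag + 1L):(max_lag + cfg$n_days)  # exposure rows of count days
  eta <- rep(cfg$alpha, cfg$n_days)
  for (l in seq_along(cfg$beta1)) {
    eta <- eta + cfg$beta1[l] * exposure$value[t_out - (l - 1L)]
  }
  if (length(cfg$trend_coefs) > 0) {
    basis <- natural_spline_basis(seq_len(cfg$n_days),
                                  df = length(cfg$trend_coefs))
    eta <- eta + drop(basis$design %*% cfg$trend_coefs)
  }
  dates <- exposure$date[t_out]
  dow <- dow_index(dates)
  eta <- eta + cfg$dow_effects[dow]
  set.seed(cfg$seed)
  counts <- rpois(cfg$n_days, exp(eta))
  stratum_counts(dates, counts)
}

# ISO day-of-week index, 1 = Monday .. 7 = Sunday
dow_index <- function(dates) {
  (as.integer(format(as.Date(dates), "%u")))
}

#' Disaggregate daily counts into record-level admissions
#'
#' Expands a stratum count series into one row per admission, drawing
#' gender, age group and ICD-10 code from the stated distributions.  Ages
#' are sampled uniformly within the drawn band (0-14, 15-64, 65-100).
#' Re-aggregating the records recovers the input series exactly.
#'
#' @param counts a [stratum_counts()] series.
#' @param gender_probs named numeric `c(male = , female = )` summing to 1.
#' @param age_group_probs numeric length-3 probabilities for the bands
#'   0-14, 15-64, 65+, summing to 1.
#' @param icd_pool character vector of ICD-10 codes to sample uniformly;
#'   must be non-empty and well-formed (letter + two digits + optional
#'   subcode).
#' @param seed RNG seed.
#' @param hospital_ids hospitals sampled uniformly per record.
#' @return a data.frame with columns `date`, `hospital`, `gender`, `age`,
#'   `icd10`; one row per admission.
#' @export
disaggregate_records <- function(counts,
                                 gender_probs = c(male = 0.601, female = 0.399),
                                 age_group_probs = c(0.85, 0.10, 0.05),
                                 icd_pool = c("J06.9", "J21", "J45"),
                                 seed = 1L,
                                 hospital_ids = "H01") {
  stopifnot(inherits(counts, "stratum_counts"))
  if (length(icd_pool) == 0) stop("icd_pool must be non-empty", call. = FALSE)
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Za-z]+)?$", icd_pool)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ", paste(icd_pool[bad], collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(gender_probs) - 1) > 1e-8 || abs(sum(age_group_probs) - 1) > 1e-8) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  n_total <- sum(counts$count)
  if (n_total == 0) {
    return(data.frame(date = as.Date(character(0)), hospital = character(0),
                      gender = character(0), age = integer(0),
                      icd10 = character(0)))
  }
  set.seed(seed)
  dates <- rep(counts$date, counts$count)
  gender <- sample(c("male", "female"), n_total, replace = TRUE,
                   prob = gender_probs[c("male", "female")])
  band <- sample(1:3, n_total, replace = TRUE, prob = age_group_probs)
  lo <- c(0, 15, 65)[band]
  hi <- c(14, 64, 100)[band]
  age <- lo + floor(runif(n_total) * (hi - lo + 1))
  data.frame(date = dates,
             hospital = sample(hospital_ids, n_total, replace = TRUE),
             gender = gender,
             age = as.integer(age),
             icd10 = sample(icd_pool, n_total, replace = TRUE))
}

#' Write admission records in the ingest CSV dialect
#'
#' Columns `date,hospital,gender,age,icd10` with ISO-8601 dates.
#'
#' @param records data.frame as produced by [disaggregate_records()].
#' @param path file path.
#' @export
write_admissions <- function(records, path) {
  write.csv(data.frame(date = format(as.Date(records$date)),
                       hospital = records$hospital, gender = records$gender,
                       age = records$age, icd10 = records$icd10),
            path, row.names = FALSE, quote = FALSE)
}
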