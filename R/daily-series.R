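#' Daily exposure series
#'
#' A daily exposure series holds one value per calendar day (daily-mean
#' pollutant concentration in ug/m3) together with a per-day validity flag:
#' days failing quality control carry `valid = FALSE` and `NA` values.
#'
#' @param dates a `Date` vector, strictly increasing.
#' @param values numeric, same length as `dates`; non-missing values must
#'   be >= 0.
#' @param valid logical flag per day; defaults to `!is.na(values)`.
#' @return a data.frame of class `daily_series` with columns
#'   `date`, `value`, `valid`.
#' @export
daily_series <- function(dates, values, valid = !is.na(values)) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values), length(valid) == length(values))
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(values[!is.na(values)] < 0)) {
    stop("exposure values must be non-negative", call. = FALSE)
  }
  values[!valid] <- NA_real_
  structure(data.frame(date = dates, value = as.numeric(values),
                       valid = as.logical(valid)),
            class = c("daily_series", "data.frame"))
}

#' Stratum count series
#'
#' Daily non-negative admission counts for one (disease category x gender x
#' age-group) stratum.
#'
#' @param dates a `Date` vector, strictly increasing.
#' @param counts non-negative integer counts, same length as `dates`.
#' @param category one of `"TOTAL_RESP"`, `"AURD"`, `"ALRD"`.
#' @param gender one of `"male"`, `"female"`, `"all"`.
#' @param age_group one of `"0-14"`, `"15-64"`, `"65+"`, `"all"`.
#' @return a data.frame of class `stratum_counts` with columns `date`,
#'   `count` and stratum labels stored as attributes.
#' @export
stratum_counts <- function(dates, counts, category = "TOTAL_RESP",
                           gender = "all", age_group = "all") {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(counts))
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  category <- match.arg(category, c("TOTAL_RESP", "AURD", "ALRD", "OTHER_RESP"))
  gender <- match.arg(gender, c("all", "male", "female"))
  age_group <- match.arg(age_group, c("all", "0-14", "15-64", "65+"))
  structure(data.frame(date = dates, count = as.integer(counts)),
            category = category, gender = gender, age_group = age_group,
            class = c("stratum_counts", "data.frame"))
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> %d days (%s .. %s), %d valid\n",
              nrow(x), format(min(x$date)), format(max(x$date)),
              sum(x$valid)))
  invisible(x)
}

#' @export
print.stratum_counts <- function(x, ...) {
  cat(sprintf("<stratum_counts> %s / %s / %s: %d days, total %d admissions\n",
              attr(x, "category"), attr(x, "gender"), attr(x, "age_group"),
              nrow(x), sum(x$count)))
  invisible(x)
}

#' Write / read a daily series CSV
#'
#' The on-disk dialect is `date,value,valid` with ISO-8601 dates; it is
#' shared between the generators and the ingest layer.
#'
#' @param x a `daily_series`.
#' @param path file path.
#' @export
write_daily_series <- function(x, path) {
  stopifnot(inherits(x, "daily_series"))
  write.csv(data.frame(date = format(x$date), value = x$value,
                       valid = x$valid),
            path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else !is.na(df$value)
  daily_series(as.Date(df$date), as.numeric(df$value), valid)
}
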