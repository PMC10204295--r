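#' Read hourly station monitoring data
#'
#' Reads a CSV with columns `station,lon,lat,timestamp,ozone_ugm3` into one
#' hourly series per station.  Unparsable concentration cells become
#' missing values with a warning; series length is unchanged.
#'
#' @param path CSV file path.
#' @param dialect timestamp dialect: `"iso"` (ISO-8601, default) or
#'   `"dmy"` (`dd/mm/yyyy HH`). Never auto-guessed.
#' @return a list of station series; each element is a list with
#'   `station_id`, `lon`, `lat`, `timestamps` (POSIXct) and `values`.
#' @export
read_station_hourly <- function(path, dialect = c("iso", "dmy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("station", "lon", "lat", "timestamp", "ozone_ugm3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) return(list())
  fmt <- if (dialect == "iso") "%Y-%m-%d %H:%M:%S" else "%d/%m/%Y %H:%M:%S"
  ts <- as.POSIXct(df$timestamp, format = fmt, tz = "UTC")
  if (anyNA(ts)) {
    # allow hour-only timestamps in either dialect
    fmt2 <- if (dialect == "iso") "%Y-%m-%dT%H:%M:%S" else "%d/%m/%Y %H"
    ts[is.na(ts)] <- as.POSIXct(df$timestamp[is.na(ts)], format = fmt2,
                                tz = "UTC")
  }
  if (anyNA(ts)) stop("unparsable timestamp(s) in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(df$ozone_ugm3))
  bad <- !is.na(df$ozone_ugm3) & df$ozone_ugm3 != "" & is.na(vals)
  if (any(bad)) {
    warning(sum(bad), " non-numeric concentration value(s) set to missing",
            call. = FALSE)
  }
  if (any(vals[!is.na(vals)] < 0)) {
    stop("negative concentration value(s) in ", path, call. = FALSE)
  }
  out <- lapply(split(seq_len(nrow(df)), df$station), function(idx) {
    o <- idx[order(ts[idx])]
    list(station_id = df$station[o[1]],
         lon = as.numeric(df$lon[o[1]]),
         lat = as.numeric(df$lat[o[1]]),
         timestamps = ts[o],
         values = vals[o])
  })
  unname(out)
}

#' Daily mean with completeness-based quality control
#'
#' Aggregates one station's hourly series to daily means.  A day is valid
#' only when the fraction of non-missing hours (out of 24) reaches
#' `min_completeness`; its value is the arithmetic mean of the non-missing
#' hours.  Days failing QC (instrument failure) are flagged invalid.  The
#' result does not depend on the order of the hourly rows.
#'
#' @param series one station series from [read_station_hourly()].
#' @param min_completeness minimum fraction of the 24 hours that must be
#'   present, in (0, 1]; default 0.75 (18 of 24 hours).
#' @return a [daily_series()].
#' @export
daily_mean_qc <- function(series, min_completeness = 0.75) {
  stopifnot(min_completeness > 0, min_completeness <= 1)
  day <- as.Date(series$timestamps, tz = "UTC")
  n_ok <- tapply(!is.na(series$values), day, sum)
  means <- tapply(series$values, day, mean, na.rm = TRUE)
  dates <- as.Date(names(n_ok))
  valid <- as.vector(n_ok) / 24 >= min_completeness
  vals <- as.vector(means)
  vals[!valid | is.nan(vals)] <- NA_real_
  o <- order(dates)
  daily_series(dates[o], vals[o], valid[o])
}

#' Pool per-station daily series into a citywide series
#'
#' The citywide daily exposure is the unweighted mean over stations with a
#' valid value that day; the day is invalid when the fraction of stations
#' reporting a valid value falls below `min_fraction`.
#'
#' @param per_station list of [daily_series()], one per station.
#' @param min_fraction minimum fraction of stations that must report for a
#'   day to be valid; default 0.5.
#' @return a [daily_series()] over the union of dates.
#' @export
pool_citywide <- function(per_station, min_fraction = 0.5) {
  stopifnot(length(per_station) >= 1)
  all_dates <- sort(unique(as.Date(unlist(lapply(per_station,
                                                 function(s) s$date)))))
  if (length(all_dates) == 0) stop("no overlapping dates", call. = FALSE)
  n_st <- length(per_station)
  sums <- numeric(length(all_dates))
  ns <- integer(length(all_dates))
  for (s in per_station) {
    idx <- match(s$date, all_dates)
    ok <- s$valid & !is.na(s$value)
    sums[idx[ok]] <- sums[idx[ok]] + s$value[ok]
    ns[idx[ok]] <- ns[idx[ok]] + 1L
  }
  valid <- ns / n_st >= min_fraction & ns > 0
  vals <- ifelse(ns > 0, sums / ns, NA_real_)
  vals[!valid] <- NA_real_
  daily_series(all_dates, vals, valid)
}

#' Map each hospital to its nearest monitoring station
#'
#' Distances are great-circle (haversine) on a 6371 km sphere; ties are
#' broken by lexicographic station id.  Exposure can then be assigned to
#' patients by the station nearest to their hospital.
#'
#' @param hospital_coords data.frame with columns `id`, `lon`, `lat`
#'   (decimal degrees).
#' @param station_coords data.frame with the same columns.
#' @return named character vector: `hospital id -> station id`.
#' @export
assign_nearest_station <- function(hospital_coords, station_coords) {
  for (df in list(hospital_coords, station_coords)) {
    stopifnot(nrow(df) >= 1, all(c("id", "lon", "lat") %in% names(df)))
    if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180)) {
      stop("invalid coordinates: |lat| > 90 or |lon| > 180", call. = FALSE)
    }
  }
  d <- geosphere::distm(cbind(hospital_coords$lon, hospital_coords$lat),
                        cbind(station_coords$lon, station_coords$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000))
  ord <- order(station_coords$id)  # tie-break: lexicographic station id
  nearest <- apply(d[, ord, drop = FALSE], 1, which.min)
  out <- station_coords$id[ord][nearest]
  names(out) <- hospital_coords$id
  out
}

#' Classify an ICD-10 code into respiratory disease categories
#'
#' Classification uses the 3-character root: J00-J06 are acute upper
#' respiratory diseases (AURD), J20-J22 acute lower respiratory diseases
#' (ALRD), any other J00-J99 code OTHER_RESP, and non-J chapters NON_RESP.
#' Subcodes such as `"J06.9"` inherit their root's category.
#'
#' @param code character vector of ICD-10 codes.
#' @return character vector of categories, same length as `code`.
#' @examples
#' classify_icd10(c("J06.9", "J21", "J45", "K52"))
#' @export
classify_icd10 <- function(code) {
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Za-z]+)?$", code)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ", paste(unique(code[bad]), collapse = ", "),
         call. = FALSE)
  }
  root_num <- as.integer(substr(code, 2, 3))
  is_j <- substr(code, 1, 1) == "J"
  out <- rep("NON_RESP", length(code))
  out[is_j] <- "OTHER_RESP"
  out[is_j & root_num <= 6] <- "AURD"
  out[is_j & root_num >= 20 & root_num <= 22] <- "ALRD"
  out
}

#' Read admission records in the standard CSV dialect
#'
#' @param path CSV with columns `date,hospital,gender,age,icd10`.
#' @param dialect date dialect, `"iso"` or `"dmy"` (`dd/mm/yyyy`).
#' @return a data.frame of admission records with `Date` dates.
#' @export
read_admissions <- function(path, dialect = c("iso", "dmy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "hospital", "gender", "age", "icd10")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fmt <- if (dialect == "iso") "%Y-%m-%d" else "%d/%m/%Y"
  df$date <- as.Date(df$date, format = fmt)
  if (anyNA(df$date)) stop("unparsable date(s) in ", path, call. = FALSE)
  df
}

ALL_CATEGORIES <- c("TOTAL_RESP", "AURD", "ALRD")
ALL_GENDERS <- c("all", "male", "female")
ALL_AGE_GROUPS <- c("all", "0-14", "15-64", "65+")

age_band <- function(age, elderly_from = 65) {
  ifelse(age <= 14, "0-14", ifelse(age < elderly_from, "15-64", "65+"))
}

#' Aggregate admission records into daily stratified count series
#'
#' Builds every (category x gender x age-group) stratum over the date
#' range, zero-filled on days without admissions.  `TOTAL_RESP` counts
#' every J00-J99 record; `AURD`/`ALRD` follow [classify_icd10()].  The
#' `all` strata are exact marginals: male + female = all and the three age
#' bands sum to all, on every date.  Age 65 falls in the elderly band.
#'
#' @param records data.frame with `date`, `gender`, `age`, `icd10`.
#' @param date_range length-2 `Date` (or ISO string) vector covering all
#'   record dates.
#' @return a named list of [stratum_counts()], keys
#'   `"<category>|<gender>|<age_group>"`.
#' @export
aggregate_daily_counts <- function(records, date_range) {
  date_range <- as.Date(date_range)
  dates <- seq(date_range[1], date_range[2], by = "day")
  if (nrow(records) > 0) {
    rd <- as.Date(records$date)
    if (any(rd < date_range[1] | rd > date_range[2])) {
      stop("record date(s) outside date_range", call. = FALSE)
    }
    cat4 <- classify_icd10(records$icd10)
    resp <- cat4 != "NON_RESP"
    band <- age_band(records$age)
  }
  out <- list()
  for (category in ALL_CATEGORIES) {
    if (nrow(records) > 0) {
      in_cat <- if (category == "TOTAL_RESP") resp else cat4 == category
    }
    for (gender in ALL_GENDERS) {
      for (ag in ALL_AGE_GROUPS) {
        if (nrow(records) == 0) {
          cnt <- integer(length(dates))
        } else {
          sel <- in_cat &
            (gender == "all" | records$gender == gender) &
            (ag == "all" | band == ag)
          tab <- table(factor(as.character(rd[sel]),
                              levels = as.character(dates)))
          cnt <- as.integer(tab)
        }
        key <- paste(category, gender, ag, sep = "|")
        out[[key]] <- stratum_counts(dates, cnt, category, gender, ag)
      }
    }
  }
  out
}

#' Extract one stratum from an aggregated count list
#'
#' @param strata result of [aggregate_daily_counts()].
#' @param category,gender,age_group stratum labels.
#' @return a [stratum_counts()].
#' @export
get_stratum <- function(strata, category = "TOTAL_RESP", gender = "all",
                        age_group = "all") {
  key <- paste(category, gender, age_group, sep = "|")
  if (is.null(strata[[key]])) stop("no such stratum: ", key, call. = FALSE)
  strata[[key]]
}
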