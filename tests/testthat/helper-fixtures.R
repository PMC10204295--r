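# Shared fixture builders; everything is generated in code at test time.

# one-way coupled benchmark (y drives x) at the generator defaults
one_way_system <- function(seed, n = 1000, beta_xy = 0.32) {
  simulate_coupled_maps(coupled_map_config(beta_xy = beta_xy, beta_yx = 0,
                                           n = n, burn_in = 200, seed = seed))
}

# hourly ozone CSV with the ingest dialect; `values` is a named list
# station -> numeric vector (one value per hour, NA allowed)
write_hourly_fixture <- function(path, values, start = "2013-01-01",
                                 lon = 114, lat = 22.5) {
  rows <- do.call(rbind, lapply(names(values), function(st) {
    v <- values[[st]]
    ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
              by = "hour", length.out = length(v))
    data.frame(station = st, lon = lon, lat = lat,
               timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
               ozone_ugm3 = v)
  }))
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# z-scored helper
zs <- function(v) (v - mean(v)) / sd(v)
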