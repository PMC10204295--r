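#' Natural cubic spline basis for calendar time
#'
#' Builds a natural cubic regression-spline basis with `df` columns:
#' interior knots at equally spaced quantiles of the evaluation times and
#' boundary knots at their range, with the natural condition (zero second
#' derivative, hence linearity) beyond the boundary knots.  This is the
#' smooth calendar-time term that absorbs season and long-term trend in
#' the admission model.
#'
#' @param times numeric time positions, strictly increasing.
#' @param df degrees of freedom (number of basis columns), >= 1 and smaller
#'   than the number of distinct times.
#' @return an object of class `spline_basis`: a list with `df`,
#'   `interior_knots`, `boundary_knots`, `times` and the `design` matrix
#'   (length(times) x df).
#' @export
natural_spline_basis <- function(times, df) {
  stopifnot(df >= 1)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (df >= length(unique(times))) {
    stop("df must be smaller than the number of distinct times", call. = FALSE)
  }
  B <- splines::ns(times, df = df)
  structure(list(df = df,
                 interior_knots = as.numeric(attr(B, "knots")),
                 boundary_knots = as.numeric(attr(B, "Boundary.knots")),
                 times = times,
                 design = unclass(B)[, , drop = FALSE]),
            class = "spline_basis")
}

#' Day-of-week indicator design
#'
#' Treatment-coded indicators for the day of the week with Monday as the
#' reference level: 6 columns (Tue..Sun), each row summing to at most 1.
#'
#' @param dates a `Date` vector.
#' @return numeric matrix with 6 columns named `dowTue`..`dowSun`.
#' @export
dow_design <- function(dates) {
  idx <- dow_index(dates)
  lev <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  M <- matrix(0, nrow = length(dates), ncol = 6,
              dimnames = list(NULL, paste0("dow", lev[2:7])))
  for (k in 2:7) M[idx == k, k - 1] <- 1
  M
}
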