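#' Delay embedding (shadow manifold) of a scalar time series
#'
#' Reconstructs the lagged-coordinate vectors
#' `x(t) = <x_t, x_{t-tau}, ..., x_{t-(E-1)tau}>` for
#' `t = 1 + (E-1)tau, ..., L`.  By Takens' theorem the resulting shadow
#' manifold is (generically) diffeomorphic to the attractor of the full
#' dynamical system, which is what makes cross-map estimation possible.
#'
#' @param series numeric vector of length `L > (E-1) * tau`.
#' @param E embedding dimension, >= 1.
#' @param tau delay in time steps, >= 1.
#' @return object of class `delay_embedding`: list with `E`, `tau`,
#'   `vectors` (matrix, one row per vector, `E` columns ordered
#'   `x_t, x_{t-tau}, ...`) and `t_index` (origin time of each vector,
#'   1-based).
#' @examples
#' delay_embed(c(1, 2, 3, 4, 5, 6), E = 2, tau = 2)$vectors
#' @export
delay_embed <- function(series, E, tau) {
  stopifnot(E >= 1, tau >= 1)
  L <- length(series)
  min_len <- (E - 1) * tau + 1
  if (L < min_len) {
    stop("series too short: need length > ", (E - 1) * tau,
         " for E = ", E, ", tau = ", tau, call. = FALSE)
  }
  t_index <- seq.int(1 + (E - 1) * tau, L)
  vectors <- vapply(0:(E - 1), function(k) series[t_index - k * tau],
                    numeric(length(t_index)))
  vectors <- matrix(vectors, nrow = length(t_index))
  structure(list(E = as.integer(E), tau = as.integer(tau),
                 vectors = vectors, t_index = as.integer(t_index)),
            class = "delay_embedding")
}

#' Exponential nearest-neighbour weights
#'
#' Given the sorted distances from a predictee to its `E + 1` nearest
#' library neighbours, the unnormalised weights are
#' `u_i = exp(-d_i / d_1)` and the weights `w_i = u_i / sum(u_j)`.
#' When the nearest distance is zero, the weight mass is split equally
#' among all zero-distance neighbours (the limit of the formula for exact
#' matches) and the rest get zero.
#'
#' @param distances numeric vector of non-negative distances sorted
#'   ascending (length `E + 1`).
#' @return numeric weights summing to 1.
#' @examples
#' neighbor_weights(c(2, 4, 6))
#' @export
neighbor_weights <- function(distances) {
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  if (is.unsorted(distances)) {
    stop("distances must be sorted ascending", call. = FALSE)
  }
  if (distances[1] == 0) {
    w <- as.numeric(distances == 0)
    return(w / sum(w))
  }
  u <- exp(-distances / distances[1])
  u / sum(u)
}

#' Select the embedding delay by average mutual information
#'
#' Computes the average mutual information I(lag) between `x_t` and
#' `x_{t+lag}` from a 2-D histogram with `n_bins` equal-width bins per
#' axis, for lags 1..`max_lag`, and returns the first local minimum of
#' I(lag) — the standard heuristic for a delay that makes the embedding
#' coordinates maximally informative.  If no local minimum exists (e.g.
#' i.i.d. noise, where I(lag) is flat), the argmin over 1..`max_lag` is
#' returned with a message.
#'
#' @param series numeric vector, non-constant, much longer than `max_lag`.
#' @param max_lag largest lag considered, >= 1.
#' @param n_bins histogram bins per axis (default 16).
#' @return the selected delay (integer in 1..`max_lag`); the AMI profile
#'   is attached as attribute `"ami"`.
#' @export
select_tau_ami <- function(series, max_lag = 10, n_bins = 16) {
  stopifnot(max_lag >= 1, n_bins >= 2)
  if (sd(series) == 0) stop("constant series", call. = FALSE)
  n <- length(series)
  if (n <= max_lag + 1) stop("series too short for max_lag", call. = FALSE)
  brk <- seq(min(series), max(series), length.out = n_bins + 1)
  bin <- findInterval(series, brk, rightmost.closed = TRUE, all.inside = TRUE)
  ami <- vapply(seq_len(max_lag), function(lag) {
    a <- bin[1:(n - lag)]
    b <- bin[(1 + lag):n]
    jt <- table(a, b) / (n - lag)
    pa <- rowSums(jt)
    pb <- colSums(jt)
    nz <- jt > 0
    sum(jt[nz] * log(jt[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
  # first local minimum; I(0) (the marginal entropy) always dominates I(1),
  # so lag 1 qualifies whenever I(1) < I(2)
  tau <- NA_integer_
  for (k in seq_len(max_lag - 1L)) {
    left_ok <- if (k == 1) TRUE else ami[k] < ami[k - 1]
    if (left_ok && ami[k] < ami[k + 1]) {
      tau <- k
      break
    }
  }
  if (is.na(tau)) {
    tau <- which.min(ami)
    message("no local minimum in the AMI profile; using global argmin lag ",
            tau)
  }
  structure(as.integer(tau), ami = ami)
}

#' Select the embedding dimension by false nearest neighbours
#'
#' For each `E = 1..E_max`, every point's nearest neighbour in the
#' E-dimensional embedding is tested: it is "false" when the distance
#' added by the next delay coordinate, relative to the E-dimensional
#' distance, exceeds `r_tol` — meaning the apparent closeness was a
#' projection artefact.  Following the usual construction, the added
#' coordinate extends the delay vector forward in time (`x[t + E * tau]`
#' for a vector starting at `t`); for non-invertible dynamics such as the
#' logistic map a backward coordinate is not a function of the state and
#' would flag genuine neighbours as false.  The smallest `E` with a
#' false-neighbour fraction below 5% is returned; if none qualifies,
#' `E_max` with a warning.
#'
#' @param series numeric vector.
#' @param tau embedding delay.
#' @param E_max largest dimension tried, >= 2.
#' @param r_tol distance-ratio tolerance (default 10, the usual Kennel
#'   choice).
#' @return selected dimension (integer in 1..`E_max`); the per-E FNN
#'   fractions are attached as attribute `"fnn"`.
#' @export
select_E_fnn <- function(series, tau = 1, E_max = 6, r_tol = 10) {
  stopifnot(E_max >= 2, tau >= 1)
  L <- length(series)
  if (L <= E_max * tau + 1) {
    stop("series too short for E_max = ", E_max, " at tau = ", tau,
         call. = FALSE)
  }
  frac <- numeric(E_max)
  for (E in seq_len(E_max)) {
    # forward delay vectors v(t) = (x_t, x_{t+tau}, ..., x_{t+(E-1)tau});
    # the (E+1)-th coordinate is x_{t+E*tau}, so only starts with
    # t + E*tau <= L are testable
    starts <- seq_len(L - E * tau)
    V <- vapply(0:(E - 1), function(k) series[starts + k * tau],
                numeric(length(starts)))
    V <- matrix(V, nrow = length(starts))
    n <- nrow(V)
    if (n < 3) stop("series too short for FNN at E = ", E, call. = FALSE)
    n_false <- 0L
    for (i in seq_len(n)) {
      d2 <- rowSums((V - matrix(V[i, ], n, ncol(V), byrow = TRUE))^2)
      d2[i] <- Inf
      j <- which.min(d2)
      dE <- sqrt(d2[j])
      extra <- abs(series[starts[i] + E * tau] - series[starts[j] + E * tau])
      false_nbr <- if (dE == 0) extra > 0 else extra / dE > r_tol
      if (false_nbr) n_false <- n_false + 1L
    }
    frac[E] <- n_false / n
    if (frac[E] < 0.05) {
      return(structure(as.integer(E), fnn = frac[seq_len(E)]))
    }
  }
  warning("false-neighbour fraction never fell below 5%; returning E_max = ",
          E_max, call. = FALSE)
  structure(as.integer(E_max), fnn = frac)
}
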