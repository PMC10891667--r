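#' Low-pass filter specification
#'
#' Parameters of the no-lag (zero-phase) low-pass Butterworth filter applied
#' to both measurement chains before indicator extraction.
#'
#' @param cutoff Cut-off frequency (Hz). Default 15 Hz, the value used
#'   throughout gait-initiation work at 85 Hz sampling.
#' @param order Filter order per pass. Default 2; the forward-backward
#'   application makes the effective magnitude response 4th order.
#' @param zero_phase Apply the filter forward then backward (no net phase
#'   shift). Default `TRUE`.
#' @return An object of class `gi_filter_spec`.
#' @export
filter_spec <- function(cutoff = 15, order = 2, zero_phase = TRUE) {
  assert_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  assert_number(order, "order", lower = 1, upper = 8)
  if (order != round(order)) stopf("'order' must be a whole number")
  stopifnot(is.logical(zero_phase), length(zero_phase) == 1L)
  structure(list(cutoff = cutoff, order = as.integer(order), zero_phase = zero_phase),
            class = "gi_filter_spec")
}

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

# Butterworth low-pass IIR design via bilinear transform.
# Returns list(b, a) with a[1] == 1.
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stopf("cutoff must lie in (0, fs/2) = (0, %g); got %g", fs / 2, cutoff)
  }
  warped <- 2 * fs * tan(pi * cutoff / fs)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p <- warped * exp(1i * theta)               # analog poles, left half-plane
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)                 # bilinear-transformed poles
  gain <- Re(warped^order / prod(fs2 - p))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(pz))
  list(b = b / a[1], a = a / a[1])
}

# Direct-form II transposed IIR filter with initial state zi (length n-1).
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  nz <- n - 1L
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nz > 1L) {
      z[1L:(nz - 1L)] <- b[2L:nz] * xi + z[2L:nz] - a[2L:nz] * yi
    }
    z[nz] <- b[nz + 1L] * xi - a[nz + 1L] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for a unit step input (scipy lfilter_zi).
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- matrix(0, n - 1, n - 1)             # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a Butterworth low-pass filter forward and then backward so the net
#' phase shift is zero and event timing is preserved. Edges are handled by
#' odd (point-reflected) padding of three filter lengths with steady-state
#' initial conditions, so a constant series passes through unchanged.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered series, same length as `x`.
#' @export
lowpass_zero_phase <- function(x, fs, spec = filter_spec()) {
  assert_numeric_vec(x, "x", min_len = 2L)
  assert_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (!inherits(spec, "gi_filter_spec")) stopf("'spec' must be a gi_filter_spec")
  ba <- butter_lowpass(spec$order, spec$cutoff, fs)
  ntaps <- max(length(ba$a), length(ba$b))
  padlen <- 3L * ntaps
  if (length(x) <= padlen) {
    stopf("series too short for filtering: need > %d samples, got %d", padlen, length(x))
  }
  if (!spec$zero_phase) {
    return(iir_filter(ba$b, ba$a, x, filter_zi(ba$b, ba$a) * x[1L]))
  }
  nx <- length(x)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L],
           x,
           2 * x[nx] - x[(nx - 1L):(nx - padlen)])
  zi <- filter_zi(ba$b, ba$a)
  y <- iir_filter(ba$b, ba$a, ext, zi * ext[1L])
  y <- rev(iir_filter(ba$b, ba$a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + nx)]
}
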