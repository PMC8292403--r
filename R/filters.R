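# Zero-phase Butterworth filtering. The coefficient design (bilinear
# transform of the analog prototype) and the forward-backward pass with
# odd-reflection padding follow the conventions of the standard DSP
# toolboxes, so "4th-order zero-phase" means a 4th-order design applied
# twice (effective order 8, zero phase lag).

#' Butterworth filter coefficients
#'
#' Designs digital low- or high-pass Butterworth coefficients by bilinear
#' transform of the analog prototype.
#'
#' @param order Filter order of a single pass.
#' @param cutoff Cutoff frequency in Hz.
#' @param fs Sampling frequency in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_coefficients <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order < 1) stop_invalid("filter order must be >= 1")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop_invalid("cutoff must lie strictly inside (0, fs/2); got ",
                 cutoff, " Hz at fs = ", fs, " Hz")
  }
  wn <- cutoff / (fs / 2)                     # normalized (0, 1)
  warped <- 2 * tan(pi * wn / 2)              # prewarped analog frequency
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_proto <- exp(1i * theta)                  # analog prototype poles
  if (type == "low") {
    p_analog <- warped * p_proto
    z_digital <- rep(-1 + 0i, order)
  } else {
    p_analog <- warped / p_proto
    z_digital <- rep(1 + 0i, order)
  }
  p_digital <- (2 + p_analog) / (2 - p_analog)   # bilinear, fs = 2
  a <- Re(poly_from_roots(p_digital))
  b <- Re(poly_from_roots(z_digital))
  # Normalize the passband gain exactly: unity at DC (low) / Nyquist (high).
  zref <- if (type == "low") 1 else -1
  gain <- sum(b * zref^(seq_along(b) - 1)) / sum(a * zref^(seq_along(a) - 1))
  list(b = b / gain, a = a)
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

# Steady-state initial filter state so that a step input produces no
# startup transient (the classic lfilter_zi construction).
filter_initial_state <- function(b, a) {
  n <- max(length(a), length(b))
  bb <- c(b, rep(0, n - length(b)))
  aa <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  companion_t <- rbind(-aa[-1], cbind(diag(1, n - 2, n - 2), rep(0, n - 2)))
  iminusa <- diag(n - 1) - t(companion_t)
  rhs <- bb[-1] - aa[-1] * bb[1]
  solve(iminusa, rhs)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards and backwards with odd-reflection edge
#' padding, giving zero phase distortion and squared magnitude response.
#'
#' @param b,a Filter coefficients as from [butter_coefficients()].
#' @param x Numeric vector to filter.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  if (any(!is.finite(x))) stop_invalid("signal contains non-finite samples")
  nfilt <- max(length(a), length(b))
  padlen <- 3 * (nfilt - 1)
  if (length(x) <= padlen) {
    stop_insufficient("signal too short (", length(x),
                      " samples) for edge padding of ", padlen)
  }
  zi <- filter_initial_state(b, a)
  # odd reflection about the end points
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)]
  ext <- c(pre, x, post)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[seq(padlen + 1, padlen + length(x))]
}
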