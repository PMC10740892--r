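# internal helpers: validation, units, small numerics

stop_invalid <- function(msg, class = "vestibsim_invalid") {
  rlang::abort(msg, class = c(class, "vestibsim_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

# round half away from zero (preserves symmetry under sign flip)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop_invalid("cannot normalize a zero vector")
  v / n
}

#' Apply an IIR digital filter (direct form, causal)
#'
#' Transposed direct-form II implementation of
#' `y[n] = (b[1] x[n] + ... + b[nb] x[n-nb+1] - a[2] y[n-1] - ...) / a[1]`.
#' Used internally for Butterworth low-pass filtering of eCAP traces; exported
#' because it is handy for testing filter designs.
#'
#' @param b numerator (moving-average) coefficients.
#' @param a denominator (autoregressive) coefficients, `a[1]` non-zero.
#' @param x signal vector.
#' @return filtered signal, same length as `x`.
#' @export
iir_filter <- function(b, a, x) {
  if (a[1] == 0) stop_invalid("a[1] must be non-zero")
  b <- b / a[1]
  a <- a / a[1]
  # FIR stage then AR recursion via stats::filter (both in C)
  v <- stats::filter(c(rep(0, length(b) - 1L), x), b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(length(b) - 1L)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

#' Design a digital low-pass Butterworth filter
#'
#' Analog Butterworth prototype poles mapped through the bilinear transform
#' with frequency pre-warping; gain normalized to exactly 1 at DC.
#'
#' @param order filter order (number of poles).
#' @param fc_hz cutoff (half-power) frequency, Hz.
#' @param fs_hz sampling frequency, Hz; must exceed `2 * fc_hz`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order, fc_hz, fs_hz) {
  check_number(order, "order", lower = 1)
  check_number(fc_hz, "fc_hz", lower = 0, strict_lower = TRUE)
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  if (fc_hz >= fs_hz / 2) {
    stop_invalid("cutoff frequency must be below the Nyquist frequency")
  }
  n <- as.integer(order)
  # pre-warped analog cutoff
  wc <- 2 * fs_hz * tan(pi * fc_hz / fs_hz)
  k <- seq_len(n)
  s_poles <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # bilinear transform: z = (2 fs + s) / (2 fs - s)
  z_poles <- (2 * fs_hz + s_poles) / (2 * fs_hz - s_poles)
  a <- Re(poly_from_roots(z_poles))
  b <- poly_from_roots(rep(-1 + 0i, n))      # n zeros at z = -1
  b <- Re(b)
  b <- b * sum(a) / sum(b)                   # unit DC gain
  list(b = b, a = a)
}

# monic polynomial coefficients (descending powers) from its roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# resolve seed-derived streams deterministically without touching the
# caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
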