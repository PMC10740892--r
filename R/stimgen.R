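#' Specify a charge-balanced biphasic stimulation pulse
#'
#' A waveform spec captures everything needed to render one biphasic pulse:
#' shape, ramp slope, polarity, phase duration, nominal amplitude, interphase
#' gap, hardware current quantization and sampling resolution. The ramp slope
#' is measured on normalized axes (phase duration = 1, nominal amplitude = 1):
#' the phase envelope rises at `tan(slope_deg)` until it reaches the nominal
#' amplitude, then plateaus, so shallow slopes (`tan < 1`) give a pure ramp
#' that peaks below the nominal amplitude while steep slopes give a trapezoid.
#'
#' @param shape one of `"rect"`, `"ramp_up"`, `"ramp_down"`, `"ramp_up_down"`.
#' @param phase_us duration of each phase, microseconds.
#' @param amp_uA nominal peak current, microamperes (>= 0).
#' @param slope_deg ramp slope in degrees, in (0, 90]; ignored for `"rect"`.
#' @param polarity `"cathodic_first"` (first phase negative) or
#'   `"anodic_first"`.
#' @param gap_frac interphase gap as a fraction of the phase duration
#'   (default 0.10).
#' @param step_uA hardware current quantization step, microamperes
#'   (default 20; 0 disables quantization).
#' @param dt_us sample interval, microseconds (default 2, the pulse
#'   generator's temporal resolution).
#' @return an object of class `waveform_spec`.
#' @examples
#' waveform_spec("ramp_up", phase_us = 200, amp_uA = 240, slope_deg = 30)
#' @export
waveform_spec <- function(shape = c("rect", "ramp_up", "ramp_down", "ramp_up_down"),
                          phase_us, amp_uA, slope_deg = 45,
                          polarity = c("cathodic_first", "anodic_first"),
                          gap_frac = 0.10, step_uA = 20, dt_us = 2) {
  shape <- match.arg(tolower(shape),
                     c("rect", "ramp_up", "ramp_down", "ramp_up_down"))
  polarity <- match.arg(tolower(polarity), c("cathodic_first", "anodic_first"))
  check_number(phase_us, "phase_us", lower = 0, strict_lower = TRUE)
  check_number(amp_uA, "amp_uA", lower = 0)
  check_number(gap_frac, "gap_frac", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(slope_deg, "slope_deg", lower = 0, upper = 90,
               strict_lower = TRUE)
  check_number(step_uA, "step_uA", lower = 0)
  check_number(dt_us, "dt_us", lower = 0, strict_lower = TRUE)
  if (dt_us > phase_us) {
    stop_invalid("`dt_us` must not exceed `phase_us`")
  }
  if (shape == "rect") slope_deg <- NA_real_
  structure(
    list(shape = shape, slope_deg = slope_deg, polarity = polarity,
         phase_us = phase_us, amp_uA = amp_uA, gap_frac = gap_frac,
         step_uA = step_uA, dt_us = dt_us),
    class = "waveform_spec"
  )
}

#' @export
print.waveform_spec <- function(x, ...) {
  slope <- if (is.na(x$slope_deg)) "" else sprintf(" %g deg,", x$slope_deg)
  cat(sprintf(
    "<waveform_spec> %s,%s %s, %g us/phase, %g uA, gap %g%%, step %g uA, dt %g us\n",
    x$shape, slope, x$polarity, x$phase_us, x$amp_uA, 100 * x$gap_frac,
    x$step_uA, x$dt_us))
  invisible(x)
}

# normalized phase envelope in [0, 1] current units at normalized time tau
phase_envelope <- function(shape, slope_deg, tau) {
  switch(shape,
    rect = rep(1, length(tau)),
    ramp_up = pmin(tan(slope_deg * pi / 180) * tau, 1),
    ramp_down = pmin(tan(slope_deg * pi / 180) * (1 - tau), 1),
    ramp_up_down = pmin(tan(slope_deg * pi / 180) * tau,
                        tan(slope_deg * pi / 180) * (1 - tau), 1),
    stop_invalid(paste("unknown shape:", shape))
  )
}

#' Render a waveform spec into a sampled current pulse
#'
#' Samples the instantaneous current at the spec's hardware resolution: first
#' phase over `[0, phase_us]`, a zero-current interphase gap of
#' `gap_frac * phase_us`, then a second phase that mirrors the first in sign
#' with an identical envelope, guaranteeing equal unsigned charge in the two
#' phases by construction. Cathodic-first means the first phase is negative.
#'
#' @param spec a [waveform_spec()].
#' @param quantize apply the spec's current quantization step (default `TRUE`).
#' @return a tibble of class `vest_waveform` with columns `t_us` and `i_uA`;
#'   the originating spec is attached as attribute `"spec"`.
#' @examples
#' w <- render_waveform(waveform_spec("rect", 200, 240))
#' range(w$i_uA)
#' @export
render_waveform <- function(spec, quantize = TRUE) {
  stopifnot(inherits(spec, "waveform_spec"))
  phase <- spec$phase_us
  gap <- spec$gap_frac * phase
  total <- 2 * phase + gap
  t_us <- seq(0, total, by = spec$dt_us)
  i <- numeric(length(t_us))

  in1 <- t_us <= phase
  in2 <- t_us >= phase + gap
  i[in1] <- phase_envelope(spec$shape, spec$slope_deg, t_us[in1] / phase)
  i[in2] <- -phase_envelope(spec$shape, spec$slope_deg,
                            (t_us[in2] - phase - gap) / phase)
  i <- i * spec$amp_uA
  if (spec$polarity == "cathodic_first") i <- -i

  w <- tibble::new_tibble(list(t_us = t_us, i_uA = i),
                          class = "vest_waveform", spec = spec,
                          quantized = FALSE)
  if (quantize && spec$step_uA > 0) w <- quantize_current(w, spec$step_uA)
  w
}

#' Quantize a sampled waveform to a hardware current step
#'
#' Every sample is rounded to an integer multiple of `step_uA`, rounding half
#' away from zero so the waveform stays symmetric under a polarity flip.
#' `step_uA = 0` is the identity.
#'
#' @param w a `vest_waveform` tibble from [render_waveform()].
#' @param step_uA quantization step, microamperes (>= 0).
#' @return the quantized waveform.
#' @export
quantize_current <- function(w, step_uA) {
  stopifnot(inherits(w, "vest_waveform"))
  check_number(step_uA, "step_uA", lower = 0)
  if (step_uA == 0) return(w)
  w$i_uA <- round_half_away(w$i_uA / step_uA) * step_uA
  attr(w, "quantized") <- TRUE
  w
}

#' Closed-form charge per phase of a pulse
#'
#' For rectangular pulses the charge is pulse width times amplitude. For
#' ramped (trapezoidal) pulses it is the rectangular plateau part plus the
#' triangular ramp part divided by two, evaluated under the normalized-slope
#' convention of [waveform_spec()]. Agrees with numeric integration of the
#' unquantized rendered waveform to better than 0.1%.
#'
#' @param spec a [waveform_spec()].
#' @return charge per phase in nanocoulombs.
#' @examples
#' charge_per_phase(waveform_spec("rect", 200, 240))       # 48 nC
#' charge_per_phase(waveform_spec("ramp_up", 200, 240, 45)) # 24 nC
#' @export
charge_per_phase <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  pw <- spec$phase_us
  a <- spec$amp_uA
  q_pc <- switch(spec$shape,
    rect = pw * a,
    ramp_up = ,
    ramp_down = {
      m <- tan(spec$slope_deg * pi / 180)
      if (m >= 1) pw * a * (1 - 1 / (2 * m)) else pw * m * a / 2
    },
    ramp_up_down = {
      m <- tan(spec$slope_deg * pi / 180)
      if (m >= 2) pw * a * (1 - 1 / m) else pw * m * a / 4
    }
  )
  q_pc / 1000  # uA * us = pC -> nC
}

#' Numerically integrate the first phase of a rendered waveform
#'
#' Trapezoidal integration of the unsigned current over the first phase;
#' companion to [charge_per_phase()] for cross-checking the closed form.
#'
#' @param w a `vest_waveform`.
#' @return charge in nanocoulombs.
#' @export
phase_charge_numeric <- function(w) {
  stopifnot(inherits(w, "vest_waveform"))
  spec <- attr(w, "spec")
  keep <- w$t_us <= spec$phase_us
  t <- w$t_us[keep]
  i <- abs(w$i_uA[keep])
  sum(diff(t) * (utils::head(i, -1) + utils::tail(i, -1)) / 2) / 1000
}

#' Build a pulse-frequency-modulated pulse train
#'
#' Pulse onsets are generated deterministically by integrating the
#' instantaneous rate `r(t) = base_pps + depth_pps * sin(2 * pi * mod_hz * t)`
#' and emitting a pulse each time the integral crosses an integer, emulating
#' how a prosthesis encodes head velocity as pulse rate.
#'
#' @param base_pps baseline pulse rate, pulses per second.
#' @param mod_hz sinusoidal modulation frequency, Hz (0 for unmodulated).
#' @param depth_pps modulation depth, pulses per second; must not exceed
#'   `base_pps` so the rate never goes negative.
#' @param duration_s train duration, seconds.
#' @param spec the per-pulse [waveform_spec()].
#' @return an object of class `pulse_train`: list with `onsets_s`, `spec`,
#'   `rate_fn` and the generating parameters.
#' @export
pfm_train <- function(base_pps, mod_hz, depth_pps, duration_s, spec) {
  check_number(base_pps, "base_pps", lower = 0)
  check_number(mod_hz, "mod_hz", lower = 0)
  check_number(depth_pps, "depth_pps", lower = 0)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(spec, "waveform_spec"))
  if (depth_pps > base_pps) {
    stop_invalid("`depth_pps` must not exceed `base_pps` (rate would go negative)")
  }
  rate_fn <- function(t) base_pps + depth_pps * sin(2 * pi * mod_hz * t)
  cum_fn <- function(t) {
    if (mod_hz == 0 || depth_pps == 0) base_pps * t
    else base_pps * t + depth_pps / (2 * pi * mod_hz) *
      (1 - cos(2 * pi * mod_hz * t))
  }
  n_total <- floor(cum_fn(duration_s))
  onsets <- numeric(0)
  if (n_total >= 1) {
    grid <- seq(0, duration_s, length.out = max(1000L, 64L * n_total))
    onsets <- stats::approx(cum_fn(grid), grid, xout = seq_len(n_total),
                            ties = "ordered")$y
  }
  structure(
    list(onsets_s = onsets, spec = spec, rate_fn = rate_fn,
         base_pps = base_pps, mod_hz = mod_hz, depth_pps = depth_pps,
         duration_s = duration_s),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> %d pulses over %g s (base %g pps, depth %g pps @ %g Hz)\n",
    length(x$onsets_s), x$duration_s, x$base_pps, x$depth_pps, x$mod_hz))
  invisible(x)
}

#' Full factorial grid of waveform specs
#'
#' Crosses pulse shapes, polarities and ramp slopes, dropping duplicates:
#' rectangular pulses have no slope, so `"rect"` contributes one spec per
#' polarity regardless of how many slopes are requested.
#'
#' @param shapes,polarities,slopes character/numeric vectors of factor levels.
#' @param phase_us,amp_uA,... passed to [waveform_spec()].
#' @return tibble with columns `shape`, `polarity`, `slope_deg` and a `spec`
#'   list-column.
#' @examples
#' nrow(waveform_grid(c("rect", "ramp_up", "ramp_down", "ramp_up_down"),
#'                    c("cathodic_first", "anodic_first"), 30, 200, 240))
#' @export
waveform_grid <- function(shapes, polarities, slopes, phase_us, amp_uA, ...) {
  if (length(shapes) == 0 || length(polarities) == 0 || length(slopes) == 0) {
    stop_invalid("factor sets must be non-empty")
  }
  grid <- tidyr::expand_grid(shape = tolower(shapes),
                             polarity = tolower(polarities),
                             slope_deg = as.numeric(slopes))
  grid <- dplyr::mutate(grid, slope_deg = ifelse(.data$shape == "rect",
                                                 NA_real_, .data$slope_deg))
  grid <- dplyr::distinct(grid)
  grid$spec <- purrr::pmap(grid, function(shape, polarity, slope_deg) {
    waveform_spec(shape, phase_us = phase_us, amp_uA = amp_uA,
                  slope_deg = if (is.na(slope_deg)) 45 else slope_deg,
                  polarity = polarity, ...)
  })
  grid
}

#' Write / read a waveform as CSV
#'
#' Two columns `t_us,i_uA` with a header row, one sample per line.
#'
#' @param w a `vest_waveform`.
#' @param path file path.
#' @return `write_waveform_csv` returns `path` invisibly; `read_waveform_csv`
#'   returns a `vest_waveform` tibble (without an originating spec).
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "vest_waveform"))
  utils::write.csv(as.data.frame(w[c("t_us", "i_uA")]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("t_us", "i_uA"))) {
    stop_invalid("waveform CSV must have exactly the columns t_us,i_uA",
                 class = "vestibsim_incompatible")
  }
  tibble::new_tibble(list(t_us = df$t_us, i_uA = df$i_uA),
                     class = "vest_waveform", spec = NULL, quantized = NA)
}

#' Write / read a waveform spec as JSON
#'
#' Field names match [waveform_spec()] exactly.
#'
#' @param spec a [waveform_spec()].
#' @param path file path.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "waveform_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path)
  need <- c("shape", "polarity", "phase_us", "amp_uA")
  if (!all(need %in% names(x))) {
    stop_invalid("not a waveform spec JSON (missing fields)",
                 class = "vestibsim_incompatible")
  }
  waveform_spec(shape = x$shape, phase_us = x$phase_us, amp_uA = x$amp_uA,
                slope_deg = if (is.null(x$slope_deg)) 45 else x$slope_deg,
                polarity = x$polarity,
                gap_frac = x$gap_frac %||% 0.10,
                step_uA = x$step_uA %||% 20,
                dt_us = x$dt_us %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
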