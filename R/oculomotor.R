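# Mapping per-branch afferent recruitment to predicted 3D VOR axes,
# misalignment against the target canal axis, eVOR velocity traces under
# pulse-frequency-modulated trains, and the pulse-shape sweep experiment.

#' Predict the VOR rotation axis from per-branch recruitment
#'
#' The evoked eye-rotation axis is the normalized weighted sum of the canal
#' rotation axes, each weighted by how strongly its ampullary nerve is
#' recruited. The fraction of fibers active is the default weight; any
#' non-negative weights (e.g. relative axial current) may be supplied.
#'
#' @param weights named numeric vector of per-branch weights (names matching
#'   `axes`); at least one must be positive.
#' @param axes named list of unit canal axes, e.g. from [canal_axes()].
#' @return object of class `vest_vor`: list with unit `axis`, `components`
#'   (projections onto the horizontal/LARP/RALP frame axes) and `magnitude`
#'   (norm of the unnormalized weighted sum, arbitrary velocity units).
#' @examples
#' anat <- build_default_labyrinth(n_per_crista = 3, seed = 1)
#' predict_axis(c(LH = 1, LA = 0, LP = 0), canal_axes(anat))
#' @export
predict_axis <- function(weights, axes) {
  if (is.null(names(weights)) || !all(names(weights) %in% names(axes))) {
    stop_invalid("`weights` must be named after branches present in `axes`")
  }
  if (any(weights < 0)) stop_invalid("weights must be non-negative")
  if (all(weights == 0)) {
    stop_invalid("all weights are zero: the VOR axis is undefined",
                 class = "vestibsim_undefined_axis")
  }
  s <- c(0, 0, 0)
  for (b in names(weights)) s <- s + weights[[b]] * unit_vec(axes[[b]])
  mag <- vec_norm(s)
  axis <- s / mag
  frame <- list(horizontal = axes$LH, LARP = axes$LA, RALP = axes$LP)
  comps <- vapply(frame, function(a) sum(axis * unit_vec(a)), numeric(1))
  structure(list(axis = axis, components = comps, magnitude = mag),
            class = "vest_vor")
}

#' @export
print.vest_vor <- function(x, ...) {
  cat(sprintf("<vest_vor> axis (%.3f, %.3f, %.3f), |sum| = %.3g\n",
              x$axis[1], x$axis[2], x$axis[3], x$magnitude))
  invisible(x)
}

#' Angle between predicted and target rotation axes
#'
#' `arccos` of the clamped dot product of the two unit vectors, in degrees;
#' symmetric in its arguments.
#'
#' @param predicted,target unit 3-vectors (or `vest_vor` objects).
#' @return misalignment in degrees, between 0 and 180.
#' @export
misalignment <- function(predicted, target) {
  p <- if (inherits(predicted, "vest_vor")) predicted$axis else predicted
  t <- if (inherits(target, "vest_vor")) target$axis else target
  if (vec_norm(p) == 0 || vec_norm(t) == 0) {
    stop_invalid("misalignment of a zero vector is undefined")
  }
  d <- sum(unit_vec(p) * unit_vec(t))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' eVOR velocity trace under a pulse-frequency-modulated train
#'
#' Linear mapping from instantaneous pulse rate to eye velocity about the
#' predicted axis: `v(t) = gain * (r(t) - baseline) * axis`, projected onto
#' the horizontal/LARP/RALP canal components. Rate above baseline is
#' excitatory by convention; `excitatory_sign = -1` flips it.
#'
#' @param train a [pfm_train()].
#' @param weights per-branch recruitment weights at the train's amplitude.
#' @param axes canal axes from [canal_axes()].
#' @param gain velocity per (pulse/s), arbitrary units (default 1).
#' @param baseline_pps baseline rate subtracted from `r(t)` (default the
#'   train's base rate).
#' @param excitatory_sign +1 or -1 sign convention (default +1).
#' @param dt_s trace sampling interval, s.
#' @return tibble of class `vest_evor`: `t_s`, `rate_pps`, `horizontal`,
#'   `LARP`, `RALP` velocity components.
#' @export
evor_trace <- function(train, weights, axes, gain = 1,
                       baseline_pps = train$base_pps, excitatory_sign = 1,
                       dt_s = 0.002) {
  stopifnot(inherits(train, "pulse_train"))
  t_s <- seq(0, train$duration_s, by = dt_s)
  r <- train$rate_fn(t_s)
  pred <- predict_axis(weights, axes)
  drive <- excitatory_sign * gain * (r - baseline_pps)
  comp <- outer(drive, pred$components)
  tibble::new_tibble(
    list(t_s = t_s, rate_pps = r,
         horizontal = comp[, "horizontal"], LARP = comp[, "LARP"],
         RALP = comp[, "RALP"]),
    class = "vest_evor", axis = pred$axis, gain = gain,
    baseline_pps = baseline_pps
  )
}

#' Pulse-shape / ramp-slope sweep experiment
#'
#' For every requested (shape, slope) combination: the eCAP detection
#' threshold and the charge per phase at that threshold, the fiber-level
#' sensory threshold (ST), discomfort threshold (DT = 1.4 ST), facial-nerve
#' upper limit (UL, when a facial branch is present), the usable dynamic
#' range, and the VOR-axis misalignment at ST. No-threshold outcomes
#' propagate as NA cells.
#'
#' @param anatomy a `vest_anatomy` (add a facial branch first for UL).
#' @param slopes ramp slopes in degrees (default c(15, 30, 45, 60)).
#' @param shapes pulse shapes (default ramp-up plus the rectangular baseline).
#' @param polarity pulse polarity.
#' @param phase_us,amp_uA base spec parameters (amplitude is swept).
#' @param model membrane model for recruitment (default surrogate tier).
#' @param ecap_model HH model for eCAP thresholds, or `NULL` to skip the
#'   eCAP columns (fast surrogate-only sweep).
#' @param amplitudes_uA sweep grid.
#' @param stim stimulating electrode label.
#' @param medium a [medium()].
#' @param detection_uV eCAP detection criterion.
#' @return tibble of class `vest_sweep`, one row per (shape, slope):
#'   `shape`, `slope_deg` (NA for rect), `ecap_threshold_uA`,
#'   `charge_at_threshold_nC`, `ST_uA`, `DT_uA`, `UL_uA`, `dyn_range_lo_uA`,
#'   `dyn_range_hi_uA`, `misalignment_deg`.
#' @export
slope_sweep <- function(anatomy, slopes = c(15, 30, 45, 60),
                        shapes = c("rect", "ramp_up"),
                        polarity = "cathodic_first", phase_us = 200,
                        amp_uA = 240, model = surrogate_model(),
                        ecap_model = hh_node_model(),
                        amplitudes_uA = default_amp_grid(),
                        stim = "LH_stim", medium = vestibsim::medium(),
                        detection_uV = 1) {
  stopifnot(inherits(anatomy, "vest_anatomy"))
  grid <- waveform_grid(shapes, polarity, slopes, phase_us, amp_uA)
  target <- sub("_stim$", "", stim)
  axes <- canal_axes(anatomy)

  rows <- purrr::pmap(grid, function(shape, polarity, slope_deg, spec) {
    curve <- recruitment_curve(anatomy, spec, amplitudes_uA, model = model,
                               stim = stim, medium = medium)
    thr <- sensory_threshold(curve)
    st <- as.numeric(thr$ST_uA)

    mis <- NA_real_
    if (!is.na(st)) {
      at_st <- curve[curve$amp_uA == st & curve$branch != "FACIAL", ]
      w <- setNames(at_st$fraction_active, at_st$branch)
      if (any(w > 0)) {
        mis <- misalignment(predict_axis(w, axes), axes[[target]])
      }
    }

    et <- NA_real_
    q_thr <- NA_real_
    if (!is.null(ecap_model)) {
      et <- as.numeric(ecap_threshold(anatomy, spec, detection_uV,
                                      grid_uA = amplitudes_uA,
                                      model = ecap_model, stim = stim,
                                      medium = medium))
      if (!is.na(et)) {
        sp <- spec
        sp$amp_uA <- et
        q_thr <- charge_per_phase(sp)
      }
    }

    tibble::tibble(
      shape = shape, slope_deg = slope_deg, polarity = polarity,
      ecap_threshold_uA = et, charge_at_threshold_nC = q_thr,
      ST_uA = st, DT_uA = thr$DT_uA, UL_uA = thr$UL_uA,
      dyn_range_lo_uA = thr$dynamic_range_uA[1],
      dyn_range_hi_uA = thr$dynamic_range_uA[2],
      misalignment_deg = mis
    )
  })
  tibble::new_tibble(dplyr::bind_rows(rows), class = "vest_sweep",
                     stim = stim, phase_us = phase_us)
}
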