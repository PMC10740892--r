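# Spike initiation: membrane model tiers, single-fiber simulation under
# extracellular drive, activation detection, per-fiber thresholds, and
# recruitment curves.
#
# Two tiers (tier equivalence -- same ordering of fiber thresholds -- is a
# test): the full HH nodal cable model yields membrane voltages and the
# transmembrane currents needed for eCAP synthesis; the deterministic
# threshold surrogate (leaky integration of the activating function against a
# per-fiber threshold) is orders of magnitude faster and exactly monotone in
# amplitude, for sweeps and property tests.

#' Hodgkin-Huxley nodal membrane model
#'
#' Myelinated-axon cable model: HH kinetics concentrated at nodes of Ranvier,
#' purely resistive internodes. Defaults are squid-derived rates accelerated
#' by a Q10 temperature factor with channel densities scaled up to
#' mammalian-node levels; every parameter sits in this one config block so any
#' published nodal model can be substituted.
#'
#' @param cm_uF_cm2 nodal capacitance per membrane area.
#' @param gna_mS_cm2,gk_mS_cm2,gl_mS_cm2 maximal Na / K / leak conductance
#'   densities.
#' @param ena_mV,ek_mV reversal potentials as displacements from rest.
#' @param v_rest_mV resting potential, absolute mV.
#' @param temp_c simulation temperature; rates scale by
#'   `q10^((temp_c - 6.3)/10)`.
#' @param q10 temperature coefficient of the gating rates.
#' @param rho_axial_ohm_cm axoplasm resistivity.
#' @param node_len_um node of Ranvier length.
#' @param node_diam_frac node (and axon) diameter as a fraction of the outer
#'   fiber diameter.
#' @param v_spike_mV spike detection level, absolute mV (upward crossing).
#' @return object of class `vest_model`, kinetics `"hh_node"`. The leak
#'   reversal is solved at construction so rest is an exact equilibrium.
#' @export
hh_node_model <- function(cm_uF_cm2 = 2, gna_mS_cm2 = 1200, gk_mS_cm2 = 90,
                          gl_mS_cm2 = 20, ena_mV = 115, ek_mV = -12,
                          v_rest_mV = -70, temp_c = 30, q10 = 3,
                          rho_axial_ohm_cm = 70, node_len_um = 1.5,
                          node_diam_frac = 0.7, v_spike_mV = 0) {
  rate_k <- q10^((temp_c - 6.3) / 10)
  # resting gate steady states (displacement v = 0)
  am <- 0.1 * 25 / (exp(2.5) - 1); bm <- 4
  ah <- 0.07; bh <- 1 / (exp(3) + 1)
  an <- 0.01 * 10 / (exp(1) - 1); bn <- 0.125
  m0 <- am / (am + bm); h0 <- ah / (ah + bh); n0 <- an / (an + bn)
  # leak reversal (displacement) making v = 0 an equilibrium
  el_mV <- -(gna_mS_cm2 * m0^3 * h0 * ena_mV + gk_mS_cm2 * n0^4 * ek_mV) /
    gl_mS_cm2
  structure(
    list(kinetics = "hh_node", cm_uF_cm2 = cm_uF_cm2,
         gna_mS_cm2 = gna_mS_cm2, gk_mS_cm2 = gk_mS_cm2,
         gl_mS_cm2 = gl_mS_cm2, ena_mV = ena_mV, ek_mV = ek_mV,
         el_mV = el_mV, v_rest_mV = v_rest_mV, temp_c = temp_c, q10 = q10,
         rate_k = rate_k, rho_axial_ohm_cm = rho_axial_ohm_cm,
         node_len_um = node_len_um, node_diam_frac = node_diam_frac,
         v_spike_mV = v_spike_mV, gates0 = c(m = m0, h = h0, n = n0)),
    class = "vest_model"
  )
}

#' Deterministic threshold-surrogate membrane model
#'
#' Leaky integration of the activating function (axial second difference of
#' the extracellular potential, scaled by the fiber's axial conductance) at
#' each node; a fiber is activated when the peak integrated depolarization
#' reaches `thr_mV`. Linear in stimulus amplitude, hence each fiber has one
#' exact threshold amplitude and recruitment is exactly monotone.
#' Alternatively, plant per-fiber threshold amplitudes directly via
#' `thresholds_uA` (keyed `branch.fiber`, or a bare vector recycled in fiber
#' order) to bypass the field computation -- used for parameter-recovery
#' tests.
#'
#' @param tau_us integration time constant, microseconds.
#' @param thr_mV activation threshold on the integrated depolarization, mV.
#' @param thresholds_uA optional planted per-fiber threshold amplitudes.
#' @param v_rest_mV resting potential, absolute mV (for trace bookkeeping).
#' @return object of class `vest_model`, kinetics `"threshold_surrogate"`.
#' @export
surrogate_model <- function(tau_us = 100, thr_mV = 2, thresholds_uA = NULL,
                            v_rest_mV = -70) {
  check_number(tau_us, "tau_us", lower = 0, strict_lower = TRUE)
  check_number(thr_mV, "thr_mV", lower = 0, strict_lower = TRUE)
  structure(
    list(kinetics = "threshold_surrogate", tau_us = tau_us, thr_mV = thr_mV,
         thresholds_uA = thresholds_uA, v_rest_mV = v_rest_mV),
    class = "vest_model"
  )
}

#' @export
print.vest_model <- function(x, ...) {
  cat(sprintf("<vest_model> kinetics = %s\n", x$kinetics))
  invisible(x)
}

# planted threshold lookup for a fiber under a surrogate model (NA if none)
planted_threshold <- function(model, fiber) {
  thr <- model$thresholds_uA
  if (is.null(thr)) return(NA_real_)
  if (!is.null(names(thr)) && is.data.frame(fiber)) {
    key <- paste0(fiber$branch, ".", fiber$fiber)
    if (key %in% names(thr)) return(unname(thr[key]))
    return(NA_real_)
  }
  idx <- if (is.data.frame(fiber) && !is.null(fiber$fiber)) fiber$fiber else 1L
  unname(thr[(idx - 1L) %% length(thr) + 1L])
}

# per-node geometry-derived electrical parameters for the cable model
fiber_electrical <- function(fiber, model) {
  nodes <- fiber_nodes(fiber)
  diam <- if (is.data.frame(fiber)) fiber$diameter_um else 3
  spacing_mm <- if (is.data.frame(fiber)) fiber$spacing_mm else 0.3
  n <- nrow(nodes)
  d_node_cm <- model$node_diam_frac * diam * 1e-4
  len_cm <- model$node_len_um * 1e-4
  area_cm2 <- pi * d_node_cm * len_cm
  # nF = uF/cm2 * cm2 * 1000; uS = mS/cm2 * cm2 * 1000
  list(
    n = n,
    c_nF = rep(model$cm_uF_cm2 * area_cm2 * 1000, n),
    gna_uS = rep(model$gna_mS_cm2 * area_cm2 * 1000, n),
    gk_uS = rep(model$gk_mS_cm2 * area_cm2 * 1000, n),
    gl_uS = rep(model$gl_mS_cm2 * area_cm2 * 1000, n),
    # internodal axial conductance, uS: g = A_axon / (rho * L)
    g_ax_uS = rep(
      1e6 * (pi * (d_node_cm / 2)^2) /
        (model$rho_axial_ohm_cm * spacing_mm * 0.1), n - 1L)
  )
}

# extracellular node potentials resampled onto the simulation grid (mV),
# zero-padded after the stimulus ends
resample_drive <- function(drive, dt_us, duration_ms) {
  t_src <- attr(drive, "t_us")
  if (is.null(t_src)) stop_invalid("drive matrix lacks a `t_us` attribute")
  nt <- as.integer(round(duration_ms * 1000 / dt_us))
  t_sim <- (seq_len(nt)) * dt_us  # backward-Euler targets t_{k+1}
  ve <- matrix(0, nrow = nrow(drive), ncol = nt)
  inside <- t_sim <= max(t_src)
  if (any(inside)) {
    for (j in seq_len(nrow(drive))) {
      ve[j, inside] <- stats::approx(t_src, drive[j, ], xout = t_sim[inside],
                                     rule = 2, ties = "ordered")$y
    }
  }
  ve
}

#' Simulate one fiber under extracellular drive
#'
#' HH tier: semi-implicit (backward-Euler voltage, exponential-Euler gates)
#' integration of the multicompartment cable equation with the extracellular
#' potentials as forcing; returns membrane voltage and the transmembrane
#' currents needed for eCAP synthesis. Surrogate tier: leaky integration of
#' the activating function. A spike is an upward crossing of the detection
#' level at three or more consecutive nodes; integration divergence
#' (|v_m| > 500 mV) raises a numerical-stability error naming dt.
#'
#' @param fiber one row of an anatomy `fibers` tibble.
#' @param drive nodes x time extracellular potential matrix from
#'   [drive_matrix()].
#' @param model a [hh_node_model()] or [surrogate_model()].
#' @param dt_us integration step, microseconds (default 2, the stimulus
#'   resolution).
#' @param duration_ms simulated duration; must cover the stimulus plus 2 ms.
#' @param keep_traces keep full v/i matrices (needed for eCAPs); set `FALSE`
#'   to retain only spike times.
#' @param on_divergence what to do when the membrane excursion exceeds 500 mV
#'   from rest: `"error"` (default) raises the numerical-stability error
#'   naming dt; `"clamp"` saturates the offending node at +/-500 mV and keeps
#'   integrating, which the sweep machinery uses because supramaximal fields
#'   legitimately drive the flanking-node hyperpolarization past any
#'   physiological range microseconds after the spike has fired.
#' @return object of class `vest_simresult`: `t_ms`, `v_mV` (nodes x time),
#'   `i_m_nA`, `spike_ms` per node, `spike_onset_ms`, `dt_us`, `duration_ms`.
#' @export
simulate_fiber <- function(fiber, drive, model, dt_us = 2, duration_ms = NULL,
                           keep_traces = TRUE,
                           on_divergence = c("error", "clamp")) {
  on_divergence <- match.arg(on_divergence)
  stopifnot(inherits(model, "vest_model"))
  check_number(dt_us, "dt_us", lower = 0, strict_lower = TRUE)
  stim_ms <- max(attr(drive, "t_us")) / 1000
  if (is.null(duration_ms)) duration_ms <- stim_ms + 2.5
  if (duration_ms < stim_ms + 2) {
    stop_invalid("`duration_ms` must cover the stimulus plus 2 ms")
  }
  ve <- resample_drive(drive, dt_us, duration_ms)
  nt <- ncol(ve)
  t_ms <- seq_len(nt) * dt_us / 1000

  if (model$kinetics == "hh_node") {
    el <- fiber_electrical(fiber, model)
    res <- cable_hh_run(
      ve, dt_us / 1000, el$c_nF, el$gna_uS, el$gk_uS, el$gl_uS, el$g_ax_uS,
      model$v_rest_mV + model$ena_mV, model$v_rest_mV + model$ek_mV,
      model$v_rest_mV + model$el_mV, model$v_rest_mV, model$rate_k,
      model$v_spike_mV, keep_traces, 500, on_divergence == "clamp")
    if (isTRUE(res$diverged)) {
      rlang::abort(sprintf(
        "cable integration diverged (|v_m| > 500 mV from rest at %.3f ms); reduce dt (dt = %g us)",
        res$diverge_ms, dt_us),
        class = c("vestibsim_numerical", "vestibsim_error"))
    }
    v <- res$v_mV
    im <- res$i_m_nA
    spike_ms <- as.numeric(res$spike_ms)
  } else {
    y <- surrogate_response(ve, dt_us, model$tau_us, fiber)
    v <- model$v_rest_mV + y
    im <- NULL
    # surrogate "spike": integrated depolarization reaching thr_mV
    spike_ms <- apply(y, 1, function(row) {
      hit <- which(row >= model$thr_mV)
      if (length(hit)) t_ms[hit[1]] else NA_real_
    })
    planted <- planted_threshold(model, fiber)
    if (!is.na(planted)) {
      amp <- attr(drive, "amp_uA") %||% max(abs(drive))
      spike_ms <- if (amp >= planted) rep(0.1, nrow(ve)) else
        rep(NA_real_, nrow(ve))
    }
  }

  structure(
    list(t_ms = t_ms, v_mV = if (keep_traces) v else NULL,
         i_m_nA = if (keep_traces) im else NULL, spike_ms = spike_ms,
         spike_onset_ms = propagated_spike_onset(spike_ms),
         dt_us = dt_us, duration_ms = duration_ms),
    class = "vest_simresult"
  )
}

# leaky integration of the activating function, nodes x time (mV)
surrogate_response <- function(ve, dt_us, tau_us, fiber) {
  n <- nrow(ve)
  af <- matrix(0, n, ncol(ve))
  if (n >= 3) {
    af[2:(n - 1), ] <- ve[1:(n - 2), ] - 2 * ve[2:(n - 1), ] + ve[3:n, ]
  }
  af[1, ] <- ve[2, ] - ve[1, ]
  af[n, ] <- ve[n - 1, ] - ve[n, ]
  # grade by diameter: axial coupling scales ~ diameter
  diam <- if (is.data.frame(fiber)) fiber$diameter_um else 3
  af <- af * (diam / 3)
  decay <- exp(-dt_us / tau_us)
  # first-order AR recursion per node: y_t = decay * y_{t-1} + (1-decay) * af_t
  y <- t(apply(af * (1 - decay), 1, function(row) {
    as.numeric(stats::filter(row, decay, method = "recursive"))
  }))
  y
}

# onset of the earliest spike seen at >= 3 consecutive nodes (NA if none)
propagated_spike_onset <- function(spike_ms) {
  ok <- !is.na(spike_ms)
  if (sum(ok) < 3) return(NA_real_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- NA_real_
  for (k in which(r$values & r$lengths >= 3)) {
    t0 <- min(spike_ms[starts[k]:ends[k]])
    if (is.na(best) || t0 < best) best <- t0
  }
  best
}

#' @export
print.vest_simresult <- function(x, ...) {
  cat(sprintf("<vest_simresult> %d nodes, %g ms at dt %g us; %s\n",
              length(x$spike_ms), x$duration_ms, x$dt_us,
              if (is.na(x$spike_onset_ms)) "no propagated spike"
              else sprintf("spike onset %.3f ms", x$spike_onset_ms)))
  invisible(x)
}

#' Activation test on a simulation result
#'
#' A fiber counts as activated if a propagated spike (upward crossing of the
#' detection level at three or more consecutive nodes) has its onset within
#' `window_ms` of pulse onset.
#'
#' @param result a `vest_simresult`.
#' @param window_ms activation window after pulse onset (default 2).
#' @return logical.
#' @export
is_activated <- function(result, window_ms = 2) {
  stopifnot(inherits(result, "vest_simresult"))
  check_number(window_ms, "window_ms", lower = 0)
  !is.na(result$spike_onset_ms) && result$spike_onset_ms <= window_ms &&
    result$spike_onset_ms > 0
}

# drive + simulate + activation for one fiber at one amplitude
activated_at <- function(fiber, spec, amp_uA, stim_mm, model, medium,
                         window_ms = 2, dt_us = spec$dt_us) {
  sp <- spec
  sp$amp_uA <- amp_uA
  w <- render_waveform(sp)
  drv <- drive_matrix(fiber, stim_mm, w, medium)
  attr(drv, "amp_uA") <- amp_uA
  res <- simulate_fiber(fiber, drv, model, dt_us = dt_us,
                        keep_traces = FALSE, on_divergence = "clamp")
  is_activated(res, window_ms)
}

#' Per-fiber threshold by bisection
#'
#' Lowest amplitude at which the fiber is activated, found by bisection to
#' `tol_uA` under the assumption (exact for the surrogate, empirically
#' verified for the HH defaults) that activation is monotone in amplitude.
#' If the fiber is not activated at the top of the bracket the function
#' returns `NA` with attribute `no_threshold = TRUE` rather than raising.
#'
#' @param fiber one row of an anatomy `fibers` tibble.
#' @param spec a [waveform_spec()]; its `amp_uA` is overridden by the search.
#' @param stim_mm stimulating electrode position (mm).
#' @param model membrane model.
#' @param bracket_uA search bracket, c(lo, hi) (default c(1, 1000)).
#' @param tol_uA bisection tolerance (default 1).
#' @param medium a [medium()].
#' @param window_ms activation window.
#' @return threshold amplitude in uA, or `NA` (no-threshold signal).
#' @export
fiber_threshold <- function(fiber, spec, stim_mm, model,
                            bracket_uA = c(1, 1000), tol_uA = 1,
                            medium = vestibsim::medium(), window_ms = 2) {
  stopifnot(inherits(spec, "waveform_spec"), inherits(model, "vest_model"))
  if (model$kinetics == "threshold_surrogate") {
    planted <- planted_threshold(model, fiber)
    if (!is.na(planted)) {
      if (planted < bracket_uA[1] || planted > bracket_uA[2]) {
        return(structure(NA_real_, no_threshold = TRUE))
      }
      return(planted)
    }
  }
  lo <- bracket_uA[1]
  hi <- bracket_uA[2]
  if (!activated_at(fiber, spec, hi, stim_mm, model, medium, window_ms)) {
    return(structure(NA_real_, no_threshold = TRUE))
  }
  if (activated_at(fiber, spec, lo, stim_mm, model, medium, window_ms)) {
    return(lo)
  }
  while (hi - lo > tol_uA) {
    mid <- (lo + hi) / 2
    if (activated_at(fiber, spec, mid, stim_mm, model, medium, window_ms)) {
      hi <- mid
    } else {
      lo <- mid
    }
  }
  hi
}

#' Recruitment curves: fraction of fibers activated versus amplitude
#'
#' For each branch and each amplitude on the grid, the fraction of that
#' branch's fibers with a propagated spike within `window_ms` of pulse onset.
#' Deterministic; exactly non-decreasing under the surrogate tier.
#'
#' @param anatomy a `vest_anatomy`.
#' @param spec a [waveform_spec()]; `amp_uA` is swept over `amplitudes_uA`.
#' @param amplitudes_uA ascending amplitude grid, uA (default 25 log-spaced
#'   points over 10-1000 uA, i.e. 0.01-1 mA).
#' @param model membrane model (default surrogate tier).
#' @param stim stimulating electrode label (default `"LH_stim"`).
#' @param medium a [medium()].
#' @param window_ms activation window (default 2).
#' @return tibble of class `vest_recruitment` with columns `amp_uA`, `branch`,
#'   `fraction_active`; the spec, stim label and target branch are attached
#'   as attributes.
#' @export
recruitment_curve <- function(anatomy, spec,
                              amplitudes_uA = default_amp_grid(),
                              model = surrogate_model(), stim = "LH_stim",
                              medium = vestibsim::medium(), window_ms = 2) {
  stopifnot(inherits(anatomy, "vest_anatomy"), inherits(spec, "waveform_spec"))
  if (length(amplitudes_uA) == 0) stop_invalid("amplitude grid is empty")
  if (is.unsorted(amplitudes_uA)) {
    stop_invalid("`amplitudes_uA` must be sorted ascending")
  }
  stim_mm <- electrode_pos(anatomy, stim)

  thr <- per_fiber_thresholds(anatomy, spec, stim_mm, model, medium,
                              window_ms, max(amplitudes_uA))
  out <- tidyr::expand_grid(amp_uA = amplitudes_uA,
                            branch = unique(anatomy$fibers$branch))
  frac <- purrr::map2_dbl(out$amp_uA, out$branch, function(a, b) {
    t_b <- thr[anatomy$fibers$branch == b]
    mean(!is.na(t_b) & t_b <= a)
  })
  out$fraction_active <- frac
  tibble::new_tibble(out, class = "vest_recruitment", spec = spec,
                     stim = stim, target_branch = sub("_stim$", "", stim),
                     thresholds_uA = thr)
}

# per-fiber threshold amplitudes (uA), NA where not activated at sweep top.
# Bisection per fiber is equivalent to evaluating activation per amplitude
# under monotone activation, and much cheaper for the HH tier.
per_fiber_thresholds <- function(anatomy, spec, stim_mm, model, medium,
                                 window_ms, amp_top) {
  n <- nrow(anatomy$fibers)
  if (model$kinetics == "threshold_surrogate" &&
      !is.null(model$thresholds_uA) && is.null(names(model$thresholds_uA))) {
    # bare planted vector: recycled over fibers in anatomy row order
    return(rep_len(as.numeric(model$thresholds_uA), n))
  }
  vapply(seq_len(n), function(i) {
    f <- anatomy$fibers[i, ]
    as.numeric(fiber_threshold(f, spec, stim_mm, model,
                               bracket_uA = c(min(1, amp_top), amp_top),
                               tol_uA = amp_top / 1000,
                               medium = medium, window_ms = window_ms))
  }, numeric(1))
}

#' Default amplitude grid: 25 log-spaced points over 0.01-1 mA
#' @param n number of grid points.
#' @param range_uA amplitude range, uA.
#' @export
default_amp_grid <- function(n = 25, range_uA = c(10, 1000)) {
  exp(seq(log(range_uA[1]), log(range_uA[2]), length.out = n))
}
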