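# Reciprocity-based eCAP synthesis and scoring: recorded voltage as the
# lead-field-weighted sum of every compartment's transmembrane current,
# bipolar differential against a nearby reference electrode, 7.5 kHz low-pass
# Butterworth, P-N amplitude, sensory/discomfort thresholds and the
# growth function.

#' Synthesize an eCAP trace from simulated transmembrane currents
#'
#' The voltage on a recording electrode is the sum over fibers and
#' compartments of the lead-field weight times the compartment's transmembrane
#' current: `v_rec(t) = sum_j w_j * i_m_j(t)`. The bipolar differential
#' subtracts the same synthesis at a nearby reference electrode.
#'
#' @param sim_results list of `vest_simresult` objects (HH tier, traces kept)
#'   sharing one time grid.
#' @param lead_rec lead-field weights for the recording electrode: a list of
#'   per-fiber weight vectors (mV per uA, one weight per node) or a single
#'   `vest_leadfield` over the stacked nodes of all fibers in order.
#' @param lead_ref same for the reference electrode, or `NULL` for a
#'   single-ended recording.
#' @param stim_end_ms end of the stimulus (pulse offset), used downstream to
#'   open the P-N measurement window.
#' @return tibble of class `vest_ecap` with `t_ms`, `v_rec_uV`, `v_ref_uV`,
#'   `v_uV` (differential when a reference is given, else single-ended).
#' @export
synthesize_ecap <- function(sim_results, lead_rec, lead_ref = NULL,
                            stim_end_ms = NA_real_) {
  if (!length(sim_results)) stop_invalid("no simulation results")
  t_ms <- sim_results[[1]]$t_ms
  for (r in sim_results) {
    if (length(r$t_ms) != length(t_ms) ||
        max(abs(r$t_ms - t_ms)) > 1e-9) {
      stop_invalid("simulation results are on mismatched time grids",
                   class = "vestibsim_alignment")
    }
    if (is.null(r$i_m_nA)) {
      stop_invalid("simulation results lack transmembrane currents (run the HH tier with keep_traces = TRUE)")
    }
  }
  w_rec <- leadfield_weights(lead_rec, sim_results)
  v_rec <- weighted_sum(sim_results, w_rec)
  v_ref <- NULL
  if (!is.null(lead_ref)) {
    v_ref <- weighted_sum(sim_results, leadfield_weights(lead_ref, sim_results))
  }
  v <- if (is.null(v_ref)) v_rec else v_rec - v_ref
  tibble::new_tibble(
    list(t_ms = t_ms, v_rec_uV = v_rec,
         v_ref_uV = if (is.null(v_ref)) rep(NA_real_, length(t_ms)) else v_ref,
         v_uV = v),
    class = "vest_ecap", filtered = FALSE, stim_end_ms = stim_end_ms,
    fs_hz = 1000 / (t_ms[2] - t_ms[1])
  )
}

# normalize lead-field input into a list of per-fiber weight vectors
leadfield_weights <- function(lead, sim_results) {
  if (inherits(lead, "vest_leadfield")) {
    sizes <- vapply(sim_results, function(r) length(r$spike_ms), integer(1))
    if (sum(sizes) != nrow(lead)) {
      stop_invalid("lead field rows do not match total compartment count",
                   class = "vestibsim_alignment")
    }
    return(split(lead$weight_mV_per_uA, rep(seq_along(sizes), sizes)))
  }
  if (!is.list(lead)) lead <- list(lead)
  if (length(lead) != length(sim_results)) {
    stop_invalid("need one weight vector per simulated fiber",
                 class = "vestibsim_alignment")
  }
  lead
}

weighted_sum <- function(sim_results, weights) {
  v <- numeric(length(sim_results[[1]]$t_ms))
  for (k in seq_along(sim_results)) {
    im <- sim_results[[k]]$i_m_nA
    if (nrow(im) != length(weights[[k]])) {
      stop_invalid("weight vector length does not match node count",
                   class = "vestibsim_alignment")
    }
    v <- v + as.numeric(crossprod(weights[[k]], im))  # mV/uA * nA = uV
  }
  v
}

#' Low-pass Butterworth filter for eCAP traces
#'
#' Causal by default (a zero-phase forward-backward variant is available);
#' DC gain exactly 1.
#'
#' @param trace a `vest_ecap`.
#' @param fc_khz cutoff (half-power) frequency, kHz (default 7.5).
#' @param order filter order (default 4).
#' @param zero_phase apply forward-backward for zero phase (default `FALSE`).
#' @return the filtered trace (all voltage columns), `filtered` attribute set.
#' @export
lowpass_filter <- function(trace, fc_khz = 7.5, order = 4,
                           zero_phase = FALSE) {
  stopifnot(inherits(trace, "vest_ecap"))
  fs <- attr(trace, "fs_hz")
  if (fc_khz * 1000 >= fs / 2) {
    stop_invalid("cutoff frequency is at or above the Nyquist frequency")
  }
  ba <- butter_lowpass(order, fc_khz * 1000, fs)
  apply_f <- function(x) {
    if (all(is.na(x))) return(x)
    y <- iir_filter(ba$b, ba$a, x)
    if (zero_phase) y <- rev(iir_filter(ba$b, ba$a, rev(y)))
    y
  }
  for (col in c("v_rec_uV", "v_ref_uV", "v_uV")) {
    trace[[col]] <- apply_f(trace[[col]])
  }
  attr(trace, "filtered") <- TRUE
  trace
}

#' P-N amplitude of an eCAP trace
#'
#' Difference between the positive and negative peak over the post-stimulus
#' window. The direct capacitive stimulus artifact is not modeled, so the
#' window simply opens at pulse offset (`stim_end_ms`); real eCAP systems
#' blank the artifact interval instead.
#'
#' @param trace a `vest_ecap` (normally filtered first).
#' @param window_ms optional c(start, end) override for the measurement
#'   window, ms.
#' @return amplitude in uV; raises an undefined-amplitude error if the window
#'   excludes every sample.
#' @export
ecap_amplitude <- function(trace, window_ms = NULL) {
  stopifnot(inherits(trace, "vest_ecap"))
  if (is.null(window_ms)) {
    start <- attr(trace, "stim_end_ms")
    if (is.na(start)) start <- 0
    window_ms <- c(start, Inf)
  }
  keep <- trace$t_ms >= window_ms[1] & trace$t_ms <= window_ms[2]
  if (!any(keep)) {
    stop_invalid("measurement window excludes every sample",
                 class = "vestibsim_undefined_amplitude")
  }
  v <- trace$v_uV[keep]
  max(v) - min(v)
}

#' Sensory and discomfort thresholds from a recruitment curve
#'
#' The sensory threshold (ST) is the lowest grid amplitude activating at
#' least `frac` (default 10%) of the target-branch fibers; the discomfort
#' threshold is exactly `1.4 * ST`. When the anatomy carries a facial-nerve
#' branch, the upper limit (UL) is the lowest amplitude activating any facial
#' fiber, and the usable dynamic range runs from ST to `min(DT, UL)`.
#'
#' @param curve a `vest_recruitment` from [recruitment_curve()].
#' @param frac activation fraction defining ST (default 0.10).
#' @param target target branch (default: the branch of the stimulating
#'   electrode recorded on the curve).
#' @return object of class `vest_thresholds`: list with `ST_uA`, `DT_uA`,
#'   `UL_uA` (NA without a facial branch), `dynamic_range_uA`. `ST_uA` is NA
#'   with attribute `no_threshold` if the fraction is never reached.
#' @export
sensory_threshold <- function(curve, frac = 0.10, target = NULL) {
  stopifnot(inherits(curve, "vest_recruitment"))
  check_number(frac, "frac", lower = 0, strict_lower = TRUE, upper = 1)
  if (is.null(target)) target <- attr(curve, "target_branch")
  tgt <- curve[curve$branch == target, ]
  if (!nrow(tgt)) stop_invalid(paste("no branch", target, "in curve"))
  hit <- tgt$amp_uA[tgt$fraction_active >= frac]
  if (!length(hit)) {
    st <- structure(NA_real_, no_threshold = TRUE)
  } else {
    st <- min(hit)
  }
  ul <- NA_real_
  if ("FACIAL" %in% curve$branch) {
    fac <- curve[curve$branch == "FACIAL", ]
    fhit <- fac$amp_uA[fac$fraction_active > 0]
    if (length(fhit)) ul <- min(fhit)
  }
  dt <- if (is.na(st)) NA_real_ else 1.4 * as.numeric(st)
  structure(
    list(ST_uA = st, DT_uA = dt, UL_uA = ul,
         dynamic_range_uA = if (is.na(st)) c(NA_real_, NA_real_)
         else c(as.numeric(st), min(dt, ul, na.rm = TRUE))),
    class = "vest_thresholds"
  )
}

#' @export
print.vest_thresholds <- function(x, ...) {
  cat(sprintf("<vest_thresholds> ST %.3g uA, DT %.3g uA, UL %s uA\n",
              as.numeric(x$ST_uA), x$DT_uA,
              if (is.na(x$UL_uA)) "-" else sprintf("%.3g", x$UL_uA)))
  invisible(x)
}

#' End-to-end eCAP simulation at one stimulus amplitude
#'
#' Renders the pulse, drives every fiber of the selected branches through the
#' volume conductor, runs the HH cable tier, and synthesizes the filtered
#' bipolar differential eCAP by reciprocity.
#'
#' @param anatomy a `vest_anatomy`.
#' @param spec a [waveform_spec()].
#' @param amp_uA stimulus amplitude (overrides the spec's).
#' @param model membrane model (HH tier required for currents).
#' @param stim,rec,ref electrode labels (defaults: LH branch array).
#' @param branches fibers to include (default: the stimulated branch).
#' @param medium a [medium()].
#' @param filter apply the 7.5 kHz Butterworth (default `TRUE`).
#' @return a `vest_ecap` trace.
#' @export
simulate_ecap <- function(anatomy, spec, amp_uA = spec$amp_uA,
                          model = hh_node_model(), stim = "LH_stim",
                          rec = "LH_rec", ref = "LH_ref",
                          branches = NULL, medium = vestibsim::medium(),
                          filter = TRUE) {
  stopifnot(inherits(anatomy, "vest_anatomy"))
  if (is.null(branches)) branches <- sub("_stim$", "", stim)
  fibers <- anatomy$fibers[anatomy$fibers$branch %in% branches, ]
  if (!nrow(fibers)) stop_invalid("no fibers in the selected branches")
  sp <- spec
  sp$amp_uA <- amp_uA
  w <- render_waveform(sp)
  stim_mm <- electrode_pos(anatomy, stim)
  rec_mm <- electrode_pos(anatomy, rec)
  ref_mm <- if (is.null(ref)) NULL else electrode_pos(anatomy, ref)

  sims <- vector("list", nrow(fibers))
  w_rec <- vector("list", nrow(fibers))
  w_ref <- if (is.null(ref_mm)) NULL else vector("list", nrow(fibers))
  for (i in seq_len(nrow(fibers))) {
    f <- fibers[i, ]
    drv <- drive_matrix(f, stim_mm, w, medium)
    attr(drv, "amp_uA") <- amp_uA
    sims[[i]] <- simulate_fiber(f, drv, model, dt_us = spec$dt_us,
                                on_divergence = "clamp")
    nodes <- f$nodes[[1]]
    w_rec[[i]] <- lead_field(rec_mm, nodes, medium)$weight_mV_per_uA
    if (!is.null(ref_mm)) {
      w_ref[[i]] <- lead_field(ref_mm, nodes, medium)$weight_mV_per_uA
    }
  }
  trace <- synthesize_ecap(sims, w_rec, w_ref,
                           stim_end_ms = max(w$t_us) / 1000)
  if (filter) trace <- lowpass_filter(trace) else trace
}

#' eCAP detection threshold over an amplitude grid
#'
#' Lowest grid amplitude whose filtered differential eCAP P-N amplitude
#' reaches `detection_uV`; the basis of the slope-sweep experiment.
#'
#' @param anatomy a `vest_anatomy`.
#' @param spec a [waveform_spec()].
#' @param detection_uV detection criterion, uV (> 0; default 1).
#' @param grid_uA ascending amplitude grid (default [default_amp_grid()]).
#' @param ... passed to [simulate_ecap()].
#' @return threshold amplitude in uA, or `NA` with attribute `no_threshold`.
#' @export
ecap_threshold <- function(anatomy, spec, detection_uV = 1,
                           grid_uA = default_amp_grid(), ...) {
  check_number(detection_uV, "detection_uV", lower = 0, strict_lower = TRUE)
  for (a in grid_uA) {
    tr <- simulate_ecap(anatomy, spec, amp_uA = a, ...)
    if (ecap_amplitude(tr) >= detection_uV) return(a)
  }
  structure(NA_real_, no_threshold = TRUE)
}

#' eCAP growth function and slope
#'
#' P-N amplitude versus stimulus level, with the growth slope from least
#' squares over the supra-threshold rising segment: from the first level
#' whose amplitude reaches `detection_uV` up to saturation (the first level
#' within 5% of the maximum amplitude).
#'
#' @param anatomy a `vest_anatomy`.
#' @param spec a [waveform_spec()].
#' @param levels_uA at least 5 stimulus levels spanning threshold, uA.
#' @param detection_uV detection criterion defining the segment start.
#' @param ... passed to [simulate_ecap()].
#' @return tibble of class `vest_growth` with `level_uA`, `ecap_amp_uV`;
#'   attributes `slope_uV_per_uA`, `segment` (logical mask of the fitted
#'   points) and `fit` (the `lm`). Slope is NA with attribute
#'   `insufficient_data` when fewer than 3 supra-threshold points exist.
#' @export
growth_function <- function(anatomy, spec, levels_uA, detection_uV = 1, ...) {
  if (length(levels_uA) < 5) {
    stop_invalid("need at least 5 stimulus levels spanning threshold")
  }
  levels_uA <- sort(levels_uA)
  amp <- vapply(levels_uA, function(a) {
    ecap_amplitude(simulate_ecap(anatomy, spec, amp_uA = a, ...))
  }, numeric(1))

  out <- tibble::new_tibble(
    list(level_uA = levels_uA, ecap_amp_uV = amp),
    class = "vest_growth", spec = spec,
    slope_uV_per_uA = NA_real_, segment = rep(FALSE, length(amp)),
    fit = NULL
  )
  supra <- which(amp >= detection_uV)
  if (length(supra) < 3) {
    attr(out, "slope_uV_per_uA") <- structure(NA_real_,
                                              insufficient_data = TRUE)
    return(out)
  }
  first <- supra[1]
  sat <- which(amp >= 0.95 * max(amp))[1]
  seg <- seq(first, max(sat, first + 2))
  seg <- seg[seg <= length(amp)]
  if (length(seg) < 3) seg <- supra[seq_len(min(3, length(supra)))]
  fit <- stats::lm(y ~ x, data = data.frame(x = levels_uA[seg], y = amp[seg]))
  mask <- rep(FALSE, length(amp))
  mask[seg] <- TRUE
  attr(out, "slope_uV_per_uA") <- unname(coef(fit)[2])
  attr(out, "segment") <- mask
  attr(out, "fit") <- fit
  out
}
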