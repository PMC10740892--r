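# cable-model physics, activation rules, thresholds, recruitment

hh <- hh_node_model()

drive_for <- function(fiber, spec, stim = c(0, 0, 0),
                      med = medium()) {
  w <- render_waveform(spec)
  drv <- drive_matrix(fiber, stim, w, med)
  attr(drv, "amp_uA") <- spec$amp_uA
  drv
}

test_that("rest is a stable equilibrium and subthreshold pulses relax back", {
  f <- line_fiber()
  # no drive: resting potential to machine precision over 10 ms
  drv0 <- drive_for(f, waveform_spec("rect", 200, 0))
  r0 <- simulate_fiber(f, drv0, hh, duration_ms = 10)
  expect_lt(max(abs(r0$v_mV - (-70))), 0.5)
  expect_true(all(is.na(r0$spike_ms)))
  expect_false(is_activated(r0))
  # charge-balanced subthreshold pulse: back within 1 mV of rest by 5 ms
  thr <- fiber_threshold(f, std_spec(step_uA = 0), c(0, 0, 0), hh)
  drv <- drive_for(f, waveform_spec("rect", 200, 0.5 * thr, step_uA = 0))
  r <- simulate_fiber(f, drv, hh, duration_ms = 6)
  late <- r$v_mV[, r$t_ms >= 5]
  expect_lt(max(abs(late - (-70))), 1)
})

test_that("a strong pulse evokes a spike that propagates to both fiber ends", {
  f <- line_fiber()
  thr <- fiber_threshold(f, std_spec(step_uA = 0), c(0, 0, 0), hh)
  drv <- drive_for(f, waveform_spec("rect", 200, 5 * thr, step_uA = 0))
  r <- simulate_fiber(f, drv, hh, on_divergence = "clamp")
  expect_true(is_activated(r))
  expect_false(is.na(r$spike_ms[1]))
  expect_false(is.na(r$spike_ms[length(r$spike_ms)]))
  # halving dt moves the spike time by less than 10 us
  r1 <- simulate_fiber(f, drv, hh, dt_us = 1, on_divergence = "clamp")
  expect_lt(abs(r$spike_onset_ms - r1$spike_onset_ms) * 1000, 10)
})

test_that("divergence handling honors the error contract and the clamp mode", {
  anat <- tiny_anatomy(6)
  f <- anat$fibers[which.max(sapply(anat$fibers$nodes, function(m)
    -min(sqrt(colSums((t(m) - c(3.7, 0, 0))^2))))), ]
  drv <- drive_for(f, waveform_spec("rect", 200, 1000, step_uA = 0),
                   stim = c(3.7, 0, 0))
  expect_error(simulate_fiber(f, drv, hh), class = "vestibsim_numerical")
  expect_error(simulate_fiber(f, drv, hh), regexp = "dt")
  r <- simulate_fiber(f, drv, hh, on_divergence = "clamp")
  expect_true(all(abs(r$v_mV - (-70)) <= 500 + 1e-9))
  expect_true(is_activated(r))
})

test_that("activation window rules", {
  mk <- function(onset) {
    structure(list(t_ms = seq(0.002, 4, by = 0.002), v_mV = NULL,
                   i_m_nA = NULL, spike_ms = rep(onset, 11),
                   spike_onset_ms = onset, dt_us = 2, duration_ms = 4),
              class = "vest_simresult")
  }
  expect_true(is_activated(mk(1.2)))
  expect_false(is_activated(mk(2.5)))
  expect_false(is_activated(mk(NA_real_)))
  expect_false(is_activated(mk(1.2), window_ms = 0))
  # non-propagating depolarization (spikes at < 3 consecutive nodes) ignored
  sp <- rep(NA_real_, 11); sp[c(3, 5)] <- 0.5
  r2 <- structure(list(t_ms = 1, spike_ms = sp,
                       spike_onset_ms = vestibsim:::propagated_spike_onset(sp),
                       dt_us = 2, duration_ms = 4), class = "vest_simresult")
  expect_false(is_activated(r2))
  sp3 <- rep(NA_real_, 11); sp3[4:6] <- 0.5
  expect_equal(vestibsim:::propagated_spike_onset(sp3), 0.5)
})

test_that("strength-duration: longer phases need less current; chronaxie is nodal", {
  f <- line_fiber()
  phases <- c(50, 120, 200, 500, 1000)
  thr <- sapply(phases, function(pw)
    fiber_threshold(f, waveform_spec("rect", pw, 240, step_uA = 0),
                    c(0, 0, 0), hh, tol_uA = 0.25))
  expect_true(all(diff(thr) <= 0))
  # Weiss fit: I(PW) = I_rh (1 + t_ch / PW)
  fit <- lm(thr ~ I(1 / phases))
  rheobase <- coef(fit)[[1]]
  chronaxie <- coef(fit)[[2]] / rheobase
  expect_lt(rheobase, thr[1])
  expect_gt(chronaxie, 50)
  expect_lt(chronaxie, 700)
})

test_that("fiber threshold search brackets, converges, and signals no-threshold", {
  f <- line_fiber()
  spec <- std_spec(step_uA = 0)
  thr <- fiber_threshold(f, spec, c(0, 0, 0), hh, tol_uA = 0.5)
  # consistency: just below not activated, just above activated
  below <- vestibsim:::activated_at(f, spec, thr - 1, c(0, 0, 0), hh, medium())
  above <- vestibsim:::activated_at(f, spec, thr + 1, c(0, 0, 0), hh, medium())
  expect_false(below)
  expect_true(above)
  # bracket excluding the threshold -> no-threshold signal, not an error
  res <- fiber_threshold(f, spec, c(0, 0, 0), hh,
                         bracket_uA = c(0.01, thr / 10))
  expect_true(is.na(res))
  expect_true(attr(res, "no_threshold"))
})

test_that("surrogate with a planted threshold recovers it by bisection", {
  f <- line_fiber()
  m <- surrogate_model(thresholds_uA = c(LH.1 = 37))
  thr <- fiber_threshold(f, std_spec(), c(0, 0, 0), m, tol_uA = 1)
  expect_equal(thr, 37, tolerance = 1)
})

test_that("recruitment is monotone under the surrogate and exact for planted CDFs", {
  anat <- tiny_anatomy(10)
  spec <- std_spec()
  curve <- recruitment_curve(anat, spec, model = surrogate_model())
  for (b in unique(curve$branch)) {
    fr <- curve$fraction_active[curve$branch == b]
    expect_true(all(diff(fr) >= 0))
  }
  # planted uniform thresholds: fractions reproduce the CDF exactly
  planted <- rep(seq(20, 200, length.out = 10), 3)
  m <- surrogate_model(thresholds_uA = planted)
  grid <- c(10, 50, 110, 200, 500)
  pc <- recruitment_curve(anat, spec, grid, model = m)
  lh <- pc$fraction_active[pc$branch == "LH"]
  expected <- sapply(grid, function(a) mean(planted[1:10] <= a))
  expect_identical(lh, expected)
  # zero amplitude activates nothing
  z <- recruitment_curve(anat, spec, c(0, 1000), model = m)
  expect_true(all(z$fraction_active[z$amp_uA == 0] == 0))
  expect_error(recruitment_curve(anat, spec, numeric(0)),
               class = "vestibsim_invalid")
  expect_error(recruitment_curve(anat, spec, c(100, 10)),
               class = "vestibsim_invalid")
})

test_that("the two model tiers rank fiber thresholds consistently", {
  anat <- build_default_labyrinth(n_per_crista = 8, seed = 5)
  lh <- anat$fibers[anat$fibers$branch == "LH", ]
  stim <- vestibsim:::electrode_pos(anat, "LH_stim")
  spec <- std_spec(step_uA = 0)  # unquantized to resolve ordering
  t_hh <- sapply(seq_len(nrow(lh)), function(i)
    fiber_threshold(lh[i, ], spec, stim, hh, tol_uA = 0.2))
  t_sur <- sapply(seq_len(nrow(lh)), function(i)
    fiber_threshold(lh[i, ], spec, stim, surrogate_model(), tol_uA = 0.2))
  expect_gt(cor(t_hh, t_sur, method = "spearman"), 0.5)
  # and the surrogate's scale calibration keeps both in the same decade
  expect_lt(abs(log10(median(t_sur) / median(t_hh))), 1)
})
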