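# eCAP synthesis by reciprocity, Butterworth filtering, amplitude and
# threshold rules, growth functions

test_that("degenerate syntheses behave as stated", {
  f <- line_fiber(11)
  drv <- drive_matrix(f, c(0, 0, 0),
                      render_waveform(std_spec(amp_uA = 100)))
  attr(drv, "amp_uA") <- 100
  r <- simulate_fiber(f, drv, hh_node_model(), on_divergence = "clamp")
  # single compartment with unit weight reproduces that compartment's i_m
  w <- rep(0, 11); w[4] <- 1
  tr <- synthesize_ecap(list(r), list(w))
  expect_equal(tr$v_uV, as.numeric(r$i_m_nA[4, ]))
  # all-zero weights give a zero trace
  tr0 <- synthesize_ecap(list(r), list(rep(0, 11)))
  expect_true(all(tr0$v_uV == 0))
  # mismatched grids are an alignment error
  r_short <- r; r_short$t_ms <- r$t_ms[-1]
  expect_error(synthesize_ecap(list(r, r_short), list(w, w)),
               class = "vestibsim_alignment")
})

test_that("lead-field synthesis equals brute-force forward summation", {
  set.seed(21)
  med <- medium(0.3)
  for (k in 1:5) {
    fibers <- lapply(1:3, function(i)
      line_fiber(11, start_mm = c(0.3 + 0.1 * i, runif(1, -0.5, 0.5),
                                  runif(1, -0.5, 0.5))))
    rec <- c(-0.4, runif(1, -0.3, 0.3), 0.2)
    spec <- std_spec(amp_uA = 150, step_uA = 0)
    sims <- lapply(fibers, function(f) {
      drv <- drive_matrix(f, c(0, 0, 0), render_waveform(spec), med)
      simulate_fiber(f, drv, hh_node_model(), on_divergence = "clamp")
    })
    w_rec <- lapply(fibers, function(f)
      lead_field(rec, f$nodes[[1]], med)$weight_mV_per_uA)
    tr <- synthesize_ecap(sims, w_rec)
    # oracle: forward-sum each compartment's current through the closed-form
    # point-source potential, written out independently of the package kernel
    fwd <- numeric(length(tr$t_ms))
    for (i in seq_along(fibers)) {
      nodes <- fibers[[i]]$nodes[[1]]
      for (j in seq_len(nrow(nodes))) {
        rj <- sqrt(sum((nodes[j, ] - rec)^2))
        fwd <- fwd + sims[[i]]$i_m_nA[j, ] / (4 * pi * 0.3 * rj)
      }
    }
    expect_equal(tr$v_uV, fwd, tolerance = 1e-10)
  }
})

test_that("the Butterworth low-pass meets its design points", {
  fs <- 500e3
  ba <- butter_lowpass(4, 7500, fs)
  t <- seq(0, 0.02, by = 1 / fs)
  # DC gain one: a constant passes unchanged after the transient
  y_const <- iir_filter(ba$b, ba$a, rep(2.5, length(t)))
  expect_equal(tail(y_const, 1000), rep(2.5, 1000), tolerance = 1e-6)
  # half-power at the cutoff within 2%
  x_fc <- sin(2 * pi * 7500 * t)
  y_fc <- iir_filter(ba$b, ba$a, x_fc)
  gain_fc <- max(abs(tail(y_fc, 2000)))
  expect_equal(gain_fc, 1 / sqrt(2), tolerance = 0.02)
  # >= 40 dB down at 4x the cutoff for order 4
  x4 <- sin(2 * pi * 4 * 7500 * t)
  y4 <- iir_filter(ba$b, ba$a, x4)
  expect_lt(max(abs(tail(y4, 2000))), 10^(-40 / 20))
  # energy non-increasing
  set.seed(2)
  x <- rnorm(5000)
  y <- iir_filter(ba$b, ba$a, x)
  expect_lte(sum(y^2), sum(x^2))
})

test_that("filtering an eCAP trace enforces Nyquist and flags state", {
  tr <- manual_trace(sin(2 * pi * 3 * seq_len(500) / 500), dt_ms = 0.002)
  attr(tr, "filtered") <- FALSE
  out <- lowpass_filter(tr)
  expect_true(attr(out, "filtered"))
  slow <- manual_trace(rep(1, 100), dt_ms = 1)  # fs = 1 kHz
  expect_error(lowpass_filter(slow, fc_khz = 7.5),
               class = "vestibsim_invalid")
})

test_that("P-N amplitude is the peak-to-peak over the post-stimulus window", {
  v <- c(rep(0, 100), 5, rep(0, 50), -3, rep(0, 100))
  tr <- manual_trace(v, stim_end_ms = 0)
  expect_equal(ecap_amplitude(tr), 8)
  expect_equal(ecap_amplitude(manual_trace(rep(0, 100))), 0)
  # DC offset leaves the difference of extrema unchanged
  tr_dc <- manual_trace(v + 12.5, stim_end_ms = 0)
  expect_equal(ecap_amplitude(tr_dc), 8)
  # stimulus window blanking: peaks inside the stimulus are excluded
  v2 <- c(50, rep(0, 99), 5, rep(0, 50), -3, rep(0, 100))
  tr2 <- manual_trace(v2, stim_end_ms = 0.1)
  expect_equal(ecap_amplitude(tr2), 8)
  expect_error(ecap_amplitude(manual_trace(v, stim_end_ms = 10)),
               class = "vestibsim_undefined_amplitude")
})

test_that("sensory threshold applies the 10% rule and DT is exactly 1.4 ST", {
  # constructed step curve: 0 below 40 uA, 0.5 at and above
  amps <- c(10, 20, 30, 40, 50)
  cv <- manual_curve(amps, matrix(c(0, 0, 0, 0.5, 0.5), ncol = 1))
  thr <- sensory_threshold(cv)
  expect_equal(as.numeric(thr$ST_uA), 40)
  expect_equal(thr$DT_uA, 56)
  # DT = 1.4 x ST on arbitrary instances
  cv2 <- manual_curve(amps, matrix(c(0, 0.12, 0.5, 0.9, 1), ncol = 1))
  thr2 <- sensory_threshold(cv2)
  expect_equal(as.numeric(thr2$ST_uA), 20)
  expect_identical(thr2$DT_uA, 1.4 * 20)
  # never reached -> no-threshold signal
  cv0 <- manual_curve(amps, matrix(rep(0, 5), ncol = 1))
  thr0 <- sensory_threshold(cv0)
  expect_true(is.na(thr0$ST_uA))
  expect_true(attr(thr0$ST_uA, "no_threshold"))
  # custom fraction
  expect_equal(as.numeric(sensory_threshold(cv2, frac = 0.5)$ST_uA), 30)
})

test_that("facial branch recruitment sets the upper limit and dynamic range", {
  amps <- c(10, 20, 40, 80)
  df <- tidyr::expand_grid(amp_uA = amps, branch = c("LH", "FACIAL"))
  frac <- c(0, 0, 0.3, 0, 0.8, 0.1, 1, 0.6)  # interleaved LH/FACIAL
  df$fraction_active <- frac
  cv <- tibble::new_tibble(df, class = "vest_recruitment", spec = NULL,
                           stim = "LH_stim", target_branch = "LH")
  thr <- sensory_threshold(cv)
  expect_equal(as.numeric(thr$ST_uA), 20)
  expect_equal(thr$UL_uA, 40)        # first facial activation
  expect_equal(thr$dynamic_range_uA, c(20, 28))  # min(DT, UL) = DT here
  expect_equal(tidy(thr)$dyn_range_hi_uA, 28)
})

test_that("eCAP detection threshold responds to the criterion monotonically", {
  anat <- tiny_anatomy(6)
  spec <- std_spec()
  grid <- c(20, 60, 180, 500)
  t_strict <- ecap_threshold(anat, spec, detection_uV = 0.5, grid_uA = grid)
  t_loose <- ecap_threshold(anat, spec, detection_uV = 0.05, grid_uA = grid)
  expect_true(is.na(t_strict) || is.na(t_loose) ||
                as.numeric(t_loose) <= as.numeric(t_strict))
  # unreachable criterion -> no-threshold signal
  t_none <- ecap_threshold(anat, spec, detection_uV = 1e6, grid_uA = grid)
  expect_true(is.na(t_none))
  expect_true(attr(t_none, "no_threshold"))
  expect_error(ecap_threshold(anat, spec, detection_uV = 0),
               class = "vestibsim_invalid")
})

test_that("growth function fits a positive slope over the rising segment", {
  anat <- tiny_anatomy(6)
  spec <- std_spec()
  levels <- c(10, 30, 60, 120, 240, 480)
  g <- growth_function(anat, spec, levels, detection_uV = 0.05)
  expect_s3_class(g, "vest_growth")
  expect_equal(nrow(g), 6)
  expect_true(all(g$ecap_amp_uV >= 0))
  gl <- glance(g)
  expect_gt(gl$slope_uV_per_uA, 0)
  expect_gte(gl$n_segment, 3)
  td <- tidy(g)
  expect_equal(sum(td$in_segment), gl$n_segment)
  expect_error(growth_function(anat, spec, c(10, 20)),
               class = "vestibsim_invalid")
})
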