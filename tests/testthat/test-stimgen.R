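# pulse construction, charge formulas, quantization, PFM trains

test_that("rectangular standard pulse renders to its printed parameters", {
  w <- render_waveform(std_spec(polarity = "cathodic_first"))
  expect_equal(min(w$i_uA), -240)
  expect_equal(max(w$i_uA), 240)
  # first phase negative (cathodic first), second positive
  expect_true(all(w$i_uA[w$t_us <= 200] == -240))
  expect_true(all(w$i_uA[w$t_us >= 220] == 240))
  # interphase gap: zero current between last cathodic and first anodic sample
  zero_t <- w$t_us[w$i_uA == 0]
  expect_equal(max(w$t_us[w$i_uA < 0]), 200)
  expect_equal(min(w$t_us[w$i_uA > 0]), 220)
  expect_true(all(zero_t > 200 & zero_t < 220))
  # uniform 2 us sampling
  expect_equal(unique(diff(w$t_us)), 2)
})

test_that("ramp envelopes follow the normalized-slope convention", {
  # 45 degrees: pure triangle from zero reaching full amplitude at offset
  w45 <- render_waveform(waveform_spec("ramp_up", 200, 240, 45), quantize = FALSE)
  p1 <- abs(w45$i_uA[w45$t_us <= 200])
  expect_equal(p1[1], 0)
  expect_equal(max(p1), 240)           # reaches amplitude at phase offset
  expect_equal(which.max(p1), length(p1))
  expect_true(all(diff(p1) >= 0))
  # 60 degrees: trapezoid -- plateau at amplitude after tan(60) rise
  w60 <- render_waveform(waveform_spec("ramp_up", 200, 240, 60), quantize = FALSE)
  p60 <- abs(w60$i_uA[w60$t_us <= 200])
  expect_equal(max(p60), 240)
  expect_gt(sum(p60 == 240), 10)       # a real plateau, not a single sample
  # 30 degrees: under-peaked ramp, peak tan(30) * amp
  w30 <- render_waveform(waveform_spec("ramp_up", 200, 240, 30), quantize = FALSE)
  expect_equal(max(abs(w30$i_uA)), tan(30 * pi / 180) * 240, tolerance = 1e-10)
  # ramp-down mirrors ramp-up in time within each phase
  wd <- render_waveform(waveform_spec("ramp_down", 200, 240, 45), quantize = FALSE)
  pu <- abs(w45$i_uA[w45$t_us <= 200])
  pd <- abs(wd$i_uA[wd$t_us <= 200])
  expect_equal(pd, rev(pu), tolerance = 1e-12)
})

test_that("zero amplitude yields an all-zero waveform of correct length", {
  w <- render_waveform(std_spec())
  wz <- render_waveform(waveform_spec("rect", 200, 0))
  expect_equal(nrow(wz), nrow(w))
  expect_true(all(wz$i_uA == 0))
})

test_that("polarity flip negates the waveform sample-wise", {
  for (shape in c("rect", "ramp_up", "ramp_down", "ramp_up_down")) {
    a <- render_waveform(waveform_spec(shape, 200, 240, 30, "cathodic_first"))
    b <- render_waveform(waveform_spec(shape, 200, 240, 30, "anodic_first"))
    expect_equal(a$i_uA, -b$i_uA)
  }
})

test_that("charge balance holds exactly before quantization and within one step after", {
  for (shape in c("rect", "ramp_up", "ramp_down", "ramp_up_down")) {
    for (th in c(15, 30, 45, 60)) {
      spec <- waveform_spec(shape, 200, 240, th)
      raw <- render_waveform(spec, quantize = FALSE)
      expect_equal(sum(raw$i_uA) * spec$dt_us, 0)
      q <- render_waveform(spec, quantize = TRUE)
      expect_lte(abs(sum(q$i_uA) * spec$dt_us), spec$step_uA * spec$dt_us)
    }
  }
})

test_that("closed-form charge matches printed values and fine-grid integration", {
  expect_equal(charge_per_phase(std_spec()), 48)       # 200 us x 240 uA
  # pure triangle at 45 degrees: half the rectangle
  expect_equal(charge_per_phase(waveform_spec("ramp_up", 200, 240, 45)), 24)
  # numeric oracle: trapezoidal integral of a finely sampled unquantized render
  for (shape in c("rect", "ramp_up", "ramp_down", "ramp_up_down")) {
    for (th in c(15, 30, 45, 60)) {
      spec <- waveform_spec(shape, 200, 240, th, step_uA = 0, dt_us = 0.01)
      num <- phase_charge_numeric(render_waveform(spec))
      expect_equal(charge_per_phase(spec), num, tolerance = 1e-3)
    }
  }
})

test_that("charge is non-decreasing in ramp slope at fixed width and amplitude", {
  for (shape in c("ramp_up", "ramp_down", "ramp_up_down")) {
    q <- sapply(c(15, 30, 45, 60, 89), function(th)
      charge_per_phase(waveform_spec(shape, 200, 240, th)))
    expect_true(all(diff(q) >= 0))
    expect_lte(max(q), charge_per_phase(std_spec()))   # rect is the ceiling
  }
})

test_that("current quantization follows the 20 uA hardware rule", {
  spec <- waveform_spec("ramp_up", 200, 240, 45, step_uA = 0)
  ramp <- render_waveform(spec)
  q <- quantize_current(ramp, 20)
  lv <- unique(abs(q$i_uA[q$i_uA != 0]))
  expect_equal(sort(lv), seq(20, 240, by = 20))        # 12 distinct levels
  expect_true(all(q$i_uA %% 20 == 0))
  # step 0 is the identity
  expect_identical(quantize_current(ramp, 0)$i_uA, ramp$i_uA)
  # round half away from zero: 15 -> 20, -15 -> -20
  flat <- ramp; flat$i_uA <- rep(15, nrow(ramp))
  expect_true(all(quantize_current(flat, 20)$i_uA == 20))
  flat$i_uA <- rep(-15, nrow(ramp))
  expect_true(all(quantize_current(flat, 20)$i_uA == -20))
  expect_error(quantize_current(ramp, -5), class = "vestibsim_invalid")
})

test_that("waveform grid is a deduplicated full factorial", {
  g <- waveform_grid(c("rect", "ramp_up", "ramp_down", "ramp_up_down"),
                     c("cathodic_first", "anodic_first"), 30, 200, 240)
  expect_equal(nrow(g), 8)                             # the eight waveforms
  expect_equal(nrow(waveform_grid("ramp_up", "cathodic_first", 30, 200, 240)), 1)
  # rect collapses the slope factor
  g2 <- waveform_grid("rect", c("cathodic_first", "anodic_first"),
                      c(15, 30), 200, 240)
  expect_equal(nrow(g2), 2)
  expect_true(all(is.na(g2$slope_deg)))
  expect_error(waveform_grid(character(0), "cathodic_first", 30, 200, 240),
               class = "vestibsim_invalid")
})

test_that("PFM trains integrate the modulated rate deterministically", {
  spec <- std_spec()
  # unmodulated: 100 pulses in 1 s, uniform spacing
  tr <- pfm_train(100, 0, 0, 1, spec)
  expect_equal(length(tr$onsets_s), 100)
  expect_lt(diff(range(diff(tr$onsets_s))), 1e-6)
  # modulated: count equals the integral of r(t)
  tr2 <- pfm_train(100, 2, 50, 1, spec)
  expect_equal(length(tr2$onsets_s), 100, tolerance = 0.011)
  expect_true(all(diff(tr2$onsets_s) > 0))
  # 2 Hz modulation over 1 s: two rate peaks -> two local IPI minima regions;
  # shortest intervals must cluster at the two times of peak rate
  ipi <- diff(tr2$onsets_s)
  mids <- (tr2$onsets_s[-1] + tr2$onsets_s[-length(tr2$onsets_s)]) / 2
  peak_times <- c(0.125, 0.625)      # sin maxima of the 2 Hz modulation
  shortest <- mids[ipi <= sort(ipi)[6]]
  expect_true(all(sapply(shortest, function(tm)
    min(abs(tm - peak_times)) < 0.1)))
  expect_error(pfm_train(100, 2, 150, 1, spec), class = "vestibsim_invalid")
})

test_that("waveform CSV and spec JSON round-trip", {
  w <- render_waveform(std_spec())
  f <- tempfile(fileext = ".csv")
  write_waveform_csv(w, f)
  w2 <- read_waveform_csv(f)
  expect_equal(w2$t_us, w$t_us)
  expect_equal(w2$i_uA, w$i_uA)
  s <- waveform_spec("ramp_up", 120, 160, 30, "anodic_first")
  fj <- tempfile(fileext = ".json")
  write_spec_json(s, fj)
  expect_equal(read_spec_json(fj), s)
})

test_that("invalid specs are rejected", {
  expect_error(waveform_spec("rect", -5, 240), class = "vestibsim_invalid")
  expect_error(waveform_spec("rect", 200, 240, dt_us = 0),
               class = "vestibsim_invalid")
  expect_error(waveform_spec("rect", 200, 240, dt_us = 500),
               class = "vestibsim_invalid")
  expect_error(waveform_spec("ramp_up", 200, 240, slope_deg = 0),
               class = "vestibsim_invalid")
  expect_error(waveform_spec("rect", 200, 240, gap_frac = 1),
               class = "vestibsim_invalid")
})
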