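test_that("a flat trace has no spikes", {
  tr <- make_trace(seq(0, 1, 1e-4), rep(-0.070, 10001))
  expect_equal(nrow(detect_spikes(tr)), 0L)
})

test_that("constructed spikes give the expected threshold, height, width", {
  ## abrupt upstroke from -70 mV to +10 mV over 1 ms, descent over 2 ms:
  ## threshold at upstroke onset, height 80 mV, half level -30 mV,
  ## width = rise/2 + fall/2 = 1.5 ms for the triangular shape
  tr <- triangular_spike_trace(0.5, baseline = -0.070, peak = 0.010,
                               rise = 1e-3, fall = 2e-3)
  s <- detect_spikes(tr)
  expect_equal(nrow(s), 1L)
  expect_equal(s$height, 0.080, tolerance = 0.02)
  expect_equal(s$threshold_V, -0.070, tolerance = 0.003)
  expect_equal(s$width, 1.5e-3, tolerance = 1e-4)  # one sample interval
})

test_that("width and height of the triangular family match closed forms", {
  dt <- 1e-4
  for (rise in c(0.5e-3, 1e-3, 2e-3)) for (fall in c(1e-3, 2e-3, 4e-3)) {
    tr <- triangular_spike_trace(0.5, rise = rise, fall = fall, dt = dt)
    s <- detect_spikes(tr)
    expect_equal(nrow(s), 1L)
    expect_equal(s$height, 0.080, tolerance = 0.08 * dt / min(rise, fall) +
                   1e-9)
    expect_equal(s$width, (rise + fall) / 2,
                 tolerance = 2 * dt, label = sprintf("rise=%g fall=%g",
                                                     rise, fall))
  }
})

test_that("the falling-curve fit recovers a known time constant", {
  tt <- seq(0, 0.4, by = 1e-4)
  onset <- 0.05
  vm <- ifelse(tt < onset, -0.070,
               -0.090 + 0.020 * exp(-(tt - onset) / 0.013))
  meta <- new_protocol_meta(onset, 0.35, -100e-12, c(0, onset),
                           c(0.36, 0.40), c(0.30, 0.35))
  f <- subthreshold_features(make_trace(tt, vm), meta)
  expect_equal(f$falling_curve, 0.013, tolerance = 0.01)
})

test_that("rectification is steady-state minus minimum deflection", {
  tt <- seq(0, 0.5, by = 1e-4)
  onset <- 0.1; offset <- 0.4
  ## dips to -90 mV then settles at -80 mV from a -70 mV baseline
  vm <- rep(-0.070, length(tt))
  inj <- tt >= onset & tt <= offset
  vm[inj] <- -0.080 - 0.010 * exp(-(tt[inj] - onset) / 0.02) *
    (tt[inj] > onset + 0.001)
  vm[which(inj)[200:220]] <- -0.090   # explicit minimum
  meta <- new_protocol_meta(onset, offset, -100e-12, c(0, onset),
                           c(0.45, 0.5), c(0.35, 0.40))
  f <- subthreshold_features(make_trace(tt, vm), meta)
  ## ss response = -10 mV, min deflection = -20 mV -> rectification 10 mV
  expect_equal(f$rectification, 0.010, tolerance = 1e-3)
  expect_equal(f$voltage_response, -0.010, tolerance = 1e-3)
  ## wrong polarity: depolarizing trace has no rectification
  meta2 <- new_protocol_meta(onset, offset, 100e-12, c(0, onset),
                            c(0.45, 0.5), c(0.35, 0.40))
  f2 <- subthreshold_features(make_trace(tt, vm), meta2)
  expect_null(f2$rectification)
  expect_null(f2$falling_curve)
})

test_that("spike timing features: counts, times, latency", {
  meta <- new_protocol_meta(0.1, 0.5, 100e-12, c(0, 0.1), c(0.55, 0.6),
                           c(0.45, 0.5))
  tr <- triangular_spike_trace(c(0.2, 0.4), duration = 0.6)
  sp <- detect_spikes(tr)
  f <- spike_features(sp, tr, meta)
  expect_equal(f$spike_count, 2L)
  expect_equal(f$spike_time, c(0.1, 0.3), tolerance = 1e-3)
  ## threshold sits at the upstroke onset, one rise time before the peak
  expect_equal(f$latency, 0.1 - 1e-3, tolerance = 2e-2)
  ## no spikes: latency and AHP features undefined, count defined
  tr0 <- make_trace(tr$times, rep(-0.070, length(tr$times)))
  f0 <- spike_features(detect_spikes(tr0), tr0, meta)
  expect_equal(f0$spike_count, 0L)
  expect_null(f0$latency)
  expect_null(f0$ahp_depth)
  expect_null(f0$ahp_curve)
})

test_that("the voltage histogram is a probability vector", {
  nrn <- make_reference_neuron("spiker")
  pr <- stimulus_protocol(240e-12, 0.1, 0.5, 0.6)
  tr <- run(nrn, pr, sim_config(V_init = -0.080))
  fv <- extract_features(tr, protocol_meta(pr))
  expect_equal(sum(fv$histogram), 1.0)
  expect_length(fv$histogram, 64L)
  expect_true(all(fv$histogram >= 0))
})

test_that("features shift correctly under time and voltage offsets", {
  nrn <- make_reference_neuron("spiker")
  pr <- stimulus_protocol(200e-12, 0.1, 0.5, 0.6)
  tr <- run(nrn, pr, sim_config(V_init = -0.080))
  meta <- protocol_meta(pr)
  fv <- extract_features(tr, meta)
  ## time-shift invariance: shift trace times and metadata together
  tr2 <- make_trace(tr$times + 2.0, tr$Vm)
  meta2 <- new_protocol_meta(meta$onset + 2, meta$offset + 2,
                            meta$amplitude, meta$baseline_pre + 2,
                            meta$baseline_post + 2, meta$steady_state + 2)
  fv2 <- extract_features(tr2, meta2)
  expect_equal(fv2$spike_time, fv$spike_time, tolerance = 1e-9)
  expect_equal(fv2$latency, fv$latency, tolerance = 1e-9)
  expect_equal(fv2$spike_width, fv$spike_width, tolerance = 1e-9)
  ## voltage offset: baselines shift, heights and widths do not
  tr3 <- make_trace(tr$times, tr$Vm + 0.005)
  fv3 <- extract_features(tr3, meta)
  expect_equal(fv3$baseline_pre, fv$baseline_pre + 0.005, tolerance = 1e-9)
  expect_equal(fv3$voltage_response, fv$voltage_response, tolerance = 1e-9)
  expect_equal(fv3$spike_height, fv$spike_height, tolerance = 1e-6)
})

test_that("feature_table reports defined features per trace", {
  nrn <- make_reference_neuron("spiker")
  prot <- reference_protocols("spiker")[c(1, 3)]
  ts <- run_protocol_set(nrn, prot, sim_config(V_init = -0.080))
  tab <- feature_table(ts)
  expect_true(all(c("trace", "feature", "value") %in% names(tab)))
  expect_true("rectification" %in%
                tab$feature[tab$trace == prot[[1]]$label])
  expect_true("latency" %in% tab$feature[tab$trace == prot[[2]]$label])
})
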