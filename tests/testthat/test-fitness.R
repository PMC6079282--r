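test_that("normalized_difference follows the fractional definition", {
  expect_equal(normalized_difference(0.3, 0.1), 0.5)
  expect_equal(normalized_difference(0, 0), 0)
  for (x in c(-2, 0.5, 13)) expect_equal(normalized_difference(x, x), 0)
  ## membrane potentials: |m - d| / (|m| + |d|)
  expect_equal(normalized_difference(-0.080, -0.070), 0.010 / 0.150,
               tolerance = 1e-12)
  ## symmetry
  for (i in 1:20) {
    m <- runif(1, -1, 1); d <- runif(1, -1, 1)
    expect_equal(normalized_difference(m, d), normalized_difference(d, m))
  }
  ## vectors: mean of pointwise; histograms: half L1
  expect_equal(normalized_difference(c(0.3, 1), c(0.1, 1)), 0.25)
  expect_equal(normalized_difference(c(1, 0, 0), c(0, 1, 0), "histogram"),
               1)
  expect_equal(normalized_difference(c(0.5, 0.5), c(0.5, 0.5), "histogram"),
               0)
})

test_that("combine is the RMS of weighted per-feature fitnesses", {
  expect_equal(combine(c(a = 0, b = 0, c = 0)), 0)
  f <- c(a = 0.3, b = 0.4)
  expect_equal(combine(f), sqrt((0.09 + 0.16) / 2))
  ## weight-0 features are excluded from N
  w <- structure(c(a = 1, b = 0), class = "feature_weights")
  expect_equal(combine(f, w), 0.3)
  expect_error(combine(f, structure(c(a = 0, b = 0),
                                    class = "feature_weights")),
               "positive weight")
  ## monotonicity: increasing one f_i strictly increases the total
  f2 <- f; f2["b"] <- f2["b"] + 0.01
  expect_gt(combine(f2), combine(f))
})

test_that("combine reproduces the published striatal totals", {
  tab <- reference_fitness_table("SPN")
  printed <- tab[tab$feature == "total", ]
  for (i in seq_len(nrow(printed))) {
    nrn <- printed$neuron[i]
    f <- tab$mean[tab$neuron == nrn & tab$feature != "total"]
    expect_length(f, 12L)
    expect_equal(combine(f), printed$mean[i], tolerance = 0.005,
                 label = nrn)
  }
  ## worked example: D1_051811 by hand
  f <- tab$mean[tab$neuron == "D1_051811" & tab$feature != "total"]
  expect_equal(combine(f), sqrt(mean(f^2)))
  expect_equal(combine(f), 0.851, tolerance = 0.005)
})

test_that("combine reproduces the published pallidal totals across models", {
  ## the published Total is a mean over the 50 best models; since the
  ## squared total is linear in f^2, the mean total obeys
  ## total^2 = (sum_i mean_i^2 + sd_i^2) / N
  tab <- reference_fitness_table("GPe")
  printed <- tab[tab$feature == "total", ]
  for (i in seq_len(nrow(printed))) {
    nrn <- printed$neuron[i]
    sub <- tab[tab$neuron == nrn & tab$feature != "total", ]
    expect_length(sub$mean, 11L)
    expect_equal(combine(sqrt(sub$mean^2 + sub$sd^2)), printed$mean[i],
                 tolerance = 0.01, label = nrn)
  }
})

test_that("weight presets cover the published feature weighting", {
  w <- feature_weights("SPN")
  expect_equal(unname(w["ahp_curve"]), 4)
  expect_equal(unname(w["rectification"]), 0)
  expect_equal(unname(w["spike_time"]), 0)
  expect_equal(unname(w["baseline_pre"]), 1)
  g <- feature_weights("GPe")
  expect_equal(unname(g["rectification"]), 2)
  expect_equal(unname(g["spike_time"]), 0.5)
  expect_equal(unname(g["spike_height"]), 0.5)
  expect_equal(unname(g["baseline_pre"]), 0)
  expect_equal(unname(g["latency"]), 0)
})

test_that("identical trace sets have zero fitness for every feature", {
  nrn <- make_reference_neuron("spiker")
  prot <- reference_protocols("spiker")
  ts <- run_protocol_set(nrn, prot, sim_config(V_init = -0.080))
  f <- feature_fitness(ts, ts)
  expect_true(all(f == 0))
  expect_equal(fitness_report(ts, ts, feature_weights("SPN"))$total, 0)
})

test_that("spike-count mismatch yields f = 1 and skips per-spike pairing", {
  tt <- seq(0, 0.6, 1e-4)
  meta <- new_protocol_meta(0.1, 0.5, 100e-12, c(0, 0.1), c(0.55, 0.6),
                           c(0.45, 0.5))
  data <- trace_set(list(triangular_spike_trace(c(0.2, 0.3, 0.4),
                                                duration = 0.6)),
                    list(meta))
  sim <- trace_set(list(make_trace(tt, rep(-0.070, length(tt)))),
                   list(meta))
  f <- feature_fitness(sim, data)
  expect_equal(unname(f["spike_count"]), 1.0)   # |3 - 0| / (3 + 0)
  expect_false("spike_width" %in% names(f))
  expect_false("spike_height" %in% names(f))
})

test_that("perturbing one feature changes only that fitness", {
  nrn <- make_reference_neuron("spiker")
  prot <- reference_protocols("spiker")[c(1, 3)]
  cfgsim <- sim_config(V_init = -0.080)
  data <- run_protocol_set(nrn, prot, cfgsim)
  sim <- run_protocol_set(nrn, prot, cfgsim)
  ## shift the hyperpolarizing trace baseline region only after offset
  i <- which(sim$traces[[1]]$times > prot[[1]]$offset + 0.02)
  sim$traces[[1]]$Vm[i] <- sim$traces[[1]]$Vm[i] + 0.004
  f <- feature_fitness(sim, data)
  expect_gt(f["baseline_post"], 0)
  ## brute-force recomputation: the per-feature fitness averages over
  ## both traces; the unperturbed trace contributes 0
  fd <- extract_features(data$traces[[1]], data$meta[[1]])
  fs <- extract_features(sim$traces[[1]], sim$meta[[1]])
  expect_equal(unname(f["baseline_post"]),
               normalized_difference(fs$baseline_post, fd$baseline_post) / 2)
  expect_equal(unname(f["baseline_pre"]), 0)
  expect_equal(unname(f["spike_count"]), 0)
})

test_that("protocol mismatch is reported with the unmatched traces", {
  nrn <- passive_soma_neuron()
  a <- generate_recordings(nrn, list(stimulus_protocol(-50e-12, .05, .25, .3)),
                           noise_sd = 0)
  b <- generate_recordings(nrn, list(stimulus_protocol(-80e-12, .05, .25, .3)),
                           noise_sd = 0)
  expect_error(feature_fitness(a, b), "unmatched")
})
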