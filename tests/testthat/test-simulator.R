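test_that("passive RC response matches the analytic solution", {
  nrn <- passive_soma_neuron(Rin = 1e8, tau_m = 0.01)
  pr <- stimulus_protocol(10e-12, onset = 0.05, offset = 0.45,
                          duration = 0.5)
  tr <- run(nrn, pr, sim_config(V_init = -0.070))
  ss <- mean(tr$Vm[tr$times > 0.40 & tr$times <= 0.45]) + 0.070
  expect_equal(ss, 1e-3, tolerance = 0.01)       # I * Rin = 1 mV
  i <- which.min(abs(tr$times - 0.06))           # onset + tau_m
  expect_equal((tr$Vm[i] + 0.070) / ss, 1 - exp(-1), tolerance = 0.01)
})

test_that("a passive model at E_leak with no input is a fixed point", {
  nrn <- passive_soma_neuron(E_leak = -0.070)
  tr <- run(nrn, stimulus_protocol(0, 0.1, 0.2, 0.5, label = "0"),
            sim_config(V_init = -0.070))
  expect_lt(max(abs(tr$Vm + 0.070)), 1e-6)       # stays within 1 uV
})

test_that("initialize_state puts gates at equilibrium and Ca at rest", {
  nrn <- make_reference_neuron("pauser")
  st <- initialize_state(nrn, V_init = -0.065)
  expect_true(all(st$V == -0.065))
  expect_true(all(st$Ca == nrn$calcium$ca_base))
  i <- which(st$gates$channel == "NaF" & st$gates$gate == "m")[1]
  eq <- gate_equilibrium(nrn$channels$NaF$gates[[1]], -0.065)
  expect_equal(st$gates$x[i], eq$x_inf)
})

test_that("two-compartment steady state matches a dense linear solve", {
  m <- morph_segments(c("s", "d"), c(NA, "s"), c(0, 80e-6),
                      c(12e-6, 2e-6))
  nrn <- passive_tree_neuron(m, RM = 1, CM = 0.01, RA = 1.5)
  pr <- stimulus_protocol(-20e-12, onset = 0.05, offset = 0.65,
                          duration = 0.65)
  tr <- run(nrn, pr, sim_config(V_init = -0.070, record_all = TRUE))
  vend <- tr$Vm_all[, ncol(tr$Vm_all)]
  oracle <- dense_steady_state(m, RM = 1, RA = 1.5, E_leak = -0.070,
                               I = -20e-12)
  expect_lt(max(abs(vend - oracle)), 1e-9)
})

test_that("tree solver equals dense solve on random passive trees", {
  for (seed in 1:4) {
    n <- sample(c(15, 30, 50), 1)
    m <- random_tree_morph(n, seed = seed)
    nrn <- passive_tree_neuron(m, RM = 0.8, CM = 0.01, RA = 1.2)
    pr <- stimulus_protocol(-30e-12, onset = 0.02, offset = 0.4,
                            duration = 0.4)
    tr <- run(nrn, pr, sim_config(V_init = -0.070, record_all = TRUE))
    vend <- tr$Vm_all[, ncol(tr$Vm_all)]
    ## compiled model re-orders compartments parent-first
    cm <- neurofit:::.compile_neuron(nrn)
    oracle <- dense_steady_state(cm$morph, RM = 0.8, RA = 1.2,
                                 E_leak = -0.070, I = -30e-12)
    expect_lt(max(abs(vend - oracle)), 1e-9)
  }
})

test_that("protocol sets are independent, labeled, and deterministic", {
  nrn <- make_reference_neuron("spiker")
  prot <- reference_protocols("spiker")[c(1, 3, 4)]
  ts <- run_protocol_set(nrn, prot, sim_config(V_init = -0.080),
                         label = "x")
  expect_equal(length(ts$traces), 3L)
  expect_equal(vapply(ts$meta, `[[`, character(1), "label"),
               vapply(prot, `[[`, character(1), "label"))
  ## identical protocol twice -> bit-identical traces
  ts2 <- run_protocol_set(nrn, prot[c(2, 2)], sim_config(V_init = -0.080))
  expect_identical(ts2$traces[[1]]$Vm, ts2$traces[[2]]$Vm)
})

test_that("the pauser fires with no injected current", {
  nrn <- make_reference_neuron("pauser")
  tr <- run(nrn, stimulus_protocol(0, 0.2, 1.2, 1.4, label = "0pA"),
            sim_config(V_init = -0.060))
  expect_gte(nrow(detect_spikes(tr)), 2L)  # >= 1 spike/s over 1.4 s
})

test_that("halving dt changes subthreshold traces by < 0.1 mV", {
  ## spiker under sub-rheobase depolarization and hyperpolarization
  nrn <- make_reference_neuron("spiker")
  for (amp in c(-100e-12, 140e-12)) {
    pr <- stimulus_protocol(amp, 0.1, 0.5, 0.6)
    a <- run(nrn, pr, sim_config(dt = 1e-5, V_init = -0.080))
    b <- run(nrn, pr, sim_config(dt = 5e-6, V_init = -0.080))
    expect_lt(max(abs(a$Vm - b$Vm)), 1e-4)
  }
  ## pauser silenced by strong hyperpolarization (nonlinear channels,
  ## calcium pool and HCN all active)
  p <- make_reference_neuron("pauser")
  pr <- stimulus_protocol(-200e-12, 0, 0.8, 0.8)
  a <- run(p, pr, sim_config(dt = 1e-5, V_init = -0.080))
  b <- run(p, pr, sim_config(dt = 5e-6, V_init = -0.080))
  expect_lt(max(abs(a$Vm - b$Vm)), 1e-4)
})

test_that("spike count of a spiking fixture matches a dt/16 reference", {
  nrn <- spiking_soma_neuron()
  pr <- stimulus_protocol(150e-12, onset = 0.05, offset = 0.45,
                          duration = 0.5)
  coarse <- run(nrn, pr, sim_config(dt = 1e-5, V_init = -0.080))
  fine <- run(nrn, pr, sim_config(dt = 1e-5 / 16, V_init = -0.080))
  expect_gt(nrow(detect_spikes(coarse)), 0L)
  expect_equal(nrow(detect_spikes(coarse)), nrow(detect_spikes(fine)))
})

test_that("calcium stays nonnegative and tracks spiking", {
  nrn <- make_reference_neuron("pauser")
  tr <- run(nrn, stimulus_protocol(0, 0.2, 1.2, 1.4), sim_config(V_init = -0.060))
  expect_true(all(tr$Ca >= 0))
  expect_gt(max(tr$Ca), nrn$calcium$ca_base)  # spikes raise [Ca]
})

test_that("configuration errors are reported", {
  expect_error(stimulus_protocol(1e-12, 0.5, 0.4, 1), "onset < offset")
  expect_error(sim_config(dt = 1e-3, record_dt = 1e-4), "dt <= record_dt")
  expect_warning(sim_config(dt = 2e-4, record_dt = 2e-4), "100 us")
  nrn <- passive_soma_neuron()
  expect_error(run(nrn, stimulus_protocol(0, 0, 0.1, 0.1),
                   sim_config(injection_site = "nosuch")),
               "injection_site")
})
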