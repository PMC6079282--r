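## Fixture builders shared across test files. Everything is generated in
## code; no binary fixtures.

## single passive spherical compartment with a given input resistance
## (Ohm) and membrane time constant (s)
passive_soma_neuron <- function(Rin = 1e8, tau_m = 0.01, RM = 1,
                                E_leak = -0.070) {
  area <- RM / Rin
  d <- sqrt(area / pi)
  m <- morph_segments("soma", NA, 0, d)
  ## a zero-density channel so the model has a channel roster
  ch <- channel_spec("null", E_leak, list(
    gate_spec("x", 0L, "tau-inf", forward = gate_rate_spec(1, 0, 1, 0, 1e9),
              backward = gate_rate_spec(2e-3, 0, 0, 0, 1e9))))
  neuron_spec(m, list(ch), conductance_map(null = 0),
              passive_spec(RM = RM, CM = tau_m / RM, RA = 1,
                           E_leak = E_leak))
}

## passive neuron over an arbitrary morphology
passive_tree_neuron <- function(morph, RM = 1, CM = 0.01, RA = 1,
                                E_leak = -0.070) {
  ch <- channel_spec("null", E_leak, list(
    gate_spec("x", 0L, "tau-inf", forward = gate_rate_spec(1, 0, 1, 0, 1e9),
              backward = gate_rate_spec(2e-3, 0, 0, 0, 1e9))))
  neuron_spec(morph, list(ch), conductance_map(null = 0),
              passive_spec(RM, CM, RA, E_leak))
}

## random passive tree with n segments (root soma + cylinders)
random_tree_morph <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  morph_segments(
    id = paste0("c", seq_len(n)),
    parent = ifelse(is.na(parent), NA, paste0("c", parent)),
    length = c(0, runif(n - 1, 20e-6, 120e-6)),
    diameter = c(runif(1, 8e-6, 20e-6), runif(n - 1, 0.5e-6, 4e-6)))
}

## single-compartment spiking fixture (somatic NaF + KDr only)
spiking_soma_neuron <- function() {
  boltz <- function(Vh, k) gate_rate_spec(A = 1, B = 0, C = 1, D = -Vh,
                                          F = -k)
  ctau <- function(tau) gate_rate_spec(A = tau, B = 0, C = 0, D = 0,
                                       F = 1e9)
  naf <- channel_spec("NaF", 0.060, list(
    gate_spec("m", 3L, "tau-inf", forward = boltz(-0.038, 0.006),
              backward = ctau(8e-5)),
    gate_spec("h", 1L, "tau-inf", forward = boltz(-0.052, -0.0065),
              backward = ctau(1.2e-3))))
  kdr <- channel_spec("KDr", -0.090, list(
    gate_spec("n", 2L, "tau-inf", forward = boltz(-0.020, 0.008),
              backward = ctau(1.5e-3))))
  m <- morph_segments("soma", NA, 0, 16e-6)
  neuron_spec(m, list(naf, kdr), conductance_map(NaF = 4000, KDr = 1000),
              passive_spec(RM = 0.6, CM = 0.01, RA = 1, E_leak = -0.080))
}

## analytic steady state of a passive tree under constant somatic current:
## dense solve of the full conductance matrix (independent oracle)
dense_steady_state <- function(morph, RM, RA, E_leak, I, inj = 1L) {
  n <- nrow(morph)
  area <- ifelse(morph$is_spherical, pi * morph$diameter^2,
                 pi * morph$diameter * morph$length)
  gl <- area / RM
  radius <- morph$diameter / 2
  len_eff <- ifelse(morph$is_spherical, morph$diameter, morph$length)
  rhalf <- RA * (len_eff / 2) / (pi * radius^2)
  pidx <- match(morph$parent, morph$id)
  A <- diag(gl, n)
  for (i in seq_len(n)) {
    if (is.na(pidx[i])) next
    g <- 1 / (rhalf[i] + rhalf[pidx[i]])
    A[i, i] <- A[i, i] + g
    A[pidx[i], pidx[i]] <- A[pidx[i], pidx[i]] + g
    A[i, pidx[i]] <- A[i, pidx[i]] - g
    A[pidx[i], i] <- A[pidx[i], i] - g
  }
  rhs <- gl * E_leak
  rhs[inj] <- rhs[inj] + I
  solve(A, rhs)
}

## synthetic trace object from time/voltage vectors
make_trace <- function(times, vm, protocol = NULL) {
  structure(list(times = times, Vm = vm, Ca = NULL, protocol = protocol),
            class = "neuro_trace")
}

## piecewise-linear "triangular" spike train on a flat baseline:
## abrupt upstroke from the baseline to peak over rise_ms, linear descent
## over fall_ms, at the given peak times
triangular_spike_trace <- function(peak_times, baseline = -0.070,
                                   peak = 0.010, rise = 1e-3, fall = 2e-3,
                                   duration = 1, dt = 1e-4) {
  tt <- seq(0, duration, by = dt)
  vm <- rep(baseline, length(tt))
  for (tp in peak_times) {
    up <- tt >= tp - rise & tt <= tp
    vm[up] <- baseline + (peak - baseline) * (tt[up] - (tp - rise)) / rise
    dn <- tt > tp & tt <= tp + fall
    vm[dn] <- pmax(baseline,
                   peak - (peak - baseline) * (tt[dn] - tp) / fall)
  }
  make_trace(tt, vm)
}
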