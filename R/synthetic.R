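## Synthetic ground-truth models and noisy synthetic "recordings", plus the
## parameter-recovery experiment used to validate the whole pipeline.

## Boltzmann steady state 1/(1 + exp(-(V - Vh)/k)) in the five-parameter
## rate form; k > 0 activates with depolarization, k < 0 inactivates.
.boltz <- function(Vh, k) gate_rate_spec(A = 1, B = 0, C = 1, D = -Vh,
                                         F = -k)
## constant time constant tau (s)
.const_tau <- function(tau) gate_rate_spec(A = tau, B = 0, C = 0, D = 0,
                                           F = 1e9)

.gate_ti <- function(name, power, Vh, k, tau, tau_min = 1e-5)
  gate_spec(name, power, "tau-inf", forward = .boltz(Vh, k),
            backward = .const_tau(tau), tau_min = tau_min)

## Channel rosters of the reference neurons: fast sodium (NaF), delayed
## rectifier (KDr), transient potassium (KA); the pauser adds a slow HCN
## (sag), an N-type calcium channel feeding the pool, and a
## calcium-activated BK channel. The two kinds use different kinetics, as
## real SP and GPe neurons do: the pauser's sodium channel activates at
## more hyperpolarized potentials, giving a subthreshold window current
## that drives pacemaking.
.reference_channels <- function(kind = "spiker") {
  if (kind == "spiker") {
    list(
      channel_spec("NaF", E_rev = 0.060, gates = list(
        .gate_ti("m", 3L, Vh = -0.038, k = 0.006, tau = 8e-5),
        .gate_ti("h", 1L, Vh = -0.052, k = -0.0065, tau = 1.2e-3))),
      channel_spec("KDr", E_rev = -0.090, gates = list(
        .gate_ti("n", 2L, Vh = -0.020, k = 0.008, tau = 1.5e-3))),
      channel_spec("KA", E_rev = -0.090, gates = list(
        .gate_ti("a", 1L, Vh = -0.038, k = 0.010, tau = 1.5e-3),
        .gate_ti("b", 1L, Vh = -0.070, k = -0.007, tau = 0.09))))
  } else {
    list(
      channel_spec("NaF", E_rev = 0.060, gates = list(
        .gate_ti("m", 3L, Vh = -0.042, k = 0.006, tau = 8e-5),
        .gate_ti("h", 1L, Vh = -0.050, k = -0.006, tau = 1.5e-3))),
      channel_spec("KDr", E_rev = -0.090, gates = list(
        .gate_ti("n", 2L, Vh = -0.025, k = 0.008, tau = 1.2e-3))),
      channel_spec("KA", E_rev = -0.090, gates = list(
        .gate_ti("a", 1L, Vh = -0.038, k = 0.010, tau = 1.5e-3),
        .gate_ti("b", 1L, Vh = -0.070, k = -0.007, tau = 0.09))),
      channel_spec("HCN", E_rev = -0.030, gates = list(
        .gate_ti("q", 1L, Vh = -0.085, k = -0.007, tau = 0.25))),
      channel_spec("CaN", E_rev = "calcium-Nernst", carries_calcium = TRUE,
                   gates = list(
        .gate_ti("c", 2L, Vh = -0.025, k = 0.007, tau = 5e-4))),
      channel_spec("BK", E_rev = -0.090, gates = list(
        gate_spec("z", 1L, "calcium-dependent", ca_half = 5e-4,
                  ca_slope = 4, tau_min = 2e-3))))
  }
}

## soma + 3-cylinder dendrite chain; proximal dendrite in region 1, the
## rest in region 2
.reference_morphology <- function() {
  morph_segments(
    id = c("soma", "dend1", "dend2", "dend3"),
    parent = c(NA, "soma", "dend1", "dend2"),
    length = c(0, 60e-6, 60e-6, 60e-6),
    diameter = c(16e-6, 2.2e-6, 1.6e-6, 1.2e-6))
}

#' Ground-truth conductance densities of the reference neurons
#'
#' Repository-defined constants (S/m^2) per region (soma, proximal,
#' distal), printed here so recovery tests are self-describing.
#'
#' @param kind `"spiker"` or `"pauser"`.
#' @return named list of length-3 density vectors.
#' @export
reference_densities <- function(kind = c("spiker", "pauser")) {
  kind <- match.arg(kind)
  if (kind == "spiker") {
    list(NaF = c(4000, 800, 300), KDr = c(1000, 300, 120),
         KA = c(120, 60, 30))
  } else {
    list(NaF = c(3000, 600, 250), KDr = c(900, 250, 100),
         KA = c(40, 20, 10), HCN = c(4, 4, 4),
         CaN = c(20, 10, 5), BK = c(200, 80, 40))
  }
}

#' Construct a ground-truth reference neuron
#'
#' Two kinds of 4-compartment (soma + 3 dendrites) models:
#' \describe{
#'   \item{`spiker`}{SP-like: hyperpolarized rest, silent at rest, fires
#'     only above a rheobase with a long (>= 50 ms) first-spike latency
#'     produced by a slowly inactivating transient potassium current.}
#'   \item{`pauser`}{GPe-like: depolarized leak reversal drives spontaneous
#'     firing at zero injected current; slow HCN produces sag under
#'     hyperpolarization; an N-type calcium current feeds the calcium pool
#'     and a calcium-activated BK current shapes the AHP.}
#' }
#'
#' @param kind `"spiker"` or `"pauser"`.
#' @return a [neuron_spec()].
#' @export
make_reference_neuron <- function(kind = c("spiker", "pauser")) {
  kind <- match.arg(kind)
  dens <- reference_densities(kind)
  passive <- if (kind == "spiker")
    passive_spec(RM = 0.6, CM = 0.01, RA = 1.0, E_leak = -0.080)
  else
    passive_spec(RM = 1.2, CM = 0.01, RA = 1.0, E_leak = -0.040)
  calcium <- if (kind == "spiker") calcium_spec(enabled = FALSE)
  else calcium_spec(tau_ca = 0.015, B_ca = 4e9, ca_base = 5e-5,
                    ca_out = 2, enabled = TRUE)
  chans <- .reference_channels(kind)
  keep <- vapply(chans, function(ch) ch$name %in% names(dens), logical(1))
  neuron_spec(.reference_morphology(), chans[keep],
              conductance_map(dens), passive, calcium,
              region_thresholds = c(70e-6, 140e-6))
}

#' Default current-clamp protocols for a reference neuron kind
#'
#' Spiker: a 400 ms hyperpolarizing step and three 400 ms depolarizing
#' steps around rheobase. Pauser: two 1 s hyperpolarizing steps plus a
#' zero-current trace capturing spontaneous firing.
#'
#' @param kind `"spiker"` or `"pauser"`.
#' @return list of [stimulus_protocol()] objects.
#' @export
reference_protocols <- function(kind = c("spiker", "pauser")) {
  kind <- match.arg(kind)
  if (kind == "spiker") {
    amps <- c(-100, 160, 200, 240) * 1e-12
    lapply(amps, function(a)
      stimulus_protocol(a, onset = 0.1, offset = 0.5, duration = 0.6))
  } else {
    c(lapply(c(-200, -100) * 1e-12, function(a)
        stimulus_protocol(a, onset = 0.2, offset = 1.2, duration = 1.4)),
      list(stimulus_protocol(0, onset = 0.2, offset = 1.2, duration = 1.4,
                             label = "0pA")))
  }
}

#' Generate synthetic current-clamp recordings
#'
#' Simulates the protocols, adds seeded zero-mean Gaussian noise of
#' standard deviation `noise_sd` to each voltage trace, and (optionally)
#' writes the result as a recording directory (CSV traces + meta.yaml)
#' consumable by [read_recording_dir()] and [fit_problem()].
#'
#' @param neuron a [neuron_spec()].
#' @param protocols list of [stimulus_protocol()] objects.
#' @param noise_sd noise standard deviation (V); default 0.5 mV,
#'   representative of whole-cell recording noise.
#' @param seed integer seed for the noise.
#' @param dir optional output directory.
#' @param sim_cfg a [sim_config()].
#' @param label neuron label.
#' @return a [trace_set()].
#' @export
generate_recordings <- function(neuron, protocols, noise_sd = 5e-4,
                                seed = 1L, dir = NULL,
                                sim_cfg = sim_config(), label = "synthetic") {
  ts <- run_protocol_set(neuron, protocols, sim_cfg, label = label)
  if (noise_sd > 0) {
    ts$traces <- .with_seed(as.integer(seed), lapply(ts$traces, function(tr) {
      tr$Vm <- tr$Vm + rnorm(length(tr$Vm), sd = noise_sd)
      tr
    }))
  }
  if (!is.null(dir)) write_recording_dir(ts, dir, overwrite = TRUE)
  ts
}

#' Default free-parameter set for a recovery experiment
#'
#' Four free parameters: the somatic NaF, KDr and KA densities and the
#' specific membrane resistance RM. Ground-truth values sit strictly
#' inside the bounds; initial values are deliberately offset from truth
#' (conductances 35% high, RM 20% low).
#'
#' @param kind `"spiker"` or `"pauser"`.
#' @return a [param_set()] with a `truth` attribute.
#' @export
default_recovery_params <- function(kind = c("spiker", "pauser")) {
  kind <- match.arg(kind)
  dens <- reference_densities(kind)
  rm_true <- if (kind == "spiker") 0.6 else 1.2
  truth <- c(NaF_0 = dens$NaF[1], KDr_0 = dens$KDr[1], KA_0 = dens$KA[1],
             RM = rm_true)
  ps <- param_set(
    name = names(truth),
    initial = unname(c(truth[1:3] * 1.35, rm_true * 0.8)),
    min = unname(c(0, 0, 0, rm_true / 3)),
    max = unname(c(truth[1:3] * 3, rm_true * 3)))
  attr(ps, "truth") <- truth
  ps
}

#' Parameter-recovery experiment against synthetic recordings
#'
#' Fits the reference model to recordings generated from itself at known
#' ground-truth parameters, reporting per-seed and median-over-seeds
#' recovery errors. Because the target was generated by the model itself,
#' a known solution (fitness 0 at truth in the noiseless case) exists.
#'
#' @param kind reference neuron kind.
#' @param params free parameters; default [default_recovery_params()].
#' @param protocols stimulation protocols; default
#'   [reference_protocols()].
#' @param noise_sd recording noise (V); 0 for a noiseless target.
#' @param seeds integer vector of experiment seeds.
#' @param generations,popsize optimization budget per seed.
#' @param sigma0 initial CMA-ES step size.
#' @param weights fitness weights; default the SPN-style preset for
#'   spikers and the GPe-style preset for pausers.
#' @param sim_cfg simulation configuration.
#' @param cores parallel workers per population.
#' @param dir storage root (one subdirectory per seed).
#' @return object of class `recovery_report`: list with `truth`, per-seed
#'   results (`best`, `best_fitness`, `rel_error`, `history`) and
#'   `median_rel_error`, `median_best_fitness`.
#' @export
recovery_experiment <- function(kind = c("spiker", "pauser"),
                                params = NULL, protocols = NULL,
                                noise_sd = 0, seeds = 1:3,
                                generations = 50L, popsize = 8L,
                                sigma0 = 0.3, weights = NULL,
                                sim_cfg = sim_config(),
                                cores = 1L, dir = tempfile("recovery_")) {
  kind <- match.arg(kind)
  if (is.null(params)) params <- default_recovery_params(kind)
  if (is.null(protocols)) protocols <- reference_protocols(kind)
  if (is.null(weights))
    weights <- feature_weights(if (kind == "spiker") "SPN" else "GPe")
  truth <- attr(params, "truth")
  neuron <- make_reference_neuron(kind)
  per_seed <- list()
  for (s in seeds) {
    data <- generate_recordings(neuron, protocols, noise_sd = noise_sd,
                                seed = s, sim_cfg = sim_cfg)
    problem <- fit_problem(neuron, params, data, weights,
                           sim_cfg = sim_cfg)
    hist <- do_fit(problem, generations = generations, popsize = popsize,
                   seed = s, sigma0 = sigma0,
                   dir = file.path(dir, sprintf("seed_%d", s)),
                   cores = cores)
    top <- select_best(hist)[1, ]
    best <- setNames(as.numeric(top[, params$name]), params$name)
    rel <- abs(best - truth[params$name]) / abs(truth[params$name])
    per_seed[[as.character(s)]] <-
      list(best = best, best_fitness = top$fitness, rel_error = rel,
           history = hist)
  }
  rel_mat <- do.call(rbind, lapply(per_seed, `[[`, "rel_error"))
  structure(list(kind = kind, truth = truth, seeds = per_seed,
                 median_rel_error = apply(rel_mat, 2L, median),
                 median_best_fitness = median(vapply(per_seed, `[[`,
                                                     numeric(1),
                                                     "best_fitness"))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report (%s, %d seeds): median best fitness %.4g\n",
              x$kind, length(x$seeds), x$median_best_fitness))
  cat("  median relative errors:\n")
  for (nm in names(x$median_rel_error))
    cat(sprintf("    %-8s %.3f\n", nm, x$median_rel_error[[nm]]))
  invisible(x)
}
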