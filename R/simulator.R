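## Current-clamp simulation of a neuron_spec: protocol/config containers,
## model compilation into flat arrays, and the run() entry points.

#' Current-injection protocol
#'
#' @param amplitude injected current (A); negative is hyperpolarizing.
#' @param onset,offset injection start/end times (s), `0 <= onset < offset
#'   <= duration`.
#' @param duration total simulated/recorded duration (s).
#' @param label protocol label; defaults to the amplitude in pA.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude, onset, offset, duration,
                              label = NULL) {
  if (!(onset >= 0 && onset < offset && offset <= duration))
    stop("stimulus_protocol: need 0 <= onset < offset <= duration")
  if (is.null(label)) label <- sprintf("%gpA", amplitude * 1e12)
  structure(list(amplitude = amplitude, onset = onset, offset = offset,
                 duration = duration, label = label),
            class = "stimulus_protocol")
}

#' Simulation configuration
#'
#' @param dt integration step (s); a warning is issued above 100 us.
#' @param record_dt recording step (s), `>= dt`.
#' @param V_init initial membrane potential (V).
#' @param injection_site segment id for current injection and recording;
#'   `NULL` means the root (soma).
#' @param record_all record voltage in every compartment.
#' @param temperature absolute temperature (K) for the calcium Nernst
#'   potential.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-5, record_dt = 1e-4, V_init = -0.075,
                       injection_site = NULL, record_all = FALSE,
                       temperature = 305) {
  if (!(dt > 0 && dt <= record_dt))
    stop("sim_config: need 0 < dt <= record_dt")
  if (dt > 1e-4) warning("sim_config: dt > 100 us is likely inaccurate")
  structure(list(dt = dt, record_dt = record_dt, V_init = V_init,
                 injection_site = injection_site, record_all = record_all,
                 temperature = temperature),
            class = "sim_config")
}

## Flatten a neuron_spec into the arrays the C++ core consumes.
## Compartments are re-ordered so every parent precedes its children
## (Hines ordering for the tree solve).
.compile_neuron <- function(neuron) {
  morph <- neuron$morphology
  ord <- .morph_topo_order(morph)
  morph <- morph[ord, , drop = FALSE]
  rownames(morph) <- NULL
  class(morph) <- c("neuro_morph", "data.frame")
  parent <- match(morph$parent, morph$id) - 1L
  parent[is.na(parent)] <- -1L
  area <- segment_areas(morph)
  region <- assign_regions(morph, neuron$region_thresholds)
  p <- neuron$passive
  Cm <- p$CM * area
  Gleak <- area / p$RM
  ## axial half-resistance; a spherical soma uses its diameter as length
  radius <- morph$diameter / 2
  len_eff <- ifelse(morph$is_spherical, morph$diameter, morph$length)
  rhalf <- p$RA * (len_eff / 2) / (pi * radius^2)
  Gax <- numeric(nrow(morph))
  for (i in seq_len(nrow(morph))) {
    if (parent[i] >= 0L)
      Gax[i] <- 1 / (rhalf[i] + rhalf[parent[i] + 1L])
  }
  ## channel instances: one per (channel, compartment) with density > 0
  inst <- list(comp = integer(0), gbar = numeric(0), erev = numeric(0),
               ca = logical(0), chan = character(0))
  igs <- list(inst = integer(0), form = integer(0), power = integer(0),
              fwd = NULL, bwd = NULL, cahalf = numeric(0),
              caslope = numeric(0), taumin = numeric(0))
  fwd <- list(); bwd <- list()
  form_code <- c("alpha-beta" = 0L, "tau-inf" = 1L, "calcium-dependent" = 2L)
  zero5 <- c(A = 0, B = 0, C = 1, D = 0, F = 1)
  for (chan_name in rownames(neuron$conductances)) {
    ch <- neuron$channels[[chan_name]]
    for (ci in seq_len(nrow(morph))) {
      dens <- neuron$conductances[chan_name, region[ci] + 1L]
      if (dens <= 0) next
      k <- length(inst$comp) + 1L
      inst$comp[k] <- ci - 1L
      inst$gbar[k] <- dens * area[ci]
      inst$erev[k] <- if (ch$nernst) NA_real_ else ch$E_rev
      inst$ca[k] <- ch$carries_calcium
      inst$chan[k] <- chan_name
      for (g in ch$gates) {
        j <- length(igs$inst) + 1L
        igs$inst[j] <- k - 1L
        igs$form[j] <- form_code[[g$form]]
        igs$power[j] <- g$power
        fwd[[j]] <- if (is.null(g$forward)) zero5 else unlist(g$forward)
        bwd[[j]] <- if (is.null(g$backward)) zero5 else unlist(g$backward)
        igs$cahalf[j] <- if (is.finite(g$ca_half)) g$ca_half else 1
        igs$caslope[j] <- g$ca_slope
        igs$taumin[j] <- g$tau_min
      }
    }
  }
  list(morph = morph, parent = parent, Cm = Cm, Gleak = Gleak,
       Eleak = p$E_leak, Gax = Gax, area = area, region = region,
       inst = inst,
       ig = list(inst = igs$inst, form = igs$form, power = igs$power,
                 fwd = if (length(fwd)) do.call(rbind, fwd)
                       else matrix(0, 0, 5),
                 bwd = if (length(bwd)) do.call(rbind, bwd)
                       else matrix(0, 0, 5),
                 cahalf = igs$cahalf, caslope = igs$caslope,
                 taumin = igs$taumin))
}

#' Initial state of a model
#'
#' Voltage uniform at `V_init`, every gating variable at its steady state
#' for (`V_init`, resting calcium), calcium at its resting concentration.
#' Mainly useful for inspection; [run()] initializes identically.
#'
#' @param neuron a [neuron_spec()].
#' @param V_init initial potential (V).
#' @return list with `V`, `Ca` (per compartment) and `gates` (data frame of
#'   per-instance gate values).
#' @export
initialize_state <- function(neuron, V_init = -0.075) {
  cm <- .compile_neuron(neuron)
  n <- nrow(cm$morph)
  ca0 <- neuron$calcium$ca_base
  gates <- data.frame(channel = character(0), compartment = character(0),
                      gate = character(0), x = numeric(0))
  for (chan_name in rownames(neuron$conductances)) {
    ch <- neuron$channels[[chan_name]]
    for (ci in seq_len(n)) {
      dens <- neuron$conductances[chan_name, cm$region[ci] + 1L]
      if (dens <= 0) next
      for (g in ch$gates) {
        eq <- gate_equilibrium(g, V_init, ca0)
        gates <- rbind(gates, data.frame(
          channel = chan_name, compartment = cm$morph$id[ci],
          gate = g$name, x = eq$x_inf))
      }
    }
  }
  list(V = rep(V_init, n), Ca = rep(ca0, n), gates = gates)
}

#' Simulate one current-clamp protocol
#'
#' Integrates the compartmental model under the protocol and returns the
#' membrane potential recorded at the injection site (the soma by default),
#' decimated to `record_dt`.
#'
#' @param neuron a [neuron_spec()].
#' @param protocol a [stimulus_protocol()].
#' @param config a [sim_config()].
#' @return An object of class `neuro_trace`: list with `times`, `Vm`, `Ca`,
#'   `protocol`, and (if `record_all`) a compartments x samples `Vm_all`
#'   matrix.
#' @export
run <- function(neuron, protocol, config = sim_config()) {
  stopifnot(inherits(neuron, "neuron_spec"),
            inherits(protocol, "stimulus_protocol"),
            inherits(config, "sim_config"))
  if (protocol$offset > protocol$duration)
    stop("run: protocol offset beyond duration")
  cm <- .compile_neuron(neuron)
  site <- config$injection_site
  comp <- if (is.null(site)) which(cm$parent == -1L)
          else match(site, cm$morph$id)
  if (is.na(comp)) stop("run: unknown injection_site '", site, "'")
  rec_every <- max(1L, as.integer(round(config$record_dt / config$dt)))
  n_steps <- as.integer(round(protocol$duration / config$dt))
  cal <- neuron$calcium
  res <- .sim_run_cpp(cm$parent, cm$Cm, cm$Gleak, cm$Eleak, cm$Gax,
                      cm$inst$comp, cm$inst$gbar, cm$inst$erev, cm$inst$ca,
                      cm$ig$inst, cm$ig$form, cm$ig$power, cm$ig$fwd,
                      cm$ig$bwd, cm$ig$cahalf, cm$ig$caslope, cm$ig$taumin,
                      cal$enabled, cal$tau_ca, cal$B_ca, cal$ca_base,
                      cal$ca_out, config$temperature,
                      config$V_init, config$dt, rec_every, n_steps,
                      comp - 1L, protocol$amplitude, protocol$onset,
                      protocol$offset, comp - 1L, config$record_all)
  structure(list(times = res$times, Vm = res$Vm, Ca = res$Ca,
                 Vm_all = res$Vm_all, protocol = protocol),
            class = "neuro_trace")
}

#' @export
print.neuro_trace <- function(x, ...) {
  cat(sprintf("neuro_trace '%s': %d samples over %.3g s, Vm in [%.1f, %.1f] mV\n",
              x$protocol$label, length(x$times), max(x$times),
              1e3 * min(x$Vm), 1e3 * max(x$Vm)))
  invisible(x)
}

#' Simulate a set of protocols
#'
#' State is re-initialized for each protocol; protocols are independent and
#' may be evaluated in parallel (results are identical regardless of the
#' degree of parallelism).
#'
#' @param neuron a [neuron_spec()].
#' @param protocols list of [stimulus_protocol()] objects.
#' @param config a [sim_config()].
#' @param label neuron label for the returned set.
#' @param cores number of worker processes (forked; 1 = serial).
#' @return A [trace_set()].
#' @export
run_protocol_set <- function(neuron, protocols, config = sim_config(),
                             label = "sim", cores = 1L) {
  if (!length(protocols)) stop("run_protocol_set: at least one protocol")
  runner <- function(p) run(neuron, p, config)
  traces <- if (cores > 1L)
    parallel::mclapply(protocols, runner, mc.cores = cores)
  else lapply(protocols, runner)
  err <- vapply(traces, inherits, logical(1), "try-error")
  for (tr in traces) if (inherits(tr, "condition")) stop(tr)
  trace_set(traces, meta = lapply(protocols, protocol_meta), label = label)
}
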