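## Declarative model specification: channel kinetics, conductance densities,
## passive and calcium parameters, and the tunable-parameter set.

#' Five-parameter voltage-dependent rate specification
#'
#' The standard GENESIS-style parameterization of a gating rate (or, for
#' `tau-inf` gates, of the steady state or time constant directly):
#' \deqn{r(V) = \frac{A + B V}{C + \exp((V + D)/F)}}
#' with `V` in volts and the result in 1/s (rates), dimensionless
#' (steady states) or seconds (time constants).
#'
#' @param A rate offset (1/s).
#' @param B rate slope (1/(s V)).
#' @param C denominator offset (dimensionless).
#' @param D voltage shift (V).
#' @param F voltage scale (V); must be nonzero.
#' @return An object of class `gate_rate_spec`.
#' @export
gate_rate_spec <- function(A, B = 0, C = 1, D = 0, F = 1) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), is.numeric(D),
            is.numeric(F), length(F) == 1L)
  if (F == 0) stop("gate_rate_spec: voltage scale F must be nonzero")
  structure(list(A = A, B = B, C = C, D = D, F = F),
            class = "gate_rate_spec")
}

#' Evaluate a rate specification at a membrane potential
#'
#' Computes (A + B V)/(C + exp((V + D)/F)). Near the removable singularity
#' where the denominator vanishes the value is linearly interpolated from
#' V +/- 1e-5 V.
#'
#' @param spec a [gate_rate_spec()].
#' @param V membrane potential(s) in volts; vectorized.
#' @param .guard internal; disables recursion of the singularity guard.
#' @return rate value(s), same length as `V`.
#' @export
rate_value <- function(spec, V, .guard = TRUE) {
  stopifnot(inherits(spec, "gate_rate_spec"))
  denom <- spec$C + exp((V + spec$D) / spec$F)
  r <- (spec$A + spec$B * V) / denom
  if (.guard) {
    bad <- abs(denom) < 1e-9
    if (any(bad)) {
      vb <- V[bad]
      r[bad] <- (rate_value(spec, vb - 1e-5, .guard = FALSE) +
                 rate_value(spec, vb + 1e-5, .guard = FALSE)) / 2
    }
  }
  if (any(!is.finite(r)))
    stop("rate_value: non-finite rate after singularity guarding")
  r
}

#' Gating-variable specification
#'
#' One Hodgkin-Huxley gating variable x with dynamics
#' dx/dt = (x_inf - x)/tau_x, raised to an integer power in the channel
#' conductance. Three functional forms are supported:
#' \describe{
#'   \item{`alpha-beta`}{`forward` and `backward` are the opening/closing
#'     rates alpha(V), beta(V); x_inf = alpha/(alpha+beta),
#'     tau = max(1/(alpha+beta), tau_min).}
#'   \item{`tau-inf`}{`forward` evaluates x_inf(V) directly (dimensionless)
#'     and `backward` evaluates tau(V) in seconds (floored at tau_min).}
#'   \item{`calcium-dependent`}{x_inf = Ca^n/(Ca^n + ca_half^n) (Hill form,
#'     n = `ca_slope`), tau = tau_min; used for BK-type channels.}
#' }
#'
#' @param name gate label.
#' @param power integer exponent >= 0.
#' @param form one of `"alpha-beta"`, `"tau-inf"`, `"calcium-dependent"`.
#' @param forward,backward [gate_rate_spec()] objects (unused for
#'   calcium-dependent gates).
#' @param ca_half half-activation calcium concentration (mM).
#' @param ca_slope Hill exponent.
#' @param tau_min floor on the time constant (s).
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(name, power, form = c("alpha-beta", "tau-inf",
                                            "calcium-dependent"),
                      forward = NULL, backward = NULL,
                      ca_half = NA_real_, ca_slope = 2,
                      tau_min = 1e-5) {
  form <- match.arg(form)
  power <- as.integer(power)
  if (power < 0L) stop("gate_spec: power must be >= 0")
  if (tau_min <= 0) stop("gate_spec: tau_min must be > 0")
  if (form == "calcium-dependent") {
    if (!is.finite(ca_half) || ca_half <= 0)
      stop("gate_spec: calcium-dependent gates require ca_half > 0")
  } else {
    stopifnot(inherits(forward, "gate_rate_spec"),
              inherits(backward, "gate_rate_spec"))
  }
  structure(list(name = name, power = power, form = form,
                 forward = forward, backward = backward,
                 ca_half = ca_half, ca_slope = ca_slope,
                 tau_min = tau_min),
            class = "gate_spec")
}

#' Steady state and time constant of a gate
#'
#' @param gate a [gate_spec()].
#' @param V membrane potential (V).
#' @param Ca calcium concentration (mM), used by calcium-dependent gates.
#' @return list with elements `x_inf` and `tau` (s).
#' @export
gate_equilibrium <- function(gate, V, Ca = 0) {
  stopifnot(inherits(gate, "gate_spec"))
  switch(gate$form,
    "alpha-beta" = {
      a <- rate_value(gate$forward, V)
      b <- rate_value(gate$backward, V)
      s <- a + b
      tau <- ifelse(s > 0, 1 / s, Inf)
      tau <- pmax(pmin(tau, 1e6), gate$tau_min)
      x_inf <- ifelse(s > 0, a / s, NA_real_)
      if (any(!is.finite(x_inf)))
        warning("gate_equilibrium: alpha + beta = 0; x_inf undefined for gate ",
                gate$name)
      list(x_inf = x_inf, tau = tau)
    },
    "tau-inf" = {
      x_inf <- rate_value(gate$forward, V)
      tau <- pmax(rate_value(gate$backward, V), gate$tau_min)
      list(x_inf = x_inf, tau = tau)
    },
    "calcium-dependent" = {
      can <- Ca ^ gate$ca_slope
      list(x_inf = can / (can + gate$ca_half ^ gate$ca_slope),
           tau = rep_len(gate$tau_min, length(Ca)))
    })
}

#' Ion-channel specification
#'
#' @param name channel label (e.g. `"NaF"`, `"KDr"`, `"KaS"`, `"BK"`).
#' @param E_rev reversal potential in volts, or the string
#'   `"calcium-Nernst"` for calcium channels whose reversal follows the
#'   Nernst potential of the internal calcium pool.
#' @param gates list of [gate_spec()] objects (at least one).
#' @param carries_calcium logical; does this current feed the calcium pool?
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, E_rev, gates, carries_calcium = FALSE) {
  if (length(gates) < 1L) stop("channel_spec: at least one gate required")
  stopifnot(all(vapply(gates, inherits, logical(1), "gate_spec")))
  nernst <- identical(E_rev, "calcium-Nernst")
  if (!nernst) stopifnot(is.numeric(E_rev), length(E_rev) == 1L)
  structure(list(name = name,
                 E_rev = if (nernst) NA_real_ else E_rev,
                 nernst = nernst, gates = gates,
                 carries_calcium = isTRUE(carries_calcium)),
            class = "channel_spec")
}

#' Passive membrane properties
#'
#' @param RM specific membrane resistance (Ohm m^2).
#' @param CM specific membrane capacitance (F/m^2).
#' @param RA axial resistivity (Ohm m).
#' @param E_leak leak reversal potential (V).
#' @return An object of class `passive_spec`.
#' @export
passive_spec <- function(RM, CM, RA, E_leak) {
  if (RM <= 0 || CM <= 0 || RA <= 0)
    stop("passive_spec: RM, CM and RA must be positive")
  structure(list(RM = RM, CM = CM, RA = RA, E_leak = E_leak),
            class = "passive_spec")
}

#' Single-exponential calcium pool parameters
#'
#' Each compartment carries one calcium pool with
#' d\[Ca\]/dt = -(\[Ca\] - ca_base)/tau_ca - B_ca * I_Ca,
#' where I_Ca is the summed calcium current (inward negative), so inward
#' calcium current raises the concentration.
#'
#' @param tau_ca decay time constant (s).
#' @param B_ca current-to-concentration factor (mM/(A s)); folds shell
#'   volume and the Faraday constant into one per-model constant.
#' @param ca_base resting concentration (mM).
#' @param ca_out external concentration (mM), used for the Nernst reversal.
#' @param enabled logical switch (`calYN`).
#' @return An object of class `calcium_spec`.
#' @export
calcium_spec <- function(tau_ca = 0.02, B_ca = 1e9, ca_base = 5e-5,
                         ca_out = 2, enabled = TRUE) {
  if (tau_ca <= 0) stop("calcium_spec: tau_ca must be > 0")
  if (ca_base < 0) stop("calcium_spec: ca_base must be >= 0")
  structure(list(tau_ca = tau_ca, B_ca = B_ca, ca_base = ca_base,
                 ca_out = ca_out, enabled = isTRUE(enabled)),
            class = "calcium_spec")
}

#' Per-region conductance-density map
#'
#' Densities in S/m^2 for each (channel, region) pair; regions are indexed
#' 0 (soma), 1 (proximal) and 2 (distal).
#'
#' @param ... named numeric vectors of length 3 (regions 0,1,2) or length 1
#'   (applied to all regions), one per channel.
#' @return A channels x 3 numeric matrix of class `conductance_map` with
#'   column names `"0","1","2"`.
#' @export
conductance_map <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      is.null(names(entries)[1])) entries <- entries[[1]]
  if (is.null(names(entries)) || any(names(entries) == ""))
    stop("conductance_map: all entries must be named by channel")
  m <- t(vapply(entries, function(g) {
    g <- as.numeric(g)
    if (length(g) == 1L) g <- rep(g, 3L)
    if (length(g) != 3L) stop("conductance_map: densities must have length 1 or 3")
    if (any(g < 0)) stop("conductance_map: densities must be >= 0")
    g
  }, numeric(3)))
  dimnames(m) <- list(names(entries), c("0", "1", "2"))
  class(m) <- c("conductance_map", class(m))
  m
}

#' Full declarative neuron model
#'
#' @param morphology a morphology data frame from [parse_p_file()],
#'   [parse_swc()] or [morph_segments()].
#' @param channels list of [channel_spec()] objects.
#' @param conductances a [conductance_map()]; every row must name a channel.
#' @param passive a [passive_spec()].
#' @param calcium a [calcium_spec()] (may be disabled).
#' @param region_thresholds two increasing path distances (m) splitting
#'   regions 1/2; region 0 is always the soma. Default 60 and 120 um.
#' @param spineYN must be FALSE (explicit spines are not supported).
#' @return An object of class `neuron_spec`.
#' @export
neuron_spec <- function(morphology, channels, conductances, passive,
                        calcium = calcium_spec(enabled = FALSE),
                        region_thresholds = c(60e-6, 120e-6),
                        spineYN = FALSE) {
  if (isTRUE(spineYN)) stop("neuron_spec: spineYN must be FALSE")
  stopifnot(inherits(passive, "passive_spec"),
            inherits(calcium, "calcium_spec"),
            is.data.frame(morphology))
  chan_names <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(chan_names))
    stop("neuron_spec: channel names must be unique")
  unknown <- setdiff(rownames(conductances), chan_names)
  if (length(unknown))
    stop("neuron_spec: conductance entries for undefined channels: ",
         paste(unknown, collapse = ", "))
  if (length(region_thresholds) != 2L ||
      region_thresholds[1] >= region_thresholds[2])
    stop("neuron_spec: region_thresholds must be two increasing distances")
  names(channels) <- chan_names
  structure(list(morphology = morphology,
                 region_thresholds = region_thresholds,
                 channels = channels, conductances = conductances,
                 passive = passive, calcium = calcium, spineYN = FALSE),
            class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat("neuron_spec:", nrow(x$morphology), "compartments,",
      length(x$channels), "channels\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat(sprintf("  passive: RM=%.3g Ohm m^2, CM=%.3g F/m^2, RA=%.3g Ohm m, E_leak=%.3g V\n",
              x$passive$RM, x$passive$CM, x$passive$RA, x$passive$E_leak))
  cat("  calcium pool:", if (x$calcium$enabled) "enabled" else "disabled", "\n")
  invisible(x)
}

#' Tunable-parameter set with bounds
#'
#' Each parameter names either a channel (optionally suffixed `_0`, `_1` or
#' `_2` to restrict it to one neuron region) whose conductance density is
#' tuned, or a passive property (`RM`, `CM`, `RA`, `E_leak`).
#'
#' @param name character vector of parameter names.
#' @param initial,min,max numeric vectors of initial values and bounds;
#'   `min <= initial <= max` and `min >= 0` for conductance parameters.
#' @return A data frame of class `param_set`.
#' @export
param_set <- function(name, initial, min, max) {
  stopifnot(length(name) == length(initial),
            length(name) == length(min), length(name) == length(max))
  if (any(min > initial | initial > max))
    stop("param_set: need min <= initial <= max for every parameter")
  cond <- !name %in% c("RM", "CM", "RA", "E_leak")
  if (any(cond & min < 0))
    stop("param_set: conductance parameters require min >= 0")
  structure(data.frame(name = name, initial = initial, min = min, max = max,
                       stringsAsFactors = FALSE),
            class = c("param_set", "data.frame"))
}

## split "KaS_0" into channel + region; region NA means all regions
.split_param_name <- function(nm) {
  m <- regmatches(nm, regexec("^(.*)_([012])$", nm))[[1]]
  if (length(m) == 3L) list(channel = m[2], region = as.integer(m[3]) + 1L)
  else list(channel = nm, region = NA_integer_)
}

#' Apply named parameter values to a neuron model
#'
#' A pure transformation: returns a modified copy, the input is untouched.
#' Unsuffixed channel names set the density in all three regions; a `_0`,
#' `_1` or `_2` suffix restricts the change to one region. `RM`, `CM`, `RA`
#' and `E_leak` set the passive properties.
#'
#' @param neuron a [neuron_spec()].
#' @param values named numeric vector of parameter values.
#' @param params optional [param_set()]; when given, every name must be
#'   declared in it and every value must lie within its bounds.
#' @return the modified `neuron_spec`.
#' @export
apply_params <- function(neuron, values, params = NULL) {
  stopifnot(inherits(neuron, "neuron_spec"), is.numeric(values))
  if (is.null(names(values)) || any(names(values) == ""))
    stop("apply_params: values must be named")
  if (!is.null(params)) {
    unknown <- setdiff(names(values), params$name)
    if (length(unknown))
      stop("apply_params: parameters not declared in the param_set: ",
           paste(unknown, collapse = ", "))
    i <- match(names(values), params$name)
    low <- values < params$min[i] - 1e-12
    high <- values > params$max[i] + 1e-12
    if (any(low | high)) {
      j <- which(low | high)[1]
      stop(sprintf("apply_params: %s = %g outside bounds [%g, %g]",
                   names(values)[j], values[j], params$min[i[j]],
                   params$max[i[j]]))
    }
  }
  passive_names <- c("RM", "CM", "RA", "E_leak")
  for (nm in names(values)) {
    v <- unname(values[[nm]])
    if (nm %in% passive_names) {
      if (nm != "E_leak" && v <= 0)
        stop(sprintf("apply_params: %s = %g violates bound min 0", nm, v))
      neuron$passive[[nm]] <- v
      next
    }
    sp <- .split_param_name(nm)
    if (!sp$channel %in% rownames(neuron$conductances))
      stop("apply_params: unknown parameter ", nm)
    if (v < 0)
      stop(sprintf("apply_params: %s = %g violates bound min 0", nm, v))
    if (is.na(sp$region)) neuron$conductances[sp$channel, ] <- v
    else neuron$conductances[sp$channel, sp$region] <- v
  }
  neuron
}
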