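## Declarative model documents on disk: one YAML file per concern
## (channel kinetics; conductances + morphology + passive; calcium),
## cross-referenced by file name, plus the morphology file itself in
## GENESIS .p or SWC format. All stored values are SI.

.rate_to_list <- function(r) {
  if (is.null(r)) NULL
  else list(A = r$A, B = r$B, C = r$C, D = r$D, F = r$F)
}
.rate_from_list <- function(l) {
  if (is.null(l)) NULL
  else gate_rate_spec(A = l$A, B = l$B, C = l$C, D = l$D, F = l$F)
}

#' Write a neuron model as declarative files
#'
#' Produces `kinetics.yaml` (channel gating), `cond.yaml` (morphology file
#' reference, per-region conductance densities, passive properties, region
#' thresholds, spine switch), `calcium.yaml` (calYN switch and pool
#' parameters), and the morphology file itself.
#'
#' @param neuron a [neuron_spec()].
#' @param dir output directory (created if needed).
#' @param morph_format `"p"` (GENESIS) or `"swc"`.
#' @return `dir`, invisibly.
#' @export
write_neuron_model <- function(neuron, dir, morph_format = c("p", "swc")) {
  stopifnot(inherits(neuron, "neuron_spec"))
  morph_format <- match.arg(morph_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  morph_file <- paste0("morphology.", morph_format)
  writeLines(if (morph_format == "p") write_p_file(neuron$morphology)
             else write_swc(neuron$morphology),
             file.path(dir, morph_file))
  chans <- lapply(neuron$channels, function(ch) {
    list(E_rev = if (ch$nernst) "calcium-Nernst" else ch$E_rev,
         carries_calcium = ch$carries_calcium,
         gates = lapply(ch$gates, function(g)
           list(name = g$name, power = g$power, form = g$form,
                forward = .rate_to_list(g$forward),
                backward = .rate_to_list(g$backward),
                ca_half = if (is.finite(g$ca_half)) g$ca_half else NULL,
                ca_slope = g$ca_slope, tau_min = g$tau_min)))
  })
  yaml::write_yaml(list(channels = chans),
                   file.path(dir, "kinetics.yaml"), precision = 15L)
  cond <- lapply(rownames(neuron$conductances), function(nm)
    as.numeric(neuron$conductances[nm, ]))
  names(cond) <- rownames(neuron$conductances)
  yaml::write_yaml(list(
    morphology = morph_file,
    kinetics = "kinetics.yaml",
    region_thresholds = as.numeric(neuron$region_thresholds),
    conductances = cond,
    passive = list(RM = neuron$passive$RM, CM = neuron$passive$CM,
                   RA = neuron$passive$RA, E_leak = neuron$passive$E_leak),
    spineYN = FALSE),
    file.path(dir, "cond.yaml"), precision = 15L)
  cal <- neuron$calcium
  yaml::write_yaml(list(calYN = cal$enabled, tau_ca = cal$tau_ca,
                        B_ca = cal$B_ca, ca_base = cal$ca_base,
                        ca_out = cal$ca_out),
                   file.path(dir, "calcium.yaml"), precision = 15L)
  invisible(dir)
}

#' Read a declarative neuron model directory
#'
#' Inverse of [write_neuron_model()].
#'
#' @param dir model directory containing `cond.yaml` (which names the
#'   morphology and kinetics files) and `calcium.yaml`.
#' @return a [neuron_spec()].
#' @export
read_neuron_model <- function(dir) {
  cond_path <- file.path(dir, "cond.yaml")
  if (!file.exists(cond_path)) stop("read_neuron_model: missing ", cond_path)
  cond <- yaml::read_yaml(cond_path)
  kin <- yaml::read_yaml(file.path(dir, cond$kinetics %||% "kinetics.yaml"))
  morph_file <- file.path(dir, cond$morphology)
  morph <- if (grepl("\\.swc$", morph_file)) parse_swc(morph_file, is_path = TRUE)
           else parse_p_file(morph_file, is_path = TRUE)
  channels <- lapply(names(kin$channels), function(nm) {
    ch <- kin$channels[[nm]]
    gates <- lapply(ch$gates, function(g)
      gate_spec(g$name, g$power, g$form,
                forward = .rate_from_list(g$forward),
                backward = .rate_from_list(g$backward),
                ca_half = g$ca_half %||% NA_real_,
                ca_slope = g$ca_slope %||% 2,
                tau_min = g$tau_min %||% 1e-5))
    channel_spec(nm, E_rev = if (identical(ch$E_rev, "calcium-Nernst"))
                   "calcium-Nernst" else ch$E_rev,
                 gates = gates,
                 carries_calcium = isTRUE(ch$carries_calcium))
  })
  gmap <- do.call(conductance_map, cond$conductances)
  cal_path <- file.path(dir, "calcium.yaml")
  calcium <- if (file.exists(cal_path)) {
    cl <- yaml::read_yaml(cal_path)
    calcium_spec(tau_ca = cl$tau_ca %||% 0.02, B_ca = cl$B_ca %||% 1e9,
                 ca_base = cl$ca_base %||% 5e-5, ca_out = cl$ca_out %||% 2,
                 enabled = isTRUE(cl$calYN))
  } else calcium_spec(enabled = FALSE)
  neuron_spec(morph, channels, gmap,
              passive_spec(cond$passive$RM, cond$passive$CM,
                           cond$passive$RA, cond$passive$E_leak),
              calcium,
              region_thresholds = unlist(cond$region_thresholds),
              spineYN = isTRUE(cond$spineYN))
}

#' Read a tunable-parameter set from YAML
#'
#' The document is a list of entries with fields `name`, `initial`, `min`,
#' `max`.
#'
#' @param path YAML file path.
#' @return a [param_set()].
#' @export
read_param_set <- function(path) {
  y <- yaml::read_yaml(path)
  param_set(name = vapply(y, `[[`, character(1), "name"),
            initial = vapply(y, `[[`, numeric(1), "initial"),
            min = vapply(y, `[[`, numeric(1), "min"),
            max = vapply(y, `[[`, numeric(1), "max"))
}

#' Read feature weights from YAML
#'
#' A flat mapping of feature name to nonnegative weight.
#'
#' @param path YAML file path.
#' @return a `feature_weights` vector.
#' @export
read_feature_weights <- function(path) {
  y <- yaml::read_yaml(path)
  structure(setNames(as.numeric(unlist(y)), names(y)),
            class = "feature_weights")
}
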