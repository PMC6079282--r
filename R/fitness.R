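## Feature-based fitness: normalized per-feature differences between a
## simulated and a recorded trace set, and their weighted combination into
## a single fitness value.

#' Normalized difference between a model and a data value
#'
#' Scalars: |m - d| / (|m| + |d|), defined as 0 when both are 0 (fractional,
#' unitless difference; absolute values in the denominator keep the measure
#' in \[0, 1\] for negative membrane potentials). Vectors: the mean of the
#' pointwise normalized differences. Histograms (probability vectors): half
#' the L1 distance.
#'
#' @param m,d model and data values (scalars or equal-length vectors).
#' @param type `"auto"` treats length-1 input as scalar and longer input as
#'   a vector feature; `"histogram"` switches to half-L1.
#' @return dimensionless fitness in \[0, 1\] for scalars and histograms.
#' @export
normalized_difference <- function(m, d, type = c("auto", "histogram")) {
  type <- match.arg(type)
  stopifnot(all(is.finite(m)), all(is.finite(d)))
  if (type == "histogram") return(sum(abs(m - d)) / 2)
  if (length(m) != length(d))
    stop("normalized_difference: length mismatch")
  denom <- abs(m) + abs(d)
  f <- ifelse(denom == 0, 0, abs(m - d) / denom)
  mean(f)
}

#' Feature weight presets
#'
#' Weights used to combine normalized feature differences into a single
#' fitness. The `"SPN"` preset is for striatal spiny projection neurons
#' (no rectification or spike-time terms, AHP curve weighted 4); the
#' `"GPe"` preset is for globus pallidus neurons (rectification weighted 2,
#' spike time and height down-weighted, no baseline-pre, latency or
#' charging-curve terms). `"uniform"` weights every feature 1.
#'
#' @param preset one of `"SPN"`, `"GPe"`, `"uniform"`.
#' @return named numeric vector of class `feature_weights`.
#' @export
feature_weights <- function(preset = c("SPN", "GPe", "uniform")) {
  preset <- match.arg(preset)
  nm <- c("baseline_pre", "baseline_post", "rectification", "falling_curve",
          "voltage_response", "latency", "spike_time", "spike_width",
          "spike_height", "spike_count", "ahp_depth", "ahp_curve",
          "charging_curve", "histogram")
  w <- switch(preset,
    SPN     = c(1, 1, 0, 1, 1, 1, 0,   1, 1,   1, 1, 4, 1, 1),
    GPe     = c(0, 1, 2, 1, 1, 0, 0.5, 1, 0.5, 1, 1, 1, 0, 1),
    uniform = rep(1, length(nm)))
  structure(setNames(w, nm), class = "feature_weights")
}

## normalized difference of one named feature present in both vectors
.feature_nd <- function(name, fs, fd) {
  s <- fs[[name]]; d <- fd[[name]]
  if (name == "histogram") return(normalized_difference(s, d, "histogram"))
  if (name %in% c("spike_time", "spike_width", "spike_height")) {
    k <- min(length(s), length(d))
    if (k == 0L) return(NA_real_)
    return(normalized_difference(s[seq_len(k)], d[seq_len(k)]))
  }
  normalized_difference(s, d)
}

#' Per-feature fitness of a simulated trace set against data
#'
#' Traces are matched one-to-one by metadata label (falling back to
#' injection amplitude). For each feature, the normalized difference is
#' averaged over the traces where the feature is defined in both sets;
#' per-spike features are paired over the first `min(n_sim, n_data)`
#' spikes, and the spike-count feature is the normalized difference of the
#' counts in each trace.
#'
#' @param sim,data [trace_set()] objects with matching protocols.
#' @param cfg a [feature_config()].
#' @return named numeric vector of per-feature fitnesses, with a
#'   `"detail"` attribute (data frame of per-trace values).
#' @export
feature_fitness <- function(sim, data, cfg = feature_config()) {
  stopifnot(inherits(sim, "trace_set"), inherits(data, "trace_set"))
  sim_labels <- vapply(sim$meta, `[[`, character(1), "label")
  data_labels <- vapply(data$meta, `[[`, character(1), "label")
  idx <- match(data_labels, sim_labels)
  if (any(is.na(idx))) {
    sim_amp <- vapply(sim$meta, `[[`, numeric(1), "amplitude")
    data_amp <- vapply(data$meta, `[[`, numeric(1), "amplitude")
    idx2 <- match(data_amp, sim_amp)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (any(is.na(idx)) || anyDuplicated(idx[!is.na(idx)]))
    stop("feature_fitness: unmatched traces: ",
         paste(data_labels[is.na(idx)], collapse = ", "))
  detail <- list()
  acc <- list()
  for (i in seq_along(idx)) {
    fs <- extract_features(sim$traces[[idx[i]]], sim$meta[[idx[i]]], cfg)
    fd <- extract_features(data$traces[[i]], data$meta[[i]], cfg)
    common <- intersect(defined_features(fs), defined_features(fd))
    for (nm in common) {
      f <- .feature_nd(nm, fs, fd)
      if (!is.finite(f)) next
      acc[[nm]] <- c(acc[[nm]], f)
      detail[[length(detail) + 1L]] <- data.frame(
        trace = data_labels[i], feature = nm, fitness = f,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(acc)) stop("feature_fitness: no feature defined in both sets")
  f <- vapply(acc, mean, numeric(1))
  structure(f, detail = do.call(rbind, detail))
}

#' Combine per-feature fitnesses into a total fitness
#'
#' Root-mean-square combination over the N features with positive weight:
#' total = sqrt( (1/N) * sum_i w_i f_i^2 ).
#'
#' @param f named numeric vector of per-feature fitnesses.
#' @param w a [feature_weights()] vector (or any named nonnegative
#'   weights); features absent from `w` get weight 1.
#' @return single nonnegative total fitness.
#' @export
combine <- function(f, w = feature_weights("uniform")) {
  stopifnot(is.numeric(f), length(f) >= 1L)
  wi <- rep(1, length(f))
  if (!is.null(names(f))) {
    known <- names(f) %in% names(w)
    wi[known] <- unname(w[names(f)[known]])
  } else if (length(w) == length(f)) wi <- unname(w)
  keep <- wi > 0
  if (!any(keep)) stop("combine: no feature with positive weight")
  sqrt(sum(wi[keep] * f[keep]^2) / sum(keep))
}

#' Published mean feature-fitness tables of the best-fitting models
#'
#' Reference per-feature fitness values (mean and standard deviation over
#' the 50 best models of each optimized neuron) for six striatal spiny
#' projection neurons (`"SPN"`) and seven globus pallidus neurons
#' (`"GPe"`), including the published totals in the `"total"` rows.
#' Shipped as plain CSV under `extdata`; used as worked examples for
#' [combine()].
#'
#' @param type `"SPN"` or `"GPe"`.
#' @return data frame with columns `feature`, `neuron`, `mean`, `sd`.
#' @export
reference_fitness_table <- function(type = c("SPN", "GPe")) {
  type <- match.arg(type)
  f <- if (type == "SPN") "spn_mean_feature_fitness.csv"
       else "gpe_mean_feature_fitness.csv"
  read.csv(system.file("extdata", f, package = "neurofit"),
           stringsAsFactors = FALSE)
}

#' Full fitness report for one parameter set
#'
#' @param sim,data [trace_set()] objects.
#' @param weights a [feature_weights()] vector.
#' @param cfg a [feature_config()].
#' @return object of class `fitness_report`: list with `features`
#'   (per-feature fitness, weight-0 features excluded), `total`, and
#'   `detail` (per-trace data frame).
#' @export
fitness_report <- function(sim, data, weights = feature_weights("uniform"),
                           cfg = feature_config()) {
  f <- feature_fitness(sim, data, cfg)
  wi <- setNames(rep(1, length(f)), names(f))
  known <- names(f) %in% names(weights)
  wi[known] <- unname(weights[names(f)[known]])
  structure(list(features = f[wi > 0], total = combine(f, weights),
                 detail = attr(f, "detail")),
            class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("fitness_report: total =", format(x$total, digits = 4), "\n")
  for (nm in names(x$features))
    cat(sprintf("  %-16s %.4f\n", nm, x$features[[nm]]))
  invisible(x)
}
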