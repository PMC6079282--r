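## Electrophysiology features of a single current-clamp trace: spike shape,
## AHP, latency, subthreshold responses, and the voltage-occupancy histogram.

#' Feature-extraction configuration
#'
#' @param peak_min minimum peak voltage counted as a spike (V).
#' @param refractory minimum separation between spike peaks (s).
#' @param ahp_window maximum afterhyperpolarization window after each peak
#'   (s); the window ends earlier at the next spike's threshold.
#' @param n_curve number of resampled points of the AHP and charging
#'   curves.
#' @param hist_bins,hist_range bin count and voltage range (V) of the
#'   membrane-potential occupancy histogram.
#' @param slope_frac threshold rule: the spike threshold is the first point
#'   on the upstroke where dV/dt exceeds this fraction of the upstroke's
#'   maximum dV/dt.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(peak_min = -0.01, refractory = 2e-3,
                           ahp_window = 20e-3, n_curve = 20L,
                           hist_bins = 64L, hist_range = c(-0.1, 0.05),
                           slope_frac = 0.05) {
  structure(list(peak_min = peak_min, refractory = refractory,
                 ahp_window = ahp_window, n_curve = as.integer(n_curve),
                 hist_bins = as.integer(hist_bins), hist_range = hist_range,
                 slope_frac = slope_frac),
            class = "feature_config")
}

#' Detect action potentials in a trace
#'
#' Peaks are local maxima above `peak_min` separated by at least the
#' refractory interval. For each spike the threshold is the first sample on
#' the upstroke where dV/dt (central differences) exceeds `slope_frac` of
#' that upstroke's maximum dV/dt; height is peak minus threshold; width is
#' the full width at half height with linear interpolation on both flanks.
#'
#' @param trace a `neuro_trace` (uniformly sampled).
#' @param cfg a [feature_config()].
#' @return data frame of class `spike_events` with one row per spike
#'   (`peak_time`, `peak_V`, `threshold_time`, `threshold_V`, `height`,
#'   `width`, `ahp_min_V`) and an `ahp_samples` attribute (spikes x
#'   `n_curve` matrix of Vm over the normalized post-spike window). Empty
#'   data frame when there are no spikes.
#' @export
detect_spikes <- function(trace, cfg = feature_config()) {
  vm <- trace$Vm; tt <- trace$times
  n <- length(vm)
  empty <- structure(data.frame(peak_time = numeric(0), peak_V = numeric(0),
                                threshold_time = numeric(0),
                                threshold_V = numeric(0), height = numeric(0),
                                width = numeric(0), ahp_min_V = numeric(0)),
                     ahp_samples = matrix(0, 0, cfg$n_curve),
                     class = c("spike_events", "data.frame"))
  if (n < 3L) return(empty)
  dt <- tt[2] - tt[1]
  dvdt <- c(vm[2] - vm[1],
            (vm[3:n] - vm[1:(n - 2)]) / 2,
            vm[n] - vm[n - 1]) / dt
  cand <- which(vm > cfg$peak_min)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[vm[cand] >= vm[cand - 1L] & vm[cand] > vm[cand + 1L]]
  if (!length(cand)) return(empty)
  ## enforce refractory separation, keeping the larger peak
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) && tt[i] - tt[peaks[length(peaks)]] < cfg$refractory) {
      if (vm[i] > vm[peaks[length(peaks)]]) peaks[length(peaks)] <- i
    } else peaks <- c(peaks, i)
  }
  ns <- length(peaks)
  thr_idx <- integer(ns)
  for (s in seq_len(ns)) {
    p <- peaks[s]
    lo <- if (s > 1L) peaks[s - 1L] else 1L
    j <- p - 1L
    while (j > lo && dvdt[j] > 0) j <- j - 1L
    up <- j:p                                   # upstroke indices
    maxslope <- max(dvdt[up])
    above <- up[dvdt[up] > cfg$slope_frac * maxslope]
    thr_idx[s] <- if (length(above)) above[1] else up[1]
  }
  height <- vm[peaks] - vm[thr_idx]
  width <- numeric(ns)
  ahp_min <- numeric(ns)
  ahp_samples <- matrix(NA_real_, ns, cfg$n_curve)
  for (s in seq_len(ns)) {
    p <- peaks[s]
    half <- vm[thr_idx[s]] + height[s] / 2
    ## left flank: last crossing of the half level before the peak
    li <- p
    while (li > thr_idx[s] && vm[li - 1L] >= half) li <- li - 1L
    t_left <- if (li == thr_idx[s] || vm[li] == vm[li - 1L]) tt[li]
      else tt[li - 1L] + dt * (half - vm[li - 1L]) / (vm[li] - vm[li - 1L])
    ## right flank: first crossing after the peak
    lim <- if (s < ns) thr_idx[s + 1L] else n
    ri <- p
    while (ri < lim && vm[ri + 1L] > half) ri <- ri + 1L
    t_right <- if (ri == lim || vm[ri + 1L] == vm[ri]) tt[ri]
      else tt[ri] + dt * (vm[ri] - half) / (vm[ri] - vm[ri + 1L])
    width[s] <- max(t_right - t_left, dt)
    ## AHP window: peak to next threshold crossing or +ahp_window
    a_end <- min(if (s < ns) tt[thr_idx[s + 1L]] else Inf,
                 tt[p] + cfg$ahp_window, tt[n])
    wi <- which(tt >= tt[p] & tt <= a_end)
    ahp_min[s] <- min(vm[wi])
    ts <- seq(tt[p], a_end, length.out = cfg$n_curve)
    ahp_samples[s, ] <- approx(tt, vm, xout = ts, rule = 2)$y
  }
  structure(data.frame(peak_time = tt[peaks], peak_V = vm[peaks],
                       threshold_time = tt[thr_idx],
                       threshold_V = vm[thr_idx], height = height,
                       width = width, ahp_min_V = ahp_min),
            ahp_samples = ahp_samples,
            class = c("spike_events", "data.frame"))
}

## windows include a half-nanosecond guard so that a sample landing
## exactly on a boundary is treated identically regardless of how the
## boundary was computed (floating-point robustness)
.win_eps <- 1e-9

.window_mean <- function(tt, vm, w) {
  i <- tt >= w[1] - .win_eps & tt <= w[2] + .win_eps
  if (!any(i)) return(NA_real_)
  mean(vm[i])
}

## least-squares single-exponential V(t) = a + b exp(-(t-t0)/tau);
## 1-D search over log(tau) with the linear coefficients solved exactly
.fit_exp_tau <- function(tt, vm, t0) {
  sse <- function(logtau) {
    e <- exp(-(tt - t0) / exp(logtau))
    fit <- tryCatch(lm.fit(cbind(1, e), vm), error = function(e2) NULL)
    if (is.null(fit)) return(Inf)
    sum(fit$residuals^2)
  }
  span <- max(tt) - t0
  opt <- optimize(sse, lower = log(span / 200), upper = log(span * 20))
  exp(opt$minimum)
}

#' Subthreshold features of a trace
#'
#' Baselines are mean Vm over the metadata windows; the steady-state
#' voltage response is the steady-state mean minus the pre-injection
#' baseline. For hyperpolarizing traces, rectification (sag) is the
#' steady-state response minus the minimum deflection, and the
#' falling-curve time constant is a least-squares single-exponential fit
#' from injection onset to the time of minimum Vm. For depolarizing
#' traces, the charging curve is Vm resampled at `n_curve` points from
#' onset to the first spike threshold (or to the steady-state window start
#' when there is no spike). Features of the wrong polarity are `NULL`
#' (undefined), never zero-filled.
#'
#' @param trace a `neuro_trace`.
#' @param meta a [new_protocol_meta()].
#' @param cfg a [feature_config()].
#' @param spikes optional precomputed [detect_spikes()] result.
#' @return named list of defined features.
#' @export
subthreshold_features <- function(trace, meta, cfg = feature_config(),
                                  spikes = NULL) {
  tt <- trace$times; vm <- trace$Vm
  out <- list()
  out$baseline_pre <- .window_mean(tt, vm, meta$baseline_pre)
  out$baseline_post <- .window_mean(tt, vm, meta$baseline_post)
  out$voltage_response <- .window_mean(tt, vm, meta$steady_state) -
    out$baseline_pre
  inj <- tt >= meta$onset - .win_eps & tt <= meta$offset + .win_eps
  if (meta$amplitude < 0) {
    vmin <- min(vm[inj])
    min_defl <- vmin - out$baseline_pre
    out$rectification <- out$voltage_response - min_defl
    t_min <- tt[inj][which.min(vm[inj])]
    fi <- tt >= meta$onset - .win_eps & tt <= t_min + .win_eps
    out$falling_curve <- if (sum(fi) >= 5L)
      .fit_exp_tau(tt[fi], vm[fi], meta$onset) else NULL
  }
  if (meta$amplitude > 0) {
    if (is.null(spikes)) spikes <- detect_spikes(trace, cfg)
    t_end <- if (nrow(spikes) > 0) spikes$threshold_time[1]
             else meta$steady_state[1]
    if (t_end - meta$onset > 5 * (tt[2] - tt[1])) {
      ts <- seq(meta$onset, t_end, length.out = cfg$n_curve)
      out$charging_curve <- approx(tt, vm, xout = ts, rule = 2)$y
    }
  }
  out
}

#' Spiking features of a trace
#'
#' Spike times are relative to injection onset and restricted to the
#' injection window; latency is the first threshold crossing after onset
#' (undefined without spikes, and only reported for depolarizing or
#' zero-current traces). AHP depth is the mean over spikes of threshold
#' minus AHP minimum; the AHP curve is the pointwise mean of the per-spike
#' resampled AHP windows. The histogram is the normalized occupancy of Vm
#' during the injection window.
#'
#' @param spikes a [detect_spikes()] result for the trace.
#' @param trace a `neuro_trace`.
#' @param meta a [new_protocol_meta()].
#' @param cfg a [feature_config()].
#' @return named list of defined features.
#' @export
spike_features <- function(spikes, trace, meta, cfg = feature_config()) {
  tt <- trace$times; vm <- trace$Vm
  keep <- spikes$peak_time >= meta$onset - .win_eps &
    spikes$peak_time <= meta$offset + .win_eps
  sp <- spikes[keep, , drop = FALSE]
  ahp <- attr(spikes, "ahp_samples")[keep, , drop = FALSE]
  out <- list()
  out$spike_count <- nrow(sp)
  out$spike_time <- sp$peak_time - meta$onset
  if (nrow(sp) > 0) {
    out$spike_width <- sp$width
    out$spike_height <- sp$height
    out$ahp_depth <- mean(sp$threshold_V - sp$ahp_min_V)
    out$ahp_curve <- colMeans(ahp)
    if (meta$amplitude >= 0)
      out$latency <- sp$threshold_time[1] - meta$onset
  }
  inj <- tt >= meta$onset - .win_eps & tt <= meta$offset + .win_eps
  v <- pmin(pmax(vm[inj], cfg$hist_range[1]), cfg$hist_range[2])
  breaks <- seq(cfg$hist_range[1], cfg$hist_range[2],
                length.out = cfg$hist_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = cfg$hist_bins)
  out$histogram <- h / sum(h)
  out
}

#' Extract the full feature vector of one trace
#'
#' Combines [detect_spikes()], [subthreshold_features()] and
#' [spike_features()]. Features that are undefined for the trace polarity
#' or spike content are simply absent.
#'
#' @inheritParams subthreshold_features
#' @return named list of class `feature_vector`.
#' @export
extract_features <- function(trace, meta, cfg = feature_config()) {
  spikes <- detect_spikes(trace, cfg)
  fv <- c(subthreshold_features(trace, meta, cfg, spikes = spikes),
          spike_features(spikes, trace, meta, cfg))
  structure(fv, class = "feature_vector")
}

#' Names of features a feature vector defines
#' @param fv a `feature_vector`.
#' @return character vector.
#' @export
defined_features <- function(fv) {
  names(fv)[vapply(fv, function(x)
    !is.null(x) && length(x) > 0 && all(is.finite(x)), logical(1))]
}

#' Feature table of a trace set
#'
#' One row per (trace, scalar feature); vector features are reported by
#' their mean.
#'
#' @param ts a [trace_set()].
#' @param cfg a [feature_config()].
#' @return data frame with columns `trace`, `feature`, `value`.
#' @export
feature_table <- function(ts, cfg = feature_config()) {
  rows <- list()
  for (i in seq_along(ts$traces)) {
    fv <- extract_features(ts$traces[[i]], ts$meta[[i]], cfg)
    for (nm in defined_features(fv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        trace = ts$meta[[i]]$label, feature = nm,
        value = mean(fv[[nm]]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
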