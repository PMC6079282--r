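## Reading/writing current-clamp traces (CSV) and protocol metadata
## (YAML sidecar), and the trace_set container.

#' Protocol metadata for a recorded or simulated trace
#'
#' Analysis windows in seconds from trace start.
#'
#' @param onset,offset injection start/end (s).
#' @param amplitude injected current (A).
#' @param baseline_pre,baseline_post,steady_state two-element windows (s)
#'   for pre-injection baseline, post-injection baseline, and steady-state
#'   response.
#' @param sampling_rate Hz (may be `NA` when times come with the trace).
#' @param label trace label.
#' @return An object of class `protocol_meta`.
#' @export
new_protocol_meta <- function(onset, offset, amplitude,
                              baseline_pre, baseline_post, steady_state,
                              sampling_rate = NA_real_, label = NULL) {
  if (!(onset < offset)) stop("protocol_meta: need onset < offset")
  chk <- function(w, nm) {
    if (length(w) != 2L || w[1] > w[2])
      stop("protocol_meta: malformed window ", nm)
    w
  }
  if (is.null(label)) label <- sprintf("%gpA", amplitude * 1e12)
  structure(list(onset = onset, offset = offset, amplitude = amplitude,
                 baseline_pre = chk(baseline_pre, "baseline_pre"),
                 baseline_post = chk(baseline_post, "baseline_post"),
                 steady_state = chk(steady_state, "steady_state"),
                 sampling_rate = sampling_rate, label = label),
            class = "protocol_meta")
}

#' Derive default analysis windows from a stimulus protocol
#'
#' Baseline-pre is the whole pre-injection span; the steady-state window is
#' the last 20% of the injection; baseline-post is the last 25% of the
#' post-injection span (when one exists).
#'
#' @param protocol a [stimulus_protocol()].
#' @return a [new_protocol_meta()] object.
#' @export
protocol_meta <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  on <- protocol$onset; off <- protocol$offset; dur <- protocol$duration
  inj <- off - on
  pre <- if (on > 0) c(0, on) else c(0, 0.05 * dur)
  post <- if (dur > off) c(dur - 0.25 * (dur - off), dur) else c(0.75 * dur, dur)
  new_protocol_meta(onset = on, offset = off,
                    amplitude = protocol$amplitude,
                    baseline_pre = pre, baseline_post = post,
                    steady_state = c(off - 0.2 * inj, off),
                    label = protocol$label)
}

#' Ordered set of traces with metadata
#'
#' @param traces list of `neuro_trace` objects (each with `times`, `Vm`).
#' @param meta list of [new_protocol_meta()] objects, one per trace.
#' @param label neuron label.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, meta, label = "neuron") {
  if (!length(traces)) stop("trace_set: at least one trace required")
  if (length(traces) != length(meta))
    stop("trace_set: traces and meta lengths differ")
  for (tr in traces) {
    if (length(tr$times) != length(tr$Vm))
      stop("trace_set: times/Vm length mismatch")
    if (any(!is.finite(tr$Vm)))
      stop("trace_set: non-finite voltage values")
  }
  structure(list(traces = traces, meta = meta, label = label),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set '%s' with %d traces:\n", x$label, length(x$traces)))
  for (i in seq_along(x$traces))
    cat(sprintf("  [%d] %s: %d samples, %.3g s\n", i, x$meta[[i]]$label,
                length(x$traces[[i]]$times), max(x$traces[[i]]$times)))
  invisible(x)
}

#' Read a current-clamp trace from CSV
#'
#' Accepts two-column `time,voltage` files (seconds, volts) or
#' voltage-only files combined with `meta$sampling_rate`. Files whose
#' voltages exceed 1 in magnitude are assumed millivolt-scaled and are
#' converted to volts with a warning; volt-scaled data (|V| <= 0.2) never
#' triggers the conversion.
#'
#' @param path CSV file path.
#' @param meta optional [new_protocol_meta()], required for voltage-only
#'   files; attached to the returned trace.
#' @return a `neuro_trace` object.
#' @export
read_csv_trace <- function(path, meta = NULL) {
  df <- read.csv(path, header = TRUE)
  if (ncol(df) >= 2L) {
    times <- as.numeric(df[[1]])
    vm <- as.numeric(df[[2]])
  } else {
    if (is.null(meta) || !is.finite(meta$sampling_rate))
      stop("read_csv_trace: voltage-only file requires meta$sampling_rate")
    vm <- as.numeric(df[[1]])
    times <- (seq_along(vm) - 1) / meta$sampling_rate
  }
  if (any(is.na(times)) || any(is.na(vm)))
    stop("read_csv_trace: non-numeric rows in ", path)
  if (length(times) > 1L) {
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-6)
      stop("read_csv_trace: non-uniform time base in ", path)
  }
  if (max(abs(vm)) > 1) {
    warning("read_csv_trace: values look millivolt-scaled; converting to volts")
    vm <- vm / 1000
  }
  protocol <- if (!is.null(meta))
    stimulus_protocol(meta$amplitude, meta$onset, meta$offset,
                      duration = max(times), label = meta$label)
  else NULL
  structure(list(times = times, Vm = vm, Ca = NULL, protocol = protocol),
            class = "neuro_trace")
}

#' Write a trace to CSV
#'
#' Header is exactly `time,voltage`; refuses to overwrite an existing file
#' unless `overwrite = TRUE` (a trace file holds exactly one trace;
#' appending is not supported).
#'
#' @param trace a `neuro_trace`.
#' @param path output path.
#' @param overwrite allow replacing an existing file.
#' @export
write_csv_trace <- function(trace, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("write_csv_trace: '", path,
         "' exists; one trace per file (set overwrite = TRUE to replace)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,voltage", con)
  writeLines(sprintf("%.12g,%.12g", trace$times, trace$Vm), con)
  invisible(path)
}

.meta_to_list <- function(m) {
  list(onset = m$onset, offset = m$offset, amplitude = m$amplitude,
       baseline_pre = as.numeric(m$baseline_pre),
       baseline_post = as.numeric(m$baseline_post),
       steady_state = as.numeric(m$steady_state),
       sampling_rate = if (is.finite(m$sampling_rate)) m$sampling_rate
                       else NULL,
       label = m$label)
}

.meta_from_list <- function(l) {
  new_protocol_meta(onset = l$onset, offset = l$offset,
                    amplitude = l$amplitude,
                    baseline_pre = unlist(l$baseline_pre),
                    baseline_post = unlist(l$baseline_post),
                    steady_state = unlist(l$steady_state),
                    sampling_rate = if (is.null(l$sampling_rate)) NA_real_
                                    else l$sampling_rate,
                    label = l$label)
}

#' Write a trace set to a recording directory
#'
#' Layout: `<dir>/<label>_<i>.csv` plus `<dir>/meta.yaml` with one entry
#' per trace file.
#'
#' @param ts a [trace_set()].
#' @param dir output directory (created if needed).
#' @param overwrite replace existing trace files.
#' @return `dir`, invisibly.
#' @export
write_recording_dir <- function(ts, dir, overwrite = FALSE) {
  stopifnot(inherits(ts, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_along(ts$traces)) {
    fname <- sprintf("trace_%02d.csv", i)
    write_csv_trace(ts$traces[[i]], file.path(dir, fname),
                    overwrite = overwrite)
    entries[[i]] <- c(list(file = fname), .meta_to_list(ts$meta[[i]]))
  }
  yaml::write_yaml(list(neuron = ts$label, traces = entries),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a recording directory into a trace set
#'
#' @param dir directory with trace CSVs and a `meta.yaml` sidecar.
#' @return a [trace_set()].
#' @export
read_recording_dir <- function(dir) {
  mpath <- file.path(dir, "meta.yaml")
  if (!file.exists(mpath)) stop("read_recording_dir: missing ", mpath)
  y <- yaml::read_yaml(mpath)
  meta <- lapply(y$traces, .meta_from_list)
  traces <- mapply(function(entry, m)
    read_csv_trace(file.path(dir, entry$file), m),
    y$traces, meta, SIMPLIFY = FALSE)
  trace_set(traces, meta, label = y$neuron %||% basename(dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
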