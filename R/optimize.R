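## Orchestration of a fit: candidate evaluation (parallel, cached,
## persisted to disk), the do_fit loop, convergence detection, and
## best-model selection.

#' Describe a fitting problem
#'
#' Bundles the base model, the tunable parameters, the target recordings
#' and the fitness configuration. The simulation protocols are rebuilt
#' from the recording metadata (amplitude, onset, offset, duration), so
#' the simulator reproduces the experimental conditions.
#'
#' @param neuron base [neuron_spec()].
#' @param params a [param_set()] of tunable parameters with bounds.
#' @param data target [trace_set()].
#' @param weights a [feature_weights()] vector.
#' @param sim_cfg a [sim_config()].
#' @param feat_cfg a [feature_config()].
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(neuron, params, data,
                        weights = feature_weights("uniform"),
                        sim_cfg = sim_config(), feat_cfg = feature_config()) {
  stopifnot(inherits(neuron, "neuron_spec"), inherits(params, "param_set"),
            inherits(data, "trace_set"))
  protocols <- lapply(seq_along(data$traces), function(i) {
    m <- data$meta[[i]]
    stimulus_protocol(m$amplitude, m$onset, m$offset,
                      duration = max(data$traces[[i]]$times),
                      label = m$label)
  })
  structure(list(neuron = neuron, params = params, data = data,
                 weights = weights, protocols = protocols,
                 sim_cfg = sim_cfg, feat_cfg = feat_cfg),
            class = "fit_problem")
}

## canonical fixed-precision serialization of a parameter map (cache key)
.param_key <- function(values) {
  paste(sprintf("%s=%.12g", names(values), values), collapse = "|")
}

## evaluate one candidate: simulate every protocol, score against the data
.evaluate_one <- function(values, problem) {
  tryCatch({
    neuron <- apply_params(problem$neuron, values, problem$params)
    sim <- run_protocol_set(neuron, problem$protocols, problem$sim_cfg)
    rep <- fitness_report(sim, problem$data, problem$weights,
                          problem$feat_cfg)
    list(total = rep$total, features = as.list(rep$features), note = "",
         sim = sim)
  }, error = function(e) {
    list(total = Inf, features = list(),
         note = paste("simulation failure:", conditionMessage(e)),
         sim = NULL)
  })
}

## persist one evaluation under store/eval_%06d/
.persist_eval <- function(store, eval_index, values, res, save_traces) {
  d <- file.path(store, sprintf("eval_%06d", eval_index))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(as.list(values), file.path(d, "params.yaml"),
                   precision = 15L)
  yaml::write_yaml(list(total = if (is.finite(res$total)) res$total
                        else "Inf",
                        features = res$features, note = res$note),
                   file.path(d, "fitness.yaml"), precision = 15L)
  if (save_traces && !is.null(res$sim)) {
    for (i in seq_along(res$sim$traces))
      write_csv_trace(res$sim$traces[[i]],
                      file.path(d, sprintf("trace_%02d.csv", i)),
                      overwrite = TRUE)
  }
  d
}

#' Evaluate a population of candidates
#'
#' Each candidate's full protocol set is simulated and scored. Duplicate
#' parameter vectors (exact match on the canonical 12-significant-digit
#' serialization) are simulated once; previously evaluated vectors are
#' served from the cache without re-simulation. Results are identical
#' regardless of the degree of parallelism. A simulation failure yields a
#' `+Inf` fitness sentinel with a failure note; the run continues.
#'
#' @param candidates lambda x n matrix (rows are parameter vectors, columns
#'   named).
#' @param problem a [fit_problem()].
#' @param store optional directory; every new evaluation is persisted there
#'   (params.yaml + fitness.yaml) before being reported.
#' @param cache optional environment used as the evaluation cache.
#' @param cores worker processes for parallel evaluation.
#' @param save_traces also persist the simulated trace CSVs.
#' @param eval_offset index of the last persisted evaluation.
#' @return list of per-candidate results (`total`, `features`, `note`,
#'   `cached`).
#' @export
evaluate_population <- function(candidates, problem, store = NULL,
                                cache = NULL, cores = 1L,
                                save_traces = FALSE, eval_offset = 0L) {
  keys <- apply(candidates, 1L, function(v) .param_key(v))
  cached <- if (is.null(cache)) rep(FALSE, length(keys))
            else vapply(keys, function(k) !is.null(cache[[k]]), logical(1))
  todo_keys <- unique(keys[!cached])
  todo_idx <- match(todo_keys, keys)
  runner <- function(i) .evaluate_one(candidates[i, ], problem)
  fresh <- if (length(todo_idx) == 0L) list()
  else if (cores > 1L)
    parallel::mclapply(todo_idx, runner, mc.cores = cores)
  else lapply(todo_idx, runner)
  names(fresh) <- todo_keys
  ## persist fresh evaluations (in candidate order) before reporting
  eval_index <- eval_offset
  for (k in todo_keys) {
    eval_index <- eval_index + 1L
    if (!is.null(store))
      .persist_eval(store, eval_index, candidates[todo_idx[match(k, todo_keys)], ],
                    fresh[[k]], save_traces)
    fresh[[k]]$sim <- NULL
    fresh[[k]]$eval_index <- eval_index
    if (!is.null(cache)) cache[[k]] <- fresh[[k]]
  }
  out <- lapply(seq_along(keys), function(i) {
    res <- if (!is.null(cache)) cache[[keys[i]]] else {
      r <- fresh[[keys[i]]]
      r
    }
    res$cached <- cached[i]
    res
  })
  attr(out, "eval_index") <- eval_index
  out
}

#' Convergence criteria on the mean-fitness history
#'
#' An optimization is converged when, over the last `window` generations,
#' the least-squares slope of the per-generation mean fitness is below
#' `slope_tol` in magnitude and its standard deviation is below `sd_tol`.
#'
#' @param window number of generations (default 25).
#' @param slope_tol slope tolerance (fitness/generation, default 0.002).
#' @param sd_tol standard-deviation tolerance (fitness, default 0.06).
#' @return object of class `convergence_criteria`.
#' @export
convergence_criteria <- function(window = 25L, slope_tol = 0.002,
                                 sd_tol = 0.06) {
  if (window < 2L) stop("convergence_criteria: window must be >= 2")
  if (slope_tol <= 0 || sd_tol <= 0)
    stop("convergence_criteria: tolerances must be > 0")
  structure(list(window = as.integer(window), slope_tol = slope_tol,
                 sd_tol = sd_tol),
            class = "convergence_criteria")
}

#' Has the optimization converged?
#'
#' @param history a `fit_history` (or a numeric vector of per-generation
#'   mean fitnesses).
#' @param criteria a [convergence_criteria()].
#' @return logical; `FALSE` with attribute `reason =
#'   "insufficient generations"` when fewer than `window` generations are
#'   available.
#' @export
check_convergence <- function(history, criteria = convergence_criteria()) {
  means <- if (is.numeric(history)) history
           else attr(history, "mean_fitness")
  W <- criteria$window
  if (length(means) < W)
    return(structure(FALSE, reason = "insufficient generations"))
  m <- tail(means, W)
  slope <- unname(coef(lm(m ~ seq_len(W)))[2])
  abs(slope) < criteria$slope_tol && sd(m) < criteria$sd_tol
}

#' Select the best-fitting models from a history
#'
#' The 2.5% lowest-fitness evaluations (ceiling, at least one), or the 50
#' lowest when more than 2,000 evaluations were performed.
#'
#' @param history a `fit_history` data frame.
#' @return the selected rows, ordered by increasing fitness.
#' @export
select_best <- function(history) {
  stopifnot(nrow(history) >= 1L)
  n <- nrow(history)
  k <- if (n > 2000L) 50L else max(1L, ceiling(0.025 * n))
  ord <- order(history$fitness, seq_len(n))
  out <- history[ord[seq_len(min(k, n))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a CMA-ES fit of a neuron model to recordings
#'
#' Performs `generations x popsize` model evaluations (cache hits counted),
#' persisting every evaluation under `dir` and appending the fitness
#' history to `dir/history.csv` after each generation, so an interrupted
#' run can be resumed from the storage directory.
#'
#' @param problem a [fit_problem()].
#' @param generations number of generations.
#' @param popsize population size (default 8).
#' @param seed integer seed for the optimizer.
#' @param sigma0 initial CMA-ES step size in scaled space.
#' @param dir storage directory for persistence.
#' @param cores parallel workers for population evaluation.
#' @param save_traces persist simulated traces per evaluation.
#' @param resume reload previously persisted evaluations into the cache
#'   and continue.
#' @return object of class `fit_history`: data frame with columns
#'   `generation`, `evaluation`, `fitness`, `cached` and one column per
#'   parameter; attributes `mean_fitness` (per generation), `best_so_far`,
#'   `cma` (final optimizer state), and `dir`.
#' @export
do_fit <- function(problem, generations, popsize = 8L, seed = 1L,
                   sigma0 = 0.3, dir = tempfile("neurofit_"), cores = 1L,
                   save_traces = FALSE, resume = FALSE) {
  stopifnot(inherits(problem, "fit_problem"))
  params <- problem$params
  x0 <- setNames(params$initial, params$name)
  st <- cma_init(x0, setNames(params$min, params$name),
                 setNames(params$max, params$name),
                 sigma0 = sigma0, popsize = popsize, seed = seed,
                 max_evals = generations * popsize)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cache <- new.env(parent = emptyenv())
  eval_offset <- 0L
  if (resume) {
    evdirs <- list.dirs(dir, recursive = FALSE)
    evdirs <- evdirs[grepl("eval_[0-9]+$", evdirs)]
    for (d in evdirs) {
      p <- tryCatch(yaml::read_yaml(file.path(d, "params.yaml")),
                    error = function(e) NULL)
      f <- tryCatch(yaml::read_yaml(file.path(d, "fitness.yaml")),
                    error = function(e) NULL)
      if (is.null(p) || is.null(f)) next
      v <- unlist(p)
      total <- if (identical(f$total, "Inf")) Inf else as.numeric(f$total)
      cache[[.param_key(v)]] <- list(total = total, features = f$features,
                                     note = f$note %||% "")
    }
    eval_offset <- length(evdirs)
  }
  rows <- vector("list", generations)
  mean_fit <- numeric(generations)
  evaluation <- 0L
  for (g in seq_len(generations)) {
    x <- cma_ask(st)
    res <- evaluate_population(x, problem, store = dir, cache = cache,
                               cores = cores, save_traces = save_traces,
                               eval_offset = eval_offset)
    eval_offset <- attr(res, "eval_index")
    fit <- vapply(res, `[[`, numeric(1), "total")
    cma_tell(st, x, fit)
    df <- data.frame(generation = g,
                     evaluation = evaluation + seq_len(nrow(x)),
                     fitness = fit,
                     cached = vapply(res, `[[`, logical(1), "cached"))
    evaluation <- evaluation + nrow(x)
    df <- cbind(df, as.data.frame(x))
    rows[[g]] <- df
    mean_fit[g] <- mean(fit[is.finite(fit)])
    hist_so_far <- do.call(rbind, rows[seq_len(g)])
    write.csv(hist_so_far, file.path(dir, "history.csv"),
              row.names = FALSE)
  }
  history <- do.call(rbind, rows)
  best <- cummin(ifelse(is.finite(history$fitness), history$fitness, Inf))
  structure(history, mean_fitness = mean_fit, best_so_far = best,
            cma = st, dir = dir, params = params,
            class = c("fit_history", "data.frame"))
}

#' Read a persisted fitness history
#'
#' @param dir a [do_fit()] storage directory.
#' @return `fit_history` data frame with `mean_fitness` and `best_so_far`
#'   attributes.
#' @export
read_fit_history <- function(dir) {
  path <- file.path(dir, "history.csv")
  if (!file.exists(path)) stop("read_fit_history: missing ", path)
  history <- read.csv(path)
  mean_fit <- tapply(history$fitness[is.finite(history$fitness)],
                     history$generation[is.finite(history$fitness)], mean)
  best <- cummin(ifelse(is.finite(history$fitness), history$fitness, Inf))
  structure(history, mean_fitness = as.numeric(mean_fit), best_so_far = best,
            dir = dir, class = c("fit_history", "data.frame"))
}
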