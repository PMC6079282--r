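## small shared fitting problem: passive neuron, one parameter, 2 traces
small_problem <- function(noise_sd = 0) {
  nrn <- passive_soma_neuron(Rin = 2e8, tau_m = 0.01)
  prot <- list(stimulus_protocol(-50e-12, 0.05, 0.25, 0.3),
               stimulus_protocol(-100e-12, 0.05, 0.25, 0.3))
  data <- generate_recordings(nrn, prot, noise_sd = noise_sd, seed = 1,
                              sim_cfg = sim_config(V_init = -0.070))
  params <- param_set(c("RM", "CM"), initial = c(0.7, 0.012),
                      min = c(0.2, 0.004), max = c(3, 0.04))
  fit_problem(nrn, params, data, feature_weights("uniform"),
              sim_cfg = sim_config(V_init = -0.070))
}

test_that("check_convergence applies the slope and sd thresholds", {
  crit <- convergence_criteria(25, 0.002, 0.06)
  expect_true(check_convergence(rep(0.5, 25), crit))
  expect_false(check_convergence(seq(1, by = -0.01, length.out = 25), crit))
  ## crafted series: slope 0.0015, sd below 0.06
  x <- 0.4 + 0.0015 * (1:25) - mean(0.0015 * (1:25))
  expect_equal(unname(coef(lm(x ~ seq_along(x)))[2]), 0.0015,
               tolerance = 1e-10)
  expect_lt(sd(x), 0.06)
  expect_true(check_convergence(x, crit))
  ## steep improvement does not count as converged (|slope| rule)
  expect_false(check_convergence(0.4 - 0.01 * (1:25), crit))
  ## short history: flagged false
  r <- check_convergence(rep(0.5, 10), crit)
  expect_false(r)
  expect_equal(attr(r, "reason"), "insufficient generations")
})

test_that("convergence fires after a plateau, never during decline", {
  ## optimization-shaped history: rapid drop then plateau
  set.seed(2)
  means <- c(2 * exp(-(1:60) / 8), rep(0.25, 60)) + rnorm(120, sd = 0.01)
  crit <- convergence_criteria()
  fired <- vapply(25:120, function(g)
    isTRUE(check_convergence(means[1:g], crit)), logical(1))
  first <- (25:120)[which(fired)[1]]
  expect_gt(first, 40)            # never during the rapid decline
  ## once the window lies entirely on the plateau it always fires
  expect_true(all(fired[(25:120) >= 90]))
  pure_decline <- seq(3, by = -0.01, length.out = 200)
  expect_false(any(vapply(25:200, function(g)
    isTRUE(check_convergence(pure_decline[1:g], crit)), logical(1))))
})

test_that("select_best implements the 2.5% / last-50 rule", {
  h <- data.frame(fitness = runif(1600), generation = 1, evaluation = 1:1600)
  expect_equal(nrow(select_best(h)), 40L)
  h2 <- data.frame(fitness = runif(2400), generation = 1, evaluation = 1:2400)
  b2 <- select_best(h2)
  expect_equal(nrow(b2), 50L)
  expect_equal(b2$fitness, sort(h2$fitness)[1:50])
  h3 <- data.frame(fitness = runif(10), generation = 1, evaluation = 1:10)
  expect_equal(nrow(select_best(h3)), 1L)
  ## boundary: exactly 2000 evaluations is still the 2.5% branch
  h4 <- data.frame(fitness = runif(2000), generation = 1, evaluation = 1:2000)
  expect_equal(nrow(select_best(h4)), 50L)
  h5 <- data.frame(fitness = runif(2001), generation = 1, evaluation = 1:2001)
  expect_equal(nrow(select_best(h5)), 50L)
})

test_that("evaluate_population caches duplicates and persists first", {
  problem <- small_problem()
  cand <- rbind(c(RM = 0.8, CM = 0.01), c(RM = 0.8, CM = 0.01),
                c(RM = 1.2, CM = 0.02))
  store <- tempfile("store")
  cache <- new.env()
  res <- evaluate_population(cand, problem, store = store, cache = cache)
  ## duplicate candidate: one simulation, two identical reports
  expect_length(list.dirs(store, recursive = FALSE), 2L)
  expect_identical(res[[1]]$total, res[[2]]$total)
  expect_true(file.exists(file.path(store, "eval_000001", "params.yaml")))
  expect_true(file.exists(file.path(store, "eval_000001", "fitness.yaml")))
  ## second call: all served from cache, nothing new persisted
  res2 <- evaluate_population(cand, problem, store = store, cache = cache)
  expect_true(all(vapply(res2, `[[`, logical(1), "cached")))
  expect_length(list.dirs(store, recursive = FALSE), 2L)
  expect_equal(res2[[3]]$total, res[[3]]$total)
})

test_that("serial and parallel evaluation give identical reports", {
  problem <- small_problem()
  set.seed(5)
  cand <- cbind(RM = runif(4, 0.3, 2), CM = runif(4, 0.005, 0.03))
  r1 <- evaluate_population(cand, problem, cores = 1L)
  r2 <- evaluate_population(cand, problem, cores = 2L)
  expect_identical(vapply(r1, `[[`, numeric(1), "total"),
                   vapply(r2, `[[`, numeric(1), "total"))
})

test_that("an evaluation failure yields +Inf and the run continues", {
  problem <- small_problem()
  ## out-of-bounds candidate triggers the failure path
  cand <- rbind(c(RM = 0.8, CM = 0.01), c(RM = 100, CM = 0.01))
  res <- evaluate_population(cand, problem)
  expect_true(is.finite(res[[1]]$total))
  expect_identical(res[[2]]$total, Inf)
  expect_match(res[[2]]$note, "failure")
})

test_that("do_fit performs generations x popsize evaluations and persists", {
  problem <- small_problem()
  dir <- tempfile("fit")
  h <- do_fit(problem, generations = 2, popsize = 8, seed = 3, dir = dir)
  expect_equal(nrow(h), 16L)
  expect_equal(attr(h, "mean_fitness"),
               tapply(h$fitness, h$generation, mean),
               ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "history.csv")))
  h2 <- read_fit_history(dir)
  expect_equal(h2$fitness, h$fitness, tolerance = 1e-12)
  ## deterministic: same seed reproduces the identical history
  h3 <- do_fit(problem, generations = 2, popsize = 8, seed = 3,
               dir = tempfile("fit"))
  expect_identical(h3$RM, h$RM)
  expect_identical(h3$CM, h$CM)
  expect_equal(h3$fitness, h$fitness, tolerance = 1e-12)
  ## best-so-far series is monotone non-increasing
  expect_true(all(diff(attr(h, "best_so_far")) <= 0))
})

test_that("a resumed run reuses persisted evaluations", {
  problem <- small_problem()
  dir <- tempfile("fit")
  h <- do_fit(problem, generations = 2, popsize = 8, seed = 3, dir = dir)
  n_before <- length(list.dirs(dir, recursive = FALSE))
  ## same seed, resumed: generation 1-2 candidates are cache hits
  h2 <- do_fit(problem, generations = 3, popsize = 8, seed = 3, dir = dir,
               resume = TRUE)
  expect_true(any(h2$cached[h2$generation <= 2]))
  expect_equal(h2$fitness[1:16], h$fitness, tolerance = 1e-9)
})

test_that("fitting a model to itself approaches zero fitness", {
  problem <- small_problem()
  truth <- c(RM = 1, CM = 0.01)
  res <- evaluate_population(rbind(truth), problem)
  expect_lt(res[[1]]$total, 1e-12)
})
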