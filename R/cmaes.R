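## Bounded covariance-matrix-adaptation evolution strategy with the
## ask/tell/stop interface. Parameters are affinely scaled to [0,1] by
## their bounds; candidates outside the box are repaired by projection and
## the squared repair distance is added to the fitness as a penalty when
## ranking. Strategy constants follow the standard published defaults.

## evaluate expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## per-generation sampling seed; deterministic in (seed, generation)
.cma_gen_seed <- function(seed, gen) {
  (as.integer(seed) + 10007L * (as.integer(gen) %% 100000L)) %% 2147483647L
}

#' Initialize a CMA-ES optimizer state
#'
#' @param x0 initial parameter vector (original units), strictly inside
#'   the bounds.
#' @param lower,upper per-dimension bounds (original units).
#' @param sigma0 initial step size in the \[0,1\]-scaled space.
#' @param popsize population size lambda (>= 4); default 8.
#' @param seed integer seed; sampling is deterministic in (seed,
#'   generation).
#' @param max_evals evaluation budget for [cma_stop()].
#' @return environment of class `cma_state`.
#' @export
cma_init <- function(x0, lower, upper, sigma0 = 0.3, popsize = 8L,
                     seed = 1L, max_evals = Inf) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(lower < upper))
  if (any(x0 < lower | x0 > upper))
    stop("cma_init: x0 must lie within the bounds")
  if (popsize < 4L) stop("cma_init: popsize must be >= 4")
  if (sigma0 <= 0) stop("cma_init: sigma0 must be > 0")
  lambda <- as.integer(popsize)
  mu <- lambda %/% 2L
  ## full standard weight scheme with negative ("active") weights for the
  ## worse half of the population, following the published defaults
  wp <- log((lambda + 1) / 2) - log(seq_len(lambda))
  mueff <- sum(wp[1:mu])^2 / sum(wp[1:mu]^2)
  mueff_neg <- sum(wp[(mu + 1):lambda])^2 / sum(wp[(mu + 1):lambda]^2)
  st <- new.env(parent = emptyenv())
  st$n <- n; st$lambda <- lambda; st$mu <- mu; st$mueff <- mueff
  st$cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  st$cs <- (mueff + 2) / (n + mueff + 5)
  st$c1 <- 2 / ((n + 1.3)^2 + mueff)
  st$cmu <- min(1 - st$c1,
                2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  amu_neg <- 1 + st$c1 / st$cmu
  amueff_neg <- 1 + 2 * mueff_neg / (mueff + 2)
  apd_neg <- (1 - st$c1 - st$cmu) / (n * st$cmu)
  w <- wp
  w[1:mu] <- wp[1:mu] / sum(wp[1:mu])
  w[(mu + 1):lambda] <- min(amu_neg, amueff_neg, apd_neg) *
    wp[(mu + 1):lambda] / abs(sum(wp[(mu + 1):lambda]))
  st$w <- w
  st$ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + st$cs
  st$chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  st$lower <- lower; st$upper <- upper
  st$m <- (x0 - lower) / (upper - lower)
  st$sigma <- sigma0
  st$C <- diag(n); st$B <- diag(n); st$D <- rep(1, n)
  st$pc <- numeric(n); st$ps <- numeric(n)
  st$gen <- 0L; st$evals <- 0L
  st$seed <- as.integer(seed); st$max_evals <- max_evals
  st$names <- names(x0)
  st$best_fit <- Inf; st$best_x <- x0
  class(st) <- "cma_state"
  st
}

#' Sample a population of candidates
#'
#' Deterministic in the state's (seed, generation): calling `cma_ask()`
#' twice on the same state yields the identical candidate set. Candidates
#' are repaired into the bounds by projection; the squared scaled repair
#' distance is recorded and added to the fitness during ranking in
#' [cma_tell()].
#'
#' @param st a `cma_state`.
#' @return lambda x n matrix of candidates in original units, with a
#'   `"penalty"` attribute (scaled squared repair distances).
#' @export
cma_ask <- function(st) {
  stopifnot(inherits(st, "cma_state"))
  if (max(st$D) / min(st$D) > 1e7) {
    warning("cma_ask: near-degenerate covariance; eigenvalue floor applied")
  }
  z <- .with_seed(.cma_gen_seed(st$seed, st$gen),
                  matrix(rnorm(st$n * st$lambda), st$n, st$lambda))
  ## sample through the symmetric square root C^{1/2} = B diag(D) B^T;
  ## unlike B diag(D) z this is a unique, well-conditioned function of C,
  ## so trajectories are reproducible across implementations
  y <- st$B %*% (st$D * t(st$B)) %*% z
  xs <- st$m + st$sigma * y            # scaled-space candidates
  xr <- pmin(pmax(xs, 0), 1)           # projection repair
  penalty <- colSums((xs - xr)^2)
  x <- t(st$lower + xr * (st$upper - st$lower))
  colnames(x) <- st$names
  st$last_ask <- list(y = y, xr = xr, penalty = penalty, gen = st$gen)
  attr(x, "penalty") <- penalty
  x
}

#' Update the search distribution from ranked fitnesses
#'
#' Standard rank-mu recombination of the best mu = floor(lambda/2)
#' candidates with log-decreasing weights, cumulative step-size adaptation,
#' and the rank-one plus rank-mu covariance update. Only the ranking of the
#' fitnesses is used; ties are broken by candidate index (stable order) and
#' non-finite fitnesses are assigned the worst ranks with a warning.
#'
#' @param st a `cma_state`.
#' @param candidates the matrix returned by the matching [cma_ask()] call.
#' @param fitnesses numeric vector of length lambda (lower is better).
#' @return the state, invisibly (updated in place).
#' @export
cma_tell <- function(st, candidates, fitnesses) {
  stopifnot(inherits(st, "cma_state"),
            nrow(candidates) == st$lambda,
            length(fitnesses) == st$lambda)
  if (is.null(st$last_ask) || st$last_ask$gen != st$gen)
    stop("cma_tell: no matching cma_ask() for this generation")
  if (any(!is.finite(fitnesses))) {
    warning("cma_tell: non-finite fitness; assigned worst rank")
    fitnesses[!is.finite(fitnesses)] <- Inf
  }
  fp <- fitnesses + st$last_ask$penalty
  ord <- order(fp, seq_along(fp))
  idx <- ord[seq_len(st$mu)]
  ibest <- ord[1]
  if (is.finite(fitnesses[ibest]) && fitnesses[ibest] < st$best_fit) {
    st$best_fit <- fitnesses[ibest]
    st$best_x <- candidates[ibest, ]
  }
  y <- st$last_ask$y
  wpos <- st$w[seq_len(st$mu)]
  yw <- as.numeric(y[, idx, drop = FALSE] %*% wpos)
  st$m <- pmin(pmax(st$m + st$sigma * yw, 0), 1)
  Cinvsqrt <- st$B %*% ((1 / st$D) * t(st$B))
  st$ps <- (1 - st$cs) * st$ps +
    sqrt(st$cs * (2 - st$cs) * st$mueff) * as.numeric(Cinvsqrt %*% yw)
  hsig <- sqrt(sum(st$ps^2)) /
    sqrt(1 - (1 - st$cs)^(2 * (st$gen + 1))) / st$chiN <
    1.4 + 2 / (st$n + 1)
  st$pc <- (1 - st$cc) * st$pc +
    (if (hsig) sqrt(st$cc * (2 - st$cc) * st$mueff) else 0) * yw
  ## rank-mu update over the whole ranked population; negative weights are
  ## rescaled by n/||C^{-1/2} y||^2 so C stays positive definite
  yall <- y[, ord, drop = FALSE]
  wo <- st$w
  neg <- wo < 0
  if (any(neg)) {
    ynorm <- colSums((Cinvsqrt %*% yall[, neg, drop = FALSE])^2)
    wo[neg] <- wo[neg] * st$n / pmax(ynorm, 1e-12)
  }
  delta_hsig <- if (hsig) 0 else st$cc * (2 - st$cc)
  st$C <- (1 + st$c1 * delta_hsig - st$c1 - st$cmu * sum(st$w)) * st$C +
    st$c1 * tcrossprod(st$pc) +
    st$cmu * yall %*% (wo * t(yall))
  st$sigma <- st$sigma *
    exp((st$cs / st$ds) * (sqrt(sum(st$ps^2)) / st$chiN - 1))
  st$C <- (st$C + t(st$C)) / 2
  e <- eigen(st$C, symmetric = TRUE)
  st$D <- sqrt(pmax(e$values, 1e-30))
  st$B <- e$vectors
  st$gen <- st$gen + 1L
  st$evals <- st$evals + st$lambda
  st$last_ask <- NULL
  invisible(st)
}

#' Stop conditions of a CMA-ES state
#'
#' @param st a `cma_state`.
#' @return character vector of active stop reasons (empty when none):
#'   `"max_evals"` (budget exhausted), `"condition"` (condition number of C
#'   above 1e14), `"sigma"` (sigma times the largest axis below 1e-12).
#' @export
cma_stop <- function(st) {
  stopifnot(inherits(st, "cma_state"))
  reasons <- character(0)
  if (st$evals >= st$max_evals) reasons <- c(reasons, "max_evals")
  if ((max(st$D) / min(st$D))^2 > 1e14) reasons <- c(reasons, "condition")
  if (st$sigma * max(st$D) < 1e-12) reasons <- c(reasons, "sigma")
  reasons
}

#' @export
print.cma_state <- function(x, ...) {
  cat(sprintf("cma_state: n=%d lambda=%d gen=%d evals=%d sigma=%.3g best=%.4g\n",
              x$n, x$lambda, x$gen, x$evals, x$sigma, x$best_fit))
  invisible(x)
}
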