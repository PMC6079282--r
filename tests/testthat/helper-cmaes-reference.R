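## Independent reference implementation of standard CMA-ES with the full
## published default weight scheme (negative "active" weights for the
## worse half), transcribed from the update equations in plain
## scalar/loop style. Used only as an oracle for trajectory equivalence;
## shares nothing with the package implementation except the sampling
## contract (per-generation seed = seed + 10007 * generation, z ~ N(0, I)
## drawn column-wise, y = C^{1/2} z through the symmetric square root).

ref_cma_run <- function(fn, x0, lower, upper, sigma0, lambda, seed,
                        generations) {
  n <- length(x0)
  mu <- floor(lambda / 2)
  wp <- numeric(lambda)
  for (i in 1:lambda) wp[i] <- log((lambda + 1) / 2) - log(i)
  spos <- sum(wp[1:mu]); sneg <- sum(wp[(mu + 1):lambda])
  mueff <- spos^2 / sum(wp[1:mu]^2)
  mueff_neg <- sneg^2 / sum(wp[(mu + 1):lambda]^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  alpha <- min(1 + c1 / cmu, 1 + 2 * mueff_neg / (mueff + 2),
               (1 - c1 - cmu) / (n * cmu))
  w <- wp
  for (i in 1:mu) w[i] <- wp[i] / spos
  for (i in (mu + 1):lambda) w[i] <- alpha * wp[i] / abs(sneg)
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  m <- (x0 - lower) / (upper - lower)
  sigma <- sigma0
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  pc <- numeric(n); ps <- numeric(n)
  traj <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  matmul <- function(A, v) {
    out <- numeric(nrow(A))
    for (i in seq_len(nrow(A))) {
      acc <- 0
      for (j in seq_len(ncol(A))) acc <- acc + A[i, j] * v[j]
      out[i] <- acc
    }
    out
  }
  for (gen in 0:(generations - 1)) {
    set.seed((seed + 10007L * gen) %% 2147483647L)
    z <- matrix(rnorm(n * lambda), n, lambda)
    ## symmetric square root C^{1/2} = B diag(D) B^T, elementwise
    sqrtC <- matrix(0, n, n)
    invsqrtC <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      a <- 0; b <- 0
      for (l in 1:n) {
        a <- a + B[i, l] * D[l] * B[j, l]
        b <- b + B[i, l] / D[l] * B[j, l]
      }
      sqrtC[i, j] <- a
      invsqrtC[i, j] <- b
    }
    y <- matrix(0, n, lambda)
    fit <- numeric(lambda)
    for (k in 1:lambda) {
      y[, k] <- matmul(sqrtC, z[, k])
      xs <- m + sigma * y[, k]
      xr <- pmin(pmax(xs, 0), 1)
      fit[k] <- fn(lower + xr * (upper - lower)) + sum((xs - xr)^2)
    }
    ord <- order(fit, 1:lambda)
    yw <- numeric(n)
    for (i in 1:mu) yw <- yw + w[i] * y[, ord[i]]
    m <- pmin(pmax(m + sigma * yw, 0), 1)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * matmul(invsqrtC, yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * (gen + 1))) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc +
      (if (hsig) sqrt(cc * (2 - cc) * mueff) else 0) * yw
    wo <- w
    for (k in 1:lambda) {
      if (w[k] < 0) {
        v <- matmul(invsqrtC, y[, ord[k]])
        wo[k] <- w[k] * n / max(sum(v^2), 1e-12)
      }
    }
    delta_hsig <- if (hsig) 0 else cc * (2 - cc)
    Cnew <- (1 + c1 * delta_hsig - c1 - cmu * sum(w)) * C
    for (i in 1:n) for (j in 1:n) {
      Cnew[i, j] <- Cnew[i, j] + c1 * pc[i] * pc[j]
      for (k in 1:lambda)
        Cnew[i, j] <- Cnew[i, j] + cmu * wo[k] * y[i, ord[k]] * y[j, ord[k]]
    }
    C <- (Cnew + t(Cnew)) / 2
    sigma <- sigma * exp((cs / ds) * (sqrt(sum(ps^2)) / chiN - 1))
    e <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(e$values, 1e-30))
    B <- e$vectors
    traj[[gen + 1]] <- list(m = m, sigma = sigma, C = C)
  }
  traj
}
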