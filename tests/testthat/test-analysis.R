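## two-subtype synthetic parameter sets: `shift` standard deviations of
## separation on one informative column plus pure-noise columns
two_subtype_matrix <- function(n_per = 25, p_noise = 5, shift = 6,
                               seed = 1) {
  set.seed(seed)
  X <- cbind(informative = c(rnorm(n_per, 0), rnorm(n_per, shift)),
             matrix(rnorm(2 * n_per * p_noise), ncol = p_noise,
                    dimnames = list(NULL, paste0("noise", 1:p_noise))))
  list(X = X, labels = rep(c("A", "B"), each = n_per))
}

test_that("standardize gives zero-mean unit-sd columns and is idempotent", {
  expect_equal(as.numeric(standardize(cbind(x = 1:3))), c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(15, mean = 5, sd = 3), 5, 3)
  Z <- standardize(X)
  expect_equal(colMeans(Z), rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(Z, 2, sd), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## direct formula oracle
  expect_equal(Z[, 2], (X[, 2] - mean(X[, 2])) / sd(X[, 2]),
               ignore_attr = TRUE)
  expect_equal(standardize(Z), Z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize(cbind(a = 1:3, b = rep(2, 3))), "constant.*b")
})

test_that("correlation_matrix matches textbook r and p", {
  x <- c(1, 2, 3, 4, 5, 6.5, 7, 8.2, 9, 10)
  set.seed(4)
  y <- 0.8 * x + rnorm(10, sd = 0.8)
  z <- rnorm(10)
  cm <- correlation_matrix(cbind(x = x, y = y, z = z))
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  ct <- cor.test(x, y)
  expect_equal(cm$r["x", "y"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["x", "y"], ct$p.value, tolerance = 1e-12)
  ## exact linear relations
  expect_equal(correlation_matrix(cbind(a = x, b = 2 * x))$r["a", "b"], 1)
  expect_equal(correlation_matrix(cbind(a = x, b = -x))$r["a", "b"], -1)
})

test_that("correlations are invariant under affine column rescaling", {
  set.seed(8)
  X <- matrix(rnorm(40), 10, 4)
  Y <- sweep(sweep(X, 2, c(2, -3, 0.5, 10), "*"), 2, c(1, -4, 0, 2), "+")
  expect_equal(abs(correlation_matrix(Y)$r), abs(correlation_matrix(X)$r),
               tolerance = 1e-12)
})

test_that("stepwise selection finds the separating column", {
  ## at a strict entry threshold the noise columns essentially never
  ## enter, so the informative column is selected alone
  hits <- 0L
  for (s in 1:100) {
    d <- two_subtype_matrix(seed = s)
    sel <- stepwise_discriminant(standardize(d$X), d$labels,
                                 enter_p = 0.001, stay_p = 0.001)
    if (identical(as.character(sel), "informative")) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  ## at the SAS default thresholds the informative column is always
  ## among the selection
  for (s in 1:10) {
    d <- two_subtype_matrix(seed = s)
    sel <- stepwise_discriminant(standardize(d$X), d$labels)
    expect_true("informative" %in% sel)
  }
})

test_that("stepwise selection returns empty on identical distributions", {
  empty <- 0L
  for (s in 1:50) {
    set.seed(s + 500)
    X <- matrix(rnorm(40 * 4), 40, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
    sel <- stepwise_discriminant(standardize(X),
                                 rep(c("A", "B"), each = 20),
                                 enter_p = 0.01, stay_p = 0.01)
    if (length(sel) == 0L) empty <- empty + 1L
  }
  expect_gte(empty, 40L)  # ~4% of null datasets admit a spurious column
})

test_that("choose_k recovers three well-separated clusters", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    Z <- rbind(matrix(rnorm(30, 0, 0.3), ncol = 2),
               matrix(rnorm(30, 5, 0.3), ncol = 2),
               cbind(rnorm(15, 0, 0.3), rnorm(15, 5, 0.3)))
    if (choose_k(standardize(Z), kmax = 6) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  ## two identical points per group, two groups -> k = 2
  Z2 <- rbind(c(0, 0), c(0, 0), c(4, 4), c(4, 4))
  expect_equal(as.integer(choose_k(Z2, kmax = 3)), 2L)
})

test_that("disjoint clustering separates two blobs perfectly", {
  set.seed(10)
  Z <- rbind(matrix(rnorm(40, 0, 0.4), ncol = 2),
             matrix(rnorm(40, 6, 0.4), ncol = 2))
  labels <- rep(c("A", "B"), each = 20)
  cl <- disjoint_cluster(standardize(Z), 2, labels = labels, seed = 1)
  conf <- cl$confusion
  ## zero off-diagonal confusion up to cluster relabeling
  expect_equal(sort(apply(conf, 1, max)), sort(rowSums(conf)))
  expect_equal(dim(cl$centroid_dist), c(2L, 2L))
  expect_gt(cl$centroid_dist[1, 2], 0)
})

test_that("small-instance clustering attains the exhaustive optimum", {
  for (s in 1:5) {
    set.seed(s + 40)
    n <- sample(6:8, 1)
    k <- sample(2:3, 1)
    Z <- matrix(rnorm(2 * n), n, 2)
    got <- disjoint_cluster(Z, k, seed = s)$wss
    ## brute force over all k^n labelings (with >= 1 point per cluster)
    best <- Inf
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    for (r in seq_len(nrow(grid))) {
      a <- grid[r, ]
      if (length(unique(a)) < k) next
      wss <- 0
      for (g in unique(a)) {
        Zg <- Z[a == g, , drop = FALSE]
        wss <- wss + sum(scale(Zg, scale = FALSE)^2)
      }
      best <- min(best, wss)
    }
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("the full chain recovers the shifted conductance and subtypes", {
  ok_sel <- 0L; acc <- numeric(0)
  for (s in 1:20) {
    d <- two_subtype_matrix(n_per = 25, p_noise = 4, shift = 5, seed = s)
    res <- analyze_subtypes(d$X, d$labels, seed = s)
    if ("informative" %in% res$selected) ok_sel <- ok_sel + 1L
    conf <- res$clusters$confusion
    acc <- c(acc, sum(apply(conf, 1, max)) / sum(conf))
  }
  expect_equal(ok_sel, 20L)
  expect_true(all(acc >= 0.9))
})
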