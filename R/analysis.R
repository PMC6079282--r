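## Post-hoc statistics on best-model parameter sets: standardization,
## correlations, stepwise linear discriminant variable selection, and
## hierarchical + disjoint (k-means) cluster analysis with confusion
## matrices.

#' Extract the parameter matrix of selected best models
#'
#' @param best output of [select_best()] (rows of a `fit_history`).
#' @param label subtype/recording label attached to every row.
#' @return numeric matrix (models x parameters) with a `labels` attribute.
#' @export
param_matrix <- function(best, label) {
  drop_cols <- c("generation", "evaluation", "fitness", "cached")
  m <- as.matrix(best[, setdiff(colnames(best), drop_cols), drop = FALSE])
  attr(m, "labels") <- rep_len(label, nrow(m))
  m
}

#' Z-score each column of a matrix
#'
#' @param X numeric matrix or data frame (>= 2 rows).
#' @return matrix with column means 0 and standard deviations 1.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("standardize: need at least 2 rows")
  s <- apply(X, 2L, sd)
  if (any(s == 0))
    stop("standardize: constant column: ",
         paste(colnames(X)[s == 0], collapse = ", "))
  scale(X, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Pairwise Pearson correlations with two-sided p-values
#'
#' @param X numeric matrix (>= 3 rows).
#' @return list with `r` (correlation matrix) and `p` (two-sided p-values
#'   from the t distribution with n-2 degrees of freedom). Zero-variance
#'   columns are flagged with a warning and yield `NA` entries.
#' @export
correlation_matrix <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("correlation_matrix: need at least 3 rows")
  s <- apply(X, 2L, sd)
  if (any(s == 0))
    warning("correlation_matrix: zero-variance column: ",
            paste(colnames(X)[s == 0], collapse = ", "))
  r <- suppressWarnings(cor(X))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p)
}

## Wilks' lambda of a column subset for a two-class (or g-class) labeling
.wilks_lambda <- function(Z, labels, cols) {
  if (!length(cols)) return(1)
  Zs <- Z[, cols, drop = FALSE]
  tot <- crossprod(scale(Zs, center = TRUE, scale = FALSE))
  within <- matrix(0, length(cols), length(cols))
  for (g in unique(labels)) {
    Zg <- Zs[labels == g, , drop = FALSE]
    within <- within + crossprod(scale(Zg, center = TRUE, scale = FALSE))
  }
  dw <- det(within); dtot <- det(tot)
  if (dtot <= 0) return(NA_real_)
  dw / dtot
}

#' Stepwise discriminant variable selection
#'
#' Greedy forward selection by largest partial F (equivalently, greatest
#' reduction of Wilks' lambda) with entry p-value below `enter_p`, followed
#' by backward removal of variables whose partial p-value exceeds
#' `stay_p`, iterated until no change. Ties are broken by column order.
#' Columns with singular within-class scatter are dropped with a warning.
#'
#' @param Z standardized matrix (use [standardize()]).
#' @param labels class labels, two classes with at least 2 rows each.
#' @param enter_p,stay_p significance thresholds (SAS STEPDISC defaults
#'   0.15).
#' @return character vector (or column indices when unnamed) of selected
#'   columns, in order of entry; attribute `"steps"` records the partial F
#'   and p of each action.
#' @export
stepwise_discriminant <- function(Z, labels, enter_p = 0.15,
                                  stay_p = 0.15) {
  Z <- as.matrix(Z)
  labels <- as.factor(labels)
  g <- nlevels(droplevels(labels))
  if (g < 2L) stop("stepwise_discriminant: need at least two classes")
  if (any(table(labels) < 2L))
    stop("stepwise_discriminant: every class needs >= 2 rows")
  n <- nrow(Z)
  cols <- colnames(Z)
  if (is.null(cols)) cols <- as.character(seq_len(ncol(Z)))
  colnames(Z) <- cols
  usable <- cols
  selected <- character(0)
  steps <- list()
  partial <- function(lam_small, lam_big, p_small) {
    ## F for the variable distinguishing models of size p_small and
    ## p_small + 1; df1 = g - 1, df2 = n - g - p_small
    df2 <- n - g - p_small
    if (df2 < 1L || !is.finite(lam_big) || lam_big <= 0)
      return(c(F = NA_real_, p = NA_real_))
    Fv <- (df2 / (g - 1)) * (lam_small / lam_big - 1)
    c(F = Fv, p = pf(Fv, g - 1, df2, lower.tail = FALSE))
  }
  repeat {
    changed <- FALSE
    ## forward step
    cand <- setdiff(usable, selected)
    if (length(cand)) {
      lam0 <- .wilks_lambda(Z, labels, selected)
      stats <- vapply(cand, function(v) {
        lam1 <- .wilks_lambda(Z, labels, c(selected, v))
        if (is.na(lam1)) return(c(F = NA_real_, p = NA_real_))
        partial(lam0, lam1, length(selected))
      }, numeric(2))
      bad <- is.na(stats["F", ])
      if (any(bad)) {
        warning("stepwise_discriminant: singular scatter; dropping ",
                paste(cand[bad], collapse = ", "))
        usable <- setdiff(usable, cand[bad])
        cand <- cand[!bad]
        stats <- stats[, !bad, drop = FALSE]
      }
      if (length(cand)) {
        ib <- which.max(stats["F", ])
        if (is.finite(stats["p", ib]) && stats["p", ib] < enter_p) {
          selected <- c(selected, cand[ib])
          steps[[length(steps) + 1L]] <-
            data.frame(action = "enter", variable = cand[ib],
                       F = stats["F", ib], p = stats["p", ib])
          changed <- TRUE
        }
      }
    }
    ## backward step
    if (length(selected) > 1L) {
      lam_full <- .wilks_lambda(Z, labels, selected)
      stats <- vapply(selected, function(v) {
        lam_red <- .wilks_lambda(Z, labels, setdiff(selected, v))
        partial(lam_red, lam_full, length(selected) - 1L)
      }, numeric(2))
      iw <- which.min(replace(stats["F", ], is.na(stats["F", ]), Inf))
      if (is.finite(stats["p", iw]) && stats["p", iw] > stay_p) {
        steps[[length(steps) + 1L]] <-
          data.frame(action = "remove", variable = selected[iw],
                     F = stats["F", iw], p = stats["p", iw])
        selected <- setdiff(selected, selected[iw])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(selected, steps = if (length(steps)) do.call(rbind, steps))
}

## within-cluster sum of squares of an assignment
.cluster_wss <- function(Z, assign) {
  wss <- 0
  for (k in unique(assign)) {
    Zk <- Z[assign == k, , drop = FALSE]
    wss <- wss + sum(scale(Zk, center = TRUE, scale = FALSE)^2)
  }
  wss
}

#' Choose the number of clusters by Ward hierarchy and pseudo-F
#'
#' Ward-linkage hierarchical clustering is cut at k = 2..kmax and each
#' partition is scored by the Calinski-Harabasz pseudo-F; the k with the
#' largest pseudo-F is returned.
#'
#' @param Z standardized matrix.
#' @param kmax maximum number of clusters considered.
#' @return the chosen k, with attribute `"pseudo_F"` (named vector over
#'   k).
#' @export
choose_k <- function(Z, kmax = 6L) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < kmax) stop("choose_k: need at least kmax rows")
  hc <- hclust(dist(Z), method = "ward.D2")
  tot <- sum(scale(Z, center = TRUE, scale = FALSE)^2)
  ks <- 2:kmax
  pf_vals <- vapply(ks, function(k) {
    a <- cutree(hc, k)
    w <- .cluster_wss(Z, a)
    ((tot - w) / (k - 1)) / (w / (n - k))
  }, numeric(1))
  names(pf_vals) <- ks
  structure(ks[which.max(pf_vals)], pseudo_F = pf_vals)
}

## deterministic k-means++ initial centers
.kmeanspp_centers <- function(Z, k, seed) {
  .with_seed(seed, {
    n <- nrow(Z)
    centers <- integer(k)
    centers[1] <- sample.int(n, 1L)
    d2 <- rowSums((Z - matrix(Z[centers[1], ], n, ncol(Z),
                              byrow = TRUE))^2)
    for (j in seq_len(k - 1L) + 1L) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1L, prob = prob)
      d2j <- rowSums((Z - matrix(Z[centers[j], ], n, ncol(Z),
                                 byrow = TRUE))^2)
      d2 <- pmin(d2, d2j)
    }
    Z[centers, , drop = FALSE]
  })
}

#' Disjoint (k-means) cluster analysis
#'
#' Deterministic k-means: `nstart` k-means++ seedings derived from `seed`,
#' Lloyd iterations to an assignment fixed point, keeping the partition
#' with the lowest within-cluster sum of squares. An empty cluster is
#' re-seeded once before failing.
#'
#' @param Z standardized matrix.
#' @param k number of clusters.
#' @param labels optional subtype labels for the confusion matrix.
#' @param seed integer seed for the deterministic seeding.
#' @param nstart number of k-means++ restarts.
#' @return list with `assignments`, `centers`, `centroid_dist` (pairwise
#'   Euclidean distances between centroids), `wss`, and (when labels are
#'   given) `confusion` (cluster x subtype counts).
#' @export
disjoint_cluster <- function(Z, k, labels = NULL, seed = 1L,
                             nstart = 10L) {
  Z <- as.matrix(Z)
  if (k > nrow(Z)) stop("disjoint_cluster: k exceeds number of rows")
  best <- NULL
  for (s in seq_len(nstart)) {
    init <- .kmeanspp_centers(Z, k, seed + 7L * s)
    km <- tryCatch(
      kmeans(Z, centers = init, iter.max = 200L, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km)) { # empty cluster: re-seed once
      km <- tryCatch(
        kmeans(Z, centers = .kmeanspp_centers(Z, k, seed + 7L * s + 1L),
               iter.max = 200L, algorithm = "Lloyd"),
        error = function(e)
          stop("disjoint_cluster: empty cluster after re-seeding"),
        warning = function(w)
          stop("disjoint_cluster: empty cluster after re-seeding"))
    }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  out <- list(assignments = best$cluster, centers = best$centers,
              centroid_dist = as.matrix(dist(best$centers)),
              wss = best$tot.withinss)
  if (!is.null(labels)) out$confusion <- table(cluster = best$cluster,
                                               subtype = labels)
  out
}

#' Full subtype-discrimination chain
#'
#' Standardize, select discriminating parameters by stepwise discriminant
#' analysis, choose the cluster count on the selected columns, and run the
#' disjoint cluster analysis.
#'
#' @param X models x parameters matrix.
#' @param labels subtype labels per row.
#' @param enter_p,stay_p stepwise thresholds.
#' @param kmax maximum cluster count.
#' @param seed clustering seed.
#' @return list with `selected`, `k`, and the [disjoint_cluster()] result.
#' @export
analyze_subtypes <- function(X, labels, enter_p = 0.15, stay_p = 0.15,
                             kmax = 6L, seed = 1L) {
  Z <- standardize(X)
  sel <- stepwise_discriminant(Z, labels, enter_p, stay_p)
  if (!length(sel))
    return(list(selected = character(0), k = NA_integer_, clusters = NULL))
  Zs <- Z[, sel, drop = FALSE]
  k <- choose_k(Zs, kmax = min(kmax, nrow(Zs) - 1L))
  cl <- disjoint_cluster(Zs, as.integer(k), labels = labels, seed = seed)
  list(selected = as.character(sel), k = as.integer(k), clusters = cl)
}
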