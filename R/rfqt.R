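#' Fit a random forest of Q trees (RFQT)
#'
#' Draws `n_trees` bootstrap resamples of the training data (with
#' replacement, each of the full training size) and grows one Q tree per
#' resample with [grow_qtree()]. At every node only a random subset of
#' `ceiling(mtry_fraction * p)` covariates (at least one, drawn without
#' replacement) is considered, which de-correlates the trees. Per-tree
#' seeds are derived deterministically from `seed`, so a fit is fully
#' reproducible and independent of evaluation order.
#'
#' @param train an [mr_dataset].
#' @param control a [qtree_control()]; its `mtry_fraction` is overridden
#'   by the `mtry_fraction` argument.
#' @param n_trees forest size (number of bootstrap samples / trees).
#' @param mtry_fraction fraction of covariates considered per node;
#'   0.4 is the standard choice for this method.
#' @param bootstrap draw bootstrap resamples (`TRUE`); `FALSE` fits every
#'   tree on the full training data (no out-of-bag individuals; useful for
#'   degenerate single-tree checks).
#' @param seed integer master seed.
#'
#' @return An object of class `rfqt_forest`: list with `trees`,
#'   `bootstrap_ids` (per-tree resampled row indices, `NULL` rows when
#'   `bootstrap = FALSE`), `n_train`, `mtry_fraction`, `control`, `seed`.
#' @export
fit_rfqt <- function(train, control = qtree_control(), n_trees = 100L,
                     mtry_fraction = 0.4, bootstrap = TRUE, seed = NULL) {
  stopifnot(inherits(train, "mr_dataset"), n_trees >= 1L)
  control$mtry_fraction <- mtry_fraction
  n <- nobs(train)
  seeds <- .derive_seeds(seed, 2L * n_trees)
  trees <- vector("list", n_trees)
  boots <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    idx <- if (bootstrap) {
      .with_seed(seeds[2L * i - 1L], sample.int(n, n, replace = TRUE))
    } else {
      seq_len(n)
    }
    boots[[i]] <- if (bootstrap) idx else NULL
    trees[[i]] <- grow_qtree(train[idx], control, seed = seeds[2L * i])
  }
  structure(list(trees = trees, bootstrap_ids = boots, n_train = n,
                 mtry_fraction = mtry_fraction, control = control,
                 bootstrap = bootstrap, seed = seed),
            class = "rfqt_forest")
}

#' @export
print.rfqt_forest <- function(x, ...) {
  depths <- vapply(x$trees, function(t) max(t$nodes$depth), 0)
  cat(sprintf("RFQT forest: %d trees (depths %d-%d), fitted on %d individuals, mtry fraction %.2f\n",
              length(x$trees), min(depths), max(depths), x$n_train,
              x$mtry_fraction))
  invisible(x)
}

#' Predict individual causal effects from an RFQT forest
#'
#' The forest estimate for an individual is the unweighted mean of the
#' per-tree predictions of [predict.qtree()].
#'
#' @param object an `rfqt_forest`.
#' @param newdata an [mr_dataset] or covariate matrix/data frame.
#' @param ... unused.
#' @return Numeric vector of per-individual effect estimates.
#' @export
predict.rfqt_forest <- function(object, newdata, ...) {
  preds <- vapply(object$trees, predict, FUN.VALUE = numeric(
    if (inherits(newdata, "mr_dataset")) nobs(newdata) else nrow(newdata)
  ), newdata = newdata)
  if (is.null(dim(preds))) {
    return(mean(preds))
  }
  rowMeans(preds)
}

#' Out-of-bag predictions
#'
#' For each training individual, averages predictions only over trees
#' whose bootstrap resample did not include that individual. Individuals
#' that are in-bag for every tree (or when the forest was fitted without
#' bootstrap) receive `NA` and are counted in `n_never_oob`.
#'
#' @param forest an `rfqt_forest`.
#' @param train the [mr_dataset] the forest was fitted on.
#' @return A list with `oob` (per-individual OOB estimate, `NA` when never
#'   out-of-bag), `n_trees_oob` (per-individual count of trees for which
#'   the individual was out-of-bag) and `n_never_oob`.
#' @export
oob_predict <- function(forest, train) {
  stopifnot(inherits(forest, "rfqt_forest"), inherits(train, "mr_dataset"))
  n <- nobs(train)
  if (n != forest$n_train) {
    stop("train does not match the data the forest was fitted on",
         call. = FALSE)
  }
  sums <- numeric(n)
  counts <- integer(n)
  if (forest$bootstrap) {
    for (i in seq_along(forest$trees)) {
      oob_rows <- which(tabulate(forest$bootstrap_ids[[i]], n) == 0L)
      if (!length(oob_rows)) next
      p <- predict(forest$trees[[i]],
                   train$M[oob_rows, , drop = FALSE])
      sums[oob_rows] <- sums[oob_rows] + p
      counts[oob_rows] <- counts[oob_rows] + 1L
    }
  }
  oob <- ifelse(counts > 0L, sums / counts, NA_real_)
  list(oob = oob, n_trees_oob = counts, n_never_oob = sum(counts == 0L))
}

#' Permutation variable importance
#'
#' For each tree and each covariate, the covariate column is permuted
#' within the tree's out-of-bag rows and the OOB individuals are
#' re-predicted; the importance contribution is the mean squared shift in
#' predicted effects relative to the unpermuted OOB predictions. The
#' importance of a covariate is the average contribution across trees,
#' and covariates are ranked by decreasing importance. A covariate never
#' used for splitting has importance exactly zero.
#'
#' @param forest an `rfqt_forest` fitted with `bootstrap = TRUE`.
#' @param train the training [mr_dataset].
#' @param seed integer seed for the permutations.
#' @param permute permutation generator, called as `permute(k)` and
#'   expected to return a permutation of `1:k`; replace by `seq_len` to
#'   verify that a no-op permutation yields zero importance.
#'
#' @return A data frame of class `rfqt_vi` with columns `covariate`,
#'   `importance`, `rank`, sorted by rank.
#' @export
variable_importance <- function(forest, train, seed = NULL,
                                permute = sample.int) {
  stopifnot(inherits(forest, "rfqt_forest"))
  if (!forest$bootstrap) {
    stop("variable importance requires a forest fitted with bootstrap resampling",
         call. = FALSE)
  }
  n <- nobs(train)
  p <- ncol(train$M)
  D <- matrix(0, nrow = length(forest$trees), ncol = p)
  used_trees <- 0L
  .with_seed(seed, {
    for (i in seq_along(forest$trees)) {
      oob_rows <- which(tabulate(forest$bootstrap_ids[[i]], n) == 0L)
      if (length(oob_rows) < 1L) next
      used_trees <- used_trees + 1L
      tree <- forest$trees[[i]]
      M_oob <- train$M[oob_rows, , drop = FALSE]
      base <- predict(tree, M_oob)
      split_covs <- unique(tree$nodes$covariate[!tree$nodes$is_leaf])
      for (j in seq_len(p)) {
        # permuting a covariate the tree never splits on cannot change
        # routing; skip the re-prediction but keep the exact zero
        if (!(colnames(train$M)[j] %in% split_covs)) next
        Mp <- M_oob
        Mp[, j] <- Mp[permute(length(oob_rows)), j]
        D[i, j] <- mean((predict(tree, Mp) - base)^2)
      }
    }
  })
  if (used_trees == 0L) {
    stop("no tree has out-of-bag individuals", call. = FALSE)
  }
  importance <- colSums(D) / used_trees
  out <- data.frame(covariate = colnames(train$M), importance = importance)
  out$rank <- as.integer(rank(-out$importance, ties.method = "first"))
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("rfqt_vi", "data.frame")
  out
}

# Leaf table of one tree: sizes (with bootstrap multiplicity), estimates.
.tree_leaves <- function(tree) {
  tree$nodes[tree$nodes$is_leaf, c("n", "theta", "beta_x", "se_x",
                                   "beta_y", "se_y", "sigma_xy")]
}

#' Forest-level heterogeneity statistics S1 and S2
#'
#' `s1_statistic()` is the mean over trees of the size-weighted variance
#' of the leaf (stratum) MR estimates,
#' \deqn{S_1 = \frac{1}{N_B}\sum_i \sum_k \frac{n_{i,k}}{n}
#'   \left(\hat\theta_{i,k} - \sum_k \frac{n_{i,k}}{n}\hat\theta_{i,k}\right)^2,}
#' where leaf sizes count bootstrap multiplicity so that
#' \eqn{\sum_k n_{i,k} = n} for every tree.
#'
#' `s2_statistic()` is the mean over trees of the tree-level Cochran Q
#' computed from the leaf instrument-exposure and instrument-outcome
#' associations (see [q_statistic()]); it allows for the variability of
#' the instrument-exposure associations and is therefore more robust to
#' weak instruments in small leaves than `S1`.
#'
#' Both statistics are zero for a forest of single-leaf trees.
#'
#' @param forest an `rfqt_forest`.
#' @return Scalar statistic value.
#' @export
s1_statistic <- function(forest) {
  stopifnot(inherits(forest, "rfqt_forest"))
  per_tree <- vapply(forest$trees, function(tree) {
    lv <- .tree_leaves(tree)
    ok <- is.finite(lv$theta)
    w <- lv$n[ok] / sum(lv$n)
    th <- lv$theta[ok]
    wm <- sum(w * th)
    sum(w * (th - wm)^2)
  }, 0)
  mean(per_tree)
}

#' @rdname s1_statistic
#' @export
s2_statistic <- function(forest) {
  stopifnot(inherits(forest, "rfqt_forest"))
  per_tree <- vapply(forest$trees, function(tree) {
    lv <- .tree_leaves(tree)
    ok <- is.finite(lv$theta) & is.finite(lv$se_y) & lv$se_y > 0
    if (sum(ok) < 1L) return(0)
    lv <- lv[ok, , drop = FALSE]
    if (nrow(lv) == 1L) return(0)
    sxy <- ifelse(is.finite(lv$sigma_xy), lv$sigma_xy, 0)
    .profile_q(lv$beta_x, lv$se_x^2, lv$beta_y, lv$se_y^2, sxy)[[1L]]
  }, 0)
  mean(per_tree)
}

#' Permutation test of effect heterogeneity
#'
#' Tests the null hypothesis that none of the candidate covariates
#' modifies the causal effect, i.e. that the variability of the forest's
#' stratum-specific estimates is no more than expected by chance. The
#' observed S1 and S2 statistics are computed from a forest on the
#' training data; for each permutation one random row permutation is
#' applied jointly to the whole covariate block (instrument, exposure and
#' outcome stay in place, so covariate-covariate correlation is preserved
#' while all covariate links to Z, X and Y are broken), a fresh forest is
#' fitted, and the statistics are recorded. The empirical p-value is the
#' proportion of permuted datasets whose statistic is at least the
#' observed one.
#'
#' @param train an [mr_dataset].
#' @param control a [qtree_control()].
#' @param n_trees forest size for the observed statistic.
#' @param n_perm number of permutations.
#' @param perm_n_trees forest size used for each permuted refit; defaults
#'   to `n_trees`, but a smaller value trades a little null-distribution
#'   accuracy for a large saving in compute.
#' @param mtry_fraction fraction of covariates per node.
#' @param small_sample_correction report `(r + 1) / (n_perm + 1)` instead
#'   of the plain proportion `r / n_perm`, guaranteeing a positive
#'   p-value.
#' @param seed integer master seed.
#'
#' @return An object of class `rfqt_permtest`: list with `s1_observed`,
#'   `s2_observed`, `s1_null`, `s2_null`, `p1`, `p2`, `n_perm`.
#' @export
permutation_test <- function(train, control = qtree_control(),
                             n_trees = 100L, n_perm = 100L,
                             perm_n_trees = n_trees, mtry_fraction = 0.4,
                             small_sample_correction = FALSE, seed = NULL) {
  stopifnot(inherits(train, "mr_dataset"), n_perm >= 1L)
  seeds <- .derive_seeds(seed, 2L * n_perm + 1L)
  obs <- fit_rfqt(train, control, n_trees = n_trees,
                  mtry_fraction = mtry_fraction, seed = seeds[1L])
  s1_obs <- s1_statistic(obs)
  s2_obs <- s2_statistic(obs)
  s1_null <- numeric(n_perm)
  s2_null <- numeric(n_perm)
  n <- nobs(train)
  for (b in seq_len(n_perm)) {
    rowperm <- .with_seed(seeds[2L * b], sample.int(n))
    perm <- train
    perm$M <- train$M[rowperm, , drop = FALSE]
    f <- fit_rfqt(perm, control, n_trees = perm_n_trees,
                  mtry_fraction = mtry_fraction, seed = seeds[2L * b + 1L])
    s1_null[b] <- s1_statistic(f)
    s2_null[b] <- s2_statistic(f)
  }
  adj <- if (small_sample_correction) 1L else 0L
  structure(list(s1_observed = s1_obs, s2_observed = s2_obs,
                 s1_null = s1_null, s2_null = s2_null,
                 p1 = (sum(s1_null >= s1_obs) + adj) / (n_perm + adj),
                 p2 = (sum(s2_null >= s2_obs) + adj) / (n_perm + adj),
                 n_perm = n_perm),
            class = "rfqt_permtest")
}

#' @export
print.rfqt_permtest <- function(x, ...) {
  cat(sprintf("Permutation test of effect heterogeneity (%d permutations)\n",
              x$n_perm))
  cat(sprintf("  S1 = %.4g, p = %.4g\n", x$s1_observed, x$p1))
  cat(sprintf("  S2 = %.4g, p = %.4g\n", x$s2_observed, x$p2))
  invisible(x)
}

#' Serialize an RFQT forest to JSON
#'
#' @param forest an `rfqt_forest`.
#' @param path optional output path; `NULL` returns the JSON string.
#' @return `path` (invisibly) or a JSON string.
#' @export
rfqt_to_json <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "rfqt_forest"))
  obj <- list(n_train = forest$n_train,
              mtry_fraction = forest$mtry_fraction,
              bootstrap = forest$bootstrap,
              seed = forest$seed,
              control = unclass(forest$control),
              trees = lapply(forest$trees, function(t) {
                list(nodes = t$nodes, n_fit = t$n_fit,
                     theta_root = t$theta_root)
              }),
              bootstrap_ids = forest$bootstrap_ids)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}

#' @rdname rfqt_to_json
#' @param json a JSON string or file path produced by [rfqt_to_json()].
#' @export
rfqt_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  control <- .control_from_json(obj$control)
  trees <- lapply(obj$trees, function(t) {
    structure(list(nodes = .nodes_from_json(t$nodes), control = control,
                   n_fit = t$n_fit, theta_root = t$theta_root),
              class = "qtree")
  })
  boots <- obj$bootstrap_ids
  boots <- if (is.null(boots)) {
    vector("list", length(trees))
  } else {
    lapply(boots, function(v) if (is.null(v)) NULL else as.integer(unlist(v)))
  }
  structure(list(trees = trees, bootstrap_ids = boots,
                 n_train = obj$n_train, mtry_fraction = obj$mtry_fraction,
                 control = control, bootstrap = isTRUE(obj$bootstrap),
                 seed = obj$seed),
            class = "rfqt_forest")
}
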