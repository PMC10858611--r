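#' Hyperparameters for Q trees and forests
#'
#' @param q_threshold minimum heterogeneity (Cochran Q on 1 df) a split
#'   must achieve; the default 3.84 is the 95th percentile of the
#'   chi-squared distribution with one degree of freedom, so a node is
#'   only split when the two candidate child estimates differ more than
#'   expected by chance at the 5% level.
#' @param min_node_size smallest permitted child node. The default 1,000
#'   targets biobank-scale data where strata of this size still yield
#'   stable IV estimates; scale it down (e.g. 200) for smaller samples.
#' @param max_depth maximum node depth; nodes at this depth are not split
#'   further (the root has depth 0).
#' @param proportions candidate splitting proportions expressed as the
#'   lower-child fraction; the default `c(0.3, 0.5, 0.7)` corresponds to
#'   the 3:7, 5:5 and 7:3 child-size ratios. A deliberately small menu
#'   limits overfitting, since leaf estimates reuse the fitting data.
#' @param stratifier stratification method used to form the two child
#'   strata at each node.
#' @param prestratum_size instrument pre-stratum size for the
#'   doubly-ranked stratifier.
#' @param mtry_fraction fraction of candidate covariates drawn (without
#'   replacement, minimum one) afresh at each node; 1 considers all
#'   covariates (single-tree setting), while forests default to 0.4 to
#'   de-correlate trees.
#'
#' @return A list of class `qtree_control`.
#' @export
qtree_control <- function(q_threshold = 3.84, min_node_size = 1000L,
                          max_depth = 5L, proportions = c(0.3, 0.5, 0.7),
                          stratifier = c("doubly_ranked", "residual", "naive"),
                          prestratum_size = 10L, mtry_fraction = 1) {
  stopifnot(q_threshold >= 0, min_node_size >= 2L, max_depth >= 0L,
            all(proportions > 0), all(proportions < 1),
            prestratum_size >= 2L,
            mtry_fraction > 0, mtry_fraction <= 1)
  structure(list(q_threshold = q_threshold,
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth),
                 proportions = proportions,
                 stratifier = match.arg(stratifier),
                 prestratum_size = as.integer(prestratum_size),
                 mtry_fraction = mtry_fraction),
            class = "qtree_control")
}

#' Boundary value separating two child strata
#'
#' The routing boundary for a fitted split is the size-weighted average of
#' the child-stratum means of the splitting covariate,
#' `(n1 * mean1 + n2 * mean2) / (n1 + n2)`; new individuals are sent to
#' the child whose mean covariate value is closer, i.e. to the lower child
#' when their covariate value is at or below this boundary.
#'
#' @param n1,n2 child sizes (lower and upper stratum).
#' @param mean1,mean2 child means of the splitting covariate.
#' @return The boundary value (scalar).
#' @export
#' @examples
#' boundary_value(3, 7, 1, 2) # 1.7
boundary_value <- function(n1, n2, mean1, mean2) {
  stopifnot(n1 > 0, n2 > 0)
  (n1 * mean1 + n2 * mean2) / (n1 + n2)
}

# ---- internal split search ---------------------------------------------
# All functions below operate on plain vectors for one node; randomness is
# taken from the current RNG stream (the tree owns one seeded stream).

# Per-group slopes, squared SEs and slope covariance from raw sums
# (n, z, z^2, x, x^2, zx, y, y^2, zy, xy); returns
# c(bx, vx, by, vy, cxy) or NAs on a degenerate group.
.pair_from_sums <- function(g) {
  n <- g[1L]
  if (n < 3) {
    return(rep(NA_real_, 5L))
  }
  czz <- g[3L] - g[2L]^2 / n
  if (czz <= 0) {
    return(rep(NA_real_, 5L))
  }
  czx <- g[6L] - g[2L] * g[4L] / n
  czy <- g[9L] - g[2L] * g[7L] / n
  bx <- czx / czz
  by <- czy / czz
  rssx <- max((g[5L] - g[4L]^2 / n) - bx^2 * czz, 0)
  rssy <- max((g[8L] - g[7L]^2 / n) - by^2 * czz, 0)
  exey <- (g[10L] - g[4L] * g[7L] / n) - czx * czy / czz
  denom <- (n - 2) * czz
  c(bx, rssx / denom, by, rssy / denom, exey / denom)
}

# Q statistic of a 2-stratum split given the lower-stratum index set and
# precomputed node totals of (1, z, z^2, x, x^2, zx, y, y^2, zy, xy).
# Uses the one-sample profile-likelihood denominator
# vy + theta^2 vx - 2 theta cov(bx, by), minimised over theta with a
# scalar golden-section search (cheaper than optimize() in this innermost
# loop; the profile Q is unimodal in theta between the two ratios).
.split_q <- function(z, x, y, i1, tot) {
  z1 <- z[i1]; x1 <- x[i1]; y1 <- y[i1]
  g1 <- c(length(i1), sum(z1), sum(z1 * z1), sum(x1), sum(x1 * x1),
          sum(z1 * x1), sum(y1), sum(y1 * y1), sum(z1 * y1), sum(x1 * y1))
  a1 <- .pair_from_sums(g1)
  a2 <- .pair_from_sums(tot - g1)
  if (anyNA(a1) || anyNA(a2) || a1[1L] == 0 || a2[1L] == 0 ||
      a1[4L] <= 0 || a2[4L] <= 0) {
    return(NA_real_)
  }
  bx1 <- a1[1L]; vx1 <- a1[2L]; by1 <- a1[3L]; vy1 <- a1[4L]; c1 <- a1[5L]
  bx2 <- a2[1L]; vx2 <- a2[2L]; by2 <- a2[3L]; vy2 <- a2[4L]; c2 <- a2[5L]
  t1 <- by1 / bx1
  t2 <- by2 / bx2
  s1 <- sqrt(vy1) / abs(bx1)
  s2 <- sqrt(vy2) / abs(bx2)
  pad <- 3 * max(s1, s2)
  lo <- min(t1, t2) - pad
  hi <- max(t1, t2) + pad
  qf <- function(t) {
    d1 <- vy1 + t * t * vx1 - 2 * t * c1
    d2 <- vy2 + t * t * vx2 - 2 * t * c2
    if (d1 <= 0 || d2 <= 0) return(Inf)
    r1 <- by1 - t * bx1
    r2 <- by2 - t * bx2
    r1 * r1 / d1 + r2 * r2 / d2
  }
  gr <- 0.618033988749895
  a <- lo; b <- hi
  c_ <- b - gr * (b - a)
  d_ <- a + gr * (b - a)
  fc <- qf(c_); fd <- qf(d_)
  tol <- 1e-5 * (abs(t1) + abs(t2) + pad) + 1e-9
  while (b - a > tol) {
    if (fc <= fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- qf(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- qf(d_)
    }
  }
  min(fc, fd)
}

# Lower-child index sets for every candidate proportion under one
# stratifier, sharing the expensive orderings across proportions.
#  - naive/residual: one sort of the (residualised) covariate; the lower
#    child is the lowest-rank block.
#  - doubly-ranked: within-pre-stratum covariate ranks; the lower child
#    collects the lowest ranks of each pre-stratum.
.lower_sets <- function(z, covariate, proportions, stratifier, ordz, pre) {
  m <- length(covariate)
  if (stratifier == "doubly_ranked") {
    o2 <- order(pre, covariate[ordz], stats::runif(m))
    idx <- ordz[o2]
    pre_sorted <- pre[o2]
    sizes_pre <- tabulate(pre_sorted)
    ranks <- sequence(sizes_pre)
    full <- sizes_pre[1L]
    last <- length(sizes_pre)
    lapply(proportions, function(a) {
      thr <- rep.int(.alloc_sizes(full, c(a, 1 - a))[1L], last)
      if (sizes_pre[last] < full) {
        thr[last] <- .alloc_sizes(sizes_pre[last], c(a, 1 - a))[1L]
      }
      idx[ranks <= thr[pre_sorted]]
    })
  } else {
    key <- covariate
    if (stratifier == "residual") {
      zc <- z - mean(z)
      szz <- sum(zc^2)
      if (szz <= 0) return(NULL)
      key <- covariate - sum(zc * (covariate - mean(covariate))) / szz * zc
    }
    ord <- order(key, stats::runif(m))
    lapply(proportions, function(a) {
      ord[seq_len(.alloc_sizes(m, c(a, 1 - a))[1L])]
    })
  }
}

# Best split over candidate covariates x proportions for one node.
# Returns NULL when no admissible split reaches the Q threshold.
.node_best_split <- function(z, x, y, M, candidates, control) {
  m <- length(z)
  props <- control$proportions
  sizes1 <- vapply(props, function(a) .alloc_sizes(m, c(a, 1 - a))[1L], 0L)
  admissible <- pmin(sizes1, m - sizes1) >= control$min_node_size
  if (!any(admissible)) {
    return(NULL)
  }
  tot <- c(m, sum(z), sum(z * z), sum(x), sum(x * x), sum(z * x),
           sum(y), sum(y * y), sum(z * y), sum(x * y))
  ordz <- NULL
  pre <- NULL
  if (control$stratifier == "doubly_ranked") {
    ordz <- order(z, stats::runif(m))
    pre <- rep(seq_len(ceiling(m / control$prestratum_size)),
               each = control$prestratum_size, length.out = m)
  }
  best <- NULL
  best_q <- -Inf
  for (j in candidates) {
    cov_j <- M[, j]
    lower <- .lower_sets(z, cov_j, props, control$stratifier, ordz, pre)
    if (is.null(lower)) next
    for (pidx in seq_along(props)) {
      if (!admissible[pidx]) next
      i1 <- lower[[pidx]]
      q <- .split_q(z, x, y, i1, tot)
      if (is.finite(q) && q > best_q) {
        best_q <- q
        best <- list(covariate = j, proportion = props[pidx], lower = i1,
                     q_value = q)
      }
    }
  }
  if (is.null(best) || best_q < control$q_threshold) {
    return(NULL)
  }
  n1 <- length(best$lower)
  mean1 <- mean(M[best$lower, best$covariate])
  mean2 <- (sum(M[, best$covariate]) - n1 * mean1) / (m - n1)
  best$n1 <- n1
  best$n2 <- m - n1
  best$mean_lower <- mean1
  best$mean_upper <- mean2
  best$boundary <- boundary_value(n1, m - n1, mean1, mean2)
  best
}

#' Search for the best collider-robust split of a node
#'
#' Evaluates every candidate covariate crossed with every candidate
#' splitting proportion: two strata are formed with the configured
#' stratifier, the two stratum-specific ratio estimates are compared with
#' the two-stratum Cochran Q statistic, and the (covariate, proportion)
#' pair with the greatest Q is returned, together with the routing
#' boundary of [boundary_value()]. Returns `NULL` when every candidate
#' split would produce a child below `min_node_size` or no split reaches
#' `q_threshold`. Ties in Q are broken by candidate order, then proportion
#' order.
#'
#' @param node_data an [mr_dataset] holding the node members.
#' @param candidates character vector of candidate covariate names
#'   (default: all columns of `node_data$M`).
#' @param control a [qtree_control()].
#' @param seed optional seed for stratification tie-breaking.
#'
#' @return `NULL`, or a list with `covariate`, `proportion` (lower-child
#'   fraction), `q_value`, `boundary`, child sizes `n1`/`n2`, child
#'   covariate means `mean_lower`/`mean_upper`, and `lower` (indices of
#'   lower-child members).
#' @export
best_split <- function(node_data, candidates = colnames(node_data$M),
                       control = qtree_control(), seed = NULL) {
  stopifnot(inherits(node_data, "mr_dataset"))
  jj <- match(candidates, colnames(node_data$M))
  if (anyNA(jj)) {
    stop("unknown candidate covariate(s): ",
         paste(candidates[is.na(jj)], collapse = ", "), call. = FALSE)
  }
  out <- .with_seed(seed, .node_best_split(node_data$Z, node_data$X,
                                           node_data$Y, node_data$M, jj,
                                           control))
  if (!is.null(out)) {
    out$covariate <- colnames(node_data$M)[out$covariate]
  }
  out
}

# Ratio estimate for a leaf; returns
# c(theta, beta_x, se_x, beta_y, se_y, sigma_xy).
.leaf_estimate <- function(z, x, y) {
  a <- .assoc_pair(z, x, y)
  if (!is.finite(a[1L]) || !is.finite(a[3L]) || a[1L] == 0) {
    return(rep(NA_real_, 6L))
  }
  unname(c(a[3L] / a[1L], a[1L], a[2L], a[3L], a[4L], a[5L]))
}

#' Grow a single Q tree
#'
#' Recursively partitions the sample by [best_split()]: at each node two
#' child strata are formed with the configured collider-robust stratifier
#' on the covariate/proportion pair maximising the two-stratum Q
#' statistic. Child membership at fit time is the stratum assignment
#' itself (not a covariate threshold); the boundary value is stored only
#' for routing new individuals. Splitting stops when no candidate split
#' reaches the Q threshold, when a child would fall below the minimum node
#' size, or at the maximum depth. Each terminal node (leaf) carries the
#' ratio-method MR estimate computed from its members.
#'
#' @param train an [mr_dataset] of fitting data.
#' @param control a [qtree_control()].
#' @param seed integer seed; one RNG stream drives all tie-breaking and
#'   covariate subsampling in this tree.
#'
#' @return An object of class `qtree`: list with `nodes` (a data frame,
#'   one row per node), `control`, `n_fit` and `theta_root` (the overall
#'   estimate, used as fallback for degenerate leaves).
#' @export
grow_qtree <- function(train, control = qtree_control(), seed = NULL) {
  stopifnot(inherits(train, "mr_dataset"))
  .with_seed(seed, .grow_qtree_impl(train$Z, train$X, train$Y, train$M,
                                    control))
}

.grow_qtree_impl <- function(z, x, y, M, control) {
  p <- ncol(M)
  mtry <- max(1L, as.integer(round(control$mtry_fraction * p)))
  root_est <- .leaf_estimate(z, x, y)
  # node fields accumulated as flat vectors (grown geometrically)
  cap <- 64L
  v_depth <- v_n <- v_left <- v_right <- integer(cap)
  v_leaf <- logical(cap)
  v_cov <- character(cap)
  v_prop <- v_bound <- v_q <- v_ml <- v_mu <- numeric(cap)
  est_mat <- matrix(NA_real_, cap, 6L)
  n_nodes <- 1L
  queue <- list(list(id = 1L, idx = seq_along(z), depth = 0L))
  while (length(queue)) {
    nd <- queue[[1L]]
    queue <- queue[-1L]
    i <- nd$idx
    id <- nd$id
    sp <- NULL
    if (nd$depth < control$max_depth &&
        length(i) >= 2L * control$min_node_size) {
      cand <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
      sp <- .node_best_split(z[i], x[i], y[i], M[i, , drop = FALSE],
                             cand, control)
    }
    v_depth[id] <- nd$depth
    v_n[id] <- length(i)
    if (is.null(sp)) {
      est <- .leaf_estimate(z[i], x[i], y[i])
      if (!is.finite(est[1L])) est <- root_est
      v_leaf[id] <- TRUE
      v_cov[id] <- NA_character_
      v_prop[id] <- v_bound[id] <- v_q[id] <- v_ml[id] <- v_mu[id] <- NA_real_
      v_left[id] <- v_right[id] <- NA_integer_
      est_mat[id, ] <- est
    } else {
      lid <- n_nodes + 1L
      rid <- n_nodes + 2L
      n_nodes <- n_nodes + 2L
      if (n_nodes > cap) {
        cap <- 2L * cap
        length(v_depth) <- length(v_n) <- length(v_left) <- cap
        length(v_right) <- length(v_leaf) <- length(v_cov) <- cap
        length(v_prop) <- length(v_bound) <- length(v_q) <- cap
        length(v_ml) <- length(v_mu) <- cap
        est_mat <- rbind(est_mat, matrix(NA_real_, cap - nrow(est_mat), 6L))
      }
      v_leaf[id] <- FALSE
      v_cov[id] <- colnames(M)[sp$covariate]
      v_prop[id] <- sp$proportion
      v_bound[id] <- sp$boundary
      v_q[id] <- sp$q_value
      v_ml[id] <- sp$mean_lower
      v_mu[id] <- sp$mean_upper
      v_left[id] <- lid
      v_right[id] <- rid
      in_lower <- logical(length(i))
      in_lower[sp$lower] <- TRUE
      queue <- c(queue, list(
        list(id = lid, idx = i[in_lower], depth = nd$depth + 1L),
        list(id = rid, idx = i[!in_lower], depth = nd$depth + 1L)
      ))
    }
  }
  k <- seq_len(n_nodes)
  nodes_df <- data.frame(id = k, depth = v_depth[k], n = v_n[k],
                         is_leaf = v_leaf[k], covariate = v_cov[k],
                         proportion = v_prop[k], boundary = v_bound[k],
                         q_value = v_q[k], mean_lower = v_ml[k],
                         mean_upper = v_mu[k], left = v_left[k],
                         right = v_right[k], theta = est_mat[k, 1L],
                         beta_x = est_mat[k, 2L], se_x = est_mat[k, 3L],
                         beta_y = est_mat[k, 4L], se_y = est_mat[k, 5L],
                         sigma_xy = est_mat[k, 6L],
                         stringsAsFactors = FALSE)
  structure(list(nodes = nodes_df, control = control,
                 n_fit = length(z),
                 theta_root = if (is.finite(root_est[1L])) root_est[1L] else NA_real_),
            class = "qtree")
}

#' @export
print.qtree <- function(x, ...) {
  nl <- sum(x$nodes$is_leaf)
  cat(sprintf("Q tree: %d nodes (%d leaves), depth %d, fitted on %d individuals\n",
              nrow(x$nodes), nl, max(x$nodes$depth), x$n_fit))
  invisible(x)
}

#' Predict individual causal effects from a fitted Q tree
#'
#' Routes each individual from the root: at every internal node the
#' individual goes to the lower child when their value of the splitting
#' covariate is at or below the stored boundary (the size-weighted average
#' of the two child means; a value exactly at the boundary routes to the
#' lower child), otherwise to the upper child. The prediction is the MR
#' estimate of the leaf reached.
#'
#' @param object a `qtree`.
#' @param newdata an [mr_dataset], or a matrix/data frame of covariates
#'   containing every covariate the tree splits on.
#' @param ... unused.
#' @return Numeric vector of per-individual effect estimates.
#' @export
predict.qtree <- function(object, newdata, ...) {
  M <- if (inherits(newdata, "mr_dataset")) newdata$M else as.matrix(newdata)
  nodes <- object$nodes
  used <- unique(nodes$covariate[!nodes$is_leaf])
  miss <- setdiff(used, colnames(M))
  if (length(miss)) {
    stop("newdata lacks covariate(s) used by the tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  at <- rep.int(1L, nrow(M))
  for (r in seq_len(nrow(nodes))) {
    if (nodes$is_leaf[r]) next
    id <- nodes$id[r]
    here <- at == id
    if (!any(here)) next
    lower <- M[here, nodes$covariate[r]] <= nodes$boundary[r]
    at[here] <- ifelse(lower, nodes$left[r], nodes$right[r])
  }
  nodes$theta[match(at, nodes$id)]
}

#' Serialize a Q tree to JSON
#'
#' Writes the node table (splitting rules, boundaries, leaf estimates) and
#' hyperparameters so that a fitted tree can be stored as text and reused
#' for prediction.
#'
#' @param tree a `qtree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
qtree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "qtree"))
  obj <- list(nodes = tree$nodes,
              control = unclass(tree$control),
              n_fit = tree$n_fit,
              theta_root = tree$theta_root)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}

# Rebuild a node table from the parsed JSON (list of row records with
# nulls standing for NA).
.nodes_from_json <- function(rows) {
  grab <- function(cl) {
    lapply(rows, function(r) if (is.null(r[[cl]])) NA else r[[cl]])
  }
  num <- function(cl) as.numeric(unlist(grab(cl)))
  int <- function(cl) as.integer(unlist(grab(cl)))
  data.frame(id = int("id"), depth = int("depth"), n = int("n"),
             is_leaf = as.logical(unlist(grab("is_leaf"))),
             covariate = as.character(unlist(grab("covariate"))),
             proportion = num("proportion"), boundary = num("boundary"),
             q_value = num("q_value"), mean_lower = num("mean_lower"),
             mean_upper = num("mean_upper"), left = int("left"),
             right = int("right"), theta = num("theta"),
             beta_x = num("beta_x"), se_x = num("se_x"),
             beta_y = num("beta_y"), se_y = num("se_y"),
             sigma_xy = num("sigma_xy"), stringsAsFactors = FALSE)
}

.control_from_json <- function(ctl) {
  qtree_control(q_threshold = ctl$q_threshold,
                min_node_size = ctl$min_node_size,
                max_depth = ctl$max_depth,
                proportions = as.numeric(unlist(ctl$proportions)),
                stratifier = ctl$stratifier,
                prestratum_size = ctl$prestratum_size,
                mtry_fraction = ctl$mtry_fraction)
}

#' @rdname qtree_to_json
#' @param json a JSON string or file path produced by [qtree_to_json()].
#' @export
qtree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(list(nodes = .nodes_from_json(obj$nodes),
                 control = .control_from_json(obj$control),
                 n_fit = obj$n_fit,
                 theta_root = obj$theta_root),
            class = "qtree")
}
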