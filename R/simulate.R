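#' Simulate an MR dataset with configurable effect modification
#'
#' Generates individual-level data from a structural model with an
#' instrument `Z`, exposure `X`, outcome `Y`, twenty unmeasured
#' confounders `U_j` and twenty candidate covariates `M_j`:
#' \deqn{X = 0.5 Z + 0.5 \sum_j U_j + \epsilon_X}
#' \deqn{M_j = b_j X + U_j}
#' \deqn{Y = (0.5 + \sum_{j \le 5} \gamma_j M_j) X + 0.5 \sum_j U_j + \epsilon_Y}
#' with `Z`, `U_j`, `eps_X`, `eps_Y` independent standard normal. The
#' first `n_modifiers` covariates carry modifier effects
#' `gamma_j ~ N(gamma, 0.1^2)` drawn once per dataset; the remaining
#' covariates have `gamma_j = 0`. The exposure-covariate coefficients
#' `b_j` follow the scenario:
#'
#' * **A** — `b_j = 0`: no covariate is a collider;
#' * **B** — `b_j = 0.5` for even `j`, 0 otherwise: half the covariates
#'   are colliders (common effects of the exposure and a confounder);
#' * **C** — `b_j = 0.1 + 0.5 U_j`, evaluated at each individual's
#'   confounder value: the exposure's effect on each covariate is itself
#'   modified by the confounder, violating both the linear-homogeneous
#'   assumption of the residual method and the rank-preserving assumption.
#'
#' Even with `gamma = 0` the random draw of `gamma_j` leaves weak effect
#' modification; `pure_null = TRUE` forces every `gamma_j = 0` exactly so
#' that the individual effect is the constant 0.5, which is what
#' null-calibration checks require.
#'
#' @param n sample size.
#' @param scenario `"A"`, `"B"` or `"C"` (see above).
#' @param gamma mean modifier effect (strength of modification); typical
#'   range 0 to 0.5.
#' @param p number of candidate covariates.
#' @param n_modifiers number of true effect modifiers (the first
#'   `n_modifiers` covariates).
#' @param pure_null force all modifier effects to zero exactly.
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-for-bit.
#'
#' @return An object of class `rfqt_sim`: list with `data` (an
#'   [mr_dataset] with covariates `M1..Mp`), `true_effect` (the
#'   per-individual controlled direct effect
#'   `0.5 + sum_j gamma_j M_j`, the evaluation target for predicted
#'   effects) and `gamma_j` (the drawn modifier effects).
#' @export
simulate_dataset <- function(n, scenario = c("A", "B", "C"), gamma = 0,
                             p = 20L, n_modifiers = 5L, pure_null = FALSE,
                             seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 1L, p >= 1L, n_modifiers >= 1L, n_modifiers <= p,
            gamma >= 0)
  .with_seed(seed, {
    Z <- stats::rnorm(n)
    U <- matrix(stats::rnorm(n * p), n, p)
    X <- 0.5 * Z + 0.5 * rowSums(U) + stats::rnorm(n)
    b <- switch(scenario,
                A = matrix(0, n, p, byrow = TRUE),
                B = matrix(rep(ifelse(seq_len(p) %% 2L == 0L, 0.5, 0),
                               each = n), n, p),
                C = 0.1 + 0.5 * U)
    M <- b * X + U
    colnames(M) <- paste0("M", seq_len(p))
    gamma_j <- numeric(p)
    if (!pure_null) {
      gamma_j[seq_len(n_modifiers)] <- stats::rnorm(n_modifiers, gamma, 0.1)
    }
    true_effect <- 0.5 +
      drop(M[, seq_len(n_modifiers), drop = FALSE] %*%
             gamma_j[seq_len(n_modifiers)])
    Y <- true_effect * X + 0.5 * rowSums(U) + stats::rnorm(n)
    structure(list(data = mr_dataset(Z = Z, X = X, Y = Y, M = M),
                   true_effect = true_effect,
                   gamma_j = gamma_j,
                   scenario = scenario, gamma = gamma,
                   pure_null = pure_null),
              class = "rfqt_sim")
  })
}

#' @export
print.rfqt_sim <- function(x, ...) {
  cat(sprintf("simulated MR dataset: scenario %s, gamma = %.2f%s, n = %d, p = %d\n",
              x$scenario, x$gamma, if (x$pure_null) " (pure null)" else "",
              nobs(x$data), ncol(x$data$M)))
  invisible(x)
}

#' Mean squared error of predicted individual effects
#'
#' @param predicted numeric vector of per-individual effect estimates.
#' @param truth numeric vector of the same length with the true
#'   individual effects (e.g. the controlled direct effects recorded by
#'   [simulate_dataset()]).
#' @return Mean squared difference (scalar).
#' @export
evaluate_mse <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  mean((predicted - truth)^2)
}

.grid_methods <- c("none",
                   "naive_tree", "residual_tree", "doubly_ranked_tree",
                   "naive_forest", "residual_forest",
                   "doubly_ranked_forest")

# Fit one method variant on a training sim and predict the test rows.
.grid_predict <- function(method, train, test_M, control, n_trees, seed) {
  if (method == "none") {
    ax <- .assoc(train$Z, train$X)
    ay <- .assoc(train$Z, train$Y)
    return(rep(ay[1L] / ax[1L], nrow(test_M)))
  }
  parts <- strsplit(method, "_(?=tree$|forest$)", perl = TRUE)[[1L]]
  control$stratifier <- parts[1L]
  if (parts[2L] == "tree") {
    tree <- grow_qtree(train, control, seed = seed)
    predict(tree, test_M)
  } else {
    forest <- fit_rfqt(train, control, n_trees = n_trees,
                       mtry_fraction = 0.4, seed = seed)
    predict(forest, test_M)
  }
}

#' Benchmark stratification and tree methods on simulated data
#'
#' Runs the simulation benchmark comparing up to seven method variants —
#' no stratification, and a single Q tree or an RFQT forest built with
#' the naive, residual or doubly-ranked stratifier — over a grid of
#' scenarios and modification strengths. Each replicate simulates one
#' dataset, fits every method on the first `n` individuals, predicts the
#' held-out `n_test` individuals, and records the mean squared error of
#' the predicted individual effects against the true controlled direct
#' effects. The summary reports the median MSE across replicates.
#'
#' @param scenarios character vector among `"A"`, `"B"`, `"C"`.
#' @param gammas numeric vector of modification strengths.
#' @param methods subset of
#'   `c("none", "naive_tree", "residual_tree", "doubly_ranked_tree",
#'   "naive_forest", "residual_forest", "doubly_ranked_forest")`.
#' @param n training-sample size per replicate.
#' @param n_test held-out individuals per replicate used for evaluation.
#' @param reps number of simulation replicates per grid cell.
#' @param n_trees forest size for the forest methods.
#' @param control a [qtree_control()].
#' @param seed integer master seed.
#'
#' @return A list with `results` (one row per scenario/gamma/method/rep
#'   with its `mse`) and `summary` (median MSE per scenario/gamma/method).
#' @export
run_method_grid <- function(scenarios = c("A", "B", "C"),
                            gammas = c(0, 0.25, 0.5),
                            methods = .grid_methods,
                            n = 10000L, n_test = 2000L, reps = 20L,
                            n_trees = 20L, control = qtree_control(),
                            seed = NULL) {
  bad <- setdiff(methods, .grid_methods)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  seeds <- .derive_seeds(seed, length(scenarios) * length(gammas) * reps * 2L)
  si <- 0L
  rows <- list()
  for (sc in scenarios) {
    for (g in gammas) {
      for (r in seq_len(reps)) {
        si <- si + 2L
        sim <- simulate_dataset(n + n_test, scenario = sc, gamma = g,
                                seed = seeds[si - 1L])
        train <- sim$data[seq_len(n)]
        test_idx <- (n + 1L):(n + n_test)
        test_M <- sim$data$M[test_idx, , drop = FALSE]
        truth <- sim$true_effect[test_idx]
        mseeds <- .derive_seeds(seeds[si], length(methods))
        for (mi in seq_along(methods)) {
          pred <- .grid_predict(methods[mi], train, test_M, control,
                                n_trees, mseeds[mi])
          rows[[length(rows) + 1L]] <-
            data.frame(scenario = sc, gamma = g, method = methods[mi],
                       rep = r, mse = evaluate_mse(pred, truth))
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(mse ~ scenario + gamma + method,
                              data = results, FUN = stats::median)
  names(summary)[names(summary) == "mse"] <- "median_mse"
  list(results = results, summary = summary)
}
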