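# Rubin's-rules pooling of one stratum's association estimates across
# resamples: point estimate = mean, total variance = U + (1 + 1/S) B,
# t-based 95% CI with df = (S - 1)(1 + U / ((1 + 1/S) B))^2; B = 0
# degenerates to the normal quantile.
.rubin_pool <- function(betas, vars) {
  S <- length(betas)
  est <- mean(betas)
  U <- mean(vars)
  B <- stats::var(betas)
  tot <- U + (1 + 1 / S) * B
  if (B > 0) {
    df <- (S - 1) * (1 + U / ((1 + 1 / S) * B))^2
    q <- stats::qt(0.975, df)
  } else {
    df <- Inf
    q <- stats::qnorm(0.975)
  }
  list(est = est, U = U, B = B, total_var = tot, df = df,
       lo = est - q * sqrt(tot), hi = est + q * sqrt(tot))
}

#' Stabilized stratum-specific estimates by repeated subsampling
#'
#' A one-shot doubly-ranked stratification is sensitive to the exact
#' sample because small perturbations change the ranking. This routine
#' repeats the stratification `S` times, each time dropping `n_drop`
#' individuals at random (which reshuffles the ranks), and pools the
#' per-resample stratum association estimates with Rubin's rules:
#' the pooled point estimate is the plain mean across resamples,
#' its total variance combines the mean within-resample sampling variance
#' `U` with the between-resample variance `B` as `U + (1 + 1/S) B`, and
#' the 95% confidence interval uses a t quantile with
#' `v = (S - 1) (1 + U / ((1 + 1/S) B))^2` degrees of freedom. When
#' `B = 0` (identical estimates in every resample) the t quantile
#' degenerates to the normal quantile. The pooled ratio estimate for
#' stratum k is `beta_Y^P / beta_X^P`, with confidence interval obtained
#' by dividing the outcome-association interval endpoints by `beta_X^P`.
#'
#' @param data an [mr_dataset].
#' @param covariate name of the stratifying covariate (a column of
#'   `data$M`), or a numeric vector aligned with the data.
#' @param K number of equal-sized strata.
#' @param S number of resampling iterations (at least 2, or the
#'   between-resample variance is undefined).
#' @param n_drop individuals removed per iteration; 10 removals are
#'   enough to perturb the rank ordering.
#' @param prestratum_size instrument pre-stratum size for the
#'   doubly-ranked stratification.
#' @param seed integer master seed.
#'
#' @return An object of class `pooled_estimates`: list with `strata` (a
#'   data frame, one row per stratum: `stratum`, `mbar`, `beta_x_p`,
#'   `beta_y_p`, `U_x`, `B_x`, `U_y`, `B_y`, `U_xy`, `B_xy` (within- and
#'   between-resample components, including the covariance between the
#'   two pooled associations), `df`, `ci_y_low`,
#'   `ci_y_high`, `theta_p`, `theta_ci_low`, `theta_ci_high`) and the
#'   settings `K`, `S`, `n_drop`.
#' @export
pooled_stratum_estimates <- function(data, covariate, K = 10L, S = 100L,
                                     n_drop = 10L, prestratum_size = 10L,
                                     seed = NULL) {
  stopifnot(inherits(data, "mr_dataset"))
  if (S < 2L) {
    stop("S must be at least 2 (between-resample variance undefined otherwise)",
         call. = FALSE)
  }
  n <- nobs(data)
  if (n <= n_drop) {
    stop("dataset too small for the requested number of dropped individuals",
         call. = FALSE)
  }
  cov_name <- NA_character_
  if (is.character(covariate)) {
    if (!covariate %in% colnames(data$M)) {
      stop(sprintf("covariate '%s' not found", covariate), call. = FALSE)
    }
    cov_name <- covariate
    covariate <- data$M[, covariate]
  }
  seeds <- .derive_seeds(seed, 2L * S)
  bX <- sX2 <- bY <- sY2 <- sXY <- mb <- matrix(NA_real_, nrow = S, ncol = K)
  for (i in seq_len(S)) {
    keep <- .with_seed(seeds[2L * i - 1L],
                       sort(sample.int(n, n - n_drop)))
    z <- data$Z[keep]; x <- data$X[keep]; y <- data$Y[keep]
    m <- covariate[keep]
    asg <- suppressWarnings(doubly_ranked_strata(
      z, m, proportions = rep(1 / K, K), seed = seeds[2L * i],
      prestratum_size = prestratum_size))
    for (k in seq_len(K)) {
      sel <- asg$labels == k
      if (sum(sel) < 3L) next
      a <- .assoc_pair(z[sel], x[sel], y[sel])
      if (!is.finite(a[1L]) || !is.finite(a[3L])) next
      bX[i, k] <- a[1L]; sX2[i, k] <- a[2L]^2
      bY[i, k] <- a[3L]; sY2[i, k] <- a[4L]^2
      sXY[i, k] <- a[5L]
      mb[i, k] <- mean(m[sel])
    }
  }
  strata <- data.frame(stratum = seq_len(K))
  for (k in seq_len(K)) {
    ok <- which(is.finite(bY[, k]) & is.finite(bX[, k]))
    s_eff <- length(ok)
    if (s_eff < 2L) {
      stop(sprintf("stratum %d estimable in fewer than 2 resamples", k),
           call. = FALSE)
    }
    px <- .rubin_pool(bX[ok, k], sX2[ok, k])
    py <- .rubin_pool(bY[ok, k], sY2[ok, k])
    strata$mbar[k] <- mean(mb[ok, k])
    strata$beta_x_p[k] <- px$est
    strata$beta_y_p[k] <- py$est
    strata$U_x[k] <- px$U
    strata$B_x[k] <- px$B
    strata$U_y[k] <- py$U
    strata$B_y[k] <- py$B
    strata$U_xy[k] <- mean(sXY[ok, k])
    strata$B_xy[k] <- stats::cov(bX[ok, k], bY[ok, k])
    strata$df[k] <- py$df
    strata$ci_y_low[k] <- py$lo
    strata$ci_y_high[k] <- py$hi
    strata$theta_p[k] <- py$est / px$est
    ci <- sort(c(py$lo, py$hi) / px$est)
    strata$theta_ci_low[k] <- ci[1L]
    strata$theta_ci_high[k] <- ci[2L]
  }
  structure(list(strata = strata, K = K, S = S, n_drop = n_drop,
                 covariate_name = cov_name),
            class = "pooled_estimates")
}

#' @export
print.pooled_estimates <- function(x, ...) {
  cat(sprintf("Pooled stratum estimates (%d strata, %d resamples%s)\n",
              x$K, x$S,
              if (!is.na(x$covariate_name)) paste0(", covariate ", x$covariate_name) else ""))
  print(format(x$strata[, c("stratum", "mbar", "theta_p", "theta_ci_low",
                            "theta_ci_high")], digits = 4))
  invisible(x)
}

#' Heterogeneity of pooled stratum estimates
#'
#' Cochran-type Q statistic over the pooled stratum estimates, with the
#' Rubin's-rules total variances `U + (1 + 1/S) B` of the two pooled
#' associations in the denominator and the inverse-variance weighted
#' average of the pooled ratio estimates as the reference effect;
#' compared against a chi-squared distribution with `K - 1` degrees of
#' freedom.
#'
#' @param pooled a `pooled_estimates` object.
#' @param iterate minimise Q over the reference effect (default, matching
#'   [q_statistic()]) rather than plugging in the closed-form IVW average.
#' @return A `q_result` (see [q_statistic()]).
#' @export
pooled_q <- function(pooled, iterate = TRUE) {
  stopifnot(inherits(pooled, "pooled_estimates"))
  st <- pooled$strata
  fac <- 1 + 1 / pooled$S
  est <- data.frame(stratum = st$stratum, n = NA_integer_, mbar = st$mbar,
                    beta_x = st$beta_x_p,
                    se_x = sqrt(st$U_x + fac * st$B_x),
                    beta_y = st$beta_y_p,
                    se_y = sqrt(st$U_y + fac * st$B_y),
                    sigma_xy = st$U_xy + fac * st$B_xy)
  est$theta <- est$beta_y / est$beta_x
  est$se_theta <- est$se_y / abs(est$beta_x)
  est$usable <- is.finite(est$theta) & est$se_theta > 0
  class(est) <- c("stratum_estimates", "data.frame")
  q_statistic(est, iterate = iterate)
}

#' Trend test of pooled stratum estimates against covariate level
#'
#' Random-effects meta-regression of the pooled stratum-specific ratio
#' estimates on the pooled stratum covariate means (the moderator), using
#' `metafor::rma()`; reports the Wald test of the moderator slope. A
#' significant slope indicates that the causal effect trends with the
#' level of the stratifying covariate.
#'
#' @param pooled a `pooled_estimates` object with at least 3 strata.
#' @param method heterogeneity-variance estimator passed to
#'   [metafor::rma()] (default restricted maximum likelihood).
#' @return A list with `slope`, `se`, `p_value` and the fitted `model`.
#' @export
trend_test <- function(pooled, method = "REML") {
  stopifnot(inherits(pooled, "pooled_estimates"))
  st <- pooled$strata
  if (nrow(st) < 3L) {
    stop("trend test requires at least 3 strata", call. = FALSE)
  }
  fac <- 1 + 1 / pooled$S
  vi <- (st$U_y + fac * st$B_y) / st$beta_x_p^2
  fit <- metafor::rma(yi = st$theta_p, vi = vi, mods = ~ st$mbar,
                      method = method)
  list(slope = unname(fit$beta[2L]), se = unname(fit$se[2L]),
       p_value = unname(fit$pval[2L]), model = fit)
}
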