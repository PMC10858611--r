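#' Stratum-specific instrument associations and ratio estimates
#'
#' Within each stratum, regresses the exposure and the outcome on the
#' instrument (ordinary least squares with intercept) and forms the ratio
#' (Wald) estimate of the causal effect,
#' `theta_k = beta_Yk / beta_Xk`, together with its first-order standard
#' error `sigma_Yk / |beta_Xk|`. The mean of the stratifying covariate in
#' each stratum (`mbar`) is recorded for downstream trend summaries.
#'
#' Because both associations are estimated on the same individuals, their
#' sampling covariance `sigma_xy = cov(beta_x_hat, beta_y_hat)` is also
#' recorded; [q_statistic()] needs it to standardize the stratum
#' residuals correctly in this one-sample setting.
#'
#' Strata in which the instrument is constant, or with fewer than three
#' individuals (so that no residual degree of freedom remains), cannot be
#' estimated: they are flagged (`usable = FALSE`), reported with `NA`
#' estimates, and excluded from heterogeneity statistics with a warning.
#'
#' @param data an [mr_dataset].
#' @param assignment a `stratum_assignment` for the same individuals.
#' @param covariate optional numeric vector of the stratifying covariate;
#'   when `NULL` it is looked up in `data$M` by the assignment's
#'   `covariate_name`.
#' @param robust use heteroskedasticity-robust (HC1) standard errors for
#'   the two instrument associations instead of classical OLS ones.
#'
#' @return An object of class `stratum_estimates`: a data frame with one
#'   row per stratum and columns `stratum`, `n`, `mbar`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `sigma_xy`, `theta`, `se_theta`, `usable`.
#' @export
stratum_associations <- function(data, assignment, covariate = NULL,
                                 robust = FALSE) {
  stopifnot(inherits(data, "mr_dataset"),
            inherits(assignment, "stratum_assignment"))
  n <- nobs(data)
  if (length(assignment$labels) != n) {
    stop("assignment does not match the dataset size", call. = FALSE)
  }
  if (is.null(covariate) && !is.na(assignment$covariate_name) &&
      assignment$covariate_name %in% colnames(data$M)) {
    covariate <- data$M[, assignment$covariate_name]
  }
  K <- assignment$K
  out <- data.frame(stratum = seq_len(K),
                    n = tabulate(assignment$labels, K),
                    mbar = NA_real_,
                    beta_x = NA_real_, se_x = NA_real_,
                    beta_y = NA_real_, se_y = NA_real_,
                    sigma_xy = NA_real_,
                    theta = NA_real_, se_theta = NA_real_,
                    usable = FALSE)
  for (k in seq_len(K)) {
    i <- which(assignment$labels == k)
    if (!is.null(covariate)) out$mbar[k] <- mean(covariate[i])
    if (length(i) < 3L) next
    z <- data$Z[i]
    a <- .assoc_pair(z, data$X[i], data$Y[i])
    if (robust && is.finite(a[1L])) {
      hc <- .hc1_pair(z, data$X[i], data$Y[i], a[1L], a[3L])
      a[2L] <- hc[1L]; a[4L] <- hc[2L]; a[5L] <- hc[3L]
    }
    if (!is.finite(a[1L]) || !is.finite(a[3L])) next
    out$beta_x[k] <- a[1L]; out$se_x[k] <- a[2L]
    out$beta_y[k] <- a[3L]; out$se_y[k] <- a[4L]
    out$sigma_xy[k] <- a[5L]
    if (a[1L] == 0) {
      stop(sprintf("instrument-exposure association is exactly zero in stratum %d; ratio estimate undefined", k),
           call. = FALSE)
    }
    out$theta[k] <- a[3L] / a[1L]
    out$se_theta[k] <- a[4L] / abs(a[1L])
    out$usable[k] <- TRUE
  }
  if (any(!out$usable)) {
    warning(sprintf("%d stratum(s) could not be estimated (constant instrument or too few individuals) and will be excluded from heterogeneity statistics",
                    sum(!out$usable)), call. = FALSE)
  }
  class(out) <- c("stratum_estimates", "data.frame")
  out
}

# HC1 sandwich SEs and slope covariance for the pair (x ~ z, y ~ z).
.hc1_pair <- function(z, x, y, beta_x, beta_y) {
  n <- length(z)
  zc <- z - mean(z)
  szz <- sum(zc^2)
  ex <- x - mean(x) - beta_x * zc
  ey <- y - mean(y) - beta_y * zc
  adj <- n / (n - 2)
  c(sqrt(adj * sum(zc^2 * ex^2) / szz^2),
    sqrt(adj * sum(zc^2 * ey^2) / szz^2),
    adj * sum(zc^2 * ex * ey) / szz^2)
}

#' Inverse-variance weighted average of stratum estimates
#'
#' Averages the stratum-specific ratio estimates with weights proportional
#' to the inverse of their squared first-order standard errors. With
#' `iterate = TRUE` the estimate instead minimises the heterogeneity
#' statistic of [q_statistic()] over the causal parameter (the
#' profile-likelihood point estimate), which additionally accounts for
#' uncertainty in the instrument-exposure associations.
#'
#' @param est a `stratum_estimates` object from [stratum_associations()].
#' @param iterate minimise the Q statistic over theta rather than using
#'   the closed-form weighted mean.
#' @return The pooled causal effect estimate (scalar).
#' @export
ivw_average <- function(est, iterate = FALSE) {
  stopifnot(inherits(est, "stratum_estimates"))
  e <- est[est$usable, , drop = FALSE]
  if (nrow(e) == 0L) stop("no usable strata", call. = FALSE)
  if (any(!is.finite(e$se_theta)) || any(e$se_theta == 0)) {
    # exact-fit strata: fall back to the unweighted mean of exact ratios
    return(mean(e$theta))
  }
  w <- 1 / e$se_theta^2
  theta0 <- sum(w * e$theta) / sum(w)
  if (!iterate || nrow(e) == 1L) {
    return(theta0)
  }
  qfun <- function(th) {
    sum((e$beta_y - th * e$beta_x)^2 / .q_denominator(e, th))
  }
  half <- max(diff(range(e$theta)), 10 * max(e$se_theta), abs(theta0), 1)
  stats::optimize(qfun, interval = c(theta0 - half, theta0 + half))$minimum
}

# Profile-likelihood variance of beta_y - theta * beta_x per stratum.
# With the recorded one-sample covariance this is exact; when sigma_xy is
# absent (summary-level input, or independent samples) the cross term is
# zero and the classic two-sample form is recovered.
.q_denominator <- function(e, theta) {
  sxy <- if (!is.null(e$sigma_xy)) ifelse(is.finite(e$sigma_xy), e$sigma_xy, 0) else 0
  pmax(e$se_y^2 + theta^2 * e$se_x^2 - 2 * theta * sxy, 0)
}

#' Cochran's Q statistic for heterogeneity of stratum-specific estimates
#'
#' Measures whether stratum-specific ratio estimates are more variable than
#' expected by chance:
#' \deqn{Q = \sum_k \frac{(\hat\beta_{Yk} - \hat\theta\,\hat\beta_{Xk})^2}
#'   {\widehat{\mathrm{var}}(\hat\beta_{Yk} - \hat\theta\,\hat\beta_{Xk})}}
#' with \eqn{\hat\theta} the inverse-variance weighted average of the
#' stratum estimates. Under homogeneity Q follows a chi-squared
#' distribution with `K - 1` degrees of freedom. The denominator is the
#' profile-likelihood variance
#' \eqn{\sigma_{Yk}^2 + \hat\theta^2\sigma_{Xk}^2 -
#'   2\hat\theta\,\sigma_{XYk}}: it allows for sampling variability of the
#' instrument-exposure associations (making the statistic robust to the
#' weak instruments that small strata tend to produce) and, through the
#' covariance term recorded by [stratum_associations()], for the fact that
#' both associations are estimated on the same individuals. For
#' summary-level input without a recorded covariance the cross term is
#' zero, giving the familiar two-sample form.
#'
#' By default the reference effect \eqn{\hat\theta} minimises Q (the
#' profile-likelihood estimate), which keeps the statistic calibrated when
#' per-stratum instruments are weak; `iterate = FALSE` instead plugs in
#' the closed-form first-order IVW average.
#'
#' @inheritParams ivw_average
#' @return An object of class `q_result`: list with `Q`, `df`, `p_value`,
#'   `theta_hat` and `K` (number of usable strata).
#' @export
q_statistic <- function(est, iterate = TRUE) {
  stopifnot(inherits(est, "stratum_estimates"))
  e <- est[est$usable, , drop = FALSE]
  if (nrow(e) < 2L) {
    stop("at least two usable strata are required for a heterogeneity test",
         call. = FALSE)
  }
  theta <- ivw_average(est, iterate = iterate)
  denom <- .q_denominator(e, theta)
  if (any(denom <= 0)) {
    # exact-fit strata have zero variance; heterogeneity is then either
    # exactly zero (all residuals zero) or infinite
    num <- (e$beta_y - theta * e$beta_x)^2
    Q <- if (all(num[denom <= 0] == 0)) {
      sum((num / denom)[denom > 0], 0)
    } else {
      Inf
    }
  } else {
    Q <- sum((e$beta_y - theta * e$beta_x)^2 / denom)
  }
  df <- nrow(e) - 1L
  structure(list(Q = Q, df = df,
                 p_value = stats::pchisq(Q, df, lower.tail = FALSE),
                 theta_hat = theta, K = nrow(e)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f on %d df (p = %.4g); IVW estimate = %.4f over %d strata\n",
              x$Q, x$df, x$p_value, x$theta_hat, x$K))
  invisible(x)
}
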