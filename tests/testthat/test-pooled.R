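test_that("Rubin pooling matches the hand-computed two-resample example", {
  # resample estimates 1 and 3 with unit sampling variances:
  # pooled 2, U = 1, B = 2, df = (S-1)(1 + U/((1+1/S)B))^2 = (4/3)^2
  p <- rfqt:::.rubin_pool(c(1, 3), c(1, 1))
  expect_equal(p$est, 2)
  expect_equal(p$U, 1)
  expect_equal(p$B, 2)
  expect_equal(p$total_var, 1 + 1.5 * 2)
  expect_equal(p$df, (4 / 3)^2)
  expect_equal(p$hi - p$est, qt(0.975, (4 / 3)^2) * sqrt(4))
  expect_equal(p$lo, p$est - (p$hi - p$est))
})

test_that("identical resample estimates collapse to the normal-quantile interval", {
  p <- rfqt:::.rubin_pool(rep(1.5, 10), rep(0.04, 10))
  expect_equal(p$est, 1.5)
  expect_equal(p$B, 0)
  expect_equal(p$df, Inf)
  expect_equal(p$hi, 1.5 + qnorm(0.975) * 0.2)
})

test_that("pooled stratum estimates are means of resample estimates with ordered CIs", {
  sim <- simulate_dataset(600, "A", 0, pure_null = TRUE, seed = 81)
  p <- pooled_stratum_estimates(sim$data, "M2", K = 3, S = 10, seed = 82)
  st <- p$strata
  expect_equal(nrow(st), 3)
  expect_true(all(st$ci_y_low < st$ci_y_high))
  expect_true(all(st$theta_ci_low < st$theta_ci_high))
  expect_true(all(st$U_y >= 0) && all(st$B_y >= 0))
  expect_true(all(st$ci_y_low <= st$beta_y_p & st$beta_y_p <= st$ci_y_high))
  # covariate coordinate increases across doubly-ranked strata
  expect_true(all(diff(st$mbar) > 0))
  expect_error(pooled_stratum_estimates(sim$data, "M2", K = 3, S = 1),
               "at least 2")
})

test_that("CI width is nondecreasing in the between-resample variance", {
  base <- rfqt:::.rubin_pool(c(0.9, 1.0, 1.1), rep(0.01, 3))
  wide <- rfqt:::.rubin_pool(c(0.5, 1.0, 1.5), rep(0.01, 3))
  expect_gt(wide$hi - wide$lo, base$hi - base$lo)
})

test_that("pooled Q vanishes for proportional pooled estimates and matches hand values", {
  st <- data.frame(stratum = 1:2, mbar = c(-1, 1),
                   beta_x_p = c(0.5, 0.8), beta_y_p = c(0.25, 0.4),
                   U_x = c(0.01, 0.01), B_x = c(0.002, 0.002),
                   U_y = c(0.02, 0.02), B_y = c(0.004, 0.004),
                   U_xy = c(0, 0), B_xy = c(0, 0),
                   df = c(20, 20), ci_y_low = 0, ci_y_high = 1,
                   theta_p = c(0.5, 0.5), theta_ci_low = 0,
                   theta_ci_high = 1)
  pooled <- structure(list(strata = st, K = 2, S = 50, n_drop = 10,
                           covariate_name = "M1"),
                      class = "pooled_estimates")
  expect_equal(pooled_q(pooled)$Q, 0, tolerance = 1e-8)
  # shift one outcome association: Q computed against the hand formula
  st2 <- st
  st2$beta_y_p <- c(0.25, 0.6)
  st2$theta_p <- st2$beta_y_p / st2$beta_x_p
  pooled2 <- structure(list(strata = st2, K = 2, S = 50, n_drop = 10,
                            covariate_name = "M1"),
                       class = "pooled_estimates")
  qres <- pooled_q(pooled2, iterate = FALSE)
  fac <- 1 + 1 / 50
  se_y2 <- st2$U_y + fac * st2$B_y
  se_x2 <- st2$U_x + fac * st2$B_x
  se_th <- sqrt(se_y2) / st2$beta_x_p
  w <- 1 / se_th^2
  th <- sum(w * st2$theta_p) / sum(w)
  expect_equal(qres$theta_hat, th)
  expect_equal(qres$Q,
               sum((st2$beta_y_p - th * st2$beta_x_p)^2 /
                     (se_y2 + th^2 * se_x2)))
})

test_that("the trend test recovers an exact linear trend and rejects tiny-variance noise", {
  st <- data.frame(stratum = 1:5, mbar = 1:5,
                   beta_x_p = rep(1, 5),
                   beta_y_p = 0.2 + 0.1 * (1:5),
                   U_x = rep(1e-8, 5), B_x = rep(0, 5),
                   U_y = rep(1e-8, 5), B_y = rep(0, 5),
                   U_xy = rep(0, 5), B_xy = rep(0, 5),
                   df = rep(50, 5), ci_y_low = 0, ci_y_high = 1,
                   theta_p = 0.2 + 0.1 * (1:5),
                   theta_ci_low = 0, theta_ci_high = 1)
  pooled <- structure(list(strata = st, K = 5, S = 50, n_drop = 10,
                           covariate_name = "M1"),
                      class = "pooled_estimates")
  tr <- trend_test(pooled)
  expect_equal(tr$slope, 0.1, tolerance = 1e-4)
  expect_lt(tr$p_value, 1e-6)
  pooled3 <- pooled
  pooled3$strata <- st[1:2, ]
  pooled3$K <- 2
  expect_error(trend_test(pooled3), "at least 3")
})

test_that("a negative effect trend is detected with the right sign", {
  signs <- vapply(1:5, function(r) {
    sim <- simulate_dataset(1500, "A", 0.4, seed = 830 + r)
    p <- pooled_stratum_estimates(sim$data, "M1", K = 5, S = 20,
                                  seed = 840 + r)
    sign(trend_test(p)$slope)
  }, 0)
  # M1 is a true modifier with positive gamma: estimates rise with M1
  expect_true(all(signs == 1))
})

test_that("pooled estimates converge to the single-fit estimates as perturbations vanish", {
  sim <- simulate_dataset(1000, "A", 0, pure_null = TRUE, seed = 85)
  d <- sim$data
  p <- pooled_stratum_estimates(d, "M4", K = 5, S = 60, n_drop = 2,
                                seed = 86)
  a <- doubly_ranked_strata(d$Z, d$M[, "M4"], proportions = rep(0.2, 5),
                            seed = 87, covariate_name = "M4")
  est <- stratum_associations(d, a)
  # remaining discrepancy reflects residual rank-reshuffling, well inside
  # the per-stratum sampling SEs (~0.25 at this scale)
  expect_lt(max(abs(p$strata$beta_y_p - est$beta_y)), 0.25)
  expect_gt(cor(p$strata$beta_y_p, est$beta_y), 0.8)
})
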