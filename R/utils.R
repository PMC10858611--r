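# Internal numerical and RNG helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state; with seed = NULL the current stream is used (callers inside a
# seeded procedure, e.g. tree growth, pass NULL so one stream drives all
# tie-breaking).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Derive child seeds from a master seed; keeps values in 32-bit range so
# they remain valid arguments to set.seed().
.derive_seeds <- function(seed, k) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Largest-remainder apportionment of n units to the given proportions.
# Deterministic: remainder ties resolved toward earlier strata.
.alloc_sizes <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions > 0))
  proportions <- proportions / sum(proportions)
  quota <- proportions * n
  base <- floor(quota)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Simple linear regression of v on z (with intercept) via centred sums.
# Returns c(beta, se); NA when the regressor is constant. Matches
# summary(lm(v ~ z)) coefficients; used in hot paths where lm() would
# dominate runtime.
.assoc <- function(z, v) {
  n <- length(z)
  if (n < 3L) {
    if (n == 2L && z[1L] != z[2L]) {
      return(c(beta = (v[2L] - v[1L]) / (z[2L] - z[1L]), se = NA_real_))
    }
    return(c(beta = NA_real_, se = NA_real_))
  }
  zc <- z - mean(z)
  vc <- v - mean(v)
  szz <- sum(zc * zc)
  if (szz <= 0) {
    return(c(beta = NA_real_, se = NA_real_))
  }
  beta <- sum(zc * vc) / szz
  rss <- max(sum(vc * vc) - beta^2 * szz, 0)
  c(beta = beta, se = sqrt(rss / ((n - 2) * szz)))
}

# Joint regressions of x on z and y on z sharing the same individuals:
# returns slopes, their SEs and the sampling covariance of the two slope
# estimates, cov(beta_x, beta_y) = sum(e_x e_y) / ((n-2) Szz). The
# covariance is what a one-sample analysis needs to standardize
# beta_y - theta beta_x correctly; with independent samples it is zero.
.assoc_pair <- function(z, x, y) {
  out <- c(beta_x = NA_real_, se_x = NA_real_, beta_y = NA_real_,
           se_y = NA_real_, cov_xy = NA_real_)
  n <- length(z)
  if (n < 3L) {
    return(out)
  }
  zc <- z - mean(z)
  xc <- x - mean(x)
  yc <- y - mean(y)
  czz <- sum(zc * zc)
  if (czz <= 0) {
    return(out)
  }
  czx <- sum(zc * xc)
  czy <- sum(zc * yc)
  bx <- czx / czz
  by <- czy / czz
  rssx <- max(sum(xc * xc) - bx^2 * czz, 0)
  rssy <- max(sum(yc * yc) - by^2 * czz, 0)
  exey <- sum(xc * yc) - czx * czy / czz
  denom <- (n - 2) * czz
  c(beta_x = bx, se_x = sqrt(rssx / denom),
    beta_y = by, se_y = sqrt(rssy / denom),
    cov_xy = exey / denom)
}

# beta and squared SE of v ~ z from raw group sums (n, sums, squared sums,
# cross sum); the group-subtraction trick in the split search feeds this.
.assoc_from_sums <- function(n, sz, szz, sv, svv, szv) {
  if (n < 3) {
    return(c(NA_real_, NA_real_))
  }
  czz <- szz - sz * sz / n
  if (czz <= 0) {
    return(c(NA_real_, NA_real_))
  }
  beta <- (szv - sz * sv / n) / czz
  rss <- max((svv - sv * sv / n) - beta^2 * czz, 0)
  c(beta, rss / ((n - 2) * czz))
}

# Profile-likelihood Q over stratum association summaries: minimises
# sum (by - t bx)^2 / (vy + t^2 vx - 2 t cxy) over the causal parameter.
# Inputs are per-stratum slope vectors with squared SEs and slope
# covariances; all must be finite with vy > 0.
.profile_q <- function(bx, vx, by, vy, cxy) {
  th <- by / bx
  se <- sqrt(vy) / abs(bx)
  w <- 1 / se^2
  t0 <- sum(w * th) / sum(w)
  pad <- 3 * max(se)
  qfun <- function(t) {
    sum((by - t * bx)^2 / pmax(vy + t * t * vx - 2 * t * cxy, 1e-300))
  }
  opt <- stats::optimize(qfun, c(min(th, t0) - pad, max(th, t0) + pad))
  c(Q = opt$objective, theta = opt$minimum)
}

# Flag covariates with heavy ties: the rank-based stratification is defined
# for continuous covariates, and coarse discrete covariates make stratum
# membership mostly a coin flip.
.warn_if_discrete <- function(values, name = "covariate") {
  n <- length(values)
  if (n >= 20L && length(unique(values)) <= max(2L, n %/% 20L)) {
    warning(sprintf(
      "%s takes few distinct values relative to n; rank-based stratification on a discrete covariate should be interpreted with caution (ties broken at random)",
      name
    ), call. = FALSE)
  }
  invisible(NULL)
}
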