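# Fixture builders shared across test files. Everything is generated in
# code; no data files are read from disk except temporaries written by
# the tests themselves.

# Tiny deterministic dataset with named covariates.
make_toy_dataset <- function(n = 40, p = 3, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("M", seq_len(p))))
    Z <- rnorm(n)
    X <- 0.5 * Z + rnorm(n)
    Y <- 0.5 * X + rnorm(n)
    mr_dataset(Z = Z, X = X, Y = Y, M = M)
  })
}

# CSV fixture on disk; returns the path.
write_toy_csv <- function(df, file = tempfile(fileext = ".csv")) {
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  file
}

# Hand-buildable stratum_estimates table for arithmetic oracles
# (summary-level input: no sampling covariance recorded).
make_estimates <- function(beta_x, se_x, beta_y, se_y, n = 10,
                           sigma_xy = NA_real_) {
  out <- data.frame(stratum = seq_along(beta_x), n = n, mbar = NA_real_,
                    beta_x = beta_x, se_x = se_x,
                    beta_y = beta_y, se_y = se_y,
                    sigma_xy = sigma_xy,
                    theta = beta_y / beta_x,
                    se_theta = se_y / abs(beta_x),
                    usable = TRUE)
  class(out) <- c("stratum_estimates", "data.frame")
  out
}
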