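#' @title Collider-robust stratification on a single covariate
#' @description
#' Three ways to cut a sample into strata on a covariate:
#'
#' * **naive** — sort on the covariate and cut into contiguous rank blocks.
#'   If the covariate is causally downstream of the exposure it is a
#'   collider, and naive strata induce instrument-confounder correlation
#'   (collider bias) in stratum-specific IV estimates.
#' * **residual** — regress the covariate on the instrument, and cut on the
#'   residuals, i.e. on an estimate of the counterfactual covariate at
#'   instrument level zero. Valid when the instrument acts on the covariate
#'   linearly and homogeneously.
#' * **doubly-ranked** — rank on the instrument, form consecutive
#'   pre-strata (size 10 by default), rank on the covariate within each
#'   pre-stratum, and assemble strata by collecting equal covariate-rank
#'   slices across pre-strata. Requires only rank preservation: an
#'   individual's covariate rank within their pre-stratum is assumed not to
#'   depend on the instrument. Strata are balanced on the instrument by
#'   construction, avoiding collider bias non-parametrically.
#'
#' All tie-breaking is random and driven by a single seeded stream per
#' call, so assignments are reproducible.
#' @name stratify
NULL

.new_assignment <- function(labels, proportions, method, covariate_name,
                            prestratum_size = NA_integer_) {
  structure(list(labels = as.integer(labels),
                 K = length(proportions),
                 proportions = proportions / sum(proportions),
                 method = method,
                 covariate_name = covariate_name,
                 prestratum_size = prestratum_size),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat(sprintf("stratum_assignment (%s%s): %d strata, sizes %s\n",
              x$method,
              if (!is.na(x$covariate_name)) paste0(" on ", x$covariate_name) else "",
              x$K, paste(tabulate(x$labels, x$K), collapse = "/")))
  invisible(x)
}

#' Naive rank stratification
#'
#' Sorts individuals on the covariate value (ties broken at random) and
#' cuts the sorted order into contiguous blocks with the requested size
#' proportions (largest-remainder rounding).
#'
#' @param values numeric covariate vector.
#' @param proportions positive target size fractions, one per stratum;
#'   normalised to sum to 1.
#' @param seed integer seed for tie-breaking; `NULL` uses the current RNG
#'   stream (for callers that manage their own stream).
#' @param covariate_name optional label stored on the assignment.
#'
#' @return A `stratum_assignment`: per-individual integer labels in
#'   `1..K` plus the stratification metadata.
#' @export
#' @seealso [doubly_ranked_strata()], [residual_strata()]
naive_strata <- function(values, proportions = c(0.5, 0.5), seed = NULL,
                         covariate_name = NA_character_) {
  n <- length(values)
  if (n < 1L) stop("empty covariate vector", call. = FALSE)
  if (any(proportions <= 0)) stop("proportions must be positive", call. = FALSE)
  if (length(proportions) > n) {
    stop("more strata requested than individuals", call. = FALSE)
  }
  .warn_if_discrete(values, if (is.na(covariate_name)) "covariate" else covariate_name)
  sizes <- .alloc_sizes(n, proportions)
  labels <- integer(n)
  ord <- .with_seed(seed, order(values, stats::runif(n)))
  labels[ord] <- rep.int(seq_along(sizes), sizes)
  .new_assignment(labels, proportions, "naive", covariate_name)
}

#' Residual-method stratification
#'
#' Computes ordinary least-squares residuals of the covariate on the
#' instrument (with intercept) and applies [naive_strata()] to the
#' residuals. The residual approximates the covariate value the individual
#' would have at instrument level zero, which is not a function of the
#' instrument and hence not a collider, under a linear homogeneous
#' instrument-covariate model.
#'
#' @param covariate numeric covariate vector.
#' @param instrument numeric instrument vector; must be non-constant.
#' @inheritParams naive_strata
#' @return A `stratum_assignment`.
#' @export
residual_strata <- function(covariate, instrument,
                            proportions = c(0.5, 0.5), seed = NULL,
                            covariate_name = NA_character_) {
  n <- length(covariate)
  if (length(instrument) != n) {
    stop("covariate and instrument must have equal length", call. = FALSE)
  }
  zc <- instrument - mean(instrument)
  szz <- sum(zc^2)
  if (szz <= 0) {
    stop("instrument is constant; residual regression is degenerate",
         call. = FALSE)
  }
  slope <- sum(zc * (covariate - mean(covariate))) / szz
  res <- covariate - mean(covariate) - slope * zc
  out <- naive_strata(res, proportions, seed, covariate_name)
  out$method <- "residual"
  out
}

# Shared engine: given the instrument ordering (with pre-stratum ids
# attached), slice each pre-stratum by within-pre-stratum covariate rank.
# `ordz` is the permutation sorting individuals by instrument; `pre` the
# pre-stratum id in that sorted order. Randomness for covariate
# tie-breaking comes from the current RNG stream.
.doubly_ranked_labels <- function(ordz, pre, covariate, proportions) {
  n <- length(ordz)
  o2 <- order(pre, covariate[ordz], stats::runif(n))
  idx <- ordz[o2]          # individuals sorted by (pre-stratum, covariate)
  pre_sorted <- pre[o2]
  sizes_pre <- tabulate(pre_sorted)
  ranks <- sequence(sizes_pre)
  full <- sizes_pre[1L]
  lab_full <- rep.int(seq_along(proportions), .alloc_sizes(full, proportions))
  labs <- lab_full[ranks]
  last <- length(sizes_pre)
  if (sizes_pre[last] < full) {
    lab_last <- rep.int(seq_along(proportions),
                        .alloc_sizes(sizes_pre[last], proportions))
    sel <- pre_sorted == last
    labs[sel] <- lab_last[ranks[sel]]
  }
  labels <- integer(n)
  labels[idx] <- labs
  labels
}

#' Doubly-ranked stratification
#'
#' Implements the doubly-ranked method for stratifying on a covariate:
#'
#' 1. rank individuals by the instrument (ties at random) and form
#'    consecutive pre-strata of `prestratum_size` individuals (the final
#'    pre-stratum may be smaller);
#' 2. rank individuals within each pre-stratum by the covariate (ties at
#'    random);
#' 3. cut each pre-stratum's covariate-rank range by the target
#'    proportions (largest-remainder rounding within the pre-stratum) and
#'    concatenate the slices across pre-strata: stratum 1 collects the
#'    lowest covariate ranks from every pre-stratum, and so on.
#'
#' Because every stratum draws the same number of individuals from each
#' pre-stratum, the instrument distribution is balanced across strata,
#' which is what prevents collider bias when the covariate is downstream
#' of the exposure.
#'
#' @param instrument numeric instrument vector.
#' @param covariate numeric covariate vector.
#' @param prestratum_size number of individuals per instrument pre-stratum.
#'   The default 10 gives integer slices for the canonical 3:7 / 5:5 / 7:3
#'   splitting proportions.
#' @inheritParams naive_strata
#' @return A `stratum_assignment`.
#' @export
#' @examples
#' a <- doubly_ranked_strata(instrument = 1:20, covariate = 1:20, seed = 1)
#' split(1:20, a$labels) # lower half of each pre-stratum goes to stratum 1
doubly_ranked_strata <- function(instrument, covariate,
                                 proportions = c(0.5, 0.5), seed = NULL,
                                 prestratum_size = 10L,
                                 covariate_name = NA_character_) {
  n <- length(instrument)
  if (n < 1L) stop("empty data", call. = FALSE)
  if (length(covariate) != n) {
    stop("instrument and covariate must have equal length", call. = FALSE)
  }
  if (any(proportions <= 0)) stop("proportions must be positive", call. = FALSE)
  if (prestratum_size < length(proportions)) {
    stop("pre-stratum size must be at least the number of strata",
         call. = FALSE)
  }
  .warn_if_discrete(covariate,
                    if (is.na(covariate_name)) "covariate" else covariate_name)
  labels <- .with_seed(seed, {
    ordz <- order(instrument, stats::runif(n))
    pre <- rep(seq_len(ceiling(n / prestratum_size)),
               each = prestratum_size, length.out = n)
    .doubly_ranked_labels(ordz, pre, covariate, proportions)
  })
  .new_assignment(labels, proportions, "doubly_ranked", covariate_name,
                  as.integer(prestratum_size))
}

#' Doubly-ranked stratification into K equal strata
#'
#' Convenience wrapper around [doubly_ranked_strata()] with `K` equal
#' proportions, e.g. `K = 10` for population deciles of a covariate. With
#' the default pre-stratum size of 10 and `K = 10`, each pre-stratum
#' contributes exactly one individual to each stratum.
#'
#' @param K number of equal-sized strata (at least 2).
#' @inheritParams doubly_ranked_strata
#' @return A `stratum_assignment`.
#' @export
doubly_ranked_deciles <- function(instrument, covariate, K = 10L, seed = NULL,
                                  prestratum_size = 10L,
                                  covariate_name = NA_character_) {
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  doubly_ranked_strata(instrument, covariate,
                       proportions = rep(1 / K, K), seed = seed,
                       prestratum_size = prestratum_size,
                       covariate_name = covariate_name)
}
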