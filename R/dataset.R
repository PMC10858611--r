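#' Assemble an individual-level Mendelian randomization dataset
#'
#' Bundles aligned per-individual vectors of a genetic instrument `Z`
#' (a single variant dosage or a weighted allele score), a continuous
#' exposure `X`, a continuous outcome `Y`, and a matrix `M` of candidate
#' effect-modifying covariates. All downstream stratification, tree and
#' forest routines operate on this container.
#'
#' @param Z numeric instrument vector.
#' @param X numeric exposure vector.
#' @param Y numeric outcome vector.
#' @param M numeric matrix or data frame of candidate covariates with
#'   unique, non-empty column names (may include a copy of the exposure as
#'   a candidate covariate to allow for non-linear exposure effects).
#' @param ids optional individual identifiers; defaults to `1:n`.
#'
#' @return An object of class `mr_dataset`: a list with elements `ids`,
#'   `Z`, `X`, `Y` and `M` (a named numeric matrix).
#' @export
#' @examples
#' d <- mr_dataset(Z = rnorm(5), X = rnorm(5), Y = rnorm(5),
#'                 M = matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("M1", "M2"))))
#' nobs(d)
mr_dataset <- function(Z, X, Y, M, ids = NULL) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  rownames(M) <- NULL
  Z <- unname(as.double(Z))
  X <- unname(as.double(X))
  Y <- unname(as.double(Y))
  n <- length(Z)
  if (n < 1L) {
    stop("dataset must contain at least one individual", call. = FALSE)
  }
  if (length(X) != n || length(Y) != n || nrow(M) != n) {
    stop("Z, X, Y and the rows of M must have identical length", call. = FALSE)
  }
  cn <- colnames(M)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn))) {
    stop("covariate columns must carry unique, non-empty names", call. = FALSE)
  }
  if (anyNA(Z) || anyNA(X) || anyNA(Y) || anyNA(M)) {
    stop("missing values are not allowed; drop incomplete rows before construction",
         call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- seq_len(n)
  }
  if (length(ids) != n || anyDuplicated(ids)) {
    stop("ids must be unique and aligned with the data", call. = FALSE)
  }
  structure(list(ids = ids, Z = Z, X = X, Y = Y, M = M),
            class = "mr_dataset")
}

#' @export
nobs.mr_dataset <- function(object, ...) length(object$Z)

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("mr_dataset: %d individuals, %d candidate covariates (%s)\n",
              nobs(x), ncol(x$M),
              paste(utils::head(colnames(x$M), 5), collapse = ", ")))
  invisible(x)
}

#' @export
`[.mr_dataset` <- function(x, i, ...) {
  structure(list(ids = x$ids[i], Z = x$Z[i], X = x$X[i], Y = x$Y[i],
                 M = x$M[i, , drop = FALSE]),
            class = "mr_dataset")
}

#' Read an MR dataset from a delimited text file
#'
#' Loads a CSV/TSV file with a header and maps named columns onto the
#' instrument, exposure, outcome and covariate roles. Rows containing any
#' missing value in a used column are dropped (complete-case analysis) and
#' the number of dropped rows is reported via `message()`.
#'
#' @param path path to a CSV (`.csv`) or tab-delimited (`.tsv`/`.txt`) file.
#' @param instrument,exposure,outcome column names for the three roles.
#' @param covariates character vector of covariate column names; `NULL`
#'   selects every remaining column.
#' @param include_exposure if `TRUE`, the exposure column is additionally
#'   appended to the covariate matrix so that strata can be formed on the
#'   exposure itself (captures non-linear exposure effects).
#' @param id optional name of an identifier column.
#' @param sep field separator; inferred from the file extension when `NULL`.
#'
#' @return An [mr_dataset].
#' @export
read_mr_dataset <- function(path, instrument, exposure, outcome,
                            covariates = NULL, include_exposure = FALSE,
                            id = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  roles <- c(instrument, exposure, outcome)
  if (is.null(covariates)) {
    covariates <- setdiff(colnames(raw), c(roles, id))
  }
  needed <- unique(c(roles, covariates, id))
  absent <- setdiff(needed, colnames(raw))
  if (length(absent)) {
    stop(sprintf("column(s) not present in %s: %s", path,
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (length(covariates) < 1L) {
    stop("at least one candidate covariate column is required", call. = FALSE)
  }
  used <- raw[, unique(c(roles, covariates)), drop = FALSE]
  for (cl in colnames(used)) {
    if (!is.numeric(used[[cl]])) {
      stop(sprintf("column '%s' is not numeric", cl), call. = FALSE)
    }
  }
  keep <- stats::complete.cases(used)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("dropped %d row(s) with missing values", dropped))
  }
  if (!any(keep)) {
    stop("no complete rows remain after removing missing values", call. = FALSE)
  }
  used <- used[keep, , drop = FALSE]
  M <- as.matrix(used[, covariates, drop = FALSE])
  if (include_exposure && !(exposure %in% covariates)) {
    M <- cbind(M, used[[exposure]])
    colnames(M)[ncol(M)] <- exposure
  }
  ids <- if (is.null(id)) which(keep) else raw[[id]][keep]
  mr_dataset(Z = used[[instrument]], X = used[[exposure]],
             Y = used[[outcome]], M = M, ids = ids)
}

#' Write an MR dataset to CSV
#'
#' Inverse of [read_mr_dataset()]: emits an `id` column followed by the
#' instrument (`Z`), exposure (`X`), outcome (`Y`) and covariate columns.
#'
#' @param data an [mr_dataset].
#' @param path output file path.
#' @export
write_mr_dataset <- function(data, path) {
  stopifnot(inherits(data, "mr_dataset"))
  df <- data.frame(id = data$ids, Z = data$Z, X = data$X, Y = data$Y,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(data$M, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Split a dataset into training and testing subsets
#'
#' @param data an [mr_dataset].
#' @param train_fraction fraction of individuals assigned to the training
#'   subset; the default 2/3 mirrors common practice of fitting the forest
#'   on two-thirds of the sample and evaluating on the held-out third.
#' @param seed integer seed making the partition reproducible.
#'
#' @return A list with elements `train` and `test`, both [mr_dataset]s,
#'   forming a disjoint partition of the input.
#' @export
split_train_test <- function(data, train_fraction = 2 / 3, seed = NULL) {
  stopifnot(inherits(data, "mr_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nobs(data)
  n_train <- as.integer(round(n * train_fraction))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- .with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx)], test = data[sort(setdiff(seq_len(n), idx))])
}

#' Weighted allele score from a variant dosage matrix
#'
#' Collapses per-variant dosages into a single continuous instrument as the
#' per-individual weighted sum of dosages, the standard construction of a
#' polygenic instrument from a set of uncorrelated variants.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns.
#' @param weights numeric vector of per-variant weights (e.g. external
#'   GWAS effect sizes).
#'
#' @return Numeric vector of length `nrow(dosages)`.
#' @export
#' @examples
#' weighted_score(rbind(c(1, 2), c(0, 1)), c(0.5, 1)) # 2.5, 1.0
weighted_score <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(weights)) {
    stop("number of dosage columns must equal the number of weights",
         call. = FALSE)
  }
  drop(dosages %*% as.double(weights))
}
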