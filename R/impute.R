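# The six analysis datasets: dataset 1 neglects missing values; datasets
# 2-6 are independently seeded left-censored imputations in which each
# missing cell is drawn from a normal placed in the low-expression range of
# its sample column (Perseus-style: mean down-shifted by `downshift` sd,
# width `width` sd).

#' Imputation parameters
#'
#' Defaults are the Perseus defaults used for left-censored proteomics
#' imputation: imputed values for a sample column with observed mean `mu` and
#' observed sd `sigma` are drawn from `Normal(mu - downshift*sigma,
#' (width*sigma)^2)`. Imputation is repeated `n_imputations` times with
#' distinct seeds to avoid relying on any one set of fabricated numbers.
#'
#' @param width Sd of the imputation distribution, in units of the observed
#'   sd (default 0.3).
#' @param downshift Downward shift of the imputation mean, in units of the
#'   observed sd (default 1.8).
#' @param n_imputations Number of imputed datasets (default 5, giving six
#'   datasets in total).
#' @param base_seed Base seed; imputed dataset i uses `base_seed + i`.
#' @param scope `"column"` (default; moments per sample column, the Perseus
#'   default) or `"matrix"` (global moments).
#' @return An `imputation_params` object.
#' @export
imputation_params <- function(width = 0.3, downshift = 1.8,
                              n_imputations = 5L, base_seed = 100L,
                              scope = c("column", "matrix")) {
  p <- list(
    width = check_number(width, "width"),
    downshift = check_number(downshift, "downshift", min = 0),
    n_imputations = check_count(n_imputations, "n_imputations"),
    base_seed = check_count(base_seed, "base_seed", min = 0L),
    scope = match.arg(scope)
  )
  if (p$width <= 0) stop_config("width", "must be > 0")
  structure(p, class = "imputation_params")
}

new_dataset <- function(id, kind, matrix, seed = NA_integer_) {
  structure(list(id = as.integer(id), kind = kind, seed = seed, matrix = matrix),
            class = "pc_dataset")
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat(sprintf("Dataset %d (%s): %d proteins x %d samples, %d missing\n",
              x$id, x$kind, nrow(x$matrix), ncol(x$matrix), sum(is.na(x$matrix))))
  invisible(x)
}

#' Dataset 1: neglect missing values
#'
#' The log2 matrix unchanged, with missing values left missing so that each
#' per-protein test uses only the observed measurements.
#'
#' @param logm Log2 matrix with `NA` for missing.
#' @return A dataset of kind `missing_neglect` with id 1.
#' @export
build_missing_dataset <- function(logm) {
  stopifnot(is.matrix(logm), is.numeric(logm))
  new_dataset(1L, "missing_neglect", logm)
}

#' One left-censored imputation
#'
#' Replaces every missing entry of each sample column by an independent draw
#' from `Normal(mu_s - downshift*sigma_s, (width*sigma_s)^2)`, where `mu_s`
#' and `sigma_s` are the mean and sample sd (n-1 denominator) of the observed
#' values in that column (or of the whole matrix when `scope = "matrix"`).
#' Observed entries are never touched; draws are not truncated. Deterministic
#' given the seed.
#'
#' @param logm Log2 matrix with `NA` for missing.
#' @param params [imputation_params()].
#' @param seed Integer seed for this imputation.
#' @param id Dataset id to assign (>= 2 in a collection).
#' @return A dataset of kind `imputed` with no missing entries.
#' @export
impute_left_censored <- function(logm, params = imputation_params(), seed,
                                 id = 2L) {
  stopifnot(is.matrix(logm), is.numeric(logm), inherits(params, "imputation_params"))
  seed <- check_count(seed, "seed", min = 0L)
  n_obs <- colSums(!is.na(logm))
  if (any(n_obs < 2L)) {
    stop("imputation error: sample(s) with fewer than 2 observed values (sd undefined): ",
         paste(colnames(logm)[n_obs < 2L], collapse = ", "), call. = FALSE)
  }
  out <- logm
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (params$scope == "matrix") {
    mu <- rep(mean(logm, na.rm = TRUE), ncol(logm))
    sigma <- rep(stats::sd(as.vector(logm), na.rm = TRUE), ncol(logm))
  } else {
    mu <- colMeans(logm, na.rm = TRUE)
    sigma <- apply(logm, 2, stats::sd, na.rm = TRUE)
  }
  for (j in seq_len(ncol(out))) {
    miss <- which(is.na(out[, j]))
    if (length(miss)) {
      out[miss, j] <- stats::rnorm(length(miss),
                                   mean = mu[j] - params$downshift * sigma[j],
                                   sd = params$width * sigma[j])
    }
  }
  new_dataset(id, "imputed", out, seed = seed)
}

#' Build the full dataset collection
#'
#' Dataset 1 (missing values neglected) plus `n_imputations` independently
#' seeded imputed datasets (seeds `base_seed + 1 ... base_seed + n`), six
#' datasets in total at the defaults.
#'
#' @inheritParams impute_left_censored
#' @return A `dataset_collection`: list with `datasets` (ordered list) and
#'   `params`.
#' @export
build_dataset_collection <- function(logm, params = imputation_params()) {
  ds <- vector("list", 1L + params$n_imputations)
  ds[[1]] <- build_missing_dataset(logm)
  for (i in seq_len(params$n_imputations)) {
    ds[[i + 1L]] <- impute_left_censored(logm, params,
                                         seed = params$base_seed + i,
                                         id = i + 1L)
  }
  structure(list(datasets = ds, params = params), class = "dataset_collection")
}

#' @export
print.dataset_collection <- function(x, ...) {
  cat(sprintf("Dataset collection: %d datasets (1 missing-neglect + %d imputed)\n",
              length(x$datasets), x$params$n_imputations))
  cat(sprintf("  imputation: width %.2g sd, downshift %.2g sd, scope %s, seeds %s\n",
              x$params$width, x$params$downshift, x$params$scope,
              paste(range(x$params$base_seed + seq_len(x$params$n_imputations)),
                    collapse = "-")))
  invisible(x)
}
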