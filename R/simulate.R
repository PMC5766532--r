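new_missing_data <- function(complete, mask, meta) {
  observed <- complete
  observed[mask] <- NA_real_
  structure(list(complete = complete, mask = mask, observed = observed,
                 meta = meta),
            class = "missing_data")
}

#' @export
print.missing_data <- function(x, ...) {
  cat(sprintf("<missing_data> %s: %d x %d, %d masked entries (%.1f%%)\n",
              x$meta$kind, nrow(x$complete), ncol(x$complete),
              sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Plant missing-completely-at-random entries in a complete matrix
#'
#' Masks exactly `round(proportion * n * p)` entries (banker's rounding),
#' drawn uniformly without replacement over all matrix positions. This is
#' the random-element generator appropriate for emulating MCAR/MAR
#' missingness from acquisition noise or preprocessing artefacts.
#'
#' @param complete Complete abundance matrix (no missing entries).
#' @param proportion Fraction of entries to mask, in `[0, 1)`.
#' @param seed Integer seed; the mask is reproducible from it.
#' @return A `missing_data` object: `complete`, logical `mask` (`TRUE` =
#'   masked), `observed` (complete with masked entries set to `NA`), and
#'   `meta` (generator, parameters, seed).
#' @export
#' @examples
#' d <- generate_complete(synth_spec(n_samples = 10, n_metabolites = 10,
#'                                   seed = 1))
#' ds <- generate_mcar(d$matrix, 0.25, seed = 2)
#' sum(ds$mask)  # 25
generate_mcar <- function(complete, proportion, seed = NULL) {
  complete <- as_abundance(complete, allow_missing = FALSE)
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      proportion < 0 || proportion >= 1) {
    stop("proportion must lie in [0, 1)", call. = FALSE)
  }
  seed <- check_seed(seed)
  n_mask <- round(proportion * length(complete))
  mask <- matrix(FALSE, nrow(complete), ncol(complete),
                 dimnames = dimnames(complete))
  if (n_mask > 0) {
    idx <- withr::with_seed(seed, sample.int(length(complete), n_mask))
    mask[idx] <- TRUE
  }
  new_missing_data(complete, mask,
                   list(kind = "mcar", proportion = proportion,
                        n_masked = n_mask, seed = seed))
}

#' Plant left-censored missing-not-at-random entries
#'
#' Emulates below-LOQ missingness: `round(var_proportion * n_metabolites)`
#' metabolites are selected uniformly as "missing variables"; for each, a
#' censoring quantile `q` is drawn uniformly from
#' `[cutoff_low, cutoff_high]` and every entry strictly below that
#' variable's empirical `q`-quantile (type-7) is masked. Missingness is
#' therefore concentrated exactly in the low tail of each censored
#' variable: the largest masked value is always smaller than the smallest
#' surviving one.
#'
#' @param complete Complete abundance matrix.
#' @param var_proportion Fraction of metabolites to censor, in `[0, 1]`.
#' @param cutoff_low,cutoff_high Bounds of the uniform censoring-quantile
#'   draw (defaults 0.30 and 0.60). Setting both to the same value forces
#'   a fixed cutoff.
#' @param seed Integer seed.
#' @return A `missing_data` object; `meta$cutoffs` records the quantile
#'   drawn for each missing variable and `meta$missing_variables` their
#'   IDs.
#' @export
generate_mnar <- function(complete, var_proportion, cutoff_low = 0.30,
                          cutoff_high = 0.60, seed = NULL) {
  complete <- as_abundance(complete, allow_missing = FALSE)
  if (!is.numeric(var_proportion) || length(var_proportion) != 1L ||
      var_proportion < 0 || var_proportion > 1) {
    stop("var_proportion must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(cutoff_low) || !is.numeric(cutoff_high) ||
      cutoff_low < 0 || cutoff_high >= 1 || cutoff_low > cutoff_high) {
    stop("need 0 <= cutoff_low <= cutoff_high < 1", call. = FALSE)
  }
  seed <- check_seed(seed)
  p <- ncol(complete)
  n_vars <- round(var_proportion * p)
  mask <- matrix(FALSE, nrow(complete), p, dimnames = dimnames(complete))
  cutoffs <- numeric(0)
  vars <- integer(0)
  if (n_vars > 0) {
    withr::with_seed(seed, {
      vars <- sort(sample.int(p, n_vars))
      cutoffs <- runif(n_vars, cutoff_low, cutoff_high)
    })
    names(cutoffs) <- colnames(complete)[vars]
    for (i in seq_along(vars)) {
      j <- vars[i]
      qv <- quantile(complete[, j], probs = cutoffs[i], names = FALSE,
                     type = 7)
      mask[, j] <- complete[, j] < qv
      if (all(mask[, j])) {
        stop(sprintf("censoring left metabolite '%s' with no observed values",
                     colnames(complete)[j]), call. = FALSE)
      }
    }
  }
  new_missing_data(complete, mask,
                   list(kind = "mnar", var_proportion = var_proportion,
                        cutoff_low = cutoff_low, cutoff_high = cutoff_high,
                        cutoffs = cutoffs,
                        missing_variables = colnames(complete)[vars],
                        seed = seed))
}

#' Standard grids of missing proportions for benchmarking
#'
#' MCAR benchmarks sweep the fraction of masked entries from 2.5% to 50%
#' in steps of 2.5%; MNAR benchmarks sweep the fraction of censored
#' metabolites from 4% to 80% in steps of 4%.
#'
#' @param kind `"mcar"` or `"mnar"`.
#' @return A numeric vector of 20 strictly increasing proportions.
#' @export
proportion_grid <- function(kind = c("mcar", "mnar")) {
  kind <- match.arg(kind)
  step <- if (kind == "mcar") 0.025 else 0.04
  seq_len(20L) * step
}
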