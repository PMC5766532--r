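#' Iterative random-forest imputation
#'
#' missForest-style chained regression: missing entries start at the
#' column mean; metabolites are visited in order of ascending missing
#' count; for each, a regression forest is fit with the metabolite's
#' observed entries as outcome and all other metabolites as predictors,
#' and its missing entries are replaced by forest predictions. Sweeps
#' repeat until the scaled sum of squared changes of the imputed values
#' first increases, at which point the previous sweep's matrix is
#' returned (or until `max_iter` sweeps, with a warning recorded in the
#' result).
#'
#' Forests are grown with [ranger::ranger()] on a single thread, with
#' per-fit seeds drawn from R's RNG, so a given `seed` reproduces the
#' imputation bit for bit.
#'
#' @param x Abundance matrix with missing entries (at least 2 columns;
#'   every column needs at least one observed entry).
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum number of sweeps (default 10).
#' @param seed Integer seed (required).
#' @return An `imputation` object; `params` records `n_trees`, the number
#'   of sweeps performed, and whether the stopping rule triggered before
#'   `max_iter`.
#' @export
impute_rf <- function(x, n_trees = 100, max_iter = 10, seed = NULL) {
  x <- as_abundance(x)
  n_trees <- check_count(n_trees, 1L)
  max_iter <- check_count(max_iter, 1L)
  seed <- check_seed(seed)
  if (ncol(x) < 2L) {
    stop("random-forest imputation needs at least 2 metabolites",
         call. = FALSE)
  }
  n_miss <- colSums(is.na(x))
  if (any(n_miss == nrow(x))) {
    stop(sprintf("metabolite '%s' has no observed values",
                 colnames(x)[which(n_miss == nrow(x))[1L]]), call. = FALSE)
  }
  miss <- is.na(x)
  if (!any(miss)) {
    return(new_imputation(x, "rf",
                          params = list(n_trees = n_trees, sweeps = 0L,
                                        stopped_early = TRUE),
                          seed = seed))
  }
  visit <- order(n_miss)
  visit <- visit[n_miss[visit] > 0L]
  w <- x
  col_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) w[miss[, j], j] <- col_means[j]
  # neutral predictor names: ranger's interface chokes on arbitrary IDs
  vn <- sprintf("V%d", seq_len(ncol(x)))
  withr::with_seed(seed, {
    diff_prev <- Inf
    stopped_early <- FALSE
    sweeps <- 0L
    while (sweeps < max_iter) {
      sweeps <- sweeps + 1L
      w_new <- w
      for (j in visit) {
        ok <- !miss[, j]
        train <- as.data.frame(w_new[ok, -j, drop = FALSE])
        names(train) <- vn[-j]
        fit <- ranger::ranger(x = train, y = w_new[ok, j],
                              num.trees = n_trees,
                              seed = sample.int(.Machine$integer.max, 1L),
                              num.threads = 1L)
        test <- as.data.frame(w_new[!ok, -j, drop = FALSE])
        names(test) <- vn[-j]
        w_new[!ok, j] <- predict(fit, data = test,
                                 num.threads = 1L)$predictions
      }
      diff_cur <- sum((w_new[miss] - w[miss])^2) / sum(w_new[miss]^2)
      if (diff_cur > diff_prev) {
        # keep the previous sweep's matrix, per the first-increase rule
        stopped_early <- TRUE
        break
      }
      w <- w_new
      diff_prev <- diff_cur
    }
  })
  if (!stopped_early && sweeps == max_iter) {
    warning(sprintf("random-forest imputation stopped at max_iter = %d before the update criterion increased",
                    max_iter))
  }
  new_imputation(w, "rf",
                 params = list(n_trees = n_trees, sweeps = sweeps,
                               stopped_early = stopped_early),
                 seed = seed)
}
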