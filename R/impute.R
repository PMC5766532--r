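IMPUTE_METHODS <- c("zero", "hm", "mean", "median", "knn", "svd", "rf",
                    "qrilc")

new_imputation <- function(imputed, method, params = list(), seed = NULL) {
  structure(list(imputed = imputed, method = method, params = params,
                 seed = seed),
            class = "imputation")
}

#' @export
print.imputation <- function(x, ...) {
  cat(sprintf("<imputation> method '%s': %d x %d matrix\n", x$method,
              nrow(x$imputed), ncol(x$imputed)))
  invisible(x)
}

#' Impute missing abundances with a named method
#'
#' Single entry point over the eight supported methods. Every method
#' leaves observed entries bit-identical, preserves the matrix shape, and
#' returns a matrix without missing values.
#'
#' * `"zero"`, `"hm"`, `"mean"`, `"median"` — per-metabolite constants
#'   (zero, half of the observed minimum, observed mean, observed median);
#'   see [impute_constant()].
#' * `"knn"` — mean of the k nearest *samples*; see [impute_knn()].
#' * `"svd"` — iterative rank-k SVD reconstruction; see [impute_svd()].
#' * `"rf"` — iterative random-forest regression; see [impute_rf()].
#' * `"qrilc"` — truncated-normal draws for left-censored data; see
#'   [impute_qrilc()].
#'
#' For missing values from random acquisition/preprocessing noise
#' (MCAR/MAR), `"rf"` is the recommended method; for left-censored
#' below-LOQ missingness (MNAR), `"qrilc"` is (see [recommend_method()]).
#'
#' @param x Abundance matrix with missing entries, or a `missing_data`
#'   object (its `observed` component is used).
#' @param method One of `r paste0('"', IMPUTE_METHODS, '"', collapse = ", ")`.
#' @param ... Method-specific parameters (`k`, `n_pcs`, `n_trees`, ...).
#' @param seed Integer seed; required for the stochastic methods `"rf"`
#'   and `"qrilc"`, ignored by the deterministic ones.
#' @return An object of class `imputation` with elements `imputed`
#'   (complete matrix), `method`, `params`, and `seed`.
#' @export
#' @examples
#' m <- matrix(c(2, 4, NA, 1, 2, 3), nrow = 3)
#' impute(m, "hm")$imputed[3, 1]  # half of min(2, 4) = 1
impute <- function(x, method = IMPUTE_METHODS, ..., seed = NULL) {
  method <- match.arg(method)
  if (inherits(x, "missing_data")) x <- x$observed
  switch(method,
    zero = ,
    hm = ,
    mean = ,
    median = impute_constant(x, strategy = method),
    knn = impute_knn(x, ...),
    svd = impute_svd(x, ...),
    rf = impute_rf(x, ..., seed = seed),
    qrilc = impute_qrilc(x, ..., seed = seed))
}

#' Constant-value imputation (zero, half-minimum, mean, median)
#'
#' Replaces each missing entry with a per-metabolite constant computed
#' from that metabolite's observed entries: `0`, half of the minimum
#' (the conventional stand-in for a value below the LOQ), the mean, or the
#' median.
#'
#' @param x Abundance matrix with missing entries.
#' @param strategy One of `"zero"`, `"hm"`, `"mean"`, `"median"`.
#' @return An `imputation` object.
#' @export
impute_constant <- function(x, strategy = c("zero", "hm", "mean",
                                            "median")) {
  strategy <- match.arg(strategy)
  x <- as_abundance(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (!any(miss)) next
    if (strategy != "zero" && all(miss)) {
      stop(sprintf("metabolite '%s' has no observed values; cannot impute with '%s'",
                   colnames(x)[j], strategy), call. = FALSE)
    }
    obs <- x[!miss, j]
    out[miss, j] <- switch(strategy,
                           zero = 0,
                           hm = min(obs) / 2,
                           mean = mean(obs),
                           median = median(obs))
  }
  new_imputation(out, strategy)
}

#' k-nearest-sample imputation
#'
#' For each sample with missing entries, Euclidean distances to every
#' other sample are computed over the variables observed in *both*
#' samples and normalised by the number of shared variables (so samples
#' with different missingness patterns are comparable). Each missing
#' entry is then imputed as the unweighted mean of that entry in the `k`
#' nearest samples that observed it. When no eligible neighbour exists
#' the metabolite's observed mean is used.
#'
#' Searching for nearest *samples* (rather than nearest metabolites, the
#' convention inherited from microarray data with tens of thousands of
#' co-expressed genes) suits metabolomics tables, which are much wider in
#' samples than in metabolites.
#'
#' @param x Abundance matrix with missing entries.
#' @param k Number of neighbours (default 10).
#' @return An `imputation` object.
#' @export
impute_knn <- function(x, k = 10) {
  x <- as_abundance(x)
  k <- check_count(k, 1L)
  n <- nrow(x)
  if (n < 2L) stop("kNN imputation needs at least 2 samples", call. = FALSE)
  out <- x
  miss <- is.na(x)
  need <- which(rowSums(miss) > 0)
  col_means <- colMeans(x, na.rm = TRUE)
  obs <- !miss
  for (i in need) {
    d <- rep(Inf, n)
    for (t in seq_len(n)) {
      if (t == i) next
      shared <- obs[i, ] & obs[t, ]
      if (any(shared)) {
        d[t] <- sqrt(mean((x[i, shared] - x[t, shared])^2))
      }
    }
    for (j in which(miss[i, ])) {
      cand <- which(obs[, j] & is.finite(d))
      if (!length(cand)) {
        if (is.nan(col_means[j])) {
          stop(sprintf("metabolite '%s' has no observed values",
                       colnames(x)[j]), call. = FALSE)
        }
        out[i, j] <- col_means[j]
        next
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(x[nb, j])
    }
  }
  new_imputation(out, "knn", params = list(k = k))
}
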