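# Scoring imputations against ground truth.
#
# All metrics compare an imputed matrix with the complete matrix it came
# from, over the mask of entries that were made missing.

zscore_pair <- function(complete, imputed) {
  m <- colMeans(complete)
  s <- col_sds(complete)
  if (any(s == 0)) {
    stop(sprintf("metabolite '%s' has zero variance in the complete matrix",
                 colnames(complete)[which(s == 0)[1L]]), call. = FALSE)
  }
  list(complete = sweep(sweep(complete, 2L, m), 2L, s, "/"),
       imputed = sweep(sweep(imputed, 2L, m), 2L, s, "/"))
}

check_eval_triplet <- function(complete, imputed, mask) {
  complete <- as_abundance(complete, allow_missing = FALSE)
  imputed <- as_abundance(imputed, allow_missing = FALSE)
  if (!is.logical(mask) || !identical(dim(mask), dim(complete))) {
    stop("mask must be a logical matrix with the same shape", call. = FALSE)
  }
  if (!identical(dim(imputed), dim(complete))) {
    stop("complete and imputed matrices must have the same shape",
         call. = FALSE)
  }
  list(complete = complete, imputed = imputed, mask = mask)
}

#' Normalised root mean squared imputation error
#'
#' \deqn{NRMSE = \sqrt{mean((X^{true} - X^{imp})^2) / var(X^{true})}}
#' evaluated over the masked entries only. With `zscore = TRUE` (default)
#' both matrices are first column-standardised using the *complete*
#' matrix's means and SDs, so metabolites measured on large abundance
#' scales do not dominate and the metric isolates imputation error.
#' 0 means perfect recovery; values near 1 mean the imputation is no more
#' informative than the variable mean.
#'
#' @param complete Ground-truth matrix (no missing entries).
#' @param imputed Imputed matrix (or [impute()] result); must equal
#'   `complete` off-mask.
#' @param mask Logical matrix, `TRUE` where entries were made missing (at
#'   least 2 such entries).
#' @param zscore Column-standardise before scoring. Default `TRUE`.
#' @return A non-negative scalar.
#' @export
nrmse <- function(complete, imputed, mask, zscore = TRUE) {
  tr <- check_eval_triplet(complete, imputed, mask)
  check_flag(zscore)
  if (sum(tr$mask) < 2L) {
    stop("mask must contain at least 2 entries", call. = FALSE)
  }
  if (zscore) {
    z <- zscore_pair(tr$complete, tr$imputed)
    tr$complete <- z$complete
    tr$imputed <- z$imputed
  }
  truth <- tr$complete[tr$mask]
  est <- tr$imputed[tr$mask]
  v <- var(truth)
  if (v == 0) stop("masked true entries have zero variance", call. = FALSE)
  sqrt(mean((truth - est)^2) / v)
}

#' Per-metabolite NRMSE over the missing variables
#'
#' Applies the [nrmse()] formula column-wise to each metabolite that
#' contains masked entries; this is the input to the sum-of-ranks
#' comparison ([sor()]). Columns with fewer than 2 masked entries or with
#' zero variance of the masked truth cannot be scored: they get `NA` with
#' a warning and are excluded from ranking.
#'
#' @inheritParams nrmse
#' @return A named numeric vector over the metabolites that contain
#'   masked entries.
#' @export
nrmse_per_variable <- function(complete, imputed, mask, zscore = TRUE) {
  tr <- check_eval_triplet(complete, imputed, mask)
  check_flag(zscore)
  if (zscore) {
    z <- zscore_pair(tr$complete, tr$imputed)
    tr$complete <- z$complete
    tr$imputed <- z$imputed
  }
  cols <- which(colSums(tr$mask) > 0L)
  out <- setNames(rep(NA_real_, length(cols)),
                  colnames(tr$complete)[cols])
  for (idx in seq_along(cols)) {
    j <- cols[idx]
    mm <- tr$mask[, j]
    if (sum(mm) < 2L) {
      warning(sprintf("metabolite '%s' has fewer than 2 masked entries; NRMSE undefined",
                      colnames(tr$complete)[j]))
      next
    }
    truth <- tr$complete[mm, j]
    v <- var(truth)
    if (v == 0) {
      warning(sprintf("masked entries of metabolite '%s' have zero variance; NRMSE undefined",
                      colnames(tr$complete)[j]))
      next
    }
    out[idx] <- sqrt(mean((truth - tr$imputed[mm, j])^2) / v)
  }
  out
}

#' NRMSE-based sum of ranks across imputation methods
#'
#' For each missing variable, methods are ranked by per-variable NRMSE
#' (rank 1 = most accurate, ties receive average ranks); each method's
#' ranks are then summed over the missing variables:
#' \deqn{SOR = \sum_{i=1}^{M} Rank_i(NRMSE)}
#' This non-parametric summary is preferred over pooled NRMSE for
#' left-censored data, where the skewed error distribution would bias a
#' direct mean. With `J` methods and `M` variables the SOR values always
#' sum to `M * J * (J + 1) / 2`.
#'
#' @param per_variable_nrmse Named list mapping method name to the vector
#'   returned by [nrmse_per_variable()]; all vectors must cover the same
#'   missing variables. Variables undefined (`NA`) for any method are
#'   dropped from the ranking with a warning.
#' @return A named numeric vector of SOR values, one per method.
#' @export
sor <- function(per_variable_nrmse) {
  if (!is.list(per_variable_nrmse) || length(per_variable_nrmse) < 2L ||
      is.null(names(per_variable_nrmse))) {
    stop("need a named list of per-variable NRMSE vectors for >= 2 methods",
         call. = FALSE)
  }
  nms <- lapply(per_variable_nrmse, names)
  if (!all(vapply(nms[-1L], identical, logical(1L), nms[[1L]]))) {
    stop("all methods must share the same missing-variable set",
         call. = FALSE)
  }
  mat <- do.call(cbind, per_variable_nrmse)  # variables x methods
  ok <- rowSums(is.na(mat)) == 0L
  if (!all(ok)) {
    warning(sprintf("%d missing variable(s) with undefined NRMSE excluded from SOR",
                    sum(!ok)))
    mat <- mat[ok, , drop = FALSE]
  }
  if (nrow(mat) == 0L) stop("no rankable missing variables", call. = FALSE)
  ranks <- t(apply(mat, 1L, rank))  # average ranks on ties
  colSums(ranks)
}

#' Procrustes residual between two score configurations
#'
#' Symmetric Procrustes error: both configurations are centred and
#' rescaled to unit sum of squares, then superimposed by the optimal
#' orthogonal rotation/reflection and isotropic scaling; the residual sum
#' of squares is returned. It lies in `[0, 1]` and is 0 exactly when the
#' two configurations are similarity-equivalent (equal up to translation,
#' rotation, reflection, and uniform scaling).
#'
#' @param target,rotated Numeric matrices of coordinates (rows = samples).
#' @return Scalar in `[0, 1]`.
#' @export
procrustes_error <- function(target, rotated) {
  target <- as.matrix(target)
  rotated <- as.matrix(rotated)
  if (!identical(dim(target), dim(rotated))) {
    stop("configurations must have the same dimensions", call. = FALSE)
  }
  if (all(col_sds(target) == 0) || all(col_sds(rotated) == 0)) {
    stop("degenerate (zero-variance) score configuration", call. = FALSE)
  }
  vegan::procrustes(target, rotated, symmetric = TRUE)$ss
}

pca_scores <- function(x, n_pcs) {
  prcomp(x, center = TRUE, scale. = TRUE)$x[, seq_len(n_pcs), drop = FALSE]
}

#' PCA-Procrustes error of an imputed matrix
#'
#' How much the imputation distorted the overall sample distribution:
#' PCA score configurations (top `n_pcs` components of the
#' column-standardised matrices) are computed for the complete and the
#' imputed matrix and compared with [procrustes_error()]. Smaller is
#' better; 0 means the imputed data reproduces the original sample map
#' exactly (up to a similarity transform, which PCA's sign/rotation
#' ambiguity makes irrelevant).
#'
#' @param complete Ground-truth matrix.
#' @param imputed Imputed matrix (or [impute()] result).
#' @param n_pcs Number of principal components (default 2, which carry
#'   the most variance).
#' @return Scalar in `[0, 1]`.
#' @export
pca_procrustes <- function(complete, imputed, n_pcs = 2) {
  complete <- as_abundance(complete, allow_missing = FALSE)
  imputed <- as_abundance(imputed, allow_missing = FALSE)
  n_pcs <- check_count(n_pcs, 1L)
  if (n_pcs > min(dim(complete))) {
    stop("n_pcs exceeds the matrix dimensions", call. = FALSE)
  }
  procrustes_error(pca_scores(complete, n_pcs), pca_scores(imputed, n_pcs))
}

#' PLS-DA-Procrustes error of an imputed matrix
#'
#' Supervised analogue of [pca_procrustes()]: PLS-DA score
#' configurations (group indicator response, standardised predictors,
#' `n_comp` components, NIPALS fit via [mixOmics::plsda()]) are computed
#' for the complete and the imputed matrix and compared with
#' [procrustes_error()].
#'
#' @inheritParams pca_procrustes
#' @param groups Two-level factor of sample labels (each group needs at
#'   least 3 samples).
#' @param n_comp Number of PLS components (default 2).
#' @return Scalar in `[0, 1]`.
#' @export
pls_procrustes <- function(complete, imputed, groups, n_comp = 2) {
  complete <- as_abundance(complete, allow_missing = FALSE)
  imputed <- as_abundance(imputed, allow_missing = FALSE)
  g <- as_groups(groups, complete, min_per_group = 3L)
  n_comp <- check_count(n_comp, 1L)
  sc <- function(x) {
    fit <- mixOmics::plsda(x, g, ncomp = n_comp, scale = TRUE)
    unname(fit$variates$X)
  }
  procrustes_error(sc(complete), sc(imputed))
}

#' Correlation of log t-test p-values before and after imputation
#'
#' How well univariate statistics survive imputation: per metabolite, a
#' two-sample Student's t-test (pooled variance by default) between the
#' two groups is run on the complete and on the imputed matrix; the
#' Pearson correlation between the two vectors of log p-values is
#' returned (p-values are log-transformed because of their skew; Pearson
#' r is invariant to the log base). 1 means the imputation left the
#' univariate results untouched.
#'
#' @inheritParams pls_procrustes
#' @param restrict_to Optional metabolite IDs or column indices to score
#'   (e.g. the censored variables of an MNAR simulation); default all.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student's t-test. Default `FALSE`.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
logp_correlation <- function(complete, imputed, groups, restrict_to = NULL,
                             welch = FALSE) {
  complete <- as_abundance(complete, allow_missing = FALSE)
  imputed <- as_abundance(imputed, allow_missing = FALSE)
  g <- as_groups(groups, complete, min_per_group = 3L)
  check_flag(welch)
  cols <- seq_len(ncol(complete))
  if (!is.null(restrict_to)) {
    cols <- if (is.character(restrict_to)) {
      match(restrict_to, colnames(complete))
    } else {
      as.integer(restrict_to)
    }
    if (anyNA(cols) || any(cols < 1L | cols > ncol(complete))) {
      stop("restrict_to refers to unknown metabolites", call. = FALSE)
    }
  }
  if (length(cols) < 3L) {
    stop("need at least 3 metabolites in scope", call. = FALSE)
  }
  pval <- function(x, j) {
    tryCatch(
      t.test(x[g == levels(g)[1L], j], x[g == levels(g)[2L], j],
             var.equal = !welch)$p.value,
      error = function(e) NA_real_)
  }
  p_true <- vapply(cols, function(j) pval(complete, j), numeric(1L))
  p_imp <- vapply(cols, function(j) pval(imputed, j), numeric(1L))
  ok <- is.finite(p_true) & is.finite(p_imp) & p_true > 0 & p_imp > 0
  if (!all(ok)) {
    warning(sprintf("%d metabolite(s) dropped from log-p correlation (degenerate t-test)",
                    sum(!ok)))
  }
  if (sum(ok) < 3L) {
    stop("fewer than 3 metabolites with valid t-tests", call. = FALSE)
  }
  cor(log(p_true[ok]), log(p_imp[ok]))
}
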