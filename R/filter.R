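#' Filter unreliable missing variables (80% rule / modified 80% rule)
#'
#' The plain 80% rule drops a metabolite when its overall non-missing
#' fraction falls below `threshold`. The modified (group-wise) rule is
#' laxer: a metabolite is dropped only when its non-missing fraction is
#' below `threshold` in *every* biological group, so a compound that is
#' well observed in one group — a potential differential metabolite that
#' may simply sit below the LOQ in the other group — is retained.
#'
#' A metabolite exactly at the threshold is kept (exclusion applies to
#' fractions strictly below it).
#'
#' @param x Abundance matrix, possibly with missing entries.
#' @param groups Two-level factor of group labels (required when
#'   `groupwise = TRUE`).
#' @param threshold Minimum non-missing fraction, in `[0, 1]`. Default 0.8.
#' @param groupwise Apply the modified (group-wise) rule. Default `TRUE`
#'   when groups are given.
#' @return A list of class `filter_result`: `filtered` (matrix with only
#'   the kept columns, original order), `kept_indices`, `dropped_ids`, and
#'   `threshold`.
#' @export
#' @examples
#' m <- matrix(c(1, NA, 3, 4, NA, NA, 7, 8), nrow = 4,
#'             dimnames = list(paste0("S", 1:4), c("M1", "M2")))
#' g <- factor(c("a", "a", "b", "b"))
#' filter_missing_variables(m, g, threshold = 0.8)$dropped_ids
filter_missing_variables <- function(x, groups = NULL, threshold = 0.8,
                                     groupwise = !is.null(groups)) {
  x <- as_abundance(x)
  check_flag(groupwise)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  obs <- !is.na(x)
  if (groupwise) {
    if (is.null(groups)) {
      stop("groupwise filtering requires group labels", call. = FALSE)
    }
    # any number of groups is fine here (one group = plain rule);
    # the two-group requirement belongs to the t-test/PLS operations
    g <- factor(groups)
    if (length(g) != nrow(x)) {
      stop("groups must have one label per sample", call. = FALSE)
    }
    frac <- vapply(levels(g), function(lv) {
      colMeans(obs[g == lv, , drop = FALSE])
    }, numeric(ncol(x)))
    frac <- matrix(frac, nrow = ncol(x))  # vapply drops dim when p == 1
    # keep if adequate in at least one group
    keep <- rowSums(frac >= threshold) > 0L
  } else {
    keep <- colMeans(obs) >= threshold
  }
  structure(list(filtered = x[, keep, drop = FALSE],
                 kept_indices = which(unname(keep)),
                 dropped_ids = colnames(x)[!keep],
                 threshold = threshold),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> kept %d, dropped %d metabolites (threshold %.0f%%)\n",
              length(x$kept_indices), length(x$dropped_ids),
              100 * x$threshold))
  if (length(x$dropped_ids)) {
    cat(" dropped:", paste(x$dropped_ids, collapse = ", "), "\n")
  }
  invisible(x)
}
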