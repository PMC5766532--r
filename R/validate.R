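# Internal coercion/validation for the two core containers.
#
# An abundance matrix is a plain numeric matrix, samples in rows and
# metabolites in columns, with unique dimnames. Group labels are a factor
# with exactly two levels, aligned with the matrix rows.

as_abundance <- function(x, allow_missing = TRUE,
                         arg = deparse(substitute(x))) {
  if (inherits(x, "imputation")) x <- x$imputed
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (samples x metabolites)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("M%d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("'%s' has duplicated sample IDs", arg), call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("'%s' has duplicated metabolite IDs", arg), call. = FALSE)
  }
  obs <- x[!is.na(x)]
  if (!all(is.finite(obs))) {
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  }
  if (!allow_missing && anyNA(x)) {
    stop(sprintf("'%s' must not contain missing values", arg), call. = FALSE)
  }
  x
}

as_groups <- function(groups, x, min_per_group = 1,
                      arg = deparse(substitute(groups))) {
  if (is.null(groups)) stop(sprintf("'%s' is required", arg), call. = FALSE)
  g <- factor(groups)
  if (length(g) != nrow(x)) {
    stop(sprintf("'%s' must have one label per sample (%d != %d)",
                 arg, length(g), nrow(x)), call. = FALSE)
  }
  if (nlevels(g) != 2L) {
    stop(sprintf("'%s' must contain exactly two groups, found %d",
                 arg, nlevels(g)), call. = FALSE)
  }
  cnt <- table(g)
  if (any(cnt < min_per_group)) {
    stop(sprintf("each group needs at least %d samples (found %s)",
                 min_per_group, paste(cnt, collapse = "/")), call. = FALSE)
  }
  names(g) <- rownames(x)
  g
}

check_flag <- function(x, arg = deparse(substitute(x))) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", arg), call. = FALSE)
  }
  x
}

check_count <- function(x, min = 1L, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != as.integer(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", arg, min), call. = FALSE)
  }
  as.integer(x)
}

check_seed <- function(seed, arg = "seed") {
  if (is.null(seed)) {
    stop(sprintf("'%s' is required for reproducibility", arg), call. = FALSE)
  }
  check_count(seed, min = -.Machine$integer.max, arg = arg)
}

col_sds <- function(x) apply(x, 2L, sd)
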