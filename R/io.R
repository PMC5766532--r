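#' Read an abundance matrix from CSV
#'
#' Expects a CSV (RFC 4180, UTF-8) with a header row of metabolite IDs and
#' the sample ID in the first column. Cells matching one of
#' `missing_tokens` (after trimming whitespace) become `NA`; everything
#' else must parse as a non-negative number.
#'
#' @param path Path to the CSV file.
#' @param missing_tokens Character vector of cell values treated as
#'   missing. Default `c("", "NA", "NaN")`.
#' @param zeros_as_missing If `TRUE`, exact zeros are additionally treated
#'   as missing. Zeros are ambiguous in exported metabolite tables (a zero
#'   may itself be the trace of an earlier replacement), hence opt-in.
#' @param transpose If `TRUE`, the file is metabolites-in-rows and is
#'   transposed after reading so that samples end up in rows.
#' @return A numeric matrix, samples in rows, metabolites in columns, with
#'   sample IDs as rownames and metabolite IDs as colnames.
#' @seealso [write_matrix()], [read_groups()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample,M1,M2", "S1,1.5,", "S2,2.5,4"), f)
#' m <- read_matrix(f)
#' sum(is.na(m))  # 1
read_matrix <- function(path, missing_tokens = c("", "NA", "NaN"),
                        zeros_as_missing = FALSE, transpose = FALSE) {
  check_flag(zeros_as_missing)
  check_flag(transpose)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("expected sample-ID column plus data columns",
                          call. = FALSE)
  ids <- trimws(df[[1L]])
  vars <- colnames(df)[-1L]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample IDs in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(vars)) {
    stop(sprintf("duplicate metabolite IDs in '%s': %s", path,
                 paste(unique(vars[duplicated(vars)]), collapse = ", ")),
         call. = FALSE)
  }
  m <- matrix(NA_real_, nrow(df), length(vars),
              dimnames = list(ids, vars))
  for (j in seq_along(vars)) {
    raw <- trimws(df[[j + 1L]])
    miss <- raw %in% missing_tokens | is.na(raw)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!miss & is.na(val))
    if (length(bad)) {
      stop(sprintf("cannot parse cell '%s' (sample '%s', metabolite '%s') in '%s'",
                   raw[bad[1L]], ids[bad[1L]], vars[j], path), call. = FALSE)
    }
    neg <- which(!miss & val < 0)
    if (length(neg)) {
      stop(sprintf("negative abundance %s (sample '%s', metabolite '%s') in '%s'",
                   raw[neg[1L]], ids[neg[1L]], vars[j], path), call. = FALSE)
    }
    val[miss] <- NA_real_
    m[, j] <- val
  }
  if (zeros_as_missing) m[!is.na(m) & m == 0] <- NA_real_
  if (transpose) m <- t(m)
  as_abundance(m)
}

#' Write an abundance matrix to CSV
#'
#' Values are formatted with 17 significant digits so that
#' `read_matrix(write_matrix(m))` round-trips doubles exactly.
#'
#' @param x Abundance matrix (or an [impute()] result).
#' @param path Output CSV path.
#' @param allow_missing Permit `NA` entries in the output (written as the
#'   token `NA`). Off by default: the writer is normally used after
#'   imputation, when no entry should be missing.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, allow_missing = FALSE) {
  x <- as_abundance(x)
  check_flag(allow_missing)
  if (!allow_missing && anyNA(x)) {
    stop("matrix contains missing values; set allow_missing = TRUE to write them",
         call. = FALSE)
  }
  chr <- matrix("NA", nrow(x), ncol(x))
  ok <- !is.na(x)
  chr[ok] <- formatC(x[ok], format = "g", digits = 17)
  out <- data.frame(sample = rownames(x), chr, check.names = FALSE)
  colnames(out) <- c("sample", colnames(x))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read two-class group labels aligned to an abundance matrix
#'
#' @param path Two-column CSV (with header): sample ID, group label.
#' @param x Abundance matrix whose sample order the labels are matched to.
#' @return A factor of length `nrow(x)`, named by sample ID, with exactly
#'   two levels.
#' @export
read_groups <- function(path, x) {
  x <- as_abundance(x)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) != 2L) stop("group file must have exactly two columns",
                           call. = FALSE)
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample IDs in group file", call. = FALSE)
  }
  absent <- setdiff(rownames(x), ids)
  if (length(absent)) {
    stop(sprintf("samples missing from group file: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  lab <- trimws(df[[2L]])[match(rownames(x), ids)]
  as_groups(lab, x, arg = "groups")
}
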