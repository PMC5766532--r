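#' QRILC: truncated-normal imputation for left-censored data
#'
#' Quantile regression imputation of left-censored data. Missing values
#' that arise because a compound fell below the limit of quantification
#' are not random: they are the low tail of the compound's abundance
#' distribution. QRILC models each metabolite's log-abundance as normal,
#' estimates the mean and SD of the *uncensored* distribution from the
#' observed (upper) tail, and replaces each missing entry with an
#' independent draw from that normal truncated above at the estimated
#' censoring point — so imputed values land in the low tail where the
#' censored values actually were, rather than collapsing onto a single
#' constant.
#'
#' Per metabolite with missing entries: (1) log-transform the observed
#' values (abundances must be positive; the log both improves the normal
#' fit and guarantees positive imputations after back-transformation);
#' (2) with `q_obs` the observed fraction, regress the sorted observed
#' log-values on the standard-normal quantiles of their plotting
#' positions `(i - a)/(n + b)` restricted to the upper `(1 - q_obs, 1]`
#' band, giving least-squares estimates of the uncensored mean and SD;
#' (3) draw each missing entry from that normal truncated above at its
#' `1 - q_obs` quantile (the estimated censoring point); (4)
#' exponentiate. Metabolites with fewer than 5 observed values or a
#' non-positive slope estimate fall back to half-minimum imputation with
#' a warning.
#'
#' @param x Abundance matrix with missing entries; all observed values
#'   must be strictly positive.
#' @param pp_offsets Plotting-position constants `c(a, b)` in
#'   `(i - a)/(n + b)`; default `c(0.375, 0.25)` (Blom's positions).
#'   Exposed because conventions vary between implementations.
#' @param seed Integer seed (required); draws are reproducible from it.
#' @return An `imputation` object. `params$fit` is a data frame with one
#'   row per imputed metabolite: estimated log-scale `mu` and `sigma`,
#'   the log-scale censoring point `censor_log`, and whether the
#'   half-minimum `fallback` was used.
#' @export
impute_qrilc <- function(x, pp_offsets = c(0.375, 0.25), seed = NULL) {
  x <- as_abundance(x)
  seed <- check_seed(seed)
  if (!is.numeric(pp_offsets) || length(pp_offsets) != 2L) {
    stop("pp_offsets must be two numbers c(a, b)", call. = FALSE)
  }
  if (any(x[!is.na(x)] <= 0)) {
    stop("QRILC requires strictly positive observed abundances (log transform)",
         call. = FALSE)
  }
  n <- nrow(x)
  out <- x
  fits <- list()
  withr::with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      n_miss <- sum(miss)
      if (n_miss == 0L) next
      obs_log <- sort(log(x[!miss, j]))
      n_obs <- length(obs_log)
      mu <- sg <- cens <- NA_real_
      fallback <- FALSE
      if (n_obs < 5L) {
        fallback <- TRUE
      } else {
        # plotting positions of the observed values within the full
        # sample of size n: ranks n_miss+1 .. n
        pp <- ((n - n_obs + seq_len(n_obs)) - pp_offsets[1L]) /
          (n + pp_offsets[2L])
        theo <- qnorm(pp)
        fit <- lm(obs_log ~ theo)
        mu <- unname(coef(fit)[1L])
        sg <- unname(coef(fit)[2L])
        if (!is.finite(sg) || sg <= 0) fallback <- TRUE
      }
      if (fallback) {
        warning(sprintf("QRILC fell back to half-minimum for metabolite '%s' (%d observed values%s)",
                        colnames(x)[j], n_obs,
                        if (n_obs >= 5L) ", non-positive SD estimate" else ""))
        out[miss, j] <- exp(min(obs_log)) / 2
      } else {
        cens <- mu + sg * qnorm(1 - n_obs / n)
        # inverse-CDF draw from N(mu, sg) truncated above at cens
        u <- runif(n_miss, 0, pnorm((cens - mu) / sg))
        out[miss, j] <- exp(mu + sg * qnorm(u))
      }
      fits[[colnames(x)[j]]] <-
        data.frame(variable = colnames(x)[j], n_obs = n_obs,
                   n_missing = n_miss, mu = mu, sigma = sg,
                   censor_log = cens, fallback = fallback)
    }
  })
  fit_df <- if (length(fits)) do.call(rbind, c(fits, make.row.names = FALSE))
            else data.frame()
  new_imputation(out, "qrilc",
                 params = list(pp_offsets = pp_offsets, fit = fit_df),
                 seed = seed)
}
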