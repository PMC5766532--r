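#' Specification for a synthetic metabolomics matrix
#'
#' Parameters of the log-normal factor model used by
#' [generate_complete()]. Metabolite abundances are positive and
#' right-skewed, and metabolite panels (fatty acids, amino acids, bile
#' acids, ...) are strongly correlated; both features are captured by
#' exponentiating a low-rank Gaussian model on the log scale:
#' \deqn{\log X = 1 o^T + S W + \Delta + E}
#' with per-metabolite baseline offsets \eqn{o_j \sim U(1, 5)} (so columns
#' span concentration ranges), standard-normal sample scores \eqn{S}
#' (`n_samples` x `latent_rank`) and loadings \eqn{W} (`latent_rank` x
#' `n_metabolites`), a two-group mean shift \eqn{\Delta} of `effect_size`
#' applied to `n_affected` randomly chosen metabolites in the second group,
#' and i.i.d. noise \eqn{E} with standard deviation `noise_sd`.
#'
#' @param n_samples,n_metabolites Matrix dimensions.
#' @param latent_rank Rank of the log-scale factor structure; the default 5
#'   matches the number of principal components the SVD imputer retains.
#' @param noise_sd Log-scale residual standard deviation.
#' @param n_affected Number of metabolites carrying a group mean shift.
#' @param effect_size Log-scale shift added to affected metabolites in the
#'   "case" group.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synth_spec`.
#' @seealso [generate_complete()]
#' @export
synth_spec <- function(n_samples = 100, n_metabolites = 50, latent_rank = 5,
                       noise_sd = 0.1, n_affected = 5, effect_size = 1,
                       seed = NULL) {
  n <- check_count(n_samples, 2L)
  p <- check_count(n_metabolites, 2L)
  r <- check_count(latent_rank, 1L)
  if (r > min(n, p)) {
    stop("latent_rank must not exceed min(n_samples, n_metabolites)",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a non-negative number", call. = FALSE)
  }
  na <- check_count(n_affected, 0L)
  if (na > p) stop("n_affected must not exceed n_metabolites", call. = FALSE)
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size)) {
    stop("effect_size must be a finite number", call. = FALSE)
  }
  structure(list(n_samples = n, n_metabolites = p, latent_rank = r,
                 noise_sd = noise_sd, n_affected = na,
                 effect_size = effect_size, seed = check_seed(seed)),
            class = "synth_spec")
}

#' Generate a complete synthetic abundance matrix with group labels
#'
#' Draws one realisation of the model described in [synth_spec()]. All
#' values are strictly positive and no entry is missing, so the result can
#' be fed directly to the missingness generators ([generate_mcar()],
#' [generate_mnar()]). Groups are balanced ("control" then "case",
#' alternating), and the same seed always reproduces the same matrix.
#'
#' @param spec A [synth_spec()] object.
#' @return A list with elements `matrix` (samples x metabolites, positive,
#'   complete), `groups` (two-level factor named by sample ID), and
#'   `affected` (IDs of the metabolites carrying the group shift).
#' @export
#' @examples
#' d <- generate_complete(synth_spec(n_samples = 20, n_metabolites = 10,
#'                                   seed = 1))
#' dim(d$matrix)
#' table(d$groups)
generate_complete <- function(spec) {
  if (!inherits(spec, "synth_spec")) {
    stop("spec must be created with synth_spec()", call. = FALSE)
  }
  n <- spec$n_samples
  p <- spec$n_metabolites
  r <- spec$latent_rank
  withr::with_seed(spec$seed, {
    scores <- matrix(rnorm(n * r), n, r)
    loadings <- matrix(rnorm(r * p), r, p)
    offsets <- runif(p, 1, 5)
    affected <- sort(sample.int(p, spec$n_affected))
    noise <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
  })
  groups <- factor(rep(c("control", "case"), length.out = n),
                   levels = c("control", "case"))
  logx <- sweep(scores %*% loadings, 2L, offsets, "+") + noise
  if (length(affected)) {
    logx[groups == "case", affected] <-
      logx[groups == "case", affected] + spec$effect_size
  }
  x <- exp(logx)
  dimnames(x) <- list(sprintf("S%03d", seq_len(n)),
                      sprintf("M%03d", seq_len(p)))
  names(groups) <- rownames(x)
  list(matrix = x, groups = groups,
       affected = colnames(x)[affected])
}
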