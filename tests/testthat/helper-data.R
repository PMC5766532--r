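# Shared fixtures, built in code.

# small positive matrix with dimnames
tiny_matrix <- function(n = 6, p = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(exp(rnorm(n * p, mean = 2, sd = 0.8)), n, p)
  })
  dimnames(m) <- list(sprintf("S%d", seq_len(n)), sprintf("M%d", seq_len(p)))
  m
}

# literal transcription of the NRMSE definition, kept independent of the
# package implementation: explicit loops, no shared helpers
nrmse_oracle <- function(complete, imputed, mask, zscore = TRUE) {
  if (zscore) {
    for (j in seq_len(ncol(complete))) {
      mu <- mean(complete[, j])
      sdev <- sqrt(sum((complete[, j] - mu)^2) / (nrow(complete) - 1))
      imputed[, j] <- (imputed[, j] - mu) / sdev
      complete[, j] <- (complete[, j] - mu) / sdev
    }
  }
  num <- 0
  truth <- c()
  k <- 0
  for (i in seq_len(nrow(complete))) {
    for (j in seq_len(ncol(complete))) {
      if (mask[i, j]) {
        num <- num + (complete[i, j] - imputed[i, j])^2
        truth <- c(truth, complete[i, j])
        k <- k + 1
      }
    }
  }
  mu_t <- sum(truth) / k
  v <- sum((truth - mu_t)^2) / (k - 1)
  sqrt((num / k) / v)
}

# a complete/imputed/mask triplet with random imputation error
random_triplet <- function(n = 20, p = 10, n_mask = NULL, seed = 1) {
  withr::with_seed(seed, {
    complete <- matrix(exp(rnorm(n * p, 2, 1)), n, p)
    if (is.null(n_mask)) n_mask <- sample(5:(n * p %/% 2), 1)
    idx <- sample(n * p, n_mask)
    imputed <- complete
    imputed[idx] <- complete[idx] * exp(rnorm(n_mask, 0, 0.5))
  })
  mask <- matrix(FALSE, n, p)
  mask[idx] <- TRUE
  dimnames(complete) <- dimnames(imputed) <- dimnames(mask) <-
    list(sprintf("S%d", 1:n), sprintf("M%d", 1:p))
  list(complete = complete, imputed = imputed, mask = mask)
}
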