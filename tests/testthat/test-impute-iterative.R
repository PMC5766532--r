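test_that("SVD imputation recovers an exact rank-1 matrix", {
  withr::with_seed(21, {
    u <- runif(6, 1, 3)
    v <- runif(5, 1, 3)
  })
  x <- outer(u, v)
  truth <- x[2, 3]
  x[2, 3] <- NA
  res <- impute_svd(x, k = 1)
  expect_lt(abs(res$imputed[2, 3] - truth) / truth, 1e-6)
  expect_true(res$params$converged)
})

test_that("SVD imputation recovers noiseless rank-5 structure", {
  d <- generate_complete(synth_spec(n_samples = 100, n_metabolites = 50,
                                    latent_rank = 5, noise_sd = 0,
                                    n_affected = 0, seed = 22))
  logx <- log(d$matrix)
  ds <- generate_mcar(logx, 0.10, seed = 23)
  res <- impute_svd(ds$observed, k = 5, tol = 1e-9, max_iter = 2000)
  rel <- abs(res$imputed[ds$mask] - logx[ds$mask]) / abs(logx[ds$mask])
  expect_lt(max(rel), 1e-6)
  expect_lt(nrmse(logx, res$imputed, ds$mask), 0.05)
})

test_that("SVD beats mean imputation on low-rank log-scale data", {
  d <- generate_complete(synth_spec(n_samples = 80, n_metabolites = 40,
                                    latent_rank = 5, noise_sd = 0.05,
                                    seed = 24))
  logx <- log(d$matrix)
  ds <- generate_mcar(logx, 0.10, seed = 25)
  n_svd <- nrmse(logx, impute_svd(ds$observed, k = 5)$imputed, ds$mask)
  n_mean <- nrmse(logx, impute_constant(ds$observed, "mean")$imputed,
                  ds$mask)
  expect_lt(n_svd, n_mean)
})

test_that("SVD leaves complete matrices unchanged and validates input", {
  m <- tiny_matrix(8, 5)
  expect_identical(impute_svd(m)$imputed, m)
  expect_error(impute_svd(m, k = 9), "k must not exceed")
  m[1:7, 2] <- NA
  expect_error(impute_svd(m), "fewer than 2 observed")
})

test_that("RF imputation is seed-reproducible and beats mean imputation", {
  d <- generate_complete(synth_spec(n_samples = 60, n_metabolites = 20,
                                    latent_rank = 5, noise_sd = 0.1,
                                    seed = 26))
  ds <- generate_mcar(d$matrix, 0.10, seed = 27)
  r1 <- impute_rf(ds$observed, seed = 28)
  r2 <- impute_rf(ds$observed, seed = 28)
  expect_identical(r1$imputed, r2$imputed)
  expect_gte(r1$params$sweeps, 1L)

  n_rf <- nrmse(d$matrix, r1$imputed, ds$mask)
  n_mean <- nrmse(d$matrix, impute_constant(ds$observed, "mean")$imputed,
                  ds$mask)
  expect_lt(n_rf, n_mean)

  complete <- tiny_matrix(6, 4)
  expect_identical(impute_rf(complete, seed = 1)$imputed, complete)
  expect_error(impute_rf(cbind(M1 = c(1, 2), M2 = c(NA, NA)), seed = 1),
               "no observed")
})

test_that("QRILC draws stay below the estimated censoring point", {
  d <- generate_complete(synth_spec(n_samples = 60, n_metabolites = 20,
                                    seed = 29))
  ds <- generate_mnar(d$matrix, 0.5, seed = 30)
  res <- impute_qrilc(ds$observed, seed = 31)
  expect_identical(impute_qrilc(ds$observed, seed = 31)$imputed,
                   res$imputed)
  expect_true(all(res$imputed > 0))

  fit <- res$params$fit
  expect_setequal(fit$variable, ds$meta$missing_variables)
  expect_false(any(fit$fallback))
  for (i in seq_len(nrow(fit))) {
    v <- fit$variable[i]
    drawn <- log(res$imputed[ds$mask[, v], v])
    expect_lte(max(drawn), fit$censor_log[i])
    # imputed values sit below the bulk of the observed ones
    expect_lt(max(drawn), median(log(ds$observed[, v]), na.rm = TRUE))
  }

  # untouched complete variables
  clean <- setdiff(colnames(d$matrix), ds$meta$missing_variables)
  expect_identical(res$imputed[, clean], ds$observed[, clean])
})

test_that("QRILC falls back to half-minimum when the fit is infeasible", {
  m <- tiny_matrix(6, 3, seed = 32)
  m[1:3, 2] <- NA  # only 3 observed values
  expect_warning(res <- impute_qrilc(m, seed = 33), "half-minimum")
  expect_equal(unique(res$imputed[1:3, 2]),
               min(m[, 2], na.rm = TRUE) / 2)
  expect_true(res$params$fit$fallback)

  m[4, 2] <- 0
  expect_error(impute_qrilc(m, seed = 33), "positive")
})
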