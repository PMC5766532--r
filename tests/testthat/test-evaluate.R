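test_that("nrmse matches hand-computed values and fixed points", {
  tr <- random_triplet(seed = 41)
  expect_equal(nrmse(tr$complete, tr$complete, tr$mask), 0)

  # pre-standardised column: masked truth (-1, 0, 1) imputed as 0
  m <- cbind(M1 = c(-1, 0, 1, 2, -2), M2 = rnorm(5))
  rownames(m) <- paste0("S", 1:5)
  imp <- m
  imp[1:3, 1] <- 0
  mask <- matrix(FALSE, 5, 2)
  mask[1:3, 1] <- TRUE
  expect_equal(nrmse(m, imp, mask, zscore = FALSE), sqrt(2 / 3))
})

test_that("nrmse agrees with the brute-force oracle on random instances", {
  for (s in 1:25) {
    tr <- random_triplet(seed = 100 + s)
    expect_equal(nrmse(tr$complete, tr$imputed, tr$mask),
                 nrmse_oracle(tr$complete, tr$imputed, tr$mask),
                 tolerance = 1e-12)
  }
})

test_that("nrmse rejects degenerate masks", {
  tr <- random_triplet(seed = 42)
  expect_error(nrmse(tr$complete, tr$imputed,
                     matrix(FALSE, 20, 10)), "at least 2")
  const <- tr$complete
  const[1:3, 1] <- 5
  mask <- matrix(FALSE, 20, 10)
  mask[1:3, 1] <- TRUE
  expect_error(nrmse(const, const * 1.01, mask, zscore = FALSE),
               "zero variance")
})

test_that("per-variable nrmse is columnwise-consistent with the oracle", {
  tr <- random_triplet(n = 30, p = 6, seed = 43)
  pv <- suppressWarnings(nrmse_per_variable(tr$complete, tr$imputed,
                                            tr$mask))
  for (v in names(pv)) {
    if (is.na(pv[[v]])) next
    sub_mask <- tr$mask
    sub_mask[, colnames(tr$complete) != v] <- FALSE
    expect_equal(pv[[v]],
                 nrmse_oracle(tr$complete, tr$imputed, sub_mask))
  }
  expect_true(all(suppressWarnings(
    nrmse_per_variable(tr$complete, tr$complete, tr$mask)) == 0,
    na.rm = TRUE))

  # a single missing variable reduces to the overall metric
  one <- random_triplet(n = 20, p = 5, seed = 44)
  mask1 <- one$mask
  mask1[, 2:5] <- FALSE
  if (sum(mask1) >= 2) {
    expect_equal(unname(nrmse_per_variable(one$complete, one$imputed,
                                           mask1)[1]),
                 nrmse(one$complete, one$imputed, mask1))
  }
})

test_that("per-variable nrmse flags unscorable columns", {
  tr <- random_triplet(n = 10, p = 4, seed = 45)
  mask <- matrix(FALSE, 10, 4, dimnames = dimnames(tr$mask))
  mask[1:3, 1] <- TRUE
  mask[5, 2] <- TRUE  # single masked entry
  expect_warning(pv <- nrmse_per_variable(tr$complete, tr$imputed, mask),
                 "fewer than 2")
  expect_false(is.na(pv[["M1"]]))
  expect_true(is.na(pv[["M2"]]))
})

test_that("sum of ranks follows the worked examples and conserves totals", {
  expect_equal(sor(list(A = c(v1 = 0.1, v2 = 0.1),
                        B = c(v1 = 0.2, v2 = 0.2))),
               c(A = 2, B = 4))
  expect_equal(sor(list(A = c(v1 = 0.1, v2 = 0.2),
                        B = c(v1 = 0.3, v2 = 0.15))),
               c(A = 3, B = 3))
  # tie between two of three methods -> average rank 1.5 each
  tied <- sor(list(A = c(v1 = 0.1), B = c(v1 = 0.1), C = c(v1 = 0.4)))
  expect_equal(tied, c(A = 1.5, B = 1.5, C = 3))

  # conservation: sum over J methods = M * J * (J+1) / 2, ties included
  withr::with_seed(46, {
    for (rep in 1:20) {
      M <- sample(2:8, 1)
      J <- sample(2:6, 1)
      vals <- matrix(sample(seq(0.1, 1, 0.1), M * J, replace = TRUE), M, J)
      rownames(vals) <- paste0("v", 1:M)
      pv <- lapply(seq_len(J), function(j) vals[, j])
      names(pv) <- paste0("m", 1:J)
      expect_equal(sum(sor(pv)), M * J * (J + 1) / 2)
    }
  })

  expect_error(sor(list(A = c(v1 = 1), B = c(v2 = 1))),
               "same missing-variable set")
  expect_error(sor(list(A = c(v1 = 1))), "2 methods")
})

test_that("Procrustes error is invariant to similarity transforms", {
  withr::with_seed(47, scores <- matrix(rnorm(40), 20, 2))
  expect_equal(procrustes_error(scores, scores), 0)
  rot <- matrix(c(0, -1, 1, 0), 2)  # 90 degree rotation
  expect_equal(procrustes_error(scores, 2 * scores %*% rot), 0,
               tolerance = 1e-12)
  refl <- scores %*% diag(c(-1, 1))
  expect_equal(procrustes_error(scores, refl), 0, tolerance = 1e-12)
  shifted <- sweep(scores, 2, c(5, -3), "+")
  expect_equal(procrustes_error(scores, shifted), 0, tolerance = 1e-12)
  expect_error(procrustes_error(scores, matrix(0, 20, 2)), "degenerate")
})

test_that("PCA-Procrustes error grows with injected noise", {
  d <- generate_complete(synth_spec(n_samples = 50, n_metabolites = 20,
                                    seed = 48))
  expect_equal(pca_procrustes(d$matrix, d$matrix), 0)
  errs <- vapply(c(0.05, 0.3, 1), function(s) {
    noisy <- d$matrix *
      exp(withr::with_seed(49, matrix(rnorm(1000, 0, s), 50, 20)))
    pca_procrustes(d$matrix, noisy)
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_true(all(errs >= 0 & errs <= 1))
})

test_that("PLS-Procrustes respects fixed points and reflection invariance", {
  d <- generate_complete(synth_spec(n_samples = 40, n_metabolites = 15,
                                    effect_size = 1.5, seed = 50))
  expect_equal(pls_procrustes(d$matrix, d$matrix, d$groups), 0,
               tolerance = 1e-10)
  ds <- generate_mcar(d$matrix, 0.1, seed = 51)
  imp <- impute(ds, "mean")$imputed
  e <- pls_procrustes(d$matrix, imp, d$groups)
  expect_true(e > 0 && e <= 1)
})

test_that("log-p correlation is 1 at the fixed point and collapses under permutation", {
  d <- generate_complete(synth_spec(n_samples = 60, n_metabolites = 20,
                                    n_affected = 6, effect_size = 1.5,
                                    seed = 52))
  expect_equal(logp_correlation(d$matrix, d$matrix, d$groups), 1)

  shuffled <- withr::with_seed(53, apply(d$matrix, 2, sample))
  dimnames(shuffled) <- dimnames(d$matrix)
  r <- logp_correlation(d$matrix, shuffled, d$groups)
  expect_lt(abs(r), 0.5)

  expect_error(logp_correlation(d$matrix, d$matrix, d$groups,
                                restrict_to = c("M001", "M002")),
               "at least 3")
  expect_error(logp_correlation(d$matrix, d$matrix, d$groups,
                                restrict_to = "nope"), "unknown")
})
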