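test_that("MCAR masks the exact rounded count of entries", {
  m <- tiny_matrix(10, 10)
  ds <- generate_mcar(m, 0.25, seed = 1)
  expect_equal(sum(ds$mask), 25)
  expect_identical(which(is.na(ds$observed)), which(ds$mask))
  expect_identical(ds$observed[!ds$mask], ds$complete[!ds$mask])

  ds0 <- generate_mcar(m, 0, seed = 1)
  expect_equal(sum(ds0$mask), 0)
  expect_identical(ds0$observed, m)

  expect_error(generate_mcar(m, 1, seed = 1), "proportion")
  expect_error(generate_mcar(ds$observed, 0.1, seed = 1), "missing")
})

test_that("MCAR masks are seed-reproducible and seed-sensitive", {
  m <- tiny_matrix(10, 10)
  expect_identical(generate_mcar(m, 0.3, seed = 7),
                   generate_mcar(m, 0.3, seed = 7))
  expect_false(identical(generate_mcar(m, 0.3, seed = 7)$mask,
                         generate_mcar(m, 0.3, seed = 8)$mask))
})

test_that("MCAR inclusion is marginally uniform over entries", {
  m <- tiny_matrix(6, 5)
  counts <- matrix(0, 6, 5)
  for (s in 1:400) counts <- counts + generate_mcar(m, 0.2, seed = s)$mask
  # 6 of 30 entries per draw; expected count 80 per cell
  pval <- chisq.test(as.vector(counts))$p.value
  expect_gt(pval, 0.001)
})

test_that("MNAR selects the exact number of variables and left-censors them", {
  d <- generate_complete(synth_spec(n_samples = 50, n_metabolites = 100,
                                    seed = 1))
  ds <- generate_mnar(d$matrix, 0.04, seed = 2)
  expect_length(ds$meta$missing_variables, 4)
  expect_equal(sum(colSums(ds$mask) > 0), 4)
  expect_length(ds$meta$cutoffs, 4)
  expect_true(all(ds$meta$cutoffs >= 0.30 & ds$meta$cutoffs <= 0.60))

  for (v in ds$meta$missing_variables) {
    masked <- ds$complete[ds$mask[, v], v]
    observed <- ds$complete[!ds$mask[, v], v]
    expect_lt(max(masked), min(observed))
    # masked count equals count below the drawn quantile value
    qv <- quantile(ds$complete[, v], ds$meta$cutoffs[v], type = 7,
                   names = FALSE)
    expect_equal(sum(ds$mask[, v]), sum(ds$complete[, v] < qv))
  }
})

test_that("a forced 0.5 cutoff masks exactly the below-median entries", {
  m <- tiny_matrix(11, 3, seed = 5)  # distinct values, odd n
  ds <- generate_mnar(m, 1, cutoff_low = 0.5, cutoff_high = 0.5, seed = 3)
  for (j in seq_len(ncol(m))) {
    expect_identical(ds$mask[, j], m[, j] < median(m[, j]))
  }
})

test_that("MNAR degenerate and invalid inputs behave", {
  m <- tiny_matrix(10, 10)
  ds <- generate_mnar(m, 0, seed = 1)
  expect_identical(ds$observed, m)
  expect_identical(generate_mnar(m, 0.4, seed = 9),
                   generate_mnar(m, 0.4, seed = 9))
  expect_error(generate_mnar(m, 1.2, seed = 1), "var_proportion")
  expect_error(generate_mnar(m, 0.5, cutoff_low = 0.7, cutoff_high = 0.4,
                             seed = 1), "cutoff")
})

test_that("proportion grids match the benchmark design", {
  g_mcar <- proportion_grid("mcar")
  expect_length(g_mcar, 20)
  expect_equal(g_mcar[1], 0.025)
  expect_equal(g_mcar[20], 0.50)

  g_mnar <- proportion_grid("mnar")
  expect_length(g_mnar, 20)
  expect_equal(g_mnar[1], 0.04)
  expect_equal(g_mnar[20], 0.80)

  expect_true(all(diff(g_mcar) > 0) && all(diff(g_mnar) > 0))
})
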