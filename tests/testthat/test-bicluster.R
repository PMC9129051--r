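test_that("msr matches hand-computed and degenerate cases", {
  expect_equal(msr(matrix(c(1, 3, 2, 4), 2))$H, 0)
  s <- msr(matrix(c(1, 0, 0, 1), 2))
  expect_equal(s$H, 0.25)
  expect_equal(unname(s$row_scores), c(0.25, 0.25))
  expect_equal(unname(s$col_scores), c(0.25, 0.25))
  expect_equal(msr(matrix(3, 3, 4))$H, 0)
  expect_error(msr(matrix(1:4, 2), integer(0), 1:2), "non-empty")
  expect_error(msr(matrix(1:4, 2), 1:3, 1:2), "out of range")
})

test_that("msr agrees with the direct residue oracle on random matrices", {
  withr::with_seed(42, {
    for (k in 1:100) {
      n <- sample(2:6, 1); m <- sample(2:5, 1)
      mat <- matrix(sample(0:2, n * m, replace = TRUE) + rnorm(n * m, 0, 0.3),
                    n, m)
      rows <- sort(sample(n, sample(2:n, 1)))
      cols <- sort(sample(m, sample(2:m, 1)))
      s <- msr(mat, rows, cols)
      expect_lt(abs(s$H - msr_oracle(mat, rows, cols)), 1e-12)
      expect_equal(s$H, mean(s$row_scores), tolerance = 1e-12)
      expect_equal(s$H, mean(s$col_scores), tolerance = 1e-12)
    }
  })
})

test_that("single node deletion isolates the additive core and never raises H", {
  mat <- rbind(c(1, 2), c(2, 3), c(0, 9))
  out <- single_node_deletion(mat, 1:3, 1:2, delta = 1e-6)
  expect_true(out$converged)
  expect_equal(out$rows, 1:2)
  expect_equal(out$H, 0)

  # already under threshold: unchanged
  ok <- single_node_deletion(mat, 1:2, 1:2, delta = 0.5)
  expect_equal(ok$rows, 1:2)
  expect_equal(ok$cols, 1:2)

  # H non-increasing along the deletion path (debug mode asserts each step)
  withr::with_seed(5, {
    for (k in 1:20) {
      m <- matrix(rnorm(48), 8, 6)
      expect_no_error(single_node_deletion(m, 1:8, 1:6, delta = 0.05,
                                           debug = TRUE))
    }
  })
})

test_that("multiple node deletion strips noise rows from a large additive block", {
  hits <- 0
  for (s in 1:20) {
    mat <- withr::with_seed(s, {
      rbind(additive_matrix(150, 10, noise = 0.05, seed = s),
            matrix(rnorm(300), 30, 10))
    })
    out <- multiple_node_deletion(mat, 1:180, 1:10, delta = 0.01,
                                  alpha = 1.2, min_size = 100L)
    out <- single_node_deletion(mat, out$rows, out$cols, delta = 0.01)
    expect_lte(out$H, 0.01)
    if (sum(out$rows <= 150) >= 0.95 * length(out$rows) &&
        length(intersect(out$rows, 1:150)) >= 0.95 * 150) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})

test_that("multiple deletion is a no-op when alpha is unreachable", {
  mat <- withr::with_seed(1, matrix(rnorm(200 * 8), 200, 8))
  out <- multiple_node_deletion(mat, 1:200, 1:8, delta = 1e-4,
                                alpha = 1e9, min_size = 100L)
  expect_equal(out$rows, 1:200)
  expect_equal(out$cols, 1:8)
  expect_false(out$converged)
  expect_error(multiple_node_deletion(mat, 1:200, 1:8, 0.1, alpha = 1),
               "alpha")
})

test_that("node addition regrows additive rows and never raises H", {
  mat <- additive_matrix(3, 4, noise = 0, seed = 2)
  out <- node_addition(mat, 1:2, 1:4)
  expect_equal(out$rows, 1:3)
  expect_equal(out$H, 0, tolerance = 1e-12)

  # nothing to add: unchanged
  mat2 <- rbind(additive_matrix(3, 4, noise = 0, seed = 3),
                matrix(rnorm(8) + 10 * c(1, -1), 2, 4))
  out2 <- node_addition(mat2, 1:3, 1:4)
  expect_equal(out2$rows, 1:3)

  # planted-block matrices: post-addition H <= pre-addition H (debug asserts)
  withr::with_seed(9, {
    for (k in 1:30) {
      m <- rbind(additive_matrix(10, 6, noise = 0.1, seed = 100 + k),
                 matrix(rnorm(30), 5, 6))
      expect_no_error(node_addition(m, 1:10, 1:6, debug = TRUE))
    }
  })
})

test_that("anova_r2 matches hand computations and its null expectation", {
  add <- additive_matrix(5, 4, noise = 0, seed = 4)
  expect_equal(anova_r2(add, 1:5, 1:4), 1)
  expect_equal(anova_r2(matrix(c(1, 0, 0, 1), 2), 1:2, 1:2), 0)
  expect_error(anova_r2(matrix(1, 3, 3), 1:3, 1:3), "Constant")

  # iid normal 50 x 10: explained and residual SS are independent
  # chi-squares, so R^2 ~ Beta with mean (m + n - 2) / (m n - 1)
  r2s <- withr::with_seed(11, {
    vapply(1:200, function(k) {
      anova_r2(matrix(rnorm(500), 50, 10), 1:50, 1:10)
    }, numeric(1))
  })
  expected <- (50 + 10 - 2) / (500 - 1)
  expect_lt(abs(mean(r2s) - expected), 3 * stats::sd(r2s) / sqrt(200))
})

test_that("find_bicluster handles trivial and degenerate thresholds", {
  add <- additive_matrix(10, 6, noise = 0.01, seed = 6)
  bc <- find_bicluster(add, delta = 0.2)
  expect_equal(bc$rows, 1:10)
  expect_equal(bc$cols, 1:6)

  noisy <- withr::with_seed(7, matrix(rnorm(200), 20, 10))
  bc0 <- find_bicluster(noisy, delta = 0)
  expect_false(bc0$converged)
  expect_lte(length(bc0$rows), 3)
})

test_that("greedy search reaches the threshold whenever the exhaustive optimum does", {
  withr::with_seed(21, {
    for (k in 1:60) {
      n <- sample(4:6, 1); m <- sample(4:5, 1)
      mat <- matrix(sample(0:2, n * m, replace = TRUE), n, m) +
        matrix(rnorm(n * m, 0, 0.01), n, m)
      delta <- 0.15
      best <- best_msr_exhaustive(mat)
      bc <- find_bicluster(mat, delta)
      if (best <= delta) {
        expect_lte(msr(mat, bc$rows, bc$cols)$H, delta)
      }
    }
  })
})

test_that("exclusive extraction partitions rows and respects delta", {
  spec <- synthetic_spec(seed = 17)
  sim <- generate_clinical_matrix(spec)
  pm <- standardize_matrix(encode_features(sim$data,
                                           spec_feature_metadata(spec)))
  bs <- find_exclusive_biclusters(pm$values, delta = 0.2, max_k = 6)
  all_rows <- sort(c(unlist(lapply(bs$biclusters, `[[`, "rows")),
                     bs$unassigned_rows))
  expect_equal(all_rows, seq_len(nrow(pm$values)))
  row_sets <- lapply(bs$biclusters, `[[`, "rows")
  expect_equal(anyDuplicated(unlist(row_sets)), 0)
  expect_true(all(vapply(bs$biclusters, `[[`, numeric(1), "msr") <= 0.2))
  expect_true(all(vapply(bs$biclusters, `[[`, numeric(1), "r2") >= 0))

  one <- find_exclusive_biclusters(pm$values, delta = 0.2, max_k = 1)
  expect_equal(length(one$biclusters), 1L)
  expect_setequal(c(one$biclusters[[1]]$rows, one$unassigned_rows),
                  seq_len(nrow(pm$values)))

  expect_error(find_exclusive_biclusters(pm$values, delta = 2), "msr_max")
})

test_that("biclustering is invariant to a constant shift of the matrix", {
  spec <- synthetic_spec(n_rows = 120, n_cols = 15, seed = 19,
                         planted_biclusters = list(
                           list(rows = 1:40, cols = 1:15, mu = 0.5,
                                row_sd = 0.3, col_sd = 0.8)
                         ),
                         col_profile = "independent")
  sim <- generate_clinical_matrix(spec)
  mat <- as.matrix(sim$data[, -1])
  rownames(mat) <- sim$data$knee_id
  bs1 <- find_exclusive_biclusters(mat, delta = 0.2, max_k = 3)
  bs2 <- find_exclusive_biclusters(mat + 5, delta = 0.2, max_k = 3)
  expect_equal(lapply(bs1$biclusters, `[[`, "rows"),
               lapply(bs2$biclusters, `[[`, "rows"))
  expect_equal(msr(mat)$H, msr(mat + 5)$H, tolerance = 1e-10)
})

test_that("tidy and glance summarize a bicluster set faithfully", {
  spec <- synthetic_spec(seed = 23)
  sim <- generate_clinical_matrix(spec)
  pm <- standardize_matrix(encode_features(sim$data,
                                           spec_feature_metadata(spec)))
  bs <- find_exclusive_biclusters(pm$values, delta = 0.2, max_k = 4)
  td <- tidy(bs)
  expect_equal(nrow(td), length(bs$biclusters))
  expect_equal(td$n_rows, vapply(bs$biclusters, function(b) length(b$rows),
                                 integer(1)))
  gl <- glance(bs)
  expect_equal(gl$n_biclusters, length(bs$biclusters))
  expect_equal(gl$n_rows, 300L)
})
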