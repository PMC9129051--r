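test_that("generation is a pure function of the seed", {
  s1 <- generate_clinical_matrix(synthetic_spec(seed = 7))
  s2 <- generate_clinical_matrix(synthetic_spec(seed = 7))
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$row_membership, s2$truth$row_membership)
  s3 <- generate_clinical_matrix(synthetic_spec(seed = 8))
  expect_false(identical(s1$data, s3$data))
})

test_that("spec validation rejects bad inputs", {
  expect_error(synthetic_spec(n_rows = 1), "n_rows")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
  expect_error(
    synthetic_spec(planted_biclusters = list(
      list(rows = 1:10, cols = 1:5, mu = 1, row_sd = 1, col_sd = 1),
      list(rows = 5:20, cols = 6:10, mu = 1, row_sd = 1, col_sd = 1)
    ), col_profile = "independent"),
    "disjoint"
  )
  expect_error(
    synthetic_spec(traj_groups = list(a = list(pi = 0.6, beta = 0),
                                      b = list(pi = 0.5, beta = 0))),
    "sum to 1"
  )
})

test_that("planted block MSR after standardization matches its expectation", {
  # oracle: an additive block plus iid noise has E[MSR] =
  # sigma'^2 (m-1)(n-1)/(mn); after per-column scaling sigma'^2 averages
  # noise_sd^2 * mean_j(1 / scale_j^2) over the block columns
  n_seeds <- 60
  h <- numeric(n_seeds); expected <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(
      n_rows = 300, n_cols = 40,
      planted_biclusters = list(
        list(rows = 1:60, cols = 1:12, mu = 1, row_sd = 0.5, col_sd = 0.5)
      ),
      col_profile = "independent",
      noise_sd = 0.3, seed = 1000 + s
    )
    sim <- generate_clinical_matrix(spec)
    pm <- standardize_matrix(encode_features(sim$data,
                                             spec_feature_metadata(spec)),
                             transform = FALSE)
    blk <- spec$planted_biclusters[[1]]
    h[s] <- msr(pm$values, blk$rows, blk$cols)$H
    scales <- pm$transform_log$scale[blk$cols]
    m <- length(blk$rows); p <- length(blk$cols)
    expected[s] <- spec$noise_sd^2 * mean(1 / scales^2) *
      (m - 1) * (p - 1) / (m * p)
  }
  mc_sd <- stats::sd(h - expected) / sqrt(n_seeds)
  expect_lt(abs(mean(h - expected)), 3 * mc_sd + 1e-4)
})

test_that("a noiseless planted block has zero residue before standardization", {
  spec <- synthetic_spec(
    n_rows = 100, n_cols = 20,
    planted_biclusters = list(
      list(rows = 1:30, cols = 1:8, mu = 2, row_sd = 1, col_sd = 1)
    ),
    col_profile = "independent",
    noise_sd = 1e-9, seed = 3
  )
  sim <- generate_clinical_matrix(spec)
  raw <- as.matrix(sim$data[, -1])
  expect_lt(msr(raw, 1:30, 1:8)$H, 1e-6)
})

test_that("mixed feature kinds produce the declared column types", {
  spec <- synthetic_spec(
    n_rows = 200, n_cols = 6,
    feature_kinds = c("continuous", "binary", "ordinal:4", "nominal:3",
                      "continuous", "binary"),
    planted_biclusters = list(
      list(rows = 1:50, cols = 1:6, mu = 1, row_sd = 0.5, col_sd = 0.5)
    ),
    col_profile = "independent", seed = 5
  )
  d <- generate_clinical_matrix(spec)$data
  expect_true(all(d$f02 %in% 0:1))
  expect_true(all(d$f03 %in% 1:4))
  expect_true(all(d$f04 %in% paste0("L", 1:3)))
  expect_type(d$f01, "double")
})

test_that("trajectory group sizes follow the mixing proportions", {
  tg <- two_group_panel(seed = 1, n = 500)
  sizes <- table(tg$truth$traj_group)
  # binomial 99% bounds for n = 500, p = 0.7
  expect_gte(sizes[[1]], qbinom(0.005, 500, 0.7))
  expect_lte(sizes[[1]], qbinom(0.995, 500, 0.7))
})

test_that("panel respects the visit schedule and change-from-baseline anchor", {
  tg <- two_group_panel(seed = 2, n = 100)
  p <- tg$panel
  expect_true(all(p$month %in% c(0, 12, 24, 36, 48, 72, 96)))
  expect_true(all(p$value[p$month == 0] == 0))
  # dropout_rate = 0 -> every knee has all 7 visits
  expect_true(all(table(p$knee_id) == 7))
})

test_that("dropout is monotone and heavier after month 48", {
  spec <- synthetic_spec(n_rows = 800, seed = 4,
                         dropout_rate = c(early = 0.02, late = 0.25))
  sim <- generate_clinical_matrix(spec)
  p <- generate_longitudinal_panel(spec, sim$truth)
  wide <- tidyr::pivot_wider(p, names_from = "month", values_from = "value")
  months <- c("12", "24", "36", "48", "72", "96")
  obs <- !is.na(as.matrix(wide[months]))
  # once missing, always missing
  for (i in seq_len(nrow(obs))) {
    first_gap <- which(!obs[i, ])
    if (length(first_gap)) {
      expect_true(all(!obs[i, first_gap[1]:length(months)]))
    }
  }
  # attrition visibly increases late
  frac <- colMeans(obs)
  expect_gt(frac[["48"]], frac[["96"]])
})

test_that("outcome tables satisfy their construction invariants", {
  spec <- synthetic_spec(seed = 6)
  sim <- generate_clinical_matrix(spec)
  out <- generate_outcomes(spec, sim$truth)
  by_knee <- split(out, out$knee_id)
  nondecr <- vapply(by_knee, function(d) {
    all(diff(d$klg[order(d$month)]) >= 0)
  }, logical(1))
  expect_true(all(nondecr))
  expect_true(all(out$klg %in% 0:4))
  expect_true(all(vapply(by_knee, function(d) length(unique(d$tka)) == 1L,
                         logical(1))))
})

test_that("noiseless qJSW series is exactly linear and TKA prob 0 yields none", {
  spec <- synthetic_spec(
    n_rows = 20, seed = 8,
    planted_biclusters = list(),
    qjsw_params = list(
      baseline_mean = c(medial = 4, lateral = 5),
      baseline_sd = c(medial = 0, lateral = 0),
      slope_mean = -1 / 96, slope_sd = 0, noise_sd = 0
    ),
    outcome_params = list(
      klg_baseline_probs = list(none = c(1, 0, 0, 0, 0)),
      prog_prob = 0, tka_prob = 0
    )
  )
  sim <- generate_clinical_matrix(spec)
  out <- generate_outcomes(spec, sim$truth)
  at96 <- out[out$month == 96, ]
  expect_equal(at96$qjsw_medial, rep(3, nrow(at96)), tolerance = 1e-12)
  expect_true(all(out$tka == 0))
})

test_that("fixture bundles round-trip and regenerate identically", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_rows = 60, n_cols = 10,
                         planted_biclusters = list(
                           list(rows = 1:20, cols = 1:5, mu = 1,
                                row_sd = 0.5, col_sd = 0.5)
                         ),
                         col_profile = "independent", seed = 11)
  paths <- write_fixture_bundle(dir, spec)
  expect_true(all(file.exists(paths)))
  bundle <- read_fixture_bundle(dir)
  sim <- generate_clinical_matrix(spec)
  expect_equal(as.data.frame(bundle$baseline), as.data.frame(sim$data))
  expect_equal(bundle$spec$seed, spec$seed)
  # regenerating from the stored spec reproduces the stored tables
  sim2 <- generate_clinical_matrix(bundle$spec)
  expect_equal(as.data.frame(bundle$baseline), as.data.frame(sim2$data))
  panel2 <- generate_longitudinal_panel(bundle$spec, sim2$truth)
  expect_equal(as.data.frame(bundle$panel), as.data.frame(panel2))
})
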