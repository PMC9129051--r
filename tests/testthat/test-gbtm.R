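# hand-built model object for likelihood oracle tests
toy_model <- function(G = 2, dropout = FALSE) {
  structure(
    list(
      G = G, degree = rep(1L, G),
      beta = list(c(0, 0), c(1, 2))[seq_len(G)],
      pi = if (G == 2) c(0.6, 0.4) else 1,
      sigma = 1.5, dropout = dropout,
      dropout_coef = if (dropout) matrix(c(-1, 0.2, -2, -0.1), 2, 2,
                                         byrow = TRUE)[seq_len(G), , drop = FALSE]
      else NULL
    ),
    class = "gbtm"
  )
}

toy_panel <- function(n = 5, months = c(0, 24, 48, 96), seed = 1) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      keep <- months[seq_len(sample(2:length(months), 1))]
      tibble::tibble(knee_id = paste0("k", i), month = keep,
                     value = c(0, rnorm(length(keep) - 1)))
    }))
  })
}

# direct summation likelihood oracle (loops, no matrix algebra)
loglik_oracle <- function(model, panel) {
  post <- sort(unique(panel$month[panel$month > 0]))
  tot <- 0
  for (id in unique(panel$knee_id)) {
    d <- panel[panel$knee_id == id & panel$month > 0, ]
    if (!nrow(d)) next
    terms <- numeric(model$G)
    for (g in seq_len(model$G)) {
      b <- model$beta[[g]]
      lg <- 0
      for (r in seq_len(nrow(d))) {
        u <- d$month[r] / 96
        mu <- sum(b * u^(seq_along(b) - 1))
        lg <- lg + dnorm(d$value[r], mu, model$sigma, log = TRUE)
      }
      if (!is.null(model$dropout_coef)) {
        prev <- 0
        for (t in seq_along(post)) {
          eta <- model$dropout_coef[g, 1] + model$dropout_coef[g, 2] * prev
          row <- d[d$month == post[t], ]
          if (nrow(row)) {
            lg <- lg + log(1 - plogis(eta))
            prev <- row$value[1]
          } else {
            lg <- lg + log(plogis(eta))
            break
          }
        }
      }
      terms[g] <- log(model$pi[g]) + lg
    }
    tot <- tot + log(sum(exp(terms)))
  }
  tot
}

test_that("model log-likelihood agrees with a direct summation oracle", {
  panel <- toy_panel()
  for (dropout in c(FALSE, TRUE)) {
    m <- toy_model(G = 2, dropout = dropout)
    expect_equal(gbtm_loglik(m, panel), loglik_oracle(m, panel),
                 tolerance = 1e-8)
  }
})

test_that("log-likelihood is additive over knees and order-invariant", {
  panel <- toy_panel(n = 6, seed = 2)
  m <- toy_model(G = 2, dropout = TRUE)
  doubled <- dplyr::bind_rows(
    panel,
    dplyr::mutate(panel, knee_id = paste0(.data$knee_id, "_copy"))
  )
  expect_equal(gbtm_loglik(m, doubled), 2 * gbtm_loglik(m, panel),
               tolerance = 1e-8)
  shuffled <- panel[withr::with_seed(3, sample(nrow(panel))), ]
  expect_equal(gbtm_loglik(m, shuffled), gbtm_loglik(m, panel),
               tolerance = 1e-10)
})

test_that("a single-group fit collapses to least squares", {
  tg <- two_group_panel(seed = 4, n = 120)
  f <- fit_gbtm(tg$panel, G = 1, degree = 2, dropout = FALSE, seed = 1)
  obs <- tg$panel[tg$panel$month > 0, ]
  u <- obs$month / 96
  ols <- lm(obs$value ~ u + I(u^2))
  expect_equal(unname(f$beta[[1]]), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(f$pi, 1)
})

test_that("relabeling groups leaves the likelihood unchanged", {
  panel <- toy_panel(n = 8, seed = 5)
  m <- toy_model(G = 2, dropout = TRUE)
  swapped <- m
  swapped$beta <- m$beta[2:1]
  swapped$pi <- m$pi[2:1]
  swapped$dropout_coef <- m$dropout_coef[2:1, ]
  expect_equal(gbtm_loglik(swapped, panel), gbtm_loglik(m, panel),
               tolerance = 1e-10)
})

test_that("EM increases the log-likelihood monotonically", {
  tg <- two_group_panel(seed = 6, n = 150, dropout = 0.05)
  # a few knees drop out before their first post-baseline visit
  f <- suppressWarnings(fit_gbtm(tg$panel, G = 2, degree = 1, dropout = TRUE,
                                 seed = 2, debug = TRUE))
  path <- f$convergence$loglik_path
  expect_true(all(diff(path) > -1e-6))
})

test_that("posterior assignment satisfies the EM identities", {
  tg <- two_group_panel(seed = 7, n = 200)
  f <- fit_gbtm(tg$panel, G = 2, degree = 1, dropout = FALSE, seed = 3)
  asn <- posterior_assign(f, tg$panel)
  pm <- as.matrix(asn[, c("p1", "p2")])
  expect_true(all(abs(rowSums(pm) - 1) < 1e-10))
  # at the EM fixed point the mean posterior equals the mixing proportion
  expect_equal(unname(colMeans(pm)), unname(f$pi), tolerance = 1e-4)
  expect_true(all(asn$good_fit == (asn$max_prob >= 0.8)))
  expect_equal(asn$assigned_group, apply(pm, 1, which.max))
})

test_that("a knee far from all but one group mean gets posterior near 1", {
  tg <- two_group_panel(seed = 8, n = 100)
  f <- fit_gbtm(tg$panel, G = 2, degree = 1, dropout = FALSE, seed = 4)
  # synthetic knee lying exactly on the steeper group's mean
  steep <- which.max(vapply(f$beta, function(b) abs(b[2]), numeric(1)))
  months <- c(0, 12, 24, 36, 48, 72, 96)
  u <- months / 96
  mu <- vapply(u, function(uu) sum(f$beta[[steep]] * uu^(0:1)), numeric(1))
  probe <- tibble::tibble(knee_id = "probe", month = months,
                          value = c(0, mu[-1]))
  asn <- posterior_assign(f, dplyr::bind_rows(tg$panel, probe))
  p <- asn[asn$knee_id == "probe", ]
  expect_equal(p$assigned_group, steep)
  expect_gt(p$max_prob, 0.9)
})

test_that("two planted groups are recovered within the stated tolerances", {
  ok_pi <- 0; ok_mean <- 0
  for (s in 1:6) {
    tg <- two_group_panel(seed = 200 + s, n = 500)
    f <- fit_gbtm(tg$panel, G = 2, degree = 1, dropout = FALSE, seed = s)
    ord <- order(f$pi, decreasing = TRUE)
    ok_pi <- ok_pi + all(abs(sort(f$pi) - c(0.3, 0.7)) <= 0.05)
    u <- c(12, 24, 36, 48, 72, 96) / 96
    means <- vapply(f$beta[ord], function(b) cbind(1, u) %*% b,
                    numeric(length(u)))
    true_means <- cbind(0 * u, 5 * u)
    ok_mean <- ok_mean + (max(abs(means - true_means)) <= 0.3)
  }
  expect_gte(ok_pi, 5)
  expect_gte(ok_mean, 5)
})

test_that("BIC selection finds two groups and prunes spurious curvature", {
  tg <- two_group_panel(seed = 301, n = 400)
  sel <- select_model(tg$panel, G_max = 3, seed = 5, dropout = FALSE)
  expect_equal(sel$G, 2L)
  expect_true(all(sel$degree <= 1L))
  expect_equal(nrow(sel$selection_path), 3L)
  expect_equal(sel$bic, min(sel$selection_path$bic))
})

test_that("a purely linear mean loses its quadratic and cubic terms", {
  hits <- 0
  for (s in 1:5) {
    spec <- synthetic_spec(
      n_rows = 300,
      traj_groups = list(lin = list(pi = 1, beta = c(0, 4))),
      traj_sd = 1, dropout_rate = c(early = 0, late = 0), seed = 400 + s
    )
    sim <- generate_clinical_matrix(spec)
    panel <- generate_longitudinal_panel(spec, sim$truth)
    sel <- select_model(panel, G_max = 1, seed = s, dropout = FALSE)
    if (sel$degree[1] <= 1L) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("mixing-proportion intervals behave like 1/sqrt(n)", {
  ci_small <- group_proportion_ci(
    fit_gbtm(two_group_panel(seed = 501, n = 150)$panel, G = 2, degree = 1,
             dropout = FALSE, seed = 1)
  )
  ci_large <- group_proportion_ci(
    fit_gbtm(two_group_panel(seed = 502, n = 600)$panel, G = 2, degree = 1,
             dropout = FALSE, seed = 1)
  )
  w_small <- ci_small$upper[1] - ci_small$lower[1]
  w_large <- ci_large$upper[1] - ci_large$lower[1]
  # width ratio should be near sqrt(600/150) = 2
  expect_gt(w_small / w_large, 1.4)
  expect_lt(w_small / w_large, 2.8)
  expect_true(all(ci_small$lower >= 0 & ci_small$upper <= 1))

  g1 <- fit_gbtm(two_group_panel(seed = 503, n = 80)$panel, G = 1,
                 degree = 1, dropout = FALSE, seed = 1)
  ci1 <- group_proportion_ci(g1)
  expect_equal(ci1$estimate, 1)
  expect_equal(ci1$lower, 1)
  expect_equal(ci1$upper, 1)
})

test_that("proportion intervals cover the truth at roughly nominal rate", {
  covered <- 0
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    tg <- two_group_panel(seed = 600 + s, n = 250)
    f <- fit_gbtm(tg$panel, G = 2, degree = 1, dropout = FALSE, seed = s)
    ci <- group_proportion_ci(f)
    big <- which.max(ci$estimate)
    covered <- covered + (ci$lower[big] <= 0.7 && ci$upper[big] >= 0.7)
  }
  # 3 binomial sd below 95% at n = 30 is ~0.83
  expect_gte(covered / n_rep, 0.8)
})

test_that("tidy and glance expose the fitted mixture faithfully", {
  tg <- two_group_panel(seed = 701, n = 150)
  f <- fit_gbtm(tg$panel, G = 2, degree = 1, dropout = TRUE, seed = 2)
  td <- tidy(f)
  expect_equal(nrow(td), 4L)
  expect_equal(td$estimate[td$group == 1], f$beta[[1]])
  gl <- glance(f)
  expect_equal(gl$bic, f$bic)
  expect_equal(gl$G, 2L)
  # BIC consistent with its convention
  expect_equal(gl$bic, -2 * f$loglik + f$n_params * log(f$n_knees))
})
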