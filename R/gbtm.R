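# Group-based trajectory modeling of change-from-baseline pain scores:
# a finite mixture of polynomial mean trajectories with shared Gaussian
# residual, optionally extended with a per-group logistic dropout model,
# fit by EM. Months are rescaled by 1/96 inside the polynomial basis for
# conditioning; month 0 is the change-from-baseline anchor (identically 0)
# and is excluded from the likelihood.

MONTH_SCALE <- 96

# assemble per-knee response/design/dropout structures from a long panel
gbtm_prepare <- function(panel, max_degree = 3L) {
  need <- c("knee_id", "month", "value")
  if (!all(need %in% names(panel))) {
    abort("Panel must have columns knee_id, month, value.")
  }
  schedule <- sort(unique(panel$month))
  post <- schedule[schedule > 0]
  if (length(post) == 0L) abort("Panel has no post-baseline visits.")
  obs <- panel[panel$month > 0, , drop = FALSE]
  ids <- unique(panel$knee_id)
  no_post <- setdiff(ids, unique(obs$knee_id))
  if (length(no_post)) {
    warn(sprintf("%d knee(s) without post-baseline observations excluded.",
                 length(no_post)))
    ids <- setdiff(ids, no_post)
  }
  idx <- match(obs$knee_id, ids)
  keep <- !is.na(idx)
  obs <- obs[keep, , drop = FALSE]; idx <- idx[keep]
  u <- obs$month / MONTH_SCALE
  U <- outer(u, 0:max_degree, `^`)

  # dropout bookkeeping: leading run of observed scheduled visits per knee
  n <- length(ids)
  obs_flag <- matrix(FALSE, n, length(post))
  for (r in seq_along(idx)) {
    obs_flag[idx[r], match(obs$month[r], post)] <- TRUE
  }
  val_mat <- matrix(NA_real_, n, length(post))
  val_mat[cbind(idx, match(obs$month, post))] <- obs$value

  drop_idx <- integer(0); drop_prev <- numeric(0); drop_event <- integer(0)
  for (i in seq_len(n)) {
    prev_val <- 0 # baseline change score
    for (t in seq_along(post)) {
      drop_idx <- c(drop_idx, i)
      drop_prev <- c(drop_prev, prev_val)
      if (obs_flag[i, t]) {
        drop_event <- c(drop_event, 0L)
        prev_val <- val_mat[i, t]
      } else {
        drop_event <- c(drop_event, 1L)
        break # monotone: observation ends at first missing visit
      }
    }
  }
  list(
    ids = ids, n = n, y = obs$value, knee = idx, U = U,
    n_obs = length(obs$value), schedule = schedule, post = post,
    drop_knee = drop_idx, drop_prev = drop_prev, drop_event = drop_event,
    max_degree = max_degree
  )
}

# n x G matrix of per-knee log component densities (Gaussian x dropout)
gbtm_logdens <- function(prep, beta, sigma, dropout_coef) {
  G <- length(beta)
  ld <- matrix(0, prep$n, G)
  for (g in seq_len(G)) {
    b <- beta[[g]]
    mu <- drop(prep$U[, seq_along(b), drop = FALSE] %*% b)
    lg <- dnorm(prep$y, mu, sigma, log = TRUE)
    ld[, g] <- drop(rowsum(lg, prep$knee, reorder = TRUE))
    if (!is.null(dropout_coef)) {
      eta <- dropout_coef[g, 1] + dropout_coef[g, 2] * prep$drop_prev
      lp <- ifelse(prep$drop_event == 1L,
                   plogis(eta, log.p = TRUE),
                   plogis(-eta, log.p = TRUE))
      ld[, g] <- ld[, g] + drop(rowsum(lp, prep$drop_knee, reorder = TRUE))
    }
  }
  ld
}

# weighted logistic regression with intercept + one covariate by Newton
# iterations; tiny closed-form 2x2 solve, warm-startable. Returns `start`
# unchanged when the information matrix is (near-)singular.
wlogit2 <- function(x, y, wt, start = c(-2, 0), maxit = 8L, tol = 1e-8) {
  b0 <- start[1]; b1 <- start[2]
  for (it in seq_len(maxit)) {
    eta <- b0 + b1 * x
    p <- plogis(eta)
    wv <- wt * p * (1 - p)
    g0 <- sum(wt * (y - p)); g1 <- sum(wt * (y - p) * x)
    h00 <- sum(wv); h01 <- sum(wv * x); h11 <- sum(wv * x * x)
    det <- h00 * h11 - h01 * h01
    if (!is.finite(det) || det < 1e-12) return(start)
    d0 <- (h11 * g0 - h01 * g1) / det
    d1 <- (h00 * g1 - h01 * g0) / det
    b0 <- b0 + d0; b1 <- b1 + d1
    if (!is.finite(b0) || !is.finite(b1)) return(start)
    if (abs(d0) + abs(d1) < tol) break
  }
  # cap runaway coefficients (quasi-separation)
  c(max(min(b0, 30), -30), max(min(b1, 30), -30))
}

gbtm_count_params <- function(degree, G, dropout) {
  sum(degree + 1L) + (G - 1L) + 1L + if (dropout) 2L * G else 0L
}

em_mstep <- function(prep, w, degree, dropout, beta_old, coef_old) {
  G <- ncol(w)
  pi_hat <- pmax(colMeans(w), 1e-10)
  pi_hat <- pi_hat / sum(pi_hat)
  beta <- vector("list", G)
  sse <- 0
  for (g in seq_len(G)) {
    wt <- w[prep$knee, g]
    X <- prep$U[, seq_len(degree[g] + 1L), drop = FALSE]
    if (sum(wt) < 1e-8) {
      beta[[g]] <- beta_old[[g]]
    } else {
      fit <- stats::lm.wfit(X, prep$y, wt)
      beta[[g]] <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    }
    resid <- prep$y - drop(X %*% beta[[g]])
    sse <- sse + sum(wt * resid^2)
  }
  sigma <- sqrt(max(sse / prep$n_obs, 1e-12))
  coefs <- NULL
  if (dropout) {
    coefs <- coef_old %||% matrix(c(-2, 0), G, 2, byrow = TRUE)
    for (g in seq_len(G)) {
      wt <- w[prep$drop_knee, g]
      if (sum(wt) < 1e-8) next
      coefs[g, ] <- wlogit2(prep$drop_prev, prep$drop_event, wt,
                            start = coefs[g, ])
    }
  }
  list(pi = pi_hat, beta = beta, sigma = sigma, dropout_coef = coefs)
}

em_run <- function(prep, w, degree, dropout, max_iter, tol,
                   debug = FALSE) {
  G <- ncol(w)
  par <- em_mstep(prep, w, degree, dropout,
                  beta_old = rep(list(rep(0, max(degree) + 1L)), G),
                  coef_old = NULL)
  ll_path <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    ld <- gbtm_logdens(prep, par$beta, par$sigma, par$dropout_coef)
    lp <- sweep(ld, 2, log(par$pi), `+`)
    lse <- row_logsumexp(lp)
    ll <- sum(lse)
    if (debug && ll < ll_prev - 1e-8 * (1 + abs(ll_prev))) {
      abort("Internal error: EM log-likelihood decreased.")
    }
    ll_path <- c(ll_path, ll)
    w <- exp(lp - lse)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      return(list(par = par, w = w, loglik = ll, path = ll_path,
                  iterations = it, converged = TRUE))
    }
    ll_prev <- ll
    par <- em_mstep(prep, w, degree, dropout, par$beta, par$dropout_coef)
  }
  list(par = par, w = w, loglik = ll_prev, path = ll_path,
       iterations = max_iter, converged = FALSE)
}

#' Fit a group-based trajectory model
#'
#' Maximum-likelihood fit (EM) of a `G`-group finite mixture of polynomial
#' mean trajectories for change-from-baseline scores observed at scheduled
#' visits, with a shared residual sd. With `dropout = TRUE` each group also
#' carries a logistic model for the probability that observation ends at a
#' visit, with intercept and the previous observed response as covariates;
#' this ties informative attrition into the group likelihoods. The best of
#' `n_starts` seeded random initializations is run to convergence.
#'
#' @param panel Long tibble `knee_id`, `month`, `value` (change from
#'   baseline; month 0 rows are anchors and do not enter the likelihood).
#' @param G Number of trajectory groups (>= 1).
#' @param degree Polynomial degree per group (scalar or length-`G` vector,
#'   each <= 3). The basis is in months / 96.
#' @param dropout Include the logistic dropout extension?
#' @param seed Integer seed for the random starts.
#' @param n_starts Random initializations (short EM runs; best continued).
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param debug Assert the EM log-likelihood is monotone every iteration.
#' @param init_posterior Optional n-by-G posterior matrix; when given, a
#'   single EM run is warm-started from it instead of the multistart.
#' @return A `gbtm` object: `G`, `degree`, `beta` (per-group coefficients on
#'   the scaled basis), `pi`, `sigma`, `dropout_coef`, `loglik`, `bic`
#'   (\eqn{-2\ell + k \log n}, minimized), `n_knees`, `posterior`,
#'   `convergence`, `schedule`.
#' @export
fit_gbtm <- function(panel, G, degree = 3L, dropout = TRUE, seed = 1L,
                     n_starts = 10L, max_iter = 500L, tol = 1e-6,
                     debug = FALSE, init_posterior = NULL) {
  check_scalar(G, "G", 1)
  G <- as.integer(G)
  degree <- rep_len(as.integer(degree), G)
  if (any(degree < 0L) || any(degree > 3L)) {
    abort("Polynomial degrees must be between 0 and 3.")
  }
  prep <- gbtm_prepare(panel, max_degree = max(degree, 3L))
  fit_gbtm_impl(prep, G, degree, dropout, seed, n_starts, max_iter, tol,
                debug, init_posterior)
}

# core fitter working from a prepared panel (avoids re-preparing in loops);
# init_posterior warm-starts a single EM run instead of multistart
fit_gbtm_impl <- function(prep, G, degree, dropout, seed, n_starts = 10L,
                          max_iter = 500L, tol = 1e-6, debug = FALSE,
                          init_posterior = NULL) {
  if (!is.null(init_posterior)) {
    stopifnot(nrow(init_posterior) == prep$n, ncol(init_posterior) == G)
    w0 <- init_posterior
  } else {
    runs <- withr::with_seed(derive_seed(seed, 30L), {
      inits <- lapply(seq_len(max(1L, if (G == 1L) 1L else n_starts)), function(s) {
        w <- matrix(stats::rexp(prep$n * G), prep$n, G)
        w / rowSums(w)
      })
      lapply(inits, function(w) {
        em_run(prep, w, degree, dropout, max_iter = 30L, tol = tol,
               debug = debug)
      })
    })
    best <- which.max(vapply(runs, `[[`, numeric(1), "loglik"))
    w0 <- runs[[best]]$w
  }
  final <- em_run(prep, w0, degree, dropout,
                  max_iter = max_iter, tol = tol, debug = debug)
  if (!final$converged) {
    warn("EM reached the iteration cap without meeting the tolerance; returning the best attempt.")
  }
  k <- gbtm_count_params(degree, G, dropout)
  structure(
    list(
      G = G, degree = degree,
      beta = final$par$beta, pi = final$par$pi, sigma = final$par$sigma,
      dropout = dropout, dropout_coef = final$par$dropout_coef,
      loglik = final$loglik,
      bic = -2 * final$loglik + k * log(prep$n),
      n_params = k, n_knees = prep$n,
      posterior = final$w,
      ids = prep$ids,
      schedule = prep$schedule,
      convergence = list(iterations = final$iterations,
                         converged = final$converged,
                         loglik_path = final$path),
      seed = as.integer(seed)
    ),
    class = "gbtm"
  )
}

#' @export
print.gbtm <- function(x, ...) {
  cat(sprintf("<gbtm> %d group(s), degrees (%s), n = %d knees\n",
              x$G, paste(x$degree, collapse = ", "), x$n_knees))
  cat(sprintf("  pi: %s | sigma %.3f | loglik %.2f | BIC %.2f\n",
              paste(sprintf("%.3f", x$pi), collapse = ", "),
              x$sigma, x$loglik, x$bic))
  invisible(x)
}

#' Log-likelihood of a trajectory model on a panel
#'
#' Evaluates \eqn{\sum_i \log \sum_g \pi_g f_g(y_i)} where \eqn{f_g} is the
#' product of normal visit densities around the group polynomial (and, when
#' the model carries a dropout extension, the logistic probabilities of the
#' knee's observation pattern). Independent of knee ordering.
#'
#' @param model A fitted `gbtm`.
#' @param panel Long panel (same layout as for [fit_gbtm()]).
#' @return Scalar log-likelihood.
#' @export
gbtm_loglik <- function(model, panel) {
  prep <- gbtm_prepare(panel, max_degree = max(model$degree))
  ld <- gbtm_logdens(prep, model$beta, model$sigma, model$dropout_coef)
  sum(row_logsumexp(sweep(ld, 2, log(model$pi), `+`)))
}

# Wald p-value of each group's highest-order coefficient, from the
# weighted-least-squares information at the current posterior weights
top_term_pvalues <- function(model, prep) {
  vapply(seq_len(model$G), function(g) {
    d <- model$degree[g]
    if (d == 0L) return(NA_real_)
    X <- prep$U[, seq_len(d + 1L), drop = FALSE]
    wt <- model$posterior[prep$knee, g]
    xtwx <- crossprod(X * sqrt(wt))
    cv <- tryCatch(model$sigma^2 * solve(xtwx), error = function(e) NULL)
    if (is.null(cv)) return(NA_real_)
    se <- sqrt(diag(cv))[d + 1L]
    zst <- model$beta[[g]][d + 1L] / se
    2 * pnorm(-abs(zst))
  }, numeric(1))
}

#' Select the number of trajectory groups by BIC
#'
#' Fits models with 1 to `G_max` groups. Each fit starts from cubic means;
#' while any group's highest-order coefficient has Wald p > `prune_p`, the
#' least significant such term is removed and the model refit, so trajectory
#' shapes are driven by the significance of their polynomial terms. The
#' model with the smallest BIC is returned, with the whole selection path
#' recorded in `$selection_path`.
#'
#' @inheritParams fit_gbtm
#' @param G_max Largest group count to consider.
#' @param prune_p Wald p-value above which the top polynomial term of a
#'   group is pruned.
#' @return The BIC-best `gbtm`, with a `selection_path` tibble attached
#'   (`G`, `degrees`, `loglik`, `bic`).
#' @export
select_model <- function(panel, G_max = 4L, seed = 1L, dropout = TRUE,
                         n_starts = 10L, prune_p = 0.05, max_iter = 500L,
                         tol = 1e-6) {
  check_scalar(G_max, "G_max", 1)
  prep <- gbtm_prepare(panel, max_degree = 3L)
  path <- list()
  fits <- vector("list", G_max)
  for (G in seq_len(G_max)) {
    degree <- rep(3L, G)
    fit <- fit_gbtm_impl(prep, G, degree, dropout,
                         seed = derive_seed(seed, 40L + G),
                         n_starts = n_starts, max_iter = max_iter, tol = tol)
    repeat {
      pv <- top_term_pvalues(fit, prep)
      worst <- which.max(ifelse(is.na(pv), -Inf, pv))
      if (!length(worst) || is.na(pv[worst]) || pv[worst] <= prune_p) break
      degree[worst] <- degree[worst] - 1L
      # warm-start the reduced model from the current posterior
      fit <- fit_gbtm_impl(prep, G, degree, dropout,
                           seed = derive_seed(seed, 40L + G),
                           n_starts = n_starts, max_iter = max_iter,
                           tol = tol, init_posterior = fit$posterior)
    }
    fits[[G]] <- fit
    path[[G]] <- tibble::tibble(
      G = G, degrees = paste(fit$degree, collapse = ","),
      loglik = fit$loglik, bic = fit$bic
    )
  }
  best <- which.min(vapply(fits, `[[`, numeric(1), "bic"))
  out <- fits[[best]]
  out$selection_path <- dplyr::bind_rows(path)
  out
}

#' Posterior trajectory-group assignment
#'
#' Computes each knee's posterior probability of belonging to each group
#' (proportional to \eqn{\pi_g} times the group likelihood of the knee's
#' observed series), assigns by the largest probability (ties to the lowest
#' group id), and flags assignments with maximum posterior of at least 0.8
#' as good fits.
#'
#' @param model A fitted `gbtm`.
#' @param panel Long panel containing the knees to assign.
#' @return A `trajectory_assignment` tibble: `knee_id`, posterior columns
#'   `p1..pG`, `assigned_group`, `max_prob`, `good_fit`.
#' @export
posterior_assign <- function(model, panel) {
  prep <- gbtm_prepare(panel, max_degree = max(model$degree))
  ld <- gbtm_logdens(prep, model$beta, model$sigma, model$dropout_coef)
  lp <- sweep(ld, 2, log(model$pi), `+`)
  lse <- row_logsumexp(lp)
  w <- exp(lp - lse)
  assigned <- apply(w, 1L, which.max) # ties -> lowest index
  out <- tibble::as_tibble(setNames(
    as.data.frame(w), paste0("p", seq_len(model$G))
  ))
  out <- dplyr::bind_cols(tibble::tibble(knee_id = prep$ids), out)
  out$assigned_group <- as.integer(assigned)
  out$max_prob <- apply(w, 1L, max)
  out$good_fit <- out$max_prob >= 0.8
  class(out) <- c("trajectory_assignment", class(out))
  out
}

#' Confidence intervals for the mixing proportions
#'
#' Normal-approximation intervals for each group's membership probability,
#' derived from the empirical observed information of the multinomial-logit
#' mixing parameters at the EM solution (outer product of per-knee scores
#' \eqn{w_{ig} - \pi_g}), mapped back to the probability scale by the delta
#' method and clamped to [0, 1]. A singular information matrix yields the
#' trivial interval [0, 1] with `degenerate = TRUE`.
#'
#' @param model A fitted `gbtm`.
#' @param level Confidence level.
#' @return Tibble: `group`, `estimate`, `lower`, `upper`, `degenerate`.
#' @export
group_proportion_ci <- function(model, level = 0.95) {
  G <- model$G
  zq <- stats::qnorm(1 - (1 - level) / 2)
  if (G == 1L) {
    return(tibble::tibble(group = 1L, estimate = 1, lower = 1, upper = 1,
                          degenerate = FALSE))
  }
  w <- model$posterior
  p <- model$pi
  s <- sweep(w[, -G, drop = FALSE], 2, p[-G]) # per-knee score of logits
  info <- crossprod(s)
  va <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(va)) {
    return(tibble::tibble(group = seq_len(G), estimate = p, lower = 0,
                          upper = 1, degenerate = TRUE))
  }
  # delta method: J = d pi / d alpha, alpha = logit weights (ref = group G)
  J <- matrix(0, G, G - 1L)
  for (g in seq_len(G)) {
    for (h in seq_len(G - 1L)) {
      J[g, h] <- p[g] * ((g == h) - p[h])
    }
  }
  vp <- J %*% va %*% t(J)
  se <- sqrt(pmax(diag(vp), 0))
  tibble::tibble(
    group = seq_len(G),
    estimate = p,
    lower = pmax(0, p - zq * se),
    upper = pmin(1, p + zq * se),
    degenerate = FALSE
  )
}

#' Tidy methods for trajectory models
#'
#' `tidy()` returns one row per group and polynomial term (coefficients on
#' the scaled basis in months / 96 and on the natural per-month scale);
#' `glance()` returns the one-row model summary.
#'
#' @param x A `gbtm`.
#' @param ... Unused.
#' @method tidy gbtm
#' @export
tidy.gbtm <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(x$G), function(g) {
    b <- x$beta[[g]]
    tibble::tibble(
      group = g,
      term = paste0("u^", seq_along(b) - 1L),
      estimate = b,
      estimate_per_month = b / MONTH_SCALE^(seq_along(b) - 1L),
      pi = x$pi[g]
    )
  }))
}

#' @rdname tidy.gbtm
#' @method glance gbtm
#' @export
glance.gbtm <- function(x, ...) {
  tibble::tibble(
    G = x$G, loglik = x$loglik, bic = x$bic, sigma = x$sigma,
    n_knees = x$n_knees, n_params = x$n_params,
    converged = x$convergence$converged,
    iterations = x$convergence$iterations
  )
}

# group mean change at given months (natural scale)
gbtm_means <- function(model, months) {
  u <- months / MONTH_SCALE
  dplyr::bind_rows(lapply(seq_len(model$G), function(g) {
    b <- model$beta[[g]]
    tibble::tibble(
      group = g, month = months,
      mean = drop(outer(u, seq_along(b) - 1L, `^`) %*% b)
    )
  }))
}
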