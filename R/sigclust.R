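#' Cluster index of a two-class split
#'
#' The ratio of within-cluster variation to total variation:
#' \deqn{CI = \frac{\sum_k \sum_{i \in k} \|x_i - \bar x_k\|^2}
#'                 {\sum_i \|x_i - \bar x\|^2}.}
#' Tight, well-separated clusters give a low index; loose, overlapping
#' clusters an index near 1.
#'
#' @param x Numeric matrix (observations in rows).
#' @param labels Two-class label vector, one per row.
#' @return Scalar cluster index in [0, 1].
#' @export
#' @examples
#' x <- matrix(c(0, 1, 2, 3), ncol = 1)
#' cluster_index(x, c(1, 1, 2, 2)) # 0.2
cluster_index <- function(x, labels) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x)) abort("One label per row required.")
  lv <- unique(labels)
  if (length(lv) != 2L) abort("`labels` must define exactly two classes.")
  if (any(tabulate(match(labels, lv)) == 0L)) abort("Both classes must be non-empty.")
  total <- sum(sweep(x, 2, colMeans(x))^2)
  if (total < .Machine$double.eps) {
    abort("Total variation is zero: all points identical.")
  }
  within <- sum(vapply(lv, function(l) {
    xi <- x[labels == l, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
  within / total
}

#' Estimate the single-Gaussian null model
#'
#' The null hypothesis is that the data come from one Gaussian — a proxy for
#' unclustered data. Its covariance is taken axis-aligned with variances
#' equal to the sample-covariance eigenvalues hard-thresholded from below at
#' a robust background noise variance
#' \eqn{\sigma_N^2 = (\mathrm{MAD}(\mathrm{cells}) / 0.6745)^2}, computed
#' from all column-centered matrix cells; when the feature count exceeds
#' n - 1 the trailing eigenvalues are padded at the background variance.
#'
#' @param x Numeric data matrix, n >= 2 rows.
#' @return A `sigclust_null` list: `eigenvalues` (non-increasing),
#'   `background_var`, `dim`, `n`.
#' @export
estimate_null_model <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("Need at least 2 observations.")
  xc <- sweep(x, 2, colMeans(x))
  m <- mad(as.vector(xc)) # mad() already rescales by 1/0.67449
  if (m < .Machine$double.eps) abort("Degenerate data: cell MAD is zero.")
  bg <- m^2
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, bg)
  structure(
    list(eigenvalues = ev, background_var = bg, dim = ncol(x), n = nrow(x)),
    class = "sigclust_null"
  )
}

#' Simulate the null distribution of the cluster index
#'
#' Draws `n_sim` datasets of `n` points from the axis-aligned Gaussian with
#' the null eigenvalue variances, splits each by 2-means (best of `restarts`
#' random starts) and records the resulting cluster index.
#'
#' @param null A `sigclust_null` from [estimate_null_model()].
#' @param n_sim Number of simulated datasets (>= 100).
#' @param seed Integer seed; identical seeds give identical CI vectors.
#' @param restarts 2-means restarts per simulated dataset.
#' @return Numeric vector of `n_sim` cluster indices.
#' @export
simulate_null_ci <- function(null, n_sim = 1000L, seed = 1L, restarts = 10L) {
  stopifnot(inherits(null, "sigclust_null"))
  if (n_sim < 100L) abort("`n_sim` must be at least 100 for a usable null.")
  sds <- sqrt(null$eigenvalues)
  n <- null$n; d <- null$dim
  withr::with_seed(derive_seed(seed, 5L), {
    vapply(seq_len(n_sim), function(s) {
      xs <- matrix(rnorm(n * d), n, d) %*% diag(sds, d)
      km <- suppressWarnings(kmeans(xs, centers = 2L, nstart = restarts))
      km$tot.withinss / km$totss
    }, numeric(1))
  })
}

#' SigClust test for one pair of clusters
#'
#' Tests whether a two-class split is stronger than splits that 2-means finds
#' in unclustered Gaussian data. The observed cluster index is computed from
#' the supplied labels (the hypothesis under test is the given clusters'
#' separation; set `use_given_labels = FALSE` to re-split the observed data
#' by 2-means instead, the classical formulation). The null is estimated from
#' the pooled data of the pair and simulated by [simulate_null_ci()]. The
#' z-score \eqn{(CI_{obs} - \bar{CI}_{null}) / sd(CI_{null})} is reported
#' with its one-sided normal p-value and the empirical p-value; a pair is
#' flagged significantly different when z < -2 (one-sided normal p below
#' 0.023).
#'
#' @param x Numeric matrix: pooled observations of the two clusters.
#' @param labels Two-class labels, one per row.
#' @param n_sim,seed,restarts Passed to [simulate_null_ci()].
#' @param use_given_labels Use the supplied labels for the observed CI
#'   (default), or re-run 2-means on `x`.
#' @return A `sigclust_result` list: `ci_observed`, `null_mean`, `null_sd`,
#'   `z`, `p_normal`, `p_empirical`, `significant`, `n_sim`, `seed`.
#' @export
sigclust_pair <- function(x, labels, n_sim = 1000L, seed = 1L,
                          restarts = 10L, use_given_labels = TRUE) {
  x <- as.matrix(x)
  ci_obs <- if (use_given_labels) {
    cluster_index(x, labels)
  } else {
    km <- suppressWarnings(kmeans(x, centers = 2L, nstart = restarts))
    km$tot.withinss / km$totss
  }
  null <- estimate_null_model(x)
  cis <- simulate_null_ci(null, n_sim = n_sim, seed = seed,
                          restarts = restarts)
  mu <- mean(cis); s <- sd(cis)
  z <- (ci_obs - mu) / s
  structure(
    list(
      ci_observed = ci_obs, null_mean = mu, null_sd = s,
      z = z, p_normal = pnorm(z), p_empirical = mean(cis <= ci_obs),
      significant = z < -2, n_sim = as.integer(n_sim),
      seed = as.integer(seed), null = null
    ),
    class = "sigclust_result"
  )
}

#' @export
print.sigclust_result <- function(x, ...) {
  cat(sprintf(
    "<sigclust> CI %.4f vs null %.4f (sd %.4f): z = %.2f, p = %.4f%s\n",
    x$ci_observed, x$null_mean, x$null_sd, x$z, x$p_normal,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' One-sided normal p-value of a SigClust z-score
#'
#' @param z z-score(s).
#' @return \eqn{\Phi(z)}; at z = -2 this is 0.02275, the basis of the
#'   "z below -2 means p below 0.023" significance rule.
#' @export
sigclust_z_to_p <- function(z) pnorm(z)

#' Pairwise SigClust over a bicluster set
#'
#' Tests every unordered pair of biclusters. For a pair, the data are the
#' rows of the two biclusters but *all* prepared columns (not the
#' biclusters' own feature subsets), so separation is judged in the full
#' feature space. K biclusters give K(K-1)/2 results. No multiplicity
#' correction is applied by default, matching exploratory use; set
#' `bonferroni = TRUE` to adjust the significance flag.
#'
#' @param prepared A `prepared_matrix` (or bare numeric matrix with row
#'   names).
#' @param bset A `bicluster_set`.
#' @param n_sim,seed,restarts Per-pair simulation settings; each pair gets a
#'   seed derived deterministically from `seed`.
#' @param bonferroni Adjust the z threshold for the number of pairs?
#' @return Tibble: one row per pair with `bicluster_a`, `bicluster_b`,
#'   `n_a`, `n_b`, `ci`, `null_mean`, `null_sd`, `z`, `p_normal`,
#'   `p_empirical`, `significant`.
#' @export
pairwise_sigclust <- function(prepared, bset, n_sim = 1000L, seed = 1L,
                              restarts = 10L, bonferroni = FALSE) {
  mat <- if (inherits(prepared, "prepared_matrix")) prepared$values else
    as.matrix(prepared)
  k <- length(bset$biclusters)
  if (k < 2L) abort("Need at least 2 biclusters for pairwise testing.")
  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)
  thr <- if (bonferroni) stats::qnorm(0.02275013 / n_pairs) else -2
  rows <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ra <- bset$biclusters[[a]]$rows; rb <- bset$biclusters[[b]]$rows
    if (length(ra) < 2L || length(rb) < 2L) {
      warn(sprintf("Pair (%d, %d) skipped: a class has fewer than 2 rows.",
                   a, b))
      next
    }
    xp <- mat[c(ra, rb), , drop = FALSE]
    lab <- rep(c(a, b), c(length(ra), length(rb)))
    res <- sigclust_pair(xp, lab, n_sim = n_sim,
                         seed = derive_seed(seed, 100L + p),
                         restarts = restarts)
    rows[[p]] <- tibble::tibble(
      bicluster_a = a, bicluster_b = b,
      n_a = length(ra), n_b = length(rb),
      ci = res$ci_observed, null_mean = res$null_mean,
      null_sd = res$null_sd, z = res$z,
      p_normal = res$p_normal, p_empirical = res$p_empirical,
      significant = res$z < thr
    )
  }
  dplyr::bind_rows(rows)
}

#' Project a cluster pair onto the mean-difference plane
#'
#' Axis 1 is the unit vector between the two class means; axis 2 is the
#' first principal component of the data after the mean-difference direction
#' has been projected out (so the two axes are orthogonal). This is the
#' two-dimensional view in which pairwise separation is inspected visually.
#'
#' @param x Numeric matrix (rows = observations).
#' @param labels Two-class labels.
#' @return Tibble: `row`, `label`, `md` (mean-difference coordinate), `pc`
#'   (orthogonal principal-component coordinate). The axes are attached as
#'   attributes `axis1`, `axis2`.
#' @export
mean_difference_projection <- function(x, labels) {
  x <- as.matrix(x)
  lv <- unique(labels)
  if (length(lv) != 2L) abort("`labels` must define exactly two classes.")
  m1 <- colMeans(x[labels == lv[1], , drop = FALSE])
  m2 <- colMeans(x[labels == lv[2], , drop = FALSE])
  md <- m2 - m1
  nrm <- sqrt(sum(md^2))
  if (nrm < .Machine$double.eps) abort("Class means are identical.")
  a1 <- md / nrm
  xc <- sweep(x, 2, colMeans(x))
  resid <- xc - outer(drop(xc %*% a1), a1)
  pc <- prcomp(resid, center = FALSE, scale. = FALSE)
  a2 <- pc$rotation[, 1]
  a2 <- a2 - sum(a2 * a1) * a1
  a2 <- a2 / sqrt(sum(a2^2))
  out <- tibble::tibble(
    row = if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x))),
    label = labels,
    md = drop(xc %*% a1),
    pc = drop(xc %*% a2)
  )
  attr(out, "axis1") <- a1
  attr(out, "axis2") <- a2
  out
}
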