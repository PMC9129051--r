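#' Specify a synthetic knee-OA cohort
#'
#' Builds the parameter object consumed by [generate_clinical_matrix()],
#' [generate_longitudinal_panel()] and [generate_outcomes()]. The generator
#' emulates the statistical structure the downstream analysis assumes: a
#' mixed-type baseline feature matrix containing planted *additive* biclusters
#' (cells \eqn{\mu_b + r_i + c_j + \varepsilon}), a longitudinal pain panel
#' drawn from a known finite mixture of polynomial trajectories with monotone
#' dropout, and structural-progression outcomes (KLG, arthroplasty, joint
#' space width) whose rates depend on planted bicluster membership.
#'
#' Defaults describe the benchmark cohort used throughout the package's
#' validation: 300 knees by 40 continuous features carrying three
#' row-disjoint planted phenotypes of 96 knees each (12 knees belong to no
#' phenotype). Each phenotype spans all features — mirroring clinical
#' biclusters, whose feature sets are broad and heavily overlapping — and is
#' distinguished by its column profile: per feature, the three phenotype
#' levels are a random permutation of `profile_levels`, giving the
#' "high in one group, low in another" patterns that make phenotypes
#' mutually distinguishable while keeping every feature's variance equal
#' (so standardization preserves within-block additivity). Within-block
#' noise sd is 0.2. The pain panel follows a four-group trajectory mixture
#' (stable / improvement / worsening / up-down) with attrition increasing
#' after month 48.
#'
#' @param n_rows,n_cols Matrix dimensions (knees by features), both >= 2.
#' @param feature_kinds Character vector of length `n_cols`; each element one
#'   of `"continuous"`, `"binary"`, `"ordinal:<k>"`, `"nominal:<k>"`.
#'   Defaults to all-continuous.
#' @param planted_biclusters List of blocks; each block is a list with
#'   integer vectors `rows`, `cols` and scalars `mu` (overall block effect),
#'   `row_sd`, `col_sd` (scales of the additive row/column effects; `col_sd`
#'   is ignored under the `"permuted-levels"` profile). Row sets must be
#'   pairwise disjoint; each knee belongs to at most one block.
#' @param col_profile How block column effects are drawn:
#'   `"permuted-levels"` (default; per column, the blocks' effects are a
#'   random permutation of `profile_levels`, which then must have one level
#'   per block) or `"independent"` (iid `N(0, col_sd)` per block).
#' @param profile_levels Numeric vector of block column-effect levels used
#'   by the `"permuted-levels"` profile.
#' @param noise_sd Gaussian noise sd inside planted blocks (> 0).
#' @param background Parameters of non-block latent cells,
#'   `list(mean =, sd =)`; the default standard-normal background matches the
#'   post-standardization scale the biclustering consumes.
#' @param binary_quantile Latent quantile above which a binary feature is 1.
#' @param traj_groups List of trajectory groups; each a list with `pi`
#'   (mixing proportion), `beta` (polynomial coefficients of the mean change
#'   from baseline, evaluated on months rescaled by 1/96) and the groups share
#'   residual sd `traj_sd`. Proportions must sum to 1.
#' @param traj_sd Residual sd of pain change scores around the group mean.
#' @param visit_months Visit schedule in months; month 0 is the baseline.
#' @param dropout_rate Named numeric: per-visit probability that a knee still
#'   under observation is lost before that visit, `c(early =, late =)`; `late`
#'   applies to visits after month 48.
#' @param qjsw_params Joint-space-width generator: baseline mm distribution
#'   per compartment and slope (mm/month) distribution per membership class
#'   (background plus one per planted block). See defaults.
#' @param outcome_params Structural outcome generator: baseline KLG level
#'   probabilities, per-visit KLG progression probability, and cumulative TKA
#'   probability, each per membership class.
#' @param seed Integer seed; generation is a pure function of the spec.
#'
#' @return An object of class `synthetic_spec` (a validated list).
#' @seealso [generate_clinical_matrix()], [write_fixture_bundle()]
#' @export
#' @examples
#' spec <- synthetic_spec(seed = 7)
#' sim <- generate_clinical_matrix(spec)
#' dim(sim$data)
synthetic_spec <- function(n_rows = 300L,
                           n_cols = 40L,
                           feature_kinds = NULL,
                           planted_biclusters = NULL,
                           col_profile = c("permuted-levels", "independent"),
                           profile_levels = c(-0.85, 0, 0.85),
                           noise_sd = 0.2,
                           background = list(mean = 0, sd = 1),
                           binary_quantile = 0.5,
                           traj_groups = NULL,
                           traj_sd = 2,
                           visit_months = c(0, 12, 24, 36, 48, 72, 96),
                           dropout_rate = c(early = 0.03, late = 0.10),
                           qjsw_params = NULL,
                           outcome_params = NULL,
                           seed = 1L) {
  check_scalar(n_rows, "n_rows", 2)
  check_scalar(n_cols, "n_cols", 2)
  check_scalar(noise_sd, "noise_sd", 0, open = TRUE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  feature_kinds <- feature_kinds %||% rep("continuous", n_cols)
  if (length(feature_kinds) != n_cols) {
    abort("`feature_kinds` must have one entry per column.")
  }

  col_profile <- match.arg(col_profile)
  if (is.null(planted_biclusters)) {
    # three row-disjoint phenotypes over all features; block means are mild
    # overall severity shifts, distinctness comes from the column profiles
    m <- max(2L, (n_rows * 24L) %/% 25L %/% 3L) # ~96 per block at n = 300
    mus <- c(0.3, -0.3, 0)
    planted_biclusters <- lapply(1:3, function(b) {
      list(rows = ((b - 1L) * m + 1L):(b * m), cols = seq_len(n_cols),
           mu = mus[b], row_sd = 0.3, col_sd = 0.5)
    })
  }
  if (col_profile == "permuted-levels" && length(planted_biclusters) > 0L &&
      length(profile_levels) != length(planted_biclusters)) {
    abort("`profile_levels` needs one level per planted bicluster.")
  }
  all_rows <- unlist(lapply(planted_biclusters, `[[`, "rows"))
  if (anyDuplicated(all_rows)) {
    abort("Planted bicluster row sets must be pairwise disjoint.")
  }
  for (b in planted_biclusters) {
    if (length(b$rows) < 2L || length(b$cols) < 2L ||
        max(b$rows) > n_rows || max(b$cols) > n_cols || min(b$rows) < 1L ||
        min(b$cols) < 1L) {
      abort("Each planted bicluster needs >= 2 in-range rows and columns.")
    }
  }

  if (is.null(traj_groups)) {
    # four shapes on u = month/96: improvement (accelerating decrease),
    # stable, gradual worsening, increase-then-return
    traj_groups <- list(
      improvement = list(pi = 0.112, beta = c(0, -2.5, -2.5)),
      stable      = list(pi = 0.765, beta = c(0, 0)),
      worsening   = list(pi = 0.090, beta = c(0, 3)),
      up_down     = list(pi = 0.033, beta = c(0, 8, -8))
    )
  }
  pis <- vapply(traj_groups, `[[`, numeric(1), "pi")
  if (abs(sum(pis) - 1) > 1e-12) {
    abort(sprintf("Trajectory mixing proportions must sum to 1 (got %.15f).",
                  sum(pis)))
  }
  check_scalar(traj_sd, "traj_sd", 0, open = TRUE)

  n_classes <- length(planted_biclusters) + 1L # "none" + one per block
  if (is.null(qjsw_params)) {
    qjsw_params <- list(
      baseline_mean = c(medial = 4.5, lateral = 5.5),
      baseline_sd = c(medial = 0.6, lateral = 0.7),
      # mm/month loss by membership class: background first, then per block
      slope_mean = rep_len(c(-0.004, -0.004, -0.012, -0.008), n_classes),
      slope_sd = 0.003,
      noise_sd = 0.15
    )
  }
  if (is.null(outcome_params)) {
    outcome_params <- list(
      klg_baseline_probs = list(
        none = c(0.35, 0.25, 0.20, 0.15, 0.05) # P(KLG = 0..4)
      ),
      prog_prob = rep_len(c(0.02, 0.02, 0.08, 0.05), n_classes),
      tka_prob = rep_len(c(0.04, 0.03, 0.16, 0.10), n_classes)
    )
  }

  spec <- structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      feature_kinds = feature_kinds,
      planted_biclusters = planted_biclusters,
      col_profile = col_profile,
      profile_levels = profile_levels,
      noise_sd = noise_sd,
      background = background,
      binary_quantile = binary_quantile,
      traj_groups = traj_groups,
      traj_sd = traj_sd,
      visit_months = sort(unique(visit_months)),
      dropout_rate = dropout_rate,
      qjsw_params = qjsw_params,
      outcome_params = outcome_params,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d knees x %d features, %d planted bicluster(s), %d trajectory group(s), seed %d\n",
    x$n_rows, x$n_cols, length(x$planted_biclusters), length(x$traj_groups),
    x$seed
  ))
  invisible(x)
}

parse_kind <- function(kind) {
  if (grepl("^(ordinal|nominal):[0-9]+$", kind)) {
    parts <- strsplit(kind, ":", fixed = TRUE)[[1]]
    list(base = parts[1], k = as.integer(parts[2]))
  } else if (kind %in% c("continuous", "binary")) {
    list(base = kind, k = NA_integer_)
  } else {
    abort(sprintf("Unknown feature kind '%s'.", kind))
  }
}

#' Generate the baseline clinical matrix with planted biclusters
#'
#' Draws the latent matrix (standard-normal background, additive planted
#' blocks \eqn{\mu_b + r_i + c_j + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \sigma^2)}), then derives non-continuous
#' features from the latents: binary columns by thresholding at a quantile,
#' ordinal columns by equal-probability binning into `k` levels, nominal
#' columns by binning into `k` unordered labels.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (tibble, `knee_id` plus one column per feature)
#'   and `truth` (a `ground_truth` list: `row_membership`, `column_membership`,
#'   `traj_group`, `true_qjsw_slopes`).
#' @export
generate_clinical_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_rows; d <- spec$n_cols
  withr::with_seed(derive_seed(spec$seed, 1L), {
    lat <- matrix(
      rnorm(n * d, spec$background$mean, spec$background$sd), n, d
    )
    membership <- rep(NA_integer_, n)
    nb <- length(spec$planted_biclusters)
    profiles <- NULL
    if (spec$col_profile == "permuted-levels" && nb > 0L) {
      # per column, block effects are a random permutation of the levels:
      # equal per-column variance, so standardization keeps blocks additive
      profiles <- vapply(seq_len(d), function(j) sample(spec$profile_levels),
                         numeric(nb))
    }
    for (b in seq_along(spec$planted_biclusters)) {
      blk <- spec$planted_biclusters[[b]]
      r <- rnorm(length(blk$rows), 0, blk$row_sd)
      cc <- if (is.null(profiles)) rnorm(length(blk$cols), 0, blk$col_sd) else
        profiles[b, blk$cols]
      eps <- matrix(rnorm(length(blk$rows) * length(blk$cols), 0, spec$noise_sd),
                    length(blk$rows), length(blk$cols))
      lat[blk$rows, blk$cols] <- blk$mu +
        matrix(r, length(blk$rows), length(blk$cols)) +
        matrix(cc, length(blk$rows), length(blk$cols), byrow = TRUE) + eps
      membership[blk$rows] <- b
    }

    cols <- vector("list", d)
    names(cols) <- sprintf("f%02d", seq_len(d))
    for (j in seq_len(d)) {
      k <- parse_kind(spec$feature_kinds[j])
      v <- lat[, j]
      cols[[j]] <- switch(
        k$base,
        continuous = v,
        binary = as.integer(v > quantile(v, spec$binary_quantile)),
        ordinal = {
          br <- quantile(v, probs = seq(0, 1, length.out = k$k + 1L))
          br[1] <- -Inf; br[length(br)] <- Inf
          as.integer(cut(v, breaks = unique(br), labels = FALSE))
        },
        nominal = {
          br <- quantile(v, probs = seq(0, 1, length.out = k$k + 1L))
          br[1] <- -Inf; br[length(br)] <- Inf
          paste0("L", cut(v, breaks = unique(br), labels = FALSE))
        }
      )
    }

    knee_id <- sprintf("K%04d", seq_len(n))
    data <- tibble::as_tibble(c(list(knee_id = knee_id), cols))

    # trajectory group per knee, independent of bicluster membership by
    # default (structural outcomes, not pain mix, carry the linkage)
    pis <- vapply(spec$traj_groups, `[[`, numeric(1), "pi")
    traj <- sample.int(length(pis), n, replace = TRUE, prob = pis)

    qp <- spec$qjsw_params
    cls <- ifelse(is.na(membership), 1L, membership + 1L)
    slopes <- cbind(
      medial = rnorm(n, qp$slope_mean[cls], qp$slope_sd),
      lateral = rnorm(n, qp$slope_mean[cls], qp$slope_sd)
    )
    rownames(slopes) <- knee_id

    truth <- structure(
      list(
        row_membership = setNames(membership, knee_id),
        column_membership = lapply(spec$planted_biclusters, function(b) {
          sprintf("f%02d", b$cols)
        }),
        traj_group = setNames(traj, knee_id),
        true_qjsw_slopes = slopes
      ),
      class = "ground_truth"
    )
    list(data = data, truth = truth)
  })
}

#' Generate the longitudinal pain panel
#'
#' One record per knee and observed visit. The response is the change from
#' baseline of a pain score: identically 0 at month 0 and
#' \eqn{N(\mathrm{poly}_g(t/96), \sigma^2)} at later visits, where `g` is the
#' knee's true trajectory group. Missingness is monotone dropout: before each
#' post-baseline visit a knee still under observation is lost with the
#' configured per-visit probability (higher after month 48 by default), and
#' once missing it stays missing.
#'
#' @param spec A [synthetic_spec()].
#' @param truth Ground truth from [generate_clinical_matrix()].
#' @return Long tibble with columns `knee_id`, `month`, `value`.
#' @export
generate_longitudinal_panel <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  ids <- names(truth$traj_group)
  if (is.null(ids) || anyNA(truth$traj_group)) {
    abort("`truth$traj_group` must assign every knee to a trajectory group.")
  }
  months <- spec$visit_months
  post <- months[months > 0]
  withr::with_seed(derive_seed(spec$seed, 2L), {
    res <- lapply(seq_along(ids), function(i) {
      g <- truth$traj_group[[i]]
      beta <- spec$traj_groups[[g]]$beta
      u <- post / 96
      mu <- as.vector(outer(u, seq_along(beta) - 1L, `^`) %*% beta)
      y <- rnorm(length(post), mu, spec$traj_sd)
      # monotone dropout: hazard before each post-baseline visit
      haz <- ifelse(post > 48, spec$dropout_rate[["late"]],
                    spec$dropout_rate[["early"]])
      drop_at <- which(runif(length(post)) < haz)
      keep <- if (length(drop_at)) seq_len(min(drop_at) - 1L) else
        seq_along(post)
      tibble::tibble(
        knee_id = ids[i],
        month = c(0, post[keep]),
        value = c(0, y[keep])
      )
    })
    dplyr::bind_rows(res)
  })
}

#' Generate structural-progression outcomes
#'
#' Emits per-visit Kellgren-Lawrence grades (integers 0-4, non-decreasing in
#' time), a total-knee-arthroplasty indicator (received by month 96), and
#' medial/lateral quantitative joint space width series
#' `baseline + slope * month + noise`. Progression and arthroplasty
#' probabilities and qJSW slopes differ by planted bicluster membership, so
#' planted phenotypes carry distinguishable prognoses.
#'
#' @inheritParams generate_longitudinal_panel
#' @return Long tibble: `knee_id`, `month`, `klg`, `tka`,
#'   `qjsw_medial`, `qjsw_lateral`. `tka` is constant within knee.
#' @export
generate_outcomes <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  ids <- names(truth$row_membership)
  months <- spec$visit_months
  op <- spec$outcome_params
  qp <- spec$qjsw_params
  withr::with_seed(derive_seed(spec$seed, 3L), {
    cls <- ifelse(is.na(truth$row_membership), 1L, truth$row_membership + 1L)
    n <- length(ids)
    klg0 <- sample(0:4, n, replace = TRUE, prob = op$klg_baseline_probs$none)
    tka <- rbinom(n, 1L, op$tka_prob[cls])
    base_med <- rnorm(n, qp$baseline_mean[["medial"]], qp$baseline_sd[["medial"]])
    base_lat <- rnorm(n, qp$baseline_mean[["lateral"]], qp$baseline_sd[["lateral"]])

    res <- lapply(seq_len(n), function(i) {
      klg <- numeric(length(months))
      klg[1] <- klg0[i]
      for (t in seq_along(months)[-1]) {
        step <- rbinom(1L, 1L, op$prog_prob[cls[i]])
        klg[t] <- min(4, klg[t - 1] + step)
      }
      med <- base_med[i] + truth$true_qjsw_slopes[i, "medial"] * months +
        rnorm(length(months), 0, qp$noise_sd)
      lat <- base_lat[i] + truth$true_qjsw_slopes[i, "lateral"] * months +
        rnorm(length(months), 0, qp$noise_sd)
      tibble::tibble(
        knee_id = ids[i], month = months, klg = as.integer(klg),
        tka = tka[i],
        qjsw_medial = pmax(med, 0.05), qjsw_lateral = pmax(lat, 0.05)
      )
    })
    dplyr::bind_rows(res)
  })
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$traj_groups <- lapply(out$traj_groups, unclass)
  # jsonlite drops names of atomic vectors; carry them as objects instead
  out$dropout_rate <- as.list(out$dropout_rate)
  out$qjsw_params <- lapply(out$qjsw_params, as.list)
  out
}

list_to_spec <- function(x) {
  tg <- x$traj_groups
  if (!is.null(names(tg))) tg <- as.list(tg)
  do.call(synthetic_spec, list(
    n_rows = x$n_rows, n_cols = x$n_cols,
    feature_kinds = as.character(x$feature_kinds),
    planted_biclusters = lapply(x$planted_biclusters, function(b) {
      list(rows = as.integer(b$rows), cols = as.integer(b$cols),
           mu = b$mu, row_sd = b$row_sd, col_sd = b$col_sd)
    }),
    col_profile = x$col_profile,
    profile_levels = as.numeric(x$profile_levels),
    noise_sd = x$noise_sd,
    background = x$background,
    binary_quantile = x$binary_quantile,
    traj_groups = lapply(tg, function(g) {
      list(pi = g$pi, beta = as.numeric(g$beta))
    }),
    traj_sd = x$traj_sd,
    visit_months = as.numeric(x$visit_months),
    dropout_rate = unlist(x$dropout_rate),
    qjsw_params = lapply(x$qjsw_params, function(p) {
      if (is.list(p)) unlist(p) else unlist(p)
    }),
    outcome_params = list(
      klg_baseline_probs = list(
        none = as.numeric(x$outcome_params$klg_baseline_probs$none)
      ),
      prog_prob = as.numeric(x$outcome_params$prog_prob),
      tka_prob = as.numeric(x$outcome_params$tka_prob)
    ),
    seed = x$seed
  ))
}

#' Write (and read back) a synthetic fixture bundle
#'
#' `write_fixture_bundle()` generates the full synthetic cohort for `spec` and
#' writes it to `dir` as plain text: `baseline.csv`, `panel.csv`,
#' `outcomes.csv`, `truth.json` and `spec.json`. `read_fixture_bundle()`
#' restores the tables and the spec; regenerating from the stored spec
#' reproduces the stored tables exactly.
#'
#' @param dir Writable directory (created if absent).
#' @param spec A [synthetic_spec()].
#' @return `write_fixture_bundle()`: invisibly, a named character vector of
#'   file paths. `read_fixture_bundle()`: a list with `baseline`, `panel`,
#'   `outcomes`, `truth`, `spec`.
#' @export
write_fixture_bundle <- function(dir, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- generate_clinical_matrix(spec)
  panel <- generate_longitudinal_panel(spec, sim$truth)
  outcomes <- generate_outcomes(spec, sim$truth)
  paths <- c(
    baseline = file.path(dir, "baseline.csv"),
    panel = file.path(dir, "panel.csv"),
    outcomes = file.path(dir, "outcomes.csv"),
    truth = file.path(dir, "truth.json"),
    spec = file.path(dir, "spec.json")
  )
  tryCatch({
    readr::write_csv(sim$data, paths[["baseline"]])
    readr::write_csv(panel, paths[["panel"]])
    readr::write_csv(outcomes, paths[["outcomes"]])
    jsonlite::write_json(
      list(
        row_membership = as.list(sim$truth$row_membership),
        column_membership = sim$truth$column_membership,
        traj_group = as.list(sim$truth$traj_group),
        true_qjsw_slopes = as.data.frame(sim$truth$true_qjsw_slopes)
      ),
      paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null"
    )
    jsonlite::write_json(spec_to_list(spec), paths[["spec"]],
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    abort(sprintf("Failed writing fixture bundle under '%s': %s",
                  dir, conditionMessage(e)))
  })
  invisible(paths)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(dir) {
  pth <- function(f) file.path(dir, f)
  for (f in c("baseline.csv", "panel.csv", "outcomes.csv", "spec.json")) {
    if (!file.exists(pth(f))) abort(sprintf("Missing bundle file '%s'.", pth(f)))
  }
  spec <- list_to_spec(jsonlite::read_json(pth("spec.json"),
                                            simplifyVector = TRUE,
                                            simplifyDataFrame = FALSE))
  tr <- jsonlite::read_json(pth("truth.json"), simplifyVector = TRUE)
  slopes <- as.matrix(tr$true_qjsw_slopes)
  rownames(slopes) <- names(tr$row_membership)
  truth <- structure(
    list(
      row_membership = unlist(lapply(tr$row_membership, function(x) {
        if (is.null(x)) NA_integer_ else as.integer(x)
      })),
      column_membership = tr$column_membership,
      traj_group = vapply(tr$traj_group, as.integer, integer(1)),
      true_qjsw_slopes = slopes
    ),
    class = "ground_truth"
  )
  list(
    baseline = readr::read_csv(pth("baseline.csv"), show_col_types = FALSE),
    panel = readr::read_csv(pth("panel.csv"), show_col_types = FALSE),
    outcomes = readr::read_csv(pth("outcomes.csv"), show_col_types = FALSE),
    truth = truth,
    spec = spec
  )
}
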