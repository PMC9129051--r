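# Figure builders. Every plot has a data twin: the *_data() helper returns
# the tibble the figure is drawn from, and render_reports() writes that
# tibble as the figure's CSV twin.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_boxplot geom_col
#'   geom_line geom_point facet_wrap labs scale_fill_viridis_c theme_minimal
#'   scale_fill_brewer position_fill geom_hline
NULL

# long heatmap table: knees ordered by bicluster ("na" block last)
heatmap_data <- function(bset, prepared) {
  mem <- bicluster_membership(bset)
  block <- ifelse(is.na(mem), "na", as.character(mem))
  ord <- names(mem)[order(block == "na", block)]
  vals <- prepared$values[ord, , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(vals))
  out$knee_id <- rownames(vals)
  out <- tidyr::pivot_longer(out, -"knee_id", names_to = "feature",
                             values_to = "value")
  out$bicluster <- block[match(out$knee_id, names(mem))]
  out$knee_order <- match(out$knee_id, ord)
  out
}

#' Heatmap of a bicluster set
#'
#' Knees on the x-axis ordered and labelled by bicluster (an `na` block
#' collects knees not placed in any bicluster), features on the y-axis,
#' standardized value as fill.
#'
#' @param object A `bicluster_set`.
#' @param prepared The `prepared_matrix` the set was extracted from.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bicluster_set
#' @export
autoplot.bicluster_set <- function(object, prepared, ...) {
  d <- heatmap_data(object, prepared)
  ggplot(d, aes(x = .data$knee_order, y = .data$feature,
                fill = .data$value)) +
    geom_tile() +
    facet_wrap(~bicluster, nrow = 1, scales = "free_x") +
    scale_fill_viridis_c() +
    labs(x = "knees (grouped by bicluster)", y = NULL,
         fill = "standardized\nvalue") +
    theme_minimal()
}

# standardized continuous features by bicluster, population row included
boxplot_data <- function(bset, prepared, features = NULL) {
  kinds <- prepared$column_kind
  cont <- names(kinds)[kinds %in% c("standardized-continuous", "ordinal-code")]
  features <- features %||% head(cont, 8L)
  mem <- bicluster_membership(bset)
  d <- tibble::as_tibble(as.data.frame(prepared$values[, features, drop = FALSE]))
  d$knee_id <- rownames(prepared$values)
  d$bicluster <- ifelse(is.na(mem[d$knee_id]), "na",
                        as.character(mem[d$knee_id]))
  long <- tidyr::pivot_longer(d, dplyr::all_of(features),
                              names_to = "feature", values_to = "value")
  pop <- long
  pop$bicluster <- "P"
  dplyr::bind_rows(long, pop)
}

#' Standardized feature distributions across biclusters
#'
#' Boxplots of selected standardized continuous features per bicluster,
#' with the overall population of knees as reference group `P`.
#'
#' @inheritParams autoplot.bicluster_set
#' @param features Character vector of prepared-column names (default: the
#'   first eight continuous columns).
#' @return A ggplot object.
#' @export
plot_feature_boxplots <- function(object, prepared, features = NULL) {
  d <- boxplot_data(object, prepared, features)
  ggplot(d, aes(x = .data$feature, y = .data$value, fill = .data$bicluster)) +
    geom_boxplot(outlier.size = 0.3) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    labs(x = NULL, y = "standardized value", fill = "bicluster") +
    theme_minimal()
}

# per-bicluster proportion of 1s for binary/indicator columns
barplot_data <- function(bset, prepared, features = NULL) {
  kinds <- prepared$column_kind
  bin <- names(kinds)[kinds == "indicator"]
  features <- features %||% head(bin, 8L)
  if (!length(features)) return(tibble::tibble())
  mem <- bicluster_membership(bset)
  d <- tibble::as_tibble(as.data.frame(prepared$values[, features, drop = FALSE]))
  d$bicluster <- ifelse(is.na(mem[rownames(prepared$values)]), "na",
                        as.character(mem[rownames(prepared$values)]))
  long <- tidyr::pivot_longer(d, dplyr::all_of(features),
                              names_to = "feature", values_to = "value")
  pop <- long
  pop$bicluster <- "pop"
  both <- dplyr::bind_rows(long, pop)
  dplyr::summarise(dplyr::group_by(both, .data$feature, .data$bicluster),
                   prop = mean(.data$value), .groups = "drop")
}

#' Binary feature proportions across biclusters
#'
#' Grouped bars of the proportion of knees with each binary feature, per
#' bicluster and for the overall population (`pop`). Binary columns are on
#' their raw 0/1 scale.
#'
#' @inheritParams plot_feature_boxplots
#' @return A ggplot object (NULL if the matrix has no binary columns).
#' @export
plot_binary_barplots <- function(object, prepared, features = NULL) {
  d <- barplot_data(object, prepared, features)
  if (!nrow(d)) return(NULL)
  ggplot(d, aes(x = .data$feature, y = .data$prop, fill = .data$bicluster)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "proportion", fill = "bicluster") +
    theme_minimal()
}

# density comparison: one bicluster vs the full cohort, top features by
# absolute standardized mean difference
density_data <- function(bset, prepared, bicluster, n_features = 6L) {
  b <- bset$biclusters[[bicluster]]
  in_rows <- rownames(prepared$values) %in% b$row_ids
  cols <- b$col_ids
  md <- abs(colMeans(prepared$values[in_rows, cols, drop = FALSE]) -
              colMeans(prepared$values[, cols, drop = FALSE]))
  top <- names(sort(md, decreasing = TRUE))[seq_len(min(n_features, length(md)))]
  d <- tibble::as_tibble(as.data.frame(prepared$values[, top, drop = FALSE]))
  d$group <- ifelse(in_rows, sprintf("bicluster %d", bicluster), "cohort")
  tidyr::pivot_longer(d, dplyr::all_of(top), names_to = "feature",
                      values_to = "value")
}

#' Marginal distributions of a bicluster's top features
#'
#' Density panels contrasting one bicluster against the overall cohort for
#' the features with the largest absolute standardized mean difference.
#'
#' @inheritParams plot_feature_boxplots
#' @param bicluster Index of the bicluster to profile.
#' @param n_features How many top features to show.
#' @return A ggplot object.
#' @export
plot_feature_densities <- function(object, prepared, bicluster = 1L,
                                   n_features = 6L) {
  d <- density_data(object, prepared, bicluster, n_features)
  ggplot(d, aes(x = .data$value, colour = .data$group)) +
    ggplot2::geom_density() +
    facet_wrap(~feature, scales = "free") +
    labs(x = "standardized value", y = "density", colour = NULL) +
    theme_minimal()
}

#' Mean-difference scatterplots for tested pairs
#'
#' For each tested bicluster pair, projects the pooled knees onto the
#' mean-difference direction (horizontal) and the orthogonal principal
#' component (vertical), annotated with the pair's z-score.
#'
#' @param prepared A `prepared_matrix`.
#' @param bset A `bicluster_set`.
#' @param sig Pairwise results from [pairwise_sigclust()].
#' @return List: `data` (tibble of projected coordinates for every pair),
#'   `plot` (ggplot).
#' @export
plot_sigclust_pairs <- function(prepared, bset, sig) {
  mat <- prepared$values
  d <- dplyr::bind_rows(lapply(seq_len(nrow(sig)), function(p) {
    a <- sig$bicluster_a[p]; b <- sig$bicluster_b[p]
    ra <- bset$biclusters[[a]]$rows; rb <- bset$biclusters[[b]]$rows
    proj <- mean_difference_projection(
      mat[c(ra, rb), , drop = FALSE],
      rep(c(a, b), c(length(ra), length(rb)))
    )
    proj$pair <- sprintf("%d vs %d (z = %.1f)", a, b, sig$z[p])
    proj
  }))
  pl <- ggplot(d, aes(x = .data$md, y = .data$pc,
                      colour = factor(.data$label))) +
    geom_point(size = 0.5, alpha = 0.6) +
    facet_wrap(~pair, scales = "free") +
    labs(x = "mean-difference direction", y = "orthogonal PC",
         colour = "bicluster") +
    theme_minimal()
  list(data = d, plot = pl)
}

#' Outcome composition by bicluster
#'
#' Stacked bars of radiographic-outcome levels plus arthroplasty rates per
#' bicluster, from an [crosstab_bicluster_outcomes()] summary.
#'
#' @param summary An `outcome_summary`.
#' @return List of two ggplots: `roa`, `tka`.
#' @export
plot_outcome_bars <- function(summary) {
  roa <- ggplot(summary$roa[summary$roa$n > 0, ],
                aes(x = .data$bicluster, y = .data$prop,
                    fill = factor(.data$roa_level))) +
    geom_col() +
    labs(x = "bicluster", y = "proportion", fill = "outcome level") +
    theme_minimal()
  tka <- ggplot(summary$tka,
                aes(x = .data$bicluster, y = .data$tka_rate)) +
    geom_col(fill = "steelblue") +
    labs(x = "bicluster", y = "arthroplasty rate") +
    theme_minimal()
  list(roa = roa, tka = tka)
}

#' Joint-space-width loss by bicluster
#'
#' Boxplots of per-knee medial and lateral percentage loss grouped by
#' bicluster.
#'
#' @param bset A `bicluster_set`.
#' @param outcomes Per-knee tibble from [knee_outcomes()].
#' @return List: `data`, `plot`.
#' @export
plot_qjsw_boxplots <- function(bset, outcomes) {
  mem <- bicluster_membership(bset)
  d <- outcomes
  d$bicluster <- ifelse(is.na(mem[d$knee_id]), "na",
                        as.character(mem[d$knee_id]))
  long <- tidyr::pivot_longer(
    d[, c("knee_id", "bicluster", "medial_loss_pct", "lateral_loss_pct")],
    c("medial_loss_pct", "lateral_loss_pct"),
    names_to = "compartment", values_to = "loss_pct"
  )
  long$compartment <- sub("_loss_pct", "", long$compartment)
  pl <- ggplot(long, aes(x = .data$bicluster, y = .data$loss_pct)) +
    geom_boxplot(outlier.size = 0.3, fill = "grey85") +
    facet_wrap(~compartment) +
    labs(x = "bicluster", y = "% qJSW loss over 96 months") +
    theme_minimal()
  list(data = long, plot = pl)
}

#' Estimated trajectories and assignment composition
#'
#' `autoplot.gbtm()` draws the estimated group mean change-from-baseline
#' trajectories over the visit schedule. `plot_trajectory_bars()` shows,
#' per bicluster, the proportion of (good-fit) knees assigned to each
#' trajectory group as stacked horizontal bars.
#'
#' @param object A fitted `gbtm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gbtm
#' @export
autoplot.gbtm <- function(object, ...) {
  months <- seq(0, max(object$schedule), by = 4)
  d <- gbtm_means(object, months)
  d$group <- factor(d$group)
  ggplot(d, aes(x = .data$month, y = .data$mean, colour = .data$group)) +
    geom_line(linewidth = 0.8) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    labs(x = "month", y = "mean change from baseline",
         colour = "trajectory\ngroup") +
    theme_minimal()
}

#' @rdname autoplot.gbtm
#' @param summary An `outcome_summary` with a `trajectory` table.
#' @export
plot_trajectory_bars <- function(summary) {
  d <- summary$trajectory
  ggplot(d, aes(x = .data$prop, y = .data$bicluster,
                fill = factor(.data$traj_group))) +
    geom_col() +
    labs(x = "proportion of good-fit knees", y = "bicluster",
         fill = "trajectory\ngroup") +
    theme_minimal()
}

#' Render the report set for a completed run
#'
#' Builds every figure of the standard report (bicluster heatmap, feature
#' boxplots and binary barplots, per-pair mean-difference scatterplots,
#' outcome and arthroplasty bars, qJSW loss boxplots, trajectory curves and
#' assignment bars) and writes each figure's underlying data as a CSV twin
#' under `file.path(run$outdir, "figures")`. PNG rendering is attempted and
#' skipped with a warning if no graphics device is available.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param write_png Attempt PNG output?
#' @return Invisibly, a named list of ggplot objects.
#' @export
render_reports <- function(run, write_png = TRUE) {
  stopifnot(inherits(run, "pipeline_run"))
  figdir <- file.path(run$outdir, "figures")
  dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
  bset <- run$biclusters; prepared <- run$prepared

  twins <- list()
  figs <- list()

  twins$heatmap <- heatmap_data(bset, prepared)
  figs$heatmap <- autoplot(bset, prepared)

  twins$boxplots <- boxplot_data(bset, prepared)
  figs$boxplots <- plot_feature_boxplots(bset, prepared)

  twins$barplots <- barplot_data(bset, prepared)
  if (nrow(twins$barplots)) {
    figs$barplots <- plot_binary_barplots(bset, prepared)
  }

  if (nrow(run$sigclust)) {
    sp <- plot_sigclust_pairs(prepared, bset, run$sigclust)
    twins$sigclust_pairs <- sp$data
    figs$sigclust_pairs <- sp$plot
  }

  ob <- plot_outcome_bars(run$summary)
  twins$outcome_roa <- run$summary$roa
  twins$outcome_tka <- run$summary$tka
  figs$outcome_roa <- ob$roa
  figs$outcome_tka <- ob$tka

  qb <- plot_qjsw_boxplots(bset, run$outcomes)
  twins$qjsw_loss <- qb$data
  figs$qjsw_loss <- qb$plot

  twins$trajectories <- gbtm_means(run$gbtm, seq(0, max(run$gbtm$schedule), 4))
  figs$trajectories <- autoplot(run$gbtm)
  twins$trajectory_bars <- run$summary$trajectory
  figs$trajectory_bars <- plot_trajectory_bars(run$summary)

  for (nm in names(twins)) {
    readr::write_csv(twins[[nm]], file.path(figdir, paste0(nm, ".csv")))
  }
  if (write_png) {
    for (nm in names(figs)) {
      ok <- tryCatch({
        grDevices::png(file.path(figdir, paste0(nm, ".png")),
                       width = 1400, height = 900, res = 140)
        print(figs[[nm]])
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        try(grDevices::dev.off(), silent = TRUE)
        warn(sprintf("Could not render '%s' to PNG: %s", nm,
                     conditionMessage(e)))
        FALSE
      })
      if (!ok) break
    }
  }
  invisible(figs)
}
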