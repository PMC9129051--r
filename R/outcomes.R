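# Longitudinal outcome classification: radiographic progression levels,
# arthroplasty, and quantitative joint-space-width loss, summarized by
# bicluster.

#' Classify a knee's radiographic progression over follow-up
#'
#' Assigns the standard coded outcome level from the baseline
#' Kellgren-Lawrence grade (KLG, 0-4) and the post-baseline KLG series:
#' \describe{
#'   \item{1}{baseline KLG 0-1, no follow-up data}
#'   \item{2}{baseline KLG 0-1, no incident radiographic OA (all follow-up
#'     KLG <= 1)}
#'   \item{3}{baseline KLG 0-1, developed incident radiographic OA (any
#'     follow-up KLG >= 2)}
#'   \item{4}{baseline KLG >= 2, no follow-up data}
#'   \item{5}{baseline KLG >= 2, no progression (no follow-up increase)}
#'   \item{6}{baseline KLG >= 2, progressive radiographic OA (any follow-up
#'     increase over baseline)}
#'   \item{7}{arthroplasty already at baseline}
#'   \item{999}{no baseline KLG (and so no classifiable trajectory)}
#' }
#'
#' @param baseline_klg Baseline KLG (integer 0-4) or `NA`.
#' @param followup_klg Integer vector of post-baseline KLG readings (possibly
#'   empty; `NA` entries are treated as unread visits and dropped).
#' @param tka_at_baseline Arthroplasty present at baseline?
#' @return Integer level in \{1,...,7, 999\}.
#' @export
#' @examples
#' classify_roa_outcome(1, c(1, 1, 2)) # incident: 3
#' classify_roa_outcome(3, c(3, 4))    # progressive: 6
classify_roa_outcome <- function(baseline_klg, followup_klg = integer(0),
                                 tka_at_baseline = FALSE) {
  fu <- followup_klg[!is.na(followup_klg)]
  klgs <- c(baseline_klg[!is.na(baseline_klg)], fu)
  if (length(klgs) && (any(klgs != round(klgs)) || any(klgs < 0 | klgs > 4))) {
    abort("KLG values must be integers in 0..4.")
  }
  if (isTRUE(tka_at_baseline)) return(7L)
  if (is.na(baseline_klg) || !length(baseline_klg)) return(999L)
  if (baseline_klg <= 1) {
    if (!length(fu)) return(1L)
    if (max(fu) >= 2) return(3L) else return(2L)
  }
  if (!length(fu)) return(4L)
  if (max(fu) > baseline_klg) 6L else 5L
}

#' Percentage joint-space-width loss with truncation
#'
#' Fits an ordinary least-squares line of qJSW (mm) on month and reports the
#' fitted percentage decrease from baseline to month 96:
#' \eqn{100 (\hat f(0) - \hat f(96)) / \hat f(0)}. Extreme fits are
#' truncated: losses above 100% are set to 100, and gains beyond the
#' compartment threshold (40% medial, 50% lateral) are capped at the
#' threshold, i.e. floored at -40 / -50. Truncation is reported so cohort
#' bookkeeping can count affected knees; `mode = "exclude"` returns `NA`
#' for gain-truncated knees instead.
#'
#' @param months Numeric vector of visit months (>= 2 distinct values).
#' @param qjsw Joint space width in mm at those visits.
#' @param compartment `"medial"` or `"lateral"` (sets the gain threshold).
#' @param mode Cap gains at the threshold (`"truncate"`, default) or drop
#'   them (`"exclude"`).
#' @return Scalar percentage loss, with attributes `truncated` (`"none"`,
#'   `"high"` or `"gain"`) and `valid` (`FALSE` when the fitted baseline is
#'   not positive, in which case the value is `NA`).
#' @export
#' @examples
#' qjsw_percent_loss(c(0, 96), c(4, 3), "medial") # 25
qjsw_percent_loss <- function(months, qjsw,
                              compartment = c("medial", "lateral"),
                              mode = c("truncate", "exclude")) {
  compartment <- match.arg(compartment)
  mode <- match.arg(mode)
  ok <- is.finite(months) & is.finite(qjsw)
  months <- months[ok]; qjsw <- qjsw[ok]
  if (length(unique(months)) < 2L) {
    abort("Need observations at >= 2 distinct months for the regression.")
  }
  fit <- lm(qjsw ~ months)
  f0 <- unname(coef(fit)[1])
  f96 <- unname(coef(fit)[1] + 96 * coef(fit)[2])
  if (!is.finite(f0) || f0 <= 0) {
    out <- NA_real_
    attr(out, "truncated") <- "none"
    attr(out, "valid") <- FALSE
    return(out)
  }
  loss <- 100 * (f0 - f96) / f0
  gain_floor <- if (compartment == "medial") -40 else -50
  trunc <- "none"
  if (loss > 100) {
    loss <- 100; trunc <- "high"
  } else if (loss < gain_floor) {
    loss <- if (mode == "truncate") gain_floor else NA_real_
    trunc <- "gain"
  }
  attr(loss, "truncated") <- trunc
  attr(loss, "valid") <- TRUE
  loss
}

#' Per-knee outcome table
#'
#' Reduces a long outcome panel (per-knee, per-visit KLG, arthroplasty flag
#' and qJSW by compartment) to one row per knee: the radiographic
#' progression level ([classify_roa_outcome()]), the arthroplasty indicator,
#' medial and lateral percentage qJSW loss with truncation flags, and the
#' assigned pain-trajectory group when an assignment is supplied.
#'
#' @param outcomes Long tibble: `knee_id`, `month`, `klg`, `tka`,
#'   `qjsw_medial`, `qjsw_lateral`. Month 0 is the baseline visit.
#' @param assignment Optional [posterior_assign()] result; only good-fit
#'   assignments (posterior >= 0.8) are carried, others become `NA`.
#' @param loss_mode Passed to [qjsw_percent_loss()].
#' @return Tibble: `knee_id`, `roa_level`, `tka`, `medial_loss_pct`,
#'   `lateral_loss_pct`, `medial_truncated`, `lateral_truncated`,
#'   `traj_group`.
#' @export
knee_outcomes <- function(outcomes, assignment = NULL,
                          loss_mode = "truncate") {
  need <- c("knee_id", "month", "klg", "tka", "qjsw_medial", "qjsw_lateral")
  if (!all(need %in% names(outcomes))) {
    abort(sprintf("`outcomes` must have columns %s.", paste(need, collapse = ", ")))
  }
  traj <- NULL
  if (!is.null(assignment)) {
    traj <- setNames(
      ifelse(assignment$good_fit, assignment$assigned_group, NA_integer_),
      assignment$knee_id
    )
  }
  res <- lapply(split(outcomes, outcomes$knee_id), function(d) {
    d <- d[order(d$month), ]
    base <- d[d$month == 0, , drop = FALSE]
    fu <- d[d$month > 0 & d$month <= 96, , drop = FALSE]
    med <- qjsw_percent_loss(d$month, d$qjsw_medial, "medial", loss_mode)
    lat <- qjsw_percent_loss(d$month, d$qjsw_lateral, "lateral", loss_mode)
    tibble::tibble(
      knee_id = d$knee_id[1],
      roa_level = classify_roa_outcome(
        if (nrow(base)) base$klg[1] else NA_integer_,
        fu$klg,
        tka_at_baseline = FALSE
      ),
      tka = as.integer(max(d$tka)),
      medial_loss_pct = as.numeric(med),
      lateral_loss_pct = as.numeric(lat),
      medial_truncated = attr(med, "truncated"),
      lateral_truncated = attr(lat, "truncated"),
      traj_group = if (is.null(traj)) NA_integer_ else
        unname(traj[d$knee_id[1]])
    )
  })
  dplyr::bind_rows(res)
}

quartiles7 <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  tibble::tibble(p25 = q[1], p50 = q[2], p75 = q[3])
}

#' Cross-tabulate outcomes by bicluster
#'
#' Builds the per-bicluster outcome summary: radiographic-level proportions,
#' arthroplasty rate, medial/lateral loss quartiles (type-7, linearly
#' interpolated), pain-trajectory group proportions among good-fit knees,
#' and truncation counts — each also for the full cohort (`bicluster =
#' "all"`) and for unassigned knees (`"na"`) when present.
#'
#' @param bset A `bicluster_set` whose row ids are knee ids.
#' @param outcomes Per-knee tibble from [knee_outcomes()]; every knee in the
#'   bicluster set must appear.
#' @return An `outcome_summary` list of tibbles: `roa`, `tka`, `qjsw`,
#'   `trajectory`, `truncation`.
#' @export
crosstab_bicluster_outcomes <- function(bset, outcomes) {
  mem <- bicluster_membership(bset)
  missing_ids <- setdiff(names(mem), outcomes$knee_id)
  if (length(missing_ids)) {
    abort(sprintf("No outcome record for knee(s): %s.",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  df <- outcomes[match(names(mem), outcomes$knee_id), ]
  df$bicluster <- ifelse(is.na(mem), "na", as.character(mem))
  groups <- c(sort(unique(df$bicluster[df$bicluster != "na"])),
              if (any(df$bicluster == "na")) "na", "all")
  slice_of <- function(g) if (g == "all") df else df[df$bicluster == g, ]

  roa <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- slice_of(g)
    tab <- table(factor(d$roa_level, levels = c(1:7, 999)))
    tibble::tibble(
      bicluster = g, roa_level = as.integer(names(tab)),
      n = as.integer(tab), prop = as.integer(tab) / nrow(d)
    )
  }))
  tka <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- slice_of(g)
    tibble::tibble(bicluster = g, n = nrow(d), tka_rate = mean(d$tka))
  }))
  qjsw <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- slice_of(g)
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(bicluster = g, compartment = "medial"),
                       quartiles7(d$medial_loss_pct)),
      dplyr::bind_cols(tibble::tibble(bicluster = g, compartment = "lateral"),
                       quartiles7(d$lateral_loss_pct))
    )
  }))
  trajectory <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- slice_of(g)
    d <- d[!is.na(d$traj_group), ]
    if (!nrow(d)) return(NULL)
    tab <- table(d$traj_group)
    tibble::tibble(
      bicluster = g, traj_group = as.integer(names(tab)),
      n = as.integer(tab), prop = as.integer(tab) / nrow(d)
    )
  }))
  truncation <- dplyr::bind_rows(lapply(groups, function(g) {
    d <- slice_of(g)
    tibble::tibble(
      bicluster = g,
      medial_high = sum(d$medial_truncated == "high"),
      medial_gain = sum(d$medial_truncated == "gain"),
      lateral_high = sum(d$lateral_truncated == "high"),
      lateral_gain = sum(d$lateral_truncated == "gain")
    )
  }))
  structure(
    list(roa = roa, tka = tka, qjsw = qjsw, trajectory = trajectory,
         truncation = truncation),
    class = "outcome_summary"
  )
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary>\n  TKA rates:\n")
  print(as.data.frame(x$tka), row.names = FALSE)
  invisible(x)
}
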