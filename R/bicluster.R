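#' Mean squared residue of a submatrix
#'
#' The residue of cell (i, j) within a submatrix (I, J) is
#' \eqn{r_{ij} = a_{ij} - a_{iJ} - a_{Ij} + a_{IJ}} (row mean, column mean and
#' overall mean of the submatrix). The mean squared residue (MSR)
#' \eqn{H(I, J)} is the average of \eqn{r_{ij}^2} over the submatrix: the
#' average squared departure of the entries from the values an additive
#' row + column model predicts. A perfectly additive block has H = 0.
#'
#' @param mat Numeric matrix.
#' @param rows,cols Integer index vectors into `mat` (non-empty, in range).
#' @return List: `H` (scalar MSR), `row_scores` `d(i)` (mean residue^2 per
#'   row) and `col_scores` `d(j)`; `H` equals the mean of either score
#'   vector weighted equally.
#' @export
#' @examples
#' msr(matrix(c(1, 3, 2, 4), 2), 1:2, 1:2)$H # additive: 0
msr <- function(mat, rows = seq_len(nrow(mat)), cols = seq_len(ncol(mat))) {
  if (length(rows) == 0L || length(cols) == 0L) {
    abort("`rows` and `cols` must be non-empty.")
  }
  if (max(rows) > nrow(mat) || max(cols) > ncol(mat) ||
      min(rows) < 1L || min(cols) < 1L) {
    abort("Row/column indices out of range.")
  }
  sub <- mat[rows, cols, drop = FALSE]
  rm_ <- rowMeans(sub)
  cm_ <- colMeans(sub)
  mm <- mean(sub)
  res <- sub - outer(rm_, cm_, function(a, b) a + b) + mm
  res2 <- res^2
  list(
    H = mean(res2),
    row_scores = setNames(rowMeans(res2), rownames(sub)),
    col_scores = setNames(colMeans(res2), colnames(sub))
  )
}

#' Greedy node deletion toward an MSR threshold
#'
#' `single_node_deletion()` repeatedly removes the single row or column with
#' the largest mean residue score until \eqn{H \le \delta} or the size floor
#' (2 x 2) is reached; H is non-increasing at every step. Ties are broken
#' deterministically: rows before columns, then lowest index.
#' `multiple_node_deletion()` is the scaling device for large matrices: in
#' each pass it deletes every row with \eqn{d(i) > \alpha H}, then every
#' column with \eqn{d(j) > \alpha H}, but only while the corresponding
#' dimension exceeds `min_size`; it stops when a pass changes nothing (the
#' caller then falls through to single deletion).
#'
#' @inheritParams msr
#' @param delta Target MSR threshold.
#' @param alpha Multiple-deletion aggressiveness (> 1; original default 1.2).
#' @param min_size Dimension size above which multiple deletion applies.
#' @param debug Assert after every step that H did not increase.
#' @return List: `rows`, `cols`, `H`, and `converged` (`FALSE` when the size
#'   floor was hit with H still above `delta`).
#' @export
single_node_deletion <- function(mat, rows, cols, delta, debug = FALSE) {
  h_prev <- Inf
  repeat {
    s <- msr(mat, rows, cols)
    if (debug && s$H > h_prev + 1e-9) {
      abort("Internal error: deletion increased H.")
    }
    h_prev <- s$H
    if (s$H <= delta) {
      return(list(rows = rows, cols = cols, H = s$H, converged = TRUE))
    }
    can_row <- length(rows) > 2L
    can_col <- length(cols) > 2L
    if (!can_row && !can_col) {
      return(list(rows = rows, cols = cols, H = s$H, converged = FALSE))
    }
    best_row <- if (can_row) max(s$row_scores) else -Inf
    best_col <- if (can_col) max(s$col_scores) else -Inf
    if (best_row >= best_col) { # rows before columns on ties
      rows <- rows[-which.max(s$row_scores)]
    } else {
      cols <- cols[-which.max(s$col_scores)]
    }
  }
}

#' @rdname single_node_deletion
#' @export
multiple_node_deletion <- function(mat, rows, cols, delta, alpha = 1.2,
                                   min_size = 100L, debug = FALSE) {
  if (alpha <= 1) abort("`alpha` must exceed 1.")
  repeat {
    s <- msr(mat, rows, cols)
    if (s$H <= delta) {
      return(list(rows = rows, cols = cols, H = s$H, converged = TRUE))
    }
    changed <- FALSE
    if (length(rows) > min_size) {
      drop <- s$row_scores > alpha * s$H
      if (any(drop) && sum(!drop) >= 2L) {
        rows <- rows[!drop]
        changed <- TRUE
        s <- msr(mat, rows, cols)
        if (s$H <= delta) {
          return(list(rows = rows, cols = cols, H = s$H, converged = TRUE))
        }
      }
    }
    if (length(cols) > min_size) {
      drop <- s$col_scores > alpha * s$H
      if (any(drop) && sum(!drop) >= 2L) {
        cols <- cols[!drop]
        changed <- TRUE
      }
    }
    if (!changed) {
      s <- msr(mat, rows, cols)
      return(list(rows = rows, cols = cols, H = s$H,
                  converged = s$H <= delta))
    }
  }
}

#' Node addition: grow a bicluster without raising its residue
#'
#' Starting from a submatrix whose MSR already meets the threshold, adds in
#' alternating passes every column not in J whose score against the current
#' bicluster means satisfies \eqn{d(j) \le H}, then every row with
#' \eqn{d(i) \le H}, repeating until a full pass adds nothing. Each pass
#' leaves H at or below its entry value. Inverse-row addition (rows whose
#' negation fits the bicluster) is available but off by default: clinical
#' features have directional meaning, so mirror-image knees are not pooled
#' unless explicitly requested.
#'
#' @inheritParams single_node_deletion
#' @param inverse_rows Also consider sign-flipped rows?
#' @return List: `rows`, `cols`, `H`, `inverted` (indices added as inverted
#'   rows, empty unless `inverse_rows`).
#' @export
node_addition <- function(mat, rows, cols, inverse_rows = FALSE,
                          debug = FALSE) {
  inverted <- integer(0)
  repeat {
    s <- msr(mat, rows, cols)
    h <- s$H
    changed <- FALSE

    cand_cols <- setdiff(seq_len(ncol(mat)), cols)
    if (length(cand_cols)) {
      sub <- mat[rows, cols, drop = FALSE]
      rm_ <- rowMeans(sub); mm <- mean(sub)
      a <- mat[rows, cand_cols, drop = FALSE]
      cm_cand <- colMeans(a)
      res <- a - rm_ - matrix(cm_cand, nrow(a), ncol(a), byrow = TRUE) + mm
      d <- colMeans(res^2)
      add <- cand_cols[d <= h + 1e-12]
      if (length(add)) {
        cols <- sort(c(cols, add))
        changed <- TRUE
        h <- msr(mat, rows, cols)$H
      }
    }

    cand_rows <- setdiff(seq_len(nrow(mat)), rows)
    if (length(cand_rows)) {
      sub <- mat[rows, cols, drop = FALSE]
      cm_ <- colMeans(sub); mm <- mean(sub)
      a <- mat[cand_rows, cols, drop = FALSE]
      rm_cand <- rowMeans(a)
      res <- a - rm_cand - matrix(cm_, nrow(a), ncol(a), byrow = TRUE) + mm
      d <- rowMeans(res^2)
      add <- cand_rows[d <= h + 1e-12]
      if (inverse_rows) {
        res_inv <- -a + rm_cand - matrix(cm_, nrow(a), ncol(a), byrow = TRUE) + mm
        d_inv <- rowMeans(res_inv^2)
        add_inv <- setdiff(cand_rows[d_inv <= h + 1e-12], add)
        inverted <- union(inverted, add_inv)
        add <- union(add, add_inv)
      }
      if (length(add)) {
        rows <- sort(c(rows, add))
        changed <- TRUE
      }
    }
    if (debug) {
      h_new <- msr(mat, rows, cols)$H
      if (h_new > s$H + 1e-9) abort("Internal error: addition increased H.")
    }
    if (!changed) {
      return(list(rows = rows, cols = cols, H = msr(mat, rows, cols)$H,
                  inverted = inverted))
    }
  }
}

#' Two-way ANOVA fit quality of a bicluster
#'
#' A good bicluster is a submatrix well fit by the additive two-way model
#' row + column effects. `anova_r2()` reports the proportion of submatrix
#' variance that model explains: \eqn{R^2 = 1 - SSE / SST} with
#' \eqn{SSE = |I||J| \cdot H(I, J)} (the residue sum of squares) and
#' \eqn{SST = \sum (a_{ij} - a_{IJ})^2}, clipped into [0, 1].
#'
#' @inheritParams msr
#' @return Scalar R-squared in [0, 1].
#' @export
anova_r2 <- function(mat, rows, cols) {
  if (length(rows) < 2L || length(cols) < 2L) {
    abort("anova_r2() needs at least a 2 x 2 submatrix.")
  }
  sub <- mat[rows, cols, drop = FALSE]
  sst <- sum((sub - mean(sub))^2)
  if (sst < .Machine$double.eps) {
    abort("Constant submatrix: R^2 undefined (SST = 0).")
  }
  sse <- length(sub) * msr(mat, rows, cols)$H
  min(1, max(0, 1 - sse / sst))
}

new_bicluster <- function(mat, rows, cols, converged, row_ids = NULL,
                          col_ids = NULL) {
  h <- msr(mat, rows, cols)$H
  sub <- mat[rows, cols, drop = FALSE]
  r2 <- if (sum((sub - mean(sub))^2) < .Machine$double.eps) 1 else
    anova_r2(mat, rows, cols)
  structure(
    list(
      rows = rows, cols = cols,
      row_ids = if (!is.null(row_ids)) row_ids[rows] else as.character(rows),
      col_ids = if (!is.null(col_ids)) col_ids[cols] else as.character(cols),
      msr = h, r2 = r2, converged = converged
    ),
    class = "bicluster"
  )
}

#' @export
print.bicluster <- function(x, ...) {
  cat(sprintf("<bicluster> %d rows x %d cols, MSR %.4f, R2 %.3f%s\n",
              length(x$rows), length(x$cols), x$msr, x$r2,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Find one large low-residue bicluster
#'
#' The full search of Cheng and Church applied to the rows still available:
#' multiple node deletion, then single node deletion until
#' \eqn{H \le \delta}, then node addition to grow the bicluster back as far
#' as the achieved residue allows. Returns the largest submatrix the greedy
#' sequence reaches with its MSR and two-way-ANOVA R-squared.
#'
#' @param mat Numeric matrix (a prepared, standardized feature matrix).
#' @param delta MSR threshold the bicluster must satisfy.
#' @param rows,cols Candidate index pools (defaults: whole matrix).
#' @param alpha,min_size Passed to [multiple_node_deletion()].
#' @param inverse_rows Passed to [node_addition()].
#' @param debug Assert monotonicity of H at every phase.
#' @return A `bicluster` object (fields `rows`, `cols`, `row_ids`, `col_ids`,
#'   `msr`, `r2`, `converged`).
#' @export
find_bicluster <- function(mat, delta, rows = seq_len(nrow(mat)),
                           cols = seq_len(ncol(mat)), alpha = 1.2,
                           min_size = 100L, inverse_rows = FALSE,
                           debug = FALSE) {
  if (length(rows) < 2L || length(cols) < 2L) {
    abort("Need at least 2 candidate rows and columns.")
  }
  st <- multiple_node_deletion(mat, rows, cols, delta, alpha = alpha,
                               min_size = min_size, debug = debug)
  st <- single_node_deletion(mat, st$rows, st$cols, delta, debug = debug)
  converged <- st$converged
  if (converged) {
    # node addition may only consider rows from the candidate pool
    sub <- mat[rows, , drop = FALSE]
    local_rows <- match(st$rows, rows)
    grown <- node_addition(sub, local_rows, st$cols,
                           inverse_rows = inverse_rows, debug = debug)
    st$rows <- rows[grown$rows]
    st$cols <- grown$cols
  }
  new_bicluster(mat, sort(st$rows), sort(st$cols), converged,
                rownames(mat), colnames(mat))
}

#' Extract mutually row-exclusive biclusters
#'
#' Repeatedly runs [find_bicluster()] and, after each accepted bicluster,
#' removes its rows from the candidate pool so that no knee is placed in more
#' than one bicluster; columns stay available to every later bicluster, so
#' feature sets may overlap. Extraction stops at `max_k` biclusters, when
#' fewer than `min_rows` candidate rows remain, or when the search fails to
#' reach the threshold. Rows never accepted are reported as unassigned.
#'
#' @inheritParams find_bicluster
#' @param max_k Maximum number of biclusters to extract.
#' @param min_rows Stop when fewer candidate rows than this remain.
#' @return A `bicluster_set`: list with `biclusters` (list of `bicluster`),
#'   `unassigned_rows` (indices), `unassigned_ids`, `delta`, `msr_max` (MSR
#'   of the whole matrix, the ceiling for `delta`), `n_rows`.
#' @export
find_exclusive_biclusters <- function(mat, delta = 0.2, max_k = 6L,
                                      min_rows = 2L, alpha = 1.2,
                                      min_size = 100L, inverse_rows = FALSE,
                                      debug = FALSE) {
  msr_max <- msr(mat)$H
  if (!is.numeric(delta) || delta <= 0 || delta >= msr_max) {
    abort(sprintf(
      "`delta` must lie in (0, msr_max); msr_max for this matrix is %.6g.",
      msr_max
    ))
  }
  pool <- seq_len(nrow(mat))
  bcs <- list()
  while (length(bcs) < max_k && length(pool) >= max(min_rows, 2L)) {
    bc <- find_bicluster(mat, delta, rows = pool, alpha = alpha,
                         min_size = min_size, inverse_rows = inverse_rows,
                         debug = debug)
    if (!bc$converged || length(bc$rows) < min_rows) break
    bcs[[length(bcs) + 1L]] <- bc
    pool <- setdiff(pool, bc$rows)
  }
  structure(
    list(
      biclusters = bcs,
      unassigned_rows = pool,
      unassigned_ids = if (!is.null(rownames(mat))) rownames(mat)[pool] else
        as.character(pool),
      delta = delta,
      msr_max = msr_max,
      n_rows = nrow(mat)
    ),
    class = "bicluster_set"
  )
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("<bicluster_set> %d bicluster(s), %d unassigned of %d rows (delta %.3g, msr_max %.3g)\n",
              length(x$biclusters), length(x$unassigned_rows), x$n_rows,
              x$delta, x$msr_max))
  for (i in seq_along(x$biclusters)) {
    b <- x$biclusters[[i]]
    cat(sprintf("  #%d: %d rows x %d cols, MSR %.4f, R2 %.3f\n",
                i, length(b$rows), length(b$cols), b$msr, b$r2))
  }
  invisible(x)
}

# named integer vector: bicluster id per row id (NA = unassigned)
bicluster_membership <- function(bset) {
  ids <- character(0); mem <- integer(0)
  for (i in seq_along(bset$biclusters)) {
    b <- bset$biclusters[[i]]
    ids <- c(ids, b$row_ids)
    mem <- c(mem, rep(i, length(b$row_ids)))
  }
  out <- c(setNames(mem, ids),
           setNames(rep(NA_integer_, length(bset$unassigned_ids)),
                    bset$unassigned_ids))
  out[order(names(out))]
}

#' @rdname tidy.bicluster_set
#' @method glance bicluster_set
#' @export
glance.bicluster_set <- function(x, ...) {
  tibble::tibble(
    n_biclusters = length(x$biclusters),
    n_rows = x$n_rows,
    n_unassigned = length(x$unassigned_rows),
    delta = x$delta,
    msr_max = x$msr_max
  )
}

#' Summarize a bicluster set as a tibble
#'
#' `tidy()` gives one row per bicluster (sizes, MSR, R-squared);
#' `glance()` one row for the whole extraction.
#'
#' @param x A `bicluster_set`.
#' @param ... Unused.
#' @method tidy bicluster_set
#' @export
tidy.bicluster_set <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$biclusters), function(i) {
    b <- x$biclusters[[i]]
    tibble::tibble(
      bicluster = i,
      n_rows = length(b$rows),
      n_cols = length(b$cols),
      msr = b$msr,
      r2 = b$r2,
      converged = b$converged
    )
  }))
}

# serialize a bicluster set to JSON (ids, not indices) and back
write_bicluster_set <- function(bset, path) {
  jsonlite::write_json(
    list(
      delta = bset$delta, msr_max = bset$msr_max, n_rows = bset$n_rows,
      unassigned_ids = bset$unassigned_ids,
      biclusters = lapply(bset$biclusters, function(b) {
        list(row_ids = b$row_ids, col_ids = b$col_ids, msr = b$msr,
             r2 = b$r2, converged = b$converged)
      })
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
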