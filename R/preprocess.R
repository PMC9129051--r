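#' Describe the features of a raw clinical table
#'
#' Per-column metadata driving [encode_features()] and
#' [standardize_matrix()]: the measurement kind, level order for ordinal
#' features, the level set for nominal features, and an optional exclusion
#' flag with its reason (e.g. a variable unrelated to the disease, redundant
#' with others, or collected only in a small subset).
#'
#' @param name Column name in the raw table.
#' @param kind One of `"continuous"`, `"ordinal"`, `"nominal"`, `"binary"`.
#' @param levels For ordinal columns, the levels in increasing order; for
#'   nominal columns, the unique level set.
#' @param exclude `NULL`, or one of `"unrelated"`, `"redundant"`,
#'   `"sparse-collection"`.
#' @return A one-row tibble; rows from several calls can be bound into a
#'   metadata table.
#' @export
feature_metadata <- function(name, kind, levels = NULL, exclude = NULL) {
  kind <- match.arg(kind, c("continuous", "ordinal", "nominal", "binary"))
  if (kind %in% c("ordinal", "nominal")) {
    if (is.null(levels) || anyDuplicated(levels)) {
      abort(sprintf("Column '%s': %s features need a unique `levels` vector.",
                    name, kind))
    }
  }
  if (!is.null(exclude)) {
    exclude <- match.arg(exclude, c("unrelated", "redundant", "sparse-collection"))
  }
  tibble::tibble(
    name = name, kind = kind,
    levels = list(levels),
    exclude = exclude %||% NA_character_
  )
}

#' Feature metadata for a synthetic baseline table
#'
#' Builds the [feature_metadata()] table matching a [synthetic_spec()]'s
#' declared feature kinds, so a generated cohort can be fed straight into
#' [encode_features()].
#'
#' @param spec A [synthetic_spec()].
#' @return A metadata tibble with one row per feature.
#' @export
spec_feature_metadata <- function(spec) {
  kinds <- lapply(spec$feature_kinds, parse_kind)
  dplyr::bind_rows(lapply(seq_along(kinds), function(j) {
    k <- kinds[[j]]
    nm <- sprintf("f%02d", j)
    switch(
      k$base,
      continuous = feature_metadata(nm, "continuous"),
      binary = feature_metadata(nm, "binary"),
      ordinal = feature_metadata(nm, "ordinal", levels = seq_len(k$k)),
      nominal = feature_metadata(nm, "nominal", levels = paste0("L", seq_len(k$k)))
    )
  }))
}

#' Encode mixed-type features as numeric columns
#'
#' Ordinal columns become integer codes 1, 2, 3, ... following their declared
#' level order; nominal columns with `k` levels expand into `k` 0/1 indicator
#' columns named `name=level`; binary and continuous columns pass through.
#' Columns flagged for exclusion are dropped and reported.
#'
#' @param raw Data frame; first column may be an id column (any non-numeric
#'   column named `knee_id` is carried through untouched).
#' @param metadata Metadata tibble built from [feature_metadata()] rows; every
#'   non-id raw column must be described.
#' @return A list: `data` (numeric tibble with `knee_id` if present),
#'   `column_kind` (named character: `continuous`, `ordinal-code`,
#'   `indicator`), `excluded` (tibble of dropped columns with reasons).
#' @export
encode_features <- function(raw, metadata) {
  id <- intersect("knee_id", names(raw))
  feats <- setdiff(names(raw), id)
  missing_meta <- setdiff(feats, metadata$name)
  if (length(missing_meta)) {
    abort(sprintf("No metadata for column(s): %s.",
                  paste(missing_meta, collapse = ", ")))
  }
  meta <- metadata[match(feats, metadata$name), ]
  excluded <- meta[!is.na(meta$exclude), c("name", "exclude")]
  keep <- meta[is.na(meta$exclude), ]

  out <- list(); kinds <- character(0)
  for (i in seq_len(nrow(keep))) {
    nm <- keep$name[i]; kind <- keep$kind[i]; v <- raw[[nm]]
    if (kind == "continuous") {
      out[[nm]] <- as.numeric(v); kinds[nm] <- "continuous"
    } else if (kind == "binary") {
      vv <- as.numeric(v)
      bad <- !is.na(vv) & !vv %in% c(0, 1)
      if (any(bad)) {
        abort(sprintf("Column '%s': binary value '%s' outside {0,1}.",
                      nm, format(vv[bad][1])))
      }
      out[[nm]] <- vv; kinds[nm] <- "indicator"
    } else if (kind == "ordinal") {
      lv <- keep$levels[[i]]
      code <- match(v, lv)
      bad <- is.na(code) & !is.na(v)
      if (any(bad)) {
        abort(sprintf("Column '%s': value '%s' outside declared ordinal levels.",
                      nm, format(v[bad][1])))
      }
      out[[nm]] <- as.numeric(code); kinds[nm] <- "ordinal-code"
    } else { # nominal -> one indicator per level
      lv <- keep$levels[[i]]
      bad <- !is.na(v) & !v %in% lv
      if (any(bad)) {
        abort(sprintf("Column '%s': value '%s' outside declared nominal levels.",
                      nm, format(v[bad][1])))
      }
      for (l in lv) {
        cn <- paste0(nm, "=", l)
        out[[cn]] <- ifelse(is.na(v), NA_real_, as.numeric(v == l))
        kinds[cn] <- "indicator"
      }
    }
  }
  data <- tibble::as_tibble(c(
    if (length(id)) setNames(list(raw[[id]]), id),
    out
  ))
  list(data = data, column_kind = kinds, excluded = excluded)
}

#' Reduce skewness of a continuous feature with a shifted-log transform
#'
#' Searches the sign-aware family \eqn{t(x) = s \log(s (x - a) + c)} with
#' \eqn{s \in \{+1, -1\}} (right- vs left-skewed), shift `a` anchoring the
#' support and offset `c` from a fixed grid of fractions of the data range,
#' and keeps the candidate minimizing absolute sample skewness. Every
#' candidate is monotone increasing, so value ordering is preserved. The
#' identity is returned when the column is near-symmetric already
#' (|skewness| <= `threshold`) or when no candidate improves on it.
#'
#' @param values Numeric vector with at least 3 distinct finite values
#'   (constant vectors are returned unchanged and flagged degenerate).
#' @param threshold Absolute skewness below which no transform is attempted.
#' @return List: `values` (transformed vector), `params` (list with `s`, `a`,
#'   `c`; `s = 0` codes the identity), `skew_before`, `skew_after`,
#'   `degenerate` flag.
#' @export
auto_transform_column <- function(values, threshold = 0.5) {
  x <- values
  finite <- x[is.finite(x)]
  if (length(unique(finite)) < 3L) {
    return(list(values = x, params = list(s = 0, a = 0, c = 0),
                skew_before = 0, skew_after = 0, degenerate = TRUE))
  }
  sk0 <- skewness_g1(finite)
  identity_out <- list(values = x, params = list(s = 0, a = 0, c = 0),
                       skew_before = sk0, skew_after = sk0, degenerate = FALSE)
  if (abs(sk0) <= threshold) return(identity_out)

  rng <- diff(range(finite))
  c_grid <- rng * c(0.001, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2)
  best <- identity_out
  for (s in c(1, -1)) {
    a <- if (s > 0) min(finite) else max(finite)
    for (cc in c_grid) {
      tx <- s * log(s * (x - a) + cc)
      sk <- skewness_g1(tx[is.finite(tx)])
      if (is.finite(sk) && abs(sk) < abs(best$skew_after)) {
        best <- list(values = tx, params = list(s = s, a = a, c = cc),
                     skew_before = sk0, skew_after = sk, degenerate = FALSE)
      }
    }
  }
  best
}

# invert auto_transform_column: x = a + s * (exp(s * y) - c)
invert_transform <- function(y, params) {
  if (params$s == 0) return(y)
  params$a + params$s * (exp(params$s * y) - params$c)
}

#' Standardize an encoded feature table into an analysis-ready matrix
#'
#' Continuous columns are optionally transformed toward symmetry
#' ([auto_transform_column()]) and, together with ordinal codes, centered and
#' scaled to mean 0 and sd 1 (sample sd, n-1 denominator) so that the
#' analysis does not depend on measurement scale. Indicator and binary
#' columns are left on their 0/1 scale. Every applied parameter is recorded
#' in `transform_log` so each column can be inverted exactly.
#'
#' @param encoded Result of [encode_features()] (or a compatible list with
#'   `data` and `column_kind`). The table must be complete; run
#'   [drop_incomplete_rows()] first.
#' @param transform Apply the skewness-reducing transform to continuous
#'   columns before standardizing?
#' @param standardize_ordinal Standardize ordinal codes like continuous
#'   features (they enter the same residue computations)? Default `TRUE`.
#' @return A `prepared_matrix`: list with `values` (numeric matrix), `row_ids`,
#'   `column_ids`, `column_kind` (per column: `standardized-continuous`,
#'   `ordinal-code`, `indicator`), `transform_log` (tibble).
#' @export
standardize_matrix <- function(encoded, transform = TRUE,
                               standardize_ordinal = TRUE) {
  data <- encoded$data
  kinds <- encoded$column_kind
  id <- intersect("knee_id", names(data))
  row_ids <- if (length(id)) as.character(data[[id]]) else
    sprintf("row%d", seq_len(nrow(data)))
  feats <- setdiff(names(data), id)
  if (anyNA(data[feats])) {
    abort("Encoded table contains missing cells; run drop_incomplete_rows() first.")
  }

  values <- matrix(NA_real_, nrow(data), length(feats),
                   dimnames = list(row_ids, feats))
  log_rows <- vector("list", length(feats))
  out_kind <- character(length(feats))
  for (j in seq_along(feats)) {
    nm <- feats[j]; v <- as.numeric(data[[nm]]); kind <- kinds[[nm]]
    std <- kind == "continuous" || (kind == "ordinal-code" && standardize_ordinal)
    tp <- list(s = 0, a = 0, c = 0)
    if (kind == "continuous" && transform) {
      tr <- auto_transform_column(v)
      v <- tr$values; tp <- tr$params
    }
    if (std) {
      sdv <- sd(v)
      if (!is.finite(sdv) || sdv < 1e-12) {
        abort(sprintf("Column '%s' has zero variance; exclude it upstream.", nm))
      }
      ctr <- mean(v)
      values[, j] <- (v - ctr) / sdv
      out_kind[j] <- if (kind == "continuous") "standardized-continuous" else
        "ordinal-code"
      log_rows[[j]] <- tibble::tibble(
        column = nm, kind = out_kind[j], s = tp$s, a = tp$a, c = tp$c,
        center = ctr, scale = sdv
      )
    } else {
      values[, j] <- v
      out_kind[j] <- if (kind == "indicator") "indicator" else kind
      log_rows[[j]] <- tibble::tibble(
        column = nm, kind = out_kind[j], s = 0, a = 0, c = 0,
        center = 0, scale = 1
      )
    }
  }
  structure(
    list(
      values = values,
      row_ids = row_ids,
      column_ids = feats,
      column_kind = setNames(out_kind, feats),
      transform_log = dplyr::bind_rows(log_rows)
    ),
    class = "prepared_matrix"
  )
}

#' @export
print.prepared_matrix <- function(x, ...) {
  cat(sprintf("<prepared_matrix> %d knees x %d columns (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$column_kind),
                            names(table(x$column_kind))), collapse = ", ")))
  invisible(x)
}

# invert one standardized column of a prepared matrix back to raw units
unprepare_column <- function(pm, column) {
  lg <- pm$transform_log[pm$transform_log$column == column, ]
  if (nrow(lg) != 1L) abort(sprintf("Unknown column '%s'.", column))
  y <- pm$values[, column] * lg$scale + lg$center
  invert_transform(y, list(s = lg$s, a = lg$a, c = lg$c))
}

#' Remove rows with any missing value
#'
#' Biclustering by mean-squared residue needs a complete matrix, so knees
#' with any missing cell are removed (no imputation). The removal report
#' names each dropped row and the offending columns.
#'
#' @param data Data frame (an id column named `knee_id` is used for the
#'   report when present).
#' @return List: `data` (complete-case tibble, column set unchanged),
#'   `removed` (tibble with `row_id` and `columns`, a list-column of the
#'   missing columns per dropped row).
#' @export
drop_incomplete_rows <- function(data) {
  feats <- setdiff(names(data), "knee_id")
  miss <- is.na(as.data.frame(data[feats]))
  bad <- rowSums(miss) > 0
  if (all(bad)) abort("All rows contain missing values; nothing left to analyze.")
  ids <- if ("knee_id" %in% names(data)) as.character(data$knee_id) else
    as.character(seq_len(nrow(data)))
  removed <- tibble::tibble(
    row_id = ids[bad],
    columns = lapply(which(bad), function(i) feats[miss[i, ]])
  )
  list(data = tibble::as_tibble(data[!bad, , drop = FALSE]), removed = removed)
}
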