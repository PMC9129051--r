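# shared oracles and small generators used across test files

# direct double-loop mean-squared-residue oracle
msr_oracle <- function(mat, rows, cols) {
  sub <- mat[rows, cols, drop = FALSE]
  n <- nrow(sub); m <- ncol(sub)
  riJ <- rowMeans(sub); aIj <- colMeans(sub); aIJ <- mean(sub)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      tot <- tot + (sub[i, j] - riJ[i] - aIj[j] + aIJ)^2
    }
  }
  tot / (n * m)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# exhaustive minimum-MSR search over all submatrices with >= 2 rows/cols
best_msr_exhaustive <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  rsets <- Filter(function(s) length(s) >= 2,
                  unlist(lapply(2:nr, function(k) combn(nr, k, simplify = FALSE)),
                         recursive = FALSE))
  csets <- Filter(function(s) length(s) >= 2,
                  unlist(lapply(2:nc, function(k) combn(nc, k, simplify = FALSE)),
                         recursive = FALSE))
  best <- Inf
  for (rs in rsets) {
    for (cs in csets) {
      h <- msr_oracle(mat, rs, cs)
      if (h < best) best <- h
    }
  }
  best
}

# small additive matrix (row + column effects) plus iid noise
additive_matrix <- function(n, m, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    outer(rnorm(n), rnorm(m), `+`) + matrix(rnorm(n * m, 0, noise), n, m)
  })
}

# two-group panel generator used by trajectory tests
two_group_panel <- function(seed, n = 500, beta2 = c(0, 5), dropout = 0) {
  spec <- synthetic_spec(
    n_rows = n,
    traj_groups = list(flat = list(pi = 0.7, beta = c(0, 0)),
                       rise = list(pi = 0.3, beta = beta2)),
    traj_sd = 1,
    dropout_rate = c(early = dropout, late = dropout),
    seed = seed
  )
  sim <- generate_clinical_matrix(spec)
  list(panel = generate_longitudinal_panel(spec, sim$truth),
       truth = sim$truth, spec = spec)
}

# independent truth-table oracle for the radiographic outcome levels,
# written as explicit case enumeration
roa_oracle <- function(baseline, fu, tka0) {
  if (tka0) return(7L)
  if (is.na(baseline)) return(999L)
  no_fu <- length(fu) == 0
  if (baseline %in% c(0, 1)) {
    if (no_fu) 1L else if (any(fu >= 2)) 3L else 2L
  } else {
    if (no_fu) 4L else if (any(fu > baseline)) 6L else 5L
  }
}
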