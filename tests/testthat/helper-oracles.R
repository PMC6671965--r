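# Independent oracles used across the test files.  These deliberately use
# naive direct computation (per-element loops, exhaustive enumeration)
# rather than the package's vectorized / refinement-based code paths.

offdiag_vals <- function(m) m[row(m) != col(m)]

corner_gap_test <- function(m) max(abs(1 - abs(offdiag_vals(m))))

random_sign_matrix <- function(n) {
  s <- matrix(sample(c(-1, 1), n * n, replace = TRUE), n, n)
  diag(s) <- 0
  sign_matrix(s)
}

# Direct elementwise evaluation of the self-evaluation index
# F_i = (1/2) sum_k (1 + s_ik) s_ki.
oracle_self_evaluation <- function(s) {
  n <- nrow(s)
  vapply(seq_len(n), function(i) {
    tot <- 0
    for (k in seq_len(n)) {
      if (k == i) next
      tot <- tot + (1 + s[i, k]) * s[k, i] / 2
    }
    tot
  }, numeric(1))
}

# Direct per-link stationarity: s_ij must equal sign(sum_k s_ik s_kj),
# with a zero sum counting as non-stationary.
oracle_stationary <- function(s) {
  n <- nrow(s)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      tot <- 0
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        tot <- tot + s[i, k] * s[k, j]
      }
      if (tot == 0 || sign(tot) != s[i, j]) return(FALSE)
    }
  }
  TRUE
}

# All set partitions of 1..n (restricted-growth strings).
all_set_partitions <- function(n) {
  grow <- function(rgs) {
    k <- max(rgs)
    lapply(seq_len(k + 1), function(v) c(rgs, v))
  }
  acc <- list(1L)
  for (i in seq_len(n - 1)) {
    acc <- unlist(lapply(acc, grow), recursive = FALSE)
  }
  acc
}

# Is every block pair (including within-block) of one sign, and the
# partition equitable with respect to friendly out-/in-link counts?
partition_is_sign_uniform <- function(s, membership) {
  ids <- unique(membership)
  for (a in ids) {
    for (b in ids) {
      ma <- which(membership == a)
      mb <- which(membership == b)
      vals <- c()
      for (i in ma) for (j in mb) if (i != j) vals <- c(vals, s[i, j])
      if (length(vals) > 0 && length(unique(vals)) > 1) return(FALSE)
    }
  }
  TRUE
}

partition_is_equitable <- function(s, membership) {
  ids <- unique(membership)
  for (b in ids) {
    mb <- which(membership == b)
    for (a in ids) {
      ma <- which(membership == a)
      outc <- vapply(mb, function(i) sum(s[i, setdiff(ma, i)] == 1),
                     numeric(1))
      inc <- vapply(mb, function(i) sum(s[setdiff(ma, i), i] == 1),
                    numeric(1))
      if (length(unique(outc)) > 1 || length(unique(inc)) > 1) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Exhaustive search for the coarsest sign-uniform equitable partitions.
oracle_coarsest_partitions <- function(s) {
  n <- nrow(s)
  parts <- all_set_partitions(n)
  ok <- Filter(function(p) {
    partition_is_sign_uniform(s, p) && partition_is_equitable(s, p)
  }, parts)
  sizes <- vapply(ok, max, integer(1))
  ok[sizes == min(sizes)]
}

same_partition <- function(m1, m2) {
  canon <- function(m) {
    b <- unname(split(seq_along(m), m))
    b <- lapply(b, as.integer)
    b[order(vapply(b, min, integer(1)))]
  }
  identical(canon(m1), canon(m2))
}

# Apply a node permutation to a sign matrix: node i becomes perm[i].
permute_sign_matrix <- function(s, perm) {
  n <- nrow(s)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[perm[i], perm[j]] <- s[i, j]
    }
  }
  sign_matrix(out)
}

# Every admissible size split of n actors for a given archetype kind
# (all classes nonempty).
all_size_splits <- function(kind, n) {
  k <- c(HB = 2L, CII = 2L, CIII = 3L, CIV = 4L)[[kind]]
  grid <- expand.grid(rep(list(seq_len(n)), k))
  grid <- grid[rowSums(grid) == n, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) as.integer(grid[r, ]))
}

balanced_triads <- function(s) {
  n <- nrow(s)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        if (s[i, j] * s[j, k] * s[k, i] != 1) return(FALSE)
      }
    }
  }
  TRUE
}
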