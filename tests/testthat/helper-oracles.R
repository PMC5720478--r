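# Independent oracles used to validate the implementation: a
# dynamic-programming local aligner, a brute-force interval-stabbing
# coverage counter, and a grid-search solver for the branch-placement
# quadratic program. These deliberately share no code with the package.

# Gotoh affine-gap LOCAL alignment score; gap of length L costs
# gap_open + L * gap_ext, matching the package's scoring convention.
oracle_local_align_score <- function(s1, s2, match = 1, mismatch = -1,
                                     gap_open = 5, gap_ext = 1) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in s2 (consuming s1)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in s1 (consuming s2)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + sub)
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Brute-force per-position coverage by interval stabbing.
oracle_interval_coverage <- function(starts, ends, len) {
  vapply(seq_len(len), function(p) sum(starts <= p & ends >= p), 0L)
}

# Forward purity/ploidy mixture: expected BAF and logR for a true state.
oracle_forward_mixture <- function(rho, psi, n1, n2) {
  d <- 2 * (1 - rho) + rho * (n1 + n2)
  list(baf = (1 - rho + rho * n1) / d,
       logr = log2(d / (2 * (1 - rho) + rho * psi)))
}

# Independent subtree-membership: walk parents.
oracle_in_subtree <- function(parent, clone, top) {
  cur <- clone
  repeat {
    if (cur == top) return(TRUE)
    cur <- parent[[cur]]
    if (is.na(cur)) return(FALSE)
  }
}

# Grid-search solution of the placement QP on every branch, step 0.01.
# The subtree grid reaches far beyond biological copy numbers (bmax1 = 20)
# because a near-zero-CCF subtree can absorb a large fitted CN; the
# remainder is a surviving allele's CN, bounded by bmax2 = 3.
oracle_grid_placement <- function(tree, cn, step = 0.01, bmax1 = 20,
                                  bmax2 = 3, lb2 = 0.5) {
  cvec <- as.numeric(cn[tree$regions])
  b1g <- seq(0, bmax1, by = step)
  b2g <- seq(lb2, bmax2, by = step)
  res <- lapply(tree$clones, function(top) {
    inside <- vapply(tree$clones, oracle_in_subtree, TRUE,
                     parent = tree$parent, top = top)
    f1 <- colSums(tree$ccf[inside, , drop = FALSE])
    f2 <- colSums(tree$ccf[!inside, , drop = FALSE])
    # evaluate ||c - b1 f1 - b2 f2||^2 at every grid point via its
    # expansion in the grid coordinates (exhaustive search, vectorised)
    errs <- outer(b1g^2 * sum(f1^2) - 2 * b1g * sum(cvec * f1),
                  b2g^2 * sum(f2^2) - 2 * b2g * sum(cvec * f2), "+") +
      2 * outer(b1g, b2g) * sum(f1 * f2) + sum(cvec^2)
    min(errs)
  })
  errs <- unlist(res)
  list(branch = tree$clones[which.min(errs)], error = min(errs),
       errors = setNames(errs, tree$clones))
}

# Exact cohort probability that ALL tumors draw a loss (used for the
# analytic enrichment check with observed fraction 1).
oracle_all_loss_probability <- function(probs) prod(probs)
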