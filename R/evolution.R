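# Placing LOH events on clone phylogenies by quadratic programming,
# clonality and focal/arm-level classification, and the permutation test
# for enrichment of focal loss.

#' Build a clone tree with regional cancer cell fractions
#'
#' @param nodes Tibble with columns `clone`, `parent` (`NA` for the
#'   trunk/root) and one numeric column per tumor region holding that
#'   clone's cancer cell fraction (CCF) in \[0, 1\].
#' @param ccf_tol Pigeonhole tolerance on the nesting constraint
#'   `child CCF <= parent CCF` per region (default 0.05); violations warn.
#' @return An object of class `clone_tree`.
#' @export
clone_tree <- function(nodes, ccf_tol = 0.05) {
  stopifnot(all(c("clone", "parent") %in% names(nodes)))
  regions <- setdiff(names(nodes), c("clone", "parent"))
  if (length(regions) == 0) abort("clone tree needs at least one region CCF column")
  clones <- as.character(nodes$clone)
  parent <- as.character(nodes$parent)
  if (anyDuplicated(clones)) abort("duplicate clone identifiers")
  root <- clones[is.na(parent)]
  if (length(root) != 1) abort("clone tree must have exactly one root (parent = NA)")
  if (!all(parent[!is.na(parent)] %in% clones)) abort("parent not among clones")
  ccf <- as.matrix(nodes[, regions, drop = FALSE])
  rownames(ccf) <- clones
  if (any(ccf < 0 | ccf > 1)) abort("CCFs must lie in [0, 1]")
  # cycle check by walking to root from every node
  par <- setNames(parent, clones)
  for (cl in clones) {
    seen <- character(); cur <- cl
    while (!is.na(par[[cur]])) {
      if (cur %in% seen) abort("clone tree contains a cycle")
      seen <- c(seen, cur); cur <- par[[cur]]
    }
  }
  viol <- vapply(clones[!is.na(par[clones])], function(cl) {
    any(ccf[cl, ] > ccf[par[[cl]], ] + ccf_tol)
  }, logical(1))
  if (any(viol)) {
    warn(paste0("child CCF exceeds parent CCF beyond tolerance for clone(s): ",
                paste(names(viol)[viol], collapse = ", ")))
  }
  structure(
    list(clones = clones, parent = par, root = root,
         regions = regions, ccf = ccf),
    class = "clone_tree"
  )
}

#' Read a clone tree from a TSV file
#'
#' Expects columns `clone`, `parent` (empty or `NA` for the root) and one
#' CCF column per region.
#'
#' @param path TSV path.
#' @param ... Passed to [clone_tree()].
#' @return A `clone_tree`.
#' @export
read_clone_tree <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("clone tree file not found: ", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  clone_tree(as_tibble(tab), ...)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", length(x$clones), " clones, root ", x$root,
      ", regions: ", paste(x$regions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

.descendants <- function(tree, clone) {
  kids <- names(tree$parent)[!is.na(tree$parent) & tree$parent == clone]
  c(clone, unlist(lapply(kids, .descendants, tree = tree)))
}

.node_depth <- function(tree, clone) {
  d <- 0L; cur <- clone
  while (!is.na(tree$parent[[cur]])) { d <- d + 1L; cur <- tree$parent[[cur]] }
  d
}

# Exact solver for the 2-variable convex QP
#   min  -d'b + 1/2 b' D b   (i.e. least squares ||c - F'b||^2 up to a constant)
#   s.t. b1 >= 0, b2 >= lb2
# by KKT active-set enumeration. D may be singular (e.g. a zero row of F,
# the trunk case): the free variable is pinned to its bound.
.solve_qp2 <- function(D, d, lb2 = 0.5) {
  obj <- function(b) -sum(d * b) + 0.5 * sum(b * (D %*% b))
  cand <- list()
  # unconstrained stationary point
  if (abs(det(D)) > 1e-12) {
    b <- drop(solve(D, d))
    if (b[1] >= -1e-12 && b[2] >= lb2 - 1e-12) cand <- c(cand, list(b))
  }
  # b1 = 0 active
  if (D[2, 2] > 1e-12) {
    b2 <- max(d[2] / D[2, 2], lb2)
    cand <- c(cand, list(c(0, b2)))
  } else cand <- c(cand, list(c(0, lb2)))
  # b2 = lb2 active
  if (D[1, 1] > 1e-12) {
    b1 <- max((d[1] - D[1, 2] * lb2) / D[1, 1], 0)
    cand <- c(cand, list(c(b1, lb2)))
  } else cand <- c(cand, list(c(0, lb2)))
  # corner
  cand <- c(cand, list(c(0, lb2)))
  feas <- Filter(function(b) b[1] >= -1e-9 && b[2] >= lb2 - 1e-9, cand)
  vals <- vapply(feas, obj, numeric(1))
  b <- feas[[which.min(vals)]]
  pmax(b, c(0, lb2))
}

#' Place an LOH event on a clone tree by quadratic programming
#'
#' The event is tested on every branch: the tree splits into the subtree
#' at/below the candidate clone and the remainder. A 2 x n matrix F of
#' regional CCF sums (subtree row; remainder row) predicts the regional
#' lost-allele copy number as `F' b`, where `b[1]` is the lost-allele copy
#' number inside the subtree and `b[2]` outside it. The quadratic program
#' `min(-d'b + 1/2 b'Db)` with `D = F F'`, `d = F c` is solved subject to
#' `b >= 0` and a floor of `remainder_floor` on the remainder copy number,
#' and the branch with the least squared error `||c - F'b||^2` wins (ties
#' go to the most ancestral branch). A best relative error above
#' `error_threshold` flags the event as not fitting the tree.
#'
#' @param tree A [clone_tree()].
#' @param regional_cn Named numeric vector of the lost allele's copy number
#'   per region (names = tree regions).
#' @param remainder_floor Minimum copy number outside the event subtree
#'   (default 0.5).
#' @param error_threshold Relative error (fraction of `||c||^2`) above
#'   which the event is reported unplaced (default 0.25).
#' @return An object of class `loh_placement`: tibble `by_branch` (clone,
#'   b1, b2, error), plus `branch`, `b`, `error`, `unplaced`.
#' @export
map_loss_to_clone <- function(tree, regional_cn, remainder_floor = 0.5,
                              error_threshold = 0.25) {
  stopifnot(inherits(tree, "clone_tree"))
  if (!all(tree$regions %in% names(regional_cn))) {
    abort("regional_cn must cover every region of the tree")
  }
  cvec <- as.numeric(regional_cn[tree$regions])
  rows <- purrr::map(tree$clones, function(cl) {
    sub <- .descendants(tree, cl)
    f1 <- colSums(tree$ccf[sub, , drop = FALSE])
    rest <- setdiff(tree$clones, sub)
    f2 <- if (length(rest) > 0) {
      colSums(tree$ccf[rest, , drop = FALSE])
    } else {
      rep(0, length(tree$regions))
    }
    FF <- rbind(f1, f2)
    D <- FF %*% t(FF)
    d <- drop(FF %*% cvec)
    b <- unname(.solve_qp2(unname(D), unname(d), lb2 = remainder_floor))
    err <- sum((cvec - drop(t(FF) %*% b))^2)
    tibble(clone = cl, depth = .node_depth(tree, cl),
           b1 = b[1], b2 = b[2], error = err)
  })
  by_branch <- bind_rows(rows) %>% arrange(.data$error, .data$depth)
  best <- by_branch %>% slice(1)
  denom <- sum(cvec^2)
  rel <- if (denom > 0) best$error / denom else best$error
  structure(
    list(
      by_branch = by_branch %>% select(-"depth"),
      branch = best$clone,
      b = c(subtree = best$b1, remainder = best$b2),
      error = best$error,
      relative_error = rel,
      unplaced = rel > error_threshold
    ),
    class = "loh_placement"
  )
}

#' @export
print.loh_placement <- function(x, ...) {
  if (x$unplaced) {
    cat(sprintf("<loh_placement> unplaced (best branch %s, relative error %.3f)\n",
                x$branch, x$relative_error))
  } else {
    cat(sprintf("<loh_placement> branch %s: subtree CN %.3f, remainder CN %.3f, error %.4g\n",
                x$branch, x$b[["subtree"]], x$b[["remainder"]], x$error))
  }
  invisible(x)
}

#' Classify an LOH event as clonal or subclonal
#'
#' Clonal events are detected in every analyzable tumor region; events
#' detected in only a subset are subclonal.
#'
#' @param detected Character vector of regions in which the event was
#'   detected (must be non-empty and a subset of `analyzable`).
#' @param analyzable Character vector of regions with usable copy-number
#'   data.
#' @return `"clonal"` or `"subclonal"`.
#' @export
classify_event_clonality <- function(detected, analyzable) {
  if (length(analyzable) == 0) abort("no analyzable regions")
  if (length(detected) == 0) abort("no detected regions: not an event")
  if (!all(detected %in% analyzable)) abort("detected regions not analyzable")
  if (setequal(detected, analyzable)) "clonal" else "subclonal"
}

#' Approximate chromosome arm table (GRCh37)
#'
#' Autosomal arm boundaries derived from the GRCh37 centromere gaps,
#' rounded to whole megabases; sufficient for focal/arm-level scale
#' classification and overridable by a user-supplied table.
#'
#' @return A tibble `chrom`, `arm`, `start`, `end`.
#' @export
chrom_arms_hg19 <- function() {
  cen <- c(`1` = 125.0, `2` = 93.3, `3` = 91.0, `4` = 50.4, `5` = 48.4,
           `6` = 61.0, `7` = 59.9, `8` = 45.6, `9` = 49.0, `10` = 40.2,
           `11` = 53.7, `12` = 35.8, `13` = 17.9, `14` = 17.6, `15` = 19.0,
           `16` = 36.6, `17` = 24.0, `18` = 17.2, `19` = 26.5, `20` = 27.5,
           `21` = 13.2, `22` = 14.7)
  len <- c(`1` = 249.25, `2` = 243.20, `3` = 198.02, `4` = 191.15,
           `5` = 180.92, `6` = 171.12, `7` = 159.14, `8` = 146.36,
           `9` = 141.21, `10` = 135.53, `11` = 135.01, `12` = 133.85,
           `13` = 115.17, `14` = 107.35, `15` = 102.53, `16` = 90.35,
           `17` = 81.20, `18` = 78.08, `19` = 59.13, `20` = 63.03,
           `21` = 48.13, `22` = 51.30)
  mb <- 1e6
  bind_rows(
    tibble(chrom = paste0("chr", names(cen)), arm = "p",
           start = 1, end = round(cen * mb)),
    tibble(chrom = paste0("chr", names(cen)), arm = "q",
           start = round(cen * mb) + 1, end = round(len * mb))
  ) %>% arrange(match(.data$chrom, paste0("chr", 1:22)), .data$arm)
}

#' Merge adjacent segments with identical minor-allele copy number
#'
#' @param segments Tibble `chrom`, `start`, `end`, `minor_cn` (extra
#'   columns are dropped), sorted or not.
#' @return Merged segment tibble.
#' @export
merge_segments <- function(segments) {
  segments %>%
    arrange(.data$chrom, .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(run = cumsum(c(TRUE, .data$minor_cn[-1] != .data$minor_cn[-n()] |
                                  .data$start[-1] > .data$end[-n()] + 1L))) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              minor_cn = .data$minor_cn[1], .groups = "drop") %>%
    select("chrom", "start", "end", "minor_cn")
}

#' Classify segments as focal or arm-level
#'
#' After merging adjacent segments with identical minor-allele copy
#' number, a segment spanning at least 75% of its chromosome arm is
#' arm-level; anything shorter is focal.
#'
#' @param segments Segment tibble `chrom`, `start`, `end`, `minor_cn`.
#' @param arms Arm table (default [chrom_arms_hg19()]).
#' @param arm_fraction Arm-level threshold (default 0.75).
#' @param merge Merge same-minor-CN neighbours first (default TRUE).
#' @return The merged segments with columns `arm`, `arm_overlap`,
#'   `arm_frac`, `scale` (`"focal"`/`"arm_level"`). Segments spanning the
#'   centromere are split at the arm boundary.
#' @export
classify_segment_scale <- function(segments, arms = chrom_arms_hg19(),
                                   arm_fraction = 0.75, merge = TRUE) {
  segs <- if (merge) merge_segments(segments) else
    segments %>% select("chrom", "start", "end", "minor_cn")
  out <- segs %>%
    left_join(arms, by = "chrom", suffix = c("", ".arm"),
              relationship = "many-to-many") %>%
    mutate(
      ov_start = pmax(.data$start, .data$start.arm),
      ov_end = pmin(.data$end, .data$end.arm)
    ) %>%
    filter(!is.na(.data$arm), .data$ov_start <= .data$ov_end) %>%
    mutate(
      arm_overlap = .data$ov_end - .data$ov_start + 1,
      arm_frac = .data$arm_overlap / (.data$end.arm - .data$start.arm + 1),
      scale = ifelse(.data$arm_frac >= arm_fraction, "arm_level", "focal")
    ) %>%
    select("chrom", "arm", start = "ov_start", end = "ov_end",
           "minor_cn", "arm_overlap", "arm_frac", "scale")
  if (nrow(out) < nrow(segs)) {
    warn("some segments fall outside the supplied arm table and were dropped")
  }
  out
}

#' Per-tumor probability of focal minor-allele loss
#'
#' The proportion of the covered autosomal genome subject to focal
#' minor-allele loss (minor CN = 0 in a focal-scale segment), used as the
#' tumor's per-draw loss probability in [simulate_loh_expectation()].
#'
#' @param segments Segment tibble for one tumor.
#' @param arms Arm table.
#' @param scale `"focal"` (default) or `"arm_level"`: which scale of loss
#'   to measure.
#' @return A proportion in \[0, 1\].
#' @export
focal_loss_probability <- function(segments, arms = chrom_arms_hg19(),
                                   scale = c("focal", "arm_level")) {
  scale <- match.arg(scale)
  cls <- classify_segment_scale(segments, arms)
  tot <- sum(cls$arm_overlap)
  if (tot == 0) return(0)
  sum(cls$arm_overlap[cls$scale == scale & cls$minor_cn == 0]) / tot
}

#' Permutation test for enrichment of LOH at a locus
#'
#' Given each tumor's genome-wide probability of (focal or arm-level)
#' minor-allele loss, simulates a loss/no-loss state per tumor and records
#' the cohort loss proportion, repeated `n_reps` times to form a
#' background distribution. The p-value is the fraction of replicates with
#' a loss proportion at least the observed one; zero counts are reported
#' at the 1/n_reps resolution floor.
#'
#' @param probs Per-tumor loss probabilities in \[0, 1\].
#' @param observed_fraction Observed cohort proportion with loss at the
#'   locus of interest.
#' @param n_reps Number of replicates (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `loh_enrichment`: list with `p_value`,
#'   `p_floor` (p-value floored at 1/n_reps), `observed`, `n_reps`,
#'   `background` (simulated proportions).
#' @export
simulate_loh_expectation <- function(probs, observed_fraction,
                                     n_reps = 10000, seed = NULL) {
  if (length(probs) == 0) abort("empty cohort")
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(probs)
  losses <- matrix(rbinom(n * n_reps, 1L, rep(probs, times = n_reps)),
                   nrow = n)
  background <- colMeans(losses)
  p <- mean(background >= observed_fraction)
  structure(
    list(p_value = p, p_floor = max(p, 1 / n_reps),
         observed = observed_fraction, n_reps = n_reps,
         background = background),
    class = "loh_enrichment"
  )
}

#' @export
print.loh_enrichment <- function(x, ...) {
  p_show <- if (x$p_value == 0) paste0("< ", format(1 / x$n_reps)) else
    format(x$p_value)
  cat(sprintf("<loh_enrichment> observed %.3f vs %d simulated cohorts: p %s\n",
              x$observed, x$n_reps, p_show))
  invisible(x)
}
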