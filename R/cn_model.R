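# BAF/logR evidence, the purity/ploidy inversion into allele-specific copy
# number, the paired t-test on per-site logR differences, and the LOH call.

#' Purity/ploidy parameter pair
#'
#' @param rho Tumor purity, in (0, 1].
#' @param psi Tumor ploidy, > 0 (e.g. from an allele-specific CN tool).
#' @return A validated list of class `purity_ploidy`.
#' @export
purity_ploidy <- function(rho, psi) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1) {
    abort("rho must be a single number in (0, 1]")
  }
  if (!is.numeric(psi) || length(psi) != 1 || psi <= 0) {
    abort("psi must be a single positive number")
  }
  structure(list(rho = rho, psi = psi), class = "purity_ploidy")
}

#' Binned logR from tumor and germline coverage over both homologs
#'
#' Coverage across the two homologous alleles is summed in fixed-width bins
#' (150 bp by default). Per bin, the tumor/germline coverage ratio is
#' rescaled by the multiplication factor M (germline unique reads divided
#' by tumor unique reads) and logR = log2 of the rescaled ratio. Bins whose
#' germline mean depth falls below `min_germline_depth` are excluded from
#' downstream estimation.
#'
#' @param coverage Tibble of per-position depth with columns `allele`,
#'   `sample` (`"tumor"`/`"germline"`), `pos`, `depth`, covering both
#'   homologs of one gene.
#' @param m_factor Multiplication factor M.
#' @param bin_width Bin width in bp (default 150).
#' @param min_germline_depth Minimum mean germline depth per bin position
#'   (default 10).
#' @return A tibble `bin`, `start`, `end`, `tumor_sum`, `germline_sum`,
#'   `m`, `logr`, `excluded`.
#' @export
compute_logr_bins <- function(coverage, m_factor, bin_width = 150,
                              min_germline_depth = 10) {
  if (nrow(coverage) == 0) abort("empty coverage: zero-length gene")
  binned <- coverage %>%
    mutate(bin = (.data$pos - 1L) %/% as.integer(bin_width) + 1L) %>%
    group_by(.data$sample, .data$bin) %>%
    summarise(sum = sum(.data$depth), npos = n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = c("sum", "npos"),
                       values_fill = list(sum = 0L, npos = 0L))
  for (col in c("sum_tumor", "sum_germline", "npos_germline")) {
    if (!col %in% names(binned)) binned[[col]] <- 0L
  }
  out <- binned %>%
    mutate(
      start = (.data$bin - 1L) * as.integer(bin_width) + 1L,
      end = .data$start + as.integer(bin_width) - 1L,
      tumor_sum = .data$sum_tumor,
      germline_sum = .data$sum_germline,
      m = m_factor,
      excluded = .data$germline_sum <
        min_germline_depth * pmax(.data$npos_germline, 1L) |
        .data$germline_sum == 0L,
      logr = ifelse(.data$germline_sum > 0 & .data$tumor_sum > 0,
                    log2(m_factor * .data$tumor_sum / .data$germline_sum),
                    NA_real_)
    ) %>%
    select("bin", "start", "end", "tumor_sum", "germline_sum", "m",
           "logr", "excluded") %>%
    arrange(.data$bin)
  if (all(out$excluded)) {
    attr(out, "insufficient_coverage") <- TRUE
  }
  out
}

#' Per-site b-allele frequency
#'
#' BAF at a discriminating site is the unique-read tumor coverage of
#' allele 1 divided by the combined unique-read tumor coverage of both
#' alleles. Sites with zero combined tumor depth are dropped.
#'
#' @param sites Tibble with per-site unique depths: `pos1`, `pos2`,
#'   `tumor1`, `tumor2` (and optionally germline columns, carried
#'   through).
#' @return The input with a `baf` column, zero-depth sites removed.
#' @export
compute_baf <- function(sites) {
  sites %>%
    filter(.data$tumor1 + .data$tumor2 > 0) %>%
    mutate(baf = .data$tumor1 / (.data$tumor1 + .data$tumor2))
}

#' Invert BAF and logR into allele-specific copy numbers
#'
#' Under the standard purity/ploidy mixture model, a site with b-allele
#' frequency `baf` inside a bin with log ratio `logr` implies
#' \deqn{n_1 = (\rho - 1 + BAF \cdot 2^{logR}(2(1-\rho)+\rho\psi)) / \rho}
#' \deqn{n_2 = (\rho - 1 - (BAF-1) \cdot 2^{logR}(2(1-\rho)+\rho\psi)) / \rho}
#' The pair satisfies the total-copy-number identity
#' `n1 + n2 = (2(rho-1) + 2^logR (2(1-rho)+rho psi)) / rho` regardless of BAF.
#'
#' @param baf B-allele frequency in \[0, 1\] (vectorised).
#' @param logr Bin log2 ratio (vectorised).
#' @param pp A [purity_ploidy()] object.
#' @return A tibble with columns `cn1`, `cn2`.
#' @export
allele_specific_cn <- function(baf, logr, pp) {
  stopifnot(inherits(pp, "purity_ploidy"))
  rho <- pp$rho; psi <- pp$psi
  scale <- 2^logr * (2 * (1 - rho) + rho * psi)
  tibble(
    cn1 = (rho - 1 + baf * scale) / rho,
    cn2 = (rho - 1 - (baf - 1) * scale) / rho
  )
}

#' Gene-level allele-specific copy number estimate
#'
#' Every discriminating site contributes a per-site (cn1, cn2) computed
#' from its own BAF and the logR of the bin it resides in. Per bin, the
#' median cn1 and median cn2 over contained sites are taken; the gene-level
#' estimate is the median over bins.
#'
#' @param sites Tibble from [compute_baf()] (needs `pos1`, `baf`).
#' @param bins Tibble from [compute_logr_bins()].
#' @param pp A [purity_ploidy()] object.
#' @param min_sites Minimum usable sites for a determinate estimate
#'   (default 5).
#' @return A list of class `allele_cn_estimate`: `cn1`, `cn2` (gene-level),
#'   `by_bin` tibble, `site_cn` tibble, `n_sites`, `n_bins`,
#'   `indeterminate` flag.
#' @export
estimate_gene_cn <- function(sites, bins, pp, min_sites = 5) {
  usable_bins <- bins %>% filter(!.data$excluded, !is.na(.data$logr))
  site_cn <- sites %>%
    left_join(usable_bins %>% select("bin", "start", "end", "logr"),
              by = dplyr::join_by(pos1 >= start, pos1 <= end)) %>%
    filter(!is.na(.data$logr))
  if (nrow(site_cn) < min_sites) {
    return(structure(
      list(cn1 = NA_real_, cn2 = NA_real_, by_bin = tibble(),
           site_cn = site_cn, n_sites = nrow(site_cn), n_bins = 0L,
           indeterminate = TRUE),
      class = "allele_cn_estimate"
    ))
  }
  site_cn <- dplyr::bind_cols(
    site_cn, allele_specific_cn(site_cn$baf, site_cn$logr, pp)
  )
  by_bin <- site_cn %>%
    group_by(.data$bin) %>%
    summarise(cn1 = median(.data$cn1), cn2 = median(.data$cn2),
              n_sites = n(), .groups = "drop")
  structure(
    list(
      cn1 = median(by_bin$cn1), cn2 = median(by_bin$cn2),
      by_bin = by_bin, site_cn = site_cn,
      n_sites = nrow(site_cn), n_bins = nrow(by_bin),
      indeterminate = FALSE
    ),
    class = "allele_cn_estimate"
  )
}

#' @export
print.allele_cn_estimate <- function(x, ...) {
  if (x$indeterminate) {
    cat("<allele_cn_estimate> indeterminate (", x$n_sites, " usable sites)\n",
        sep = "")
  } else {
    cat(sprintf("<allele_cn_estimate> cn1 = %.4f, cn2 = %.4f (%d sites, %d bins)\n",
                x$cn1, x$cn2, x$n_sites, x$n_bins))
  }
  invisible(x)
}

#' Paired t-test for allelic imbalance
#'
#' Tests whether the two homologs carry systematically different coverage,
#' via the per-site pairwise difference of logR values between homologs,
#' using unique-read depths so each read is counted once:
#' `d = log2(M t1/g1) - log2(M t2/g2)` (M cancels). A two-sided paired
#' Student's t-test is applied to the differences.
#'
#' @param sites Tibble with unique-read depths `tumor1`, `tumor2`,
#'   `germline1`, `germline2`; sites with any zero depth are dropped
#'   (their log ratio is undefined).
#' @param min_sites Minimum number of usable paired sites (default 5);
#'   below this the test is indeterminate and `NA` is returned.
#' @return The two-sided p-value, `NA_real_` if indeterminate. All-zero
#'   differences give p = 1; zero variance around a non-zero mean returns
#'   a near-zero sentinel (1e-16) with a warning.
#' @export
test_allelic_imbalance <- function(sites, min_sites = 5) {
  ok <- sites %>%
    filter(.data$tumor1 > 0, .data$tumor2 > 0,
           .data$germline1 > 0, .data$germline2 > 0)
  if (nrow(ok) < min_sites) return(NA_real_)
  d <- log2(ok$tumor1 / ok$germline1) - log2(ok$tumor2 / ok$germline2)
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) {
    warn("zero-variance logR differences with non-zero mean; p set to 1e-16")
    return(1e-16)
  }
  t.test(d)$p.value
}

#' Classify a gene's LOH status
#'
#' LOH is called when the smaller allele copy number falls below
#' `cn_threshold` (0.5) AND the allelic-imbalance p-value is below `alpha`
#' (0.01) — the p-value guard avoids over-calling loss from copy-number
#' noise alone. Imbalance without LOH is p < alpha with both copy numbers
#' at or above the threshold.
#'
#' @param est An `allele_cn_estimate`.
#' @param p Allelic-imbalance p-value (or `NA`).
#' @param cn_threshold Copy number below which an allele is lost
#'   (default 0.5).
#' @param alpha Imbalance significance level (default 0.01).
#' @return A one-row tibble: `cn1`, `cn2`, `p_value`, `verdict`,
#'   `lost_allele` (1, 2 or `NA`). Verdict is one of `"loh"`,
#'   `"allelic_imbalance"`, `"no_imbalance"`, `"indeterminate"`.
#' @export
classify_loh <- function(est, p, cn_threshold = 0.5, alpha = 0.01) {
  if (inherits(est, "allele_cn_estimate") && est$indeterminate ||
      is.na(p)) {
    return(tibble(cn1 = if (inherits(est, "allele_cn_estimate")) est$cn1 else NA_real_,
                  cn2 = if (inherits(est, "allele_cn_estimate")) est$cn2 else NA_real_,
                  p_value = p, verdict = "indeterminate",
                  lost_allele = NA_integer_))
  }
  cn1 <- est$cn1; cn2 <- est$cn2
  lo <- min(cn1, cn2)
  verdict <- if (lo < cn_threshold && p < alpha) {
    "loh"
  } else if (p < alpha) {
    "allelic_imbalance"
  } else {
    "no_imbalance"
  }
  tibble(
    cn1 = cn1, cn2 = cn2, p_value = p, verdict = verdict,
    lost_allele = if (verdict == "loh") which.min(c(cn1, cn2)) else NA_integer_
  )
}

#' Normalized allelic ratio from fragment-analysis peak areas
#'
#' Orthogonal (PCR fragment / STR marker) imbalance readout:
#' `(A_tumor/B_tumor) / (A_normal/B_normal)`. A value of 1 indicates
#' balance; deviation from 1 indicates allelic imbalance.
#'
#' @param a_tumor,b_tumor,a_normal,b_normal Peak areas (> 0).
#' @return The normalized allelic ratio.
#' @export
normalized_allelic_ratio <- function(a_tumor, b_tumor, a_normal, b_normal) {
  if (any(c(b_tumor, a_normal, b_normal) == 0)) {
    abort("zero denominator in normalized allelic ratio")
  }
  (a_tumor / b_tumor) / (a_normal / b_normal)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Convenience wrapper used for cohort enrichment questions (e.g. is LOH
#' more frequent in one histological subtype than another), returning a
#' tidy one-row tibble.
#'
#' @param x11,x12,x21,x22 The four cell counts, row-wise: row 1 is group 1
#'   (event / no event), row 2 is group 2.
#' @return A tibble `estimate` (odds ratio), `p_value`, `conf_low`,
#'   `conf_high`, `method`.
#' @export
fisher_2x2 <- function(x11, x12, x21, x22) {
  ft <- fisher.test(matrix(c(x11, x21, x12, x22), nrow = 2))
  tibble(
    estimate = unname(ft$estimate),
    p_value = ft$p.value,
    conf_low = ft$conf.int[1],
    conf_high = ft$conf.int[2],
    method = "Fisher's exact test (two-sided)"
  )
}
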