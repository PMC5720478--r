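# The end-to-end calling pipeline: extraction, re-alignment, filtering,
# evidence, copy-number model and per-gene verdicts, plus report writing.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the calling pipeline with their
#' published defaults: 150-bp logR bins, at least 5 discriminating sites,
#' germline bin depth floor 10, loss below copy number 0.5, imbalance at
#' p < 0.01.
#'
#' @param bin_width logR bin width in bp (default 150).
#' @param min_sites Minimum discriminating sites per gene (default 5).
#' @param min_germline_depth Germline mean depth floor per bin (default 10).
#' @param cn_threshold Copy number below which an allele counts as lost
#'   (default 0.5).
#' @param alpha Allelic-imbalance significance level (default 0.01).
#' @param min_score_frac Minimum re-alignment score as fraction of read
#'   length (default 0.8).
#' @param regions,contigs Extraction target overrides (defaults
#'   [hla_target_regions()], [hla_alt_contigs()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(bin_width = 150, min_sites = 5,
                       min_germline_depth = 10, cn_threshold = 0.5,
                       alpha = 0.01, min_score_frac = 0.8,
                       regions = hla_target_regions(),
                       contigs = hla_alt_contigs()) {
  stopifnot(bin_width > 0, min_sites > 0, min_germline_depth > 0,
            cn_threshold > 0, alpha > 0, min_score_frac > 0)
  structure(
    list(bin_width = bin_width, min_sites = min_sites,
         min_germline_depth = min_germline_depth,
         cn_threshold = cn_threshold, alpha = alpha,
         min_score_frac = min_score_frac,
         regions = regions, contigs = contigs),
    class = "run_config"
  )
}

.empty_call_row <- function(gene, allele1, allele2, verdict, n_sites = 0L) {
  tibble(gene = gene, allele1 = allele1, allele2 = allele2,
         cn1 = NA_real_, cn2 = NA_real_, p_value = NA_real_,
         n_sites = as.integer(n_sites), n_bins = 0L, verdict = verdict,
         lost_allele = NA_character_)
}

#' Call HLA allele-specific copy number and LOH for one tumor sample
#'
#' Runs the full published workflow: extract candidate reads from the
#' tumor and germline alignments, re-align them to the patient's own
#' allele sequences, apply the post-alignment filters, derive binned logR
#' and per-site BAF from unique-read coverage at the discriminating
#' positions, invert the purity/ploidy mixture into allele copy numbers,
#' and classify each heterozygous gene. Homozygous genes (LOH undetectable)
#' and genes with too few discriminating sites are reported as flagged
#' rows, never as LOH.
#'
#' @param tumor_bam,germline_bam Paths to indexed BAM files.
#' @param hla_fasta Path to the allele-sequence FASTA.
#' @param genotype A genotype tibble from [hla_genotype()] /
#'   [read_hla_genotype()].
#' @param pp A [purity_ploidy()] object.
#' @param config A [run_config()] (defaults).
#' @return An object of class `hla_loh_call`: `calls` (per-gene tibble),
#'   `sites` (per-site evidence with BAF and copy numbers), `bins`
#'   (per-gene logR bins), `log` (filter and parameter provenance).
#' @export
call_hla_loh <- function(tumor_bam, germline_bam, hla_fasta, genotype,
                         pp, config = run_config()) {
  stopifnot(inherits(pp, "purity_ploidy"), inherits(config, "run_config"))
  wanted <- unique(c(genotype$allele1, genotype$allele2))
  registry <- read_hla_alleles(hla_fasta, wanted)
  reads <- list(
    tumor = extract_candidate_reads(tumor_bam, config$regions, config$contigs),
    germline = extract_candidate_reads(germline_bam, config$regions,
                                       config$contigs)
  )
  log <- list(
    parameters = unclass(config)[c("bin_width", "min_sites",
                                   "min_germline_depth", "cn_threshold",
                                   "alpha", "min_score_frac")],
    purity = pp$rho, ploidy = pp$psi,
    n_extracted = vapply(reads, nrow, 0L),
    genes = list()
  )

  calls <- list(); site_rows <- list(); bin_rows <- list()
  aln_by_gene <- list()
  for (g in seq_len(nrow(genotype))) {
    row <- genotype[g, ]
    if (row$homozygous) next
    alleles <- registry %>% filter(.data$allele %in% c(row$allele1, row$allele2))
    aln_by_gene[[row$gene]] <- lapply(reads, function(rd) {
      filter_alignments(align_reads_to_alleles(rd, alleles,
                                               config$min_score_frac))
    })
  }
  # multiplication factor M over the extracted, re-aligned read sets
  n_unique <- vapply(c("tumor", "germline"), function(smp) {
    al <- bind_rows(lapply(aln_by_gene, `[[`, smp))
    if (nrow(al) == 0) 0L else nrow(distinct(al, .data$read, .data$mate))
  }, 0L)
  m_factor <- if (n_unique[["tumor"]] > 0) {
    n_unique[["germline"]] / n_unique[["tumor"]]
  } else {
    NA_real_
  }
  log$n_unique_aligned <- n_unique
  log$m_factor <- m_factor

  for (g in seq_len(nrow(genotype))) {
    row <- genotype[g, ]
    if (row$homozygous) {
      calls[[row$gene]] <- .empty_call_row(row$gene, row$allele1, row$allele2,
                                           "homozygous")
      next
    }
    a1 <- registry$sequence[registry$allele == row$allele1]
    a2 <- registry$sequence[registry$allele == row$allele2]
    haln <- align_homologs(a1, a2, row$allele1, row$allele2)
    sites <- find_mismatch_sites(haln)
    if (nrow(sites) < config$min_sites) {
      calls[[row$gene]] <- .empty_call_row(row$gene, row$allele1, row$allele2,
                                           "insufficiently_polymorphic",
                                           nrow(sites))
      next
    }
    alns <- aln_by_gene[[row$gene]]
    log$genes[[row$gene]] <- list(
      n_mismatch_sites = nrow(sites),
      n_discarded = lapply(alns, attr, "n_discarded")
    )
    cov <- bind_rows(lapply(c("tumor", "germline"), function(smp) {
      bind_rows(
        compute_coverage(alns[[smp]] %>% filter(.data$allele == row$allele1),
                         nchar(a1), "allele1", smp),
        compute_coverage(alns[[smp]] %>% filter(.data$allele == row$allele2),
                         nchar(a2), "allele2", smp)
      )
    }))
    bins <- compute_logr_bins(cov, m_factor, config$bin_width,
                              config$min_germline_depth)
    # unique-read site evidence from unambiguously assigned reads only
    site_depth <- lapply(c("tumor", "germline"), function(smp) {
      best <- assign_best_allele(alns[[smp]])
      assigned <- alns[[smp]] %>%
        dplyr::inner_join(best, by = c("read", "mate")) %>%
        filter(!is.na(.data$best_allele), .data$allele == .data$best_allele)
      list(
        a1 = site_coverage_unique(assigned %>%
                                    filter(.data$allele == row$allele1),
                                  sites$pos1),
        a2 = site_coverage_unique(assigned %>%
                                    filter(.data$allele == row$allele2),
                                  sites$pos2)
      )
    })
    names(site_depth) <- c("tumor", "germline")
    ev <- sites %>%
      mutate(
        tumor1 = site_depth$tumor$a1$unique_depth[match(.data$pos1,
                                                        site_depth$tumor$a1$pos)],
        tumor2 = site_depth$tumor$a2$unique_depth[match(.data$pos2,
                                                        site_depth$tumor$a2$pos)],
        germline1 = site_depth$germline$a1$unique_depth[match(.data$pos1,
                                                              site_depth$germline$a1$pos)],
        germline2 = site_depth$germline$a2$unique_depth[match(.data$pos2,
                                                              site_depth$germline$a2$pos)]
      )
    baf_sites <- compute_baf(ev)
    est <- estimate_gene_cn(baf_sites, bins, pp, config$min_sites)
    p <- test_allelic_imbalance(ev, config$min_sites)
    call <- classify_loh(est, p, config$cn_threshold, config$alpha)
    calls[[row$gene]] <- tibble(
      gene = row$gene, allele1 = row$allele1, allele2 = row$allele2,
      cn1 = call$cn1, cn2 = call$cn2, p_value = call$p_value,
      n_sites = est$n_sites, n_bins = est$n_bins, verdict = call$verdict,
      lost_allele = if (!is.na(call$lost_allele)) {
        c(row$allele1, row$allele2)[call$lost_allele]
      } else {
        NA_character_
      }
    )
    if (nrow(est$site_cn) > 0) {
      site_rows[[row$gene]] <- est$site_cn %>% mutate(gene = row$gene)
    }
    bin_rows[[row$gene]] <- bins %>% mutate(gene = row$gene)
  }
  structure(
    list(
      calls = bind_rows(calls) %>% arrange(.data$gene),
      sites = bind_rows(site_rows),
      bins = bind_rows(bin_rows),
      log = log
    ),
    class = "hla_loh_call"
  )
}

#' @export
print.hla_loh_call <- function(x, ...) {
  cat("<hla_loh_call> ", nrow(x$calls), " genes; verdicts: ",
      paste(sprintf("%s=%s", x$calls$gene, x$calls$verdict), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy
#' @title Tidy methods for fitted objects
#' @description `tidy()` on an `hla_loh_call` returns the per-gene call
#'   table; `glance()` returns a one-row run summary.
#' @param x An `hla_loh_call` or `loh_placement`.
#' @param ... Unused.
#' @method tidy hla_loh_call
#' @export
tidy.hla_loh_call <- function(x, ...) x$calls

#' @rdname tidy
#' @method glance hla_loh_call
#' @export
glance.hla_loh_call <- function(x, ...) {
  tibble(
    n_genes = nrow(x$calls),
    n_loh = sum(x$calls$verdict == "loh"),
    n_imbalance = sum(x$calls$verdict == "allelic_imbalance"),
    n_homozygous = sum(x$calls$verdict == "homozygous"),
    m_factor = x$log$m_factor
  )
}

#' @rdname tidy
#' @method tidy loh_placement
#' @export
tidy.loh_placement <- function(x, ...) x$by_branch

#' @rdname tidy
#' @method glance loh_placement
#' @export
glance.loh_placement <- function(x, ...) {
  tibble(branch = x$branch, subtree_cn = x$b[["subtree"]],
         remainder_cn = x$b[["remainder"]], error = x$error,
         relative_error = x$relative_error, unplaced = x$unplaced)
}

#' Write pipeline reports to a directory
#'
#' Writes the per-gene call table, per-site evidence and a provenance log
#' with fixed column order; floating point to 4 decimals. Re-running on
#' the same call object reproduces byte-identical files.
#'
#' @param call An `hla_loh_call`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(call, out_dir) {
  stopifnot(inherits(call, "hla_loh_call"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) sprintf("%.4f", col) else col
    })
    df
  }
  gene_cols <- c("gene", "allele1", "allele2", "cn1", "cn2", "p_value",
                 "n_sites", "n_bins", "verdict", "lost_allele")
  paths <- list(
    genes = file.path(out_dir, "hla_loh_genes.tsv"),
    sites = file.path(out_dir, "hla_loh_sites.tsv"),
    log = file.path(out_dir, "hla_loh_log.json")
  )
  write.table(fmt(call$calls[, gene_cols]), paths$genes, sep = "\t",
              quote = FALSE, row.names = FALSE)
  site_df <- if (nrow(call$sites) > 0) {
    call$sites %>%
      select("gene", "pos1", "pos2", "tumor1", "tumor2", "germline1",
             "germline2", "baf", "logr", "cn1", "cn2")
  } else {
    tibble(gene = character(), pos1 = integer(), pos2 = integer(),
           tumor1 = integer(), tumor2 = integer(), germline1 = integer(),
           germline2 = integer(), baf = double(), logr = double(),
           cn1 = double(), cn2 = double())
  }
  write.table(fmt(site_df), paths$sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(call$log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
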