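# Seeded generators: homologous allele pairs with planted differences,
# tumor/germline read sets under the purity/ploidy/copy-number mixture
# model, site-level evidence, toy clone trees and segmentations. Every
# generator emits a machine-readable truth record.

#' Simulation configuration
#'
#' Defines one synthetic patient-gene scenario: an allele pair with
#' planted differences and a tumor contaminated with normal cells at
#' purity `rho`, carrying `cn` = (n1, n2) copies of the two alleles
#' against tumor ploidy `psi`.
#'
#' @param seed Integer seed; all randomness flows through it.
#' @param gene_length Allele length in bp (default 1000).
#' @param n_snps Planted substitutions between the homologs (default 25,
#'   a typical exon-2/3 difference count for distinct class I alleles).
#' @param indel_lengths Integer vector of planted deletion lengths in
#'   allele 2 (default none).
#' @param read_length Read length in bp (default 100).
#' @param depth Mean germline coverage (default 100, exome-like depth at
#'   the MHC).
#' @param rho Tumor purity (default 1).
#' @param psi Tumor ploidy (default 2).
#' @param cn Length-2 vector of true allele copy numbers (default c(1, 1)).
#' @param error_rate Per-base sequencing error rate in \[0, 0.05\]
#'   (default 0.005).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, gene_length = 1000, n_snps = 25,
                       indel_lengths = integer(0), read_length = 100,
                       depth = 100, rho = 1, psi = 2, cn = c(1, 1),
                       error_rate = 0.005) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  if (any(cn < 0)) abort("true copy numbers must be >= 0")
  if (error_rate < 0 || error_rate > 0.05) abort("error_rate must lie in [0, 0.05]")
  if (n_snps > gene_length) abort("more substitutions requested than positions")
  structure(
    list(seed = as.integer(seed), gene_length = as.integer(gene_length),
         n_snps = as.integer(n_snps), indel_lengths = as.integer(indel_lengths),
         read_length = as.integer(read_length), depth = depth,
         rho = rho, psi = psi, cn = cn, error_rate = error_rate),
    class = "sim_config"
  )
}

# Substitutions are planted away from the allele termini (5 bp margin) so
# the local homolog alignment always spans every planted site: a mismatch
# in the terminal bases cannot be part of an optimal local alignment.
.sample_snp_positions <- function(gene_length, n_snps, margin = 5L) {
  lo <- margin + 1L
  hi <- gene_length - margin
  if (hi - lo + 1L < n_snps) abort("more substitutions requested than positions")
  sample(seq.int(lo, hi), n_snps)
}

# Mixture-model expectations shared by the generators and tests.
.mixture_truth <- function(rho, psi, n1, n2) {
  d <- 2 * (1 - rho) + rho * (n1 + n2)
  list(
    baf = if (d > 0) (1 - rho + rho * n1) / d else NA_real_,
    ratio = d / (2 * (1 - rho) + rho * psi)
  )
}

.expected_verdict <- function(rho, n1, n2) {
  if (min(n1, n2) < 0.5 && n1 != n2) "loh"
  else if (n1 != n2) "allelic_imbalance"
  else "no_imbalance"
}

#' Generate a homologous allele pair with planted differences
#'
#' Allele 2 is allele 1 with `n_snps` substitutions at distinct random
#' positions (always to a different base) and optional planted deletions.
#' Deletions never overlap a substitution site.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_pair`: `allele1`, `allele2` (sequences),
#'   `truth` (planted site positions on each allele and bases, expected
#'   BAF/logR under the mixture model, expected verdict, a
#'   `homozygous_like` flag when no substitutions were planted).
#' @export
make_homolog_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  s1 <- sample(bases, cfg$gene_length, replace = TRUE)
  snp_pos <- sort(.sample_snp_positions(cfg$gene_length, cfg$n_snps))
  s2 <- s1
  for (p in snp_pos) s2[p] <- sample(setdiff(bases, s1[p]), 1)
  # plant deletions in allele 2, avoiding substitution sites
  del <- tibble(start = integer(), length = integer())
  occupied <- snp_pos
  for (len in cfg$indel_lengths) {
    repeat {
      st <- sample.int(cfg$gene_length - len, 1)
      span <- st:(st + len - 1)
      if (!any(span %in% occupied)) break
    }
    occupied <- c(occupied, span)
    del <- bind_rows(del, tibble(start = st, length = len))
  }
  keep <- rep(TRUE, cfg$gene_length)
  if (nrow(del) > 0) {
    for (i in seq_len(nrow(del))) {
      keep[del$start[i]:(del$start[i] + del$length[i] - 1)] <- FALSE
    }
  }
  # allele-2 coordinate of each surviving allele-1 position
  pos2_of <- cumsum(keep)
  mix <- .mixture_truth(cfg$rho, cfg$psi, cfg$cn[1], cfg$cn[2])
  truth <- list(
    config = unclass(cfg),
    sites = tibble(
      pos1 = snp_pos, pos2 = pos2_of[snp_pos],
      base1 = s1[snp_pos], base2 = s2[snp_pos]
    ),
    deletions = del,
    expected_baf = mix$baf,
    expected_logr = log2(mix$ratio),
    expected_verdict = .expected_verdict(cfg$rho, cfg$cn[1], cfg$cn[2]),
    homozygous_like = cfg$n_snps == 0 && length(cfg$indel_lengths) == 0
  )
  structure(
    list(allele1 = paste(s1, collapse = ""),
         allele2 = paste(s2[keep], collapse = ""),
         truth = truth),
    class = "sim_pair"
  )
}

.mutate_read <- function(seq_chars, error_rate) {
  if (error_rate <= 0) return(seq_chars)
  bases <- c("A", "C", "G", "T")
  hit <- which(runif(length(seq_chars)) < error_rate)
  for (i in hit) seq_chars[i] <- sample(setdiff(bases, seq_chars[i]), 1)
  seq_chars
}

#' Simulate a tumor or germline read set for an allele pair
#'
#' The germline draws read pairs from both alleles at equal expected
#' depth (`depth`/2 per homolog). The tumor draws from allele i in
#' proportion to `(1-rho) + rho * n_i`, with total depth scaled by
#' `(2(1-rho) + rho(n1+n2)) / (2(1-rho) + rho*psi)` relative to the
#' germline — the same mixture the copy-number equations invert. Per-base
#' errors are i.i.d. at the configured rate; read-pair start positions are
#' uniform. Reads also receive genome placements inside the class I MHC
#' interval so that extraction from a BAM can be exercised.
#'
#' @param pair A `sim_pair` from [make_homolog_pair()].
#' @param cfg The [sim_config()].
#' @param sample `"tumor"` or `"germline"`.
#' @return A tibble `read`, `mate`, `seq`, `qual`, `allele_origin`,
#'   `start` (position on the source allele), `gchrom`, `gpos` (genome
#'   placement).
#' @export
simulate_sample_reads <- function(pair, cfg, sample = c("tumor", "germline")) {
  stopifnot(inherits(pair, "sim_pair"), inherits(cfg, "sim_config"))
  sample <- match.arg(sample)
  set.seed(cfg$seed + if (sample == "tumor") 1L else 2L)
  rl <- cfg$read_length
  alleles <- c(pair$allele1, pair$allele2)
  lens <- nchar(alleles)
  cov <- if (sample == "germline") {
    c(cfg$depth / 2, cfg$depth / 2)
  } else {
    w <- (1 - cfg$rho) + cfg$rho * cfg$cn
    cfg$depth * w / (2 * (1 - cfg$rho) + cfg$rho * cfg$psi)
  }
  region <- hla_target_regions()[1, ]
  rows <- list()
  for (a in 1:2) {
    if (lens[a] < rl) next
    n_frags <- rpois(1, cov[a] * lens[a] / (2 * rl))
    if (n_frags == 0) next
    chars <- strsplit(alleles[a], "")[[1]]
    max_start <- lens[a] - rl + 1L
    s1 <- sample.int(max_start, n_frags, replace = TRUE)
    s2 <- pmin(s1 + rl + 50L, max_start)
    name <- sprintf("%s_a%d_f%04d", sample, a, seq_len(n_frags))
    gpos1 <- region$start + ((s1 + a * 7L) %% (region$end - region$start - 2L * rl))
    mk <- function(starts, mate, gpos) {
      tibble(
        read = name, mate = mate,
        seq = vapply(starts, function(s) {
          paste(.mutate_read(chars[s:(s + rl - 1L)], cfg$error_rate),
                collapse = "")
        }, ""),
        qual = strrep("I", rl),
        allele_origin = a, start = starts,
        gchrom = region$chrom, gpos = as.integer(gpos)
      )
    }
    rows <- c(rows, list(mk(s1, 1L, gpos1), mk(s2, 2L, gpos1 + rl + 50L)))
  }
  if (length(rows) == 0) {
    return(tibble(read = character(), mate = integer(), seq = character(),
                  qual = character(), allele_origin = integer(),
                  start = integer(), gchrom = character(), gpos = integer()))
  }
  bind_rows(rows) %>% arrange(.data$read, .data$mate)
}

#' Simulate site-level evidence directly under the mixture model
#'
#' A fast generator for the copy-number model: per-position coverage
#' tracks and per-site unique-read depths are drawn as Poisson counts with
#' the mixture-model means, bypassing read construction. The emulated
#' samples have equal library scale, so the multiplication factor is 1.
#'
#' @param cfg A [sim_config()].
#' @return A list: `sites` (tibble `pos1`, `pos2`, `tumor1`, `tumor2`,
#'   `germline1`, `germline2`), `coverage` (per-position tibble as
#'   [compute_coverage()] produces, both samples and homologs), `m` (1),
#'   and `truth`.
#' @export
simulate_site_evidence <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  snp_pos <- sort(.sample_snp_positions(cfg$gene_length, cfg$n_snps))
  set.seed(cfg$seed + 3L)
  L <- cfg$gene_length
  g_mean <- cfg$depth / 2
  w <- (1 - cfg$rho) + cfg$rho * cfg$cn
  t_mean <- cfg$depth * w / (2 * (1 - cfg$rho) + cfg$rho * cfg$psi)
  cov <- bind_rows(
    tibble(allele = "allele1", sample = "germline", pos = 1:L,
           depth = rpois(L, g_mean)),
    tibble(allele = "allele2", sample = "germline", pos = 1:L,
           depth = rpois(L, g_mean)),
    tibble(allele = "allele1", sample = "tumor", pos = 1:L,
           depth = rpois(L, t_mean[1])),
    tibble(allele = "allele2", sample = "tumor", pos = 1:L,
           depth = rpois(L, t_mean[2]))
  )
  k <- length(snp_pos)
  sites <- tibble(
    pos1 = snp_pos, pos2 = snp_pos,
    tumor1 = rpois(k, t_mean[1]), tumor2 = rpois(k, t_mean[2]),
    germline1 = rpois(k, g_mean), germline2 = rpois(k, g_mean)
  )
  mix <- .mixture_truth(cfg$rho, cfg$psi, cfg$cn[1], cfg$cn[2])
  list(
    sites = sites, coverage = cov, m = 1,
    truth = list(expected_baf = mix$baf, expected_logr = log2(mix$ratio),
                 expected_verdict = .expected_verdict(cfg$rho, cfg$cn[1],
                                                      cfg$cn[2]))
  )
}

#' Write a complete synthetic patient fixture to disk
#'
#' Emits everything the calling pipeline consumes: an allele FASTA (the
#' heterozygous focal gene plus homozygous filler genes so all three
#' class I genes are represented), tumor and germline FASTQ, sorted and
#' indexed BAM files with the reads placed inside the class I MHC
#' interval, an HLA calls file and a truth JSON. Re-running with the same
#' seed reproduces byte-identical FASTA/FASTQ/JSON.
#'
#' @param pair A `sim_pair`.
#' @param cfg The [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
emit_fixture <- function(pair, cfg, out_dir) {
  stopifnot(inherits(pair, "sim_pair"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  set.seed(cfg$seed + 4L)
  bases <- c("A", "C", "G", "T")
  filler_b <- paste(sample(bases, 400, replace = TRUE), collapse = "")
  filler_c <- paste(sample(bases, 400, replace = TRUE), collapse = "")
  alleles <- c(
    hla_a_01_01 = pair$allele1, hla_a_02_01 = pair$allele2,
    hla_b_07_02 = filler_b, hla_c_07_01 = filler_c
  )
  paths <- list(
    fasta = file.path(out_dir, "alleles.fasta"),
    hla_calls = file.path(out_dir, "hla_calls.tsv"),
    truth = file.path(out_dir, "truth.json"),
    tumor_fastq = file.path(out_dir, "tumor.fastq"),
    germline_fastq = file.path(out_dir, "germline.fastq"),
    tumor_bam = file.path(out_dir, "tumor.bam"),
    germline_bam = file.path(out_dir, "germline.bam")
  )
  writeLines(
    as.vector(rbind(paste0(">", names(alleles)), unname(alleles))),
    paths$fasta
  )
  writeLines(c("hla_a_01_01", "hla_a_02_01", "hla_b_07_02", "hla_b_07_02",
               "hla_c_07_01", "hla_c_07_01"), paths$hla_calls)
  jsonlite::write_json(pair$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (smp in c("tumor", "germline")) {
    reads <- simulate_sample_reads(pair, cfg, smp)
    fq <- as.vector(rbind(
      paste0("@", reads$read, "/", reads$mate), reads$seq, "+", reads$qual
    ))
    writeLines(fq, paths[[paste0(smp, "_fastq")]])
    .write_reads_bam(reads, paths[[paste0(smp, "_bam")]])
  }
  invisible(paths)
}

# Writes a minimal coordinate-sorted, indexed BAM placing the reads at
# their simulated genome coordinates on chr6.
.write_reads_bam <- function(reads, bam_path) {
  sam_path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr6\tLN:171115067")
  if (nrow(reads) > 0) {
    flag <- ifelse(reads$mate == 1L, 99L, 147L)
    mate_pos <- reads %>%
      group_by(.data$read) %>%
      mutate(mpos = rev(.data$gpos)) %>%
      ungroup() %>%
      pull(.data$mpos)
    body <- paste(reads$read, flag, "chr6", reads$gpos, 60L,
                  paste0(nchar(reads$seq), "M"), "=", mate_pos, 0L,
                  reads$seq, reads$qual, sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), sam_path)
  tmp_bam <- Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(tmp_bam, sub("\\.bam$", "", bam_path))
  Rsamtools::indexBam(sorted)
  unlink(c(sam_path, tmp_bam))
  invisible(sorted)
}

#' Simulate a random clone tree with nested regional CCFs
#'
#' Builds a rooted tree by attaching each new clone to a uniformly chosen
#' existing clone, then draws per-region CCFs respecting the nesting
#' constraint (children of a clone share at most its CCF; the trunk has
#' CCF 1 in every region).
#'
#' @param seed Integer seed.
#' @param n_clones Number of clones including the trunk (default 5).
#' @param n_regions Number of tumor regions (default 3).
#' @return A [clone_tree()].
#' @export
sim_clone_tree <- function(seed, n_clones = 5, n_regions = 3) {
  set.seed(seed)
  clones <- paste0("clone", seq_len(n_clones))
  parent <- c(NA_character_,
              if (n_clones > 1)
                clones[vapply(2:n_clones, function(i) sample.int(i - 1L, 1),
                              1L)])
  ccf <- matrix(0, n_clones, n_regions,
                dimnames = list(clones, paste0("R", seq_len(n_regions))))
  ccf[1, ] <- 1
  for (i in seq_len(n_clones)[-1]) {
    p <- match(parent[i], clones)
    sibs <- which(parent == parent[i]); sibs <- sibs[sibs < i]
    for (r in seq_len(n_regions)) {
      avail <- ccf[p, r] - sum(ccf[sibs[sibs != i], r])
      ccf[i, r] <- runif(1, 0, max(avail, 0))
    }
  }
  nodes <- dplyr::bind_cols(
    tibble(clone = clones, parent = parent),
    as_tibble(ccf)
  )
  clone_tree(nodes)
}

#' Simulate a regional lost-allele copy-number vector for a planted event
#'
#' Plants an LOH event on a chosen branch: inside the event subtree the
#' lost allele has copy number `subtree_cn` (typically 0), outside it
#' `remainder_cn` (typically 1); the observed regional copy number is the
#' CCF-weighted sum plus Gaussian noise.
#'
#' @param tree A [clone_tree()].
#' @param branch Clone at the top of the event subtree.
#' @param subtree_cn,remainder_cn True lost-allele copy numbers inside and
#'   outside the subtree (defaults 0 and 1).
#' @param noise_sd Gaussian noise on each region (default 0).
#' @param seed Optional seed.
#' @return Named numeric vector of regional copy numbers, with the truth
#'   attached as attributes `branch` and `b`.
#' @export
sim_loh_event <- function(tree, branch, subtree_cn = 0, remainder_cn = 1,
                          noise_sd = 0, seed = NULL) {
  stopifnot(inherits(tree, "clone_tree"), branch %in% tree$clones)
  if (!is.null(seed)) set.seed(seed)
  sub <- .descendants(tree, branch)
  f1 <- colSums(tree$ccf[sub, , drop = FALSE])
  rest <- setdiff(tree$clones, sub)
  f2 <- if (length(rest) > 0) colSums(tree$ccf[rest, , drop = FALSE]) else
    rep(0, length(tree$regions))
  cn <- subtree_cn * f1 + remainder_cn * f2 +
    if (noise_sd > 0) stats::rnorm(length(f1), 0, noise_sd) else 0
  cn <- pmax(cn, 0)
  names(cn) <- tree$regions
  attr(cn, "branch") <- branch
  attr(cn, "b") <- c(subtree = subtree_cn, remainder = remainder_cn)
  cn
}

#' Simulate a toy genome segmentation with known focal/arm-level truth
#'
#' For each autosomal arm, independently plants either no loss, a focal
#' minor-allele loss (10% of the arm) or an arm-level loss (80% of the
#' arm), with the stated probabilities; the remainder of the arm is
#' copy-neutral (minor CN 1).
#'
#' @param seed Integer seed.
#' @param arms Arm table (default [chrom_arms_hg19()]).
#' @param p_focal,p_arm Probabilities of planting a focal / arm-level loss
#'   per arm (defaults 0.15 and 0.05).
#' @return A list: `segments` tibble (`chrom`, `start`, `end`,
#'   `minor_cn`), `truth` tibble (`chrom`, `arm`, `planted` in
#'   no_loss/focal/arm_level).
#' @export
sim_segmentation <- function(seed, arms = chrom_arms_hg19(),
                             p_focal = 0.15, p_arm = 0.05) {
  set.seed(seed)
  segs <- list(); truth <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    alen <- a$end - a$start + 1
    u <- runif(1)
    planted <- if (u < p_arm) "arm_level" else
      if (u < p_arm + p_focal) "focal" else "no_loss"
    if (planted == "no_loss") {
      segs[[length(segs) + 1]] <- tibble(chrom = a$chrom, start = a$start,
                                         end = a$end, minor_cn = 1)
    } else {
      frac <- if (planted == "arm_level") 0.8 else 0.1
      loss_len <- round(alen * frac)
      loss_start <- a$start + floor(runif(1, 0, alen - loss_len))
      segs[[length(segs) + 1]] <- bind_rows(
        tibble(chrom = a$chrom, start = a$start, end = loss_start - 1,
               minor_cn = 1),
        tibble(chrom = a$chrom, start = loss_start,
               end = loss_start + loss_len - 1, minor_cn = 0),
        tibble(chrom = a$chrom, start = loss_start + loss_len, end = a$end,
               minor_cn = 1)
      ) %>% filter(.data$start <= .data$end)
    }
    truth[[length(truth) + 1]] <- tibble(chrom = a$chrom, arm = a$arm,
                                         planted = planted)
  }
  list(segments = bind_rows(segs), truth = bind_rows(truth))
}
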