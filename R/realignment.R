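# Candidate-read extraction from genome alignments, re-alignment to the
# patient's HLA allele references, post-alignment filtering and coverage.

#' Default MHC target regions (GRCh37 coordinates)
#'
#' The three class I intervals (HLA-A, HLA-B, HLA-C) whose overlapping
#' reads are extracted before re-alignment.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
hla_target_regions <- function() {
  tibble(
    chrom = c("chr6", "chr6", "chr6"),
    start = c(29909037L, 31321649L, 31236526L),
    end   = c(29913661L, 31324964L, 31239869L)
  )
}

#' Default chromosome 6 alternate haplotype contigs
#'
#' Reads mapped to the MHC alternate haplotype assemblies are also
#' candidate HLA reads.
#'
#' @return Character vector of contig names.
#' @export
hla_alt_contigs <- function() {
  c("chr6_cox_hap2", "chr6_dbb_hap3", "chr6_mann_hap4",
    "chr6_mcf_hap5", "chr6_qbl_hap6", "chr6_ssto_hap7")
}

.mate_index <- function(flag) {
  ifelse(bitwAnd(flag, 0x40L) > 0L, 1L,
         ifelse(bitwAnd(flag, 0x80L) > 0L, 2L, 1L))
}

#' Extract candidate HLA reads from a coordinate-sorted alignment file
#'
#' Pulls all reads overlapping the MHC target regions or mapped to any of
#' the listed alternate contigs, then removes reads whose mate was not
#' itself extracted (unpaired mates), so the output consists of complete
#' pairs ready for re-alignment.
#'
#' @param bam_path Path to an indexed BAM file (a `.bai` index must exist
#'   or be creatable).
#' @param regions Tibble of target regions (`chrom`, `start`, `end`),
#'   1-based inclusive; defaults to [hla_target_regions()].
#' @param contigs Character vector of contig names whose reads are taken
#'   wholesale; defaults to [hla_alt_contigs()].
#' @return A tibble of reads: `read` (name), `mate` (1/2), `seq`, `qual`.
#' @export
extract_candidate_reads <- function(bam_path,
                                    regions = hla_target_regions(),
                                    contigs = hla_alt_contigs()) {
  if (!file.exists(bam_path)) abort(paste0("alignment file not found: ", bam_path))
  if (!all(c("chrom", "start", "end") %in% names(regions)) ||
      any(regions$start > regions$end)) {
    abort("malformed region table: need chrom/start/end with start <= end")
  }
  bf <- Rsamtools::BamFile(bam_path)
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  reg <- regions %>% filter(.data$chrom %in% names(hdr))
  ctg <- intersect(contigs, names(hdr))
  if (length(ctg) > 0) {
    reg <- bind_rows(reg, tibble(chrom = ctg, start = 1L,
                                 end = unname(hdr[ctg])))
  }
  gr_regions <- GenomicRanges::GRanges(
    reg$chrom, IRanges::IRanges(reg$start, reg$end)
  )
  if (length(gr_regions) == 0) {
    return(tibble(read = character(), mate = integer(),
                  seq = character(), qual = character()))
  }
  param <- Rsamtools::ScanBamParam(
    which = gr_regions,
    what = c("qname", "flag", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  res <- Rsamtools::scanBam(bf, param = param)
  reads <- bind_rows(lapply(res, function(r) {
    tibble(read = r$qname, flag = r$flag,
           seq = as.character(r$seq), qual = as.character(r$qual))
  }))
  if (nrow(reads) == 0) {
    return(tibble(read = character(), mate = integer(),
                  seq = character(), qual = character()))
  }
  reads <- reads %>%
    mutate(mate = .mate_index(.data$flag),
           paired = bitwAnd(.data$flag, 0x1L) > 0L) %>%
    distinct(.data$read, .data$mate, .keep_all = TRUE)
  # unpaired mates removed: keep only names for which both mates survived
  complete <- reads %>%
    filter(.data$paired) %>%
    group_by(.data$read) %>%
    filter(dplyr::n_distinct(.data$mate) == 2) %>%
    ungroup()
  complete %>%
    arrange(.data$read, .data$mate) %>%
    select("read", "mate", "seq", "qual")
}

#' Re-align extracted reads to one patient HLA allele
#'
#' Each read is locally aligned to the allele sequence under the package's
#' affine-gap scoring. Alignments scoring below `min_score_frac` times the
#' read length are dropped (the read simply does not map to this allele; a
#' read may map to several alleles). The alignment is decomposed into event
#' counts where a contiguous gap counts as a single insertion or deletion
#' event.
#'
#' @param reads Tibble of reads (`read`, `mate`, `seq`).
#' @param allele_seq Allele nucleotide sequence.
#' @param allele Allele name recorded in the output.
#' @param min_score_frac Minimum alignment score as a fraction of read
#'   length (default 0.8).
#' @return A tibble of alignments: `read`, `mate`, `allele`, `start`,
#'   `end` (covered allele interval, 1-based), `subs`, `ins`, `del`
#'   (event counts), `score`.
#' @export
align_reads_to_allele <- function(reads, allele_seq, allele,
                                  min_score_frac = 0.8) {
  empty <- tibble(read = character(), mate = integer(), allele = character(),
                  start = integer(), end = integer(), subs = integer(),
                  ins = integer(), del = integer(), score = double())
  if (nrow(reads) == 0) return(empty)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = .aln_scoring$match, mismatch = .aln_scoring$mismatch
  )
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(toupper(reads$seq)),
    Biostrings::DNAString(toupper(allele_seq)),
    type = "local", substitutionMatrix = sm,
    gapOpening = .aln_scoring$gap_opening,
    gapExtension = .aln_scoring$gap_extension
  )
  ni <- Biostrings::nindel(pa)
  out <- tibble(
    read = reads$read, mate = reads$mate, allele = allele,
    start = IRanges::start(Biostrings::subject(pa)),
    end = IRanges::end(Biostrings::subject(pa)),
    subs = Biostrings::nmismatch(pa),
    ins = ni@insertion[, "Length"],
    del = ni@deletion[, "Length"],
    score = Biostrings::score(pa)
  )
  out %>% filter(.data$score >= min_score_frac * nchar(reads$seq))
}

#' Re-align reads to every allele of a registry
#'
#' Convenience wrapper binding [align_reads_to_allele()] across alleles.
#'
#' @param reads Tibble of reads.
#' @param alleles Tibble with columns `allele`, `sequence`.
#' @param min_score_frac Passed through.
#' @return A single alignment tibble across all alleles.
#' @export
align_reads_to_alleles <- function(reads, alleles, min_score_frac = 0.8) {
  bind_rows(purrr::map2(
    alleles$sequence, alleles$allele,
    function(s, a) align_reads_to_allele(reads, s, a, min_score_frac)
  ))
}

#' Best-allele assignment per read mate
#'
#' For each (read, mate), the allele with the highest re-alignment score.
#' Score ties between alleles leave the assignment ambiguous (`NA`): at a
#' discriminating site a read's base determines its allele, so ambiguous
#' reads carry no allele-specific evidence.
#'
#' @param alignments Alignment tibble across the gene's two alleles.
#' @return Tibble `read`, `mate`, `best_allele` (`NA` if tied).
#' @export
assign_best_allele <- function(alignments) {
  if (nrow(alignments) == 0) {
    return(tibble(read = character(), mate = integer(),
                  best_allele = character()))
  }
  alignments %>%
    group_by(.data$read, .data$mate) %>%
    summarise(
      best_allele = if (sum(.data$score == max(.data$score)) > 1) {
        NA_character_
      } else {
        .data$allele[which.max(.data$score)]
      },
      .groups = "drop"
    )
}

#' Apply the post-alignment read filters
#'
#' Two published filters: (a) reads carrying more than one event in total
#' (substitution, insertion or deletion, a contiguous gap being one event)
#' against the reference allele are discarded; (b) read pairs whose two
#' mates best-align to different homologs are discarded entirely. A mate
#' whose best allele is ambiguous (tie) is treated as same-allele and not
#' discarded.
#'
#' @param alignments Alignment tibble over the two homologs of one gene.
#' @return The filtered alignment tibble, with attribute `n_discarded`
#'   recording counts per filter.
#' @export
filter_alignments <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  n0 <- nrow(alignments)
  kept <- alignments %>%
    filter(.data$subs + .data$ins + .data$del <= 1)
  n_event <- n0 - nrow(kept)

  best <- assign_best_allele(kept) %>%
    tidyr::pivot_wider(names_from = "mate", values_from = "best_allele",
                       names_prefix = "m")
  if (!"m1" %in% names(best)) best$m1 <- NA_character_
  if (!"m2" %in% names(best)) best$m2 <- NA_character_
  discordant <- best %>%
    filter(!is.na(.data$m1), !is.na(.data$m2), .data$m1 != .data$m2) %>%
    pull(.data$read)
  out <- kept %>% filter(!(.data$read %in% discordant))
  attr(out, "n_discarded") <- c(
    event_filter = n_event,
    mate_allele_filter = nrow(kept) - nrow(out)
  )
  out
}

#' Per-position coverage of one allele by filtered alignments
#'
#' @param alignments Filtered alignment tibble (rows for one allele).
#' @param allele_length Length of the allele sequence.
#' @param allele,sample Labels carried into the track.
#' @return A tibble `allele`, `sample`, `pos`, `depth` of length
#'   `allele_length`.
#' @export
compute_coverage <- function(alignments, allele_length, allele, sample) {
  depth <- integer(allele_length)
  if (nrow(alignments) > 0) {
    # difference-array interval stabbing
    d <- integer(allele_length + 1L)
    s <- pmax(alignments$start, 1L)
    e <- pmin(alignments$end, allele_length)
    ok <- s <= e
    for (i in which(ok)) {
      d[s[i]] <- d[s[i]] + 1L
      d[e[i] + 1L] <- d[e[i] + 1L] - 1L
    }
    depth <- cumsum(d[seq_len(allele_length)])
  }
  tibble(allele = allele, sample = sample,
         pos = seq_len(allele_length), depth = as.integer(depth))
}

#' Unique-read coverage at mismatch sites
#'
#' Counts each read at most once across all mismatch sites it spans, to
#' avoid over-counting reads covering more than one discriminating
#' position: a read is credited to the leftmost site it covers.
#'
#' @param alignments Alignment tibble (rows for one allele, one sample);
#'   only `start`/`end` are used, one row per read.
#' @param site_pos Sorted vector of mismatch-site positions in this
#'   allele's coordinates.
#' @return A tibble `pos`, `unique_depth`, `plain_depth` with one row per
#'   site.
#' @export
site_coverage_unique <- function(alignments, site_pos) {
  site_pos <- sort(site_pos)
  k <- length(site_pos)
  uniq <- integer(k)
  plain <- integer(k)
  if (nrow(alignments) > 0 && k > 0) {
    for (i in seq_len(nrow(alignments))) {
      s <- alignments$start[i]; e <- alignments$end[i]
      covered <- which(site_pos >= s & site_pos <= e)
      if (length(covered) > 0) {
        uniq[covered[1]] <- uniq[covered[1]] + 1L
        plain[covered] <- plain[covered] + 1L
      }
    }
  }
  tibble(pos = site_pos, unique_depth = uniq, plain_depth = plain)
}
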