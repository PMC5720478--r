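# Programmatic fixtures: tiny SAM/BAM files and random sequences built at
# test time.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Writes a sorted, indexed BAM from a tibble of reads:
# columns read, flag, chrom, pos, seq (qual auto-filled).
# Returns the BAM path.
write_test_bam <- function(reads, contigs = c(chr6 = 171115067L)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- if (nrow(reads) > 0) {
    paste(reads$read, reads$flag, reads$chrom, reads$pos, 60L,
          paste0(nchar(reads$seq), "M"), "*", 0L, 0L,
          reads$seq, strrep("I", nchar(reads$seq)), sep = "\t")
  } else character()
  writeLines(c(hdr, body), sam)
  bam0 <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                           indexDestination = FALSE)
  dest <- tempfile()
  sorted <- Rsamtools::sortBam(bam0, dest)
  Rsamtools::indexBam(sorted)
  sorted
}

# A proper read pair inside (or outside) the target region.
pair_rows <- function(name, chrom, pos, len = 50, seed = NULL) {
  tibble::tibble(
    read = name, flag = c(99L, 147L), chrom = chrom,
    pos = c(pos, pos + len + 20L),
    seq = c(random_dna(len, seed), random_dna(len))
  )
}
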