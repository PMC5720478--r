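# Patient HLA genotypes, allele sequences, homolog alignment and the
# catalog of discriminating (mismatch) positions between the two homologs.

# Local alignment scoring used throughout the package: conservative gap
# costs keep dense SNP stretches as substitutions rather than gaps.
.aln_scoring <- list(match = 1, mismatch = -1, gap_opening = 5, gap_extension = 1)

.norm_allele_name <- function(x) {
  tolower(gsub("[^A-Za-z0-9]+", "_", trimws(x)))
}

#' Read HLA allele sequences from a FASTA file
#'
#' Loads the requested alleles from a (possibly multi-record, wrapped)
#' FASTA file keyed by allele identifiers such as `hla_a_01_01`. Record
#' identifiers and the `wanted` names are normalised to lowercase with
#' underscore delimiters before matching; sequences are stored uppercase.
#'
#' @param fasta_path Path to a FASTA file of HLA allele sequences.
#' @param wanted Character vector of allele names to load. `NULL` loads
#'   every record.
#' @return A tibble with columns `allele` and `sequence`, one row per
#'   requested allele, in the order of `wanted`.
#' @export
read_hla_alleles <- function(fasta_path, wanted = NULL) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- .norm_allele_name(sub("\\s.*$", "", names(seqs)))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA identifiers: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(seqs) <- ids
  if (is.null(wanted)) {
    wanted <- ids
  } else {
    wanted <- .norm_allele_name(wanted)
    missing <- setdiff(wanted, ids)
    if (length(missing) > 0) {
      abort(paste0("allele(s) not present in FASTA: ",
                   paste(missing, collapse = ", ")))
    }
  }
  tibble(
    allele = wanted,
    sequence = unname(toupper(as.character(seqs[wanted])))
  )
}

#' Build a patient HLA class I genotype table
#'
#' A patient carries two alleles at each of HLA-A, HLA-B and HLA-C. Genes
#' where the two alleles are identical are flagged homozygous; LOH is not
#' detectable there and downstream analysis skips them.
#'
#' @param alleles Character vector of six allele names (two per gene), e.g.
#'   `c("hla_a_01_01", "hla_a_02_01", "hla_b_07_02", ...)`. The gene is
#'   inferred from the name (`hla_a_*` etc.).
#' @return A tibble with columns `gene` (`"A"`, `"B"`, `"C"`), `allele1`,
#'   `allele2` and `homozygous`.
#' @export
hla_genotype <- function(alleles) {
  alleles <- .norm_allele_name(alleles)
  if (length(alleles) != 6) {
    abort("expected exactly six allele names (two per HLA-A/B/C gene)")
  }
  gene <- toupper(sub("^hla_([abc])_.*$", "\\1", alleles))
  if (!all(gene %in% c("A", "B", "C"))) {
    abort("allele names must start with hla_a_, hla_b_ or hla_c_")
  }
  tab <- split(alleles, gene)
  if (!all(lengths(tab) == 2)) {
    abort("expected two alleles per gene for each of HLA-A/B/C")
  }
  tibble(
    gene = c("A", "B", "C"),
    allele1 = unname(vapply(tab[c("A", "B", "C")], `[`, "", 1)),
    allele2 = unname(vapply(tab[c("A", "B", "C")], `[`, "", 2))
  ) %>%
    mutate(homozygous = .data$allele1 == .data$allele2)
}

#' Read a patient HLA genotype from a text file
#'
#' Accepts the common one-allele-per-line format (optionally with extra
#' whitespace-separated columns; the first token on each line is taken as
#' the allele name).
#'
#' @param path Path to the HLA calls file.
#' @return A genotype tibble, as [hla_genotype()].
#' @export
read_hla_genotype <- function(path) {
  if (!file.exists(path)) abort(paste0("HLA calls file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hla_genotype(vapply(strsplit(trimws(lines), "\\s+"), `[`, "", 1))
}

#' Locally align the two homologous alleles of one HLA gene
#'
#' Performs an optimal local pairwise alignment (affine gaps; match +1,
#' mismatch -1, gap open -5, gap extend -1) between a patient's two alleles
#' at one gene and records the column-by-column coordinate map between the
#' two allele coordinate systems.
#'
#' @param seq1,seq2 Nucleotide sequences of allele 1 and allele 2.
#' @param allele1,allele2 Optional allele names carried into the result.
#' @return An object of class `homolog_alignment`: a list with `allele1`,
#'   `allele2`, `score`, and `map`, a tibble with one row per alignment
#'   column (`column`, `pos1`, `pos2`, `base1`, `base2`; gap positions are
#'   `NA` with base `"-"`). Coordinates are 1-based on each allele.
#' @export
align_homologs <- function(seq1, seq2, allele1 = "allele1", allele2 = "allele2") {
  if (!nzchar(seq1) || !nzchar(seq2)) abort("allele sequences must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = .aln_scoring$match, mismatch = .aln_scoring$mismatch
  )
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq1)), Biostrings::DNAString(toupper(seq2)),
    type = "local", substitutionMatrix = sm,
    gapOpening = .aln_scoring$gap_opening,
    gapExtension = .aln_scoring$gap_extension
  )
  g1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  g2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pos1 <- ifelse(g1 == "-", NA_integer_,
                 Biostrings::pattern(pa)@range@start - 1L + cumsum(g1 != "-"))
  pos2 <- ifelse(g2 == "-", NA_integer_,
                 Biostrings::subject(pa)@range@start - 1L + cumsum(g2 != "-"))
  structure(
    list(
      allele1 = allele1, allele2 = allele2,
      score = Biostrings::score(pa),
      map = tibble(
        column = seq_along(g1),
        pos1 = as.integer(pos1), pos2 = as.integer(pos2),
        base1 = g1, base2 = g2
      )
    ),
    class = "homolog_alignment"
  )
}

#' @export
print.homolog_alignment <- function(x, ...) {
  n_mm <- nrow(find_mismatch_sites(x))
  cat("<homolog_alignment> ", x$allele1, " vs ", x$allele2,
      ": score ", x$score, ", ", nrow(x$map), " columns, ",
      n_mm, " mismatch sites\n", sep = "")
  invisible(x)
}

#' Extract the mismatch (discriminating) positions between two homologs
#'
#' Substitution columns of a homolog alignment are the positions at which a
#' sequencing read's base identifies which allele it came from. Gap columns
#' are not mismatch sites.
#'
#' @param aln A `homolog_alignment` from [align_homologs()].
#' @return A tibble with one row per substitution column, sorted by
#'   allele-1 position: `pos1`, `pos2`, `base1`, `base2`.
#' @export
find_mismatch_sites <- function(aln) {
  stopifnot(inherits(aln, "homolog_alignment"))
  aln$map %>%
    filter(!is.na(.data$pos1), !is.na(.data$pos2),
           .data$base1 != .data$base2) %>%
    arrange(.data$pos1) %>%
    select("pos1", "pos2", "base1", "base2")
}
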