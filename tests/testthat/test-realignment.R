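test_that("extraction returns reads overlapping the MHC targets, paired", {
  region <- hla_target_regions()[1, ]
  inside <- dplyr::bind_rows(lapply(1:10, function(i) {
    pair_rows(sprintf("in%02d", i), "chr6", region$start + 10L * i)
  }))
  outside <- dplyr::bind_rows(lapply(1:5, function(i) {
    pair_rows(sprintf("out%02d", i), "chr6", 5000L + 200L * i)
  }))
  bam <- write_test_bam(dplyr::bind_rows(inside, outside))
  got <- extract_candidate_reads(bam)
  expect_equal(nrow(got), 20)
  expect_setequal(unique(got$read), sprintf("in%02d", 1:10))
  expect_equal(as.integer(table(got$mate)), c(10L, 10L))
})

test_that("a read whose mate was not extracted is removed", {
  region <- hla_target_regions()[1, ]
  full <- pair_rows("ok", "chr6", region$start + 100L)
  widow <- pair_rows("widow", "chr6", region$start + 300L)[1, ]  # mate absent
  bam <- write_test_bam(dplyr::bind_rows(full, widow))
  got <- extract_candidate_reads(bam)
  expect_setequal(unique(got$read), "ok")
  expect_equal(nrow(got), 2)
})

test_that("empty region overlap yields an empty tibble, not an error", {
  bam <- write_test_bam(pair_rows("far", "chr6", 1000L))
  got <- extract_candidate_reads(bam)
  expect_equal(nrow(got), 0)
})

test_that("reads on alternate haplotype contigs are extracted", {
  ctg <- "chr6_cox_hap2"
  bam <- write_test_bam(pair_rows("alt", ctg, 500L),
                        contigs = c(chr6 = 171115067L,
                                    setNames(4795371L, ctg)))
  got <- extract_candidate_reads(bam)
  expect_equal(nrow(got), 2)
})

test_that("re-alignment recovers offsets and event decompositions", {
  allele <- random_dna(400, seed = 5)
  exact <- substr(allele, 101, 150)
  sub1 <- exact
  substr(sub1, 20, 20) <- if (substr(sub1, 20, 20) == "A") "C" else "A"
  del3 <- paste0(substr(allele, 101, 120), substr(allele, 124, 153))
  reads <- tibble::tibble(
    read = c("exact", "sub1", "del3"), mate = 1L,
    seq = c(exact, sub1, del3)
  )
  al <- align_reads_to_allele(reads, allele, "a1")
  expect_equal(nrow(al), 3)
  ex <- al[al$read == "exact", ]
  expect_equal(ex$start, 101L)
  expect_equal(ex$subs + ex$ins + ex$del, 0L)
  s1 <- al[al$read == "sub1", ]
  expect_equal(unname(unlist(s1[, c("subs", "ins", "del")])), c(1L, 0L, 0L))
  d3 <- al[al$read == "del3", ]
  # one deletion EVENT, not three
  expect_equal(unname(unlist(d3[, c("subs", "ins", "del")])), c(0L, 0L, 1L))
  # score agrees with the DP oracle
  expect_equal(d3$score, oracle_local_align_score(del3, allele))
})

test_that("unalignable reads are absent from the output", {
  allele <- random_dna(200, seed = 8)
  reads <- tibble::tibble(read = "junk", mate = 1L,
                          seq = random_dna(60, seed = 1234))
  expect_equal(nrow(align_reads_to_allele(reads, allele, "a1")), 0)
})

test_that("the more-than-one-event filter is exact at the boundary", {
  alns <- tibble::tibble(
    read = c("r1", "r2", "r3", "r4"), mate = 1L, allele = "a1",
    start = 1L, end = 50L,
    subs = c(2L, 1L, 0L, 1L), ins = c(0L, 0L, 0L, 1L),
    del = c(0L, 0L, 1L, 0L), score = 45
  )
  kept <- filter_alignments(alns)
  expect_setequal(kept$read, c("r2", "r3"))  # total events <= 1 kept
  expect_equal(unname(attr(kept, "n_discarded")[["event_filter"]]), 2L)
})

test_that("pairs whose mates best-align to different homologs are discarded", {
  alns <- tibble::tibble(
    read = rep(c("split", "same"), each = 2),
    mate = c(1L, 2L, 1L, 2L),
    allele = c("a1", "a2", "a1", "a1"),
    start = 1L, end = 50L, subs = 0L, ins = 0L, del = 0L,
    score = 50
  )
  kept <- filter_alignments(alns)
  expect_setequal(kept$read, "same")
  # a tie between alleles is treated as same-allele: no discard
  tie <- tibble::tibble(
    read = "tied", mate = c(1L, 1L, 2L),
    allele = c("a1", "a2", "a2"),
    start = 1L, end = 50L, subs = 0L, ins = 0L, del = 0L,
    score = c(50, 50, 50)
  )
  expect_equal(nrow(filter_alignments(tie)), 3)
})

test_that("coverage equals the brute-force interval-stab count", {
  set.seed(21)
  n <- 80
  starts <- sample.int(151, n, replace = TRUE)
  ends <- pmin(starts + 49L, 200L)
  alns <- tibble::tibble(read = sprintf("r%03d", 1:n), mate = 1L,
                         allele = "a1", start = starts, end = ends,
                         subs = 0L, ins = 0L, del = 0L, score = 50)
  cov <- compute_coverage(alns, 200L, "a1", "tumor")
  expect_equal(cov$depth, oracle_interval_coverage(starts, ends, 200L))
  # no alignments -> all-zero track
  cov0 <- compute_coverage(alns[0, ], 200L, "a1", "tumor")
  expect_true(all(cov0$depth == 0))
  # identical full-length reads -> constant depth
  full <- tibble::tibble(read = sprintf("f%02d", 1:10), mate = 1L,
                         allele = "a1", start = 1L, end = 200L,
                         subs = 0L, ins = 0L, del = 0L, score = 200)
  expect_true(all(compute_coverage(full, 200L, "a1", "t")$depth == 10L))
})

test_that("unique-site counting credits each read to one site only", {
  sites <- c(100L, 105L, 200L)
  spanner <- tibble::tibble(read = "s", mate = 1L, allele = "a1",
                            start = 95L, end = 140L,
                            subs = 0L, ins = 0L, del = 0L, score = 46)
  u <- site_coverage_unique(spanner, sites)
  expect_equal(sum(u$unique_depth), 1L)       # one read, one credit
  expect_equal(u$unique_depth[u$pos == 100L], 1L)  # leftmost covered site
  expect_equal(u$plain_depth[u$pos %in% c(100L, 105L)], c(1L, 1L))

  # reads each spanning exactly one site: unique == plain
  singles <- tibble::tibble(read = c("a", "b"), mate = 1L, allele = "a1",
                            start = c(98L, 190L), end = c(103L, 210L),
                            subs = 0L, ins = 0L, del = 0L, score = 6)
  u2 <- site_coverage_unique(singles, sites)
  expect_equal(u2$unique_depth, u2$plain_depth)

  # randomized: total unique credit never exceeds the number of reads,
  # and unique <= plain per site
  set.seed(31)
  rnd <- tibble::tibble(read = sprintf("r%02d", 1:40), mate = 1L,
                        allele = "a1",
                        start = sample.int(250, 40, replace = TRUE)) |>
    dplyr::mutate(end = start + 49L, subs = 0L, ins = 0L, del = 0L,
                  score = 50)
  u3 <- site_coverage_unique(rnd, sites)
  expect_true(sum(u3$unique_depth) <= 40L)
  expect_true(all(u3$unique_depth <= u3$plain_depth))
})

test_that("zero-error simulated reads pass the filters onto their allele", {
  cfg <- sim_config(seed = 17, gene_length = 400, n_snps = 15, depth = 20,
                    error_rate = 0)
  pair <- make_homolog_pair(cfg)
  reads <- simulate_sample_reads(pair, cfg, "germline")
  alleles <- tibble::tibble(allele = c("a1", "a2"),
                            sequence = c(pair$allele1, pair$allele2))
  alns <- align_reads_to_alleles(reads, alleles)
  kept <- filter_alignments(alns)
  # every read passes the <=1-event filter on its own allele
  own <- kept |>
    dplyr::inner_join(
      dplyr::mutate(reads, allele = c("a1", "a2")[allele_origin]),
      by = c("read", "mate", "allele")
    )
  expect_equal(nrow(dplyr::distinct(own, read, mate)),
               nrow(reads))
  expect_true(all(own$subs + own$ins + own$del == 0))
  # and best-allele assignment matches the source allele where unambiguous
  best <- assign_best_allele(kept) |>
    dplyr::inner_join(
      dplyr::mutate(reads, origin = c("a1", "a2")[allele_origin]),
      by = c("read", "mate")
    ) |>
    dplyr::filter(!is.na(best_allele))
  expect_true(all(best$best_allele == best$origin))
})
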