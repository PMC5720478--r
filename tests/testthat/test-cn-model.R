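make_cov <- function(t1, t2, g1, g2, len = 300L) {
  dplyr::bind_rows(
    tibble::tibble(allele = "allele1", sample = "tumor", pos = 1:len, depth = t1),
    tibble::tibble(allele = "allele2", sample = "tumor", pos = 1:len, depth = t2),
    tibble::tibble(allele = "allele1", sample = "germline", pos = 1:len, depth = g1),
    tibble::tibble(allele = "allele2", sample = "germline", pos = 1:len, depth = g2)
  )
}

test_that("binned logR follows M x tumor/germline", {
  # constant depths: tumor 25+25, germline 50+50 per position; M = 2
  bins <- compute_logr_bins(make_cov(25L, 25L, 50L, 50L), m_factor = 2)
  expect_equal(unique(bins$logr), 0)
  expect_true(all(!bins$excluded))
  expect_equal(bins$start, c(1L, 151L))
  # halved tumor -> logR -1
  bins2 <- compute_logr_bins(make_cov(12L, 13L, 50L, 50L), m_factor = 2)
  expect_equal(unique(bins2$logr), log2(2 * 25 / 100))
  # germline below the floor: excluded
  bins3 <- compute_logr_bins(make_cov(25L, 25L, 4L, 4L), m_factor = 2)
  expect_true(all(bins3$excluded))
  expect_true(isTRUE(attr(bins3, "insufficient_coverage")))
})

test_that("logR stays near zero for a balanced diploid pure tumor", {
  cfg <- sim_config(seed = 101, gene_length = 1500, n_snps = 25,
                    depth = 100, rho = 1, psi = 2, cn = c(1, 1))
  ev <- simulate_site_evidence(cfg)
  bins <- compute_logr_bins(ev$coverage, ev$m)
  ok <- bins[!bins$excluded, ]
  # Poisson sampling: bin sums ~ Poisson(15000); sd of logR ~ 0.017
  expect_true(all(abs(ok$logr) < 0.2))
})

test_that("BAF is allele-1 depth over combined depth", {
  sites <- tibble::tibble(pos1 = 1:3, pos2 = 1:3,
                          tumor1 = c(30L, 10L, 0L),
                          tumor2 = c(10L, 10L, 25L))
  expect_equal(compute_baf(sites)$baf, c(0.75, 0.5, 0))
  # zero combined depth omitted
  z <- tibble::tibble(pos1 = 1L, pos2 = 1L, tumor1 = 0L, tumor2 = 0L)
  expect_equal(nrow(compute_baf(z)), 0)
})

test_that("copy-number equations invert the forward mixture exactly", {
  grid <- expand.grid(n1 = 0:3, n2 = 0:3, rho = seq(0.2, 1, by = 0.1),
                      psi = c(1.5, 2, 3))
  # a pure tumor with zero copies of both alleles yields no DNA at the
  # locus: the forward BAF is undefined there, so the point is skipped
  grid <- grid[2 * (1 - grid$rho) + grid$rho * (grid$n1 + grid$n2) > 0, ]
  fw <- with(grid, {
    d <- 2 * (1 - rho) + rho * (n1 + n2)
    list(baf = (1 - rho + rho * n1) / d,
         logr = log2(d / (2 * (1 - rho) + rho * psi)))
  })
  for (i in seq_len(nrow(grid))) {
    cn <- allele_specific_cn(fw$baf[i], fw$logr[i],
                             purity_ploidy(grid$rho[i], grid$psi[i]))
    expect_true(abs(cn$cn1 - grid$n1[i]) < 1e-9 &&
                  abs(cn$cn2 - grid$n2[i]) < 1e-9)
  }
})

test_that("trivial and forward-oracle copy-number examples hold", {
  expect_equal(unlist(allele_specific_cn(0.5, 0, purity_ploidy(1, 2))),
               c(cn1 = 1, cn2 = 1))
  expect_equal(unlist(allele_specific_cn(0.25, 0, purity_ploidy(0.5, 2))),
               c(cn1 = 0, cn2 = 2))
  or <- oracle_forward_mixture(0.5, 2, 1, 2)
  expect_equal(or$logr, log2(1.25))
  expect_equal(unlist(allele_specific_cn(or$baf, or$logr, purity_ploidy(0.5, 2))),
               c(cn1 = 1, cn2 = 2), tolerance = 1e-12)
})

test_that("cn1 + cn2 equals the total-CN closed form independently of BAF", {
  set.seed(5)
  for (i in 1:50) {
    rho <- runif(1, 0.1, 1); psi <- runif(1, 1, 4); lr <- runif(1, -2, 2)
    pp <- purity_ploidy(rho, psi)
    total <- (2 * (rho - 1) + 2^lr * (2 * (1 - rho) + rho * psi)) / rho
    bafs <- runif(5)
    cn <- allele_specific_cn(bafs, lr, pp)
    expect_equal(cn$cn1 + cn$cn2, rep(total, 5), tolerance = 1e-9)
  }
})

test_that("gene-level estimate is the median over per-bin medians", {
  bins <- tibble::tibble(bin = 1:3, start = c(1L, 151L, 301L),
                         end = c(150L, 300L, 450L),
                         tumor_sum = 1, germline_sum = 1000, m = 1,
                         logr = 0, excluded = FALSE)
  pp <- purity_ploidy(1, 2)
  # constant sites -> (1, 1)
  sites <- tibble::tibble(pos1 = seq(10, 440, by = 50),
                          pos2 = seq(10, 440, by = 50),
                          tumor1 = 20L, tumor2 = 20L) |> compute_baf()
  est <- estimate_gene_cn(sites, bins, pp)
  expect_equal(c(est$cn1, est$cn2), c(1, 1))
  expect_equal(est$n_bins, 3L)
  # per-bin medians {0.1, 0.2, 0.9} -> gene 0.2 (bafs chosen per bin)
  baf_for_cn1 <- function(cn1) cn1 / 2  # rho=1, psi=2, logR=0
  sites2 <- tibble::tibble(
    pos1 = c(10L, 160L, 310L), pos2 = c(10L, 160L, 310L),
    tumor1 = 1L, tumor2 = 1L
  ) |>
    compute_baf() |>
    dplyr::mutate(baf = baf_for_cn1(c(0.1, 0.2, 0.9)))
  est2 <- estimate_gene_cn(sites2, bins, pp, min_sites = 3)
  expect_equal(est2$cn1, 0.2)
  # sites outside covered bins -> indeterminate
  far <- dplyr::mutate(sites2, pos1 = pos1 + 10000L)
  expect_true(estimate_gene_cn(far, bins, pp, min_sites = 3)$indeterminate)
})

test_that("allelic-imbalance test handles degenerate and null inputs", {
  flat <- tibble::tibble(tumor1 = rep(20L, 8), tumor2 = rep(20L, 8),
                         germline1 = rep(20L, 8), germline2 = rep(20L, 8))
  expect_equal(test_allelic_imbalance(flat), 1)
  # fewer than the minimum paired sites -> indeterminate NA, not p = 1
  expect_true(is.na(test_allelic_imbalance(flat[1:3, ])))
  # constant non-zero shift: sentinel near zero with a warning
  shift <- dplyr::mutate(flat, tumor1 = 40L)
  expect_warning(p <- test_allelic_imbalance(shift), "zero-variance")
  expect_lt(p, 1e-10)
})

test_that("imbalance test has power against a true loss state", {
  cfg <- sim_config(seed = 7, gene_length = 1000, n_snps = 25, depth = 100,
                    rho = 0.6, psi = 2, cn = c(0, 2))
  ev <- simulate_site_evidence(cfg)
  expect_lt(test_allelic_imbalance(ev$sites), 0.01)
})

test_that("swapping homolog labels preserves the imbalance p-value", {
  cfg <- sim_config(seed = 13, gene_length = 800, n_snps = 20, depth = 80,
                    rho = 0.5, psi = 2, cn = c(1, 2))
  s <- simulate_site_evidence(cfg)$sites
  swapped <- dplyr::rename(s, tumor1 = tumor2, tumor2 = tumor1,
                           germline1 = germline2, germline2 = germline1)
  expect_equal(test_allelic_imbalance(s), test_allelic_imbalance(swapped))
})

test_that("LOH verdicts follow the copy-number and p-value rules", {
  mk <- function(cn1, cn2) {
    structure(list(cn1 = cn1, cn2 = cn2, indeterminate = FALSE),
              class = "allele_cn_estimate")
  }
  v1 <- classify_loh(mk(0.1, 1.8), 1e-6)
  expect_equal(v1$verdict, "loh")
  expect_equal(v1$lost_allele, 1L)
  expect_equal(classify_loh(mk(0.7, 1.5), 0.001)$verdict, "allelic_imbalance")
  expect_equal(classify_loh(mk(0.4, 1.6), 0.05)$verdict, "no_imbalance")
  expect_equal(classify_loh(mk(0.4, 1.6), NA_real_)$verdict, "indeterminate")
})

test_that("normalized allelic ratio reproduces the worked examples", {
  expect_equal(normalized_allelic_ratio(200, 100, 100, 100), 2)
  expect_equal(normalized_allelic_ratio(100, 100, 100, 100), 1)
  expect_equal(normalized_allelic_ratio(50, 100, 100, 100), 0.5)
  expect_error(normalized_allelic_ratio(50, 0, 100, 100), "denominator")
})
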