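# site-inclusion rules: coverage/MAC, high-coverage exclusion,
# placement/strand, interval masks, and their set-algebra properties

# a biallelic object with prescribed major/minor count matrices
bi_from_counts <- function(maj, minr, chrom = "2L", pos = NULL) {
  n <- nrow(maj)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  structure(list(chrom = rep(chrom, n), pos = pos, ref = rep("A", n),
                 major = rep("A", n), minor = rep("C", n),
                 maj = maj, minr = minr,
                 other = matrix(0L, n, ncol(maj)),
                 sample_names = paste0("s", seq_len(ncol(maj)))),
            class = "biallelic")
}

meta_row <- function(pos, sample, allele, fwd, rev, med, chrom = "2L") {
  data.frame(chrom = chrom, pos = pos, sample = sample, allele = allele,
             fwd = fwd, rev = rev, mean_end_dist = med,
             stringsAsFactors = FALSE)
}

test_that("coverage and minor-allele-count bounds are inclusive as stated", {
  pops <- c("p1", "p1", "p2", "p2")
  # site 1: one sample coverage 14; site 2: MACs {8, 9}; site 3: MACs {7, 20}
  maj <- rbind(c(10, 20, 20, 20), c(22, 20, 20, 21), c(23, 20, 10, 10))
  minr <- rbind(c(4, 5, 5, 5), c(4, 4, 4, 5), c(3, 4, 10, 10))
  b <- bi_from_counts(maj, minr)
  cov <- maj + minr
  pass <- coverage_mac_filter(b, cov, pops, filter_config())
  expect_equal(pass, c(FALSE, TRUE, FALSE))
  # attribution via the cascade
  rep_ <- suppressWarnings(apply_filters(b, cov, pops))  # < 50 sites
  expect_equal(rep_$first_fail, c("min_coverage", NA, "min_mac"))
})

test_that("high-coverage exclusion matches a sort-and-threshold oracle", {
  set.seed(21)
  cov <- cbind(sample(1:100), sample(seq(40, 535, 5)))
  keep <- high_coverage_filter(cov, filter_config())
  # oracle: per sample, cutoff = 98th percentile by inverse ECDF; a site
  # fails if strictly above any cutoff
  oracle_keep <- rep(TRUE, nrow(cov))
  for (j in 1:2) {
    cut <- sort(cov[, j])[ceiling(0.98 * 100)]
    oracle_keep <- oracle_keep & cov[, j] <= cut
  }
  expect_equal(keep, oracle_keep)
  # one sample with coverages 1..100: the two sites above the 98th
  # percentile (99 and 100) are removed
  keep1 <- high_coverage_filter(cbind(1:100), filter_config())
  expect_equal(which(!keep1), c(99L, 100L))

  expect_true(all(high_coverage_filter(matrix(60, 100, 2))))
  expect_true(all(high_coverage_filter(cov,
    filter_config(high_coverage_quantile = 1))))
  expect_warning(hk <- high_coverage_filter(matrix(60, 10, 1)), "fewer than 50")
  expect_true(all(hk))
})

test_that("end-distance rule is strict and the strand rule uses min ratio", {
  b <- bi_from_counts(rbind(c(50, 50)), rbind(c(5, 5)), pos = 100L)
  # mean end distance exactly 8 must fail
  m <- rbind(meta_row(100L, "s1", "A", 25, 25, 8),
             meta_row(100L, "s1", "C", 3, 2, 8),
             meta_row(100L, "s2", "A", 25, 25, 8),
             meta_row(100L, "s2", "C", 2, 3, 8))
  expect_false(placement_strand_filter(b, m))
  # distance above 8 with balanced minor strands passes (ratio 1 > 0.1)
  m$mean_end_dist <- 20
  expect_true(placement_strand_filter(b, m))
  # missing metadata leaves the site untestable, not passed
  expect_true(is.na(placement_strand_filter(b, m[m$pos != 100L, ])))
})

test_that("one-sided minor strands trigger the Fisher arbiter, matching enumeration", {
  cfg <- filter_config()
  # minor fwd = 0, rev = 30 against major 50/50: ratio 0 <= 0.1, so the
  # Fisher p on {major, minor} x {fwd, rev} decides
  b <- bi_from_counts(rbind(c(50, 50)), rbind(c(15, 15)), pos = 100L)
  m <- rbind(meta_row(100L, "s1", "A", 25, 25, 20),
             meta_row(100L, "s1", "C", 0, 15, 20),
             meta_row(100L, "s2", "A", 25, 25, 20),
             meta_row(100L, "s2", "C", 0, 15, 20))
  p_oracle <- oracle_fisher_p(rbind(c(50, 50), c(0, 30)))
  expect_equal(placement_strand_filter(b, m, cfg),
               p_oracle > cfg$strand_fisher_p_threshold)
  expect_false(placement_strand_filter(b, m, cfg))  # p ~ 2e-9 here
  # a threshold below the exact p flips the decision
  cfg2 <- filter_config(strand_fisher_p_threshold = p_oracle / 2)
  expect_true(placement_strand_filter(b, m, cfg2))
})

test_that("Fisher decisions agree with hypergeometric enumeration on small tables", {
  set.seed(31)
  cfg <- filter_config()
  for (i in 1:40) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab[2, ]) == 0 || sum(tab[1, ]) == 0) next
    b <- bi_from_counts(rbind(c(30, 30)), rbind(c(10, 10)), pos = 100L)
    m <- rbind(meta_row(100L, "s1", "A", tab[1, 1], tab[1, 2], 20),
               meta_row(100L, "s1", "C", tab[2, 1], tab[2, 2], 20))
    ratio <- min(tab[2, 1] / tab[2, 2], tab[2, 2] / tab[2, 1])
    expected <- if (!is.nan(ratio) && ratio > cfg$strand_ratio_threshold) TRUE
                else oracle_fisher_p(tab) > cfg$strand_fisher_p_threshold
    expect_equal(placement_strand_filter(b, m, cfg), expected)
  }
})

test_that("the literal 'max' strand aggregator never fails a nonzero table", {
  cfg <- filter_config(strand_ratio_aggregator = "max")
  b <- bi_from_counts(rbind(c(50, 50)), rbind(c(15, 15)), pos = 100L)
  m <- rbind(meta_row(100L, "s1", "A", 25, 25, 20),
             meta_row(100L, "s1", "C", 0, 15, 20),
             meta_row(100L, "s2", "A", 25, 25, 20),
             meta_row(100L, "s2", "C", 0, 15, 20))
  expect_true(placement_strand_filter(b, m, cfg))
})

test_that("indel masks cover the footprint plus radius, inclusive", {
  pos <- 990:1010
  keep <- mask_intervals(rep("2L", length(pos)), pos,
                         indels = data.frame(chrom = "2L", pos = 1000L,
                                             length = 1L))
  expect_equal(pos[!keep], 995:1006)
  expect_true(keep[pos == 994])
  expect_true(keep[pos == 1007])
  # empty interval sets are the identity
  expect_true(all(mask_intervals(rep("2L", 5), 1:5)))
  # repeat intervals remove contained sites only on the right chromosome
  keep <- mask_intervals(c("2L", "2L", "3R"), c(100L, 200L, 150L),
                         repeats = data.frame(chrom = "2L", start = 150L,
                                              end = 250L))
  expect_equal(keep, c(TRUE, FALSE, TRUE))
})

test_that("raising thresholds never enlarges the surviving set", {
  set.seed(41)
  fx <- generate_filter_fixture()
  base_cfg <- filter_config()
  b <- call_biallelic(fx$sync)
  cov <- sync_coverage(fx$sync)
  base <- apply_filters(b, cov, fx$design$population, fx$meta,
                        fx$indels, fx$repeats, base_cfg)
  sweeps <- list(filter_config(min_coverage_per_sample = 30),
                 filter_config(min_minor_count_per_population = 40),
                 filter_config(high_coverage_quantile = 0.90),
                 filter_config(min_mean_end_distance = 26),
                 filter_config(indel_mask_radius = 5000L))
  for (cfg in sweeps) {
    r <- apply_filters(b, cov, fx$design$population, fx$meta,
                       fx$indels, fx$repeats, cfg)
    expect_true(all(r$surviving %in% base$surviving))
  }
})

test_that("the pass set equals the intersection of the individual rules", {
  set.seed(42)
  fx <- generate_filter_fixture(n_sites = 150)
  cfg <- filter_config()
  b <- call_biallelic(fx$sync)
  cov <- sync_coverage(fx$sync)
  cascade <- apply_filters(b, cov, fx$design$population, fx$meta,
                           fx$indels, fx$repeats, cfg)
  r1 <- coverage_mac_filter(b, cov, fx$design$population, cfg)
  r2 <- high_coverage_filter(cov, cfg)
  r3 <- placement_strand_filter(b, fx$meta, cfg)
  r4 <- mask_intervals(b$chrom, b$pos, fx$indels, fx$repeats, cfg)
  expect_equal(cascade$pass, r1 & r2 & (!is.na(r3) & r3) & r4)
  expect_equal(sum(cascade$tally), sum(!cascade$pass))
})
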