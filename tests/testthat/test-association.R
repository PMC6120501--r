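# CMH test, odds ratios and confidence intervals, downsampling, strata
# assembly and empirical-null FDR

random_tables <- function(n, max_k = 5, max_cell = 200) {
  lapply(seq_len(n), function(i) {
    K <- sample(1:max_k, 1)
    lapply(seq_len(K), function(k) {
      matrix(sample(0:max_cell, 4, replace = TRUE), 2)
    })
  })
}

test_that("perfectly independent strata give statistic 0 and odds ratio 1", {
  strata <- list(matrix(10, 2, 2), matrix(10, 2, 2))
  r <- cmh_test(strata, correct = FALSE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$or_mh, 1)
  expect_equal(r$log_or, 0)
})

test_that("swapping allele columns inverts the odds ratio and keeps p", {
  set.seed(51)
  for (tabs in random_tables(15)) {
    ok <- tryCatch({cmh_test(tabs); TRUE}, error = function(e) FALSE)
    if (!ok) next
    r1 <- cmh_test(tabs)
    r2 <- cmh_test(lapply(tabs, function(m) m[, 2:1]))
    expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
    if (is.finite(r1$or_mh) && r1$or_mh > 0) {
      expect_equal(r2$or_mh, 1 / r1$or_mh, tolerance = 1e-12)
      expect_equal(r2$log_or, -r1$log_or, tolerance = 1e-12)
    }
  }
})

test_that("statistic, p, OR and RBG CI match the formula oracle", {
  tabs <- list(matrix(c(12, 3, 5, 10), 2, byrow = TRUE),
               matrix(c(7, 8, 9, 6), 2, byrow = TRUE))
  for (corr in c(TRUE, FALSE)) {
    r <- cmh_test(tabs, correct = corr)
    o <- oracle_cmh(tabs, correct = corr)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
    expect_equal(r$or_mh, o$or_mh, tolerance = 1e-10)
    expect_equal(r$ci95, o$ci95, tolerance = 1e-10)
  }
})

test_that("results agree with stats::mantelhaen.test", {
  set.seed(52)
  n_checked <- 0
  for (tabs in random_tables(40, max_cell = 50)) {
    arr <- array(unlist(lapply(tabs, t)), dim = c(2, 2, length(tabs)))
    arr <- aperm(arr, c(2, 1, 3))
    ref <- tryCatch(stats::mantelhaen.test(arr, correct = TRUE),
                    error = function(e) NULL)
    if (is.null(ref) || !is.finite(ref$statistic)) next
    r <- cmh_test(tabs, correct = TRUE)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-8)
    expect_equal(r$or_mh, unname(ref$estimate), tolerance = 1e-8)
    expect_equal(r$ci95, unname(ref$conf.int[1:2]), tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("a single stratum reduces to the sample odds ratio", {
  tab <- matrix(c(12, 3, 5, 10), 2, byrow = TRUE)
  r <- cmh_test(tab)
  expect_equal(r$or_mh, (12 * 10) / (3 * 5))
  expect_equal(r$K, 1L)
})

test_that("the statistic is invariant under stratum permutation", {
  set.seed(53)
  for (tabs in random_tables(10, max_k = 5)) {
    if (length(tabs) < 2) next
    ok <- tryCatch({cmh_test(tabs); TRUE}, error = function(e) FALSE)
    if (!ok) next
    r1 <- cmh_test(tabs)
    r2 <- cmh_test(tabs[sample(length(tabs))])
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
    expect_equal(r1$or_mh, r2$or_mh, tolerance = 1e-12)
  }
})

test_that("duplicating a stratum never flips the effect direction", {
  set.seed(54)
  for (i in 1:20) {
    tab <- matrix(sample(1:50, 4), 2)
    r1 <- cmh_test(list(tab), correct = FALSE)
    r2 <- cmh_test(list(tab, tab), correct = FALSE)
    expect_equal(sign(r2$log_or), sign(r1$log_or))
  }
})

test_that("degenerate strata are tolerated and all-degenerate is an error", {
  r <- cmh_test(list(matrix(0, 2, 2), matrix(c(12, 3, 5, 10), 2, byrow = TRUE)))
  expect_true(is.finite(r$statistic))
  expect_error(cmh_test(list(matrix(0, 2, 2))), "degenerate")
  # zero MH denominator: infinite OR, CI flagged unbounded
  r <- cmh_test(list(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), correct = FALSE)
  expect_equal(r$or_mh, Inf)
  expect_true(all(is.na(r$ci95)))
})

test_that("downsampling conserves totals and is unbiased", {
  set.seed(55)
  out <- downsample_counts(c(10, 10), 0.5)
  expect_equal(sum(out), 10)
  expect_true(all(out >= 0 & out <= 10))
  expect_equal(downsample_counts(c(7, 3), 1), c(7, 3))
  expect_equal(downsample_counts(c(0, 0), 0.5), c(0, 0))
  # hypergeometric expectation oracle: counts (40, 10) at fraction 0.5
  draws <- replicate(1e4, downsample_counts(c(40, 10), 0.5)[1])
  se <- sqrt(25 * 0.8 * 0.2 * (50 - 25) / (50 - 1)) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 20), 3 * se)
  # three categories: conservation still exact
  for (i in 1:20) {
    cnt <- sample(0:30, 3)
    out <- downsample_counts(cnt, 0.5)
    expect_equal(sum(out), floor(sum(cnt) / 2))
    expect_true(all(out <= cnt))
  }
})

make_bi <- function(maj, minr, chrom = "2L") {
  n <- nrow(maj)
  structure(list(chrom = rep(chrom, n), pos = seq_len(n) * 10L,
                 ref = rep("A", n), major = rep("A", n), minor = rep("C", n),
                 maj = maj, minr = minr, other = matrix(0L, n, ncol(maj)),
                 sample_names = paste0("s", seq_len(ncol(maj)))),
            class = "biallelic")
}

two_rep_design <- data.frame(
  replicate = c("r1", "r1", "r2", "r2"),
  pool = c("light", "dark", "light", "dark"),
  stringsAsFactors = FALSE)

test_that("strata assembly yields one stratum per replicate", {
  b <- make_bi(rbind(c(30, 28, 25, 27)), rbind(c(10, 12, 15, 13)))
  st <- assemble_strata(b, 1, two_rep_design, downsample_fraction = 1)
  expect_equal(dim(st$full), c(2L, 2L, 2L))
  expect_equal(unname(st$full[1, "light", ]), c(30L, 10L))
  expect_equal(unname(st$full[2, "dark", ]), c(27L, 13L))
})

test_that("X-linked sites skip downsampling; autosomes are halved", {
  set.seed(56)
  bx <- make_bi(rbind(c(30, 28, 25, 27)), rbind(c(10, 12, 15, 13)), chrom = "X")
  st <- assemble_strata(bx, 1, two_rep_design, downsample_fraction = 0.5)
  expect_identical(st$pvalue_counts, st$full)
  ba <- make_bi(rbind(c(30, 28, 25, 27)), rbind(c(10, 12, 15, 13)), chrom = "2L")
  st <- assemble_strata(ba, 1, two_rep_design, downsample_fraction = 0.5)
  expect_equal(sum(st$pvalue_counts), floor(sum(st$full[1, 1, ]) / 2) +
                 floor(sum(st$full[1, 2, ]) / 2) +
                 floor(sum(st$full[2, 1, ]) / 2) + floor(sum(st$full[2, 2, ]) / 2))
  # a stratum with an empty pool is retained
  b0 <- make_bi(rbind(c(30, 0, 25, 27)), rbind(c(10, 0, 15, 13)))
  st <- assemble_strata(b0, 1, two_rep_design, downsample_fraction = 1)
  expect_equal(unname(st$full[1, "dark", ]), c(0L, 0L))
})

test_that("design validation catches missing pools and wrong sizes", {
  bad <- data.frame(replicate = c("r1", "r1"), pool = c("light", "light"))
  expect_error(check_design(bad), "missing a light or dark pool")
  expect_error(check_design(two_rep_design, n_samples = 3), "4 rows")
})

test_that("the genome scan reports effects from full counts", {
  set.seed(57)
  maj <- matrix(rpois(8, 40), 2)
  minr <- matrix(rpois(8, 15), 2)
  b <- make_bi(maj, minr, chrom = "X")
  res <- cmh_pipeline(b, two_rep_design, correct = TRUE)
  for (i in 1:2) {
    tabs <- list(rbind(c(maj[i, 1], minr[i, 1]), c(maj[i, 2], minr[i, 2])),
                 rbind(c(maj[i, 3], minr[i, 3]), c(maj[i, 4], minr[i, 4])))
    r <- cmh_test(tabs)
    expect_equal(res$statistic[i], r$statistic, tolerance = 1e-12)
    expect_equal(res$or_mh[i], r$or_mh, tolerance = 1e-12)
  }
  expect_equal(res$freq_light_r1, minr[, 1] / (maj[, 1] + minr[, 1]))
})

test_that("empirical FDR matches the exhaustive-scan oracle", {
  r <- empirical_fdr(c(0.001, 0.002, 0.5), c(0.01, 0.2, 0.9), q = 0.05)
  o <- oracle_fdr(c(0.001, 0.002, 0.5), c(0.01, 0.2, 0.9), q = 0.05)
  expect_equal(r$p_threshold, o$p_threshold)
  expect_equal(r$n_significant, o$n_significant)
  set.seed(58)
  for (i in 1:20) {
    obs <- runif(60)^2
    null <- runif(45)
    for (q in c(0.01, 0.05, 0.2)) {
      r <- empirical_fdr(obs, null, q)
      o <- oracle_fdr(obs, null, q)
      expect_equal(r$p_threshold, o$p_threshold)
      expect_equal(r$n_significant, o$n_significant)
      expect_equal(r$estimated_fdr_at_threshold, o$estimated_fdr_at_threshold)
    }
  }
})

test_that("an FDR null identical to the observations yields no hits", {
  p <- c(0.001, 0.02, 0.3, 0.7)
  r <- empirical_fdr(p, p, q = 0.05)
  expect_equal(r$n_significant, 0L)
  # a null concentrated at 1 certifies everything below it
  r <- empirical_fdr(c(0.2, 0.4, 1), rep(1, 10), q = 0.05)
  expect_equal(r$n_significant, 2L)
})

test_that("same-pool and split nulls produce p-values on null data", {
  set.seed(59)
  spec <- scenario_spec(n_sites = 300, coverage_range = c(54L, 66L))
  ex <- generate_pool_experiment(spec, with_metadata = FALSE)
  b <- call_biallelic(ex$sync)
  p1 <- null_contrast_same_pool(b, ex$design, correct = FALSE)
  p2 <- null_within_pool_split(b, ex$design, correct = FALSE)
  expect_true(all(is.na(p1) | (p1 >= 0 & p1 <= 1)))
  expect_true(all(is.na(p2) | (p2 >= 0 & p2 <= 1)))
  expect_gt(length(p1), 0)
  expect_equal(length(p2), length(b$pos))
  # both should look null: no excess of tiny p-values
  expect_lt(mean(p2 < 0.01, na.rm = TRUE), 0.05)
})
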