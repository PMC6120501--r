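# haplotype-based phenotype simulation, extreme-pool selection and the
# in-silico replicated Pool-GWAS

two_hap <- function(f = 0.3, gap = 10) {
  haplotype_model(c("D", "L"), c(f, 1 - f), c(gap, 0))
}

test_that("heritability fixes the noise variance via V_E = V_G (1-h2)/h2", {
  m <- two_hap(0.5, 10)
  vg <- 0.5 * 0.5 * 100  # variance of a two-point score distribution
  expect_equal(noise_sd(m, 1), 0)
  expect_equal(noise_sd(m, 0.5)^2, vg)
  expect_equal(noise_sd(m, 0.2)^2, 4 * vg)
  expect_error(noise_sd(m, 0), "h2")
  m0 <- haplotype_model(c("D", "L"), c(0.5, 0.5), c(7, 7))
  expect_warning(s <- noise_sd(m0, 0.2), "genetic variance is 0")
  expect_equal(s, 0)
})

test_that("model validation enforces the D/L alphabet and frequency simplex", {
  expect_error(haplotype_model(c("DX"), 1, 0), "alphabet")
  expect_error(haplotype_model(c("DD", "L"), c(0.5, 0.5), c(1, 0)), "equal length")
  expect_error(haplotype_model(c("DD", "DD"), c(0.5, 0.5), c(1, 0)), "unique")
  expect_error(haplotype_model(c("D", "L"), c(0.7, 0.7), c(1, 0)), "sum to 1")
})

test_that("zero noise yields exactly the base scores", {
  set.seed(71)
  pop <- simulate_replicate(two_hap(0.4, 5), 500, sd = 0)
  expect_setequal(unique(pop$phenotype), c(0, 5))
  pop1 <- simulate_replicate(haplotype_model("D", 1, 3), 100, sd = 0)
  expect_true(all(pop1$haplotype == 1))
  expect_true(all(pop1$phenotype == 3))
})

test_that("haplotype draws follow the model frequencies", {
  set.seed(72)
  m <- haplotype_model(c("DDD", "DDL", "LLD", "LLL"),
                       c(0.12, 0.08, 0.25, 0.55), c(4, 3, 2, 1))
  pop <- simulate_replicate(m, 1e5, sd = 1)
  for (h in 1:4) {
    f <- m$frequencies[h]
    se <- sqrt(f * (1 - f) / 1e5)
    expect_lt(abs(mean(pop$haplotype == h) - f), 3 * se)
  }
})

test_that("extreme selection picks the order statistics", {
  set.seed(73)
  ph <- sample(1:1500)
  ext <- select_extremes(ph, 100, 75)
  expect_setequal(ph[ext$light], 1:100)
  expect_setequal(ph[ext$dark], 1426:1500)
  expect_length(intersect(ext$light, ext$dark), 0)
  # random data against a full-sort oracle (unique values)
  x <- rnorm(400)
  ext <- select_extremes(x, 40, 25)
  expect_setequal(ext$light, order(x)[1:40])
  expect_setequal(ext$dark, order(x)[376:400])
  # all-tied phenotypes still give disjoint pools of the right sizes
  ext <- select_extremes(rep(1, 50), 20, 20)
  expect_length(ext$light, 20)
  expect_length(ext$dark, 20)
  expect_length(intersect(ext$light, ext$dark), 0)
  expect_error(select_extremes(1:10, 6, 6), "exceed")
})

test_that("experiments have the declared replicate and pool structure", {
  set.seed(74)
  cfg <- sim_config(n_experiments = 2)
  sim <- run_experiment(coupled_snp_model(), cfg)
  expect_equal(nrow(sim$per_experiment), 2 * 3)  # 3 SNPs per experiment
  expect_equal(sim$summary$snp, c("SNP1", "SNP2", "SNP3"))
  expect_true(all(sim$per_experiment$p_value >= 0 &
                    sim$per_experiment$p_value <= 1, na.rm = TRUE))
  expect_error(sim_config(n_light = 1000, n_dark = 1000, n_individuals = 1500),
               "exceed")
  expect_error(sim_config(h2 = 0), "h2")
})

test_that("identical seeds reproduce the simulation exactly", {
  cfg <- sim_config(n_individuals = 300, n_light = 30, n_dark = 20,
                    n_experiments = 3)
  set.seed(75); s1 <- run_experiment(coupled_snp_model(), cfg)
  set.seed(75); s2 <- run_experiment(coupled_snp_model(), cfg)
  expect_identical(s1$per_experiment, s2$per_experiment)
})

test_that("a model without score variation gives uniform p-values", {
  set.seed(76)
  m <- haplotype_model(c("DD", "DL", "LD", "LL"), rep(0.25, 4), rep(5, 4))
  cfg <- sim_config(n_individuals = 400, n_light = 50, n_dark = 40,
                    n_experiments = 200, correct = FALSE)
  sim <- suppressWarnings(run_experiment(m, cfg))
  for (s in c("SNP1", "SNP2")) {
    p <- sim$per_experiment$p_value[sim$per_experiment$snp == s]
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("full coupling reverses SNP2's apparent effect direction", {
  set.seed(77)
  model <- coupled_snp_model()
  # SNP2's isolated (transgene) effect is lightening by construction
  # (negative additive effect), but the coupled SNP1/SNP2 pair's net effect
  # is darkening:
  net_pair <- mean(model$base_scores[model$haplotypes %in% c("DDD", "DDL")]) -
    mean(model$base_scores[model$haplotypes %in% c("LLD", "LLL")])
  expect_gt(net_pair, 0)
  # hence the zero-noise ranking oracle predicts D-allele enrichment in the
  # dark pool for every SNP, including SNP2
  signs <- oracle_zero_noise_signs(model, 1500, 100, 75)
  expect_equal(signs, c(1, 1, 1))
  cfg <- sim_config(n_experiments = 25)
  sim <- run_experiment(model, cfg)
  pe <- sim$per_experiment
  s1 <- pe$log_or[pe$snp == "SNP1"]
  s2 <- pe$log_or[pe$snp == "SNP2"]
  expect_equal(sign(s2), sign(s1))           # coupling: identical counts
  expect_gte(mean(sign(s2) == signs[2]), 0.95)
  expect_gt(sim$summary$median_log_or[2], 0)  # reversed vs the transgene sign
})

test_that("more heritable phenotypes are not harder to map", {
  med_logp <- vapply(c(0.1, 0.8), function(h2) {
    set.seed(78)
    cfg <- sim_config(n_individuals = 600, n_light = 60, n_dark = 45,
                      h2 = h2, n_experiments = 10)
    sim <- run_experiment(two_hap(0.3, 10), cfg)
    -log10(sim$summary$median_p[1])
  }, 0)
  expect_gte(med_logp[2], med_logp[1])
})

test_that("at h2 near 1 a uniquely dark haplotype saturates the dark pool", {
  set.seed(79)
  m <- haplotype_model(c("D", "L"), c(0.2, 0.8), c(100, 0))
  pop <- simulate_replicate(m, 1000, sd = 0)
  ext <- select_extremes(pop$phenotype, 100, 75)
  expect_true(all(pop$haplotype[ext$dark] == 1))
})
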