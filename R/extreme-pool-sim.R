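# In-silico Pool-GWAS of linked regulatory SNPs.
#
# Individuals carry one haplotype over the focal SNPs (the hemizygous-male
# convention: the focal enhancer SNPs are X-linked and only males were
# phenotyped, so a single haplotype copy per individual is the natural
# model; a diploid mode is available). Phenotype = the haplotype's base
# pigmentation score plus Gaussian noise whose variance is set by the
# assumed heritability. The lightest and darkest individuals of each
# replicate form the pools, and per-SNP allele counts are contrasted with
# the CMH test across replicates — exposing how haplotype structure
# (linkage disequilibrium) distorts apparent single-SNP effects.

#' Construct a haplotype model over focal SNPs
#'
#' @param haplotypes Character vector of equal-length allele strings over
#'   `{D, L}` (dark/light allele per SNP), unique.
#' @param frequencies Non-negative frequencies summing to 1.
#' @param base_scores Base pigmentation score per haplotype (intensity
#'   units; higher = darker).
#' @param snp_names SNP labels (default `SNP1..SNPk`).
#' @return List of class `"haplotype_model"`.
#' @export
haplotype_model <- function(haplotypes, frequencies, base_scores,
                            snp_names = NULL) {
  if (length(unique(nchar(haplotypes))) != 1L) {
    stop("haplotype strings must have equal length")
  }
  if (anyDuplicated(haplotypes)) stop("haplotype strings must be unique")
  if (!all(strsplit(paste(haplotypes, collapse = ""), "")[[1L]] %in% c("D", "L"))) {
    stop("haplotype strings must be over the alphabet {D, L}")
  }
  if (length(frequencies) != length(haplotypes) ||
      length(base_scores) != length(haplotypes)) {
    stop("frequencies and base_scores must match the haplotypes")
  }
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-8) {
    stop("frequencies must be non-negative and sum to 1")
  }
  k <- nchar(haplotypes[1L])
  if (is.null(snp_names)) snp_names <- paste0("SNP", seq_len(k))
  stopifnot(length(snp_names) == k)
  alleles <- do.call(rbind, strsplit(haplotypes, ""))
  colnames(alleles) <- snp_names
  structure(list(haplotypes = haplotypes, frequencies = frequencies,
                 base_scores = base_scores, snp_names = snp_names,
                 alleles = alleles),
            class = "haplotype_model")
}

#' Read a haplotype model TSV (haplotype, frequency, base_score)
#' @param file Tab-separated file with header.
#' @return A [haplotype_model()].
#' @export
read_haplotype_model <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  haplotype_model(tab$haplotype, tab$frequency, tab$base_score)
}

#' Illustrative three-SNP enhancer haplotype model
#'
#' A configurable example of the haplotype structure observed at the three
#' focal enhancer SNPs: SNP1 and SNP2 fully coupled (their alleles occur
#' only in the LL and DD combinations), SNP2's isolated effect lightening
#' (negative) and opposed to the coupled pair's net darkening effect, and
#' SNP3 segregating on both backgrounds. Frequencies and scores are
#' illustrative defaults for simulation studies, not estimates from any
#' specific population; replication work must supply its own model via
#' [haplotype_model()] or [read_haplotype_model()].
#'
#' @param effects Named per-SNP additive effects on the intensity scale
#'   (applied as `+e` for the D allele, `-e` for L).
#' @param grand_mean Baseline intensity.
#' @param frequencies Haplotype frequencies for (DDD, DDL, LLD, LLL).
#' @return A [haplotype_model()].
#' @export
coupled_snp_model <- function(effects = c(SNP1 = 20, SNP2 = -8, SNP3 = 14),
                              grand_mean = 140,
                              frequencies = c(0.12, 0.08, 0.25, 0.55)) {
  haps <- c("DDD", "DDL", "LLD", "LLL")
  sign <- function(ch) ifelse(ch == "D", 1, -1)
  scores <- vapply(haps, function(h) {
    s <- strsplit(h, "")[[1L]]
    grand_mean + sum(effects * sign(s))
  }, 0)
  haplotype_model(haps, frequencies, unname(scores))
}

#' Simulation configuration for in-silico extreme-pool experiments
#'
#' Defaults follow the standard design of such simulations: five replicates
#' of 1500 phenotyped individuals, pools of the 100 lightest and 75 darkest,
#' and heritability 0.2.
#'
#' @param n_replicates Replicates per experiment.
#' @param n_individuals Individuals per replicate.
#' @param n_light,n_dark Extreme-pool sizes (must fit in `n_individuals`).
#' @param h2 Heritability of the phenotype in `(0, 1]`: fraction of
#'   phenotypic variance attributable to the haplotype base scores.
#' @param n_experiments Number of repeated in-silico experiments.
#' @param correct CMH continuity correction flag.
#' @param diploid If `TRUE`, individuals carry two haplotypes and their
#'   phenotype is the mean of the two base scores plus noise (default
#'   `FALSE`: hemizygous/haploid carriers).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_replicates = 5L, n_individuals = 1500L,
                       n_light = 100L, n_dark = 75L, h2 = 0.2,
                       n_experiments = 1L, correct = TRUE, diploid = FALSE) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  if (n_light + n_dark > n_individuals) {
    stop("n_light + n_dark must not exceed n_individuals")
  }
  structure(list(n_replicates = n_replicates, n_individuals = n_individuals,
                 n_light = n_light, n_dark = n_dark, h2 = h2,
                 n_experiments = n_experiments, correct = correct,
                 diploid = diploid),
            class = "sim_config")
}

#' Environmental noise standard deviation implied by a heritability
#'
#' With genetic variance `V_G` (the frequency-weighted variance of the
#' haplotype base scores) and `h2 = V_G / (V_G + V_E)`, the noise standard
#' deviation is `sqrt(V_G (1 - h2) / h2)`. A model without score variation
#' returns 0 with a warning.
#'
#' @param model A [haplotype_model()].
#' @param h2 Heritability in `(0, 1]`.
#' @return Noise standard deviation (phenotype units).
#' @export
noise_sd <- function(model, h2) {
  stopifnot(inherits(model, "haplotype_model"))
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  mu <- sum(model$frequencies * model$base_scores)
  vg <- sum(model$frequencies * (model$base_scores - mu)^2)
  if (vg == 0) {
    warning("all base scores equal: genetic variance is 0, noise sd is 0")
    return(0)
  }
  sqrt(vg * (1 - h2) / h2)
}

#' Simulate one replicate population
#'
#' Each individual draws one haplotype from the model frequencies (two in
#' diploid mode) and a phenotype equal to its base score (mean of the two
#' base scores in diploid mode) plus `Normal(0, sd)` noise.
#'
#' @param model A [haplotype_model()].
#' @param n_individuals Population size.
#' @param sd Noise standard deviation, typically [noise_sd()].
#' @param diploid Diploid mode flag.
#' @return Data.frame with `haplotype` (index into the model; in diploid
#'   mode `haplotype2` as well) and `phenotype`.
#' @export
simulate_replicate <- function(model, n_individuals, sd, diploid = FALSE) {
  stopifnot(inherits(model, "haplotype_model"))
  h1 <- sample.int(length(model$haplotypes), n_individuals, replace = TRUE,
                   prob = model$frequencies)
  if (diploid) {
    h2_ <- sample.int(length(model$haplotypes), n_individuals, replace = TRUE,
                      prob = model$frequencies)
    base <- (model$base_scores[h1] + model$base_scores[h2_]) / 2
    out <- data.frame(haplotype = h1, haplotype2 = h2_,
                      phenotype = base + stats::rnorm(n_individuals, 0, sd))
  } else {
    out <- data.frame(haplotype = h1,
                      phenotype = model$base_scores[h1] +
                        stats::rnorm(n_individuals, 0, sd))
  }
  out
}

#' Select the phenotypic extremes of a replicate
#'
#' The light pool holds the `n_light` lowest-phenotype individuals, the dark
#' pool the `n_dark` highest (lower value = lighter). Exact ties at a pool
#' boundary are resolved by a random (RNG-stream-seeded) permutation, and
#' the two pools are disjoint by construction.
#'
#' @param phenotype Numeric phenotype vector.
#' @param n_light,n_dark Pool sizes with `n_light + n_dark <= length(phenotype)`.
#' @return List with integer index vectors `light` and `dark`.
#' @export
select_extremes <- function(phenotype, n_light, n_dark) {
  n <- length(phenotype)
  if (n_light + n_dark > n) stop("pool sizes exceed the population size")
  ord <- order(phenotype, sample.int(n))  # random tie-break
  list(light = ord[seq_len(n_light)],
       dark = ord[seq.int(n - n_dark + 1L, n)])
}

#' Run replicated in-silico extreme-pool experiments
#'
#' For each experiment: simulate `n_replicates` populations, select the
#' extremes, tabulate per SNP the D/L allele counts in the dark and light
#' pools (one allele per individual; two in diploid mode), and run the CMH
#' test with `K = n_replicates` strata. Strata are oriented rows = (light,
#' dark) and columns = (L allele, D allele), so a positive `log_or` means
#' the D allele is enriched in the dark pool (the allele acts darkening in
#' the pooled contrast).
#'
#' @param model A [haplotype_model()].
#' @param config A [sim_config()].
#' @return List of class `"pool_gwas_sim"`: `per_experiment` (data.frame
#'   with `experiment`, `snp`, `p_value`, `or_mh`, `log_or`; `p_value` is
#'   `NA` for a SNP monomorphic across all pools of an experiment) and
#'   `summary` (per SNP: `median_p`, `median_log_or`, `sign_consistency` =
#'   fraction of experiments whose `log_or` shares the median's sign).
#' @export
run_experiment <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "haplotype_model"), inherits(config, "sim_config"))
  sd <- noise_sd(model, config$h2)
  k_snps <- length(model$snp_names)
  n_hap <- length(model$haplotypes)
  is_D <- model$alleles == "D"  # n_hap x k_snps
  res <- vector("list", config$n_experiments)
  for (e in seq_len(config$n_experiments)) {
    # haplotype composition of each pool: n_replicates x n_hap
    light_h <- dark_h <- matrix(0L, config$n_replicates, n_hap)
    for (r in seq_len(config$n_replicates)) {
      pop <- simulate_replicate(model, config$n_individuals, sd,
                                diploid = config$diploid)
      ext <- select_extremes(pop$phenotype, config$n_light, config$n_dark)
      tab_pool <- function(idx) {
        h <- pop$haplotype[idx]
        if (config$diploid) h <- c(h, pop$haplotype2[idx])
        tabulate(h, nbins = n_hap)
      }
      light_h[r, ] <- tab_pool(ext$light)
      dark_h[r, ] <- tab_pool(ext$dark)
    }
    snp_res <- lapply(seq_len(k_snps), function(s) {
      a <- light_h %*% (!is_D[, s])  # light pool, L allele
      b <- light_h %*% is_D[, s]     # light pool, D allele
      cc_ <- dark_h %*% (!is_D[, s])
      d <- dark_h %*% is_D[, s]
      if (all(b + d == 0) || all(a + cc_ == 0)) {
        return(data.frame(snp = model$snp_names[s], p_value = NA_real_,
                          or_mh = NA_real_, log_or = NA_real_))
      }
      r <- .cmh_core(t(a), t(b), t(cc_), t(d), correct = config$correct)
      data.frame(snp = model$snp_names[s], p_value = r$p_value,
                 or_mh = r$or_mh, log_or = r$log_or)
    })
    res[[e]] <- cbind(experiment = e, do.call(rbind, snp_res))
  }
  per_exp <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(per_exp, per_exp$snp), function(d) {
    med_lor <- stats::median(d$log_or, na.rm = TRUE)
    data.frame(snp = d$snp[1L],
               median_p = stats::median(d$p_value, na.rm = TRUE),
               median_log_or = med_lor,
               sign_consistency = mean(sign(d$log_or) == sign(med_lor),
                                       na.rm = TRUE))
  }))
  summ <- summ[match(model$snp_names, summ$snp), ]
  rownames(summ) <- NULL
  structure(list(per_experiment = per_exp, summary = summ,
                 config = config, model = model),
            class = "pool_gwas_sim")
}

#' @export
print.pool_gwas_sim <- function(x, ...) {
  cat(sprintf("in-silico Pool-GWAS: %d experiment(s), %d replicates x %d individuals, pools %d/%d, h2 = %g\n",
              x$config$n_experiments, x$config$n_replicates,
              x$config$n_individuals, x$config$n_light, x$config$n_dark,
              x$config$h2))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
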