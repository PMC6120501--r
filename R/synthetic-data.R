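# Synthetic data with known ground truth for every pipeline stage:
# pooled sync experiments with planted associations, fragment observations
# for haplotype/LD estimation, factorial phenotype datasets, and a filter
# fixture with one planted violation per site-inclusion rule.

#' Scenario specification for a synthetic pool experiment
#'
#' Defaults emulate a two-population replicated extreme-pool design: one
#' population with 2 replicates and 120/120 light/dark individuals, one
#' with 3 replicates and 100/50, around 1500 phenotyped individuals per
#' replicate at causal sites, per-sample read depths drawn uniformly from
#' the coverage range, and neutral allele frequencies from a U-shaped
#' Beta(0.2, 0.2) site-frequency spectrum.
#'
#' @param populations Data.frame with columns `name`, `n_replicates`,
#'   `n_light`, `n_dark`.
#' @param n_sites Number of sites.
#' @param causal Data.frame with columns `index` (site index), `freq`
#'   (population frequency of the dark allele), `effect` (additive effect of
#'   the dark allele on the phenotype scale; sign = direction), or `NULL`.
#' @param h2 Heritability used when simulating phenotypes at causal sites.
#' @param coverage_range Integer bounds for per-sample site depth.
#' @param neutral_shape Beta shape parameter of the neutral site-frequency
#'   spectrum (both shapes equal; smaller = more U-shaped).
#' @param n_phenotyped Individuals phenotyped per replicate before pool
#'   selection at causal sites.
#' @param chrom Chromosome label for the generated sites (default `"X"`:
#'   sites enter the association test without autosomal downsampling).
#' @param pos_start,pos_step Site coordinates: `pos_start + (0:(n-1)) *
#'   pos_step`.
#' @param end_dist_mean,end_dist_sd Mean/SD of simulated mean-end-distances.
#' @param violation_rate Fraction of sites whose minor-allele metadata is
#'   drawn to violate the read-placement filter (end distance at or below
#'   8), for filter-recovery experiments.
#' @param overdispersion Beta-binomial overdispersion `rho` in `[0, 1)` for
#'   read sampling; `0` (default) is pure binomial.
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(populations = data.frame(
                            name = c("Vienna", "Bolzano"),
                            n_replicates = c(2L, 3L),
                            n_light = c(120L, 100L),
                            n_dark = c(120L, 50L)),
                          n_sites = 1000L, causal = NULL, h2 = 0.2,
                          coverage_range = c(54L, 112L),
                          neutral_shape = 0.2, n_phenotyped = 1500L,
                          chrom = "X", pos_start = 100000L, pos_step = 100L,
                          end_dist_mean = 25, end_dist_sd = 4,
                          violation_rate = 0, overdispersion = 0) {
  stopifnot(all(populations$n_light > 0), all(populations$n_dark > 0),
            coverage_range[1L] <= coverage_range[2L],
            neutral_shape > 0, overdispersion >= 0, overdispersion < 1)
  if (!is.null(causal)) {
    stopifnot(all(c("index", "freq", "effect") %in% names(causal)),
              all(causal$index >= 1L & causal$index <= n_sites),
              all(causal$freq > 0 & causal$freq < 1))
  }
  structure(as.list(environment()), class = "scenario_spec")
}

# truncated U-shaped spectrum via inverse-CDF (exactly reproducible,
# vectorised); avoids frequencies so extreme that a site is monomorphic in
# expectation at pool depth
.rspectrum <- function(n, shape, eps = 0.005) {
  lo <- stats::pbeta(eps, shape, shape)
  hi <- stats::pbeta(1 - eps, shape, shape)
  stats::qbeta(stats::runif(n, lo, hi), shape, shape)
}

# binomial or beta-binomial read draw
.rreads <- function(depth, freq, rho) {
  if (rho > 0) {
    s <- (1 - rho) / rho
    freq <- stats::rbeta(length(freq), freq * s, (1 - freq) * s)
  }
  stats::rbinom(length(depth), depth, freq)
}

#' Generate a synthetic pooled extreme-phenotype experiment
#'
#' Produces a sync dataset, a design table, a read-placement/strand
#' metadata sidecar and the generating ground truth. Neutral sites draw
#' reads in every pool binomially from one shared population frequency (so
#' the replicated light/dark contrast is exactly null there). At causal
#' sites, phenotypes arise from the extreme-pool simulation machinery: each
#' replicate phenotypes `n_phenotyped` haploid carriers of the dark/light
#' allele (dark-allele effect `effect`, heritability `h2`), the extremes
#' form the pools, and reads are drawn binomially from each pool's realised
#' allele frequency.
#'
#' @param spec A [scenario_spec()].
#' @param with_metadata Generate the per-site per-sample per-allele
#'   metadata sidecar (default `TRUE`).
#' @return List of class `"pool_experiment"`: `sync` (a `"sync"` object),
#'   `design` (sample, population, replicate, pool), `meta` (sidecar
#'   data.frame or `NULL`), and `truth` (list with `site` data.frame —
#'   `chrom`, `pos`, `true_freq`, `causal`, `effect_direction`,
#'   `violates_placement` — and `pool_freq`, the per-site per-sample
#'   frequency each read draw used).
#' @export
generate_pool_experiment <- function(spec = scenario_spec(),
                                     with_metadata = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  pops <- spec$populations
  design <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    do.call(rbind, lapply(seq_len(pops$n_replicates[i]), function(r) {
      data.frame(population = pops$name[i],
                 replicate = paste0(pops$name[i], "_", r),
                 pool = c("light", "dark"),
                 n_individuals = c(pops$n_light[i], pops$n_dark[i]),
                 stringsAsFactors = FALSE)
    }))
  }))
  design$sample <- paste(design$replicate, design$pool, sep = "_")
  n_samp <- nrow(design)
  n <- spec$n_sites
  pos <- spec$pos_start + (seq_len(n) - 1L) * spec$pos_step
  chrom <- rep(spec$chrom, n)
  # site alleles: allele1 = dark/reference-frequency allele, allele2 = other
  bases <- c("A", "C", "G", "T")
  al1 <- sample(bases, n, replace = TRUE)
  al2 <- vapply(al1, function(b) sample(setdiff(bases, b), 1L), "")
  f <- .rspectrum(n, spec$neutral_shape)
  causal <- rep(FALSE, n)
  eff_dir <- rep(NA_real_, n)
  if (!is.null(spec$causal) && nrow(spec$causal) > 0L) {
    causal[spec$causal$index] <- TRUE
    eff_dir[spec$causal$index] <- sign(spec$causal$effect)
    f[spec$causal$index] <- spec$causal$freq
  }
  depth <- matrix(sample(seq.int(spec$coverage_range[1L], spec$coverage_range[2L]),
                         n * n_samp, replace = TRUE), n, n_samp)
  # frequency each pool's read draw uses: shared f at neutral sites,
  # realised extreme-pool frequency at causal sites
  pool_freq <- matrix(f, n, n_samp)
  if (any(causal)) {
    for (ci in seq_len(nrow(spec$causal))) {
      i <- spec$causal$index[ci]
      model <- haplotype_model(c("D", "L"),
                               c(spec$causal$freq[ci], 1 - spec$causal$freq[ci]),
                               c(spec$causal$effect[ci], 0))
      sd <- noise_sd(model, spec$h2)
      for (r in unique(design$replicate)) {
        sel <- design$replicate == r
        nl <- design$n_individuals[sel & design$pool == "light"]
        nd <- design$n_individuals[sel & design$pool == "dark"]
        pop <- simulate_replicate(model, spec$n_phenotyped, sd)
        ext <- select_extremes(pop$phenotype, nl, nd)
        pool_freq[i, which(sel & design$pool == "light")] <-
          mean(pop$haplotype[ext$light] == 1L)
        pool_freq[i, which(sel & design$pool == "dark")] <-
          mean(pop$haplotype[ext$dark] == 1L)
      }
    }
  }
  a_counts <- matrix(.rreads(depth, pool_freq, spec$overdispersion), n, n_samp)
  b_counts <- depth - a_counts
  counts <- array(0L, dim = c(n, n_samp, 6L),
                  dimnames = list(NULL, design$sample, SYNC_CATEGORIES))
  for (bi in seq_along(SYNC_CATEGORIES)) {
    m1 <- al1 == SYNC_CATEGORIES[bi]
    m2 <- al2 == SYNC_CATEGORIES[bi]
    if (any(m1)) counts[m1, , bi] <- a_counts[m1, ]
    if (any(m2)) counts[m2, , bi] <- b_counts[m2, ]
  }
  sync <- structure(list(chrom = chrom, pos = pos, ref = al1,
                         counts = counts, sample_names = design$sample),
                    class = "sync")
  violates <- rep(FALSE, n)
  meta <- NULL
  if (with_metadata) {
    if (spec$violation_rate > 0) {
      violates <- stats::runif(n) < spec$violation_rate
    }
    mk_meta <- function(allele, cnt, viol_allele) {
      fwd <- matrix(stats::rbinom(n * n_samp, cnt, 0.5), n, n_samp)
      med <- matrix(pmax(0, stats::rnorm(n * n_samp, spec$end_dist_mean,
                                         spec$end_dist_sd)), n, n_samp)
      if (viol_allele && any(violates)) {
        med[violates, ] <- matrix(stats::runif(sum(violates) * n_samp, 0, 8),
                                  sum(violates), n_samp)
      }
      data.frame(chrom = rep(chrom, n_samp),
                 pos = rep(pos, n_samp),
                 sample = rep(design$sample, each = n),
                 allele = rep(allele, n_samp),
                 fwd = as.vector(fwd), rev = as.vector(cnt - fwd),
                 mean_end_dist = round(as.vector(med), 3L),
                 stringsAsFactors = FALSE)
    }
    meta <- rbind(mk_meta(al1, a_counts, FALSE), mk_meta(al2, b_counts, TRUE))
    meta <- meta[order(meta$pos, meta$sample, meta$allele), ]
    rownames(meta) <- NULL
  }
  truth <- list(site = data.frame(chrom = chrom, pos = pos, true_freq = f,
                                  causal = causal, effect_direction = eff_dir,
                                  violates_placement = violates,
                                  stringsAsFactors = FALSE),
                pool_freq = pool_freq)
  structure(list(sync = sync, design = design, meta = meta, truth = truth,
                 spec = spec),
            class = "pool_experiment")
}

#' @export
print.pool_experiment <- function(x, ...) {
  cat(sprintf("synthetic pool experiment: %d sites, %d pools (%d causal sites)\n",
              length(x$sync$pos), nrow(x$design), sum(x$truth$site$causal)))
  invisible(x)
}

#' Generate fragment observations from a haplotype model
#'
#' Fragments sample a haplotype by frequency and cover each focal locus
#' independently with the given probability; fragments covering no locus
#' are dropped. Haplotype D/L alleles are written as bases via
#' `allele_bases`.
#'
#' @param model A [haplotype_model()].
#' @param n_fragments Number of fragments to draw (before dropping empty
#'   ones).
#' @param loci Integer positions of the focal SNPs (sorted; default
#'   `100, 200, ...`).
#' @param locus_probs Per-locus coverage probability (default 1: every
#'   fragment covers every locus).
#' @param allele_bases Matrix with one row per locus and columns `D`, `L`
#'   giving the base written for each allele (default: `A` for D, `T` for
#'   L at every locus).
#' @return Data.frame with `fragment_id`, `locus`, `base` (the
#'   [read_fragments()] layout).
#' @export
generate_fragments <- function(model, n_fragments, loci = NULL,
                               locus_probs = NULL, allele_bases = NULL) {
  stopifnot(inherits(model, "haplotype_model"), n_fragments >= 1L)
  k <- length(model$snp_names)
  if (is.null(loci)) loci <- 100L * seq_len(k)
  stopifnot(length(loci) == k, !is.unsorted(loci, strictly = TRUE))
  if (is.null(locus_probs)) locus_probs <- rep(1, k)
  stopifnot(length(locus_probs) == k)
  if (is.null(allele_bases)) {
    allele_bases <- matrix(rep(c("A", "T"), each = k), k, 2L,
                           dimnames = list(NULL, c("D", "L")))
  }
  hap <- sample.int(length(model$haplotypes), n_fragments, replace = TRUE,
                    prob = model$frequencies)
  cover <- matrix(stats::runif(n_fragments * k), n_fragments, k)
  cover <- sweep(cover, 2L, locus_probs, "<=")
  frag_idx <- which(cover, arr.ind = TRUE)
  if (nrow(frag_idx) == 0L) {
    return(data.frame(fragment_id = character(), locus = integer(),
                      base = character(), stringsAsFactors = FALSE))
  }
  al <- model$alleles[cbind(hap[frag_idx[, 1L]], frag_idx[, 2L])]
  base <- allele_bases[cbind(frag_idx[, 2L], ifelse(al == "D", 1L, 2L))]
  out <- data.frame(fragment_id = sprintf("frag%06d", frag_idx[, 1L]),
                    locus = loci[frag_idx[, 2L]],
                    base = base, stringsAsFactors = FALSE)
  out[order(out$fragment_id, out$locus), ]
}

#' Generate a factorial transgenic phenotype dataset with planted effects
#'
#' Builds the eight genotype cell means from zero-sum contrast coefficients
#' scaled so that each model term's share of the population phenotypic
#' variance equals the plan, and adds Gaussian residual noise making up the
#' remainder. With `n_per_cell` observations per cell, [fit_factorial()]
#' recovers the planted eta-squared values up to sampling noise.
#'
#' @param eta2_plan Named numeric vector of target variance shares; names
#'   from `snp1, snp2, snp3, snp1:snp2, snp1:snp3, snp2:snp3,
#'   snp1:snp2:snp3`. Shares must be non-negative and sum to at most 1; the
#'   remainder is residual noise.
#' @param n_per_cell Observations per genotype cell (default 10).
#' @param grand_mean Baseline intensity (default 140).
#' @param total_sd Population phenotypic standard deviation (default 20
#'   intensity units).
#' @return Data.frame with `snp1`, `snp2`, `snp3`, `intensity`; the planted
#'   cell means, coefficients and residual sd are attached as attribute
#'   `"truth"`.
#' @export
generate_transgenic <- function(eta2_plan, n_per_cell = 10L,
                                grand_mean = 140, total_sd = 20) {
  if (is.null(names(eta2_plan)) ||
      !all(names(eta2_plan) %in% .FACTORIAL_TERMS)) {
    stop("eta2_plan must be named by the factorial terms: ",
         paste(.FACTORIAL_TERMS, collapse = ", "))
  }
  if (any(eta2_plan < 0) || sum(eta2_plan) > 1 + 1e-12) {
    stop("infeasible plan: shares must be non-negative and sum to at most 1")
  }
  shares <- stats::setNames(rep(0, length(.FACTORIAL_TERMS)), .FACTORIAL_TERMS)
  shares[names(eta2_plan)] <- eta2_plan
  resid_share <- 1 - sum(shares)
  cells <- expand.grid(snp1 = c("D", "L"), snp2 = c("D", "L"),
                       snp3 = c("D", "L"), stringsAsFactors = FALSE)
  code <- function(s) ifelse(s == "D", 1, -1)
  Xc <- cbind(snp1 = code(cells$snp1), snp2 = code(cells$snp2),
              snp3 = code(cells$snp3))
  Xc <- cbind(Xc,
              "snp1:snp2" = Xc[, 1L] * Xc[, 2L],
              "snp1:snp3" = Xc[, 1L] * Xc[, 3L],
              "snp2:snp3" = Xc[, 2L] * Xc[, 3L],
              "snp1:snp2:snp3" = Xc[, 1L] * Xc[, 2L] * Xc[, 3L])
  coefs <- sqrt(shares) * total_sd
  mu <- grand_mean + as.vector(Xc %*% coefs)
  noise_sd_ <- sqrt(resid_share) * total_sd
  d <- cells[rep(seq_len(8L), each = n_per_cell), , drop = FALSE]
  d$intensity <- rep(mu, each = n_per_cell) +
    stats::rnorm(nrow(d), 0, noise_sd_)
  rownames(d) <- NULL
  attr(d, "truth") <- list(cell_means = cbind(cells, mu = mu),
                           coefficients = coefs, noise_sd = noise_sd_,
                           plan = shares, resid_share = resid_share)
  d
}

#' Deterministic 200-site filter fixture with planted rule violations
#'
#' Builds a small sync dataset in which every non-planted site passes every
#' site-inclusion rule by construction (constant depth 60, mid-range allele
#' frequencies with per-sample minor counts clamped well above the
#' minor-allele-count floor, balanced strands, end distances of 25), and
#' one or more sites violate exactly one rule each: a sample at coverage
#' 14, a population minor-allele count of 7, a minor-allele mean end
#' distance of exactly 8.0, a fully strand-imbalanced minor allele, sites
#' adjacent to a planted indel, a site inside a repeat interval, and a site
#' at depth 500 in one sample (top-2% coverage).
#'
#' @param n_sites Number of sites (default 200).
#' @return List of class `"filter_fixture"`: `sync`, `meta`, `design`,
#'   `indels`, `repeats`, `planted` (data.frame `pos`, `rule`), and
#'   `expected_surviving` (positions that must survive the full cascade).
#' @export
generate_filter_fixture <- function(n_sites = 200L) {
  stopifnot(n_sites >= 140L)  # planted sites occupy fixed indices up to 130
  pops <- data.frame(name = c("Vienna", "Bolzano"),
                     n_replicates = c(2L, 3L),
                     n_light = c(120L, 100L), n_dark = c(120L, 50L))
  design <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    do.call(rbind, lapply(seq_len(pops$n_replicates[i]), function(r) {
      data.frame(population = pops$name[i],
                 replicate = paste0(pops$name[i], "_", r),
                 pool = c("light", "dark"), stringsAsFactors = FALSE)
    }))
  }))
  design$sample <- paste(design$replicate, design$pool, sep = "_")
  n_samp <- nrow(design)
  pos <- 1000L + (seq_len(n_sites) - 1L) * 100L
  chrom <- rep("2L", n_sites)
  depth <- matrix(60L, n_sites, n_samp)
  f <- stats::runif(n_sites, 0.2, 0.8)
  minr <- matrix(stats::rbinom(n_sites * n_samp, 60L, f), n_sites, n_samp)
  minr <- pmin(pmax(minr, 3L), 30L)  # every population's MAC comfortably >= 8
  maj <- depth - minr
  fwd_minr <- ceiling(minr / 2L)
  fwd_maj <- ceiling(maj / 2L)
  med_minr <- matrix(25, n_sites, n_samp)
  med_maj <- matrix(25, n_sites, n_samp)
  pop1 <- design$population == "Vienna"
  planted <- list()
  plant <- function(i, rule) planted[[length(planted) + 1L]] <<-
    data.frame(pos = pos[i], rule = rule, stringsAsFactors = FALSE)
  # 1: coverage 14 in one sample
  i <- 10L; depth[i, 3L] <- 14L; minr[i, 3L] <- 7L; maj[i, 3L] <- 7L
  fwd_minr[i, 3L] <- 4L; fwd_maj[i, 3L] <- 4L
  plant(i, "min_coverage")
  # 2: MAC 7 in population 1 (Vienna), comfortable in population 2
  i <- 30L
  minr[i, pop1] <- c(2L, 2L, 2L, 1L)   # sums to 7
  minr[i, !pop1] <- 5L
  maj[i, ] <- depth[i, ] - minr[i, ]
  fwd_minr[i, ] <- ceiling(minr[i, ] / 2L); fwd_maj[i, ] <- ceiling(maj[i, ] / 2L)
  plant(i, "min_mac")
  # 3: top-coverage site, depth 500 in sample 1
  i <- 50L; depth[i, 1L] <- 500L; maj[i, 1L] <- depth[i, 1L] - minr[i, 1L]
  fwd_maj[i, 1L] <- ceiling(maj[i, 1L] / 2L)
  plant(i, "high_coverage")
  # 4: mean end distance exactly 8.0 (fails the strict > 8 rule)
  i <- 70L; med_minr[i, ] <- 8
  plant(i, "placement_strand")
  # 5: fully strand-imbalanced minor allele
  i <- 90L; fwd_minr[i, ] <- 0L
  plant(i, "placement_strand")
  # 6: sites flanking a planted indel (radius 5): indel anchored 3 bp
  # after site 110 covers it; site 111 is 100 bp away and unaffected
  i <- 110L
  indels <- data.frame(chrom = "2L", pos = pos[i] + 3L, length = 2L)
  plant(i, "interval_mask")
  # 7: site inside a repeat interval
  i <- 130L
  repeats <- data.frame(chrom = "2L", start = pos[i] - 10L, end = pos[i] + 10L)
  plant(i, "interval_mask")
  planted <- do.call(rbind, planted)
  # assemble sync: minor allele C, major allele A everywhere (site 10's
  # equal split keeps A as major through the A<C tie rule)
  counts <- array(0L, dim = c(n_sites, n_samp, 6L),
                  dimnames = list(NULL, design$sample, SYNC_CATEGORIES))
  counts[, , "A"] <- maj
  counts[, , "C"] <- minr
  sync <- structure(list(chrom = chrom, pos = pos,
                         ref = rep("A", n_sites), counts = counts,
                         sample_names = design$sample),
                    class = "sync")
  meta <- rbind(
    data.frame(chrom = rep(chrom, n_samp), pos = rep(pos, n_samp),
               sample = rep(design$sample, each = n_sites), allele = "A",
               fwd = as.vector(fwd_maj), rev = as.vector(maj - fwd_maj),
               mean_end_dist = as.vector(med_maj), stringsAsFactors = FALSE),
    data.frame(chrom = rep(chrom, n_samp), pos = rep(pos, n_samp),
               sample = rep(design$sample, each = n_sites), allele = "C",
               fwd = as.vector(fwd_minr), rev = as.vector(minr - fwd_minr),
               mean_end_dist = as.vector(med_minr), stringsAsFactors = FALSE))
  meta <- meta[order(meta$pos, meta$sample, meta$allele), ]
  rownames(meta) <- NULL
  structure(list(sync = sync, meta = meta, design = design,
                 indels = indels, repeats = repeats, planted = planted,
                 expected_surviving = setdiff(pos, planted$pos)),
            class = "filter_fixture")
}

#' Read/write a design table TSV
#'
#' @param file Path to a tab-separated file with header columns `sample`,
#'   `population`, `replicate`, `pool` (one row per sync sample column, in
#'   order).
#' @return Data.frame accepted by [check_design()].
#' @export
read_design <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  check_design(d)
  d
}

#' @rdname read_design
#' @param design Design data.frame to write.
#' @export
write_design <- function(design, file) {
  utils::write.table(design, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(design)
}
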