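# Replicated light/dark association testing.
#
# The Cochran-Mantel-Haenszel (CMH) chi-square statistic, the
# Mantel-Haenszel common odds ratio with its Robins-Breslow-Greenland (RBG)
# confidence interval, hypergeometric count downsampling for cross-chromosome
# p-value comparability, and false-discovery control against an empirical
# null distribution.
#
# Stratum convention: each stratum is a 2x2 table with rows = pools
# (row 1 = light, row 2 = dark) and columns = alleles (allele1, allele2),
# i.e. ((a, b), (c, d)). The statistic is symmetric in this labelling; the
# odds ratio is reported for allele1 in row 1 versus row 2.

# Vectorised CMH core: a, b, c, d are n_sites x K matrices.
# Strata with n_k == 0 contribute nothing; n_k == 1 contributes its
# (zero-variance) expectation term.
.cmh_core <- function(a, b, c, d, correct = TRUE) {
  # double arithmetic: margin products overflow 32-bit integers
  storage.mode(a) <- storage.mode(b) <- "double"
  storage.mode(c) <- storage.mode(d) <- "double"
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  E <- ifelse(n > 0, r1 * c1 / n, 0)
  V <- ifelse(n > 1, r1 * r2 * c1 * c2 / (n^2 * (n - 1)), 0)
  sumV <- rowSums(V)
  dev <- abs(rowSums(a - E))
  cc <- if (correct) 0.5 else 0
  stat <- pmax(dev - cc, 0)^2 / sumV
  stat[sumV == 0] <- NA_real_
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  R <- ifelse(n > 0, a * d / n, 0)
  S <- ifelse(n > 0, b * c / n, 0)
  sumR <- rowSums(R); sumS <- rowSums(S)
  or_mh <- ifelse(sumS > 0, sumR / sumS, ifelse(sumR > 0, Inf, NA_real_))
  # RBG variance of log OR_MH
  P <- ifelse(n > 0, (a + d) / n, 0)
  Q <- ifelse(n > 0, (b + c) / n, 0)
  var_log <- rowSums(P * R) / (2 * sumR^2) +
    rowSums(P * S + Q * R) / (2 * sumR * sumS) +
    rowSums(Q * S) / (2 * sumS^2)
  se <- sqrt(var_log)
  z <- stats::qnorm(0.975)
  finite_or <- is.finite(or_mh) & or_mh > 0
  lo <- ifelse(finite_or, exp(log(or_mh) - z * se), NA_real_)
  hi <- ifelse(finite_or, exp(log(or_mh) + z * se), NA_real_)
  data.frame(statistic = stat, p_value = p, or_mh = or_mh,
             ci_low = lo, ci_high = hi, log_or = log(or_mh))
}

#' Cochran-Mantel-Haenszel test on stratified 2x2 allele-count tables
#'
#' Tests whether the allele distribution differs between the light and dark
#' pools consistently across replicates (strata). The statistic is
#' `(|sum_k (a_k - E[a_k])| - cc)^2 / sum_k Var(a_k)` with conditional
#' hypergeometric moments given the stratum margins and `cc = 0.5` when the
#' continuity correction is on; the p-value is the upper tail of a 1-df
#' chi-square. The common odds ratio is the Mantel-Haenszel estimator
#' `sum_k (a_k d_k / n_k) / sum_k (b_k c_k / n_k)` and its 95% confidence
#' interval uses the Robins-Breslow-Greenland variance of its logarithm.
#'
#' @param strata A `K x 2 x 2` array, a list of K `2 x 2` matrices, or a
#'   single `2 x 2` matrix. Rows are pools (light, dark), columns alleles.
#' @param correct Apply the 0.5 continuity correction (default `TRUE`,
#'   matching the correction applied by standard CMH implementations).
#' @return An object of class `"cmh_result"`: list with `statistic`,
#'   `p_value`, `or_mh`, `ci95` (length-2 vector; `NA` when the odds ratio
#'   is infinite or undefined), `log_or`, `K`, and `correct`.
#' @examples
#' cmh_test(list(matrix(c(12, 3, 5, 10), 2, byrow = TRUE),
#'               matrix(c(7, 8, 9, 6), 2, byrow = TRUE)))
#' @export
cmh_test <- function(strata, correct = TRUE) {
  if (is.matrix(strata) && all(dim(strata) == c(2L, 2L))) {
    strata <- list(strata)
  }
  if (is.list(strata)) {
    stopifnot(all(vapply(strata, function(m) all(dim(m) == c(2L, 2L)), TRUE)))
    a <- vapply(strata, function(m) m[1L, 1L], 0)
    b <- vapply(strata, function(m) m[1L, 2L], 0)
    cc_ <- vapply(strata, function(m) m[2L, 1L], 0)
    d <- vapply(strata, function(m) m[2L, 2L], 0)
  } else if (is.array(strata) && length(dim(strata)) == 3L) {
    stopifnot(all(dim(strata)[2:3] == 2L))
    a <- strata[, 1L, 1L]; b <- strata[, 1L, 2L]
    cc_ <- strata[, 2L, 1L]; d <- strata[, 2L, 2L]
  } else {
    stop("strata must be a 2x2 matrix, a list of 2x2 matrices, or a Kx2x2 array")
  }
  if (any(c(a, b, cc_, d) < 0)) stop("all stratum cells must be non-negative")
  res <- .cmh_core(matrix(a, 1L), matrix(b, 1L), matrix(cc_, 1L),
                   matrix(d, 1L), correct = correct)
  if (is.na(res$statistic)) {
    stop("all strata are degenerate (zero row or column margins); site untestable")
  }
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 or_mh = res$or_mh, ci95 = c(res$ci_low, res$ci_high),
                 log_or = res$log_or, K = length(a), correct = correct),
            class = "cmh_result")
}

#' @export
print.cmh_result <- function(x, ...) {
  cat(sprintf("CMH test (K = %d strata%s)\n", x$K,
              if (x$correct) ", continuity-corrected" else ""))
  cat(sprintf("  chi-square = %.4g (1 df), p = %.4g\n", x$statistic, x$p_value))
  cat(sprintf("  OR_MH = %.4g  [%.4g, %.4g]  log OR = %.4g\n",
              x$or_mh, x$ci95[1L], x$ci95[2L], x$log_or))
  invisible(x)
}

#' Vectorised CMH scan over many sites
#'
#' @param a,b,c,d Matrices of dimension `n_sites x K` holding the four cells
#'   of each stratum (`a`,`b` = light pool allele1/allele2; `c`,`d` = dark
#'   pool allele1/allele2).
#' @param correct Continuity correction flag as in [cmh_test()].
#' @return Data.frame with columns `statistic`, `p_value`, `or_mh`,
#'   `ci_low`, `ci_high`, `log_or`; rows with all-degenerate strata carry
#'   `NA`.
#' @export
cmh_scan <- function(a, b, c, d, correct = TRUE) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(c)),
            all(dim(a) == dim(d)))
  .cmh_core(a, b, c, d, correct = correct)
}

#' Downsample per-allele counts without replacement
#'
#' Draws `floor(total * fraction)` reads from the multiset of reads labelled
#' by allele (a multivariate hypergeometric draw), so the reduced counts sum
#' exactly to the target and the expected allele frequency is preserved.
#' `fraction = 1` returns the input unchanged; a zero total returns zeros.
#'
#' @param counts Non-negative integer vector of per-allele counts.
#' @param fraction Sampling fraction in `(0, 1]` (default 0.5, halving
#'   autosomal depth to match X-chromosome depth in males).
#' @return Integer vector of reduced counts, same length as `counts`.
#' @export
downsample_counts <- function(counts, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (fraction == 1 || total == 0L) return(counts)
  k <- floor(total * fraction)
  out <- integer(length(counts))
  remaining <- total
  to_draw <- k
  for (i in seq_along(counts)) {
    if (to_draw == 0L) break
    remaining_other <- remaining - counts[i]
    out[i] <- stats::rhyper(1L, counts[i], remaining_other, to_draw)
    to_draw <- to_draw - out[i]
    remaining <- remaining_other
  }
  out
}

# vectorised 2-allele downsampling: maj/minr are n x K matrices
.downsample_pair <- function(maj, minr, fraction) {
  total <- maj + minr
  k <- floor(total * fraction)
  a <- matrix(stats::rhyper(length(maj), maj, minr, k), nrow = nrow(maj))
  list(maj = a, minr = k - a)
}

#' Assemble per-replicate 2x2 strata for one biallelic site
#'
#' Builds the `K x 2 x 2` count array for [cmh_test()] from a biallelic site
#' and an experimental design, with rows (light, dark) and columns
#' (major allele, minor allele). For autosomal sites the counts feeding the
#' p-value pathway are downsampled to `fraction`; odds ratios and allele
#' frequencies must always be computed from the full counts.
#'
#' @param x A `"biallelic"` object.
#' @param site Site index into `x`.
#' @param design Data.frame with one row per sample (in sync column order)
#'   and columns `replicate` and `pool` (`"light"`/`"dark"`). Each replicate
#'   must have exactly one light and one dark pool.
#' @param downsample_fraction Autosomal downsampling fraction; `1` disables.
#' @param x_chroms Chromosome names exempt from downsampling (default
#'   `"X"`).
#' @return List with `full` (the `K x 2 x 2` array of full counts) and
#'   `pvalue_counts` (same shape, downsampled when the site is autosomal).
#' @export
assemble_strata <- function(x, site, design, downsample_fraction = 0.5,
                            x_chroms = "X") {
  stopifnot(inherits(x, "biallelic"))
  check_design(design, ncol(x$maj))
  reps <- unique(design$replicate)
  K <- length(reps)
  full <- array(0L, dim = c(K, 2L, 2L),
                dimnames = list(as.character(reps), c("light", "dark"),
                                c(x$major[site], x$minor[site])))
  for (k in seq_len(K)) {
    for (pool in c("light", "dark")) {
      sel <- design$replicate == reps[k] & design$pool == pool
      row <- if (pool == "light") 1L else 2L
      full[k, row, 1L] <- sum(x$maj[site, sel])
      full[k, row, 2L] <- sum(x$minr[site, sel])
    }
  }
  pv <- full
  if (!(x$chrom[site] %in% x_chroms) && downsample_fraction < 1) {
    for (k in seq_len(K)) {
      for (row in 1:2) {
        pv[k, row, ] <- downsample_counts(full[k, row, ], downsample_fraction)
      }
    }
  }
  list(full = full, pvalue_counts = pv)
}

#' Validate an experimental design table
#'
#' @param design Data.frame with columns `replicate` and `pool`; one row per
#'   sync sample column, in order. An optional `population` column is
#'   carried by the pipeline functions.
#' @param n_samples Expected number of samples.
#' @return The design, invisibly; errors describe the violation.
#' @export
check_design <- function(design, n_samples = NULL) {
  if (!all(c("replicate", "pool") %in% names(design))) {
    stop("design must have columns 'replicate' and 'pool'")
  }
  if (!is.null(n_samples) && nrow(design) != n_samples) {
    stop(sprintf("design has %d rows but the dataset has %d samples",
                 nrow(design), n_samples))
  }
  if (!all(design$pool %in% c("light", "dark"))) {
    stop("design 'pool' entries must be 'light' or 'dark'")
  }
  for (r in unique(design$replicate)) {
    pools <- design$pool[design$replicate == r]
    if (!all(c("light", "dark") %in% pools)) {
      stop(sprintf("replicate '%s' is missing a light or dark pool", r))
    }
  }
  invisible(design)
}

#' Genome scan: CMH association at every site
#'
#' Runs the replicated light/dark CMH contrast at each biallelic site.
#' P-values at autosomal sites are computed from counts downsampled to
#' `downsample_fraction` (sampling without replacement), making them
#' comparable to X-linked sites sequenced at half depth in males; odds
#' ratios, confidence intervals and the per-pool allele frequencies are
#' always computed from full counts. Sites whose downsampled total in some
#' pool falls below 1 read are dropped from the p-value pathway (`NA`).
#'
#' @param x A `"biallelic"` object (typically after filtering).
#' @param design Design table, see [check_design()].
#' @param correct Continuity correction flag.
#' @param downsample_fraction Autosomal downsampling fraction (default 0.5;
#'   `1` disables downsampling).
#' @param x_chroms Chromosomes exempt from downsampling.
#' @return Data.frame with one row per site: coordinates, alleles,
#'   `statistic`, `p_value` (downsampled pathway), `or_mh`, `ci_low`,
#'   `ci_high`, `log_or` (full counts), and per-replicate light/dark
#'   minor-allele frequencies.
#' @export
cmh_pipeline <- function(x, design, correct = TRUE,
                         downsample_fraction = 0.5, x_chroms = "X") {
  stopifnot(inherits(x, "biallelic"))
  check_design(design, ncol(x$maj))
  reps <- unique(design$replicate)
  K <- length(reps)
  n <- length(x$pos)
  # per-replicate pooled counts; columns = strata
  A <- B <- C <- D <- matrix(0L, n, K)
  freq <- matrix(NA_real_, n, 2L * K)
  fn <- character(2L * K)
  for (k in seq_len(K)) {
    sl <- design$replicate == reps[k] & design$pool == "light"
    sd_ <- design$replicate == reps[k] & design$pool == "dark"
    A[, k] <- rowSums(x$maj[, sl, drop = FALSE])
    B[, k] <- rowSums(x$minr[, sl, drop = FALSE])
    C[, k] <- rowSums(x$maj[, sd_, drop = FALSE])
    D[, k] <- rowSums(x$minr[, sd_, drop = FALSE])
    freq[, 2L * k - 1L] <- B[, k] / pmax(A[, k] + B[, k], 1L)
    freq[, 2L * k] <- D[, k] / pmax(C[, k] + D[, k], 1L)
    fn[2L * k - 1L] <- paste0("freq_light_", reps[k])
    fn[2L * k] <- paste0("freq_dark_", reps[k])
  }
  # effect sizes from full depth
  full <- .cmh_core(A, B, C, D, correct = correct)
  # p-values from the (autosome-downsampled) pathway
  auto <- !(x$chrom %in% x_chroms) & downsample_fraction < 1
  Ad <- A; Bd <- B; Cd <- C; Dd <- D
  if (any(auto)) {
    dl <- .downsample_pair(A[auto, , drop = FALSE], B[auto, , drop = FALSE],
                           downsample_fraction)
    dd <- .downsample_pair(C[auto, , drop = FALSE], D[auto, , drop = FALSE],
                           downsample_fraction)
    Ad[auto, ] <- dl$maj; Bd[auto, ] <- dl$minr
    Cd[auto, ] <- dd$maj; Dd[auto, ] <- dd$minr
  }
  pv <- .cmh_core(Ad, Bd, Cd, Dd, correct = correct)
  too_thin <- rowSums((Ad + Bd) < 1L) > 0L | rowSums((Cd + Dd) < 1L) > 0L
  pv$p_value[too_thin] <- NA_real_
  pv$statistic[too_thin] <- NA_real_
  out <- data.frame(chrom = x$chrom, pos = x$pos,
                    major = x$major, minor = x$minor,
                    statistic = pv$statistic, p_value = pv$p_value,
                    or_mh = full$or_mh, ci_low = full$ci_low,
                    ci_high = full$ci_high, log_or = full$log_or,
                    stringsAsFactors = FALSE)
  freq <- as.data.frame(freq)
  names(freq) <- fn
  cbind(out, freq)
}

#' False-discovery control against an empirical null
#'
#' Estimates, at each candidate threshold `t` (the sorted observed
#' p-values), `FDR(t) = (#\{null <= t\} * N_obs / N_null) / max(1, #\{obs <= t\})`
#' and returns the largest threshold with estimated FDR at most `q`.
#'
#' @param observed_p P-values from the real light/dark contrast.
#' @param null_p P-values from a contrast expected to carry no signal (see
#'   [null_contrast_same_pool()] and [null_within_pool_split()]).
#' @param q Target FDR level (default 0.05).
#' @return List of class `"fdr_result"`: `q`, `p_threshold` (`NA` when no
#'   threshold achieves the target; then `n_significant = 0`),
#'   `n_significant`, `estimated_fdr_at_threshold`.
#' @export
empirical_fdr <- function(observed_p, null_p, q = 0.05) {
  observed_p <- observed_p[!is.na(observed_p)]
  null_p <- null_p[!is.na(null_p)]
  if (length(observed_p) == 0L || length(null_p) == 0L) {
    stop("observed and null p-value vectors must be non-empty")
  }
  if (any(observed_p < 0 | observed_p > 1) || any(null_p < 0 | null_p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  thresholds <- sort(unique(observed_p))
  sorted_null <- sort(null_p)
  n_obs_le <- findInterval(thresholds, sort(observed_p))
  n_null_le <- findInterval(thresholds, sorted_null)
  scale <- length(observed_p) / length(null_p)
  fdr <- (n_null_le * scale) / pmax(1L, n_obs_le)
  ok <- which(fdr <= q)
  if (length(ok) == 0L) {
    res <- list(q = q, p_threshold = NA_real_, n_significant = 0L,
                estimated_fdr_at_threshold = NA_real_)
  } else {
    i <- max(ok)
    res <- list(q = q, p_threshold = thresholds[i],
                n_significant = n_obs_le[i],
                estimated_fdr_at_threshold = fdr[i])
  }
  structure(res, class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("empirical FDR at q = %g: threshold %s, %d significant (est. FDR %s)\n",
              x$q,
              if (is.na(x$p_threshold)) "none" else format(x$p_threshold),
              x$n_significant,
              if (is.na(x$estimated_fdr_at_threshold)) "-" else
                format(x$estimated_fdr_at_threshold)))
  invisible(x)
}

#' Null p-values from same-phenotype contrasts
#'
#' Builds an empirical null by contrasting pools of the same phenotype class
#' (light vs light, dark vs dark) across replicates: replicates are paired
#' within each pool class (1 vs 2, 3 vs 4, ...; an unpaired replicate is
#' dropped) and the paired pools are fed through the same CMH machinery as
#' the real contrast.
#'
#' @inheritParams cmh_pipeline
#' @param classes Which pool classes to pair (default both).
#' @return Numeric vector of null p-values (one per site per class with at
#'   least one pair).
#' @export
null_contrast_same_pool <- function(x, design, correct = TRUE,
                                    downsample_fraction = 0.5,
                                    x_chroms = "X",
                                    classes = c("light", "dark")) {
  stopifnot(inherits(x, "biallelic"))
  check_design(design, ncol(x$maj))
  out <- NULL
  for (cl in classes) {
    reps <- unique(design$replicate[design$pool == cl])
    n_pairs <- length(reps) %/% 2L
    if (n_pairs == 0L) next
    fake <- design
    keep_samples <- rep(FALSE, nrow(design))
    for (pr in seq_len(n_pairs)) {
      r1 <- reps[2L * pr - 1L]; r2 <- reps[2L * pr]
      s1 <- design$replicate == r1 & design$pool == cl
      s2 <- design$replicate == r2 & design$pool == cl
      fake$replicate[s1 | s2] <- paste0(cl, "_pair", pr)
      fake$pool[s1] <- "light"
      fake$pool[s2] <- "dark"
      keep_samples <- keep_samples | s1 | s2
    }
    fake <- fake[keep_samples, , drop = FALSE]
    xs <- x
    xs$maj <- x$maj[, keep_samples, drop = FALSE]
    xs$minr <- x$minr[, keep_samples, drop = FALSE]
    xs$other <- x$other[, keep_samples, drop = FALSE]
    xs$sample_names <- x$sample_names[keep_samples]
    res <- cmh_pipeline(xs, fake, correct = correct,
                        downsample_fraction = downsample_fraction,
                        x_chroms = x_chroms)
    out <- c(out, res$p_value)
  }
  out
}

#' Null p-values from random within-pool read splits
#'
#' Builds an empirical null by randomly splitting each pool's reads into two
#' halves (hypergeometric split of each allele's count) and contrasting the
#' halves as pseudo light/dark pools within each replicate.
#'
#' @inheritParams cmh_pipeline
#' @return Numeric vector of null p-values, one per site.
#' @export
null_within_pool_split <- function(x, design, correct = TRUE,
                                   downsample_fraction = 0.5,
                                   x_chroms = "X") {
  stopifnot(inherits(x, "biallelic"))
  check_design(design, ncol(x$maj))
  reps <- unique(design$replicate)
  K <- length(reps)
  n <- length(x$pos)
  A <- B <- C <- D <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    sel <- design$replicate == reps[k]  # both pools of the replicate
    mj <- rowSums(x$maj[, sel, drop = FALSE])
    mn <- rowSums(x$minr[, sel, drop = FALSE])
    half <- .downsample_pair(matrix(mj), matrix(mn), 0.5)
    A[, k] <- half$maj; B[, k] <- half$minr
    C[, k] <- mj - half$maj; D[, k] <- mn - half$minr
  }
  auto <- !(x$chrom %in% x_chroms) & downsample_fraction < 1
  if (any(auto)) {
    dl <- .downsample_pair(A[auto, , drop = FALSE], B[auto, , drop = FALSE],
                           downsample_fraction)
    dd <- .downsample_pair(C[auto, , drop = FALSE], D[auto, , drop = FALSE],
                           downsample_fraction)
    A[auto, ] <- dl$maj; B[auto, ] <- dl$minr
    C[auto, ] <- dd$maj; D[auto, ] <- dd$minr
  }
  .cmh_core(A, B, C, D, correct = correct)$p_value
}
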