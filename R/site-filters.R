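# Site-inclusion rules applied before association testing: per-sample
# coverage, per-population minor allele count, removal of the most highly
# covered sites, read-placement and strand-bias checks, and masking of
# indel neighborhoods and repeat intervals.
#
# Rules are evaluated in a fixed order (coverage -> mac -> high_coverage ->
# placement/strand -> mask) so that failure attribution is reproducible.

#' Filter thresholds for site inclusion
#'
#' Defaults follow the filtering regime of replicated extreme-pool
#' pigmentation GWAS: per-sample coverage of at least 15 reads, at least 8
#' copies of the minor allele in each population, exclusion of the 2% most
#' highly covered sites (per sample), supporting reads on average more than
#' 8 bases from the read end, a strand-balance ratio of at least 0.1, a
#' two-sided Fisher strand-balance p above 0.01, and a 5-bp mask on either
#' side of indels.
#'
#' @param min_coverage_per_sample Minimum total site depth per sample.
#' @param min_minor_count_per_population Minimum summed minor-allele count in
#'   every population.
#' @param high_coverage_quantile Per-sample empirical coverage quantile above
#'   which sites are excluded (in `(0, 1]`; `1` disables the rule).
#' @param min_mean_end_distance Supporting reads must lie on average strictly
#'   more than this many bases from the nearer read end.
#' @param strand_ratio_threshold Threshold for the strand-balance ratio of
#'   minor-allele reads.
#' @param strand_fisher_p_threshold Sites fail the strand rule only if both
#'   the ratio condition fails and the Fisher strand-balance p-value is at or
#'   below this threshold.
#' @param indel_mask_radius Bases masked up- and downstream of an indel.
#' @param strand_ratio_aggregator `"min"` (default) requires
#'   `min(fwd/rev, rev/fwd)` above the threshold, i.e. neither strand in
#'   worse than 10:1 deficit at the default threshold. `"max"` reproduces the
#'   literal published clause `max(fwd/rev, rev/fwd) > 0.1`, which is
#'   satisfied by every table with any nonzero count and thus never fails.
#' @param coverage_categories Count categories contributing to coverage
#'   (default: all six, including N and deletions).
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_coverage_per_sample = 15L,
                          min_minor_count_per_population = 8L,
                          high_coverage_quantile = 0.98,
                          min_mean_end_distance = 8,
                          strand_ratio_threshold = 0.1,
                          strand_fisher_p_threshold = 0.01,
                          indel_mask_radius = 5L,
                          strand_ratio_aggregator = c("min", "max"),
                          coverage_categories = SYNC_CATEGORIES) {
  strand_ratio_aggregator <- match.arg(strand_ratio_aggregator)
  cfg <- list(min_coverage_per_sample = min_coverage_per_sample,
              min_minor_count_per_population = min_minor_count_per_population,
              high_coverage_quantile = high_coverage_quantile,
              min_mean_end_distance = min_mean_end_distance,
              strand_ratio_threshold = strand_ratio_threshold,
              strand_fisher_p_threshold = strand_fisher_p_threshold,
              indel_mask_radius = indel_mask_radius,
              strand_ratio_aggregator = strand_ratio_aggregator,
              coverage_categories = coverage_categories)
  num <- c("min_coverage_per_sample", "min_minor_count_per_population",
           "min_mean_end_distance", "strand_ratio_threshold",
           "strand_fisher_p_threshold", "indel_mask_radius")
  if (any(unlist(cfg[num]) < 0)) stop("filter thresholds must be non-negative")
  if (high_coverage_quantile <= 0 || high_coverage_quantile > 1) {
    stop("high_coverage_quantile must be in (0, 1]")
  }
  class(cfg) <- "filter_config"
  cfg
}

#' Coverage and minor-allele-count filter
#'
#' A site passes when every sample's coverage is at least
#' `min_coverage_per_sample` and, within each population, the summed count
#' of the site's (dataset-wide) minor allele is at least
#' `min_minor_count_per_population`. Both bounds are inclusive.
#'
#' @param x A `"biallelic"` object.
#' @param coverage Coverage matrix from [sync_coverage()] restricted to the
#'   same sites as `x`.
#' @param populations Character or factor vector assigning each sample to a
#'   population.
#' @param cfg A [filter_config()].
#' @return Logical pass vector, one entry per site.
#' @export
coverage_mac_filter <- function(x, coverage, populations, cfg = filter_config()) {
  stopifnot(inherits(x, "biallelic"))
  n_samp <- ncol(x$maj)
  if (length(populations) != n_samp || anyNA(populations)) {
    stop("every sample must be assigned to exactly one population")
  }
  if (nrow(coverage) != length(x$pos)) {
    stop("coverage matrix does not match the site set")
  }
  cov_ok <- rowSums(coverage < cfg$min_coverage_per_sample) == 0L
  mac_ok <- rep(TRUE, length(x$pos))
  for (p in unique(populations)) {
    sel <- populations == p
    mac_ok <- mac_ok &
      rowSums(x$minr[, sel, drop = FALSE]) >= cfg$min_minor_count_per_population
  }
  cov_ok & mac_ok
}

#' Per-sample coverage cutoffs for the high-coverage rule
#'
#' Computes the empirical `high_coverage_quantile` of each sample's coverage
#' over the whole dataset (inverse-ECDF quantile, `type = 1`).
#'
#' @inheritParams coverage_mac_filter
#' @return Numeric vector of per-sample cutoffs.
#' @export
high_coverage_cutoffs <- function(coverage, cfg = filter_config()) {
  apply(coverage, 2L, stats::quantile,
        probs = cfg$high_coverage_quantile, type = 1L, names = FALSE)
}

#' High-coverage site filter
#'
#' Excludes a site when any sample's coverage strictly exceeds that sample's
#' dataset-wide quantile cutoff (default: the 98th percentile, i.e. the 2%
#' most highly covered sites per sample are removed). With fewer than 50
#' sites the quantile is ill-defined and all sites pass with a warning.
#'
#' @inheritParams coverage_mac_filter
#' @return Logical pass vector, one entry per site.
#' @export
high_coverage_filter <- function(coverage, cfg = filter_config()) {
  if (nrow(coverage) < 50L) {
    warning("fewer than 50 sites: high-coverage filter skipped")
    return(rep(TRUE, nrow(coverage)))
  }
  cut <- high_coverage_cutoffs(coverage, cfg)
  rowSums(sweep(coverage, 2L, cut, ">")) == 0L
}

# strand-balance ratio with the conventions 0/x = 0 and x/0 = Inf (x > 0);
# a 0/0 table yields 0 under "min" so that alleles without reads fail
.strand_ratio <- function(fwd, rev, aggregator) {
  r1 <- ifelse(fwd == 0, 0, ifelse(rev == 0, Inf, fwd / rev))
  r2 <- ifelse(rev == 0, 0, ifelse(fwd == 0, Inf, rev / fwd))
  if (aggregator == "min") pmin(r1, r2) else pmax(r1, r2)
}

#' Read-placement and strand-bias filter
#'
#' A site passes when the mean distance of supporting base calls from the
#' nearer read end is strictly above `min_mean_end_distance` for both
#' alleles, and the strand condition holds: either the strand-balance ratio
#' of the minor (variant-supporting) allele exceeds
#' `strand_ratio_threshold`, or the two-sided Fisher exact p-value on the
#' 2x2 table {major, minor} x {forward, reverse} exceeds
#' `strand_fisher_p_threshold`.
#'
#' @param x A `"biallelic"` object.
#' @param meta Metadata data.frame as from [read_site_metadata()]. Counts and
#'   end distances are aggregated over samples per allele (distances weighted
#'   by supporting depth).
#' @param cfg A [filter_config()].
#' @return Logical vector, one entry per site; `NA` marks sites without
#'   metadata for both alleles (untestable, never silently passed).
#' @export
placement_strand_filter <- function(x, meta, cfg = filter_config()) {
  stopifnot(inherits(x, "biallelic"))
  key_site <- paste(x$chrom, x$pos)
  key_meta <- paste(meta$chrom, meta$pos)
  pass <- rep(NA, length(x$pos))
  meta_split <- split(meta, key_meta)
  for (i in seq_along(x$pos)) {
    ms <- meta_split[[key_site[i]]]
    if (is.null(ms)) next
    mj <- ms[ms$allele == x$major[i], , drop = FALSE]
    mn <- ms[ms$allele == x$minor[i], , drop = FALSE]
    if (nrow(mj) == 0L || nrow(mn) == 0L) next
    agg <- function(d) {
      w <- d$fwd + d$rev
      med <- if (sum(w) > 0) sum(d$mean_end_dist * w) / sum(w) else 0
      c(fwd = sum(d$fwd), rev = sum(d$rev), med = med)
    }
    a_mj <- agg(mj); a_mn <- agg(mn)
    dist_ok <- a_mj[["med"]] > cfg$min_mean_end_distance &&
      a_mn[["med"]] > cfg$min_mean_end_distance
    ratio <- .strand_ratio(a_mn[["fwd"]], a_mn[["rev"]],
                           cfg$strand_ratio_aggregator)
    strand_ok <- ratio > cfg$strand_ratio_threshold
    if (!strand_ok) {
      tab <- matrix(c(a_mj[["fwd"]], a_mj[["rev"]],
                      a_mn[["fwd"]], a_mn[["rev"]]), nrow = 2L, byrow = TRUE)
      fp <- stats::fisher.test(tab)$p.value
      strand_ok <- fp > cfg$strand_fisher_p_threshold
    }
    pass[i] <- dist_ok && strand_ok
  }
  pass
}

#' Mask sites in indel neighborhoods and repeat intervals
#'
#' Removes sites lying within `indel_mask_radius` bases of an indel's
#' reference footprint (`[pos - radius, pos + length + radius]`, inclusive:
#' an indel anchored at `pos` with footprint length `len` disturbs
#' alignment up to `pos + len`) or inside any repeat interval.
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param indels Data.frame with `chrom`, `pos` (1-based anchor) and
#'   optionally `length` (reference footprint, default 1), or `NULL`.
#' @param repeats Data.frame with `chrom`, `start`, `end` (1-based closed,
#'   e.g. from [read_bed()]), or `NULL`.
#' @param cfg A [filter_config()].
#' @return Logical vector: `TRUE` for sites that survive the mask.
#' @export
mask_intervals <- function(chrom, pos, indels = NULL, repeats = NULL,
                           cfg = filter_config()) {
  keep <- rep(TRUE, length(pos))
  iv <- NULL
  if (!is.null(indels) && nrow(indels) > 0L) {
    len <- if ("length" %in% names(indels)) indels$length else rep(1L, nrow(indels))
    iv <- data.frame(chrom = indels$chrom,
                     start = indels$pos - cfg$indel_mask_radius,
                     end = indels$pos + len + cfg$indel_mask_radius)
  }
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    iv <- rbind(iv, repeats[, c("chrom", "start", "end")])
  }
  if (is.null(iv) || nrow(iv) == 0L) return(keep)
  for (ch in unique(iv$chrom)) {
    ii <- iv[iv$chrom == ch, , drop = FALSE]
    ii <- ii[order(ii$start), , drop = FALSE]
    # merge overlapping intervals so findInterval logic is valid
    merged_start <- ii$start[1L]; merged_end <- ii$end[1L]
    ms <- c(); me <- c()
    for (k in seq_len(nrow(ii))[-1L]) {
      if (ii$start[k] <= merged_end + 1L) {
        merged_end <- max(merged_end, ii$end[k])
      } else {
        ms <- c(ms, merged_start); me <- c(me, merged_end)
        merged_start <- ii$start[k]; merged_end <- ii$end[k]
      }
    }
    ms <- c(ms, merged_start); me <- c(me, merged_end)
    sel <- chrom == ch
    hit <- findInterval(pos[sel], ms)
    inside <- hit > 0L & pos[sel] <= me[pmax(hit, 1L)]
    keep[which(sel)[inside]] <- FALSE
  }
  keep
}

#' Apply the full site-filter cascade
#'
#' Evaluates the rules in the fixed order coverage, minor allele count,
#' high coverage, placement/strand (skipped when no metadata is supplied),
#' interval mask, and attributes each failing site to the first rule it
#' fails.
#'
#' @param x A `"biallelic"` object.
#' @param coverage Coverage matrix matching `x` (from [sync_coverage()],
#'   subset to the sites of `x`).
#' @param populations Per-sample population labels.
#' @param meta Optional metadata data.frame ([read_site_metadata()] layout).
#'   Sites lacking metadata fail with rule `"no_metadata"`.
#' @param indels,repeats Optional mask inputs (see [mask_intervals()]).
#' @param cfg A [filter_config()].
#' @return A list of class `"filter_report"`: `pass` (logical per site),
#'   `first_fail` (rule name or `NA`), `tally` (named failure counts), and
#'   `surviving` (site indices).
#' @export
apply_filters <- function(x, coverage, populations, meta = NULL,
                          indels = NULL, repeats = NULL,
                          cfg = filter_config()) {
  n <- length(x$pos)
  first_fail <- rep(NA_character_, n)
  note <- function(ok, rule) {
    new_fail <- is.na(first_fail) & !ok
    first_fail[new_fail] <<- rule
  }
  cov_ok <- rowSums(coverage < cfg$min_coverage_per_sample) == 0L
  note(cov_ok, "min_coverage")
  mac_ok <- rep(TRUE, n)
  for (p in unique(populations)) {
    sel <- populations == p
    mac_ok <- mac_ok &
      rowSums(x$minr[, sel, drop = FALSE]) >= cfg$min_minor_count_per_population
  }
  note(mac_ok, "min_mac")
  hc_ok <- high_coverage_filter(coverage, cfg)
  note(hc_ok, "high_coverage")
  if (!is.null(meta)) {
    ps <- placement_strand_filter(x, meta, cfg)
    note(!is.na(ps), "no_metadata")
    note(is.na(ps) | ps, "placement_strand")
  }
  mask_ok <- mask_intervals(x$chrom, x$pos, indels, repeats, cfg)
  note(mask_ok, "interval_mask")
  pass <- is.na(first_fail)
  tally <- table(factor(first_fail[!pass],
                        levels = c("min_coverage", "min_mac", "high_coverage",
                                   "no_metadata", "placement_strand",
                                   "interval_mask")))
  structure(list(pass = pass, first_fail = first_fail,
                 tally = c(tally), surviving = which(pass)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: %d of %d sites pass\n",
              sum(x$pass), length(x$pass)))
  for (r in names(x$tally)) {
    if (x$tally[[r]] > 0) cat(sprintf("  %-18s %d\n", r, x$tally[[r]]))
  }
  invisible(x)
}
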