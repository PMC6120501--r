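# Frequencies of marker-defined entities in pools.
#
# A set of diagnostic marker SNPs (e.g. the 62 inversion-specific SNPs of
# In(3R)Payne, or species-diagnostic fixed differences used to quantify
# contamination) tags an entity whose pool frequency is estimated as the
# median of the per-marker diagnostic-allele frequencies. Inversion
# association with the light/dark contrast is then tested with a linear
# model on the arcsine-square-root scale.

#' Construct a marker set
#'
#' @param name Name of the tagged entity (e.g. `"In(3R)Payne"`).
#' @param markers Data.frame with columns `chrom`, `pos`, `allele` (the
#'   diagnostic base, one of A/C/G/T). Positions must be unique.
#' @return List of class `"marker_set"`.
#' @export
marker_set <- function(name, markers) {
  need <- c("chrom", "pos", "allele")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns chrom, pos, allele")
  }
  if (nrow(markers) == 0L) stop("marker set must be non-empty")
  if (anyDuplicated(paste(markers$chrom, markers$pos))) {
    stop("marker positions must be unique")
  }
  if (!all(markers$allele %in% c("A", "C", "G", "T"))) {
    stop("diagnostic alleles must be A, C, G or T")
  }
  structure(list(name = name, markers = markers[need]), class = "marker_set")
}

#' Read a marker TSV (inversion, chrom, pos, allele)
#'
#' @param file Tab-separated file with header columns `inversion` (or
#'   `name`), `chrom`, `pos`, `allele`.
#' @return Named list of `"marker_set"` objects, one per inversion.
#' @export
read_marker_sets <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if ("inversion" %in% names(tab)) tab$name <- tab$inversion
  sets <- lapply(split(tab, tab$name), function(d) {
    marker_set(d$name[1L], d[, c("chrom", "pos", "allele")])
  })
  sets
}

#' Median marker frequency of an entity in each pool
#'
#' For every sample (pool), computes per covered marker the frequency of the
#' diagnostic allele (diagnostic count over the site's A+C+G+T depth) and
#' summarises by the median (mean of the central two values for an even
#' marker count). Markers with zero base coverage in a pool are skipped, not
#' imputed.
#'
#' @param sync A `"sync"` object containing the marker positions.
#' @param set A [marker_set()].
#' @param samples Sample indices or names (default: all).
#' @return Data.frame of class `"marker_freq"` with one row per pool:
#'   `sample`, `median_frequency`, `n_markers_used`; the per-marker
#'   frequency matrix (markers x pools) is attached as attribute
#'   `"per_marker"` for audit.
#' @export
marker_median_frequency <- function(sync, set, samples = NULL) {
  stopifnot(inherits(sync, "sync"), inherits(set, "marker_set"))
  if (is.null(samples)) samples <- seq_along(sync$sample_names)
  if (is.character(samples)) samples <- match(samples, sync$sample_names)
  key_sync <- paste(sync$chrom, sync$pos)
  idx <- match(paste(set$markers$chrom, set$markers$pos), key_sync)
  covered <- !is.na(idx)
  if (!any(covered)) stop(sprintf("no marker of '%s' is present in the data", set$name))
  mk <- set$markers[covered, , drop = FALSE]
  idx <- idx[covered]
  base_counts <- sync$counts[idx, samples, c("A", "T", "C", "G"), drop = FALSE]
  depth <- apply(base_counts, c(1L, 2L), sum)
  diag_count <- matrix(0L, length(idx), length(samples))
  for (i in seq_along(idx)) {
    diag_count[i, ] <- sync$counts[idx[i], samples, mk$allele[i]]
  }
  per_marker <- ifelse(depth > 0, diag_count / depth, NA_real_)
  rownames(per_marker) <- paste(mk$chrom, mk$pos, sep = ":")
  colnames(per_marker) <- sync$sample_names[samples]
  med <- apply(per_marker, 2L, function(f) stats::median(f, na.rm = TRUE))
  n_used <- colSums(!is.na(per_marker))
  if (any(n_used == 0L)) {
    stop(sprintf("no covered marker of '%s' in pool(s): %s", set$name,
                 paste(colnames(per_marker)[n_used == 0L], collapse = ", ")))
  }
  out <- data.frame(sample = sync$sample_names[samples],
                    median_frequency = unname(med),
                    n_markers_used = unname(n_used),
                    stringsAsFactors = FALSE)
  attr(out, "per_marker") <- per_marker
  attr(out, "name") <- set$name
  class(out) <- c("marker_freq", "data.frame")
  out
}

#' Arcsine-square-root transform of a frequency
#'
#' The variance-stabilising transform `asin(sqrt(f))`, mapping `[0, 1]` to
#' `[0, pi/2]`.
#'
#' @param f Frequencies in `[0, 1]`.
#' @return Transformed values.
#' @export
arcsine_sqrt <- function(f) {
  if (any(is.na(f)) || any(f < 0 | f > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  asin(sqrt(f))
}

#' Test inversion association with the extreme-pool contrast
#'
#' Fits, by ordinary least squares, the arcsine-square-root transformed pool
#' frequencies on the categorical predictors population and pool
#' (treatment coding, light as reference; the pool coefficient's two-sided
#' t-test p-value is coding-invariant for a binary factor). The pool
#' coefficient's p-value is Bonferroni-corrected over `family_size`
#' inversions tested.
#'
#' @param freqs Data.frame with columns `frequency` (raw pool frequency in
#'   `[0, 1]`), `population`, and `pool` (`"light"`/`"dark"`); one row per
#'   pool.
#' @param family_size Number of inversions in the tested family (default 7,
#'   the cosmopolitan inversions usually screened together).
#' @return List of class `"inversion_fit"`: `coefficients`, `pool_p_value`,
#'   `bonferroni_adjusted_p`, `family_size`, and the underlying `lm` fit.
#' @export
inversion_association <- function(freqs, family_size = 7L) {
  need <- c("frequency", "population", "pool")
  if (!all(need %in% names(freqs))) {
    stop("freqs must have columns frequency, population, pool")
  }
  if (!all(freqs$pool %in% c("light", "dark"))) {
    stop("pool entries must be 'light' or 'dark'")
  }
  for (cl in c("light", "dark")) {
    if (sum(freqs$pool == cl) < 2L) {
      stop(sprintf("need at least 2 pools of class '%s'", cl))
    }
  }
  d <- data.frame(y = arcsine_sqrt(freqs$frequency),
                  population = factor(freqs$population),
                  pool = factor(freqs$pool, levels = c("light", "dark")))
  fit <- stats::lm(y ~ population + pool, data = d)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    stop("design matrix is rank deficient")
  }
  coefs <- summary(fit)$coefficients
  pool_row <- grep("^pool", rownames(coefs))
  p <- coefs[pool_row, "Pr(>|t|)"]
  structure(list(coefficients = stats::coef(fit),
                 pool_coefficient = unname(stats::coef(fit)[pool_row]),
                 pool_p_value = unname(p),
                 bonferroni_adjusted_p = min(1, unname(p) * family_size),
                 family_size = family_size,
                 fit = fit),
            class = "inversion_fit")
}

#' @export
print.inversion_fit <- function(x, ...) {
  cat(sprintf("inversion association: pool(dark) coefficient %.4g, p = %.4g (Bonferroni x%d: %.4g)\n",
              x$pool_coefficient, x$pool_p_value, x$family_size,
              x$bonferroni_adjusted_p))
  invisible(x)
}
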