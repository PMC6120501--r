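# Synchronized ("sync") pooled allele-count input/output and the biallelic
# site representation consumed by the filters and the association test.
#
# Coordinates are 1-based and fully closed throughout; BED inputs (0-based,
# half-open) are converted at the boundary by read_bed().

#' Order of the six count categories in a sync field
#'
#' A sync line carries one colon-separated field of six counts per sample, in
#' the fixed popoolation2 order A:T:C:G:N:deletion. This constant names the
#' columns of the per-sample count slices used throughout the package.
#'
#' @format Character vector of length 6.
#' @export
SYNC_CATEGORIES <- c("A", "T", "C", "G", "N", "del")

#' Read a synchronized pooled allele-count file
#'
#' Parses the tab-separated sync format (one line per site: chromosome,
#' 1-based position, reference base, then one `A:T:C:G:N:del` count field per
#' sample). Lines starting with `#` are skipped. Plain and gzip-compressed
#' files are both accepted.
#'
#' @param file Path to a sync file (optionally gzip-compressed) or a
#'   connection.
#' @param sample_names Optional character vector naming the sample columns;
#'   defaults to `sample1..sampleN`.
#' @return An object of class `"sync"`: a list with `chrom`, `pos`, `ref`
#'   (per-site vectors), and `counts`, an integer array of dimension
#'   `n_sites x n_samples x 6` with category order [SYNC_CATEGORIES].
#' @export
read_sync <- function(file, sample_names = NULL) {
  if (inherits(file, "connection")) {
    lines <- readLines(file)
  } else {
    con <- gzfile(file, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  }
  line_no <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (length(lines) == 0L) {
    stop("sync input contains no data lines")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1L]
    stop(sprintf("sync line %d: expected at least 4 tab-separated fields, got %d",
                 line_no[bad], nf[bad]))
  }
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("sync line %d: inconsistent sample count (%d fields, expected %d)",
                 line_no[bad], nf[bad], nf[1L]))
  }
  n_samples <- nf[1L] - 3L
  m <- matrix(unlist(fields), ncol = nf[1L], byrow = TRUE)
  chrom <- m[, 1L]
  pos <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- which(is.na(pos) | pos < 1L)[1L]
    stop(sprintf("sync line %d: invalid position '%s'", line_no[bad], m[bad, 2L]))
  }
  ref <- toupper(m[, 3L])
  bad_ref <- !(ref %in% c("A", "C", "G", "T", "N"))
  if (any(bad_ref)) {
    bad <- which(bad_ref)[1L]
    stop(sprintf("sync line %d: invalid reference base '%s'", line_no[bad], m[bad, 3L]))
  }
  counts <- array(NA_integer_, dim = c(length(lines), n_samples, 6L),
                  dimnames = list(NULL, NULL, SYNC_CATEGORIES))
  for (j in seq_len(n_samples)) {
    parts <- strsplit(m[, 3L + j], ":", fixed = TRUE)
    np <- lengths(parts)
    if (any(np != 6L)) {
      bad <- which(np != 6L)[1L]
      stop(sprintf("sync line %d, sample %d: count field '%s' does not have 6 entries",
                   line_no[bad], j, m[bad, 3L + j]))
    }
    vals <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(vals) || any(vals < 0L)) {
      flat_bad <- which(is.na(vals) | vals < 0L)[1L]
      bad <- (flat_bad - 1L) %/% 6L + 1L
      stop(sprintf("sync line %d, sample %d: non-integer or negative count in '%s'",
                   line_no[bad], j, m[bad, 3L + j]))
    }
    counts[, j, ] <- matrix(vals, ncol = 6L, byrow = TRUE)
  }
  if (is.null(sample_names)) {
    sample_names <- paste0("sample", seq_len(n_samples))
  }
  stopifnot(length(sample_names) == n_samples)
  dimnames(counts)[[2L]] <- sample_names
  structure(list(chrom = chrom, pos = pos, ref = ref, counts = counts,
                 sample_names = sample_names),
            class = "sync")
}

#' Write a sync object to a file
#'
#' Inverse of [read_sync()]; `write_sync(read_sync(f), g)` reproduces a
#' canonical file `f` byte-identically.
#'
#' @param x A `"sync"` object.
#' @param file Output path or connection.
#' @export
write_sync <- function(x, file) {
  stopifnot(inherits(x, "sync"))
  n_samples <- dim(x$counts)[2L]
  sample_fields <- vapply(seq_len(n_samples), function(j) {
    cnt <- x$counts[, j, , drop = FALSE]
    apply(matrix(cnt, ncol = 6L), 1L, paste, collapse = ":")
  }, character(length(x$pos)))
  sample_fields <- matrix(sample_fields, ncol = n_samples)
  lines <- paste(x$chrom, x$pos, x$ref,
                 apply(sample_fields, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, file)
  invisible(x)
}

#' Per-sample site coverage
#'
#' Coverage of a site in a sample is the sum over count categories. By
#' default all six categories (including N and deletion) contribute, because
#' read depth at the site includes those calls; set `categories` to
#' `c("A","T","C","G")` for base-only coverage.
#'
#' @param x A `"sync"` object.
#' @param categories Which of [SYNC_CATEGORIES] to sum (default all six).
#' @return Integer matrix `n_sites x n_samples`.
#' @export
sync_coverage <- function(x, categories = SYNC_CATEGORIES) {
  stopifnot(inherits(x, "sync"))
  categories <- match.arg(categories, SYNC_CATEGORIES, several.ok = TRUE)
  cov <- apply(x$counts[, , categories, drop = FALSE], c(1L, 2L), sum)
  dimnames(cov) <- list(NULL, x$sample_names)
  cov
}

#' Number of sites in a sync or biallelic object
#' @param x A `"sync"` or `"biallelic"` object.
#' @return Integer site count.
#' @export
n_sites <- function(x) length(x$pos)

# fixed base order used for tie-breaking in biallelic calling
.BASE_ORDER <- c("A", "C", "G", "T")

#' Reduce sync sites to their two most frequent alleles
#'
#' For every site, the major and minor allele are the two bases (A/C/G/T
#' only; N and deletion never qualify) with the largest counts summed across
#' samples, ties broken by the fixed base order A < C < G < T. Depth in the
#' remaining categories is retained per sample in `other`, so downstream
#' filters can reject sites with substantial third-allele depth.
#'
#' @param x A `"sync"` object.
#' @param drop_monomorphic If `TRUE` (default), sites with fewer than two
#'   segregating bases are dropped (their indices are recorded in the
#'   `monomorphic` attribute); if `FALSE`, any such site is an error.
#' @return An object of class `"biallelic"`: list with `chrom`, `pos`, `ref`,
#'   `major`, `minor` (per-site), `maj` and `minr` (count matrices
#'   `n_sites x n_samples`), `other` (remaining per-sample depth), and
#'   `sample_names`. Attribute `monomorphic` holds the original indices of
#'   dropped sites.
#' @export
call_biallelic <- function(x, drop_monomorphic = TRUE) {
  stopifnot(inherits(x, "sync"))
  base_counts <- x$counts[, , .BASE_ORDER, drop = FALSE]  # reorders to A,C,G,T
  tot <- apply(base_counts, c(1L, 3L), sum)               # n_sites x 4
  n <- nrow(tot)
  # ranks within each row; max.first ties => earlier base (A<C<G<T) wins
  ord1 <- max.col(tot, ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(n), ord1)] <- -1L
  ord2 <- max.col(tot2, ties.method = "first")
  mono <- tot[cbind(seq_len(n), ord2)] <= 0L | rowSums(tot > 0L) < 2L
  if (any(mono) && !drop_monomorphic) {
    stop(sprintf("site %s:%d is monomorphic (fewer than two segregating bases)",
                 x$chrom[which(mono)[1L]], x$pos[which(mono)[1L]]))
  }
  keep <- which(!mono)
  n_samples <- dim(x$counts)[2L]
  idx <- function(ord) {
    # extract counts[site, sample, ord[site]] as a matrix
    out <- matrix(0L, length(keep), n_samples)
    for (j in seq_len(n_samples)) {
      out[, j] <- base_counts[cbind(keep, j, ord[keep])]
    }
    out
  }
  maj <- idx(ord1)
  minr <- idx(ord2)
  total <- apply(x$counts[keep, , , drop = FALSE], c(1L, 2L), sum)
  other <- total - maj - minr
  dimnames(maj) <- dimnames(minr) <- dimnames(other) <- list(NULL, x$sample_names)
  structure(list(chrom = x$chrom[keep], pos = x$pos[keep], ref = x$ref[keep],
                 major = .BASE_ORDER[ord1[keep]], minor = .BASE_ORDER[ord2[keep]],
                 maj = maj, minr = minr, other = other,
                 sample_names = x$sample_names),
            class = "biallelic", monomorphic = which(mono))
}

#' Minor-allele frequency of biallelic sites
#'
#' Frequency is the minor-allele count over the major+minor count, summed
#' across the chosen samples, always at full (never downsampled) depth.
#'
#' @param x A `"biallelic"` object.
#' @param samples Sample indices or names to pool (default: all samples).
#' @param sites Site indices (default: all).
#' @return Numeric vector of frequencies in `[0, 1]`, one per site.
#' @export
allele_frequency <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "biallelic"))
  if (is.null(samples)) samples <- seq_along(x$sample_names)
  if (is.character(samples)) samples <- match(samples, x$sample_names)
  if (anyNA(samples)) stop("unknown sample in 'samples'")
  if (is.null(sites)) sites <- seq_along(x$pos)
  mj <- rowSums(x$maj[sites, samples, drop = FALSE])
  mn <- rowSums(x$minr[sites, samples, drop = FALSE])
  depth <- mj + mn
  if (any(depth == 0)) {
    bad <- sites[which(depth == 0)[1L]]
    stop(sprintf("site %s:%d has zero major+minor depth over the selected samples",
                 x$chrom[bad], x$pos[bad]))
  }
  mn / depth
}

#' Subset a biallelic object by site
#' @param x A `"biallelic"` object.
#' @param i Site indices or a logical vector.
#' @return A `"biallelic"` object restricted to the selected sites.
#' @export
subset_sites <- function(x, i) {
  stopifnot(inherits(x, "biallelic"))
  structure(list(chrom = x$chrom[i], pos = x$pos[i], ref = x$ref[i],
                 major = x$major[i], minor = x$minor[i],
                 maj = x$maj[i, , drop = FALSE], minr = x$minr[i, , drop = FALSE],
                 other = x$other[i, , drop = FALSE],
                 sample_names = x$sample_names),
            class = "biallelic")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync dataset: %d sites, %d samples (%s)\n",
              length(x$pos), dim(x$counts)[2L],
              paste(utils::head(x$sample_names, 4L), collapse = ", ")))
  invisible(x)
}

#' @export
print.biallelic <- function(x, ...) {
  cat(sprintf("biallelic sites: %d sites, %d samples\n",
              length(x$pos), ncol(x$maj)))
  invisible(x)
}

#' Read a per-site read-placement/strand metadata sidecar
#'
#' Tab-separated with header: `chrom, pos, sample, allele, fwd, rev,
#' mean_end_dist`. `fwd`/`rev` are forward- and reverse-strand counts of
#' reads supporting the allele; `mean_end_dist` is the mean distance of the
#' supporting base calls from the nearer read end.
#'
#' @param file Path to the TSV.
#' @return A data.frame with those columns.
#' @export
read_site_metadata <- function(file) {
  meta <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "sample", "allele", "fwd", "rev", "mean_end_dist")
  if (!all(need %in% names(meta))) {
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(meta$fwd < 0 | meta$rev < 0 | meta$mean_end_dist < 0)) {
    stop("metadata counts and distances must be non-negative")
  }
  meta[need]
}

#' Write a site metadata sidecar TSV
#' @param meta Data.frame as returned by [read_site_metadata()].
#' @param file Output path.
#' @export
write_site_metadata <- function(meta, file) {
  utils::write.table(meta, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(meta)
}

#' Read a BED file of intervals
#'
#' BED is 0-based, half-open; intervals are converted here to the package's
#' 1-based fully-closed convention (`start + 1, end`).
#'
#' @param file Path to a BED file (first three columns used).
#' @return Data.frame with `chrom`, `start`, `end` (1-based, closed).
#' @export
read_bed <- function(file) {
  bed <- tryCatch(
    utils::read.table(file, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed BED file: ", conditionMessage(e))
  )
  if (ncol(bed) < 3L) stop("malformed BED file: fewer than 3 columns")
  start <- suppressWarnings(as.integer(bed[[2L]]))
  end <- suppressWarnings(as.integer(bed[[3L]]))
  if (anyNA(start) || anyNA(end) || any(end < start)) {
    stop("malformed BED file: non-integer or inverted coordinates")
  }
  data.frame(chrom = as.character(bed[[1L]]), start = start + 1L, end = end,
             stringsAsFactors = FALSE)
}
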