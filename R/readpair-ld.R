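# Haplotype counting and linkage disequilibrium from sequencing fragments.
#
# A paired-end fragment that spans several focal SNPs observes those
# alleles on one chromosome, so direct tallies of allele strings over
# fragments covering all focal loci estimate multi-locus haplotype
# frequencies without phasing. Only direct fragment evidence is used; no
# EM over partially covering fragments.

#' Read a fragment observation TSV
#'
#' Tab-separated with header: `fragment_id`, `locus` (integer position),
#' `base` (A/C/G/T). A fragment appears once per covered locus; read1/read2
#' of a pair may both report the same locus (consistency is checked by
#' [count_haplotypes()]).
#'
#' @param file Path to the TSV.
#' @return Data.frame with those three columns.
#' @export
read_fragments <- function(file) {
  fr <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("fragment_id", "locus", "base")
  if (!all(need %in% names(fr))) {
    stop("fragment file must have columns fragment_id, locus, base")
  }
  if (!all(fr$base %in% c("A", "C", "G", "T"))) {
    stop("fragment bases must be A, C, G or T")
  }
  fr[need]
}

#' Count haplotypes over a set of focal loci
#'
#' Tallies allele strings over the fragments that cover every locus in
#' `loci`. A fragment with conflicting duplicate calls at a locus (read1 vs
#' read2 disagree) is discarded entirely; consistent duplicate calls count
#' once. Counting is invariant to the input order of fragments.
#'
#' @param fragments Data.frame as from [read_fragments()].
#' @param loci Sorted vector of focal positions (non-empty).
#' @return List of class `"haplotype_counts"`: `loci`, `counts` (named
#'   integer vector, names are allele strings in locus order), `total`,
#'   `n_discarded_conflict`. A result with `total = 0` is flagged via its
#'   printed form and usable as an explicit empty result.
#' @export
count_haplotypes <- function(fragments, loci) {
  if (length(loci) == 0L) stop("loci must be non-empty")
  if (is.unsorted(loci, strictly = TRUE)) stop("loci must be sorted and unique")
  fr <- fragments[fragments$locus %in% loci, , drop = FALSE]
  n_conflict <- 0L
  counts <- integer(0)
  if (nrow(fr) > 0L) {
    by_frag <- split(fr[, c("locus", "base")], fr$fragment_id)
    strings <- vapply(by_frag, function(d) {
      # collapse duplicate calls; conflict => NA
      calls <- tapply(d$base, d$locus, function(b) {
        u <- unique(b)
        if (length(u) == 1L) u else NA_character_
      })
      if (anyNA(calls)) return("!conflict")
      if (!all(as.character(loci) %in% names(calls))) return("")
      paste(calls[as.character(loci)], collapse = "")
    }, character(1L))
    n_conflict <- sum(strings == "!conflict")
    strings <- strings[strings != "" & strings != "!conflict"]
    if (length(strings) > 0L) {
      tab <- table(strings)
      counts <- as.integer(tab)
      names(counts) <- names(tab)
    }
  }
  structure(list(loci = loci, counts = counts, total = sum(counts),
                 n_discarded_conflict = n_conflict),
            class = "haplotype_counts")
}

#' @export
print.haplotype_counts <- function(x, ...) {
  cat(sprintf("haplotype counts over %d loci: total %d fragments%s%s\n",
              length(x$loci), x$total,
              if (x$total == 0L) " [EMPTY: no qualifying fragment]" else "",
              if (x$n_discarded_conflict > 0L)
                sprintf(" (%d discarded for read1/read2 conflicts)",
                        x$n_discarded_conflict) else ""))
  if (x$total > 0L) print(x$counts)
  invisible(x)
}

#' Haplotype frequencies
#'
#' @param x A `"haplotype_counts"` object with `total >= 1`.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
haplotype_frequencies <- function(x) {
  stopifnot(inherits(x, "haplotype_counts"))
  if (x$total < 1L) stop("haplotype frequencies undefined: no qualifying fragments")
  x$counts / x$total
}

#' Marginalise haplotype counts to a locus subset
#'
#' @param x A `"haplotype_counts"` object.
#' @param loci Subset of `x$loci` to keep (sorted).
#' @return A `"haplotype_counts"` object over the subset, with counts summed
#'   over the dropped loci.
#' @export
marginalize_haplotypes <- function(x, loci) {
  stopifnot(inherits(x, "haplotype_counts"))
  keep <- match(loci, x$loci)
  if (anyNA(keep)) stop("loci must be a subset of the counted loci")
  if (x$total == 0L) return(count_haplotypes(data.frame(fragment_id = character(),
                                                        locus = integer(),
                                                        base = character()), loci))
  sub <- vapply(strsplit(names(x$counts), ""), function(s)
    paste(s[keep], collapse = ""), character(1L))
  agg <- tapply(x$counts, sub, sum)
  counts <- as.integer(agg)
  names(counts) <- names(agg)
  structure(list(loci = loci, counts = counts, total = sum(counts),
                 n_discarded_conflict = x$n_discarded_conflict),
            class = "haplotype_counts")
}

#' Two-locus linkage disequilibrium from haplotype counts
#'
#' For two biallelic loci with haplotype frequencies `p_AB` etc.,
#' `D = p_AB - p_A * p_B` (computed for the alphabetically first allele at
#' each locus) and `r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#'
#' @param x A `"haplotype_counts"` object over exactly 2 loci with
#'   `total >= 1`.
#' @return List of class `"pair_ld"`: `D`, `r2`, `alleles` (the reference
#'   allele per locus), `defined`. When a locus is monomorphic among the
#'   counted haplotypes the result is flagged `defined = FALSE` with `NA`
#'   values (never silently 0).
#' @export
pair_ld <- function(x) {
  stopifnot(inherits(x, "haplotype_counts"))
  if (length(x$loci) != 2L) stop("pair_ld requires exactly 2 loci")
  if (x$total < 1L) stop("no qualifying fragments")
  hs <- strsplit(names(x$counts), "")
  a1 <- vapply(hs, `[`, "", 1L)
  a2 <- vapply(hs, `[`, "", 2L)
  u1 <- sort(unique(a1)); u2 <- sort(unique(a2))
  if (length(u1) > 2L || length(u2) > 2L) {
    stop("pair_ld requires biallelic loci among the counted haplotypes")
  }
  if (length(u1) < 2L || length(u2) < 2L) {
    return(structure(list(D = NA_real_, r2 = NA_real_,
                          alleles = c(u1[1L], u2[1L]), defined = FALSE),
                     class = "pair_ld"))
  }
  f <- x$counts / x$total
  pA <- sum(f[a1 == u1[1L]])
  pB <- sum(f[a2 == u2[1L]])
  pAB <- sum(f[a1 == u1[1L] & a2 == u2[1L]])
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, r2 = r2, alleles = c(u1[1L], u2[1L]), defined = TRUE),
            class = "pair_ld")
}

#' @export
print.pair_ld <- function(x, ...) {
  if (!x$defined) {
    cat("pairwise LD undefined: a locus is monomorphic among counted haplotypes\n")
  } else {
    cat(sprintf("pairwise LD (alleles %s/%s): D = %.4g, r2 = %.4g\n",
                x$alleles[1L], x$alleles[2L], x$D, x$r2))
  }
  invisible(x)
}
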