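# Variance partitioning of the 2x2x2 transgenic assay.
#
# Trident intensity is quantified as 255 minus the mean pixel value inside
# the delimited trident polygon, so 0 is white and 255 black. The eight
# genotypes over three regulatory SNPs are analysed with a full-factorial
# three-way ANOVA under zero-sum contrasts and type-III sums of squares;
# effect sizes are eta-squared, the term's share of the total sum of
# squares about the grand mean.

#' Trident pigmentation intensity from pixel values
#'
#' @param pixels Pixel values in `[0, 255]` inside the trident polygon.
#' @return `255 - mean(pixels)`: 0 = white, 255 = black.
#' @export
trident_intensity <- function(pixels) {
  if (length(pixels) == 0L) stop("empty pixel region: intensity undefined")
  if (any(is.na(pixels)) || any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]")
  }
  255 - mean(pixels)
}

.FACTORIAL_TERMS <- c("snp1", "snp2", "snp3", "snp1:snp2", "snp1:snp3",
                      "snp2:snp3", "snp1:snp2:snp3")

#' Read a factorial phenotype TSV
#'
#' Accepts either explicit columns `snp1, snp2, snp3, intensity` or a
#' compact `genotype` column with three-letter strings over `{D, L}` (e.g.
#' `"DLD"`) plus `intensity`.
#'
#' @param file Path to the tab-separated file (with header).
#' @return Data.frame with factor columns `snp1`, `snp2`, `snp3` (levels
#'   `D`, `L`) and numeric `intensity`.
#' @export
read_factorial_data <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if ("genotype" %in% names(tab)) {
    if (any(nchar(tab$genotype) != 3L)) {
      stop("genotype strings must have length 3")
    }
    g <- do.call(rbind, strsplit(tab$genotype, ""))
    tab$snp1 <- g[, 1L]; tab$snp2 <- g[, 2L]; tab$snp3 <- g[, 3L]
  }
  need <- c("snp1", "snp2", "snp3", "intensity")
  if (!all(need %in% names(tab))) {
    stop("need columns snp1, snp2, snp3 (or genotype) and intensity")
  }
  as_factorial_data(tab[need])
}

# validate and coerce a factorial dataset
as_factorial_data <- function(d) {
  for (s in c("snp1", "snp2", "snp3")) {
    if (!all(d[[s]] %in% c("D", "L"))) {
      stop(sprintf("%s levels must be 'D' or 'L'", s))
    }
    d[[s]] <- factor(d[[s]], levels = c("D", "L"))
  }
  if (any(is.na(d$intensity)) || any(d$intensity < 0 | d$intensity > 255)) {
    stop("intensity must lie in [0, 255]")
  }
  d
}

# type-III SS by explicit orthogonal projection onto each term's zero-sum
# contrast column (valid for the balanced 2x2x2 design); used as the
# cross-check path against the model-comparison route
.projection_ss <- function(d) {
  code <- function(s) ifelse(s == "D", 1, -1)
  X <- cbind(snp1 = code(d$snp1), snp2 = code(d$snp2), snp3 = code(d$snp3))
  X <- cbind(X,
             "snp1:snp2" = X[, "snp1"] * X[, "snp2"],
             "snp1:snp3" = X[, "snp1"] * X[, "snp3"],
             "snp2:snp3" = X[, "snp2"] * X[, "snp3"],
             "snp1:snp2:snp3" = X[, "snp1"] * X[, "snp2"] * X[, "snp3"])
  y <- d$intensity
  ss <- vapply(.FACTORIAL_TERMS, function(t) {
    v <- X[, t]
    sum(v * y)^2 / sum(v * v)
  }, 0)
  ss
}

#' Full-factorial three-way ANOVA with type-III sums of squares
#'
#' Fits the full `2 x 2 x 2` model `intensity ~ snp1 * snp2 * snp3` under
#' zero-sum factor contrasts and computes type-III sums of squares per term
#' (via `car::Anova`), `F = (SS/df) / (SS_res/df_res)`, the F-distribution
#' p-value, and eta-squared (`SS_term / SS_total` with `SS_total` the total
#' sum of squares about the grand mean). For balanced data the zero-sum
#' type-III decomposition is orthogonal, so it equals both the sequential
#' (type-I) decomposition and a direct projection onto contrast columns;
#' this equality is asserted internally on every balanced fit. Unbalanced
#' data are accepted (the type-III path is then authoritative and the
#' orthogonality check is skipped), but every genotype cell must be
#' non-empty. With one observation per cell the residual df is 0: sums of
#' squares are reported and the F tests are refused (`NA`).
#'
#' @param data Data.frame with columns `snp1`, `snp2`, `snp3` (values
#'   `"D"`/`"L"`) and `intensity` in `[0, 255]`.
#' @return Data.frame of class `"anova_table"` with rows
#'   `snp1, snp2, snp3, snp1:snp2, snp1:snp3, snp2:snp3, snp1:snp2:snp3,
#'   Residuals` and columns `SS`, `df`, `F`, `p_value`, `eta2`.
#' @export
fit_factorial <- function(data) {
  d <- as_factorial_data(data)
  cells <- table(d$snp1, d$snp2, d$snp3)
  if (any(cells == 0L)) {
    stop("design error: every of the 8 genotype cells must be non-empty")
  }
  ss_total <- sum((d$intensity - mean(d$intensity))^2)
  if (ss_total <= 0) {
    stop("degenerate data: constant response, no variance to partition")
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit <- stats::lm(intensity ~ snp1 * snp2 * snp3, data = d)
  terms <- .FACTORIAL_TERMS
  balanced <- length(unique(c(cells))) == 1L
  n <- nrow(d)
  df <- stats::setNames(c(rep(1L, length(terms)), n - 8L),
                        c(terms, "Residuals"))
  can_drop_test <- df[["Residuals"]] > 0L &&
    stats::deviance(fit) > 1e-10 * ss_total
  if (can_drop_test) {
    # type-III via model comparison under zero-sum coding (the standard
    # definition); authoritative for unbalanced data
    a3 <- car::Anova(fit, type = 3)
    term_map <- gsub(" ", "", rownames(a3))
    ss <- stats::setNames(a3[["Sum Sq"]], term_map)
    if (!all(c(terms, "Residuals") %in% term_map)) {
      stop("unexpected ANOVA table structure")
    }
    ss <- ss[c(terms, "Residuals")]
  } else if (balanced) {
    # saturated or noise-free balanced fits: the orthogonal projection
    # decomposition is exact and needs no residual variance
    ss <- c(.projection_ss(d), Residuals = max(stats::deviance(fit), 0))
  } else {
    stop("cannot partition unbalanced data without residual variance")
  }
  if (balanced && can_drop_test) {
    proj <- .projection_ss(d)
    if (max(abs(proj - ss[terms])) > 1e-6 * max(ss_total, 1)) {
      stop("internal check failed: type-III and projection sums of squares disagree on balanced data")
    }
  }
  df_res <- df[["Residuals"]]
  ss_res <- unname(ss[["Residuals"]])
  if (df_res > 0L) {
    ms_res <- ss_res / df_res
    Fval <- (ss[terms] / df[terms]) / ms_res
    pval <- stats::pf(Fval, df[terms], df_res, lower.tail = FALSE)
  } else {
    Fval <- rep(NA_real_, length(terms))
    pval <- rep(NA_real_, length(terms))
  }
  out <- data.frame(term = c(terms, "Residuals"),
                    SS = c(unname(ss[terms]), ss_res),
                    df = c(unname(df[terms]), df_res),
                    F = c(unname(Fval), NA_real_),
                    p_value = c(unname(pval), NA_real_),
                    stringsAsFactors = FALSE)
  out$eta2 <- out$SS / ss_total
  attr(out, "ss_total") <- ss_total
  attr(out, "balanced") <- balanced
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Eta-squared effect sizes from an ANOVA table
#'
#' `eta2 = SS_term / SS_total` for every row, residuals included; across
#' rows the shares sum to 1 for a balanced design.
#'
#' @param table An `"anova_table"` from [fit_factorial()], or any data.frame
#'   with columns `term` and `SS`.
#' @return Named numeric vector of eta-squared values.
#' @export
eta_squared <- function(table) {
  ss_total <- attr(table, "ss_total")
  if (is.null(ss_total)) ss_total <- sum(table$SS)
  if (ss_total <= 0) stop("degenerate data: total sum of squares is 0")
  stats::setNames(table$SS / ss_total, table$term)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("three-way factorial ANOVA (type-III SS, zero-sum contrasts)\n")
  y <- as.data.frame(x)
  y$SS <- signif(y$SS, 5L)
  y$F <- signif(y$F, 4L)
  y$p_value <- signif(y$p_value, 3L)
  y$eta2 <- round(y$eta2, 4L)
  print(y, row.names = FALSE)
  invisible(x)
}
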