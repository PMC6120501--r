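# Independent oracles, written as direct scalar transcriptions of the
# defining formulas; deliberately naive (loops, no vectorisation, no code
# shared with the package implementation).

# CMH statistic, p, MH odds ratio and RBG confidence interval for a list of
# 2x2 matrices (rows = pools, columns = alleles)
oracle_cmh <- function(tables, correct = TRUE) {
  num <- 0; den <- 0; sumR <- 0; sumS <- 0
  sPR <- 0; sPSQR <- 0; sQS <- 0
  for (tb in tables) {
    tb <- matrix(as.numeric(tb), 2)
    a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
    n <- a + b + c_ + d
    if (n > 0) {
      num <- num + a - (a + b) * (a + c_) / n
      R <- a * d / n; S <- b * c_ / n
      P <- (a + d) / n; Q <- (b + c_) / n
      sumR <- sumR + R; sumS <- sumS + S
      sPR <- sPR + P * R
      sPSQR <- sPSQR + P * S + Q * R
      sQS <- sQS + Q * S
    }
    if (n > 1) {
      den <- den + (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
    }
  }
  cc <- if (correct) 0.5 else 0
  stat <- max(abs(num) - cc, 0)^2 / den
  or <- sumR / sumS
  v <- sPR / (2 * sumR^2) + sPSQR / (2 * sumR * sumS) + sQS / (2 * sumS^2)
  lo <- exp(log(or) - qnorm(0.975) * sqrt(v))
  hi <- exp(log(or) + qnorm(0.975) * sqrt(v))
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE),
       or_mh = or, ci95 = c(lo, hi), log_or = log(or))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (with the observed margins) no more
# probable than the observed one
oracle_fisher_p <- function(tb) {
  m <- tb[1, 1] + tb[1, 2]
  n <- tb[2, 1] + tb[2, 2]
  k <- tb[1, 1] + tb[2, 1]
  obs <- dhyper(tb[1, 1], m, n, k)
  p <- 0
  for (x in max(0, k - n):min(k, m)) {
    px <- dhyper(x, m, n, k)
    if (px <= obs * (1 + 1e-7)) p <- p + px
  }
  min(p, 1)
}

# brute-force empirical-FDR scan over every observed p as threshold
oracle_fdr <- function(obs, null, q) {
  best_t <- NA_real_; best_n <- 0L; best_fdr <- NA_real_
  for (t in sort(unique(obs))) {
    n_obs <- sum(obs <= t)
    n_null <- sum(null <= t)
    fdr <- (n_null * length(obs) / length(null)) / max(1, n_obs)
    if (fdr <= q && (is.na(best_t) || t > best_t)) {
      best_t <- t; best_n <- n_obs; best_fdr <- fdr
    }
  }
  list(p_threshold = best_t, n_significant = best_n,
       estimated_fdr_at_threshold = best_fdr)
}

# per-term sums of squares of the balanced 2x2x2 factorial by explicit
# projection of the response onto each term's contrast column
oracle_projection_ss <- function(d) {
  s <- function(v) ifelse(v == "D", 1, -1)
  cols <- list(
    "snp1" = s(d$snp1), "snp2" = s(d$snp2), "snp3" = s(d$snp3),
    "snp1:snp2" = s(d$snp1) * s(d$snp2),
    "snp1:snp3" = s(d$snp1) * s(d$snp3),
    "snp2:snp3" = s(d$snp2) * s(d$snp3),
    "snp1:snp2:snp3" = s(d$snp1) * s(d$snp2) * s(d$snp3))
  y <- d$intensity
  out <- numeric(length(cols))
  names(out) <- names(cols)
  for (t in names(cols)) {
    v <- cols[[t]]
    yhat <- v * sum(v * y) / sum(v * v)   # projection onto span(v)
    out[t] <- sum(yhat^2)
  }
  out
}

# OLS coefficients from the normal equations
oracle_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# expected extreme-pool composition at zero environmental noise: rank
# haplotypes by base score and fill the pools deterministically from the
# expected per-haplotype counts; returns the sign of each SNP's dark-pool
# enrichment (positive = D allele enriched in the dark pool)
oracle_zero_noise_signs <- function(model, n_individuals, n_light, n_dark) {
  expected <- model$frequencies * n_individuals
  fill <- function(ord, target) {
    take <- numeric(length(expected))
    left <- target
    for (h in ord) {
      take[h] <- min(expected[h], left)
      left <- left - take[h]
      if (left <= 0) break
    }
    take
  }
  dark <- fill(order(model$base_scores, decreasing = TRUE), n_dark)
  light <- fill(order(model$base_scores), n_light)
  vapply(seq_along(model$snp_names), function(s) {
    isD <- model$alleles[, s] == "D"
    fd <- sum(dark[isD]) / sum(dark)
    fl <- sum(light[isD]) / sum(light)
    sign(fd - fl)
  }, 0)
}
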