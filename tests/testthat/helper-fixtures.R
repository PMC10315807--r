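# Shared fixture builders and independent oracles.

# Quick harmonized set from effect vectors.
make_h <- function(bx, by, sx = rep(0.01, length(bx)),
                   sy = rep(0.01, length(bx)),
                   snp = sprintf("rs%03d", seq_along(bx))) {
  harmonized_set(snp = snp, bx = bx, sx = sx,
                 px = 2 * pnorm(-abs(bx / sx)),
                 by = by, sy = sy, py = 2 * pnorm(-abs(by / sy)))
}

# A small GWAS table data frame with sensible defaults.
make_gwas_df <- function(n = 5, beta = rnorm(n, 0, 0.1), se = rep(0.02, n),
                         snp = sprintf("rs%03d", seq_len(n)),
                         ea = rep("A", n), oa = rep("G", n),
                         eaf = rep(0.3, n), chr = rep(1L, n),
                         pos = seq_len(n) * 1e6, nn = 10000) {
  data.frame(snp = snp, chr = chr, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), n = nn,
             stringsAsFactors = FALSE)
}

# Independent weighted-least-squares oracle via stats::lm. Returns the
# coefficients and the *unscaled* SEs sqrt(diag((X'WX)^-1)) plus lm's own
# sigma-scaled SEs.
wls_oracle <- function(y, X, w, intercept = FALSE) {
  df <- data.frame(y = y)
  fit <- if (intercept) lm(y ~ X, weights = w) else lm(y ~ 0 + X, weights = w)
  s <- summary(fit)
  list(coef = unname(coef(fit)),
       se_unscaled = unname(sqrt(diag(vcov(fit))) / s$sigma),
       se_scaled = unname(sqrt(diag(vcov(fit)))),
       sigma = s$sigma,
       rss = sum(w * resid(fit)^2))
}

# Brute-force greedy clumping oracle: literal restatement of the rule with
# nested loops, independent of the package implementation.
clump_oracle <- function(cand, r2mat, clump_r2, window_kb) {
  cand <- cand[order(cand$pval, cand$pos, cand$snp), ]
  kept <- character(0)
  alive <- cand$snp
  while (length(alive) > 0) {
    lead <- alive[1]
    kept <- c(kept, lead)
    alive <- alive[-1]
    drop <- logical(length(alive))
    for (i in seq_along(alive)) {
      a <- cand[cand$snp == lead, ]
      b <- cand[cand$snp == alive[i], ]
      if (!is.na(a$chr) && !is.na(b$chr) && a$chr == b$chr &&
          abs(a$pos - b$pos) <= window_kb * 1000 &&
          r2mat[lead, alive[i]] > clump_r2) {
        drop[i] <- TRUE
      }
    }
    alive <- alive[!drop]
  }
  kept
}
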