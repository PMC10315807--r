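# Cross-cohort random-effects meta-analysis (DerSimonian-Laird).

#' Random-effects meta-analysis of log-odds estimates
#'
#' DerSimonian-Laird: with fixed-effect weights w_i = 1/se_i^2 and
#' heterogeneity Q about the fixed-effect pooled mean,
#' tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)); the pooled
#' estimate then re-weights by 1/(se_i^2 + tau2), with a normal CI and
#' two-sided p. Estimates are pooled on the log-OR scale for symmetry and
#' approximate normality. A single study is returned as-is with tau2 = 0.
#'
#' @param beta,se Per-study estimates (log-OR) and SEs.
#' @param alpha Two-sided level for the CI.
#' @return List of class `meta_result`: `beta`, `se`, `ci_low`, `ci_high`
#'   (on the OR scale), `pvalue`, `tau2`, `q_meta`, `k_studies`.
#' @export
meta_random_effects <- function(beta, se, alpha = 0.05) {
  k <- length(beta)
  if (k == 0) stop("no estimates to pool")
  stopifnot(length(se) == k, all(se > 0))
  if (k == 1) {
    q <- 0
    tau2 <- 0
    pooled <- beta
    pooled_se <- se
  } else {
    w <- 1 / se^2
    fixed <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - fixed)^2)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    pooled <- sum(ws * beta) / sum(ws)
    pooled_se <- sqrt(1 / sum(ws))
  }
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(beta = pooled, se = pooled_se,
                 ci_low = exp(pooled - z * pooled_se),
                 ci_high = exp(pooled + z * pooled_se),
                 or = exp(pooled),
                 pvalue = 2 * stats::pnorm(-abs(pooled / pooled_se)),
                 tau2 = tau2, q_meta = q, k_studies = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k=%d: OR %.3g (%.3g-%.3g), p=%.3g, tau2=%.3g\n",
              x$k_studies, x$or, x$ci_low, x$ci_high, x$pvalue, x$tau2))
  invisible(x)
}
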