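# Core two-sample MR estimators on a harmonized exposure/outcome set:
# Wald ratio, fixed/random-effects IVW, MR-Egger, weighted median.

check_harmonized <- function(h, min_snps = 1) {
  stopifnot(is.data.frame(h), all(c("bx", "sx", "by", "sy") %in% names(h)))
  if (nrow(h) < min_snps) {
    stop("insufficient data: ", nrow(h), " SNP(s), need >= ", min_snps)
  }
  invisible(h)
}

mr_estimate <- function(method, n_snp, beta, se, pvalue, df = NULL, ...) {
  ci <- to_or(beta, se, df = df)
  structure(list(method = method, n_snp = n_snp, beta = beta, se = se,
                 pvalue = pvalue, or = ci$or, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, ...),
            class = "mr_estimate")
}

#' Convert a log-odds estimate to an odds ratio with confidence interval
#'
#' @param beta Estimate on the log-odds scale.
#' @param se Standard error (>= 0).
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @param df Degrees of freedom for a t-based interval/p (e.g. MR-Egger);
#'   `NULL` for the normal approximation.
#' @return List with `or`, `ci_low`, `ci_high`, `pvalue`.
#' @export
to_or <- function(beta, se, alpha = 0.05, df = NULL) {
  stopifnot(se >= 0)
  crit <- if (is.null(df)) stats::qnorm(1 - alpha / 2)
          else stats::qt(1 - alpha / 2, df)
  p <- if (se == 0) {
    if (beta == 0) 1 else 0
  } else if (is.null(df)) {
    2 * stats::pnorm(-abs(beta / se))
  } else {
    2 * stats::pt(-abs(beta / se), df)
  }
  list(or = exp(beta), ci_low = exp(beta - crit * se),
       ci_high = exp(beta + crit * se), pvalue = p)
}

#' Wald ratio causal estimate for a single variant
#'
#' beta = by/bx with the first-order delta-method standard error sy/|bx|.
#'
#' @param bx,sx SNP-exposure effect and its SE.
#' @param by,sy SNP-outcome effect and its SE.
#' @return List with `beta` and `se`.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (any(bx == 0)) stop("undefined ratio: bx = 0")
  list(beta = by / bx, se = sy / abs(bx))
}

#' Inverse-variance weighted estimate
#'
#' Combines per-SNP Wald ratios with weights bx^2/sy^2 (equivalently, a
#' weighted no-intercept regression of by on bx). The random-effects model
#' inflates the fixed-effect SE by sqrt(max(1, Q/(J-1))) - multiplicative
#' overdispersion, floored so that underdispersion never tightens the
#' interval. P-values are two-sided normal.
#'
#' @param h Harmonized set (needs `bx`, `sx`, `by`, `sy`).
#' @param model `"random"` (primary) or `"fixed"`.
#' @return An `mr_estimate` with extras `q`, `q_df`, `re_scale`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_harmonized(h, 1)
  j <- nrow(h)
  if (j == 1) {
    warning("single SNP: IVW degrades to the Wald ratio")
    wr <- wald_ratio(h$bx, h$sx, h$by, h$sy)
    p <- 2 * stats::pnorm(-abs(wr$beta / wr$se))
    return(mr_estimate("wald", 1L, wr$beta, wr$se, p,
                       q = 0, q_df = 0, re_scale = 1))
  }
  if (all(h$bx == 0)) stop("singular: all bx are zero")
  w <- h$bx^2 / h$sy^2
  ratio <- h$by / h$bx
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  re_scale <- sqrt(max(1, q / (j - 1)))
  se <- if (model == "random") se_fixed * re_scale else se_fixed
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate(paste0("ivw_", substr(model, 1, 2)), as.integer(j),
              beta, se, p, q = q, q_df = j - 1, re_scale = re_scale)
}

# Weighted least squares with optional intercept; returns coefficients,
# covariance with multiplicative dispersion floored at 1, and the weighted RSS.
wls_fit <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * y))
  resid <- y - X %*% coef
  rss <- sum(w * resid^2)
  df <- length(y) - ncol(X)
  scale2 <- if (df > 0) max(1, rss / df) else 1
  list(coef = drop(coef), cov = solve(xtwx) * scale2, rss = rss, df = df,
       scale = sqrt(scale2))
}

#' MR-Egger regression
#'
#' Weighted regression of by on bx with an intercept (weights 1/sy^2), after
#' orienting every row so bx >= 0. The intercept estimates the average
#' directional pleiotropic effect; the slope is the causal estimate, valid
#' under the InSIDE assumption. Both SEs carry the multiplicative dispersion
#' sqrt(max(1, Q_egger/(J-2))) and p-values use the t distribution with J-2
#' degrees of freedom.
#'
#' @param h Harmonized set with at least 3 SNPs and non-constant bx.
#' @return An `mr_estimate` for the slope with extras `intercept`,
#'   `intercept_se`, `intercept_p`, `q_egger`, `re_scale`.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3)
  flip <- sign(h$bx)
  flip[flip == 0] <- 1
  bx <- h$bx * flip
  by <- h$by * flip
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("singular: no spread in bx")
  }
  j <- nrow(h)
  fit <- wls_fit(bx, by, 1 / h$sy^2, intercept = TRUE)
  ses <- unname(sqrt(diag(fit$cov)))
  slope <- unname(fit$coef[2])
  intercept <- unname(fit$coef[1])
  slope_p <- 2 * stats::pt(-abs(slope / ses[2]), j - 2)
  int_p <- 2 * stats::pt(-abs(intercept / ses[1]), j - 2)
  mr_estimate("egger", as.integer(j), slope, ses[2], slope_p, df = j - 2,
              intercept = intercept, intercept_se = ses[1],
              intercept_p = int_p, q_egger = fit$rss, re_scale = fit$scale)
}

# Interpolated weighted median of per-SNP ratios. Weights need not be
# normalized.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Orders per-SNP Wald ratios, assigns normalized inverse-variance weights,
#' and interpolates the weight-midpoint positions S_j = cumsum(w)_j - w_j/2
#' linearly at S = 0.5. Consistent when valid instruments carry more than
#' half the weight. The SE comes from a parametric bootstrap: bx and by are
#' resampled from their sampling normals and the median recomputed.
#'
#' @param h Harmonized set with at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE (default 1000; 0 skips the
#'   bootstrap and returns `NA` SE, for simulation loops that only need the
#'   point estimate).
#' @param seed RNG seed for the bootstrap (set it for reproducible output).
#' @return An `mr_estimate` with extras `n_boot`, `seed`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  check_harmonized(h, 3)
  if (any(h$bx == 0)) stop("undefined ratio: bx = 0")
  j <- nrow(h)
  ratio <- h$by / h$bx
  w <- h$bx^2 / h$sy^2
  beta <- weighted_median_point(ratio, w)
  se <- NA_real_
  p <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    bxs <- matrix(stats::rnorm(n_boot * j, h$bx, h$sx), n_boot, j, byrow = TRUE)
    bys <- matrix(stats::rnorm(n_boot * j, h$by, h$sy), n_boot, j, byrow = TRUE)
    sy2 <- matrix(h$sy^2, n_boot, j, byrow = TRUE)
    est <- vapply(seq_len(n_boot), function(b) {
      weighted_median_point(bys[b, ] / bxs[b, ], bxs[b, ]^2 / sy2[b, ])
    }, numeric(1))
    se <- stats::sd(est)
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  mr_estimate("weighted_median", as.integer(j), beta,
              if (is.na(se)) 0 else se, p,
              n_boot = n_boot, seed = seed)
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (J=%d): beta=%.4g se=%.4g p=%.3g  OR %.3g (%.3g-%.3g)\n",
              x$method, x$n_snp, x$beta, x$se, x$pvalue, x$or, x$ci_low,
              x$ci_high))
  if (!is.null(x$intercept)) {
    cat(sprintf("  egger intercept %.4g (se %.4g, p %.3g)\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, b = x$beta, se = x$se,
             p = x$pvalue, OR = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}
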