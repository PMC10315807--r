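# Heterogeneity and pleiotropy diagnostics: Cochran Q, Radial-MR outliers,
# MR-PRESSO, leave-one-out, and the four-criterion candidate screen.

#' Cochran Q heterogeneity test
#'
#' Q = sum_j w_j (beta_j - beta_hat)^2 over per-SNP Wald ratios beta_j with
#' first-order weights w_j = bx_j^2/sy_j^2. In the IVW context beta_hat is
#' the fixed-effect IVW estimate and Q is referred to chi-square(J-1); in
#' the Egger context Q is the weighted residual sum of squares of the
#' intercept model on chi-square(J-2).
#'
#' @param h Harmonized set with at least 2 SNPs (3 for the Egger context).
#' @param context `"ivw"` or `"egger"`.
#' @return List of class `heterogeneity_result`: `q`, `df`, `pvalue`,
#'   `context`.
#' @export
cochran_q <- function(h, context = c("ivw", "egger")) {
  context <- match.arg(context)
  check_harmonized(h, 2)
  j <- nrow(h)
  if (context == "ivw") {
    w <- h$bx^2 / h$sy^2
    ratio <- h$by / h$bx
    beta <- sum(w * ratio) / sum(w)
    q <- sum(w * (ratio - beta)^2)
    df <- j - 1
  } else {
    check_harmonized(h, 3)
    flip <- ifelse(h$bx < 0, -1, 1)
    fit <- wls_fit(h$bx * flip, h$by * flip, 1 / h$sy^2, intercept = TRUE)
    q <- fit$rss
    df <- j - 2
  }
  structure(list(q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE),
                 context = context),
            class = "heterogeneity_result")
}

#' Radial-MR outlier detection
#'
#' The radial reparameterization regresses ratio_j * sqrt(w_j) on sqrt(w_j)
#' through the origin (first-order weights w_j = bx_j^2/sy_j^2), which
#' reproduces the IVW estimate while decomposing Cochran Q exactly into
#' per-SNP contributions q_j = w_j (ratio_j - beta_hat)^2. SNPs whose q_j is
#' extreme on chi-square(1) at `alpha` are flagged; with `iterate = TRUE`
#' flagged SNPs are removed and the fit repeated until no new outliers
#' emerge or fewer than 3 SNPs would remain.
#'
#' @param h Harmonized set with at least 3 SNPs.
#' @param alpha Per-SNP flagging level.
#' @param iterate Repeat removal to convergence.
#' @return List of class `radial_result`: `qstat` (per-SNP q and p from the
#'   first pass over the full set), `total_q`, `outliers`, `iterations`,
#'   `estimate` (random-effects IVW after removal).
#' @export
radial_outliers <- function(h, alpha = 0.05, iterate = TRUE) {
  check_harmonized(h, 3)
  full_w <- h$bx^2 / h$sy^2
  full_ratio <- h$by / h$bx
  full_beta <- sum(full_w * full_ratio) / sum(full_w)
  qstat <- data.frame(
    snp = h$snp,
    q = full_w * (full_ratio - full_beta)^2,
    stringsAsFactors = FALSE
  )
  qstat$pvalue <- stats::pchisq(qstat$q, 1, lower.tail = FALSE)

  keep <- rep(TRUE, nrow(h))
  outliers <- character(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    w <- h$bx[keep]^2 / h$sy[keep]^2
    ratio <- h$by[keep] / h$bx[keep]
    beta <- sum(w * ratio) / sum(w)
    q_j <- w * (ratio - beta)^2
    p_j <- stats::pchisq(q_j, 1, lower.tail = FALSE)
    new_out <- p_j < alpha
    if (!any(new_out) || sum(keep) - sum(new_out) < 3 || !iterate) {
      if (!iterate && any(new_out) && sum(keep) - sum(new_out) >= 3) {
        outliers <- c(outliers, h$snp[keep][new_out])
        keep[which(keep)[new_out]] <- FALSE
      }
      break
    }
    outliers <- c(outliers, h$snp[keep][new_out])
    idx <- which(keep)[new_out]
    keep[idx] <- FALSE
  }
  structure(list(qstat = qstat, total_q = sum(qstat$q),
                 outliers = outliers, iterations = iterations,
                 estimate = mr_ivw(subset_harmonized(h, keep),
                                   model = "random"),
                 retained = h$snp[keep]),
            class = "radial_result")
}

# Leave-one-out IVW estimates (fixed-effect weights) via sufficient sums.
loo_ivw_beta <- function(bx, by, sy2) {
  wxy <- bx * by / sy2
  wxx <- bx^2 / sy2
  (sum(wxy) - wxy) / (sum(wxx) - wxx)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The observed statistic is the weighted residual sum of squares
#' RSS = sum_j (by_j - beta_(-j) bx_j)^2 / sy_j^2 with beta_(-j) the
#' leave-one-out IVW estimate. Its null distribution is simulated by drawing
#' bx*_j ~ N(bx_j, sx_j) and by*_j ~ N(beta_(-j) bx_j, sy_j) and recomputing
#' RSS (including the leave-one-out estimates) on each simulated set. The
#' global p uses the add-one rule, so it is bounded below by 1/(n_sim + 1).
#' Per-SNP empirical outlier p-values are Bonferroni-adjusted over J; the
#' distortion test compares the raw-vs-corrected estimate shift against a
#' bootstrap of shifts from removing equally many randomly chosen SNPs.
#'
#' @param h Harmonized set with at least 4 SNPs.
#' @param n_sim Simulated null replicates.
#' @param outlier_alpha Level for flagging Bonferroni-adjusted per-SNP tests.
#' @param seed RNG seed (set it for reproducible output).
#' @param n_boot_distortion Bootstrap draws for the distortion test.
#' @return List of class `presso_result`: `rss_observed`, `global_p`,
#'   `outlier_p` (per SNP, adjusted), `outliers`, `distortion_p`,
#'   `estimate_raw`, `estimate_outlier_corrected`, `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL,
                      n_boot_distortion = 1000) {
  check_harmonized(h, 4)
  if (!is.null(seed)) set.seed(seed)
  # Work in canonical (sorted-id) order so the simulated null - and hence
  # the global p - does not depend on the input row order.
  h_input <- h
  h <- subset_harmonized(h, order(h$snp))
  j <- nrow(h)
  sy2 <- h$sy^2
  beta_loo <- loo_ivw_beta(h$bx, h$by, sy2)
  res_obs <- (h$by - beta_loo * h$bx)^2 / sy2
  rss_obs <- sum(res_obs)

  # Simulated null: matrices are n_sim x J; leave-one-out estimates are
  # recomputed on every simulated set via sufficient sums.
  bxs <- matrix(stats::rnorm(n_sim * j, mean = rep(h$bx, each = n_sim),
                             sd = rep(h$sx, each = n_sim)), n_sim, j)
  bys <- matrix(stats::rnorm(n_sim * j, mean = rep(beta_loo * h$bx, each = n_sim),
                             sd = rep(h$sy, each = n_sim)), n_sim, j)
  sy2m <- matrix(sy2, n_sim, j, byrow = TRUE)
  wxy <- bxs * bys / sy2m
  wxx <- bxs^2 / sy2m
  beta_loo_sim <- (rowSums(wxy) - wxy) / (rowSums(wxx) - wxx)
  res_sim <- (bys - beta_loo_sim * bxs)^2 / sy2m
  rss_sim <- rowSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p_raw <- (colSums(res_sim >= matrix(res_obs, n_sim, j,
                                              byrow = TRUE)) + 1) / (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * j)
  out_flag <- outlier_p < outlier_alpha
  if (all(out_flag)) stop("degenerate removal: every SNP flagged as outlier")
  outliers <- h$snp[out_flag]

  estimate_raw <- mr_ivw(h_input, model = "random")
  estimate_corr <- NULL
  distortion_p <- NA_real_
  if (any(out_flag)) {
    estimate_corr <- mr_ivw(subset_harmonized(h, !out_flag), model = "random")
    d_obs <- (estimate_raw$beta - estimate_corr$beta) / abs(estimate_corr$beta)
    n_out <- sum(out_flag)
    d_boot <- vapply(seq_len(n_boot_distortion), function(b) {
      drop_idx <- sample.int(j, n_out)
      w <- h$bx[-drop_idx]^2 / sy2[-drop_idx]
      beta_b <- sum(w * h$by[-drop_idx] / h$bx[-drop_idx]) / sum(w)
      (estimate_raw$beta - beta_b) / abs(beta_b)
    }, numeric(1))
    distortion_p <- mean(abs(d_boot) >= abs(d_obs))
  }
  structure(list(rss_observed = rss_obs, global_p = global_p,
                 outlier_p = stats::setNames(outlier_p, h$snp),
                 outliers = outliers, distortion_p = distortion_p,
                 estimate_raw = estimate_raw,
                 estimate_outlier_corrected = estimate_corr,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' Leave-one-out analysis
#'
#' Refits the random-effects IVW J times, excluding each SNP in turn, and
#' flags exclusions that flip the sign of the full-sample estimate or lose
#' its nominal significance.
#'
#' @param h Harmonized set with at least 2 SNPs.
#' @param alpha Significance level for the significance-loss flag.
#' @return Data frame of class `loo_table` with one row per excluded SNP:
#'   `snp`, `beta`, `se`, `pvalue`, `sign_flip`, `significance_loss`. The
#'   full-sample estimate is in `attr(, "full")`.
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  check_harmonized(h, 2)
  full <- mr_ivw(h, model = "random")
  rows <- lapply(seq_len(nrow(h)), function(jj) {
    fit <- mr_ivw(subset_harmonized(h, -jj), model = "random")
    data.frame(snp = h$snp[jj], beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue,
               sign_flip = sign(fit$beta) != sign(full$beta) &&
                 full$beta != 0,
               significance_loss = full$pvalue < alpha &&
                 fit$pvalue >= alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  class(out) <- c("loo_table", "data.frame")
  out
}

#' Candidate screen over a bundle of per-exposure MR results
#'
#' A candidate exposure is retained only if: the IVW estimate is nominally
#' significant; the IVW, MR-Egger and weighted-median estimates share the
#' same direction; Cochran Q shows no heterogeneity; the Egger intercept
#' shows no directional pleiotropy; and no single-SNP exclusion flips the
#' sign of the estimate. Direction-and-magnitude consistency is
#' operationalized as sign agreement (magnitude agreement is not separately
#' quantified).
#'
#' @param ivw,egger,wm `mr_estimate` objects (`egger` must carry the
#'   intercept extras).
#' @param q A `heterogeneity_result`.
#' @param loo A `loo_table`.
#' @param alpha Significance level used throughout.
#' @return List of class `candidate_decision` with the five booleans and
#'   `retained` (their conjunction).
#' @export
screen_candidates <- function(ivw, egger, wm, q, loo, alpha = 0.05) {
  if (is.null(ivw) || is.null(egger) || is.null(wm) || is.null(q) ||
      is.null(loo)) {
    stop("incomplete bundle: ivw, egger, wm, q and loo are all required")
  }
  ivw_significant <- ivw$pvalue < alpha
  directions_consistent <- sign(ivw$beta) == sign(egger$beta) &&
    sign(ivw$beta) == sign(wm$beta)
  no_heterogeneity <- q$pvalue > alpha
  no_pleiotropy <- egger$intercept_p > alpha
  loo_stable <- !any(loo$sign_flip)
  structure(list(ivw_significant = ivw_significant,
                 directions_consistent = directions_consistent,
                 no_heterogeneity = no_heterogeneity,
                 no_pleiotropy = no_pleiotropy,
                 loo_stable = loo_stable,
                 retained = ivw_significant && directions_consistent &&
                   no_heterogeneity && no_pleiotropy && loo_stable),
            class = "candidate_decision")
}

#' @export
print.candidate_decision <- function(x, ...) {
  flags <- unlist(x[c("ivw_significant", "directions_consistent",
                      "no_heterogeneity", "no_pleiotropy", "loo_stable")])
  cat("<candidate_decision>", if (x$retained) "RETAINED" else "dropped", "\n")
  print(flags)
  invisible(x)
}
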