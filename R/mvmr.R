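# Multivariable MR: direct effect of each exposure conditional on the
# others, by multivariate weighted regression of outcome effects on the
# exposure-effect matrix.

#' Construct multivariable-MR inputs directly
#'
#' @param bx SNP x exposure effect matrix (column names = exposure ids).
#' @param sx Matching SE matrix.
#' @param by,sy Outcome effects and SEs.
#' @param snp SNP ids.
#' @param audit Optional data frame (`snp`, `reason`) of SNPs dropped during
#'   assembly.
#' @return An `mvmr_inputs` list.
#' @export
mvmr_inputs <- function(bx, sx, by, sy, snp = rownames(bx), audit = NULL) {
  bx <- as.matrix(bx)
  sx <- as.matrix(sx)
  stopifnot(ncol(bx) >= 2, all(dim(bx) == dim(sx)),
            nrow(bx) == length(by), length(by) == length(sy),
            all(sy > 0), all(sx > 0), !anyNA(bx), !anyNA(by))
  if (is.null(colnames(bx))) colnames(bx) <- paste0("exposure", seq_len(ncol(bx)))
  if (is.null(snp)) snp <- paste0("snp", seq_len(nrow(bx)))
  if (is.null(audit)) {
    audit <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(bx = bx, sx = sx, by = by, sy = sy, snp = as.character(snp),
                 audit = audit),
            class = "mvmr_inputs")
}

#' Assemble multivariable-MR inputs from per-exposure instrument sets
#'
#' Takes the union of each exposure's univariable instruments, jointly
#' re-clumps it ranking SNPs by their minimum p-value across exposures (so
#' no exposure is privileged), extracts every exposure's effect for each
#' retained SNP on a common effect-allele orientation, harmonizes to the
#' outcome, and keeps complete cases only. Incomplete or incompatible SNPs
#' are dropped with an audited reason.
#'
#' @param exposures Named list of [gwas_table()] objects (>= 2).
#' @param outcome Outcome [gwas_table()].
#' @param ld [ld_matrix()] for the joint clump (may be `NULL`).
#' @param config A [selection_config()].
#' @return An [mvmr_inputs()].
#' @export
build_mvmr_inputs <- function(exposures, outcome, ld = NULL,
                              config = selection_config()) {
  stopifnot(length(exposures) >= 2)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, attr, "", "trait_id")
  }
  sels <- lapply(exposures, select_instruments, outcome = outcome, ld = ld,
                 config = config)
  insufficient <- names(sels)[vapply(sels, function(s)
    s$status != "ok", logical(1))]
  if (length(insufficient)) {
    stop("insufficient instruments for exposure(s): ",
         paste(insufficient, collapse = ", "))
  }
  inst_ids <- unique(unlist(lapply(sels, function(s) s$instruments$snp)))

  # Rank each union SNP by its minimum p across the exposures that carry it;
  # chr/pos come from the first exposure that records the SNP.
  minp <- rep(Inf, length(inst_ids))
  chr <- rep(NA, length(inst_ids))
  pos <- rep(NA_real_, length(inst_ids))
  ea <- oa <- rep(NA_character_, length(inst_ids))
  for (tab in exposures) {
    m <- match(inst_ids, tab$snp)
    ok <- !is.na(m)
    minp[ok] <- pmin(minp[ok], tab$pval[m[ok]])
    fill <- ok & is.na(chr)
    chr[fill] <- tab$chr[m[fill]]
    pos[fill] <- tab$pos[m[fill]]
    ea[fill] <- tab$effect_allele[m[fill]]
    oa[fill] <- tab$other_allele[m[fill]]
  }
  cand <- data.frame(snp = inst_ids, chr = chr, pos = pos, pval = minp,
                     stringsAsFactors = FALSE)
  kept <- clump_variants(cand, ld = ld, clump_r2 = config$clump_r2,
                         window_kb = config$clump_window_kb)
  clumped <- setdiff(inst_ids, kept)
  audit <- data.frame(snp = clumped,
                      reason = rep("joint_clump", length(clumped)),
                      stringsAsFactors = FALSE)
  ref <- cand[match(kept, cand$snp), ]
  ref$effect_allele <- ea[match(kept, inst_ids)]
  ref$other_allele <- oa[match(kept, inst_ids)]

  # Align a table's effect for each reference SNP onto the reference
  # orientation; NA where missing or allele-incompatible.
  aligned <- function(tab) {
    m <- match(ref$snp, tab$snp)
    beta <- se <- rep(NA_real_, nrow(ref))
    ok <- !is.na(m)
    same <- ok & tab$effect_allele[m] == ref$effect_allele &
      tab$other_allele[m] == ref$other_allele
    swap <- ok & tab$effect_allele[m] == ref$other_allele &
      tab$other_allele[m] == ref$effect_allele
    beta[same] <- tab$beta[m[same]]
    beta[swap] <- -tab$beta[m[swap]]
    se[same | swap] <- tab$se[m[same | swap]]
    list(beta = beta, se = se)
  }
  bx <- sapply(exposures, function(tab) aligned(tab)$beta)
  sx <- sapply(exposures, function(tab) aligned(tab)$se)
  out <- aligned(outcome)
  pal <- is_palindromic(ref$effect_allele, ref$other_allele)

  complete <- !pal & stats::complete.cases(bx) & !is.na(out$beta)
  if (any(!complete)) {
    reason <- ifelse(pal, "palindromic",
                     ifelse(is.na(out$beta), "incomplete_outcome",
                            "incomplete_exposure"))
    audit <- rbind(audit, data.frame(snp = ref$snp[!complete],
                                     reason = reason[!complete],
                                     stringsAsFactors = FALSE))
  }
  j <- sum(complete)
  if (j < length(exposures) + 2) {
    stop("insufficient instruments: ", j, " complete SNPs for ",
         length(exposures), " exposures")
  }
  mvmr_inputs(bx[complete, , drop = FALSE], sx[complete, , drop = FALSE],
              out$beta[complete], out$se[complete],
              snp = ref$snp[complete], audit = audit)
}

#' Multivariable IVW
#'
#' Weighted least squares of the outcome effects on all exposure-effect
#' columns with no intercept and weights 1/sy^2; each coefficient is an
#' exposure's direct effect conditional on the others. SEs carry the
#' multiplicative dispersion sqrt(max(1, Q_mv/(J-m))); p-values are t-based
#' with J-m degrees of freedom.
#'
#' @param inputs An [mvmr_inputs()].
#' @return Data frame of class `mvmr_estimate`: one row per exposure with
#'   `exposure`, `nsnp`, `b`, `se`, `p`, `OR`, `ci_low`, `ci_high`,
#'   `method`; attributes `re_scale` and `q_mv`.
#' @export
mvmr_ivw <- function(inputs) {
  stopifnot(inherits(inputs, "mvmr_inputs"))
  X <- inputs$bx
  j <- nrow(X)
  m <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < m) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):m]]
    stop("collinearity among exposure effects; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  w <- 1 / inputs$sy^2
  xtwx <- crossprod(X, w * X)
  coef <- drop(solve(xtwx, crossprod(X, w * inputs$by)))
  resid <- inputs$by - drop(X %*% coef)
  q_mv <- sum(w * resid^2)
  scale2 <- max(1, q_mv / (j - m))
  se <- sqrt(diag(solve(xtwx)) * scale2)
  p <- 2 * stats::pt(-abs(coef / se), j - m)
  crit <- stats::qt(0.975, j - m)
  out <- data.frame(exposure = colnames(X), nsnp = j, b = coef, se = se,
                    p = p, OR = exp(coef), ci_low = exp(coef - crit * se),
                    ci_high = exp(coef + crit * se), method = "mvmr_ivw",
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "re_scale") <- sqrt(scale2)
  attr(out, "q_mv") <- q_mv
  class(out) <- c("mvmr_estimate", "data.frame")
  out
}

# Multivariate leave-one-out WLS coefficients for each left-out SNP.
mvmr_loo_coefs <- function(X, y, w) {
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * y)
  t(vapply(seq_len(nrow(X)), function(jj) {
    xj <- X[jj, ]
    drop(solve(xtwx - w[jj] * tcrossprod(xj),
               xtwy - w[jj] * xj * y[jj]))
  }, numeric(ncol(X))))
}

#' Multivariable MR-PRESSO
#'
#' The univariable PRESSO logic with multivariate leave-one-out fits
#' generating the expected outcome effects: observed weighted RSS against a
#' simulated null (bx* and by* drawn from their sampling normals around the
#' leave-one-out predictions), add-one global p, Bonferroni-adjusted
#' per-SNP outlier tests, and an outlier-corrected [mvmr_ivw()] refit.
#'
#' @param inputs An [mvmr_inputs()] with at least m + 3 SNPs.
#' @param n_sim Simulated null replicates.
#' @param outlier_alpha Flagging level for adjusted per-SNP tests.
#' @param seed RNG seed.
#' @return List of class `presso_result` (multivariable flavour): fields as
#'   [mr_presso()] with `estimate_raw` / `estimate_outlier_corrected` being
#'   `mvmr_estimate` tables.
#' @export
mvmr_presso <- function(inputs, n_sim = 1000, outlier_alpha = 0.05,
                        seed = NULL) {
  stopifnot(inherits(inputs, "mvmr_inputs"))
  X <- inputs$bx
  j <- nrow(X)
  m <- ncol(X)
  if (j < m + 3) stop("insufficient data: need at least m + 3 SNPs")
  if (!is.null(seed)) set.seed(seed)
  w <- 1 / inputs$sy^2
  loo <- mvmr_loo_coefs(X, inputs$by, w)
  mu <- rowSums(X * loo)
  res_obs <- (inputs$by - mu)^2 * w
  rss_obs <- sum(res_obs)

  rss_sim <- matrix(NA_real_, n_sim, j)
  for (s in seq_len(n_sim)) {
    Xs <- X + inputs$sx * matrix(stats::rnorm(j * m), j, m)
    ys <- stats::rnorm(j, mu, inputs$sy)
    loos <- mvmr_loo_coefs(Xs, ys, w)
    rss_sim[s, ] <- (ys - rowSums(Xs * loos))^2 * w
  }
  tot_sim <- rowSums(rss_sim)
  global_p <- (1 + sum(tot_sim >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (colSums(rss_sim >= matrix(res_obs, n_sim, j,
                                              byrow = TRUE)) + 1) / (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * j)
  out_flag <- outlier_p < outlier_alpha
  if (all(out_flag)) stop("degenerate removal: every SNP flagged as outlier")

  estimate_raw <- mvmr_ivw(inputs)
  estimate_corr <- NULL
  if (any(out_flag)) {
    keep <- !out_flag
    estimate_corr <- mvmr_ivw(
      mvmr_inputs(X[keep, , drop = FALSE], inputs$sx[keep, , drop = FALSE],
                  inputs$by[keep], inputs$sy[keep],
                  snp = inputs$snp[keep]))
    estimate_corr$method <- "mvmr_presso"
  }
  structure(list(rss_observed = rss_obs, global_p = global_p,
                 outlier_p = stats::setNames(outlier_p, inputs$snp),
                 outliers = inputs$snp[out_flag], distortion_p = NA_real_,
                 estimate_raw = estimate_raw,
                 estimate_outlier_corrected = estimate_corr,
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}
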