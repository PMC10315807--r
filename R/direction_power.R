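# Directionality (Steiger), asymptotic power for binary outcomes, and a
# lightweight LD-score regression for heritability / genetic correlation.

#' Steiger directionality test
#'
#' Sums per-SNP variance explained on each trait (frequency-free reduced
#' formula), converts each trait-level R2 to a correlation r = sqrt(R2)
#' (clipped just below 1), and compares the two Fisher-transformed
#' correlations: z = (atanh r_exp - atanh r_out) /
#' sqrt(1/(n_exp-3) + 1/(n_out-3)). The causal direction is declared
#' forward when the instruments explain strictly more variance in the
#' exposure than in the outcome. For a binary outcome the observed-scale
#' R2 with total N is used - an approximation, with no liability-scale
#' correction.
#'
#' @param h Harmonized set.
#' @param n_exp,n_out Cohort sample sizes (default: carried on `h`); both
#'   must exceed 3.
#' @return List of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `direction_forward`, `ambiguous`, `z`, `pvalue`.
#' @export
steiger_test <- function(h, n_exp = attr(h, "n_exposure"),
                         n_out = attr(h, "n_outcome")) {
  check_harmonized(h, 1)
  if (is.null(n_exp) || is.null(n_out) || is.na(n_exp) || is.na(n_out) ||
      n_exp <= 3 || n_out <= 3) {
    stop("sample sizes must be known and exceed 3")
  }
  r2x <- sum(variance_explained(h$bx, h$sx, n_exp))
  r2y <- sum(variance_explained(h$by, h$sy, n_out))
  rx <- sqrt(min(r2x, 1 - 1e-12))
  ry <- sqrt(min(r2y, 1 - 1e-12))
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(list(r2_exposure = r2x, r2_outcome = r2y,
                 direction_forward = r2x > r2y,
                 ambiguous = r2x == r2y,
                 z = z, pvalue = 2 * stats::pnorm(-abs(z))),
            class = "steiger_result")
}

#' Asymptotic power of an IVW test for a binary outcome
#'
#' Non-centrality approximation: power =
#' Phi(|log OR| * sqrt(n * R2 * K(1-K)) - z_(1-alpha/2)), where n is the
#' outcome sample size, K the case fraction and R2 the variance in the
#' exposure explained by the instruments. The opposite-direction tail is
#' ignored, as in the standard online calculator's model.
#'
#' @param n Outcome sample size.
#' @param K Case fraction, strictly in (0, 1).
#' @param r2_instrument Instrument variance explained.
#' @param or_alt Odds ratio under the alternative.
#' @param alpha Type-I error rate.
#' @return List of class `power_result` echoing the inputs plus `power`.
#' @export
mr_power <- function(n, K, r2_instrument, or_alt, alpha = 0.05) {
  if (K <= 0 || K >= 1) stop("case fraction K must lie strictly in (0, 1)")
  stopifnot(n >= 1, r2_instrument >= 0, r2_instrument < 1, or_alt > 0,
            alpha > 0, alpha < 1)
  ncp <- abs(log(or_alt)) * sqrt(n * r2_instrument * K * (1 - K))
  structure(list(n = n, case_fraction = K, r2_instrument = r2_instrument,
                 or_alt = or_alt, alpha = alpha,
                 power = stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))),
            class = "power_result")
}

#' LD-score panel of per-SNP z-scores and LD scores
#'
#' @param l2 Per-SNP LD scores (conventionally >= 1).
#' @param z1 Z-scores for trait 1.
#' @param z2 Optional z-scores for trait 2 (same SNPs, same order).
#' @param M Number of SNPs in the reference from which `l2` was computed.
#' @param N1,N2 GWAS sample sizes.
#' @param snp Optional SNP ids.
#' @return An `ldsc_panel` list.
#' @export
ldsc_panel <- function(l2, z1, z2 = NULL, M, N1, N2 = NULL, snp = NULL) {
  stopifnot(length(l2) == length(z1), all(l2 >= 0), M > 0, N1 > 0)
  if (!is.null(z2)) {
    stopifnot(length(z2) == length(z1), !is.null(N2), N2 > 0)
  }
  structure(list(l2 = l2, z1 = z1, z2 = z2, M = M, N1 = N1, N2 = N2,
                 snp = snp),
            class = "ldsc_panel")
}

#' Write / read an LD-score panel (TSV + JSON sidecar for M and N)
#'
#' @param panel An [ldsc_panel()].
#' @param path TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path` (writer) or an `ldsc_panel` (reader).
#' @export
write_ldsc_panel <- function(panel, path) {
  df <- data.frame(snp = if (is.null(panel$snp))
                     paste0("snp", seq_along(panel$l2)) else panel$snp,
                   l2 = panel$l2, z_trait1 = panel$z1)
  if (!is.null(panel$z2)) df$z_trait2 <- panel$z2
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(M = panel$M, N1 = panel$N1, N2 = panel$N2),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ldsc_panel
#' @export
read_ldsc_panel <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  ldsc_panel(l2 = df$l2, z1 = df$z_trait1,
             z2 = if ("z_trait2" %in% names(df)) df$z_trait2 else NULL,
             M = meta$M, N1 = meta$N1, N2 = meta$N2, snp = df$snp)
}

# Weighted simple regression y ~ 1 + x via per-block sufficient statistics,
# enabling delete-one-block jackknife without refitting. Returns the full
# fit and the B delete-block (intercept, slope) pairs.
block_jackknife_fit <- function(x, y, w, n_blocks) {
  m <- length(x)
  if (m < 2 * n_blocks) {
    warning("fewer SNPs than 2x blocks; reducing block count")
    n_blocks <- max(2, m %/% 2)
  }
  block <- ceiling(seq_along(x) / (m / n_blocks))
  sw <- tapply(w, block, sum)
  swx <- tapply(w * x, block, sum)
  swxx <- tapply(w * x^2, block, sum)
  swy <- tapply(w * y, block, sum)
  swxy <- tapply(w * x * y, block, sum)
  tot <- c(sum(sw), sum(swx), sum(swxx), sum(swy), sum(swxy))
  solve_fit <- function(s) {
    det <- s[1] * s[3] - s[2]^2
    if (abs(det) < .Machine$double.eps * s[1] * max(s[3], 1)) {
      stop("singular design: no spread in LD scores")
    }
    c(intercept = (s[3] * s[4] - s[2] * s[5]) / det,
      slope = (s[1] * s[5] - s[2] * s[4]) / det)
  }
  full <- solve_fit(tot)
  dele <- t(vapply(seq_along(sw), function(b) {
    solve_fit(tot - c(sw[b], swx[b], swxx[b], swy[b], swxy[b]))
  }, c(intercept = 0, slope = 0)))
  list(full = full, delete = dele, n_blocks = length(sw))
}

jackknife_se <- function(theta) {
  b <- length(theta)
  sqrt((b - 1) / b * sum((theta - mean(theta))^2))
}

ldsc_weights <- function(l2, n, h2_guess, M) {
  # Heteroskedasticity + over-counting weights of the standard estimator,
  # with the first-pass heritability clamped into [0, 1].
  h2 <- min(max(h2_guess, 0), 1)
  1 / (2 * (1 + n * h2 * l2 / M)^2 * pmax(l2, 1))
}

#' SNP-heritability by LD-score regression (lean single-component variant)
#'
#' Fits E[chi2_j] = 1 + N a + N h2 l_j / M by weighted regression of the
#' chi-square statistics on the LD scores with a free intercept, so that
#' uniform confounding inflation is absorbed by the intercept while the
#' slope estimates h2. Weights follow the standard heteroskedasticity /
#' over-counting form evaluated at a first-pass OLS estimate. Standard
#' errors come from a delete-one-block jackknife over contiguous blocks.
#'
#' @param panel An [ldsc_panel()].
#' @param trait 1 or 2 (which z-score vector to use).
#' @param n_blocks Jackknife blocks (default 200; reduced with a warning if
#'   the panel is small).
#' @return List of class `ldsc_result`: `h2`, `h2_se`, `intercept`,
#'   `intercept_se`, `n_blocks`.
#' @export
ldsc_h2 <- function(panel, trait = 1, n_blocks = 200) {
  stopifnot(inherits(panel, "ldsc_panel"))
  z <- if (trait == 1) panel$z1 else panel$z2
  n <- if (trait == 1) panel$N1 else panel$N2
  if (is.null(z)) stop("panel has no trait ", trait)
  chi2 <- z^2
  if (stats::var(panel$l2) == 0) stop("singular design: no spread in LD scores")
  ols <- stats::coef(stats::lm(chi2 ~ panel$l2))
  w <- ldsc_weights(panel$l2, n, ols[2] * panel$M / n, panel$M)
  fit <- block_jackknife_fit(panel$l2, chi2, w, n_blocks)
  h2 <- unname(fit$full["slope"]) * panel$M / n
  h2_del <- fit$delete[, "slope"] * panel$M / n
  structure(list(h2 = h2, h2_se = jackknife_se(h2_del),
                 intercept = unname(fit$full["intercept"]),
                 intercept_se = jackknife_se(fit$delete[, "intercept"]),
                 n_blocks = fit$n_blocks),
            class = "ldsc_result")
}

#' Genetic correlation by cross-trait LD-score regression
#'
#' Regresses the z-score products z1_j z2_j on the LD scores, fitting
#' E[z1 z2] = sqrt(N1 N2) rho_g l_j / M + intercept; the genetic covariance
#' slope is combined with the two single-trait heritability fits into
#' rg = rho_g / sqrt(h2_1 h2_2). The jackknife recomputes all three
#' regressions on every block deletion so the SE reflects their joint
#' sampling variability; rg is clamped to \[-1, 1\] after estimation.
#'
#' @param panel An [ldsc_panel()] with two traits on the same SNPs.
#' @param n_blocks Jackknife blocks.
#' @return List of class `ldsc_result`: `rg`, `rg_se`, `pvalue`, `gencov`,
#'   `h2_1`, `h2_2`, `intercept` (of the cross regression), `n_blocks`.
#' @export
ldsc_rg <- function(panel, n_blocks = 200) {
  stopifnot(inherits(panel, "ldsc_panel"))
  if (is.null(panel$z2)) stop("two z-score vectors on the same SNPs required")
  if (stats::var(panel$l2) == 0) stop("singular design: no spread in LD scores")
  M <- panel$M
  ols1 <- stats::coef(stats::lm(I(panel$z1^2) ~ panel$l2))
  ols2 <- stats::coef(stats::lm(I(panel$z2^2) ~ panel$l2))
  w1 <- ldsc_weights(panel$l2, panel$N1, ols1[2] * M / panel$N1, M)
  w2 <- ldsc_weights(panel$l2, panel$N2, ols2[2] * M / panel$N2, M)
  wx <- sqrt(w1 * w2)
  f1 <- block_jackknife_fit(panel$l2, panel$z1^2, w1, n_blocks)
  f2 <- block_jackknife_fit(panel$l2, panel$z2^2, w2, n_blocks)
  fx <- block_jackknife_fit(panel$l2, panel$z1 * panel$z2, wx, n_blocks)
  rg_of <- function(s1, s2, sx) {
    h2_1 <- s1 * M / panel$N1
    h2_2 <- s2 * M / panel$N2
    gencov <- sx * M / sqrt(panel$N1 * panel$N2)
    gencov / sqrt(max(h2_1, 1e-12) * max(h2_2, 1e-12))
  }
  rg_raw <- rg_of(f1$full["slope"], f2$full["slope"], fx$full["slope"])
  rg_del <- vapply(seq_len(nrow(fx$delete)), function(b) {
    rg_of(f1$delete[b, "slope"], f2$delete[b, "slope"], fx$delete[b, "slope"])
  }, numeric(1))
  rg_se <- jackknife_se(rg_del)
  rg <- unname(min(max(rg_raw, -1), 1))
  structure(list(rg = rg, rg_se = rg_se,
                 pvalue = 2 * stats::pnorm(-abs(rg_raw / rg_se)),
                 gencov = unname(fx$full["slope"]) * M /
                   sqrt(panel$N1 * panel$N2),
                 h2_1 = unname(f1$full["slope"]) * M / panel$N1,
                 h2_2 = unname(f2$full["slope"]) * M / panel$N2,
                 intercept = unname(fx$full["intercept"]),
                 n_blocks = fx$n_blocks),
            class = "ldsc_result")
}
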