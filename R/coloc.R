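# Bayesian colocalization of two regional association signals via per-SNP
# Wakefield approximate Bayes factors and the five-hypothesis posterior.

#' Wakefield approximate Bayes factor (log scale)
#'
#' With V = se^2, W = prior_sd^2 and z = beta/se:
#' lABF = 0.5 log(V/(V+W)) + (z^2/2) * W/(V+W). Positive values favour
#' association; as the effect prior collapses (W -> 0) the factor tends
#' to 0.
#'
#' @param beta,se Marginal effect and its SE (se > 0).
#' @param prior_sd Prior SD of a true effect (> 0).
#' @return Log approximate Bayes factor (vectorized).
#' @export
log_abf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd > 0))
  v <- se^2
  w <- prior_sd^2
  r <- w / (v + w)
  0.5 * log1p(-r) + (beta / se)^2 / 2 * r
}

#' Regional association statistics for one trait
#'
#' If `se` is absent but `z` is supplied, the SE is reconstructed from the
#' allele frequency and sample size under a unit-variance trait
#' (se ~ 1/sqrt(2 p (1-p) n)) and beta = z * se.
#'
#' @param df Data frame with `snp`, `maf`, and either `beta` + `se` or `z`.
#' @param n Sample size.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param case_fraction Case fraction for binary traits.
#' @param trait_id Label.
#' @return A `regional_assoc` data frame with attributes `n`, `trait_type`,
#'   `case_fraction`, `trait_id`.
#' @export
regional_assoc <- function(df, n, trait_type = c("quantitative", "binary"),
                           case_fraction = NULL, trait_id = "trait") {
  trait_type <- match.arg(trait_type)
  stopifnot(all(c("snp", "maf") %in% names(df)))
  if (anyDuplicated(df$snp)) stop("single region: snp ids must be unique")
  if (any(df$maf <= 0 | df$maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (!all(c("beta", "se") %in% names(df))) {
    if (!"z" %in% names(df)) stop("need beta+se or z columns")
    se <- 1 / sqrt(2 * df$maf * (1 - df$maf) * n)
    df$se <- se
    df$beta <- df$z * se
  }
  if (any(df$se <= 0)) stop("se must be positive")
  structure(as.data.frame(df)[, c("snp", "beta", "se", "maf")],
            class = c("regional_assoc", "data.frame"),
            n = n, trait_type = trait_type, case_fraction = case_fraction,
            trait_id = trait_id)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf (with warning) on cancellation.
logdiffexp <- function(a, b) {
  if (b >= a) {
    warning("H3 weight clamped at 0 after numerical cancellation")
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}

#' Colocalization under the single-causal-variant model
#'
#' Computes per-SNP Wakefield log-ABFs for both traits and evaluates the
#' posterior over the five hypotheses: H0 no association with either trait,
#' H1/H2 association with one trait only, H3 both traits with distinct
#' causal variants, H4 a shared causal variant. Sums over single-SNP
#' configurations are taken in log space; the H3 term S1*S2 - S12 is a
#' log-space difference clamped at zero if cancellation makes it negative.
#' PP.H4 > 0.8 is flagged as strong evidence for a shared variant.
#'
#' @param t1,t2 [regional_assoc()] objects; SNPs matched by id (inner join,
#'   at least one shared SNP).
#' @param p1,p2 Prior probability that a SNP is causal for trait 1 / 2 only.
#' @param p12 Prior probability that a SNP is causal for both.
#' @param prior_sd1,prior_sd2 Effect-size prior SDs; default 0.2 for a
#'   quantitative trait and 0.15 for a binary one.
#' @return List of class `coloc_result`: `pp` (named `pp_h0`..`pp_h4`,
#'   summing to 1), `labf` (per-SNP data frame), `n_snps`, `top_snp` (the
#'   SNP dominating the shared-variant term), `decision` (`pp_h4 > 0.8`),
#'   `priors`.
#' @export
coloc_abf <- function(t1, t2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0)
  default_sd <- function(t) if (identical(attr(t, "trait_type"), "binary"))
    0.15 else 0.2
  if (is.null(prior_sd1)) prior_sd1 <- default_sd(t1)
  if (is.null(prior_sd2)) prior_sd2 <- default_sd(t2)
  shared <- intersect(t1$snp, t2$snp)
  if (length(shared) == 0) stop("no shared SNPs between the two traits")
  a <- t1[match(shared, t1$snp), ]
  b <- t2[match(shared, t2$snp), ]
  m <- length(shared)
  if (m * (p1 + p2 + p12) + m^2 * p1 * p2 >= 1) {
    warning("priors are large for this region size; posterior may be ",
            "dominated by the prior structure")
  }
  l1 <- log_abf(a$beta, a$se, prior_sd1)
  l2 <- log_abf(b$beta, b$se, prior_sd2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lw <- c(
    h0 = 0,
    h1 = log(p1) + ls1,
    h2 = log(p2) + ls2,
    h3 = log(p1) + log(p2) + logdiffexp(ls1 + ls2, ls12),
    h4 = log(p12) + ls12
  )
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("pp_", names(lw))
  structure(list(pp = pp,
                 labf = data.frame(snp = shared, labf_1 = l1, labf_2 = l2,
                                   stringsAsFactors = FALSE),
                 n_snps = m,
                 top_snp = shared[which.max(l1 + l2)],
                 decision = unname(pp["pp_h4"] > 0.8),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs, top shared SNP %s%s\n", x$n_snps,
              x$top_snp,
              if (x$decision) " [PP.H4 > 0.8: shared causal variant]" else ""))
  print(round(x$pp, 4))
  invisible(x)
}

#' Serialize a colocalization result (posterior + per-SNP lABFs) to JSON
#'
#' @param x A `coloc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coloc_result <- function(x, path) {
  jsonlite::write_json(
    list(pp = as.list(x$pp), n_snps = x$n_snps, top_snp = x$top_snp,
         decision = x$decision, priors = as.list(x$priors),
         labf = x$labf),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
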