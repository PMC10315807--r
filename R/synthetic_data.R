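# Generators producing GWAS summary statistics, LD regions, LD-score panels
# and confounder tables with known ground truth for every pipeline stage.

.NONPALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Configuration for the two-sample summary-statistics generator
#'
#' Defaults emulate the study conditions of a metabolite-to-cancer screen:
#' a quantitative exposure GWAS of 7,824 individuals and a binary outcome
#' GWAS of 32,072 (19,938 cases). Per-SNP exposure effects gamma_j are drawn
#' from N(`gamma_mean`, `gamma_sd`); the defaults give exposure association
#' z-scores around 6.5, comfortably past the p < 1e-5 instrument threshold
#' with per-SNP F around 40.
#'
#' @param J Number of instruments.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Outcome case fraction K in (0, 1).
#' @param theta True causal effect of the exposure on the outcome
#'   (log-odds per exposure SD).
#' @param gamma_mean,gamma_sd Law of the per-SNP exposure effects.
#' @param pleiotropy One of `"none"`, `"balanced"` (mean-zero direct
#'   effects), `"directional"` (positive-mean direct effects) or
#'   `"inside_violating"` (direct effects correlated with instrument
#'   strength).
#' @param pleiotropy_scale Magnitude of the direct effects (log-odds).
#' @param prop_invalid Fraction of SNPs receiving a direct effect.
#' @param eaf_range Uniform range for effect-allele frequencies.
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(J = 15, n_exposure = 7824, n_outcome = 32072,
                       case_fraction = 19938 / 32072, theta = 0,
                       gamma_mean = 0.12, gamma_sd = 0.06,
                       pleiotropy = c("none", "balanced", "directional",
                                      "inside_violating"),
                       pleiotropy_scale = 0, prop_invalid = 1,
                       eaf_range = c(0.05, 0.95), seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(J >= 1, n_exposure > 1, n_outcome > 1,
            case_fraction > 0, case_fraction < 1,
            prop_invalid >= 0, prop_invalid <= 1,
            eaf_range[1] > 0, eaf_range[2] < 1, eaf_range[1] < eaf_range[2])
  structure(list(J = J, n_exposure = n_exposure, n_outcome = n_outcome,
                 case_fraction = case_fraction, theta = theta,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 pleiotropy = pleiotropy,
                 pleiotropy_scale = pleiotropy_scale,
                 prop_invalid = prop_invalid, eaf_range = eaf_range,
                 seed = seed),
            class = "sim_config")
}

draw_pleiotropy <- function(config, gamma) {
  j <- config$J
  alpha <- numeric(j)
  n_inv <- round(config$prop_invalid * j)
  if (config$pleiotropy == "none" || n_inv == 0 ||
      config$pleiotropy_scale == 0) {
    return(list(alpha = alpha, invalid = integer(0)))
  }
  invalid <- sort(sample.int(j, n_inv))
  s <- config$pleiotropy_scale
  alpha[invalid] <- switch(
    config$pleiotropy,
    balanced = stats::rnorm(n_inv, 0, s),
    directional = stats::rnorm(n_inv, s, s / 4),
    inside_violating = s * gamma[invalid] / config$gamma_mean +
      stats::rnorm(n_inv, 0, s / 4)
  )
  list(alpha = alpha, invalid = invalid)
}

#' Simulate a two-sample MR data set with known ground truth
#'
#' Draws per-SNP exposure effects gamma_j, places each instrument far from
#' the others (distinct chromosomes, then 10 Mb apart), and generates
#' summary statistics on both sides: for a unit-variance quantitative
#' exposure se_x = 1/sqrt(2 N_exp f(1-f)) with bx ~ N(gamma, se_x); for the
#' binary outcome on the log-odds scale
#' se_y = 1/sqrt(2 N_out f(1-f) K(1-K)) with
#' by ~ N(theta gamma + alpha, se_y), where the direct (pleiotropic)
#' effects alpha follow the configured mode. Outcome effects are generated
#' directly on the summary log-odds scale - two-sample MR consumes nothing
#' else - and the exposure and outcome draws are independent (no sample
#' overlap).
#'
#' @param config A [sim_config()].
#' @param snp_prefix Prefix for generated rsID-style ids.
#' @param exposure_id,outcome_id Trait labels.
#' @return List with `exposure` and `outcome` [gwas_table()]s and `truth`
#'   (`theta`, `gamma`, `alpha`, `invalid` indices, `eaf`, config echo).
#' @export
simulate_two_sample <- function(config = sim_config(), snp_prefix = "rs",
                                exposure_id = "exposure",
                                outcome_id = "outcome") {
  if (!is.null(config$seed)) set.seed(config$seed)
  j <- config$J
  idx <- seq_len(j) - 1L
  snp <- sprintf("%s%06d", snp_prefix, seq_len(j))
  chr <- idx %% 22L + 1L
  pos <- 1e6 + (idx %/% 22L) * 1e7
  eaf <- stats::runif(j, config$eaf_range[1], config$eaf_range[2])
  gamma <- stats::rnorm(j, config$gamma_mean, config$gamma_sd)
  plei <- draw_pleiotropy(config, gamma)

  sex <- 1 / sqrt(2 * config$n_exposure * eaf * (1 - eaf))
  bx <- stats::rnorm(j, gamma, sex)
  K <- config$case_fraction
  sey <- 1 / sqrt(2 * config$n_outcome * eaf * (1 - eaf) * K * (1 - K))
  by <- stats::rnorm(j, config$theta * gamma + plei$alpha, sey)

  pair <- .NONPALINDROMIC_PAIRS[sample.int(nrow(.NONPALINDROMIC_PAIRS), j,
                                           replace = TRUE), , drop = FALSE]
  base <- data.frame(snp = snp, chr = chr, pos = pos,
                     effect_allele = pair[, 1], other_allele = pair[, 2],
                     eaf = eaf, stringsAsFactors = FALSE)
  exposure <- gwas_table(
    cbind(base, beta = bx, se = sex,
          pval = 2 * stats::pnorm(-abs(bx / sex)), n = config$n_exposure),
    trait_id = exposure_id, trait_type = "quantitative",
    n_total = config$n_exposure)
  outcome <- gwas_table(
    cbind(base, beta = by, se = sey,
          pval = 2 * stats::pnorm(-abs(by / sey)), n = config$n_outcome),
    trait_id = outcome_id, trait_type = "binary",
    n_total = config$n_outcome,
    n_cases = round(K * config$n_outcome))
  list(exposure = exposure, outcome = outcome,
       truth = list(theta = config$theta, gamma = gamma,
                    alpha = plei$alpha, invalid = plei$invalid,
                    eaf = eaf, config = config))
}

#' Simulate a synthetic metabolite universe for pipeline tests
#'
#' Generates `n_exposures` exposures with disjoint instrument sets, of which
#' the first `length(causal_theta)` have the given true causal effects on a
#' shared binary outcome and the rest are null. Two independent outcome
#' cohorts (primary and replication) are produced over the union of all
#' instruments, sharing the same true per-SNP outcome means.
#'
#' The default per-SNP effect law here is narrower and weaker than
#' [sim_config()]'s: instruments must clear the exposure significance
#' threshold while the outcome-side effects of causal-exposure instruments
#' (theta * gamma) stay below the outcome-exclusion threshold - the regime
#' of a metabolite screen, where per-variant effects on disease are small.
#'
#' @param n_exposures Number of exposures.
#' @param causal_theta True effects of the causal exposures (defaults to
#'   the planted set -0.5, 0.5, -0.4).
#' @param J Instruments per exposure.
#' @param n_exposure,n_outcome_primary,n_outcome_replication,case_fraction_primary,case_fraction_replication
#'   Cohort sizes (defaults at the scale of the motivating study).
#' @param gamma_mean,gamma_sd Per-SNP exposure effect law.
#' @param seed RNG seed.
#' @return List with `exposures` (named list of tables), `outcome_primary`,
#'   `outcome_replication`, and `truth` (`theta` per exposure, per-exposure
#'   instrument ids).
#' @export
simulate_metabolite_universe <- function(n_exposures = 20,
                                         causal_theta = c(-0.5, 0.5, -0.4),
                                         J = 30,
                                         n_exposure = 7824,
                                         n_outcome_primary = 32072,
                                         case_fraction_primary = 19938 / 32072,
                                         n_outcome_replication = 8554,
                                         case_fraction_replication = 4439 / 8554,
                                         gamma_mean = 0.11, gamma_sd = 0.03,
                                         seed = 1) {
  stopifnot(n_exposures >= length(causal_theta))
  set.seed(seed)
  theta <- c(causal_theta, rep(0, n_exposures - length(causal_theta)))
  ids <- sprintf("metabolite_%02d", seq_len(n_exposures))
  exposures <- vector("list", n_exposures)
  names(exposures) <- ids
  out_primary <- vector("list", n_exposures)
  out_replication <- vector("list", n_exposures)
  instrument_ids <- vector("list", n_exposures)
  gammas <- vector("list", n_exposures)

  for (i in seq_len(n_exposures)) {
    j <- J
    snp <- sprintf("rs%02d%05d", i, seq_len(j))
    chr <- (seq_len(j) - 1L) %% 22L + 1L
    # Each exposure's instruments sit in an exposure-specific 10 Mb slot so
    # instruments from different exposures never share a clumping window.
    pos <- 1e6 + (i - 1L) * 1e7 + ((seq_len(j) - 1L) %/% 22L) * 2e6
    eaf <- stats::runif(j, 0.05, 0.95)
    gamma <- stats::rnorm(j, gamma_mean, gamma_sd)
    sex <- 1 / sqrt(2 * n_exposure * eaf * (1 - eaf))
    bx <- stats::rnorm(j, gamma, sex)
    K1 <- case_fraction_primary
    K2 <- case_fraction_replication
    sey1 <- 1 / sqrt(2 * n_outcome_primary * eaf * (1 - eaf) * K1 * (1 - K1))
    sey2 <- 1 / sqrt(2 * n_outcome_replication * eaf * (1 - eaf) *
                       K2 * (1 - K2))
    mu <- theta[i] * gamma
    by1 <- stats::rnorm(j, mu, sey1)
    by2 <- stats::rnorm(j, mu, sey2)
    pair <- .NONPALINDROMIC_PAIRS[sample.int(8, j, replace = TRUE), ,
                                  drop = FALSE]
    base <- data.frame(snp = snp, chr = chr, pos = pos,
                       effect_allele = pair[, 1], other_allele = pair[, 2],
                       eaf = eaf, stringsAsFactors = FALSE)
    exposures[[i]] <- gwas_table(
      cbind(base, beta = bx, se = sex,
            pval = 2 * stats::pnorm(-abs(bx / sex)), n = n_exposure),
      trait_id = ids[i], trait_type = "quantitative", n_total = n_exposure)
    out_primary[[i]] <- cbind(base, beta = by1, se = sey1,
                              pval = 2 * stats::pnorm(-abs(by1 / sey1)),
                              n = n_outcome_primary)
    out_replication[[i]] <- cbind(base, beta = by2, se = sey2,
                                  pval = 2 * stats::pnorm(-abs(by2 / sey2)),
                                  n = n_outcome_replication)
    instrument_ids[[i]] <- snp
    gammas[[i]] <- gamma
  }
  outcome_primary <- gwas_table(
    do.call(rbind, out_primary), trait_id = "outcome_primary",
    trait_type = "binary", n_total = n_outcome_primary,
    n_cases = round(case_fraction_primary * n_outcome_primary))
  outcome_replication <- gwas_table(
    do.call(rbind, out_replication), trait_id = "outcome_replication",
    trait_type = "binary", n_total = n_outcome_replication,
    n_cases = round(case_fraction_replication * n_outcome_replication))
  list(exposures = exposures, outcome_primary = outcome_primary,
       outcome_replication = outcome_replication,
       truth = list(theta = stats::setNames(theta, ids),
                    causal = ids[seq_along(causal_theta)],
                    instruments = stats::setNames(instrument_ids, ids),
                    gamma = stats::setNames(gammas, ids), seed = seed))
}

#' Simulate a pair of LD-structured regional association signals
#'
#' Builds an AR(1) LD correlation matrix R (R_ij = rho^|i-j|), places causal
#' variants according to the mode, and draws marginal z-scores
#' z ~ MVN(R lambda sqrt(n), R) per trait, where lambda carries the causal
#' standardized effects (effect r^2 at the causal SNP). Betas and SEs are
#' reconstructed from z via the allele-frequency/sample-size approximation.
#'
#' @param m_snps Number of SNPs in the region (>= 2).
#' @param rho AR(1) correlation between adjacent SNPs, |rho| < 1.
#' @param causal_mode `"shared"`, `"distinct"`, `"null"` or `"trait1_only"`.
#' @param r2_causal Variance explained by the causal variant.
#' @param n1,n2 Sample sizes of the two traits.
#' @param seed RNG seed.
#' @return List with `t1`, `t2` ([regional_assoc()]) and `truth` (causal
#'   indices, shared flag, `rho`).
#' @export
simulate_ld_region <- function(m_snps = 100, rho = 0.7,
                               causal_mode = c("shared", "distinct", "null",
                                               "trait1_only"),
                               r2_causal = 0.01, n1 = 30000, n2 = 30000,
                               seed = NULL) {
  causal_mode <- match.arg(causal_mode)
  stopifnot(m_snps >= 2, abs(rho) < 1)
  if (!is.null(seed)) set.seed(seed)
  R <- rho^abs(outer(seq_len(m_snps), seq_len(m_snps), "-"))
  U <- chol(R)
  b <- sqrt(r2_causal)
  c1 <- c2 <- NA_integer_
  lam1 <- lam2 <- numeric(m_snps)
  mid <- ceiling(m_snps / 2)
  if (causal_mode %in% c("shared", "trait1_only")) {
    c1 <- mid
    lam1[c1] <- b
  }
  if (causal_mode == "shared") {
    c2 <- mid
    lam2[c2] <- b
  } else if (causal_mode == "distinct") {
    c1 <- max(1L, ceiling(m_snps / 4))
    c2 <- min(m_snps, ceiling(3 * m_snps / 4))
    lam1[c1] <- b
    lam2[c2] <- b
  }
  z1 <- drop(R %*% lam1) * sqrt(n1) + drop(crossprod(U, stats::rnorm(m_snps)))
  z2 <- drop(R %*% lam2) * sqrt(n2) + drop(crossprod(U, stats::rnorm(m_snps)))
  maf <- stats::runif(m_snps, 0.05, 0.5)
  snp <- sprintf("reg%05d", seq_len(m_snps))
  mk <- function(z, n, id) {
    regional_assoc(data.frame(snp = snp, z = z, maf = maf,
                              stringsAsFactors = FALSE),
                   n = n, trait_type = "quantitative", trait_id = id)
  }
  list(t1 = mk(z1, n1, "trait1"), t2 = mk(z2, n2, "trait2"),
       truth = list(causal_1 = c1, causal_2 = c2,
                    shared = causal_mode == "shared", rho = rho,
                    mode = causal_mode))
}

#' Simulate an LD-score panel with known heritability / genetic correlation
#'
#' LD scores are 1 plus Gamma-distributed excess; per SNP the pair
#' (z1, z2) is bivariate normal with Var(z_t) = 1 + N_t h2_t l_j / M and
#' Cov = sqrt(N1 N2) rg sqrt(h2_1 h2_2) l_j / M, the generative identity
#' that LD-score regression inverts.
#'
#' @param m_snps Panel size.
#' @param M Reference SNP count entering the slope.
#' @param N1,N2 GWAS sample sizes (`N2` may be `NULL` for one trait).
#' @param h2_1,h2_2 SNP-heritabilities in \[0, 1).
#' @param rg Genetic correlation, |rg| <= 1.
#' @param l2_shape,l2_scale Gamma law of the LD-score excess.
#' @param seed RNG seed.
#' @return List with `panel` ([ldsc_panel()]) and `truth`.
#' @export
simulate_ldsc_panel <- function(m_snps = 50000, M = 20000, N1 = 50000,
                                N2 = NULL, h2_1 = 0.3, h2_2 = NULL,
                                rg = NULL, l2_shape = 2, l2_scale = 50,
                                seed = NULL) {
  stopifnot(h2_1 >= 0, h2_1 < 1)
  if (!is.null(seed)) set.seed(seed)
  l2 <- 1 + stats::rgamma(m_snps, shape = l2_shape, scale = l2_scale)
  v1 <- 1 + N1 * h2_1 * l2 / M
  if (is.null(N2)) {
    z1 <- stats::rnorm(m_snps, 0, sqrt(v1))
    panel <- ldsc_panel(l2 = l2, z1 = z1, M = M, N1 = N1)
    return(list(panel = panel, truth = list(h2_1 = h2_1)))
  }
  stopifnot(!is.null(h2_2), h2_2 >= 0, h2_2 < 1, !is.null(rg), abs(rg) <= 1)
  v2 <- 1 + N2 * h2_2 * l2 / M
  cv <- sqrt(N1 * N2) * rg * sqrt(h2_1 * h2_2) * l2 / M
  if (any(cv^2 > v1 * v2)) stop("covariance matrix not positive definite")
  z1 <- stats::rnorm(m_snps, 0, sqrt(v1))
  # z2 | z1 is normal with mean (cv/v1) z1 and variance v2 - cv^2/v1.
  z2 <- stats::rnorm(m_snps, cv / v1 * z1, sqrt(v2 - cv^2 / v1))
  panel <- ldsc_panel(l2 = l2, z1 = z1, z2 = z2, M = M, N1 = N1, N2 = N2)
  list(panel = panel, truth = list(h2_1 = h2_1, h2_2 = h2_2, rg = rg))
}

#' Simulate a confounder-association table (PhenoScanner-style export)
#'
#' Planted SNP-trait pairs receive associations past the removal threshold;
#' optional noise rows for the remaining instruments get p-values well
#' above it.
#'
#' @param instrument_snps Character vector of instrument ids.
#' @param planted Data frame (`snp`, `trait`) of confounded instruments
#'   (must be a subset of `instrument_snps`).
#' @param n_noise Number of additional null rows to emit.
#' @param seed RNG seed.
#' @return Data frame (`snp`, `trait`, `pvalue`).
#' @export
simulate_confounder_table <- function(instrument_snps,
                                      planted = NULL, n_noise = 0,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(snp = character(), trait = character(),
                    pvalue = numeric(), stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0) {
    stopifnot(all(planted$snp %in% instrument_snps))
    out <- data.frame(snp = planted$snp, trait = planted$trait,
                      pvalue = 10^stats::runif(nrow(planted), -9, -6),
                      stringsAsFactors = FALSE)
  }
  if (n_noise > 0) {
    pool <- setdiff(instrument_snps, out$snp)
    pick <- sample(pool, min(n_noise, length(pool)))
    out <- rbind(out, data.frame(
      snp = pick, trait = "unrelated_trait",
      pvalue = stats::runif(length(pick), 1e-3, 1),
      stringsAsFactors = FALSE))
  }
  out
}
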