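# Data model and IO for GWAS summary statistics.
#
# Canonical TSV dialect: columns snp, chr, pos, effect_allele, other_allele,
# eaf, beta, se, pval, n (chr, pos, eaf optional). A column map adapts foreign
# headers at load time.

.GWAS_REQUIRED <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
.GWAS_OPTIONAL <- c("chr", "pos", "eaf", "n")
.GWAS_COLUMNS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct a validated GWAS summary-statistics table
#'
#' Wraps a data frame of per-SNP association records into a `gwas_table`,
#' enforcing the per-record invariants: single-base A/C/G/T alleles with
#' effect allele distinct from the other allele, `se > 0`, p-value in
#' \[0, 1\], effect-allele frequency strictly inside (0, 1) when present,
#' and sample size >= 1. Rows violating an invariant (including indels and
#' multi-allelic records) are dropped and counted in the load report;
#' duplicated SNP ids are an error because silently picking one record
#' would hide a data problem.
#'
#' @param df Data frame with at least columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; optionally `chr`, `pos`, `eaf`, `n`.
#' @param trait_id Character label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param n_total Total sample size (used to fill a missing `n` column).
#' @param n_cases Number of cases, binary traits only; must not exceed
#'   `n_total`.
#' @return A `gwas_table` (a data frame with the canonical columns) carrying
#'   attributes `trait_id`, `trait_type`, `n_total`, `n_cases` and
#'   `load_report` (named integer vector of dropped-row counts by reason).
#' @export
gwas_table <- function(df, trait_id, trait_type = c("quantitative", "binary"),
                       n_total = NULL, n_cases = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.GWAS_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(n_cases) && !is.null(n_total) && n_cases > n_total) {
    stop("n_cases must not exceed n_total")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in .GWAS_OPTIONAL) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  if (all(is.na(df$n)) && !is.null(n_total)) df$n <- n_total
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  bad_allele <- !(df$effect_allele %in% .BASES) |
    !(df$other_allele %in% .BASES) |
    df$effect_allele == df$other_allele
  bad_se <- is.na(df$se) | df$se <= 0 | !is.finite(df$se)
  bad_beta <- is.na(df$beta) | !is.finite(df$beta)
  bad_pval <- is.na(df$pval) | df$pval < 0 | df$pval > 1
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  bad_n <- !is.na(df$n) & df$n < 1

  report <- c(
    bad_allele = sum(bad_allele),
    nonpositive_se = sum(bad_se & !bad_allele),
    bad_beta = sum(bad_beta & !bad_allele & !bad_se),
    bad_pval = sum(bad_pval & !bad_allele & !bad_se & !bad_beta),
    bad_eaf = sum(bad_eaf & !bad_allele & !bad_se & !bad_beta & !bad_pval),
    bad_n = sum(bad_n & !bad_allele & !bad_se & !bad_beta & !bad_pval & !bad_eaf)
  )
  keep <- !(bad_allele | bad_se | bad_beta | bad_pval | bad_eaf | bad_n)
  df <- df[keep, .GWAS_COLUMNS, drop = FALSE]
  rownames(df) <- NULL

  dup <- df$snp[duplicated(df$snp)]
  if (length(dup)) {
    stop("validation error: duplicate snp id(s): ",
         paste(unique(dup), collapse = ", "))
  }

  structure(df,
            class = c("gwas_table", "data.frame"),
            trait_id = trait_id,
            trait_type = trait_type,
            n_total = n_total,
            n_cases = n_cases,
            load_report = report)
}

#' Read a GWAS summary-statistics table from delimited text
#'
#' @param path Path to a delimited text file with a header row.
#' @param trait_id,trait_type,n_total,n_cases Passed to [gwas_table()].
#' @param column_map Optional named character vector mapping canonical column
#'   names to the file's header names, e.g.
#'   `c(snp = "variant_id", pval = "p_value")`. Unmapped canonical names are
#'   looked up verbatim.
#' @param sep Field separator (default tab).
#' @return A [gwas_table()].
#' @export
read_gwas_table <- function(path, trait_id,
                            trait_type = c("quantitative", "binary"),
                            n_total = NULL, n_cases = NULL,
                            column_map = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("format error: column '", src, "' (mapped to '", canon,
             "') not found in ", path)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  gwas_table(raw, trait_id = trait_id, trait_type = trait_type,
             n_total = n_total, n_cases = n_cases)
}

#' Write a GWAS table in the canonical TSV dialect
#'
#' @param x A [gwas_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(x, path) {
  stopifnot(inherits(x, "gwas_table"))
  data.table::fwrite(as.data.frame(x)[, .GWAS_COLUMNS], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

is_palindromic <- function(effect_allele, other_allele) {
  other_allele == unname(.COMPLEMENT[effect_allele])
}

#' Construct a harmonized exposure/outcome effect set directly
#'
#' Low-level constructor used by the simulators and tests; [harmonize_pair()]
#' is the user-facing route from two GWAS tables.
#'
#' @param snp,bx,sx,px,by,sy,py,eaf Per-SNP vectors: id, exposure beta/se/p,
#'   outcome beta/se/p, effect-allele frequency (may be `NA`).
#' @param effect_allele,other_allele Optional allele columns (exposure
#'   orientation).
#' @param exposure_id,outcome_id Trait labels.
#' @param drops Data frame (`snp`, `reason`) of SNPs removed on the way in.
#' @param n_exposure,n_outcome Cohort sample sizes (carried for Steiger).
#' @return A `harmonized_set` data frame.
#' @export
harmonized_set <- function(snp, bx, sx, px, by, sy, py, eaf = NA,
                           effect_allele = NA, other_allele = NA,
                           exposure_id = "exposure", outcome_id = "outcome",
                           drops = NULL, n_exposure = NA, n_outcome = NA) {
  stopifnot(all(sx > 0), all(sy > 0))
  h <- data.frame(snp = as.character(snp),
                  effect_allele = effect_allele, other_allele = other_allele,
                  bx = bx, sx = sx, px = px, by = by, sy = sy, py = py,
                  eaf = eaf, stringsAsFactors = FALSE)
  if (is.null(drops)) {
    drops <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  }
  structure(h,
            class = c("harmonized_set", "data.frame"),
            exposure_id = exposure_id, outcome_id = outcome_id,
            drops = drops, n_exposure = n_exposure, n_outcome = n_outcome)
}

#' Harmonize outcome effects onto the exposure's effect-allele orientation
#'
#' Matches SNPs by rsID, re-signs outcome effects (beta negated, frequency
#' complemented) where the outcome's alleles are recorded in the swapped
#' order, and drops SNPs that cannot be harmonized: palindromic variants
#' (A/T or G/C pairs, whose strand cannot be resolved from alleles alone),
#' allele-incompatible pairs (e.g. A/G against A/C), and SNPs absent from
#' the outcome table. Every removal is recorded with a reason code so that
#' retained + dropped always equals the number of SNPs requested.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param snps SNP ids to harmonize; defaults to all SNPs in `exposure`.
#'   Must all be present in `exposure`.
#' @return A `harmonized_set`: per-SNP rows (`snp`, `bx`, `sx`, `px`, `by`,
#'   `sy`, `py`, `eaf`) on the exposure's effect-allele orientation, with a
#'   drop audit in `attr(, "drops")` (reason codes `palindromic`,
#'   `incompatible_alleles`, `missing_in_outcome`).
#' @export
harmonize_pair <- function(exposure, outcome, snps = NULL) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  if (is.null(snps)) snps <- exposure$snp
  missing_exp <- setdiff(snps, exposure$snp)
  if (length(missing_exp)) {
    stop("snp(s) not present in exposure table: ",
         paste(utils::head(missing_exp, 5), collapse = ", "))
  }
  ex <- as.data.frame(exposure)[match(snps, exposure$snp), ]
  om <- match(snps, outcome$snp)

  reason <- rep(NA_character_, length(snps))
  reason[is.na(om)] <- "missing_in_outcome"
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  reason[is.na(reason) & pal] <- "palindromic"

  ou <- as.data.frame(outcome)[ifelse(is.na(om), 1L, om), ]
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  reason[is.na(reason) & !(same | swapped)] <- "incompatible_alleles"

  keep <- is.na(reason)
  if (!any(keep)) stop("no overlapping instruments after harmonization")

  by <- ifelse(swapped, -ou$beta, ou$beta)
  eaf_out <- ifelse(swapped, 1 - ou$eaf, ou$eaf)
  eaf <- ifelse(is.na(ex$eaf), eaf_out, ex$eaf)

  drops <- data.frame(snp = snps[!keep], reason = reason[!keep],
                      stringsAsFactors = FALSE)
  harmonized_set(snp = snps[keep],
                 bx = ex$beta[keep], sx = ex$se[keep], px = ex$pval[keep],
                 by = by[keep], sy = ou$se[keep], py = ou$pval[keep],
                 eaf = eaf[keep],
                 effect_allele = ex$effect_allele[keep],
                 other_allele = ex$other_allele[keep],
                 exposure_id = attr(exposure, "trait_id"),
                 outcome_id = attr(outcome, "trait_id"),
                 drops = drops,
                 n_exposure = attr(exposure, "n_total"),
                 n_outcome = attr(outcome, "n_total"))
}

#' Serialize a harmonized set (rows + drop audit) to TSV
#'
#' @param h A `harmonized_set`.
#' @param path Output path for the retained rows; the drop audit goes to
#'   `paste0(path, ".drops.tsv")`.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(h, path) {
  stopifnot(inherits(h, "harmonized_set"))
  data.table::fwrite(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     na = "NA")
  data.table::fwrite(attr(h, "drops"), paste0(path, ".drops.tsv"),
                     sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# Subset a harmonized set by row index, preserving attributes.
subset_harmonized <- function(h, idx) {
  out <- as.data.frame(h)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("exposure_id", "outcome_id", "drops", "n_exposure", "n_outcome")) {
    attr(out, a) <- attr(h, a)
  }
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> trait '%s' (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  rep <- attr(x, "load_report")
  if (sum(rep) > 0) {
    cat("  dropped at load:",
        paste(sprintf("%s=%d", names(rep)[rep > 0], rep[rep > 0]),
              collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s, %d SNPs (%d dropped)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"),
              nrow(x), nrow(attr(x, "drops"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
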