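# Instrument selection: significance thresholding, greedy LD clumping,
# variance explained / F statistics, outcome-overlap exclusion, and
# confounder filtering.

#' Selection thresholds for instrument screening
#'
#' Defaults follow the screening conditions used for metabolite GWAS with a
#' modest number of genome-wide signals: an eased exposure threshold of
#' p < 1e-5, clumping at r^2 > 0.1 within 500 kb, per-SNP F >= 10,
#' exclusion of SNPs associated with the outcome at p < 1e-5, and a minimum
#' of three instruments ("more than two SNPs") per exposure.
#'
#' @param p_exposure Exposure significance threshold.
#' @param clump_r2 LD r-squared above which the weaker SNP is removed
#'   (exclusive: removal requires r2 > `clump_r2`).
#' @param clump_window_kb Clumping window in kilobases.
#' @param f_min Minimum per-SNP F statistic.
#' @param p_outcome_exclude Outcome-association threshold for exclusion.
#' @param min_snps Minimum surviving instruments for an exposure to be
#'   analysable.
#' @param k_for_f Number of instruments `k` entering the F formula. The
#'   filter is applied per SNP, so the default is 1; the aggregate F with
#'   k = J is reported alongside by [select_instruments()].
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_exposure = 1e-5, clump_r2 = 0.1,
                             clump_window_kb = 500, f_min = 10,
                             p_outcome_exclude = 1e-5, min_snps = 3,
                             k_for_f = 1) {
  stopifnot(p_exposure > 0, clump_r2 > 0, clump_window_kb > 0, f_min >= 0,
            p_outcome_exclude > 0, min_snps >= 1, k_for_f >= 1)
  structure(list(p_exposure = p_exposure, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 p_outcome_exclude = p_outcome_exclude, min_snps = min_snps,
                 k_for_f = k_for_f),
            class = "selection_config")
}

#' Variance in the exposure explained by a single variant
#'
#' Computes R2 = 2 b^2 f(1-f) / (2 b^2 f(1-f) + 2 se^2 N f(1-f)). The shared
#' 2 f(1-f) factor cancels, so the value reduces to b^2 / (b^2 + N se^2) and
#' is returned even when the effect-allele frequency is unknown.
#'
#' @param beta Per-allele effect size.
#' @param se Standard error of `beta` (> 0).
#' @param n Exposure sample size (>= 2).
#' @param eaf Effect-allele frequency in (0, 1), or `NA`/`NULL` when unknown.
#' @return Variance explained, in \[0, 1).
#' @export
variance_explained <- function(beta, se, n, eaf = NULL) {
  stopifnot(all(se > 0), all(n >= 2))
  if (!is.null(eaf) && any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) {
    stop("eaf must lie strictly inside (0, 1)")
  }
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F statistic
#'
#' F = (N - k - 1)/k * R2/(1 - R2); variants with F < 10 are conventionally
#' regarded as poor instruments.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments in the regression (1 for the per-SNP
#'   filter).
#' @return F statistic (>= 0).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  stopifnot(k >= 1)
  (n - k - 1) / k * r2 / (1 - r2)
}

#' In-memory pairwise LD matrix
#'
#' @param mat Square numeric matrix of pairwise r-squared values; symmetric,
#'   unit diagonal, entries in \[0, 1\].
#' @param snps SNP ids in matrix order (defaults to `rownames(mat)`).
#' @return An `ld_matrix`.
#' @export
ld_matrix <- function(mat, snps = rownames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(snps)) stop("ld_matrix needs snp ids (rownames or `snps`)")
  stopifnot(nrow(mat) == ncol(mat), length(snps) == nrow(mat))
  if (any(mat < 0 | mat > 1)) stop("LD r2 values must lie in [0, 1]")
  if (max(abs(mat - t(mat))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(mat) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  dimnames(mat) <- list(snps, snps)
  structure(mat, class = c("ld_matrix", "matrix"))
}

#' Read a square LD r-squared matrix from TSV (rsID header row and column)
#'
#' @param path File path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- ids
  ld_matrix(mat, snps = ids)
}

ld_r2_between <- function(ld, a, b) {
  if (is.null(ld)) return(NA_real_)
  ia <- match(a, rownames(ld))
  ib <- match(b, rownames(ld))
  out <- rep(NA_real_, length(b))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- ld[cbind(rep(ia, length.out = length(b))[ok], ib[ok])]
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as the index
#' and removes all remaining SNPs on the same chromosome within the window
#' whose r-squared with the index exceeds `clump_r2`. Ties on p-value break
#' by smaller position, then lexicographic rsID, so the result is
#' deterministic and invariant to input ordering.
#'
#' @param candidates Data frame with columns `snp`, `chr`, `pos`, `pval`.
#' @param ld An [ld_matrix()] (or `NULL` when no two candidates share a
#'   window). A missing r2 for an in-window pair is an error, never silently
#'   treated as independence.
#' @param clump_r2 Removal threshold (exclusive).
#' @param window_kb Window in kilobases.
#' @return Character vector of retained SNP ids, in selection order.
#' @export
clump_variants <- function(candidates, ld = NULL, clump_r2 = 0.1,
                           window_kb = 500) {
  stopifnot(all(c("snp", "chr", "pos", "pval") %in% names(candidates)))
  cand <- as.data.frame(candidates)[, c("snp", "chr", "pos", "pval")]
  cand <- cand[order(cand$pval, cand$pos, cand$snp), , drop = FALSE]
  window <- window_kb * 1000
  retained <- character(0)
  while (nrow(cand) > 0) {
    idx <- cand[1, ]
    retained <- c(retained, idx$snp)
    cand <- cand[-1, , drop = FALSE]
    if (nrow(cand) == 0) break
    in_window <- !is.na(cand$chr) & !is.na(idx$chr) & cand$chr == idx$chr &
      abs(cand$pos - idx$pos) <= window
    if (any(in_window)) {
      r2 <- ld_r2_between(ld, idx$snp, cand$snp[in_window])
      if (any(is.na(r2))) {
        bad <- cand$snp[in_window][is.na(r2)]
        stop("missing LD entry for in-window pair(s): ", idx$snp, " vs ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      drop <- rep(FALSE, nrow(cand))
      drop[which(in_window)[r2 > clump_r2]] <- TRUE
      cand <- cand[!drop, , drop = FALSE]
    }
  }
  retained
}

#' Select genetic instruments for one exposure
#'
#' Runs the full instrument pipeline: exposure significance filter, greedy
#' LD clumping, per-SNP variance explained and F statistic with removal of
#' weak variants, harmonization against the outcome, and exclusion of SNPs
#' associated with the outcome. Every removal is audited with a per-stage
#' reason so survivors plus removals always reconcile with the initial
#' significant count. Falling below `min_snps` survivors is a recorded
#' outcome (`status = "insufficient_instruments"`), not an error, so a
#' screen across hundreds of exposures keeps running.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param ld [ld_matrix()] covering exposure-significant SNPs that share a
#'   clumping window (may be `NULL` if none do).
#' @param config A [selection_config()].
#' @return A list of class `instrument_selection` with elements
#'   `instruments` (data frame incl. `r2` and `f_stat`), `harmonized`
#'   (a `harmonized_set` of the survivors), `audit` (data frame
#'   `snp`/`stage`), `status` (`"ok"` or `"insufficient_instruments"`),
#'   `n_significant`, `f_aggregate` (F with k = J) and the config.
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               config = selection_config()) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  audit <- data.frame(snp = character(), stage = character(),
                      stringsAsFactors = FALSE)
  note <- function(snps, stage) {
    if (length(snps)) {
      audit <<- rbind(audit, data.frame(snp = snps, stage = stage,
                                        stringsAsFactors = FALSE))
    }
  }

  sig <- as.data.frame(exposure)[exposure$pval < config$p_exposure, ,
                                 drop = FALSE]
  n_significant <- nrow(sig)
  result <- function(instr, h, status) {
    structure(list(instruments = instr, harmonized = h, audit = audit,
                   status = status, n_significant = n_significant,
                   f_aggregate = if (!is.null(instr) && nrow(instr) > 1)
                     f_statistic(min(sum(instr$r2), 1 - 1e-12),
                                 attr(exposure, "n_total"), k = nrow(instr))
                   else NA_real_,
                   exposure_id = attr(exposure, "trait_id"),
                   config = config),
              class = "instrument_selection")
  }
  if (n_significant == 0) return(result(NULL, NULL, "insufficient_instruments"))

  kept <- clump_variants(sig, ld = ld, clump_r2 = config$clump_r2,
                         window_kb = config$clump_window_kb)
  note(setdiff(sig$snp, kept), "clumped")
  sig <- sig[match(kept, sig$snp), , drop = FALSE]

  n_exp <- attr(exposure, "n_total")
  if (is.null(n_exp)) n_exp <- sig$n
  sig$r2 <- variance_explained(sig$beta, sig$se, n_exp, eaf = sig$eaf)
  sig$f_stat <- f_statistic(sig$r2, n_exp, k = config$k_for_f)
  weak <- sig$f_stat < config$f_min
  note(sig$snp[weak], "weak_instrument")
  sig <- sig[!weak, , drop = FALSE]
  if (nrow(sig) == 0) return(result(NULL, NULL, "insufficient_instruments"))

  h <- tryCatch(harmonize_pair(exposure, outcome, snps = sig$snp),
                error = function(e) NULL)
  if (is.null(h)) {
    note(sig$snp, "missing_in_outcome")
    return(result(NULL, NULL, "insufficient_instruments"))
  }
  hd <- attr(h, "drops")
  note(hd$snp, hd$reason)

  out_assoc <- h$py < config$p_outcome_exclude
  note(h$snp[out_assoc], "outcome_associated")
  h <- subset_harmonized(h, !out_assoc)

  instr <- sig[match(h$snp, sig$snp), , drop = FALSE]
  rownames(instr) <- NULL
  status <- if (nrow(h) >= config$min_snps) "ok" else "insufficient_instruments"
  result(instr, h, status)
}

#' Remove instruments associated with known confounders
#'
#' Drops any instrument that a locally supplied confounder-association table
#' (e.g. a PhenoScanner export: `snp`, `trait`, `pvalue`) links to a
#' confounding trait at `p < p_threshold`. MR is intended to be re-run on
#' the survivors downstream. An empty table is the identity.
#'
#' @param h A `harmonized_set` (or any data frame with a `snp` column).
#' @param confounder_table Data frame with columns `snp`, `trait`, `pvalue`.
#' @param p_threshold Association threshold for removal.
#' @return List with `retained` (same class as `h`) and `removed` (the
#'   confounder rows that triggered removals).
#' @export
filter_confounders <- function(h, confounder_table, p_threshold = 1e-5) {
  if (is.null(confounder_table) || nrow(confounder_table) == 0) {
    return(list(retained = h,
                removed = data.frame(snp = character(), trait = character(),
                                     pvalue = numeric())))
  }
  stopifnot(all(c("snp", "trait", "pvalue") %in% names(confounder_table)))
  hits <- confounder_table[confounder_table$pvalue < p_threshold &
                             confounder_table$snp %in% h$snp, , drop = FALSE]
  keep <- !(h$snp %in% hits$snp)
  retained <- if (inherits(h, "harmonized_set")) subset_harmonized(h, keep)
              else h[keep, , drop = FALSE]
  list(retained = retained, removed = hits)
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat(sprintf("<instrument_selection> %s: %s, %d significant -> %d instruments\n",
              x$exposure_id, x$status, x$n_significant,
              if (is.null(x$harmonized)) 0L else nrow(x$harmonized)))
  if (nrow(x$audit)) print(table(x$audit$stage))
  invisible(x)
}
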