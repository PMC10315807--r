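# End-to-end screening pipeline across many exposures, with replication,
# meta-analysis, directionality, power and reporting.

#' Pipeline configuration
#'
#' @param selection A [selection_config()].
#' @param alpha Significance level used by the screen.
#' @param wm_n_boot Bootstrap replicates for the weighted-median SE.
#' @param presso_n_sim MR-PRESSO simulated null replicates.
#' @param radial_alpha Radial-MR per-SNP flagging level.
#' @param seed Master seed; per-exposure seeds are derived deterministically
#'   from it so reruns reproduce the report exactly.
#' @param confounder_p Threshold for the confounder filter.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(selection = selection_config(), alpha = 0.05,
                            wm_n_boot = 1000, presso_n_sim = 1000,
                            radial_alpha = 0.05, seed = 1,
                            confounder_p = 1e-5) {
  structure(list(selection = selection, alpha = alpha,
                 wm_n_boot = wm_n_boot, presso_n_sim = presso_n_sim,
                 radial_alpha = radial_alpha, seed = seed,
                 confounder_p = confounder_p),
            class = "pipeline_config")
}

empty_row <- function(exposure_id, status) {
  data.frame(exposure = exposure_id, status = status, n_snp = NA_integer_,
             n_radial_outliers = NA_integer_, f_aggregate = NA_real_,
             beta_ivw = NA_real_, se_ivw = NA_real_, p_ivw = NA_real_,
             or_ivw = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             beta_egger = NA_real_, p_egger = NA_real_,
             egger_intercept = NA_real_, egger_intercept_p = NA_real_,
             beta_wm = NA_real_, p_wm = NA_real_,
             q = NA_real_, q_p = NA_real_, presso_global_p = NA_real_,
             loo_max_p = NA_real_, ivw_significant = NA,
             directions_consistent = NA, no_heterogeneity = NA,
             no_pleiotropy = NA, loo_stable = NA, retained = FALSE,
             beta_rep = NA_real_, se_rep = NA_real_, p_rep = NA_real_,
             rep_direction_consistent = NA,
             beta_meta = NA_real_, se_meta = NA_real_, p_meta = NA_real_,
             or_meta = NA_real_, tau2 = NA_real_,
             steiger_forward = NA, steiger_p = NA_real_,
             r2_instruments = NA_real_, power = NA_real_,
             n_confounded_snps = NA_integer_, p_ivw_confounder_filtered = NA_real_,
             final = FALSE, stringsAsFactors = FALSE)
}

#' Run the full MR screening pipeline across a set of exposures
#'
#' For each exposure: instrument selection ([select_instruments()]), radial
#' outlier pre-removal, IVW / MR-Egger / weighted-median estimation, Cochran
#' Q, MR-PRESSO, leave-one-out, and the candidate screen
#' ([screen_candidates()]). Exposures passing the screen are replicated with
#' IVW in a second outcome cohort, pooled by DerSimonian-Laird
#' random-effects meta-analysis, tested for directionality (Steiger), and
#' given an asymptotic power estimate; if a confounder-association table is
#' supplied, confounded instruments are removed and IVW re-run on the
#' survivors. The final flag requires a retained candidate whose replication
#' direction is consistent and whose meta-analysis is significant.
#'
#' Per-exposure failures (insufficient instruments, degenerate fits) are
#' recorded in the report, never fatal to the run. Benjamini-Hochberg
#' adjusted IVW p-values across all attempted exposures are emitted for
#' transparency; the screen itself uses raw p-values, relying on
#' replication and meta-analysis as in the study design.
#'
#' @param exposures Named list of [gwas_table()] objects.
#' @param outcome_primary Primary outcome [gwas_table()].
#' @param outcome_replication Optional replication outcome [gwas_table()].
#' @param ld Optional [ld_matrix()] for clumping.
#' @param config A [pipeline_config()].
#' @param confounder_table Optional data frame (`snp`, `trait`, `pvalue`).
#' @return A `pipeline_report`: data frame with one row per exposure and an
#'   attribute `details` (per-exposure result bundles) plus `config`.
#' @export
run_pipeline <- function(exposures, outcome_primary,
                         outcome_replication = NULL, ld = NULL,
                         config = pipeline_config(),
                         confounder_table = NULL) {
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, attr, "", "trait_id")
  }
  alpha <- config$alpha
  details <- list()
  rows <- vector("list", length(exposures))

  for (i in seq_along(exposures)) {
    id <- names(exposures)[i]
    seed_i <- (config$seed + 7919L * i) %% 2147483647L
    row <- empty_row(id, "ok")
    det <- list()

    res <- tryCatch({
      sel <- select_instruments(exposures[[i]], outcome_primary, ld = ld,
                                config = config$selection)
      det$selection <- sel
      if (sel$status != "ok") {
        row$status <- "insufficient_instruments"
        list(row = row, det = det)
      } else {
        h <- sel$harmonized
        rad <- radial_outliers(h, alpha = config$radial_alpha)
        det$radial <- rad
        h <- subset_harmonized(h, match(rad$retained, h$snp))
        row$n_radial_outliers <- length(rad$outliers)
        row$n_snp <- nrow(h)
        row$f_aggregate <- sel$f_aggregate

        ivw <- mr_ivw(h, model = "random")
        egger <- mr_egger(h)
        wm <- mr_weighted_median(h, n_boot = config$wm_n_boot, seed = seed_i)
        q <- cochran_q(h, context = "ivw")
        presso <- if (nrow(h) >= 4)
          mr_presso(h, n_sim = config$presso_n_sim, seed = seed_i + 1L)
        else NULL
        loo <- leave_one_out(h, alpha = alpha)
        dec <- screen_candidates(ivw, egger, wm, q, loo, alpha = alpha)
        det <- c(det, list(harmonized = h, ivw = ivw, egger = egger,
                           wm = wm, q = q, presso = presso, loo = loo,
                           decision = dec))

        row[c("beta_ivw", "se_ivw", "p_ivw", "or_ivw", "ci_low",
              "ci_high")] <-
          list(ivw$beta, ivw$se, ivw$pvalue, ivw$or, ivw$ci_low, ivw$ci_high)
        row[c("beta_egger", "p_egger", "egger_intercept",
              "egger_intercept_p")] <-
          list(egger$beta, egger$pvalue, egger$intercept, egger$intercept_p)
        row[c("beta_wm", "p_wm")] <- list(wm$beta, wm$pvalue)
        row[c("q", "q_p")] <- list(q$q, q$pvalue)
        row$presso_global_p <- if (is.null(presso)) NA_real_
                               else presso$global_p
        row$loo_max_p <- max(loo$pvalue)
        row[c("ivw_significant", "directions_consistent", "no_heterogeneity",
              "no_pleiotropy", "loo_stable", "retained")] <-
          dec[c("ivw_significant", "directions_consistent",
                "no_heterogeneity", "no_pleiotropy", "loo_stable",
                "retained")]

        if (dec$retained) {
          if (!is.null(outcome_replication)) {
            h_rep <- harmonize_pair(exposures[[i]], outcome_replication,
                                    snps = h$snp)
            rep_ivw <- mr_ivw(h_rep, model = "random")
            det$replication <- rep_ivw
            row[c("beta_rep", "se_rep", "p_rep")] <-
              list(rep_ivw$beta, rep_ivw$se, rep_ivw$pvalue)
            row$rep_direction_consistent <-
              sign(rep_ivw$beta) == sign(ivw$beta)
            meta <- meta_random_effects(c(ivw$beta, rep_ivw$beta),
                                        c(ivw$se, rep_ivw$se))
            det$meta <- meta
            row[c("beta_meta", "se_meta", "p_meta", "or_meta", "tau2")] <-
              list(meta$beta, meta$se, meta$pvalue, meta$or, meta$tau2)
            row$final <- row$rep_direction_consistent &&
              meta$pvalue < alpha
          } else {
            row$final <- TRUE
          }

          st <- steiger_test(h)
          det$steiger <- st
          row[c("steiger_forward", "steiger_p")] <-
            list(st$direction_forward, st$pvalue)
          r2_total <- sum(sel$instruments$r2[match(h$snp,
                                                   sel$instruments$snp)])
          row$r2_instruments <- r2_total
          nc <- attr(outcome_primary, "n_cases")
          nt <- attr(outcome_primary, "n_total")
          if (!is.null(nc) && !is.null(nt)) {
            row$power <- mr_power(nt, nc / nt, r2_total,
                                  exp(ivw$beta), alpha = alpha)$power
          }
          if (!is.null(confounder_table)) {
            fc <- filter_confounders(h, confounder_table,
                                     p_threshold = config$confounder_p)
            det$confounder_filter <- fc
            row$n_confounded_snps <- length(unique(fc$removed$snp))
            if (nrow(fc$retained) >= 2 &&
                nrow(fc$retained) < nrow(h)) {
              row$p_ivw_confounder_filtered <-
                mr_ivw(fc$retained, model = "random")$pvalue
            } else if (nrow(fc$retained) == nrow(h)) {
              row$p_ivw_confounder_filtered <- ivw$pvalue
            }
          }
        }
        list(row = row, det = det)
      }
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      list(row = row, det = det)
    })
    rows[[i]] <- res$row
    details[[id]] <- res$det
  }

  report <- do.call(rbind, rows)
  report$p_ivw_bh <- stats::p.adjust(report$p_ivw, method = "BH")
  rownames(report) <- NULL
  structure(report,
            class = c("pipeline_report", "data.frame"),
            details = details, config = config)
}

#' Write a pipeline report as TSV (plus a JSON provenance sidecar)
#'
#' The TSV is written with fixed formatting so identical runs produce
#' byte-identical files; the sidecar records thresholds and seeds.
#'
#' @param report A `pipeline_report`.
#' @param path Output TSV path; provenance goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  cfg <- attr(report, "config")
  jsonlite::write_json(
    list(selection = unclass(cfg$selection), alpha = cfg$alpha,
         wm_n_boot = cfg$wm_n_boot, presso_n_sim = cfg$presso_n_sim,
         radial_alpha = cfg$radial_alpha, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("mrscreen"))),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Forest-plot-ready table from a pipeline report
#'
#' One row per exposure and cohort with the OR and CI, for external
#' plotting.
#'
#' @param report A `pipeline_report`.
#' @return Data frame with `exposure`, `cohort`, `OR`, `ci_low`, `ci_high`.
#' @export
forest_table <- function(report) {
  z <- stats::qnorm(0.975)
  prim <- data.frame(exposure = report$exposure, cohort = "primary",
                     OR = report$or_ivw, ci_low = report$ci_low,
                     ci_high = report$ci_high, stringsAsFactors = FALSE)
  repl <- data.frame(exposure = report$exposure, cohort = "replication",
                     OR = exp(report$beta_rep),
                     ci_low = exp(report$beta_rep - z * report$se_rep),
                     ci_high = exp(report$beta_rep + z * report$se_rep),
                     stringsAsFactors = FALSE)
  out <- rbind(prim, repl[!is.na(repl$OR), ])
  out[order(out$exposure, out$cohort), ]
}
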