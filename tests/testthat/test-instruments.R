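test_that("variance explained matches the closed form and is frequency-free", {
  expect_equal(variance_explained(0, 0.01, 1000), 0)
  # z = 10 -> r2 = z^2/(z^2 + N) = 100/1100
  expect_equal(variance_explained(0.1, 0.01, 1000, eaf = 0.25), 100 / 1100)
  # identical for any eaf, and for the frequency-free reduced form
  for (p in c(0.01, 0.2, 0.5, 0.8, 0.99)) {
    expect_equal(variance_explained(0.07, 0.02, 5000, eaf = p),
                 0.07^2 / (0.07^2 + 5000 * 0.02^2), tolerance = 1e-12)
    expect_equal(variance_explained(0.07, 0.02, 5000, eaf = p),
                 variance_explained(0.07, 0.02, 5000, eaf = 1 - p))
  }
  expect_error(variance_explained(0.1, 0.01, 1000, eaf = 1), "strictly inside")
})

test_that("F statistic evaluates the printed formula with its boundary", {
  expect_equal(f_statistic(0, 1000), 0)
  expect_equal(f_statistic(1 / 11, 1000, k = 1), 998 * 0.1)
  # filter boundary: F = 10 at r2 = 10/7832 for N = 7824, k = 1
  expect_equal(f_statistic(10 / 7832, 7824, k = 1), 10, tolerance = 1e-12)
  expect_error(f_statistic(1, 1000), "\\[0, 1\\)")
  expect_error(f_statistic(0.1, 2, k = 1), "exceed")
})

test_that("greedy clumping follows the smallest-p-first rule", {
  # independent SNPs: everything is retained
  cand <- data.frame(snp = c("a", "b", "c"), chr = 1,
                     pos = c(1e6, 1.1e6, 1.2e6), pval = c(1e-8, 1e-7, 1e-6))
  ld0 <- ld_matrix(diag(3), snps = cand$snp)
  expect_setequal(clump_variants(cand, ld0), c("a", "b", "c"))

  # correlated pair: only the more significant survives
  m <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  cand2 <- data.frame(snp = c("a", "b"), chr = 1, pos = c(1e6, 1.1e6),
                      pval = c(1e-8, 1e-6))
  expect_equal(clump_variants(cand2, ld_matrix(m)), "a")

  # chain A-B r2=0.2, B-C r2=0.2, A-C r2=0: greedy keeps {A, C}
  m3 <- matrix(c(1, 0.2, 0, 0.2, 1, 0.2, 0, 0.2, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cand3 <- data.frame(snp = c("A", "B", "C"), chr = 1,
                      pos = c(1e6, 1.05e6, 1.1e6), pval = c(1e-9, 1e-8, 1e-7))
  expect_equal(clump_variants(cand3, ld_matrix(m3), clump_r2 = 0.1),
               c("A", "C"))
  expect_equal(clump_variants(cand3, ld_matrix(m3), clump_r2 = 0.1),
               clump_oracle(cand3, m3, 0.1, 500))
})

test_that("clumping agrees with a brute-force oracle and ignores input order", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 12
    ids <- sprintf("s%02d", 1:n)
    r <- matrix(runif(n * n), n, n)
    r2 <- (r + t(r)) / 2
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    cand <- data.frame(snp = ids, chr = sample(1:2, n, TRUE),
                       pos = sample(seq(1e6, 2e6, by = 1e4), n),
                       pval = runif(n, 1e-10, 1e-5))
    got <- clump_variants(cand, ld_matrix(r2), clump_r2 = 0.3,
                          window_kb = 300)
    expect_equal(got, clump_oracle(cand, r2, 0.3, 300))
    shuffled <- cand[sample(n), ]
    expect_equal(clump_variants(shuffled, ld_matrix(r2), clump_r2 = 0.3,
                                window_kb = 300), got)
  }
})

test_that("a missing LD entry for an in-window pair is an error", {
  cand <- data.frame(snp = c("a", "b"), chr = 1, pos = c(1e6, 1.1e6),
                     pval = c(1e-8, 1e-6))
  ld <- ld_matrix(diag(1), snps = "a")
  expect_error(clump_variants(cand, ld), "missing LD entry")
  expect_error(clump_variants(cand, NULL), "missing LD entry")
})

test_that("instrument selection audits every removal stage exhaustively", {
  # 10 SNPs: 2 non-significant, 2 clumped, 1 weak-F (inconsistent file z),
  # 1 palindromic, 1 missing in outcome, 1 outcome-associated, 2 survivors.
  n <- 10000
  df <- make_gwas_df(10, beta = rep(0.15, 10), se = rep(0.02, 10),
                     chr = c(1:8, 9, 9), pos = c(1:8 * 1e6, 5e7, 5.05e7),
                     nn = n)
  df$pval[1:2] <- 0.5                      # below significance
  df$pval[3] <- 1e-6; df$beta[3] <- 0.002  # significant on file, F ~ 0.1
  df$other_allele[4] <- "T"                # palindromic A/T
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
               dimnames = list(c("rs009", "rs010"), c("rs009", "rs010")))
  exposure <- gwas_table(df, "exp", "quantitative", n_total = n)

  # rs006 (5th id) carries an outcome association with p << 1e-5
  out_beta <- c(rep(0.001, 4), 0.08, rep(0.001, 3))
  out_df <- make_gwas_df(8, snp = sprintf("rs%03d", c(1:4, 6, 7, 9, 10)),
                         beta = out_beta, se = rep(0.01, 8), nn = 30000)
  outcome <- gwas_table(out_df, "out", "binary", n_total = 30000)

  sel <- select_instruments(exposure, outcome, ld = ld_matrix(ld),
                            config = selection_config())
  expect_equal(sel$n_significant, 8)
  expect_equal(sel$status, "insufficient_instruments")  # 2 survivors < 3
  stages <- table(sel$audit$stage)
  expect_equal(unname(stages["clumped"]), 1L)        # rs010 clumped into rs009
  expect_equal(unname(stages["weak_instrument"]), 1L)
  expect_equal(unname(stages["palindromic"]), 1L)
  expect_equal(unname(stages["missing_in_outcome"]), 2L)  # rs005, rs008
  expect_equal(unname(stages["outcome_associated"]), 1L)
  # exhaustive: survivors + removals = significant SNPs
  expect_equal(nrow(sel$harmonized) + nrow(sel$audit), sel$n_significant)
})

test_that("well-powered independent instruments all survive selection", {
  set.seed(3)
  s <- simulate_two_sample(sim_config(J = 10, theta = 0))
  sel <- select_instruments(s$exposure, s$outcome)
  expect_equal(sel$status, "ok")
  expect_true(all(sel$instruments$f_stat >= 10))
  expect_true(all(sel$instruments$r2 < 1))
  expect_equal(nrow(sel$harmonized) + nrow(sel$audit), sel$n_significant)
})

test_that("confounder filtering removes exactly the flagged instruments", {
  h <- make_h(bx = rep(0.1, 10), by = rep(0.02, 10))
  expect_identical(filter_confounders(h, NULL)$retained, h)
  conf <- data.frame(snp = c("rs001", "rs005", "rs007"),
                     trait = c("smoking", "bmi", "bmi"),
                     pvalue = c(1e-8, 1e-9, 0.2))
  res <- filter_confounders(h, conf)
  expect_equal(nrow(res$retained), 8)
  expect_setequal(res$removed$snp, c("rs001", "rs005"))
  expect_setequal(res$removed$trait, c("smoking", "bmi"))
})
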