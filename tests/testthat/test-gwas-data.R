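test_that("a well-formed table loads identically and round-trips through TSV", {
  df <- make_gwas_df(3)
  tab <- gwas_table(df, "met1", "quantitative", n_total = 10000)
  expect_s3_class(tab, "gwas_table")
  expect_equal(nrow(tab), 3)
  expect_true(all(attr(tab, "load_report") == 0))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas_table(tab, path)
  back <- read_gwas_table(path, "met1", "quantitative", n_total = 10000)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})

test_that("invariant-violating rows are dropped and counted, never kept", {
  df <- make_gwas_df(5)
  df$se[2] <- 0                 # nonpositive SE
  df$other_allele[3] <- "AT"    # indel -> rejected as bad allele
  df$eaf[4] <- 1                # boundary frequency
  tab <- gwas_table(df, "met1", "quantitative", n_total = 10000)
  expect_equal(nrow(tab), 2)
  rep <- attr(tab, "load_report")
  expect_equal(unname(rep["nonpositive_se"]), 1L)
  expect_equal(unname(rep["bad_allele"]), 1L)
  expect_equal(unname(rep["bad_eaf"]), 1L)
})

test_that("duplicate and missing-column inputs raise informative errors", {
  df <- make_gwas_df(3)
  df$snp[2] <- df$snp[1]
  expect_error(gwas_table(df, "x", "quantitative"), "rs001")
  expect_error(gwas_table(make_gwas_df(3)[, -7], "x", "quantitative"),
               "missing required column")
  expect_error(gwas_table(make_gwas_df(3), "x", "binary",
                          n_total = 10, n_cases = 11),
               "n_cases")
})

test_that("harmonization keeps matched orientations and flips swapped ones", {
  ex <- gwas_table(make_gwas_df(2, beta = c(0.1, 0.2), eaf = NA),
                   "exp", "quantitative", n_total = 1000)
  out_df <- make_gwas_df(2, beta = c(0.05, 0.3), eaf = c(0.4, 0.7))
  # second SNP recorded on the swapped orientation G/A
  out_df$effect_allele[2] <- "G"
  out_df$other_allele[2] <- "A"
  out <- gwas_table(out_df, "out", "binary", n_total = 2000)
  h <- harmonize_pair(ex, out)
  expect_equal(nrow(h), 2)
  expect_equal(h$by, c(0.05, -0.3))
  expect_equal(h$eaf, c(0.4, 0.3))
  expect_equal(nrow(attr(h, "drops")), 0)
})

test_that("palindromic, incompatible and absent SNPs are dropped with reasons", {
  exd <- make_gwas_df(4)
  exd$other_allele[1] <- "T"  # A/T palindrome
  ex <- gwas_table(exd, "exp", "quantitative", n_total = 1000)
  outd <- make_gwas_df(3, snp = c("rs001", "rs002", "rs003"))
  outd$other_allele[2] <- "C"  # A/G vs A/C incompatibility
  out <- gwas_table(outd, "out", "binary", n_total = 2000)
  h <- harmonize_pair(ex, out)
  drops <- attr(h, "drops")
  expect_equal(h$snp, "rs003")
  expect_setequal(drops$reason,
                  c("palindromic", "incompatible_alleles",
                    "missing_in_outcome"))
  expect_equal(drops$reason[drops$snp == "rs001"], "palindromic")
  expect_equal(drops$reason[drops$snp == "rs002"], "incompatible_alleles")
  # conservation: retained + dropped = requested
  expect_equal(nrow(h) + nrow(drops), 4)
  # no overlap at all is an explicit error
  out2 <- gwas_table(make_gwas_df(2, snp = c("zz1", "zz2")), "out", "binary")
  expect_error(harmonize_pair(ex, out2, snps = c("rs002")),
               "no overlapping instruments")
})

test_that("sign flip is an involution and harmonization is idempotent", {
  set.seed(7)
  s <- simulate_two_sample(sim_config(J = 12, theta = 0.3))
  h1 <- harmonize_pair(s$exposure, s$outcome)

  # re-express the harmonized outcome as a table (exposure orientation) and
  # harmonize again: nothing may change
  out2 <- gwas_table(
    data.frame(snp = h1$snp, chr = NA, pos = NA,
               effect_allele = h1$effect_allele,
               other_allele = h1$other_allele,
               eaf = h1$eaf, beta = h1$by, se = h1$sy, py = h1$py,
               pval = h1$py, n = attr(h1, "n_outcome"))[,
               c("snp", "chr", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")],
    "out", "binary", n_total = attr(h1, "n_outcome"))
  h2 <- harmonize_pair(s$exposure, out2, snps = h1$snp)
  expect_equal(h2$by, h1$by, tolerance = 1e-12)
  expect_equal(h2$eaf, h1$eaf, tolerance = 1e-12)

  # swapping outcome alleles twice restores by and eaf
  out_sw <- as.data.frame(out2)
  tmp <- out_sw$effect_allele
  out_sw$effect_allele <- out_sw$other_allele
  out_sw$other_allele <- tmp
  out_sw$beta <- -out_sw$beta
  out_sw$eaf <- 1 - out_sw$eaf
  h3 <- harmonize_pair(s$exposure,
                       gwas_table(out_sw, "out", "binary",
                                  n_total = attr(h1, "n_outcome")),
                       snps = h1$snp)
  expect_equal(h3$by, h1$by, tolerance = 1e-12)
  expect_equal(h3$eaf, h1$eaf, tolerance = 1e-12)
})
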