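test_that("the Wakefield log-ABF matches hand arithmetic and its limits", {
  # z = 0: evidence against association, strictly negative
  expect_lt(log_abf(0, 0.1, 0.2), 0)
  expect_equal(log_abf(0, 0.1, 0.2), 0.5 * log(0.01 / 0.05))
  # vanishing prior: no evidence either way
  expect_equal(log_abf(0.3, 0.1, 1e-9), 0, tolerance = 1e-12)
  # V = 0.01, W = 0.04, z = 5
  expect_equal(log_abf(0.5, 0.1, 0.2), 0.5 * log(0.2) + 12.5 * 0.8,
               tolerance = 1e-12)
})

null_region <- function(m, id = "t") {
  regional_assoc(data.frame(snp = sprintf("s%03d", 1:m), beta = 0,
                            se = 1e9, maf = 0.3), n = 1000,
                 trait_id = id)
}

test_that("the all-null 100-SNP region reproduces the closed-form prior posterior", {
  res <- coloc_abf(null_region(100), null_region(100))
  w <- c(1, 1e-4 * 100, 1e-4 * 100, 1e-8 * (100 * 100 - 100), 1e-5 * 100)
  expect_equal(unname(res$pp), w / sum(w), tolerance = 1e-6)
  expect_equal(unname(res$pp["pp_h0"]), 0.979, tolerance = 1e-3)
  expect_equal(sum(res$pp), 1, tolerance = 1e-9)
  expect_false(res$decision)
})

test_that("one strong shared signal drives the posterior onto H4", {
  m <- 50
  z <- rep(0, m)
  z[25] <- 12
  mk <- function() regional_assoc(
    data.frame(snp = sprintf("s%03d", 1:m), z = z, maf = rep(0.3, m)),
    n = 30000)
  res <- suppressWarnings(coloc_abf(mk(), mk()))  # H3 clamp expected at saturation
  expect_gt(res$pp["pp_h4"], 0.99)
  expect_true(res$decision)
  expect_equal(res$top_snp, "s025")
})

test_that("the posterior equals brute-force configuration enumeration", {
  set.seed(61)
  for (rep in 1:5) {
    m <- 4
    t1 <- regional_assoc(data.frame(snp = paste0("s", 1:m),
                                    beta = rnorm(m, 0, 0.1),
                                    se = runif(m, 0.01, 0.05),
                                    maf = runif(m, 0.05, 0.5)), n = 10000)
    t2 <- regional_assoc(data.frame(snp = paste0("s", 1:m),
                                    beta = rnorm(m, 0, 0.1),
                                    se = runif(m, 0.01, 0.05),
                                    maf = runif(m, 0.05, 0.5)), n = 10000)
    p1 <- 1e-4; p2 <- 1e-4; p12 <- 1e-5
    res <- suppressWarnings(coloc_abf(t1, t2, p1 = p1, p2 = p2, p12 = p12))

    # enumeration over all (causal-for-1, causal-for-2) configurations,
    # 0 meaning "no causal variant" - fully independent code path
    bf1 <- exp(log_abf(t1$beta, t1$se, 0.2))
    bf2 <- exp(log_abf(t2$beta, t2$se, 0.2))
    w <- c(h0 = 0, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
    for (a in 0:m) for (b in 0:m) {
      if (a == 0 && b == 0) w["h0"] <- w["h0"] + 1
      else if (b == 0) w["h1"] <- w["h1"] + p1 * bf1[a]
      else if (a == 0) w["h2"] <- w["h2"] + p2 * bf2[b]
      else if (a != b) w["h3"] <- w["h3"] + p1 * p2 * bf1[a] * bf2[b]
      else w["h4"] <- w["h4"] + p12 * bf1[a] * bf2[a]
    }
    expect_equal(unname(res$pp), unname(w / sum(w)), tolerance = 1e-9)
  }
})

test_that("the posterior ignores SNP order and responds to the p12 prior", {
  # modest sample sizes keep the posterior away from saturation
  reg <- simulate_ld_region(60, rho = 0.5, causal_mode = "shared",
                            n1 = 2000, n2 = 2000, seed = 62)
  base <- coloc_abf(reg$t1, reg$t2)
  perm <- sample(60)
  t1p <- regional_assoc(as.data.frame(reg$t1)[perm, ], n = 2000)
  res_p <- coloc_abf(t1p, reg$t2)
  expect_equal(res_p$pp, base$pp, tolerance = 1e-12)
  # doubling p12 strictly increases the shared-variant posterior
  up <- coloc_abf(reg$t1, reg$t2, p12 = 2e-5)
  expect_gt(up$pp["pp_h4"], base$pp["pp_h4"])
  # disjoint SNP sets cannot be colocalized
  t_other <- null_region(5)
  t_other$snp <- paste0("x", 1:5)
  expect_error(coloc_abf(regional_assoc(t_other, n = 1000), reg$t2),
               "no shared SNPs")
})

test_that("shared and distinct causal architectures land on H4 and H3", {
  shared <- simulate_ld_region(150, rho = 0.6, causal_mode = "shared",
                               r2_causal = 0.01, seed = 63)
  ps <- suppressWarnings(coloc_abf(shared$t1, shared$t2))$pp
  expect_gt(ps["pp_h4"], 0.8)
  distinct <- simulate_ld_region(150, rho = 0.2, causal_mode = "distinct",
                                 r2_causal = 0.01, seed = 64)
  pd <- coloc_abf(distinct$t1, distinct$t2)$pp
  expect_equal(names(which.max(pd)), "pp_h3")
})
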