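test_that("Cochran Q matches hand arithmetic and the WLS residual identity", {
  # identical ratios: no heterogeneity at all
  h0 <- make_h(bx = c(0.1, 0.2), by = 0.4 * c(0.1, 0.2))
  q0 <- cochran_q(h0)
  expect_equal(q0$q, 0, tolerance = 1e-18)
  expect_equal(q0$pvalue, 1)

  # two unit-weight SNPs with ratios 0 and 1: beta_hat = 0.5, Q = 0.5
  h <- make_h(bx = c(1, 1), by = c(0, 1), sy = c(1, 1))
  q <- cochran_q(h)
  expect_equal(q$q, 0.5)
  expect_equal(q$df, 1)

  # algebraic identity: Q equals the weighted RSS of the no-intercept fit
  set.seed(31)
  hr <- make_h(bx = runif(8, 0.05, 0.3), by = rnorm(8, 0.04, 0.03),
               sy = runif(8, 0.01, 0.05))
  o <- wls_oracle(hr$by, hr$bx, 1 / hr$sy^2)
  expect_equal(cochran_q(hr)$q, o$rss, tolerance = 1e-10)
  expect_error(cochran_q(make_h(bx = 0.1, by = 0.1)), "insufficient")
})

test_that("radial q contributions decompose Cochran Q exactly", {
  set.seed(32)
  h <- make_h(bx = runif(10, 0.05, 0.3), by = rnorm(10, 0.05, 0.04),
              sy = runif(10, 0.01, 0.05))
  rad <- radial_outliers(h)
  expect_equal(sum(rad$qstat$q), cochran_q(h)$q, tolerance = 1e-12)
  expect_true(all(rad$outliers %in% h$snp))
})

test_that("a grossly displaced SNP is flagged by radial MR in one pass", {
  set.seed(33)
  theta <- 0.5
  bx <- runif(12, 0.1, 0.3)
  sy <- rep(0.01, 12)
  by <- rnorm(12, theta * bx, sy)
  by[5] <- theta * bx[5] + 8 * sy[5]   # 8 fixed-effect SEs off the ratio
  h <- make_h(bx = bx, by = by, sy = sy)
  rad <- radial_outliers(h)
  expect_true("rs005" %in% rad$outliers)
  expect_false("rs005" %in% rad$retained)
  # the refit after removal is closer to the truth than the raw fit
  expect_lt(abs(rad$estimate$beta - theta), abs(mr_ivw(h)$beta - theta))
})

test_that("MR-PRESSO honours the add-one bound and finds a planted outlier", {
  set.seed(34)
  theta <- 0.4
  bx <- runif(15, 0.1, 0.3)
  sy <- rep(0.012, 15)
  by <- rnorm(15, theta * bx, sy)
  by[7] <- theta * bx[7] + 10 * sy[7]
  h <- make_h(bx = bx, by = by, sy = sy)
  pr <- mr_presso(h, n_sim = 400, seed = 9)
  expect_gte(pr$global_p, 1 / 401)
  expect_equal(pr$outliers, "rs007")
  expect_lt(abs(pr$estimate_outlier_corrected$beta - theta),
            abs(pr$estimate_raw$beta - theta))
  expect_true(is.finite(pr$distortion_p))
  expect_error(mr_presso(make_h(bx = c(1, 1, 1), by = c(1, 1, 1))),
               "insufficient")
})

test_that("MR-PRESSO is seed-reproducible and invariant to SNP order", {
  set.seed(35)
  h <- make_h(bx = runif(10, 0.1, 0.3), by = rnorm(10, 0.05, 0.03),
              sy = runif(10, 0.01, 0.03))
  a <- mr_presso(h, n_sim = 300, seed = 77)
  b <- mr_presso(h, n_sim = 300, seed = 77)
  expect_identical(a$global_p, b$global_p)
  perm <- sample(10)
  hp <- make_h(bx = h$bx[perm], by = h$by[perm], sy = h$sy[perm],
               snp = h$snp[perm])
  cc <- mr_presso(hp, n_sim = 300, seed = 77)
  expect_identical(cc$global_p, a$global_p)
  expect_identical(sort(names(cc$outlier_p)), sort(names(a$outlier_p)))
})

test_that("leave-one-out returns one row per SNP with sensible flags", {
  # identical SNPs: every exclusion reproduces the full estimate
  h <- make_h(bx = rep(0.2, 5), by = rep(0.08, 5))
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 5)
  expect_true(all(abs(loo$beta - attr(loo, "full")$beta) < 1e-12))
  expect_false(any(loo$sign_flip))
  expect_false(any(loo$significance_loss))

  # a dominant opposite-direction SNP flips the sign when removed
  h2 <- make_h(bx = c(1, rep(0.05, 4)), by = c(0.5, rep(-0.005, 4)),
               sy = c(0.01, rep(0.05, 4)))
  loo2 <- leave_one_out(h2)
  expect_gt(attr(loo2, "full")$beta, 0)
  expect_true(loo2$sign_flip[loo2$snp == "rs001"])
})

test_that("candidate screening is the conjunction of the five criteria", {
  set.seed(36)
  s <- simulate_two_sample(sim_config(J = 20, theta = -0.5))
  h <- harmonize_pair(s$exposure, s$outcome)
  ivw <- mr_ivw(h)
  egger <- mr_egger(h)
  wm <- mr_weighted_median(h, n_boot = 200, seed = 1)
  q <- cochran_q(h)
  loo <- leave_one_out(h)
  dec <- screen_candidates(ivw, egger, wm, q, loo)
  expect_true(dec$retained)

  # a non-significant IVW p fails the screen
  ivw_ns <- ivw
  ivw_ns$pvalue <- 0.06
  expect_false(screen_candidates(ivw_ns, egger, wm, q, loo)$retained)

  # an Egger slope of opposite sign fails direction consistency
  egger_flip <- egger
  egger_flip$beta <- -egger$beta
  d2 <- screen_candidates(ivw, egger_flip, wm, q, loo)
  expect_false(d2$directions_consistent)
  expect_false(d2$retained)

  expect_error(screen_candidates(ivw, NULL, wm, q, loo), "incomplete bundle")
})
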