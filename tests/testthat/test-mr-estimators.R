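test_that("Wald ratio uses the first-order delta SE and rejects bx = 0", {
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  wr <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "bx = 0")
})

test_that("IVW reduces to the Wald ratio for one SNP and is exact under homogeneity", {
  h1 <- make_h(bx = 0.2, by = 0.1, sy = 0.05)
  expect_warning(fit1 <- mr_ivw(h1), "single SNP")
  expect_equal(fit1$beta, 0.5)
  expect_equal(fit1$se, 0.25)

  # all per-SNP ratios exactly theta: beta = theta, Q = 0, fixed = random
  h <- make_h(bx = c(0.1, 0.2, 0.3), by = 0.7 * c(0.1, 0.2, 0.3))
  ffix <- mr_ivw(h, model = "fixed")
  fran <- mr_ivw(h, model = "random")
  expect_equal(ffix$beta, 0.7)
  expect_equal(ffix$q, 0, tolerance = 1e-20)
  expect_equal(fran$se, ffix$se)
  expect_error(mr_ivw(make_h(bx = c(0, 0), by = c(0.1, 0.2))), "singular")
})

test_that("IVW equals an independent no-intercept WLS oracle to 1e-10", {
  set.seed(21)
  for (j in c(3, 10, 50)) {
    h <- make_h(bx = rnorm(j, 0.1, 0.05), by = rnorm(j, 0.03, 0.02),
                sy = runif(j, 0.005, 0.05))
    o <- wls_oracle(h$by, h$bx, 1 / h$sy^2)
    fit <- mr_ivw(h, model = "fixed")
    expect_equal(fit$beta, o$coef, tolerance = 1e-10)
    expect_equal(fit$se, o$se_unscaled, tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact linear law and matches the WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.25)
  h <- make_h(bx = bx, by = 0.1 + 0.3 * bx)
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)

  set.seed(22)
  hr <- make_h(bx = runif(10, 0.05, 0.3),
               by = 0.05 + 0.2 * runif(10, 0.05, 0.3) + rnorm(10, 0, 0.05),
               sy = runif(10, 0.005, 0.02))
  o <- wls_oracle(hr$by, hr$bx, 1 / hr$sy^2, intercept = TRUE)
  fe <- mr_egger(hr)
  expect_equal(fe$intercept, o$coef[1], tolerance = 1e-10)
  expect_equal(fe$beta, o$coef[2], tolerance = 1e-10)
  # residual dispersion here far exceeds 1, so the floored scale equals lm's
  expect_gt(o$sigma, 1)
  expect_equal(fe$intercept_se, o$se_scaled[1], tolerance = 1e-10)
  expect_equal(fe$se, o$se_scaled[2], tolerance = 1e-10)

  expect_error(mr_egger(make_h(bx = c(0.1, 0.2), by = c(0.1, 0.2))),
               "insufficient")
  expect_error(mr_egger(make_h(bx = rep(0.1, 4), by = rnorm(4))), "singular")
})

test_that("MR-Egger orients rows so the fit is invariant to allele sign flips", {
  set.seed(23)
  bx <- runif(8, 0.05, 0.3)
  h <- make_h(bx = bx, by = 0.02 + 0.4 * bx + rnorm(8, 0, 0.03))
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  hf <- make_h(bx = h$bx * flip, by = h$by * flip, sy = h$sy)
  f1 <- mr_egger(h)
  f2 <- mr_egger(hf)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  # equal weights, ratios {0.1, 0.2, 0.9}: S = {1/6, 1/2, 5/6} -> 0.2 exactly
  h <- make_h(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.9), sy = c(1, 1, 1))
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.2)

  # all ratios identical
  h2 <- make_h(bx = c(0.1, 0.2, 0.4), by = -0.3 * c(0.1, 0.2, 0.4))
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta, -0.3)

  # a SNP with dominant weight pins the estimate near its own ratio
  h3 <- make_h(bx = c(1, 1, 1), by = c(1, 2, 3), sy = c(0.1, 1, 1))
  expect_equal(mr_weighted_median(h3, n_boot = 0)$beta, 1, tolerance = 0.05)

  # bootstrap SE is reproducible under a fixed seed
  set.seed(24)
  h4 <- make_h(bx = runif(8, 0.05, 0.3), by = rnorm(8, 0.05, 0.03),
               sy = runif(8, 0.01, 0.03))
  a <- mr_weighted_median(h4, n_boot = 200, seed = 5)
  b <- mr_weighted_median(h4, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("odds-ratio conversion matches hand arithmetic", {
  z <- to_or(0, 0.2)
  expect_equal(z$or, 1)
  expect_lt(z$ci_low, 1)
  expect_gt(z$ci_high, 1)
  d <- to_or(log(2), 0)
  expect_equal(d$or, 2)
  expect_equal(d$ci_low, 2)
  e <- to_or(-0.713, 0.224)
  expect_equal(e$or, 0.49, tolerance = 0.005)
  expect_equal(e$ci_low, 0.32, tolerance = 0.02)
  expect_equal(e$ci_high, 0.76, tolerance = 0.01)
})

test_that("all three estimators are equivariant under exposure rescaling", {
  set.seed(25)
  h <- make_h(bx = runif(10, 0.05, 0.3), by = rnorm(10, 0.05, 0.02),
              sx = runif(10, 0.005, 0.02), sy = runif(10, 0.01, 0.03))
  cc <- 3.7
  hc <- make_h(bx = cc * h$bx, by = h$by, sx = cc * h$sx, sy = h$sy)
  expect_equal(mr_ivw(hc)$beta, mr_ivw(h)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(hc)$beta, mr_egger(h)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hc, n_boot = 0)$beta,
               mr_weighted_median(h, n_boot = 0)$beta / cc,
               tolerance = 1e-12)
})

test_that("Egger slope equals IVW when the fitted intercept is zero", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx = bx, by = 0.6 * bx)
  expect_equal(mr_egger(h)$intercept, 0, tolerance = 1e-12)
  expect_equal(mr_egger(h)$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-10)
})
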