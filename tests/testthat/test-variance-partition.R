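test_that("degenerate groupings are handled explicitly", {
  # perfect separation: all variance between groups
  expect_warning(
    f <- fit_random_intercept(c(0, 0, 1, 1), c("a", "a", "b", "b")),
    "within")
  expect_gt(f$pct_between, 99.9)

  # constant response: nothing to partition
  expect_warning(f0 <- fit_random_intercept(rep(2, 6), rep(1:3, each = 2)),
                 "equal")
  expect_equal(f0$sigma2_between, 0)
  expect_equal(f0$pct_between, 0)

  expect_error(fit_random_intercept(1:5, rep("a", 5)), "2 groups")
})

test_that("profile fit matches the brute-force grid oracle to 4 decimals", {
  for (seed in c(3, 17)) {
    d <- make_grouped_data(seed)
    fit <- fit_random_intercept(d$values, d$groups, method = "ML")
    oracle <- oracle_random_intercept_ml(d$values, d$groups)
    rho_fit <- fit$sigma2_between / (fit$sigma2_between + fit$sigma2_within)
    expect_lt(abs(rho_fit - oracle$rho), 1.5e-4)
    expect_equal(fit$sigma2_between, oracle$sigma2_between,
                 tolerance = 5e-4)
    expect_equal(fit$sigma2_within, oracle$sigma2_within,
                 tolerance = 5e-4)
    # optimality: the profile optimum cannot fall below any grid point
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
  }
})

test_that("REML estimates agree with lme4 on a seeded fixture", {
  skip_if_not_installed("lme4")
  d <- make_grouped_data(23)
  fit <- fit_random_intercept(d$values, d$groups, method = "REML")
  lmm <- lme4::lmer(y ~ 1 + (1 | g),
                    data = data.frame(y = d$values, g = d$groups),
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(fit$sigma2_between, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_within, vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lmm)), tolerance = 1e-6)

  ml <- fit_random_intercept(d$values, d$groups, method = "ML")
  lmm_ml <- lme4::lmer(y ~ 1 + (1 | g),
                       data = data.frame(y = d$values, g = d$groups),
                       REML = FALSE)
  expect_equal(ml$loglik, as.numeric(stats::logLik(lmm_ml)),
               tolerance = 1e-6)
  # REML shrinks the between component less than ML on balanced small samples
  expect_gte(fit$sigma2_between, ml$sigma2_between - 1e-12)
})

test_that("variance components are location and scale equivariant", {
  d <- make_grouped_data(31)
  base <- fit_random_intercept(d$values, d$groups)
  shifted <- fit_random_intercept(d$values + 5, d$groups)
  expect_equal(shifted$sigma2_between, base$sigma2_between, tolerance = 1e-6)
  expect_equal(shifted$sigma2_within, base$sigma2_within, tolerance = 1e-6)
  for (c in c(0.01, 40)) {
    scaled <- fit_random_intercept(c * d$values, d$groups)
    expect_equal(scaled$sigma2_between, c^2 * base$sigma2_between,
                 tolerance = 1e-6)
    expect_equal(scaled$sigma2_within, c^2 * base$sigma2_within,
                 tolerance = 1e-6)
    expect_equal(scaled$pct_between, base$pct_between, tolerance = 1e-4)
  }
})

test_that("pct_between is the between share of total variance", {
  d <- make_grouped_data(7)
  f <- fit_random_intercept(d$values, d$groups)
  expect_equal(pct_between(f),
               100 * f$sigma2_between / (f$sigma2_between + f$sigma2_within))
  expect_equal(f$pct_between, pct_between(f), tolerance = 1e-9)
})

test_that("likelihood-ratio test separates structured from unstructured data", {
  # no group structure: chi2 near zero, p near 1
  set.seed(12)
  y0 <- rnorm(20)
  l0 <- lrt_random_effect(y0, rep(1:4, each = 5))
  expect_lt(l0$chi2, 1)
  expect_gt(l0$p_value, 0.3)
  expect_equal(l0$chi2, max(0, 2 * (l0$loglik_full - l0$loglik_null)))

  # strong separation: significant
  y1 <- rep(c(0, 2, 4, 6), each = 5) + rnorm(20, 0, 0.2)
  l1 <- lrt_random_effect(y1, rep(1:4, each = 5))
  expect_gt(l1$chi2, 3.84)
  expect_lt(l1$p_value, 0.05)
  expect_equal(l1$p_value_mixture, l1$p_value / 2)
})

test_that("unbalanced designs are supported", {
  set.seed(44)
  g <- rep(1:4, times = c(5, 5, 4, 4))  # n varies as in the field data
  y <- rep(c(0.6, 0.65, 0.7, 0.62), times = c(5, 5, 4, 4)) +
    rnorm(length(g), 0, 0.03)
  f <- fit_random_intercept(y, g)
  expect_true(f$pct_between >= 0 && f$pct_between <= 100)
  oracle <- oracle_random_intercept_ml(y, g)
  ml <- fit_random_intercept(y, g, method = "ML")
  rho_fit <- ml$sigma2_between / (ml$sigma2_between + ml$sigma2_within)
  expect_lt(abs(rho_fit - oracle$rho), 1.5e-4)
})

test_that("variance partitioning summarizes a measurement table", {
  cfg <- simulation_config(seed = 6)
  bio <- simulate_biopsy_dataset(cfg)
  vp <- variance_partition(bio$measurements)
  expect_setequal(vp$component, cfg$components$component)
  expect_true(all(vp$pct_between >= 0 & vp$pct_between <= 100))
  expect_true(all(vp$chi2 >= 0))
  expect_true(all(vp$p_value >= vp$p_value_mixture))
})
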