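test_that("standard curves are ordinary least squares lines", {
  c1 <- fit_standard_curve(c(0, 10, 20), c(0, 10, 20))
  expect_equal(c1$slope, 1)
  expect_equal(c1$intercept, 0)
  expect_equal(c1$r_squared, 1)

  c2 <- fit_standard_curve(c(0, 5, 10), c(1, 11, 21))
  expect_equal(c2$slope, 2)
  expect_equal(c2$intercept, 1)

  expect_error(fit_standard_curve(c(5, 5, 5), c(1, 2, 3)), "distinct")
  expect_error(fit_standard_curve(c(0, 10), c(0, 1)), "at least 3")
})

test_that("noisy standard curves recover the true slope", {
  set.seed(42)
  conc <- rep(seq(0, 100, by = 20), each = 2)
  sig <- 0.8 * conc + 3 + rnorm(length(conc), 0, 1.5)
  cv <- fit_standard_curve(conc, sig)
  se_slope <- summary(stats::lm(sig ~ conc))$coefficients["conc", "Std. Error"]
  expect_lt(abs(cv$slope - 0.8), 3 * se_slope)
})

test_that("component quantification inverts the curve and scales to g/gDW", {
  ident <- fit_standard_curve(c(0, 10, 20), c(0, 10, 20))
  v <- quantify_component(c(10, 10, 10), ident, 1, 1, 1)
  expect_equal(as.numeric(v), 1.0e-5)

  c2 <- fit_standard_curve(c(0, 5, 10), c(1, 11, 21))
  v2 <- quantify_component(c(5, 6, 7), c2, dilution_factor = 50,
                           extract_volume_ml = 6, dry_mass_g = 0.5)
  expect_equal(as.numeric(v2), 1.5e-3)

  # signals below the intercept clamp to zero with a warning (the same call
  # also warns about extrapolating below the curve range)
  w <- testthat::capture_warnings(
    v3 <- quantify_component(c(0.1, 0.2, 0.1), c2, 1, 6, 0.5))
  expect_true(any(grepl("clamped", w)))
  expect_equal(as.numeric(v3), 0)
  expect_true(attr(v3, "clamped"))
})

test_that("quantification is linear in the mean signal above the clamp", {
  curve <- fit_standard_curve(c(0, 50, 100), c(2, 52, 102))
  base <- as.numeric(quantify_component(c(12, 12, 12), curve, 1, 3, 0.5))
  for (m in c(2, 3, 5)) {
    v <- as.numeric(quantify_component(rep(2 + (12 - 2) * m, 3), curve,
                                       1, 3, 0.5))
    expect_equal(v, base * m, tolerance = 1e-12)
  }
})

test_that("RNA follows the A260 conversion arithmetic", {
  expect_equal(rna_from_a260(0, 40, 1, 4, 1), 0)
  expect_equal(rna_from_a260(0.5, 40, 1, 4.0, 0.1), 8.0e-4)
  # fixture engineered to give the published population mean exactly
  a260 <- 0.0021 * 1e6 * 0.5 / (40 * 1 * 4)
  expect_equal(rna_from_a260(a260, 40, 1, 4, 0.5), 0.0021)
})

test_that("component summaries reproduce published-style statistics", {
  x <- sample_with_moments(0.0881, 0.0082, 20)
  s <- summarize_component(x, "protein")
  expect_equal(s$mean, 0.0881)
  expect_equal(s$sd, 0.0082)
  expect_equal(round(s$cv_percent, 2), 9.31)
  expect_equal(round(s$se, 4), 0.0018)

  s2 <- summarize_component(c(5, 5, 5))
  expect_equal(s2$sd, 0)
  expect_equal(s2$cv_percent, 0)
  expect_equal(s2$se, 0)

  s3 <- summarize_component(c(1, 2, 3))
  expect_equal(s3$mean, 2)
  expect_equal(s3$sd, 1)
  expect_equal(s3$se, 0.5774, tolerance = 1e-4)
  expect_equal(s3$cv_percent, 50)

  expect_warning(summarize_component(c(0, 0, 0) + c(0, 0, 0)), NA)
})

test_that("summaries are scale equivariant and the CV scale free", {
  set.seed(5)
  x <- rlnorm(15, 0, 0.4)
  s <- summarize_component(x)
  for (c in c(0.01, 3, 1e4)) {
    sc <- summarize_component(c * x)
    expect_equal(sc$mean, c * s$mean)
    expect_equal(sc$sd, c * s$sd)
    expect_equal(sc$se, c * s$se)
    expect_equal(sc$cv_percent, s$cv_percent)
  }
})

test_that("synthetic assay round trip recovers component values", {
  # noise-free configuration: quantification must invert the generator
  cfg0 <- simulation_config(seed = 9, assay_cv = 0)
  bio <- simulate_biopsy_dataset(cfg0)
  sim <- simulate_assay_readings(bio$measurements, bio$records, cfg0)
  curves <- lapply(split(sim$standards, sim$standards$component),
                   function(s) fit_standard_curve(s$concentration, s$signal))
  got <- quantify_assay_table(sim$readings, curves)
  truth <- bio$measurements[bio$measurements$component %in%
                              unique(got$component), ]
  m <- merge(got, truth, by = c("component", "sponge_id", "biopsy_id"))
  expect_equal(m$g_per_gDW.x, m$g_per_gDW.y, tolerance = 1e-10)
})

test_that("noisy assays recover the drawn component values faithfully", {
  # assay fidelity: with 3 % triplicate noise, the recovered population mean
  # tracks the generator's drawn sample mean to well under the assay CV
  # (generator-level unbiasedness is checked separately over replicates)
  cfg <- simulation_config(seed = 1)
  bio <- simulate_biopsy_dataset(cfg)
  sim <- simulate_assay_readings(bio$measurements, bio$records, cfg)
  curves <- lapply(split(sim$standards, sim$standards$component),
                   function(s) fit_standard_curve(s$concentration, s$signal))
  got <- quantify_assay_table(sim$readings, curves)
  for (cc in unique(got$component)) {
    recovered <- mean(got$g_per_gDW[got$component == cc])
    drawn <- mean(bio$measurements$g_per_gDW[
      bio$measurements$component == cc])
    expect_lt(abs(recovered - drawn) / drawn, 0.02)
  }
})
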