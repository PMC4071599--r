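test_that("intensity cut-off keeps peaks above 0.05% of the largest", {
  pk <- data.frame(sample_id = "s1", compound_id = c("a", "b", "c"),
                   compound_class = "known_fa", area = c(10000, 6, 4),
                   mw = 256)
  out <- apply_intensity_cutoff(pk)
  expect_setequal(out$compound_id, c("a", "b"))

  single <- pk[1, ]
  expect_equal(nrow(apply_intensity_cutoff(single)), 1L)

  equal <- transform(pk, area = 7)
  expect_equal(nrow(apply_intensity_cutoff(equal)), 3L)
})

test_that("intensity cut-off is idempotent and spares the internal standard", {
  fx <- fame_fixture()
  pk <- fx$peaks
  pk$area[pk$compound_id == "U1-FA"] <- 0.01  # below threshold
  once <- apply_intensity_cutoff(pk)
  twice <- apply_intensity_cutoff(once)
  expect_identical(once, twice)
  expect_true(all(c("s1", "s2") %in%
                    once$sample_id[once$compound_class == "istd"]))
  expect_false("U1-FA" %in% once$compound_id)
})

test_that("consistency filter needs >75% presence for unknowns only", {
  mk <- function(n_present, n_samples = 23, id = "UX-FA") {
    rows <- lapply(seq_len(n_samples), function(s) {
      base <- data.frame(sample_id = sprintf("s%02d", s),
                         compound_id = "palmitic_acid",
                         compound_class = "known_fa", area = 1000, mw = 256.42)
      if (s <= n_present) {
        base <- rbind(base, data.frame(
          sample_id = sprintf("s%02d", s), compound_id = id,
          compound_class = "unknown_fa", area = 100, mw = NA))
      }
      base
    })
    do.call(rbind, rows)
  }
  expect_true("UX-FA" %in% consistency_filter(mk(18)))   # 78.3 %
  expect_false("UX-FA" %in% consistency_filter(mk(17)))  # 73.9 %
  expect_true("UX-FA" %in% consistency_filter(mk(23)))
  # known compounds pass even when rare
  rare_known <- mk(0)
  rare_known$compound_id[1] <- "cholesterol"
  rare_known$compound_class[1] <- "sterol"
  expect_true("cholesterol" %in% consistency_filter(rare_known))
})

test_that("backbone fraction follows the residue-mass arithmetic", {
  expect_equal(backbone_fraction(1, 0, mean_fa_mw = 256, chains_per_lipid = 2,
                                 glycerol_backbone_mw = 38),
               38 / (38 + 512), tolerance = 1e-4)
  expect_equal(backbone_fraction(0.2, 0.8, mean_fa_mw = 300,
                                 glycerol_backbone_mw = 0,
                                 phospho_backbone_mw = 0), 0)
  expect_error(backbone_fraction(0.5, 0.6, mean_fa_mw = 300), "sum to 1")
  # default 20:80 value, computed once from the configured residue masses
  # and the catalogue mean molecular weight, frozen as a regression value
  mw <- spongebiomass:::fame_mw_map(ref_fame_catalogue())
  f_b <- backbone_fraction(mean_fa_mw = mean(mw, na.rm = TRUE))
  expect_equal(f_b, 0.1381051, tolerance = 1e-6)
})

test_that("lipid quantification distributes backbone-corrected mass by area", {
  one <- data.frame(sample_id = "s1", compound_id = "x",
                    compound_class = "known_fa", area = 500, mw = 250)
  lm1 <- data.frame(sample_id = "s1", lipid_g_per_gdw = 0.1)
  p1 <- quantify_lipids(one, lm1, f_b = 0, mw_map = c(x = 250),
                        retained = "x")
  expect_equal(p1$mean_umol_per_gdw, 400)

  two <- data.frame(sample_id = "s1", compound_id = c("x", "y"),
                    compound_class = "known_fa", area = c(300, 100),
                    mw = c(250, 500))
  p2 <- quantify_lipids(two, lm1, f_b = 0, mw_map = c(x = 250, y = 500),
                        retained = c("x", "y"))
  expect_equal(p2$mean_umol_per_gdw[p2$compound_id == "x"], 300)
  expect_equal(p2$mean_umol_per_gdw[p2$compound_id == "y"], 50)

  expect_error(quantify_lipids(two, lm1, 0, c(x = 250), character()), "empty")
  # a sample without a lipid mass is skipped with a warning
  two_s <- two; two_s$sample_id <- c("s1", "s1")
  extra <- rbind(two_s, transform(two_s, sample_id = "s2"))
  expect_warning(
    p3 <- quantify_lipids(extra, lm1, 0, c(x = 250, y = 500), c("x", "y")),
    "skipped")
  expect_equal(p3$n_samples[1], 1L)
})

test_that("per-sample mass closure is exact after renormalization", {
  cfg <- simulation_config(seed = 4)
  fm <- simulate_fame_tables(cfg)
  retained <- consistency_filter(fm$peaks)
  mw <- spongebiomass:::fame_mw_map(ref_fame_catalogue())
  lp <- quantify_lipids(fm$peaks, fm$lipid_mass, fm$f_b, mw, retained)
  ps <- attr(lp, "per_sample")
  mwq <- mw[rownames(ps)]
  mwq[is.na(mwq)] <- attr(lp, "imputed_mw")
  accounted <- colSums(ps * mwq) / 1e6
  expected <- fm$lipid_mass$lipid_g_per_gdw[
    match(colnames(ps), fm$lipid_mass$sample_id)] * (1 - fm$f_b)
  expect_equal(accounted, expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("quantification is invariant to uniform area rescaling", {
  fx <- fame_fixture()
  mw <- c(palmitic_acid = 256.42, octadecanoic_acid = 284.48)
  ret <- c("palmitic_acid", "octadecanoic_acid", "U1-FA")
  base <- quantify_lipids(fx$peaks, fx$lipid, 0.1, mw, ret)
  scaled <- fx$peaks
  scaled$area[scaled$sample_id == "s1"] <-
    scaled$area[scaled$sample_id == "s1"] * 37
  again <- quantify_lipids(scaled, fx$lipid, 0.1, mw, ret)
  expect_equal(again$mean_umol_per_gdw, base$mean_umol_per_gdw)
})

test_that("equal molecular weights make abundances proportional to areas", {
  fx <- fame_fixture()
  mw <- c(palmitic_acid = 300, octadecanoic_acid = 300)
  ret <- c("palmitic_acid", "octadecanoic_acid", "U1-FA")
  lp <- quantify_lipids(fx$peaks, fx$lipid, 0, mw, ret)
  ps <- attr(lp, "per_sample")
  areas_s1 <- c(`octadecanoic_acid` = 300, `palmitic_acid` = 600,
                `U1-FA` = 100)
  expect_equal(ps[names(areas_s1), "s1"] / sum(ps[, "s1"]),
               areas_s1 / sum(areas_s1), tolerance = 1e-12)
})

test_that("coverage is the retained share of total signal", {
  fx <- fame_fixture()
  expect_equal(
    fame_coverage(fx$peaks, c("palmitic_acid", "octadecanoic_acid", "U1-FA")),
    1.0)
  # retained area 825 of 1000 in one sample
  pk <- data.frame(sample_id = "s1", compound_id = c("a", "b"),
                   compound_class = c("known_fa", "unknown_fa"),
                   area = c(825, 175), mw = c(256, NA))
  expect_equal(fame_coverage(pk, "a"), 0.825)
})

test_that("simulated peak tables reproduce the catalogue end to end", {
  cfg <- simulation_config(seed = 1)
  fm <- simulate_fame_tables(cfg)
  retained <- consistency_filter(fm$peaks)
  # junk peaks fall below the cut-off; inconsistent background compounds
  # fail the presence rule; exactly the catalogue survives
  expect_setequal(retained, cfg$fame_catalogue$compound_id)
  mw <- spongebiomass:::fame_mw_map(ref_fame_catalogue())
  lp <- quantify_lipids(fm$peaks, fm$lipid_mass, fm$f_b, mw, retained)
  pal <- lp[lp$compound_id == "palmitic_acid", ]
  se <- ref_fame_catalogue()$sd_umol[
    ref_fame_catalogue()$compound_id == "palmitic_acid"] / sqrt(23)
  expect_lt(abs(pal$mean_umol_per_gdw - 98.140), 2 * se)
  cov <- fame_coverage(fm$peaks, retained)
  expect_gt(cov, 0.75)
  expect_lt(cov, 0.9)
})
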