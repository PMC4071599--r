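# Synthetic-data generator.
#
# Emulates the study's hierarchical sampling design (biopsies nested in
# individual sponges) with the published component means, spreads and
# between-individual variance shares as the true generating values, so every
# pipeline stage can be exercised and its recovery tested without the
# unpublished field data.

rnorm_trunc0 <- function(n, mean, sd) {
  # truncation at zero by resampling (not clipping) to avoid mean bias for
  # small-mean components such as DNA and RNA; mean/sd may be vectors
  mm <- rep_len(mean, n)
  ss <- rep_len(sd, n)
  x <- stats::rnorm(n, mm, ss)
  x[ss == 0] <- mm[ss == 0]
  bad <- which(x <= 0 & ss > 0)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mm[bad], ss[bad])
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L) stop("truncation resampling failed to converge")
  }
  if (any(x <= 0)) stop("non-positive value with zero sd in truncated draw")
  x
}

rlnorm_ms <- function(n, mean, sd) {
  # lognormal parameterized by its arithmetic mean and sd (positivity for
  # FAME abundances)
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

#' Configuration for the synthetic-data generator
#'
#' Bundles every generating parameter with defaults equal to the published
#' study conditions: 4 individuals x 5 biopsies, the reference component
#' means/SDs and between-individual shares, 23 FAME fractions, 20
#' hydrolysate samples, 3 % triplicate assay noise, and the reference
#' compound catalogues.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_individuals,n_biopsies Sampling design; defaults 4 and 5.
#' @param components Data frame with `component`, `mean`, `sd`,
#'   `pct_between`; default [ref_macro_composition()].
#' @param assay_cv Relative triplicate noise SD; default 0.03.
#' @param fame_catalogue Compound catalogue; default [ref_fame_catalogue()].
#' @param n_fame_samples Number of lipid fractions; default 23.
#' @param fame_dropout Probability that an unidentified compound is missing
#'   from a given sample (capped so catalogue compounds still satisfy the
#'   75 % presence rule); default 0.08.
#' @param fame_coverage Target chromatographic coverage of the catalogue
#'   compounds, i.e. the share of total signal they generate; the remainder
#'   is emitted as inconsistently present background peaks. Default 0.825.
#' @param aa_table Amino-acid catalogue; default [ref_amino_acids()].
#' @param n_aa_samples Hydrolysate samples per profile; default 20.
#' @param aa_noise_scale Multiplier on the amino-acid SDs (0 = noise-free);
#'   default 1.
#' @param conversion_n,conversion_mean,conversion_sd Displacement-pair
#'   design; defaults 97 pairs at 0.091 gDW/mL with ratio SD 0.012.
#' @param salt_coefficient,a260_conversion,mw_basis,genome_gc,transcriptome_gc
#'   Analysis constants passed through to the pipeline stages.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_individuals = 4L,
                              n_biopsies = 5L,
                              components = ref_macro_composition(),
                              assay_cv = 0.03,
                              fame_catalogue = ref_fame_catalogue(),
                              n_fame_samples = 23L,
                              fame_dropout = 0.08,
                              fame_coverage = 0.825,
                              aa_table = ref_amino_acids(),
                              n_aa_samples = 20L,
                              aa_noise_scale = 1,
                              conversion_n = 97L,
                              conversion_mean = 0.091,
                              conversion_sd = 0.012,
                              salt_coefficient = 0.035,
                              a260_conversion = 40,
                              mw_basis = "fatty_acid",
                              genome_gc = 0.3114,
                              transcriptome_gc = 0.3976) {
  stopifnot(n_individuals >= 2L, n_biopsies >= 1L)
  stop_if_not_number(components$mean, "components$mean", min = 0,
                     strict_min = TRUE)
  stop_if_not_number(components$sd, "components$sd", min = 0)
  stop_if_not_number(components$pct_between, "components$pct_between",
                     min = 0, max = 100)
  cfg <- list(
    seed = as.integer(seed),
    n_individuals = as.integer(n_individuals),
    n_biopsies = as.integer(n_biopsies),
    components = components,
    assay_cv = assay_cv,
    fame_catalogue = fame_catalogue,
    n_fame_samples = as.integer(n_fame_samples),
    fame_dropout = fame_dropout,
    fame_coverage = fame_coverage,
    aa_table = aa_table,
    n_aa_samples = as.integer(n_aa_samples),
    aa_noise_scale = aa_noise_scale,
    conversion_n = as.integer(conversion_n),
    conversion_mean = conversion_mean,
    conversion_sd = conversion_sd,
    salt_coefficient = salt_coefficient,
    a260_conversion = a260_conversion,
    mw_basis = mw_basis,
    genome_gc = genome_gc,
    transcriptome_gc = transcriptome_gc,
    # per-assay true curves and reaction geometry (slope in signal per
    # ug/mL; volumes in mL). Dilutions keep expected concentrations inside
    # the standard ranges.
    assays = list(
      protein = list(slope = 0.002, intercept = 0.05, dilution = 200,
                     volume_ml = 3, standards = seq(0, 200, by = 25)),
      carbohydrate = list(slope = 0.008, intercept = 0.02, dilution = 50,
                          volume_ml = 6, standards = seq(0, 100, by = 12.5)),
      dna = list(slope = 1.5, intercept = 10, dilution = 1,
                 volume_ml = 3, standards = seq(0, 200, by = 25)),
      rna = list(dilution = 40 / 3, volume_ml = 4)
    )
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate the hierarchical biopsy dataset
#'
#' Draws, for every macro-component, individual-level effects
#' `a_i ~ N(0, sigma2_b)` and biopsy residuals `e_ij ~ N(0, sigma2_w)` with
#' `sigma2_b + sigma2_w = sd^2` and `sigma2_b/(sigma2_b+sigma2_w)` equal to
#' the configured between-individual share, then sets
#' `value = mean + a_i + e_ij`, truncated at zero by resampling. Biopsy mass
#' records (wet, lyophilized, displacement) consistent with the salt
#' correction and the displacement conversion factor are generated
#' alongside.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (biopsy mass table), `measurements` (tidy
#'   per-biopsy component values, g/gDW) and `truth` (generating
#'   parameters).
#' @export
simulate_biopsy_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1L))
  n_ind <- config$n_individuals
  n_bio <- config$n_biopsies
  n <- n_ind * n_bio
  sponge <- rep(sprintf("sponge%02d", seq_len(n_ind)), each = n_bio)
  biopsy <- rep(sprintf("b%02d", seq_len(n_bio)), times = n_ind)

  ## mass records ------------------------------------------------------
  wet <- rnorm_trunc0(n, 5, 1)
  dry_frac <- rnorm_trunc0(n, 0.10, 0.01)
  corrected <- wet * dry_frac
  k <- config$salt_coefficient
  lyophilized <- (corrected + k * wet) / (1 + k)
  ratio <- rnorm_trunc0(n, config$conversion_mean, config$conversion_sd)
  records <- data.frame(
    sponge_id = sponge, biopsy_id = biopsy,
    wet_mass_g = wet, lyophilized_mass_g = lyophilized,
    displacement_mL = corrected / ratio,
    stringsAsFactors = FALSE
  )

  ## component measurements --------------------------------------------
  comp <- config$components
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    share <- comp$pct_between[i] / 100
    s2b <- share * comp$sd[i]^2
    s2w <- (1 - share) * comp$sd[i]^2
    if (share == 1 && n_bio > 1L) {
      warning("between-individual share of 100% with replicate biopsies ",
              "for component ", comp$component[i], call. = FALSE)
    }
    a <- rep(stats::rnorm(n_ind, 0, sqrt(s2b)), each = n_bio)
    value <- comp$mean[i] + a + stats::rnorm(n, 0, sqrt(s2w))
    bad <- which(value <= 0)
    guard <- 0L
    while (length(bad)) {
      value[bad] <- comp$mean[i] + a[bad] +
        stats::rnorm(length(bad), 0, sqrt(s2w))
      bad <- bad[value[bad] <= 0]
      guard <- guard + 1L
      if (guard > 10000L) stop("truncation resampling failed to converge")
    }
    data.frame(component = comp$component[i], sponge_id = sponge,
               biopsy_id = biopsy, g_per_gDW = value,
               stringsAsFactors = FALSE)
  })
  list(records = records,
       measurements = do.call(rbind, rows),
       truth = list(components = comp,
                    conversion_mean = config$conversion_mean,
                    conversion_sd = config$conversion_sd,
                    salt_coefficient = k))
}

#' Simulate displacement-volume / dry-mass calibration pairs
#'
#' @param config A [simulation_config()]; uses `conversion_n`,
#'   `conversion_mean`, `conversion_sd`.
#' @return Data frame with `displacement_mL` and `corrected_dry_mass_g`;
#'   attribute `true_mean` carries the generating ratio.
#' @export
simulate_conversion_pairs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 5L))
  vol <- stats::runif(config$conversion_n, 5, 30)
  ratio <- rnorm_trunc0(config$conversion_n, config$conversion_mean,
                        config$conversion_sd)
  structure(
    data.frame(displacement_mL = vol, corrected_dry_mass_g = vol * ratio),
    true_mean = config$conversion_mean, true_sd = config$conversion_sd
  )
}

#' Simulate assay readings and standards from component measurements
#'
#' Inverts the assay arithmetic: each protein/carbohydrate/DNA value is
#' pushed through the configured true standard curve to an expected signal
#' and RNA values to an expected A260, then triplicate multiplicative noise
#' at the configured CV is added. Standard-curve points receive noise at
#' half the CV. A noise-free configuration round-trips exactly through the
#' quantification functions.
#'
#' @param measurements Component measurement table from
#'   [simulate_biopsy_dataset()].
#' @param records Matching biopsy record table (for dry masses).
#' @param config A [simulation_config()].
#' @return List with `standards` (component, concentration, signal) and
#'   `readings` (component, sponge_id, biopsy_id, s1..s3, dilution,
#'   volume_mL, dry_mass_g).
#' @export
simulate_assay_readings <- function(measurements, records, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2L))
  records <- account_biopsies(records, config$salt_coefficient)
  key <- paste(records$sponge_id, records$biopsy_id)
  cv <- config$assay_cv

  standards <- do.call(rbind, lapply(
    c("protein", "carbohydrate", "dna"), function(cc) {
      a <- config$assays[[cc]]
      sig <- (a$slope * a$standards + a$intercept) *
        (1 + stats::rnorm(length(a$standards), 0, cv / 2))
      data.frame(component = cc, concentration = a$standards, signal = sig,
                 stringsAsFactors = FALSE)
    }))

  assayed <- c("protein", "carbohydrate", "dna", "rna")
  sub <- measurements[measurements$component %in% assayed, , drop = FALSE]
  dry <- records$corrected_dry_mass_g[
    match(paste(sub$sponge_id, sub$biopsy_id), key)]
  if (anyNA(dry)) stop("measurements without matching biopsy record")

  n <- nrow(sub)
  s <- matrix(NA_real_, n, 3L)
  dilution <- volume <- numeric(n)
  for (i in seq_len(n)) {
    cc <- sub$component[i]
    a <- config$assays[[cc]]
    dilution[i] <- a$dilution
    volume[i] <- a$volume_ml
    if (cc == "rna") {
      a260 <- sub$g_per_gDW[i] * 1e6 * dry[i] /
        (config$a260_conversion * a$dilution * a$volume_ml)
      s[i, ] <- a260 * (1 + stats::rnorm(3L, 0, cv))
    } else {
      conc <- sub$g_per_gDW[i] * 1e6 * dry[i] / a$volume_ml / a$dilution
      sig <- a$slope * conc + a$intercept
      s[i, ] <- sig * (1 + stats::rnorm(3L, 0, cv))
    }
  }
  readings <- data.frame(
    component = sub$component, sponge_id = sub$sponge_id,
    biopsy_id = sub$biopsy_id,
    s1 = s[, 1L], s2 = s[, 2L], s3 = s[, 3L],
    dilution = dilution, volume_mL = volume, dry_mass_g = dry,
    stringsAsFactors = FALSE
  )
  list(standards = standards, readings = readings)
}

#' Simulate GC-MS FAME peak tables and gravimetric lipid masses
#'
#' Per sample, each catalogue compound's true abundance is drawn lognormally
#' around its catalogue mean/SD, converted to a mass via its (simulation)
#' molecular weight and to a peak area through a per-sample instrument gain.
#' Unidentified catalogue compounds are omitted from a few samples (never
#' enough to violate the 75 % presence rule), inconsistently present
#' background compounds carry the configured non-covered signal share, and
#' sub-cutoff junk peaks exercise the intensity filter. The per-sample
#' gravimetric lipid mass is the summed compound mass divided by
#' `1 - f_b`, making the backbone subtraction and per-sample mass closure
#' exact by construction.
#'
#' @param config A [simulation_config()].
#' @return List with `peaks` (tidy peak table across samples), `lipid_mass`
#'   (sample_id, lipid_g_per_gdw), `f_b` (the generating backbone fraction)
#'   and `truth` (per-compound generating means).
#' @export
simulate_fame_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 3L))
  cat <- config$fame_catalogue
  n_s <- config$n_fame_samples
  samples <- sprintf("s%02d", seq_len(n_s))
  mwmap <- fame_mw_map(cat, config$mw_basis)
  mean_mw <- mean(mwmap, na.rm = TRUE)
  f_b <- backbone_fraction(mean_fa_mw = mean_mw)

  is_unknown <- !(cat$compound_class %in% fame_known_classes)
  # cap dropout so every catalogue compound keeps > 75 % presence
  max_absent <- max(0L, ceiling(n_s * 0.25) - 2L)

  peak_rows <- vector("list", n_s)
  lipid_g <- numeric(n_s)
  present_mat <- matrix(TRUE, nrow(cat), n_s)
  for (j in which(is_unknown)) {
    n_absent <- min(stats::rbinom(1L, n_s, config$fame_dropout), max_absent)
    if (n_absent > 0L) {
      present_mat[j, sample.int(n_s, n_absent)] <- FALSE
    }
  }
  # background compounds: present in under 75 % of samples, excluded by the
  # consistency filter; they carry the non-covered share of the signal
  n_bg <- 3L
  bg_ids <- sprintf("BG%d-FA", seq_len(n_bg))
  bg_present <- matrix(FALSE, n_bg, n_s)
  n_bg_present <- floor(0.5 * n_s)
  for (b in seq_len(n_bg)) {
    bg_present[b, sample.int(n_s, n_bg_present)] <- TRUE
  }
  bg_expected <- n_bg * n_bg_present / n_s

  for (si in seq_len(n_s)) {
    present <- present_mat[, si]
    abund <- rlnorm_ms(sum(present), cat$mean_umol[present],
                       cat$sd_umol[present])
    mass_ug <- abund * cat$sim_mw[present]  # umol * g/mol = ug per gDW
    gain <- stats::rlnorm(1L, log(50), 0.3)
    area <- mass_ug * gain
    max_area <- max(area)

    rows <- data.frame(
      sample_id = samples[si],
      compound_id = cat$compound_id[present],
      compound_class = cat$compound_class[present],
      area = area,
      mw = ifelse(cat$compound_class[present] %in% fame_known_classes,
                  unname(mwmap[cat$compound_id[present]]), NA_real_),
      stringsAsFactors = FALSE
    )
    # background signal not contributing quantified lipid mass
    bg_here <- which(bg_present[, si])
    if (length(bg_here)) {
      bg_total <- (1 / config$fame_coverage - 1) * sum(area) *
        length(bg_here) / bg_expected
      share <- stats::runif(length(bg_here), 0.5, 1.5)
      rows <- rbind(rows, data.frame(
        sample_id = samples[si], compound_id = bg_ids[bg_here],
        compound_class = "unknown_fa",
        area = bg_total * share / sum(share), mw = NA_real_,
        stringsAsFactors = FALSE))
    }
    # sub-cutoff junk peaks
    n_junk <- 4L
    rows <- rbind(rows, data.frame(
      sample_id = samples[si],
      compound_id = sprintf("sub%d", seq_len(n_junk)),
      compound_class = "unknown_fa",
      area = stats::runif(n_junk, 0, 0.3 * 5e-4 * max_area),
      mw = NA_real_, stringsAsFactors = FALSE))
    # internal standard (5.1 ug nondecanoic acid)
    rows <- rbind(rows, data.frame(
      sample_id = samples[si], compound_id = "nondecanoic_acid_istd",
      compound_class = "istd", area = 5.1 * gain, mw = 298.50,
      stringsAsFactors = FALSE))
    peak_rows[[si]] <- rows
    lipid_g[si] <- sum(mass_ug) / 1e6 / (1 - f_b)
  }
  list(
    peaks = do.call(rbind, peak_rows),
    lipid_mass = data.frame(sample_id = samples, lipid_g_per_gdw = lipid_g,
                            stringsAsFactors = FALSE),
    f_b = f_b,
    truth = list(catalogue = cat, mean_mw = mean_mw)
  )
}

#' Simulate per-sample amino-acid hydrolysate tables
#'
#' Draws per-sample abundances around the catalogue means with the
#' catalogue SDs (scaled by `aa_noise_scale`; zero gives the means exactly),
#' truncated at zero by resampling. Aspartate/asparagine and
#' glutamine/glutamate are emitted as combined `ASX`/`GLX` pools, as an acid
#' hydrolysate reports them, to exercise the amide splitter.
#'
#' @param config A [simulation_config()].
#' @return List with `total` and `skeleton`, each a tidy data frame
#'   (sample_id, amino_acid, mmol_per_gdw).
#' @export
simulate_aa_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 4L))
  tab <- config$aa_table
  scale <- config$aa_noise_scale
  one <- function(mean_col, sd_col) {
    species <- tab$amino_acid
    means <- tab[[mean_col]]
    sds <- tab[[sd_col]] * scale
    # combined amide pools: the 50:50 split is deterministic, so pool mean
    # and sd are twice the per-species values
    keep <- !(species %in% c("ASP", "ASN", "GLN", "GLU"))
    sp_out <- c(species[keep], "ASX", "GLX")
    mean_out <- c(means[keep], 2 * means[match("ASP", species)],
                  2 * means[match("GLN", species)])
    sd_out <- c(sds[keep], 2 * sds[match("ASP", species)],
                2 * sds[match("GLN", species)])
    rows <- lapply(seq_len(config$n_aa_samples), function(s) {
      data.frame(sample_id = sprintf("aa%02d", s),
                 amino_acid = sp_out,
                 mmol_per_gdw = rnorm_trunc0(length(sp_out), mean_out, sd_out),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  list(total = one("total_mean", "total_sd"),
       skeleton = one("skeleton_mean", "skeleton_sd"))
}

#' Write a complete synthetic input bundle to disk
#'
#' Runs every generator stage and writes the CSV bundle the pipeline
#' consumes, plus a YAML analysis config and a ground-truth YAML for
#' recovery tests. Identical configurations (including the seed) produce
#' byte-identical bundles.
#'
#' @param dir Output directory (created if needed).
#' @param config A [simulation_config()].
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_bundle <- function(dir, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bio <- simulate_biopsy_dataset(config)
  assays <- simulate_assay_readings(bio$measurements, bio$records, config)
  fame <- simulate_fame_tables(config)
  aa <- simulate_aa_tables(config)

  records <- account_biopsies(bio$records, config$salt_coefficient)
  skel <- bio$measurements[bio$measurements$component == "skeleton", ]
  key <- paste(records$sponge_id, records$biopsy_id)
  dry <- records$corrected_dry_mass_g[
    match(paste(skel$sponge_id, skel$biopsy_id), key)]
  skeleton_tab <- data.frame(
    sponge_id = skel$sponge_id, biopsy_id = skel$biopsy_id,
    skeleton_dry_mass_g = skel$g_per_gDW * dry, total_dry_mass_g = dry,
    stringsAsFactors = FALSE)
  lip <- bio$measurements[bio$measurements$component == "lipid", ]
  lipid_tab <- data.frame(
    sponge_id = lip$sponge_id, biopsy_id = lip$biopsy_id,
    lipid_g_per_gdw = lip$g_per_gDW, stringsAsFactors = FALSE)

  cfg_hash_src <- paste(deparse(config[setdiff(names(config),
                                               c("components",
                                                 "fame_catalogue",
                                                 "aa_table", "assays"))]),
                        collapse = "")
  hash <- fnv1a_hash(cfg_hash_src)
  paths <- c(
    records = file.path(dir, "records.csv"),
    skeleton = file.path(dir, "skeleton.csv"),
    lipid_gravimetric = file.path(dir, "lipid_gravimetric.csv"),
    standards = file.path(dir, "standards.csv"),
    readings = file.path(dir, "readings.csv"),
    fame_peaks = file.path(dir, "fame_peaks.csv"),
    fame_lipid_mass = file.path(dir, "fame_lipid_mass.csv"),
    aa_total = file.path(dir, "aa_total.csv"),
    aa_skeleton = file.path(dir, "aa_skeleton.csv"),
    config = file.path(dir, "config.yaml"),
    truth = file.path(dir, "truth.yaml")
  )
  write_table(bio$records, paths[["records"]], hash)
  write_table(skeleton_tab, paths[["skeleton"]], hash)
  write_table(lipid_tab, paths[["lipid_gravimetric"]], hash)
  write_table(assays$standards, paths[["standards"]], hash)
  write_table(assays$readings, paths[["readings"]], hash)
  write_table(fame$peaks, paths[["fame_peaks"]], hash)
  write_table(fame$lipid_mass, paths[["fame_lipid_mass"]], hash)
  write_table(aa$total, paths[["aa_total"]], hash)
  write_table(aa$skeleton, paths[["aa_skeleton"]], hash)

  yaml::write_yaml(list(
    seed = config$seed,
    salt_coefficient = config$salt_coefficient,
    a260_conversion = config$a260_conversion,
    mw_basis = config$mw_basis,
    genome_gc = config$genome_gc,
    transcriptome_gc = config$transcriptome_gc
  ), paths[["config"]])
  yaml::write_yaml(list(
    components = as.list(stats::setNames(config$components$mean,
                                         config$components$component)),
    pct_between = as.list(stats::setNames(config$components$pct_between,
                                          config$components$component)),
    conversion_mean = config$conversion_mean,
    conversion_sd = config$conversion_sd,
    fame_f_b = fame$f_b
  ), paths[["truth"]])
  invisible(paths)
}
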