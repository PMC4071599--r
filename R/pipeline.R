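# Shared CSV/YAML I/O and the end-to-end pipeline driver.

#' Read a schema-checked CSV table
#'
#' Reads a comma-separated table (UTF-8, `.` decimal separator), skipping
#' `#` comment lines, and verifies that the required columns are present.
#'
#' @param path File path.
#' @param required_cols Character vector of column names that must exist.
#' @return A data frame.
#' @export
read_table <- function(path, required_cols = character()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         encoding = "UTF-8")
  if (nrow(tab) == 0L) {
    stop("no records in ", path, call. = FALSE)
  }
  missing <- setdiff(required_cols, names(tab))
  if (length(missing)) {
    stop("table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Write a CSV table with a provenance header
#'
#' Writes a comma-separated table preceded by a `#` comment line carrying
#' the package version and a configuration hash, so outputs are auditable
#' and byte-identical across reruns of the same configuration.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @param config_hash Short hash string identifying the run configuration.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path, config_hash = "none") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# spongebiomass %s config=%s",
                     as.character(utils::packageVersion("spongebiomass")),
                     config_hash), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration YAML
#'
#' @param path YAML file with scalar keys `seed`, `salt_coefficient`,
#'   `a260_conversion`, `mw_basis`, `genome_gc`, `transcriptome_gc`.
#'   Unknown keys are rejected.
#' @return Named list of configuration values (missing keys filled with
#'   defaults).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "salt_coefficient", "a260_conversion", "mw_basis",
             "genome_gc", "transcriptome_gc")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(seed = 1L, salt_coefficient = 0.035, a260_conversion = 40,
                   mw_basis = "fatty_acid", genome_gc = 0.3114,
                   transcriptome_gc = 0.3976)
  utils::modifyList(defaults, cfg)
}

#' Run the full composition pipeline on an input bundle
#'
#' Executes dry-weight accounting, assay quantification, the FAME, amino
#' acid and nucleotide analyses, variance partitioning and biomass-equation
#' assembly over a directory of input CSVs (as written by
#' [simulate_bundle()]), writing published-style output tables. A missing
#' FAME peak table downgrades the lipid building-block stage to a warning;
#' every other input is required.
#'
#' @param input_dir Directory holding `records.csv`, `skeleton.csv`,
#'   `lipid_gravimetric.csv`, `standards.csv`, `readings.csv`,
#'   `aa_total.csv`, `aa_skeleton.csv`, optionally `fame_peaks.csv` +
#'   `fame_lipid_mass.csv`, and `config.yaml`.
#' @param output_dir Directory for the outputs (created if needed).
#' @return Invisibly, a list with the main in-memory results (`summaries`,
#'   `variance`, `lipid_profile`, `aa`, `nucleotides`, `equation`,
#'   `outputs` = named vector of written paths).
#' @export
run_pipeline <- function(input_dir, output_dir) {
  cfg <- read_pipeline_config(file.path(input_dir, "config.yaml"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- fnv1a_hash(paste(deparse(cfg), collapse = ""))
  outp <- function(name) file.path(output_dir, name)
  outputs <- character()

  ## sample accounting -------------------------------------------------
  records <- read_table(file.path(input_dir, "records.csv"),
                        c("sponge_id", "biopsy_id", "wet_mass_g",
                          "lyophilized_mass_g"))
  records <- account_biopsies(records, cfg$salt_coefficient)
  write_table(records, outp("accounting.csv"), hash)
  outputs["accounting"] <- outp("accounting.csv")
  conv <- if ("displacement_mL" %in% names(records)) {
    displacement_conversion(records$displacement_mL,
                            records$corrected_dry_mass_g)
  } else NULL

  ## gravimetric components --------------------------------------------
  skel <- read_table(file.path(input_dir, "skeleton.csv"),
                     c("sponge_id", "biopsy_id", "skeleton_dry_mass_g",
                       "total_dry_mass_g"))
  skel_meas <- data.frame(
    component = "skeleton", sponge_id = skel$sponge_id,
    biopsy_id = skel$biopsy_id,
    g_per_gDW = skeleton_fraction(skel$skeleton_dry_mass_g,
                                  skel$total_dry_mass_g),
    stringsAsFactors = FALSE)
  lip <- read_table(file.path(input_dir, "lipid_gravimetric.csv"),
                    c("sponge_id", "biopsy_id", "lipid_g_per_gdw"))
  lip_meas <- data.frame(
    component = "lipid", sponge_id = lip$sponge_id,
    biopsy_id = lip$biopsy_id, g_per_gDW = lip$lipid_g_per_gdw,
    stringsAsFactors = FALSE)

  ## assays -------------------------------------------------------------
  standards <- read_table(file.path(input_dir, "standards.csv"),
                          c("component", "concentration", "signal"))
  curves <- lapply(split(standards, standards$component), function(s) {
    fit_standard_curve(s$concentration, s$signal)
  })
  readings <- read_table(file.path(input_dir, "readings.csv"),
                         c("component", "sponge_id", "biopsy_id", "s1", "s2",
                           "s3", "dilution", "volume_mL", "dry_mass_g"))
  assay_meas <- quantify_assay_table(readings, curves,
                                     a260_conversion = cfg$a260_conversion)
  measurements <- rbind(skel_meas, lip_meas, assay_meas)
  write_table(measurements, outp("composition.csv"), hash)
  outputs["composition"] <- outp("composition.csv")

  ## population summaries ----------------------------------------------
  components <- c("skeleton", "lipid", "protein", "carbohydrate", "rna",
                  "dna")
  summaries <- do.call(rbind, lapply(components, function(cc) {
    summarize_component(
      measurements$g_per_gDW[measurements$component == cc], cc)
  }))
  write_table(summaries, outp("table1_summary.csv"), hash)
  outputs["summary"] <- outp("table1_summary.csv")

  ## variance partitioning ----------------------------------------------
  variance <- variance_partition(measurements)
  write_table(variance, outp("table2_variance.csv"), hash)
  outputs["variance"] <- outp("table2_variance.csv")

  ## FAME ---------------------------------------------------------------
  lipid_profile <- NULL
  coverage <- NA_real_
  fame_path <- file.path(input_dir, "fame_peaks.csv")
  if (file.exists(fame_path)) {
    peaks <- read_table(fame_path, c("sample_id", "compound_id",
                                     "compound_class", "area"))
    fame_mass <- read_table(file.path(input_dir, "fame_lipid_mass.csv"),
                            c("sample_id", "lipid_g_per_gdw"))
    retained <- consistency_filter(peaks)
    mwmap <- fame_mw_map(ref_fame_catalogue(), cfg$mw_basis)
    f_b <- backbone_fraction(mean_fa_mw = mean(mwmap, na.rm = TRUE))
    lipid_profile <- quantify_lipids(peaks, fame_mass, f_b, mwmap, retained)
    coverage <- fame_coverage(peaks, retained)
    out3 <- lipid_profile
    out3$coverage <- coverage
    write_table(out3, outp("table3_lipids.csv"), hash)
    outputs["lipids"] <- outp("table3_lipids.csv")
  } else {
    warning("fame_peaks.csv not found; lipid building-block stage skipped",
            call. = FALSE)
  }

  ## amino acids ---------------------------------------------------------
  aa_total <- make_aa_profile(
    read_table(file.path(input_dir, "aa_total.csv"),
               c("sample_id", "amino_acid", "mmol_per_gdw")))
  aa_skeleton <- make_aa_profile(
    read_table(file.path(input_dir, "aa_skeleton.csv"),
               c("sample_id", "amino_acid", "mmol_per_gdw")))
  write_table(mole_fractions(aa_total), outp("table4_aa_total.csv"), hash)
  write_table(mole_fractions(aa_skeleton), outp("table5_aa_skeleton.csv"),
              hash)
  cellular <- cellular_profile(aa_total, aa_skeleton)
  pct_cell <- normalize_percent(cellular)
  pct_skel <- normalize_percent(aa_skeleton)
  fig3 <- data.frame(amino_acid = pct_cell$amino_acid,
                     cellular_percent = pct_cell$percent,
                     skeleton_percent = pct_skel$percent,
                     stringsAsFactors = FALSE)
  write_table(fig3, outp("fig3_percentages.csv"), hash)
  outputs["aa_total"] <- outp("table4_aa_total.csv")
  outputs["aa_skeleton"] <- outp("table5_aa_skeleton.csv")
  outputs["aa_percent"] <- outp("fig3_percentages.csv")

  ## nucleotides ---------------------------------------------------------
  dna_mass <- summaries$mean[summaries$component == "dna"]
  rna_mass <- summaries$mean[summaries$component == "rna"]
  nt_dna <- nucleotide_composition(dna_mass, cfg$genome_gc, "DNA")
  nt_rna <- nucleotide_composition(rna_mass, cfg$transcriptome_gc, "RNA")
  write_table(nt_dna, outp("table6_dna.csv"), hash)
  write_table(nt_rna, outp("table7_rna.csv"), hash)
  outputs["dna"] <- outp("table6_dna.csv")
  outputs["rna"] <- outp("table7_rna.csv")

  ## biomass equation ----------------------------------------------------
  equation <- assemble_biomass_equation(summaries, aa_total, aa_skeleton,
                                        nt_dna, nt_rna, lipid_profile)
  write_biomass_equation(equation, outp("biomass_equation.csv"), "csv")
  write_biomass_equation(equation, outp("biomass_reaction.txt"),
                         "reaction_string")
  outputs["equation"] <- outp("biomass_equation.csv")
  outputs["reaction"] <- outp("biomass_reaction.txt")

  ## run log: every analysis default left open by the protocol ----------
  log_lines <- c(
    sprintf("spongebiomass %s",
            as.character(utils::packageVersion("spongebiomass"))),
    sprintf("config_hash=%s", hash),
    sprintf("salt_coefficient=%g", cfg$salt_coefficient),
    sprintf("a260_conversion=%g", cfg$a260_conversion),
    sprintf("mw_basis=%s", cfg$mw_basis),
    sprintf("genome_gc=%g", cfg$genome_gc),
    sprintf("transcriptome_gc=%g", cfg$transcriptome_gc),
    sprintf("fame_coverage=%.6f", coverage),
    sprintf("accounted_mass_fraction=%.6f",
            attr(equation, "accounted_mass_fraction")),
    if (!is.null(conv)) {
      sprintf("conversion_factor=%.6f sd=%.6f n=%d", conv$mean, conv$sd,
              conv$n)
    },
    "lrt_reference=chi2_df1_naive (boundary mixture reported alongside)"
  )
  log_con <- file(outp("run_log.txt"), open = "wb")
  writeLines(log_lines, log_con)
  close(log_con)
  outputs["log"] <- outp("run_log.txt")

  invisible(list(summaries = summaries, variance = variance,
                 lipid_profile = lipid_profile, coverage = coverage,
                 aa = list(total = aa_total, skeleton = aa_skeleton,
                           cellular = cellular),
                 nucleotides = list(dna = nt_dna, rna = nt_rna),
                 equation = equation, conversion = conv,
                 outputs = outputs))
}
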