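# Biomass equation assembly.
#
# A biomass equation is a data frame of class "biomass_equation" with one row
# per species: species label, macro_class, coefficient, unit ("mmol/gDW" or
# "g/gDW"), basis ("molar" or "mass"), mw (g/mol used for mass accounting; NA
# for mass-basis entries) and unresolved (TRUE for placeholder compounds with
# imputed molecular weight).

biomass_classes <- c("protein_aa", "skeleton_aa", "dna_nt", "rna_nt",
                     "fatty_acid", "sterol", "carbohydrate",
                     "skeleton_inorganic", "lipid_backbone")

new_equation_rows <- function(species, macro_class, coefficient, unit, basis,
                              mw = NA_real_, unresolved = FALSE) {
  data.frame(species = species, macro_class = macro_class,
             coefficient = coefficient, unit = unit, basis = basis,
             mw = mw, unresolved = unresolved, stringsAsFactors = FALSE)
}

#' Assemble a biomass equation from building-block profiles
#'
#' Combines the macro-component summaries with the amino-acid, nucleotide
#' and lipid building-block profiles into a single species -> coefficient
#' map per gram of dry biomass, the drain reaction needed by genome-scale
#' metabolic models.
#'
#' @details Conventions:
#' * Amino acids enter on a molar basis (mmol/gDW), as separate cellular
#'   (`protein_aa`) and skeleton (`skeleton_aa`, species prefixed `skel_`)
#'   classes; the cellular profile is the skeleton-subtracted one and
#'   negative subtraction artefacts are dropped (flagged upstream). With
#'   `pool_aa = TRUE` the two classes are pooled into `protein_aa` using the
#'   complete-biomass profile.
#' * Nucleotides (`dna_nt`, `rna_nt`) are taken from
#'   [nucleotide_composition()] and converted from umol to mmol.
#' * Fatty acids and sterols come from a [quantify_lipids()] profile;
#'   unknowns keep their placeholder labels, carry the imputed mean
#'   molecular weight and are flagged `unresolved`. Compounds classified as
#'   neither FA nor sterol are carried under `fatty_acid`, flagged
#'   `unresolved`. When `include_backbone = TRUE` the glycerol/phosphate
#'   backbone mass excluded from the FAME signal is retained as a mass-basis
#'   `lipid_backbone` entry so the lipid class re-sums to the gravimetric
#'   lipid mass.
#' * Carbohydrate is modelled as anhydro-glucose (glucan residue) monomers:
#'   `carbohydrate g/gDW / carbohydrate_monomer_mw`, in mmol/gDW.
#' * The inorganic skeleton (silica) is carried as a mass-basis remainder:
#'   skeleton mass minus the skeleton amino-acid residue mass, clamped at
#'   zero with a warning when hydrolysate over-recovery makes it negative.
#'
#' Amino-acid mass accounting uses residue (peptide-bond) masses,
#' `mw_free - 18.02`.
#'
#' @param summaries Data frame with columns `component` and `mean` (g/gDW)
#'   covering `skeleton`, `lipid`, `protein`, `carbohydrate`, `rna`, `dna`
#'   (e.g. [ref_macro_composition()] or stacked [summarize_component()]
#'   rows).
#' @param aa_total,aa_skeleton `aa_profile` objects for the complete biomass
#'   and the skeleton (mmol/gDW).
#' @param nt_dna,nt_rna `nucleotide_composition` objects.
#' @param lipid_profile A `lipid_profile` from [quantify_lipids()], or NULL
#'   (empty lipid class, with a warning).
#' @param carbohydrate_monomer_mw Glucose residue mass, g/mol; default 162.
#' @param pool_aa Pool cellular and skeleton amino acids into one class.
#' @param include_backbone Keep the lipid backbone mass remainder entry.
#' @return A `biomass_equation` data frame (see module description), with
#'   attribute `accounted_mass_fraction`.
#' @export
assemble_biomass_equation <- function(summaries, aa_total, aa_skeleton,
                                      nt_dna, nt_rna, lipid_profile,
                                      carbohydrate_monomer_mw = 162,
                                      pool_aa = FALSE,
                                      include_backbone = TRUE) {
  if (!all(c("component", "mean") %in% names(summaries))) {
    stop("summaries needs columns component and mean", call. = FALSE)
  }
  mean_of <- function(cc) {
    i <- match(cc, summaries$component)
    if (is.na(i)) stop("summaries is missing component '", cc, "'",
                       call. = FALSE)
    summaries$mean[i]
  }
  aa_ref <- ref_amino_acids()
  residue_mw <- stats::setNames(aa_ref$mw - 18.02, aa_ref$amino_acid)

  rows <- list()

  ## amino acids -------------------------------------------------------
  aa_total <- validate_aa_profile(aa_total)
  aa_skeleton <- validate_aa_profile(aa_skeleton)
  if (pool_aa) {
    rows$aa <- new_equation_rows(
      aa_total$amino_acid, "protein_aa", aa_total$mmol_per_gdw,
      "mmol/gDW", "molar", mw = unname(residue_mw[aa_total$amino_acid]))
  } else {
    cellular <- cellular_profile(aa_total, aa_skeleton)
    keep <- cellular$mmol_per_gdw >= 0
    if (!all(keep)) {
      warning("dropping negative cellular amino acid(s): ",
              paste(cellular$amino_acid[!keep], collapse = ", "),
              call. = FALSE)
    }
    rows$aa_cell <- new_equation_rows(
      cellular$amino_acid[keep], "protein_aa",
      cellular$mmol_per_gdw[keep], "mmol/gDW", "molar",
      mw = unname(residue_mw[cellular$amino_acid[keep]]))
    rows$aa_skel <- new_equation_rows(
      paste0("skel_", aa_skeleton$amino_acid), "skeleton_aa",
      aa_skeleton$mmol_per_gdw, "mmol/gDW", "molar",
      mw = unname(residue_mw[aa_skeleton$amino_acid]))
  }

  ## nucleotides -------------------------------------------------------
  for (nt in list(list(x = nt_dna, class = "dna_nt"),
                  list(x = nt_rna, class = "rna_nt"))) {
    if (!inherits(nt$x, "nucleotide_composition")) {
      stop("nt_dna/nt_rna must be nucleotide_composition objects",
           call. = FALSE)
    }
    rows[[nt$class]] <- new_equation_rows(
      nt$x$residue, nt$class, nt$x$umol_per_gdw / 1000,
      "mmol/gDW", "molar", mw = nt$x$mw)
  }

  ## lipids ------------------------------------------------------------
  lipid_mass <- mean_of("lipid")
  if (is.null(lipid_profile) || nrow(lipid_profile) == 0L) {
    warning("empty lipid profile; lipid class left empty", call. = FALSE)
  } else {
    imputed <- attr(lipid_profile, "imputed_mw")
    cat_mw <- fame_mw_map(ref_fame_catalogue())
    known <- lipid_profile$compound_class %in% fame_known_classes
    mw <- unname(cat_mw[lipid_profile$compound_id])
    mw[is.na(mw)] <- imputed
    eq_class <- ifelse(
      lipid_profile$compound_class %in% c("sterol", "unknown_sterol"),
      "sterol", "fatty_acid")
    rows$lipid <- new_equation_rows(
      lipid_profile$compound_id, eq_class,
      lipid_profile$mean_umol_per_gdw / 1000, "mmol/gDW", "molar",
      mw = mw, unresolved = !known)
    if (include_backbone) {
      f_b <- attr(lipid_profile, "f_b") %||% 0
      rows$backbone <- new_equation_rows(
        "lipid_backbone", "lipid_backbone", f_b * lipid_mass,
        "g/gDW", "mass")
    }
  }

  ## carbohydrate ------------------------------------------------------
  stop_if_not_number(carbohydrate_monomer_mw, "carbohydrate_monomer_mw",
                     min = 0, strict_min = TRUE)
  rows$carb <- new_equation_rows(
    "glucose_equivalent", "carbohydrate",
    mean_of("carbohydrate") / carbohydrate_monomer_mw * 1000,
    "mmol/gDW", "molar", mw = carbohydrate_monomer_mw)

  ## inorganic skeleton remainder --------------------------------------
  skel_aa_mass <- sum(aa_skeleton$mmol_per_gdw *
                        residue_mw[aa_skeleton$amino_acid]) / 1000
  remainder <- mean_of("skeleton") - skel_aa_mass
  if (remainder < 0) {
    warning(sprintf(
      "skeleton amino-acid residue mass (%.3f g/gDW) exceeds the skeleton mass; ",
      skel_aa_mass), "inorganic remainder clamped to 0 (over-recovery)",
      call. = FALSE)
    remainder <- 0
  }
  rows$skel_inorg <- new_equation_rows(
    "skeleton_inorganic", "skeleton_inorganic", remainder, "g/gDW", "mass")

  eq <- do.call(rbind, rows)
  rownames(eq) <- NULL
  if (anyDuplicated(eq$species)) {
    stop("overlapping species labels across classes: ",
         paste(unique(eq$species[duplicated(eq$species)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(eq$coefficient < 0)) {
    stop("negative biomass coefficients", call. = FALSE)
  }
  class(eq) <- c("biomass_equation", class(eq))
  acc <- mass_closure(eq)
  if (acc > 1.05) {
    warning(sprintf(
      "accounted mass fraction %.3f g/gDW exceeds 1.05: building-block ",
      acc), "over-recovery relative to dry mass (see vignette)",
      call. = FALSE)
  }
  attr(eq, "accounted_mass_fraction") <- acc
  eq
}

#' @export
print.biomass_equation <- function(x, ...) {
  cat(sprintf("Biomass equation: %d species in %d classes\n",
              nrow(x), length(unique(x$macro_class))))
  cat(sprintf("  accounted mass: %.4f g/gDW\n",
              attr(x, "accounted_mass_fraction") %||% mass_closure(x)))
  NextMethod()
}

#' Mass closure of a biomass equation
#'
#' Re-sums the equation to grams per gram dry weight: molar coefficients
#' times their molecular weights plus the mass-basis entries. Optionally
#' compares against the summed measured macro-component means.
#'
#' @param equation A `biomass_equation`.
#' @param measured_totals Optional numeric vector of measured component
#'   means (g/gDW), e.g. `ref_macro_composition()$mean`.
#' @return Accounted mass in g/gDW. When `measured_totals` is supplied the
#'   result carries attributes `measured` (their sum) and `ratio`
#'   (accounted/measured).
#' @export
mass_closure <- function(equation, measured_totals = NULL) {
  if (nrow(equation) == 0L) return(0)
  molar <- equation$basis == "molar"
  accounted <- sum(equation$coefficient[molar] * equation$mw[molar]) / 1000 +
    sum(equation$coefficient[!molar])
  if (!is.null(measured_totals)) {
    measured <- sum(measured_totals)
    attr(accounted, "measured") <- measured
    attr(accounted, "ratio") <- accounted / measured
  }
  accounted
}

#' Write a biomass equation to disk
#'
#' Deterministic writers: rows are sorted by class then species and
#' coefficients fixed at 6 decimals, so identical equations produce
#' byte-identical files.
#'
#' @param equation A `biomass_equation`.
#' @param path Output file path.
#' @param format `"csv"` (species table) or `"reaction_string"` (a single
#'   drain reaction `a X + b Y + ... -> 1 g_biomass`).
#' @return `path`, invisibly.
#' @export
write_biomass_equation <- function(equation, path,
                                   format = c("csv", "reaction_string")) {
  format <- match.arg(format)
  ord <- order(match(equation$macro_class, biomass_classes),
               equation$species)
  eq <- equation[ord, , drop = FALSE]
  coef_chr <- sprintf("%.6f", eq$coefficient)
  if (format == "csv") {
    out <- data.frame(species = eq$species, macro_class = eq$macro_class,
                      coefficient = coef_chr, unit = eq$unit,
                      basis = eq$basis, stringsAsFactors = FALSE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("species,macro_class,coefficient,unit,basis", con)
    writeLines(do.call(paste, c(out, sep = ",")), con)
  } else {
    terms <- paste(coef_chr, eq$species)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(paste(terms, collapse = " + "), "-> 1 g_biomass"), con)
  }
  invisible(path)
}

#' Read a biomass equation written by [write_biomass_equation()]
#'
#' @param path CSV path.
#' @return A `biomass_equation` data frame (molecular weights are not stored
#'   in the CSV and come back as `NA`).
#' @export
read_biomass_equation <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "macro_class", "coefficient", "unit", "basis")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("equation file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$coefficient <- as.numeric(tab$coefficient)
  tab$mw <- NA_real_
  tab$unresolved <- FALSE
  class(tab) <- c("biomass_equation", class(tab))
  tab
}
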