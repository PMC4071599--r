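#' Reference macromolecular composition of *Amphimedon queenslandica*
#'
#' Published population summary of the skeletal and macromolecular composition
#' of the sponge *A. queenslandica* (Heron Island Reef), together with the
#' between-individual variance decomposition of each component. These values
#' parameterize the synthetic-data generator ([simulation_config()]) and serve
#' as reference inputs throughout the package.
#'
#' @details Columns:
#' \describe{
#'   \item{component}{one of `skeleton`, `lipid`, `protein`, `carbohydrate`,
#'     `rna`, `dna`.}
#'   \item{mean, sd, se}{population mean, standard deviation and standard
#'     error, all in g/gDW (grams per gram dry weight).}
#'   \item{cv_percent}{coefficient of variation, 100·sd/mean.}
#'   \item{n}{number of biopsies measured.}
#'   \item{pct_between}{percentage of total variance attributed to
#'     between-individual variation by a random-intercept model.}
#'   \item{chi2, p_value}{likelihood-ratio test of the individual-level
#'     random effect.}
#' }
#'
#' @return A data frame with one row per macro-component.
#' @export
#' @examples
#' ref_macro_composition()
ref_macro_composition <- function() {
  data.frame(
    component   = c("skeleton", "lipid", "protein", "carbohydrate", "rna", "dna"),
    mean        = c(0.6343, 0.1252, 0.0881, 0.0197, 0.0021, 0.0003),
    sd          = c(0.0647, 0.0251, 0.0082, 0.0055, 0.0005, 0.0001),
    se          = c(0.0152, 0.0058, 0.0018, 0.0012, 0.0001, 0.00002),
    cv_percent  = c(9.81, 20.09, 9.31, 27.53, 22.24, 25.78),
    n           = c(18L, 19L, 20L, 20L, 20L, 19L),
    pct_between = c(58, 54, 24, 15, 1, 32),
    chi2        = c(6.691, 5.763, 1.393, 0.597, 2.309, 3.53e-8),
    p_value     = c(0.009, 0.016, 0.237, 0.439, 0.128, 0.999),
    stringsAsFactors = FALSE
  )
}

#' Reference FAME compound catalogue
#'
#' The fatty acids, sterols and unresolved GC-MS compounds that contribute to
#' the sponge lipid fraction, with their published mean abundances and
#' standard deviations (across 23 biomass fractions) and molecular weights.
#'
#' @details Compound classes follow the peak-table convention used throughout
#' the FAME module:
#' \describe{
#'   \item{known_fa}{fatty acid confirmed against an authentic standard.}
#'   \item{database_fa}{matched a spectral database but not a standard.}
#'   \item{unknown_fa / unknown_sterol}{classified from the fragmentation
#'     pattern only; no molecular weight is known.}
#'   \item{sterol}{database-matched sterol.}
#'   \item{other}{consistently detected compounds that are neither fatty acid
#'     nor sterol.}
#' }
#' `mw_fa` is the free fatty-acid (or sterol) molecular weight in g/mol;
#' `mw_me` the corresponding methyl ester (`mw_fa + 14.027`; sterols are not
#' methylated so `mw_me = mw_fa`). Both are `NA` for unknowns, whose weight is
#' imputed at quantification time as the mean over identified compounds.
#' `sim_mw` is a plausible molecular weight used only by the synthetic
#' generator to convert simulated molar abundances into peak areas.
#'
#' @return A data frame with one row per compound.
#' @export
#' @examples
#' head(ref_fame_catalogue())
ref_fame_catalogue <- function() {
  fa <- function(mw) c(mw, mw + 14.027)
  tab <- rbind(
    # compound_id, lipid_number, class, mean, sd, mw_fa, mw_me, sim_mw
    data.frame(compound_id = "docosanoic_acid",    lipid_number = "C22:0",
               compound_class = "known_fa", mean_umol = 9.769,  sd_umol = 4.299,
               mw_fa = 340.58, mw_me = 354.61, sim_mw = 340.58),
    data.frame(compound_id = "eicosenoic_acid",    lipid_number = "C20:1",
               compound_class = "known_fa", mean_umol = 1.947,  sd_umol = 0.579,
               mw_fa = 310.51, mw_me = 324.54, sim_mw = 310.51),
    data.frame(compound_id = "erucic_acid",        lipid_number = "C22:1w9",
               compound_class = "known_fa", mean_umol = 1.721,  sd_umol = 0.668,
               mw_fa = 338.57, mw_me = 352.60, sim_mw = 338.57),
    data.frame(compound_id = "heptadecanoic_acid", lipid_number = "C17:0",
               compound_class = "known_fa", mean_umol = 0.922,  sd_umol = 0.234,
               mw_fa = 270.45, mw_me = 284.48, sim_mw = 270.45),
    data.frame(compound_id = "myristic_acid",      lipid_number = "C14:0",
               compound_class = "known_fa", mean_umol = 3.957,  sd_umol = 1.455,
               mw_fa = 228.37, mw_me = 242.40, sim_mw = 228.37),
    data.frame(compound_id = "nervonic_acid",      lipid_number = "C24:1w9",
               compound_class = "known_fa", mean_umol = 10.090, sd_umol = 3.451,
               mw_fa = 366.62, mw_me = 380.65, sim_mw = 366.62),
    data.frame(compound_id = "octadecanoic_acid",  lipid_number = "C18:0",
               compound_class = "known_fa", mean_umol = 62.210, sd_umol = 19.095,
               mw_fa = 284.48, mw_me = 298.51, sim_mw = 284.48),
    data.frame(compound_id = "palmitic_acid",      lipid_number = "C16:0",
               compound_class = "known_fa", mean_umol = 98.140, sd_umol = 22.426,
               mw_fa = 256.42, mw_me = 270.45, sim_mw = 256.42),
    data.frame(compound_id = "pentadecanoic_acid", lipid_number = "C15:0",
               compound_class = "known_fa", mean_umol = 7.065,  sd_umol = 2.468,
               mw_fa = 242.40, mw_me = 256.43, sim_mw = 242.40),
    data.frame(compound_id = "tetracosanoic_acid", lipid_number = "C24:0",
               compound_class = "known_fa", mean_umol = 6.769,  sd_umol = 3.546,
               mw_fa = 368.63, mw_me = 382.66, sim_mw = 368.63),
    data.frame(compound_id = "tricosanoic_acid",   lipid_number = "C23:0",
               compound_class = "known_fa", mean_umol = 1.147,  sd_umol = 0.323,
               mw_fa = 354.61, mw_me = 368.64, sim_mw = 354.61),
    data.frame(compound_id = "eicosenoic_acid_11", lipid_number = "C20:1w9",
               compound_class = "database_fa", mean_umol = 5.342, sd_umol = 1.737,
               mw_fa = 310.51, mw_me = 324.54, sim_mw = 310.51),
    data.frame(compound_id = c("U6-FA", "U7-FA", "U8-FA", "U10-FA", "UU2-FA",
                               "UU3-FA", "UU4-FA", "UU7-FA", "UU8-FA",
                               "UU9-FA", "UU11-FA"),
               lipid_number = "",
               compound_class = "unknown_fa",
               mean_umol = c(1.005, 5.973, 2.279, 3.288, 7.732, 5.669, 71.749,
                             0.690, 4.215, 29.843, 4.460),
               sd_umol   = c(0.580, 3.845, 0.722, 3.014, 2.805, 1.897, 17.820,
                             0.604, 2.155, 10.551, 1.846),
               mw_fa = NA_real_, mw_me = NA_real_,
               sim_mw = c(282, 296, 310, 324, 268, 338, 296, 352, 312, 284, 326)),
    data.frame(compound_id = c("UU1", "UU6"), lipid_number = "",
               compound_class = "other",
               mean_umol = c(1.728, 9.617), sd_umol = c(1.766, 4.268),
               mw_fa = NA_real_, mw_me = NA_real_, sim_mw = c(255, 305)),
    data.frame(compound_id = "cholesterol", lipid_number = "",
               compound_class = "sterol", mean_umol = 4.706, sd_umol = 2.477,
               mw_fa = 386.65, mw_me = 386.65, sim_mw = 386.65),
    data.frame(compound_id = "brassicasterol", lipid_number = "",
               compound_class = "sterol", mean_umol = 7.581, sd_umol = 4.806,
               mw_fa = 398.66, mw_me = 398.66, sim_mw = 398.66),
    data.frame(compound_id = "UU13-sterol", lipid_number = "",
               compound_class = "unknown_sterol", mean_umol = 6.264,
               sd_umol = 3.375, mw_fa = NA_real_, mw_me = NA_real_, sim_mw = 392)
  )
  rownames(tab) <- NULL
  tab
}

#' Reference amino-acid composition tables
#'
#' Published mean amino-acid abundances (mmol/gDW) and standard deviations for
#' the complete sponge biomass and for the isolated skeleton (spongin +
#' spicules), over the 18 quantifiable species. Methionine and cysteine are
#' destroyed or not measurable under acid hydrolysis and are absent by design;
#' tryptophan is partially destroyed, so its total-biomass value is a lower
#' bound.
#'
#' Asparagine/aspartate and glutamine/glutamate are oxidized to a common pool
#' during hydrolysis; the published per-species values assume a 50:50 amide
#' split (see [split_amide_pairs()]).
#'
#' @return A data frame with columns `amino_acid` (3-letter code), `mw` (free
#'   amino-acid molecular weight, g/mol), `total_mean`, `total_sd`,
#'   `skeleton_mean`, `skeleton_sd` (mmol/gDW).
#' @export
#' @examples
#' ref_amino_acids()
ref_amino_acids <- function() {
  data.frame(
    amino_acid = c("ALA", "ARG", "ASP", "ASN", "GLN", "GLU", "GLY", "HIS",
                   "ILE", "LEU", "LYS", "PHE", "PRO", "SER", "THR", "TRP",
                   "TYR", "VAL"),
    mw = c(89.09, 174.20, 133.10, 132.12, 146.15, 147.13, 75.07, 155.15,
           131.17, 131.17, 146.19, 165.19, 115.13, 105.09, 119.12, 204.23,
           181.19, 117.15),
    total_mean = c(1.538, 0.694, 0.841, 0.841, 0.767, 0.767, 4.582, 0.110,
                   0.402, 0.597, 0.688, 0.369, 1.050, 0.806, 0.826, 0.089,
                   0.157, 0.753),
    total_sd = c(0.565, 0.258, 0.312, 0.312, 0.287, 0.287, 1.702, 0.042,
                 0.149, 0.222, 0.268, 0.137, 0.387, 0.318, 0.304, 0.053,
                 0.060, 0.281),
    skeleton_mean = c(1.257, 0.545, 0.594, 0.594, 0.573, 0.573, 4.248, 0.034,
                      0.176, 0.290, 0.442, 0.239, 0.916, 0.534, 0.559, 0.100,
                      0.066, 0.440),
    skeleton_sd = c(0.537, 0.226, 0.250, 0.250, 0.243, 0.243, 1.807, 0.016,
                    0.080, 0.121, 0.173, 0.102, 0.351, 0.211, 0.226, 0.041,
                    0.028, 0.177),
    stringsAsFactors = FALSE
  )
}

#' Nucleotide residue molecular-weight tables
#'
#' Per-residue molecular weights used to convert nucleic-acid mass into molar
#' nucleotide abundances.
#'
#' @details The `"printed"` set reproduces the published composition tables
#' verbatim, including the shared AMP/CMP/GMP weights between the DNA and RNA
#' tables. The `"residue"` set holds standard polymerized (nucleoside
#' monophosphate minus water) residue weights, offered as the chemically
#' conventional alternative.
#'
#' @param molecule `"DNA"` or `"RNA"`.
#' @param set `"printed"` (default) or `"residue"`.
#' @return A named numeric vector of g/mol over the four residues (names
#'   `A`, `C`, `G`, and `T` for DNA or `U` for RNA).
#' @export
#' @examples
#' ref_nucleotide_mw("DNA")
#' ref_nucleotide_mw("RNA", set = "residue")
ref_nucleotide_mw <- function(molecule = c("DNA", "RNA"),
                              set = c("printed", "residue")) {
  molecule <- match.arg(molecule)
  set <- match.arg(set)
  if (set == "printed") {
    if (molecule == "DNA") c(A = 313, C = 289, G = 329, T = 304)
    else                   c(A = 313, C = 289, G = 329, U = 308)
  } else {
    if (molecule == "DNA") c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
    else                   c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
  }
}

#' Reference scalar constants
#'
#' Genome and transcriptome GC fractions, the displacement-volume conversion
#' factor, and the seawater constants used in dry-weight bookkeeping.
#'
#' @return A named list: `genome_gc` (0.3114), `transcriptome_gc` (0.3976),
#'   `conversion_factor_mean` (0.091 gDW/mL), `conversion_factor_sd` (0.012),
#'   `conversion_factor_n` (97), `seawater_specific_gravity` (1.025) and
#'   `salt_coefficient` (0.035 g salt per g seawater-derived water).
#' @export
#' @examples
#' ref_constants()$genome_gc
ref_constants <- function() {
  list(
    genome_gc = 0.3114,
    transcriptome_gc = 0.3976,
    conversion_factor_mean = 0.091,
    conversion_factor_sd = 0.012,
    conversion_factor_n = 97L,
    seawater_specific_gravity = 1.025,
    salt_coefficient = 0.035
  )
}
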