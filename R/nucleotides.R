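#' Nucleotide mole fractions from GC content
#'
#' Under base pairing with even guanine:cytosine and adenine:thymine (or
#' adenine:uracil, treating the transcriptome GC as strand-symmetric) ratios,
#' the four residue mole fractions follow directly from the GC fraction:
#' G = C = gc/2 and A = T/U = (1 - gc)/2.
#'
#' @param gc_fraction GC content as a fraction in (0, 1).
#' @param molecule `"DNA"` or `"RNA"` (controls the T/U label).
#' @return Named numeric vector of mole fractions over `A`, `C`, `G`, `T`/`U`,
#'   summing to 1.
#' @export
#' @examples
#' base_fractions(0.3114)          # dAMP fraction 0.3443
#' base_fractions(0.3976, "RNA")   # AMP fraction 0.3012
base_fractions <- function(gc_fraction, molecule = c("DNA", "RNA")) {
  molecule <- match.arg(molecule)
  stop_if_not_number(gc_fraction, "gc_fraction", min = 0, max = 1)
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("`gc_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  out <- c(A = at, C = gc, G = gc, at)
  names(out)[4L] <- if (molecule == "DNA") "T" else "U"
  out
}

#' Abundance-weighted mean residue molecular weight
#'
#' @param fractions Named mole fractions summing to 1 (see
#'   [base_fractions()]).
#' @param mw_table Named residue molecular weights, g/mol, matching the
#'   fraction names (see [ref_nucleotide_mw()]).
#' @return Mean residue molecular weight, g/mol.
#' @export
#' @examples
#' mean_residue_mw(base_fractions(0.3976, "RNA"), ref_nucleotide_mw("RNA"))
mean_residue_mw <- function(fractions, mw_table) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("mole fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(fractions) %in% names(mw_table))) {
    stop("mw_table is missing residue(s): ",
         paste(setdiff(names(fractions), names(mw_table)), collapse = ", "),
         call. = FALSE)
  }
  mw <- mw_table[names(fractions)]
  stop_if_not_number(mw, "mw_table", min = 0, strict_min = TRUE)
  sum(fractions * mw)
}

#' Per-residue molar abundances from a total nucleic-acid mass
#'
#' Divides the measured nucleic-acid mass by the mean residue weight to get
#' total residue moles per gDW, then distributes them over the mole
#' fractions. Mass closure `sum(abundance_i * mw_i) == total_mass` holds
#' exactly.
#'
#' @param total_mass Total DNA or RNA mass, g/gDW (>= 0).
#' @inheritParams mean_residue_mw
#' @return Named vector of residue abundances in umol/gDW.
#' @export
#' @examples
#' residue_abundances(0.0021, base_fractions(0.3976, "RNA"),
#'                    ref_nucleotide_mw("RNA"))
residue_abundances <- function(total_mass, fractions, mw_table) {
  stop_if_not_number(total_mass, "total_mass", min = 0)
  mw_mean <- mean_residue_mw(fractions, mw_table)
  total_umol <- total_mass / mw_mean * 1e6
  fractions * total_umol
}

#' Full nucleotide composition table for DNA or RNA
#'
#' Convenience wrapper combining [base_fractions()], [mean_residue_mw()] and
#' [residue_abundances()] into a published-style composition table.
#'
#' @param total_mass Nucleic-acid mass, g/gDW.
#' @param gc_fraction GC content fraction.
#' @param molecule `"DNA"` or `"RNA"`.
#' @param mw_table Residue weights; defaults to the printed reference table
#'   for `molecule` (see [ref_nucleotide_mw()]).
#' @return An object of class `nucleotide_composition`: data frame with
#'   columns `residue`, `mw`, `mole_fraction`, `umol_per_gdw`, plus
#'   attributes `mean_residue_mw`, `gc_fraction` and `molecule`.
#' @export
#' @examples
#' nucleotide_composition(0.0021, 0.3976, "RNA")
nucleotide_composition <- function(total_mass, gc_fraction,
                                   molecule = c("DNA", "RNA"),
                                   mw_table = NULL) {
  molecule <- match.arg(molecule)
  mw_table <- mw_table %||% ref_nucleotide_mw(molecule)
  fr <- base_fractions(gc_fraction, molecule)
  ab <- residue_abundances(total_mass, fr, mw_table)
  prefix <- if (molecule == "DNA") "d" else ""
  out <- data.frame(
    residue = paste0(prefix, names(fr), "MP"),
    mw = as.numeric(mw_table[names(fr)]),
    mole_fraction = as.numeric(fr),
    umol_per_gdw = as.numeric(ab),
    stringsAsFactors = FALSE
  )
  structure(out,
            mean_residue_mw = mean_residue_mw(fr, mw_table),
            gc_fraction = gc_fraction,
            molecule = molecule,
            class = c("nucleotide_composition", class(out)))
}
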