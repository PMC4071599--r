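#' Correct a lyophilized dry mass for residual sea salt
#'
#' Biopsies lyophilized from seawater-saturated tissue retain the salt that
#' was dissolved in the evaporated water. The retained salt mass is estimated
#' as the water lost during lyophilization times a salt coefficient, and
#' subtracted from the lyophilized mass.
#'
#' @details The salt coefficient is the mass of salt carried per gram of
#' seawater-derived water. The default 0.035 treats the lost water as
#' seawater of ~3.5 % salinity. An alternative reading — the specific gravity
#' excess of seawater, `1.025 - 1 = 0.025` — can be supplied instead; both
#' conventions are discussed in the methods vignette.
#'
#' @param lyophilized_mass Dry mass after lyophilization, grams. Vectorized.
#' @param water_loss Water lost during lyophilization (wet − lyophilized),
#'   grams.
#' @param salt_coefficient Grams of salt per gram of water lost, in `[0, 1)`.
#' @return Corrected dry mass in grams. Errors if any corrected mass is not
#'   strictly positive (salt estimate exceeding dry mass flags an implausible
#'   record).
#' @export
#' @examples
#' correct_for_salt(1.0, 0.0, 0.035)   # no water lost -> unchanged
#' correct_for_salt(0.20, 2.0, 0.035)  # 0.13 g
correct_for_salt <- function(lyophilized_mass, water_loss,
                             salt_coefficient = 0.035) {
  stop_if_not_number(lyophilized_mass, "lyophilized_mass", min = 0,
                     strict_min = TRUE)
  stop_if_not_number(water_loss, "water_loss", min = 0)
  stop_if_not_number(salt_coefficient, "salt_coefficient", min = 0, max = 1)
  if (salt_coefficient >= 1) {
    stop("`salt_coefficient` must be < 1", call. = FALSE)
  }
  corrected <- lyophilized_mass - water_loss * salt_coefficient
  if (any(corrected <= 0)) {
    stop("salt correction produced a non-positive dry mass; ",
         "estimated salt exceeds the lyophilized mass for ",
         sum(corrected <= 0), " record(s)", call. = FALSE)
  }
  corrected
}

#' Estimate the displacement-volume to dry-weight conversion factor
#'
#' Live sponge biomass is conveniently measured by seawater displacement; dry
#' weight is what composition is expressed against. This estimates grams of
#' dry weight per millilitre of displacement as the mean of per-sample
#' mass/volume ratios, with the standard deviation of those ratios.
#'
#' The per-ratio mean (rather than a regression through the origin) is used
#' so that the reported SD describes the spread of the factor itself.
#'
#' @param displacement_volume Displacement volumes, mL, all > 0.
#' @param corrected_dry_mass Salt-corrected dry masses, grams, all > 0.
#' @return An object of class `conversion_factor`: a list with elements
#'   `mean`, `sd` (both gDW/mL) and `n`.
#' @export
#' @examples
#' displacement_conversion(c(10, 20), c(0.91, 1.82))
displacement_conversion <- function(displacement_volume, corrected_dry_mass) {
  stop_if_not_number(displacement_volume, "displacement_volume", min = 0,
                     strict_min = TRUE)
  stop_if_not_number(corrected_dry_mass, "corrected_dry_mass", min = 0,
                     strict_min = TRUE)
  if (length(displacement_volume) != length(corrected_dry_mass)) {
    stop("volume and mass vectors must have equal length", call. = FALSE)
  }
  if (length(displacement_volume) < 2L) {
    stop("at least 2 records are required to estimate a conversion factor",
         call. = FALSE)
  }
  ratios <- corrected_dry_mass / displacement_volume
  structure(
    list(mean = mean(ratios), sd = stats::sd(ratios),
         n = length(ratios)),
    class = "conversion_factor"
  )
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("Displacement conversion factor: %.4f gDW/mL (sd %.4f, n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Convert a reagent mass to a dispensed volume
#'
#' Reagent additions recorded by mass on an analytical balance are converted
#' to volumes through the reagent's specific gravity, so that concentration
#' arithmetic can stay in volume units.
#'
#' @param mass Reagent mass, grams (>= 0).
#' @param specific_gravity Reagent specific gravity (g/mL), > 0.
#' @return Volume in millilitres.
#' @export
#' @examples
#' mass_to_volume(2.05, 1.025)  # 2 mL
mass_to_volume <- function(mass, specific_gravity) {
  stop_if_not_number(mass, "mass", min = 0)
  stop_if_not_number(specific_gravity, "specific_gravity", min = 0,
                     strict_min = TRUE)
  mass / specific_gravity
}

#' Skeleton mass fraction of a biopsy
#'
#' The skeleton (silica spicules plus the spongin collagen matrix) is the
#' SDS-resistant residue of a biopsy; its dry mass over the total dry mass
#' gives the skeleton fraction in g/gDW.
#'
#' @param skeleton_dry_mass Dry mass of the SDS-cleaned skeleton, grams, > 0.
#' @param total_dry_mass Total (salt-corrected) dry mass of the biopsy,
#'   grams, >= `skeleton_dry_mass`.
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' skeleton_fraction(0.6343, 1.0)
skeleton_fraction <- function(skeleton_dry_mass, total_dry_mass) {
  stop_if_not_number(skeleton_dry_mass, "skeleton_dry_mass", min = 0,
                     strict_min = TRUE)
  stop_if_not_number(total_dry_mass, "total_dry_mass", min = 0,
                     strict_min = TRUE)
  if (any(skeleton_dry_mass > total_dry_mass)) {
    stop("skeleton dry mass exceeds total dry mass", call. = FALSE)
  }
  skeleton_dry_mass / total_dry_mass
}

#' Augment a biopsy mass table with water loss and corrected dry mass
#'
#' Applies [correct_for_salt()] row-wise to a tidy biopsy record table.
#'
#' @param records Data frame with columns `sponge_id`, `biopsy_id`,
#'   `wet_mass_g`, `lyophilized_mass_g` and optionally `displacement_mL`.
#' @param salt_coefficient Passed to [correct_for_salt()].
#' @return The input with `water_loss_g` and `corrected_dry_mass_g` appended.
#' @export
account_biopsies <- function(records, salt_coefficient = 0.035) {
  required <- c("sponge_id", "biopsy_id", "wet_mass_g", "lyophilized_mass_g")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("records table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(records$wet_mass_g < records$lyophilized_mass_g)) {
    stop("wet mass below lyophilized mass; check record units", call. = FALSE)
  }
  records$water_loss_g <- records$wet_mass_g - records$lyophilized_mass_g
  records$corrected_dry_mass_g <- correct_for_salt(
    records$lyophilized_mass_g, records$water_loss_g, salt_coefficient
  )
  records
}
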