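# Amino-acid hydrolysate profiles.
#
# A profile is a data frame of class "aa_profile" with columns amino_acid
# (3-letter code), mmol_per_gdw, sd (NA when unknown) and flag (""
# or a qualifier such as "lower_bound" for tryptophan or "negative" for
# subtraction artefacts). Exactly the 18 species measurable after acid
# hydrolysis are carried: MET and CYS are absent by design, not zero.

aa_species <- function() ref_amino_acids()$amino_acid

new_aa_profile <- function(amino_acid, mmol_per_gdw, sd = NA_real_,
                           flag = "") {
  out <- data.frame(amino_acid = amino_acid,
                    mmol_per_gdw = mmol_per_gdw,
                    sd = sd, flag = flag, stringsAsFactors = FALSE)
  validate_aa_profile(out)
}

validate_aa_profile <- function(profile) {
  species <- aa_species()
  if (!setequal(profile$amino_acid, species) ||
      nrow(profile) != length(species)) {
    stop("profile must contain exactly the 18 hydrolysate species (",
         paste(species, collapse = ", "), ")", call. = FALSE)
  }
  profile <- profile[match(species, profile$amino_acid), , drop = FALSE]
  rownames(profile) <- NULL
  if (any(profile$mmol_per_gdw < 0 & profile$flag != "negative")) {
    stop("negative abundances must carry the 'negative' flag", call. = FALSE)
  }
  class(profile) <- unique(c("aa_profile", class(profile)))
  profile
}

#' Split combined amide pools into their acid and amide species
#'
#' Acid hydrolysis converts asparagine to aspartate and glutamine to
#' glutamate, so HPLC reports combined ASX and GLX pools. These are resolved
#' by an assumed 50:50 amide:acid abundance ratio.
#'
#' @param asx_total Combined ASP+ASN pool, mmol/gDW (>= 0).
#' @param glx_total Combined GLU+GLN pool, mmol/gDW (>= 0).
#' @return Named numeric vector `c(asp, asn, gln, glu)`; ASP = ASN =
#'   `asx_total/2` and GLN = GLU = `glx_total/2`.
#' @export
#' @examples
#' split_amide_pairs(1.682, 1.534)
split_amide_pairs <- function(asx_total, glx_total) {
  stop_if_not_number(asx_total, "asx_total", min = 0)
  stop_if_not_number(glx_total, "glx_total", min = 0)
  c(asp = asx_total / 2, asn = asx_total / 2,
    gln = glx_total / 2, glu = glx_total / 2)
}

#' Build an amino-acid profile from tidy hydrolysate measurements
#'
#' Accepts either an already-averaged table (one row per species) or
#' per-sample measurements (a `sample_id` column present), which are averaged
#' with an n-1 standard deviation. Combined `ASX`/`GLX` rows are split via
#' [split_amide_pairs()] before validation. Tryptophan is flagged as a lower
#' bound (partially destroyed during hydrolysis).
#'
#' @param data Data frame with columns `amino_acid`, `mmol_per_gdw` and
#'   optionally `sample_id`.
#' @return An `aa_profile` data frame (see [split_amide_pairs()] for the
#'   amide convention).
#' @export
make_aa_profile <- function(data) {
  required <- c("amino_acid", "mmol_per_gdw")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("amino-acid table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stop_if_not_number(data$mmol_per_gdw, "mmol_per_gdw", min = 0)
  if ("sample_id" %in% names(data)) {
    agg_mean <- tapply(data$mmol_per_gdw, data$amino_acid, mean)
    agg_sd <- tapply(data$mmol_per_gdw, data$amino_acid,
                     function(x) if (length(x) > 1L) stats::sd(x) else NA_real_)
    data <- data.frame(amino_acid = names(agg_mean),
                       mmol_per_gdw = as.numeric(agg_mean),
                       sd = as.numeric(agg_sd[names(agg_mean)]),
                       stringsAsFactors = FALSE)
  } else if (!"sd" %in% names(data)) {
    data$sd <- NA_real_
  }
  # resolve combined amide pools
  for (pool in c("ASX", "GLX")) {
    i <- which(data$amino_acid == pool)
    if (length(i) == 1L) {
      halves <- if (pool == "ASX") c("ASP", "ASN") else c("GLN", "GLU")
      split_val <- data$mmol_per_gdw[i] / 2
      split_sd <- data$sd[i] / 2
      data <- rbind(data[-i, , drop = FALSE],
                    data.frame(amino_acid = halves,
                               mmol_per_gdw = split_val, sd = split_sd,
                               stringsAsFactors = FALSE))
    }
  }
  data$flag <- ifelse(data$amino_acid == "TRP", "lower_bound", "")
  validate_aa_profile(data)
}

#' Mole fractions of an amino-acid profile
#'
#' @param profile An `aa_profile`.
#' @return The profile with a `mole_fraction` column
#'   (`abundance / sum(abundances)`); fractions sum to 1.
#' @export
#' @examples
#' prof <- make_aa_profile(data.frame(
#'   amino_acid = ref_amino_acids()$amino_acid,
#'   mmol_per_gdw = ref_amino_acids()$total_mean))
#' mole_fractions(prof)
mole_fractions <- function(profile) {
  profile <- validate_aa_profile(profile)
  total <- sum(profile$mmol_per_gdw)
  if (total <= 0) {
    stop("all-zero profile: mole fractions undefined", call. = FALSE)
  }
  profile$mole_fraction <- profile$mmol_per_gdw / total
  profile
}

#' Cellular amino-acid profile by skeleton subtraction
#'
#' The cellular (soluble) fraction is estimated by subtracting the skeleton
#' profile from the complete-biomass profile species-wise. Because the two
#' profiles are averages from different sample sets, individual differences
#' can be negative; these are reported as-is with a `"negative"` flag rather
#' than silently clamped.
#'
#' @param total Complete-biomass `aa_profile` (mmol per gDW of sponge).
#' @param skeleton Skeleton `aa_profile` on the same per-gDW basis.
#' @return An `aa_profile` of differences.
#' @export
cellular_profile <- function(total, skeleton) {
  total <- validate_aa_profile(total)
  skeleton <- validate_aa_profile(skeleton)
  diff <- total$mmol_per_gdw - skeleton$mmol_per_gdw
  flag <- ifelse(diff < 0, "negative", total$flag)
  sd <- sqrt(ifelse(is.na(total$sd), 0, total$sd)^2 +
               ifelse(is.na(skeleton$sd), 0, skeleton$sd)^2)
  sd[is.na(total$sd) & is.na(skeleton$sd)] <- NA_real_
  new_aa_profile(total$amino_acid, diff, sd = sd, flag = flag)
}

#' Percentage composition of an amino-acid profile
#'
#' Converts abundances to percentages for cross-profile comparison.
#' Flagged-negative species (possible after skeleton subtraction) are
#' excluded from the denominator and rendered as 0 % with a warning.
#'
#' @param profile An `aa_profile`.
#' @return Data frame with columns `amino_acid` and `percent`; percentages
#'   sum to 100.
#' @export
#' @examples
#' prof <- make_aa_profile(data.frame(
#'   amino_acid = ref_amino_acids()$amino_acid,
#'   mmol_per_gdw = ref_amino_acids()$skeleton_mean))
#' normalize_percent(prof)  # glycine 34.9 %
normalize_percent <- function(profile) {
  profile <- validate_aa_profile(profile)
  x <- profile$mmol_per_gdw
  neg <- x < 0
  if (any(neg)) {
    warning("negative abundance for ",
            paste(profile$amino_acid[neg], collapse = ", "),
            "; reported as 0 % and excluded from the denominator",
            call. = FALSE)
    x[neg] <- 0
  }
  total <- sum(x)
  if (total <= 0) stop("profile has no positive abundances", call. = FALSE)
  data.frame(amino_acid = profile$amino_acid,
             percent = 100 * x / total,
             stringsAsFactors = FALSE)
}
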