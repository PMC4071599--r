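#' Fit a linear standard curve
#'
#' Ordinary least-squares fit of assay signal on known standard
#' concentration, `signal = slope * concentration + intercept`. Used by the
#' Bradford protein, phenol-sulfuric carbohydrate and Hoechst DNA assays.
#'
#' @param concentration Known standard concentrations, ug/mL. At least 3
#'   points with at least 2 distinct concentrations.
#' @param signal Measured signals, arbitrary units, same length.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `signal_range` and `n`.
#' @export
#' @examples
#' fit_standard_curve(c(0, 10, 20), c(0.02, 0.21, 0.40))
fit_standard_curve <- function(concentration, signal) {
  stop_if_not_number(concentration, "concentration", min = 0)
  stop_if_not_number(signal, "signal")
  if (length(concentration) != length(signal)) {
    stop("concentration and signal must have equal length", call. = FALSE)
  }
  if (length(concentration) < 3L) {
    stop("at least 3 standard points are required", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("standards must span at least 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(signal ~ concentration)
  if (stats::coef(fit)[2L] == 0) {
    stop("flat standard curve (zero slope)", call. = FALSE)
  }
  sst <- sum((signal - mean(signal))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         signal_range = range(signal),
         n = length(signal)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: signal = %.6g * conc + %.6g  (r^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Back-calculate a macro-component content from triplicate assay signals
#'
#' Averages the triplicate signals, inverts the standard curve, applies the
#' dilution factor, and scales by the extract volume over the biopsy dry mass
#' to express the component in g/gDW.
#'
#' @details Signals whose back-calculated concentration is negative (below
#' the curve intercept) are clamped to zero with a warning, so population
#' summaries remain computable. A warning is also issued when the mean signal
#' falls outside the fitted curve's signal range (extrapolation).
#'
#' @param signals Numeric vector of exactly 3 replicate signals.
#' @param curve A [fit_standard_curve()] object.
#' @param dilution_factor Fold dilution of the extract before reading
#'   (>= 1).
#' @param extract_volume_ml Volume of the digestion/extraction reaction, mL.
#' @param dry_mass_g Salt-corrected dry mass of the assayed biopsy, grams.
#' @return The component content in g/gDW (concentrations in ug/mL implied),
#'   with attribute `clamped` = TRUE if the value was clamped at zero.
#' @export
#' @examples
#' curve <- fit_standard_curve(c(0, 10, 20), c(0, 10, 20))
#' quantify_component(c(10, 10, 10), curve, 1, 1, 1)  # 1e-5 g/gDW
quantify_component <- function(signals, curve, dilution_factor,
                               extract_volume_ml, dry_mass_g) {
  stop_if_not_number(signals, "signals")
  if (length(signals) != 3L) {
    stop("exactly 3 replicate signals are required", call. = FALSE)
  }
  if (!inherits(curve, "standard_curve")) {
    stop("`curve` must be a standard_curve object", call. = FALSE)
  }
  stop_if_not_number(dilution_factor, "dilution_factor", min = 1)
  stop_if_not_number(extract_volume_ml, "extract_volume_ml", min = 0,
                     strict_min = TRUE)
  stop_if_not_number(dry_mass_g, "dry_mass_g", min = 0, strict_min = TRUE)

  mean_signal <- mean(signals)
  if (mean_signal < curve$signal_range[1L] ||
      mean_signal > curve$signal_range[2L]) {
    warning("mean signal outside the standard-curve range; extrapolating",
            call. = FALSE)
  }
  conc <- (mean_signal - curve$intercept) / curve$slope * dilution_factor
  clamped <- FALSE
  if (conc < 0) {
    warning("back-calculated concentration negative; clamped to 0",
            call. = FALSE)
    conc <- 0
    clamped <- TRUE
  }
  value <- conc * extract_volume_ml / dry_mass_g * 1e-6  # ug/g -> g/gDW
  structure(value, clamped = clamped)
}

#' RNA content from A260 absorbance
#'
#' Converts a UV absorbance reading at 260 nm of an alkaline-hydrolysis RNA
#' extract into g RNA per gDW, via the standard absorbance-to-concentration
#' factor.
#'
#' @param a260 Absorbance at 260 nm (>= 0). If a vector (triplicate) is
#'   given, it is averaged.
#' @param conversion ug/mL of RNA per absorbance unit; default 40.
#' @param dilution_factor Fold dilution between the extract and the cuvette.
#'   Volume changes from reagent additions (e.g. acidification) are encoded
#'   here by the caller.
#' @param extract_volume_ml Extraction volume, mL.
#' @param dry_mass_g Biopsy dry mass, grams.
#' @return RNA content in g/gDW.
#' @export
#' @examples
#' rna_from_a260(0.5, 40, 1, 4, 0.1)  # 8e-4 g/gDW
rna_from_a260 <- function(a260, conversion = 40, dilution_factor = 1,
                          extract_volume_ml = 4, dry_mass_g = 1) {
  stop_if_not_number(a260, "a260", min = 0)
  stop_if_not_number(conversion, "conversion", min = 0, strict_min = TRUE)
  stop_if_not_number(dilution_factor, "dilution_factor", min = 1)
  stop_if_not_number(extract_volume_ml, "extract_volume_ml", min = 0,
                     strict_min = TRUE)
  stop_if_not_number(dry_mass_g, "dry_mass_g", min = 0, strict_min = TRUE)
  mean(a260) * conversion * dilution_factor * extract_volume_ml /
    dry_mass_g * 1e-6
}

#' Summarize a macro-component across biopsies
#'
#' Sample mean, standard deviation (n-1 denominator), standard error and
#' coefficient of variation of a set of per-biopsy component values.
#'
#' @param values Component values, g/gDW, all >= 0, length >= 1.
#' @param component Optional component label carried into the result.
#' @return An object of class `component_summary`: one-row data frame with
#'   columns `component`, `mean`, `sd`, `se`, `cv_percent`, `n`. When the
#'   mean is zero with positive spread the CV is undefined and reported as
#'   `NA` with a warning.
#' @export
#' @examples
#' summarize_component(c(1, 2, 3))
summarize_component <- function(values, component = NA_character_) {
  stop_if_not_number(values, "values", min = 0)
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1L) stats::sd(values) else 0
  se <- s / sqrt(n)
  cv <- if (m > 0) 100 * s / m else if (s == 0) 0 else NA_real_
  if (is.na(cv)) {
    warning("mean is zero with positive sd; CV undefined", call. = FALSE)
  }
  out <- data.frame(component = component, mean = m, sd = s, se = se,
                    cv_percent = cv, n = n, stringsAsFactors = FALSE)
  class(out) <- c("component_summary", class(out))
  out
}

#' Quantify a table of assay readings against fitted standard curves
#'
#' Row-wise driver for [quantify_component()] and [rna_from_a260()] over a
#' tidy readings table, producing per-biopsy component measurements.
#'
#' @param readings Data frame with columns `component`, `sponge_id`,
#'   `biopsy_id`, `s1`, `s2`, `s3`, `dilution`, `volume_mL`, `dry_mass_g`.
#'   RNA rows carry the A260 reading in the signal columns.
#' @param curves Named list of `standard_curve` objects keyed by component;
#'   RNA needs no curve.
#' @param a260_conversion ug/mL per absorbance unit for RNA rows.
#' @return Data frame with columns `component`, `sponge_id`, `biopsy_id`,
#'   `g_per_gDW`.
#' @export
quantify_assay_table <- function(readings, curves, a260_conversion = 40) {
  required <- c("component", "sponge_id", "biopsy_id", "s1", "s2", "s3",
                "dilution", "volume_mL", "dry_mass_g")
  missing <- setdiff(required, names(readings))
  if (length(missing)) {
    stop("readings table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- vapply(seq_len(nrow(readings)), function(i) {
    row <- readings[i, ]
    sig <- c(row$s1, row$s2, row$s3)
    if (identical(row$component, "rna")) {
      rna_from_a260(sig, conversion = a260_conversion,
                    dilution_factor = row$dilution,
                    extract_volume_ml = row$volume_mL,
                    dry_mass_g = row$dry_mass_g)
    } else {
      curve <- curves[[row$component]]
      if (is.null(curve)) {
        stop("no standard curve supplied for component '", row$component,
             "'", call. = FALSE)
      }
      as.numeric(quantify_component(sig, curve,
                                    dilution_factor = row$dilution,
                                    extract_volume_ml = row$volume_mL,
                                    dry_mass_g = row$dry_mass_g))
    }
  }, numeric(1))
  data.frame(component = readings$component,
             sponge_id = readings$sponge_id,
             biopsy_id = readings$biopsy_id,
             g_per_gDW = values,
             stringsAsFactors = FALSE)
}
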