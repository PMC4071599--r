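# FAME (fatty acid methyl ester) peak-table quantification.
#
# Peak tables arrive pre-annotated (compound_id, compound_class, area, mw);
# retention-time matching and spectral deconvolution are upstream of this
# module. A peak table is a data frame with columns sample_id, compound_id,
# compound_class, area and mw (NA for unknowns). Internal-standard rows carry
# compound_class "istd"; they are kept for QC but excluded from every
# composition computation.

fame_known_classes <- c("known_fa", "database_fa", "sterol")
fame_all_classes <- c(fame_known_classes,
                      c("unknown_fa", "unknown_sterol", "other", "istd"))

check_peak_table <- function(peaks) {
  required <- c("sample_id", "compound_id", "compound_class", "area")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) {
    stop("peak table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(peaks) == 0L) stop("peak table has no rows", call. = FALSE)
  bad <- setdiff(unique(peaks$compound_class), fame_all_classes)
  if (length(bad)) {
    stop("unknown compound_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stop_if_not_number(peaks$area, "area", min = 0)
  invisible(peaks)
}

#' Apply the relative intensity cut-off to FAME peak tables
#'
#' Discards, within each sample, peaks whose area falls below a fraction
#' (default 0.05 %) of that sample's largest peak. The internal standard is
#' never the reference maximum and is never itself discarded (it is retained
#' for recovery QC).
#'
#' @param peaks Peak table (one or more samples; see module description).
#' @param rel_cutoff Relative cut-off in (0, 1); default `5e-4` (0.05 % of
#'   the largest peak).
#' @return The filtered peak table. Idempotent.
#' @export
#' @examples
#' pk <- data.frame(sample_id = "s1",
#'                  compound_id = c("a", "b", "c"),
#'                  compound_class = "known_fa",
#'                  area = c(10000, 6, 4), mw = 256)
#' apply_intensity_cutoff(pk)  # drops the area-4 peak (threshold 5)
apply_intensity_cutoff <- function(peaks, rel_cutoff = 5e-4) {
  check_peak_table(peaks)
  stop_if_not_number(rel_cutoff, "rel_cutoff", min = 0, strict_min = TRUE)
  if (rel_cutoff >= 1) stop("`rel_cutoff` must be < 1", call. = FALSE)
  keep <- unlist(lapply(split(seq_len(nrow(peaks)), peaks$sample_id),
    function(idx) {
      sub <- peaks[idx, ]
      comp <- sub$compound_class != "istd"
      if (!any(comp)) return(idx)
      threshold <- rel_cutoff * max(sub$area[comp])
      idx[!comp | sub$area >= threshold]
    }), use.names = FALSE)
  out <- peaks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-sample consistency filter for unidentified compounds
#'
#' Unidentified compounds (classes `unknown_fa`, `unknown_sterol`, `other`)
#' are only credited to the biomass when they are detected, after the
#' intensity cut-off, in strictly more than `presence_threshold` of the
#' samples. Identified compounds (standard- or database-matched) pass
#' unconditionally.
#'
#' @param peaks Peak table covering at least 2 samples.
#' @param presence_threshold Required presence fraction; default 0.75
#'   (present in > 75 % of samples).
#' @param rel_cutoff Intensity cut-off applied per sample before counting
#'   presence; see [apply_intensity_cutoff()].
#' @return Character vector of retained `compound_id`s.
#' @export
consistency_filter <- function(peaks, presence_threshold = 0.75,
                               rel_cutoff = 5e-4) {
  check_peak_table(peaks)
  samples <- unique(peaks$sample_id)
  if (length(samples) < 2L) {
    stop("at least 2 samples are required for the consistency filter",
         call. = FALSE)
  }
  stop_if_not_number(presence_threshold, "presence_threshold",
                     min = 0, max = 1)
  filtered <- apply_intensity_cutoff(peaks, rel_cutoff)
  filtered <- filtered[filtered$compound_class != "istd", , drop = FALSE]
  known <- unique(filtered$compound_id[
    filtered$compound_class %in% fame_known_classes])
  unknown <- filtered[!(filtered$compound_class %in% fame_known_classes), ,
                      drop = FALSE]
  presence <- tapply(unknown$sample_id, unknown$compound_id,
                     function(s) length(unique(s)))
  retained_unknown <- names(presence)[
    presence / length(samples) > presence_threshold]
  sort(unique(c(known, retained_unknown)))
}

#' Backbone mass fraction of the lipid extract
#'
#' The gravimetric lipid mass includes glycerol and phosphate backbones that
#' generate no FAME signal. Assuming a fixed glycerolipid:phospholipid ratio
#' (default 20:80) and two acyl chains per lipid, this returns the mass
#' fraction of the extract attributed to backbones, which is subtracted
#' before distributing lipid mass over FA/sterol peaks.
#'
#' @details The backbone residue masses are declared conventions: the
#' glycerolipid backbone defaults to a fully esterified glycerol residue
#' (glycerol − 3 H2O ≈ 38.05 g/mol) and the phospholipid backbone to that
#' residue plus a metaphosphate group (+ 79.98 ≈ 118.03 g/mol), head groups
#' not counted. The mean chain mass is the mean identified fatty-acid
#' molecular weight.
#'
#' @param glycerolipid_share,phospholipid_share Mole shares of the two lipid
#'   families; must sum to 1.
#' @param mean_fa_mw Mean fatty-acid molecular weight, g/mol.
#' @param chains_per_lipid Acyl chains per lipid molecule; default 2.
#' @param glycerol_backbone_mw,phospho_backbone_mw Backbone residue masses,
#'   g/mol.
#' @return Backbone mass fraction in `[0, 1)`.
#' @export
#' @examples
#' backbone_fraction(1, 0, mean_fa_mw = 256,
#'                   glycerol_backbone_mw = 38)  # 38 / (38 + 512)
backbone_fraction <- function(glycerolipid_share = 0.20,
                              phospholipid_share = 0.80,
                              mean_fa_mw,
                              chains_per_lipid = 2,
                              glycerol_backbone_mw = 38.05,
                              phospho_backbone_mw = 118.03) {
  stop_if_not_number(glycerolipid_share, "glycerolipid_share", 0, 1)
  stop_if_not_number(phospholipid_share, "phospholipid_share", 0, 1)
  if (abs(glycerolipid_share + phospholipid_share - 1) > 1e-9) {
    stop("glycerolipid and phospholipid shares must sum to 1", call. = FALSE)
  }
  stop_if_not_number(mean_fa_mw, "mean_fa_mw", min = 0, strict_min = TRUE)
  stop_if_not_number(chains_per_lipid, "chains_per_lipid", min = 1)
  stop_if_not_number(glycerol_backbone_mw, "glycerol_backbone_mw", min = 0)
  stop_if_not_number(phospho_backbone_mw, "phospho_backbone_mw", min = 0)
  backbone <- glycerolipid_share * glycerol_backbone_mw +
    phospholipid_share * phospho_backbone_mw
  backbone / (backbone + chains_per_lipid * mean_fa_mw)
}

# Molecular-weight map for quantification: named vector compound_id -> g/mol
# from a catalogue data frame, on the requested basis. Unknowns get NA here;
# quantify_lipids() imputes them.
fame_mw_map <- function(catalogue, mw_basis = c("fatty_acid", "methyl_ester")) {
  mw_basis <- match.arg(mw_basis)
  col <- if (mw_basis == "fatty_acid") "mw_fa" else "mw_me"
  stats::setNames(catalogue[[col]], catalogue$compound_id)
}

#' Quantify fatty acids and sterols from filtered FAME peak tables
#'
#' Within each sample, the areas of the retained compounds are renormalized
#' to their own total (assuming comparable MS response across FA and sterol
#' ions), multiplied by the backbone-corrected lipid mass, and divided by the
#' compound molecular weight to give micromoles per gram dry weight.
#' Compounds with unknown molecular weight receive the mean weight of all
#' identified fatty acids and sterols in `mw_map`.
#'
#' @details Per sample, `abundance_i = share_i * lipid_g_per_gdw * (1 - f_b)
#' / mw_i * 1e6` with `share_i` the area fraction among retained peaks. This
#' renormalization makes the per-sample mass closure
#' `sum(abundance_i * mw_i) = lipid_g_per_gdw * (1 - f_b)` exact. A compound
#' absent from a sample after filtering contributes zero in that sample.
#'
#' @param peaks Peak table (all samples, pre-filter; the intensity cut-off is
#'   applied internally).
#' @param lipid_mass Data frame with columns `sample_id` and
#'   `lipid_g_per_gdw` (gravimetric lipid mass per sample). Samples without
#'   a lipid mass are skipped with a warning.
#' @param f_b Backbone mass fraction from [backbone_fraction()].
#' @param mw_map Named vector compound_id -> g/mol (NA for unknowns), e.g.
#'   from the reference catalogue.
#' @param retained Character vector of compound ids to quantify, from
#'   [consistency_filter()].
#' @param rel_cutoff Intensity cut-off; see [apply_intensity_cutoff()].
#' @return An object of class `lipid_profile`: data frame with columns
#'   `compound_id`, `compound_class`, `mean_umol_per_gdw`, `sd_umol_per_gdw`,
#'   `n_samples`, plus attributes `per_sample` (compound x sample matrix of
#'   umol/gDW) and `imputed_mw` (the mean identified molecular weight).
#' @export
quantify_lipids <- function(peaks, lipid_mass, f_b, mw_map, retained,
                            rel_cutoff = 5e-4) {
  check_peak_table(peaks)
  if (length(retained) == 0L) {
    stop("empty retained compound set", call. = FALSE)
  }
  stop_if_not_number(f_b, "f_b", min = 0, max = 1)
  if (!all(c("sample_id", "lipid_g_per_gdw") %in% names(lipid_mass))) {
    stop("lipid_mass needs columns sample_id and lipid_g_per_gdw",
         call. = FALSE)
  }
  filtered <- apply_intensity_cutoff(peaks, rel_cutoff)
  filtered <- filtered[filtered$compound_class != "istd" &
                         filtered$compound_id %in% retained, , drop = FALSE]

  avg_mw <- mean(mw_map, na.rm = TRUE)
  mw_of <- function(id) {
    mw <- unname(mw_map[id])
    ifelse(is.na(mw) | is.null(mw), avg_mw, mw)
  }

  samples <- unique(peaks$sample_id)
  have_mass <- samples %in% lipid_mass$sample_id
  if (!all(have_mass)) {
    warning("no lipid mass for sample(s) ",
            paste(samples[!have_mass], collapse = ", "), "; skipped",
            call. = FALSE)
    samples <- samples[have_mass]
  }
  if (length(samples) == 0L) stop("no quantifiable samples", call. = FALSE)

  ids <- sort(intersect(retained, unique(filtered$compound_id)))
  if (length(ids) == 0L) {
    stop("no retained compounds survive the intensity cut-off", call. = FALSE)
  }
  per_sample <- matrix(0, nrow = length(ids), ncol = length(samples),
                       dimnames = list(ids, samples))
  for (s in samples) {
    sub <- filtered[filtered$sample_id == s, , drop = FALSE]
    if (nrow(sub) == 0L) next
    total_area <- sum(sub$area)
    if (total_area <= 0) next
    lip <- lipid_mass$lipid_g_per_gdw[match(s, lipid_mass$sample_id)]
    share <- sub$area / total_area
    per_sample[sub$compound_id, s] <-
      share * lip * (1 - f_b) / mw_of(sub$compound_id) * 1e6
  }

  class_of <- peaks$compound_class[match(ids, peaks$compound_id)]
  out <- data.frame(
    compound_id = ids,
    compound_class = class_of,
    mean_umol_per_gdw = rowMeans(per_sample),
    sd_umol_per_gdw = apply(per_sample, 1L, stats::sd),
    n_samples = length(samples),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, per_sample = per_sample, imputed_mw = avg_mw, f_b = f_b,
            class = c("lipid_profile", class(out)))
}

#' Chromatographic coverage of the quantified compounds
#'
#' Fraction of the total (pre-filter, internal standard excluded) peak area
#' accounted for by the retained compounds, averaged across samples. Under
#' the assumption that total signal represents the whole lipid fraction,
#' this is the share of the lipid fraction covered by the reported
#' compounds.
#'
#' @param peaks Full peak table (pre-filter).
#' @param retained Character vector of retained compound ids.
#' @return Coverage fraction in `[0, 1]`.
#' @export
fame_coverage <- function(peaks, retained) {
  check_peak_table(peaks)
  peaks <- peaks[peaks$compound_class != "istd", , drop = FALSE]
  per_sample <- vapply(split(peaks, peaks$sample_id), function(sub) {
    total <- sum(sub$area)
    if (total <= 0) return(NA_real_)
    sum(sub$area[sub$compound_id %in% retained]) / total
  }, numeric(1))
  mean(per_sample, na.rm = TRUE)
}
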