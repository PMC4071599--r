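---
title: "Methods: from compositional assays to a sponge biomass equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from compositional assays to a sponge biomass equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongebiomass)
```

This vignette documents the models, conventions and numerical choices
behind the package, the way a methods section would: what each stage
assumes, which parameters matter and why their defaults are what they are,
and what the synthetic-data generator does and does not emulate.

## The problem

A genome-scale metabolic model needs a biomass equation: a drain reaction
consuming amino acids, nucleotides, fatty acids and sugars in the molar
proportions found in one gram of dry biomass (gDW). For a sponge holobiont
the inputs are bulk biochemical assays of biopsies sampled from wild
individuals, so the pipeline must (i) convert raw assay readings to g/gDW,
(ii) resolve the macromolecules into building blocks, (iii) quantify how
composition varies between and within individuals, and (iv) assemble and
mass-check the equation.

## Dry-weight bookkeeping

Biopsies are lyophilized from seawater-saturated tissue, so the dry pellet
retains sea salt. The correction subtracts `water_loss × k` from the
lyophilized mass. The coefficient `k` is configurable because two readings
of the underlying protocol exist:

* `k = 0.035` (default): the water lost is treated as seawater of ~3.5 %
  salinity, so each gram of evaporated water leaves 0.035 g of salt;
* `k = SG_seawater − 1 ≈ 0.025`: the specific-gravity excess of seawater.

Neither convention is asserted as the original one; the choice is logged
with every run. A corrected mass that is not positive is an error, not a
clamp — it flags an implausible record.

The displacement-volume conversion factor (gDW per mL of displaced
seawater) is estimated as the mean of per-sample mass/volume ratios rather
than a regression through the origin, because the quantity of interest is
the factor itself together with the spread of that factor across samples
(reported as the SD of the ratios).

## Assay quantification

Protein (Bradford), carbohydrate (phenol–sulfuric) and DNA (Hoechst) use
ordinary least-squares standard curves `signal = slope·conc + intercept`;
RNA uses the A260 absorbance factor (40 µg/mL per absorbance unit by
default, configurable). Triplicates are averaged *before* back-calculation
— standard plate practice, and each biopsy contributes one population
value. Back-calculated concentrations below zero (signal under the curve
intercept) are clamped to zero with a warning rather than erroring, so
population summaries remain computable; extrapolation beyond the standard
range warns. Reaction geometry (digestion volume, dilution — e.g. the
3 mL KOH + 1 mL acid RNA step is a 4/3 volume factor folded into the
dilution) is supplied by the caller per reading.

Population summaries use the n−1 sample SD, `SE = sd/√n` and
`CV% = 100·sd/mean`. The published protein row (mean 0.0881, SD 0.0082,
n = 20 → CV 9.31 %, SE 0.0018) pins down these conventions and is used as
a fixed check in the tests.

## FAME lipidomics

Peak tables arrive pre-annotated (compound id, class, area); spectral
deconvolution and retention-time matching are upstream instrument-software
steps, out of scope. The procedure is:

1. **Intensity cut-off**: within each sample, drop peaks below 0.05 % of
   the largest peak. The internal standard (nondecanoic acid) is never the
   reference maximum and is retained for recovery QC only — the final
   quantification is area-normalized, not ISTD-normalized.
2. **Consistency filter**: unidentified compounds (no standard or database
   match) count toward the biomass only if present, post-cut-off, in
   strictly more than 75 % of samples. Identified compounds always pass.
3. **Backbone subtraction**: the gravimetric lipid mass includes glycerol
   and phosphate backbones that produce no FAME signal. Assuming a 20:80
   glycerolipid:phospholipid mole ratio and two acyl chains per lipid, the
   backbone mass fraction is `f_b = B/(B + 2·MW̄_FA)` with
   `B = 0.2·38.05 + 0.8·118.03` g/mol. The residue masses are declared
   conventions (glycerol − 3 H₂O; plus a metaphosphate group for the
   phospholipid backbone, head groups not counted): the 20:80 ratio is the
   stated assumption, the arithmetic behind it is this package's. With the
   default catalogue `f_b ≈ 0.138`.
4. **Quantification**: areas of retained compounds are renormalized to
   their own per-sample total (assuming comparable MS response across FA
   and sterol ions — a stated approximation, adopted, not tested against
   chemistry), multiplied by `lipid_mass × (1 − f_b)` and divided by the
   compound molecular weight. This renormalization makes
   `Σ mol_i·MW_i = (1 − f_b)·lipid_mass` exact per sample, which the test
   suite asserts to machine precision.

Molecular weights default to the **free fatty acid** basis
(`mw_basis = "fatty_acid"`), because the biomass equation consumes fatty
acids, not their methyl esters; the methyl-ester basis is one switch away.
Unknown compounds receive the mean weight of all identified fatty acids
and sterols. Coverage — the retained share of total (pre-filter,
ISTD-excluded) signal, averaged over samples — quantifies how much of the
lipid fraction the reported compounds represent (~82–83 % under the
default catalogue).

## Amino acids

Acid hydrolysis converts asparagine → aspartate and glutamine → glutamate,
so the chromatograph reports combined ASX/GLX pools; these are split 50:50
by assumption. Methionine and cysteine do not survive the chemistry and
are absent *by design* (the 18-species set is closed and validated, not
padded with zeros). Tryptophan is partially destroyed and carries a
`lower_bound` flag.

The cellular profile is the complete-biomass profile minus the skeleton
profile, species-wise. Because both are averages over different sample
sets, differences can be negative (tryptophan is, with the catalogue
means: 0.089 − 0.100); such values are kept and flagged rather than
silently clamped, and the percentage normalization excludes them from the
denominator, reporting 0 % with a warning. Mole fractions and percentages
are invariant to uniform rescaling, which the tests exercise.

## Nucleotides

With only GC content available, base-pairing symmetry forces
`G = C = gc/2` and `A = T(U) = (1 − gc)/2` (the transcriptome GC is
treated the same way — a simplification, since mRNA is single-stranded).
The mean residue weight `Σ fraction_i·MW_i` converts the measured
nucleic-acid mass into total residue moles, distributed over the
fractions; mass closure is exact by construction.

The default molecular-weight table reproduces the published composition
tables verbatim — including the fact that the RNA table shares the
AMP/CMP/GMP weights of the DNA table — with a standard
polymerized-ribonucleotide table (`set = "residue"`) available when
chemical convention matters more than reproduction. All nucleic acid is
attributed to the sponge host (no bacterial partitioning; community
sequence data are not available).

One reproduction limit is worth stating precisely: the published DNA
abundances (dAMP/dTMP 0.37, dCMP/dGMP 0.17 µmol/gDW) imply an unrounded
DNA mass of ≈ 3.33 × 10⁻⁴ g/gDW, whereas the printed mass is rounded to
3 × 10⁻⁴ (one significant figure, ±17 %). Feeding the rounded value
yields dAMP ≈ 0.335 µmol/gDW, ~10 % below the printed figure. The
acceptance suite keeps a 1 % check on those rows, which therefore fails —
deliberately — as documentation of that input-rounding inconsistency. The
RNA rows, whose mass input carries two significant figures, reproduce
within 1 %.

## Variance partitioning

Each component is modelled as `y_ij = µ + a_i + e_ij` with individual
effects `a_i ~ N(0, σ²_b)` and residuals `e_ij ~ N(0, σ²_w)`. The
likelihood is profiled over `λ = σ²_b/σ²_w`: given λ, the GLS mean and
σ²_w have closed forms, leaving a bounded 1-D search (coarse log-spaced
scan, then Brent refinement; `λ ∈ [0, 10⁶]`, the boundary λ = 0 always
considered; converged well below 10⁻⁸ relative tolerance). Both ML and
REML are implemented; REML is the default for variance shares (it does
not shrink σ²_b by the estimated-mean degree of freedom), ML feeds the
likelihood-ratio test, as is conventional when comparing models that
differ in a random effect.

The LRT reports the naive χ²₁ p-value. Because `σ²_b = 0` lies on the
parameter-space boundary, that reference is conservative; the 50:50
χ²₀:χ²₁ mixture p-value is reported alongside, and the naive convention
is kept as the headline number for comparability with common practice
(a boundary-null fit typically lands at λ = 0, χ² ≈ 0, p ≈ 1). A
simulation test confirms the naive test's rejection rate under the null
stays at or below the nominal 5 %.

Two estimation facts shape the tests. First, at 4 groups the *share*
`100·σ̂²_b/(σ̂²_b+σ̂²_w)` is a strongly concave function of the components,
so its per-replicate estimates are biased low (≈ 45 for a true 54 under
REML) even though the variance components themselves are estimated
without bias. Recovery is therefore assessed on the across-replicate mean
components, whose implied share does centre on the generating value.
Second, the fit is cross-checked two independent ways: a brute-force grid
oracle that evaluates the likelihood through explicit covariance-matrix
algebra (agreement to 4 decimals in the intraclass correlation), and
`lme4::lmer` (agreement in both variance components and log-likelihoods).

## Biomass equation

Conventions, each of which was a genuinely open choice:

* Cellular and skeleton amino acids stay **separate classes** (their
  compositions differ — spongin is glycine/alanine/proline-rich), with a
  `pool_aa` switch to merge them. Skeleton species are prefixed `skel_`
  so labels stay unique.
* Amino-acid mass accounting uses **residue masses** (free MW − 18.02),
  since polymerized protein is what the dry mass weighs.
* Carbohydrate becomes anhydro-glucose monomers (residue MW 162,
  configurable) because the assay standard is glucose and no sugar
  profile exists.
* Unknown FAME compounds enter under their placeholder labels with the
  imputed mean weight, flagged `unresolved`; compounds that are neither
  fatty acid nor sterol are carried in the fatty-acid class with the same
  flag.
* The lipid backbone mass removed before FAME distribution is retained
  as a mass-basis `lipid_backbone` entry, so the lipid class re-sums to
  the gravimetric lipid mass.
* The inorganic skeleton (silica) is a mass-basis remainder: skeleton
  mass minus the skeleton amino-acid residue mass.

**Known limitation — mass closure.** The hydrolysate amino-acid
catalogue is not mass-consistent with the colorimetric protein assay or
with total dry mass: the skeleton hydrolysate alone re-sums to ≈ 1.1 g of
residue mass per gram of skeleton, an over-recovery. The assembler
therefore warns (rather than errors) when the accounted mass fraction
exceeds 1.05 g/gDW and clamps the inorganic remainder at zero with a
warning. Users who need a closed equation can use the mole fractions with
an independently chosen protein mass; the package keeps the measured
molar values as the primary representation because re-scaling them is a
modelling decision, not a measurement.

Writers are deterministic: rows sorted by class then species,
coefficients fixed at six decimals, so identical equations give
byte-identical files.

## The synthetic-data generator

The generator's defaults are the study conditions: 4 individuals × 5
biopsies; component means, SDs and between-individual shares equal to the
reference composition table; 3 % triplicate assay CV; 23 lipid fractions
with the reference FAME catalogue; 20 hydrolysate samples per amino-acid
profile; 97 displacement calibration pairs at ratio 0.091 ± 0.012.

Choices worth knowing:

* Macro-components are Gaussian (matching the mixed model being tested)
  with zero-truncation by **resampling**, not clipping — clipping would
  bias the means of the small components (DNA, RNA) upward.
* FAME abundances are **lognormal** (positivity at CVs up to ~100 %),
  parameterized by their arithmetic mean and SD.
* Per-sample gravimetric lipid mass is emitted as
  `Σ compound mass / (1 − f_b)`, so backbone subtraction and mass closure
  are exact by construction and catalogue abundances are recovered
  without bias. Above-cut-off peaks that fail the 75 % presence rule are
  emitted as background signal that carries no quantified lipid mass —
  they exist to exercise the filter and the coverage statistic (the
  default background share targets ~82.5 % coverage).
* Unidentified catalogue compounds are dropped from a few samples at
  random, capped so their presence never falls below the retention
  threshold; three dedicated background compounds sit at 50 % presence to
  be excluded.
* Everything is integer-seeded; per-stage child seeds are derived
  deterministically, and a full input bundle written twice from the same
  configuration is byte-identical.

What the generator does **not** emulate: spatial correlation of biopsies
within an individual beyond the shared random intercept, seasonal or
ontogenetic composition shifts, assay-specific systematic biases
(inter-plate drift, matrix effects), bacterial vs host partitioning, and
chromatographic artefacts other than sub-threshold noise peaks. Passing
recovery tests therefore demonstrates the *arithmetic and statistical*
correctness of the pipeline under the declared model, not robustness to
real-data pathologies.

## Problem sizes and numerical settings

The validation suite uses the study-scale designs throughout: 4 × 5 for
variance partitioning (500 replicates for share recovery, 1000 for the
null rejection rate), 23 samples for FAME recovery, 97 pairs per
conversion-factor calibration (20 replicate calibrations when assessing
estimator bias), 20 hydrolysate samples. Optimizer tolerances are 10⁻¹²
on the profiled ratio; mass-closure identities are asserted at 10⁻¹²
relative; published-value reproductions are asserted at the precision the
values were printed with (three decimals for mole fractions, 1 % for
rounded-input abundances).
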