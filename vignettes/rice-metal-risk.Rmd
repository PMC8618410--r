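---
title: "From in vitro digestion to health risk: the ricerisk methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From in vitro digestion to health risk: the ricerisk methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricerisk)
```

# The problem

Trace metals (Al, Cd, Cr, Pb) and the metalloid As accumulate in rice
grain, and chronic dietary exposure to them is a recognized public
health concern.  The exposure that matters physiologically is not the
element content of the cooked grain but the part released into the
aqueous-micellar phase during digestion — the *bioaccessible* fraction —
since only that part can cross the intestinal epithelium.  `ricerisk`
implements the computational chain from static in vitro digestion
bookkeeping to the standard risk metrics, together with the
group-comparison statistics used to annotate survey tables, and a
synthetic-study generator so the whole chain can be exercised and tested
without laboratory data.

# Digestion fluid recipes

The static digestion protocol mixes food 50:50 with simulated salivary
fluid (SSF, pH 7), then bolus 50:50 with simulated gastric fluid (SGF,
pH 3), then chyme 50:50 with simulated intestinal fluid (SIF, pH 7).
Each fluid is prepared by diluting electrolyte stocks into a 500 mL
batch; `stock_to_fluid()` is the dilution
`c_fluid = c_stock * V_stock / V_fluid`, and `fluid_to_final_mixture()`
applies the 50:50 mixing factor.  Three registry conventions are worth
stating:

* The HCl stock is stored as 6 mol/L.  Its published recipe sheet lists
  "6" under a g/L heading, but only the molar reading reproduces the
  published gastric (15.6 mmol/L) and intestinal (8.4 mmol/L) acid
  concentrations from the dispensed volumes, so internal consistency
  wins and the registry documents the choice.
* CaCl2 is dosed at mixing time, not into the electrolyte batch, so the
  registry stores its target fluid concentrations (1.5 / 0.15 / 0.6
  mmol/L) directly; the in-mixture values (0.75 / 0.075 / 0.3 mmol/L)
  follow from the 50:50 dilution.
* NaOH appears as an optional pH-adjustment constituent with zero
  default volume.

The intermediate "five parts to four parts" staging of the protocol is
deliberately not modelled: the stated *final* ratio after enzyme and
CaCl2 additions is 50:50, and that single exact factor is what the
recipe arithmetic uses.  Amount of substance is conserved at every step
(stock aliquot, fluid, final mixture), which the test suite checks
directly.  `enzyme_mass()` converts a target activity (e.g. pepsin at
2000 U/mL of mixture, 367 U/mg solid) into the mass of solid to weigh.

A note on precision: two cells of the published recipe sheet (SGF
MgCl2(H2O)6, printed 0.1 vs computed 0.12 mmol/L; SSF HCl, printed 1.1
vs computed 1.08) are printed at coarser precision than the arithmetic
gives.  The golden-file test therefore compares computed values rounded
to the printed decimals; all other cells match without rounding.

# Fractions and protein mass balance

Centrifugation after digestion yields a digestible (supernatant) and a
non-digestible (pellet) fraction; `fraction_split()` turns recovered
masses into percentages that sum to 100 by construction.  In the
packaged survey the non-digestible fraction spans 25.5% to 73.1% of the
cooked dry mass (mean 44.3% +/- 12.9).

Protein in the digestible fraction is estimated by *fraction-weighted*
mass balance,

\[ p_d = \frac{p_{cooked} - f_{nd}\, p_{nd}}{f_d}, \]

not by naive subtraction of the two measured percentages: percentages of
different bases cannot be subtracted, and only the weighted form
recombines exactly (`f_nd p_nd + f_d p_d = p_cooked`).  Measurement
noise can push the balance negative; such values are clamped to zero and
flagged rather than silently propagated.  `protein_liberation()` then
gives grams of absorbable protein per 100 g of cooked rice as
`f_d * p_d`.  The published per-variety "calculated digestible protein"
column of the source survey is not reproducible from its own printed
inputs under either subtraction or mass balance (the per-variety splits
are only available as a figure), so those printed values are shipped as
data (`rice_protein_fractions()`) but never asserted as test
expectations.

Dry-weight conversion (`to_dry_weight()`) divides by the moisture-free
mass share and is applied only to records flagged as-is; the packaged
composition tables are already on a dry-weight basis.

# Bioaccessibility

`bioaccessibility_pct()` is the ratio definition
`100 * digestible / cooked`.  Two routes to the digestible
concentration are supported and always reported: direct measurement of
the supernatant, and subtraction of the pellet concentration from the
cooked one (`digestible_by_subtraction()`).  The survey this package
derives from used both without reconciling them, so the route is an
explicit argument, never a silent default.  Ratios above 100% — easy to
produce from inputs rounded to two significant figures — are flagged and
excluded from summary means by default rather than rejected, because
they are informative about data quality.

# Exposure and risk

The estimated daily intake is

\[ EDI = \frac{EF \times ED \times FIR \times MC}{BW \times AT}, \]

with defaults describing an adult rice consumer in Spain: FIR = 7.67
g/person/d, BW = 68.5 kg, EF = 365 d/y, ED = 54 y, AT = ED x 365 d
(non-carcinogenic) or 70 x 365 d (carcinogenic).  With these defaults
the non-carcinogenic prefactor `EF*ED/AT` is exactly 1 and
`EDI_c / EDI_nc = 54/70` exactly; the full form is kept so users can
vary any parameter.  THQ divides by the oral reference dose (Al 0.0004,
Cr 0.003, As 0.0003, Cd 0.001, Pb 0.0035 mg/kg/d), TTHQ sums the five
elements, and ILCR multiplies the carcinogenic EDI by the slope factor
(As 1.5, Cr 0.5, Cd 0.38, Pb 0.0085 per mg/kg/d; none exists for Al, so
its ILCR is absent, not zero).

Boundary conventions are closed exactly as the risk framework phrases
them: TTHQ of exactly 1 is still "acceptable" (exceedance is *above* 1)
and ILCR of exactly 1e-4 is still "tolerable".  Per-variety total ILCR
sums the element ILCRs; per-element values are always reported alongside
so no information is lost in the aggregation.

Censored measurements follow the worst-case convention: values below the
limit of quantification (and missing values) are substituted by the LOQ
itself (`loq_substitute()`), with each substitution flagged.  The
packaged parameter registry carries no numeric LOQs — they are
instrument-specific — so the policy activates only when the user
registers limits.

## The unit question

The packaged concentration tables carry their published unit label,
ng/g.  That label is internally inconsistent with the published intake
and risk magnitudes (cancer risks "around 1e-8" and reference-dose
percentages of a few percent are only approached if the same numerals
are read as ug/g).  No single reading reconciles all published figures,
so the package refuses to guess: `rice_metals()` returns the table as
printed by default, and `reinterpret = "ug/g"` applies the alternative
reading explicitly.  The headline safety conclusions — every variety's
TTHQ at or below 1 and every ILCR below 1e-4 — hold under the ug/g
reading (which is the conservative choice, 1000x higher than the
printed label) and a fortiori under the printed one.  A few printed
per-variety risk values in the source survey (e.g. variety-level THQ
extremes of 0.0045 and 0.001) are not reproducible under any unit
reading of its own concentration tables; they are mentioned here for
transparency but not used as test expectations.

# Survey statistics

Per-row variety comparisons use classical one-way ANOVA
(`one_way_anova()`), with Kolmogorov-Smirnov (`ks_normality()`) and
mean-centered Levene (`levene_mean()`) as the assumption checks.  Design
choices:

* **Pairwise procedure.** The letter displays are generated from Tukey
  HSD on the pooled ANOVA mean square at alpha = 0.05.  The survey
  methodology this mirrors says only "ANOVA ... with a t-test", so the
  procedure is configurable (`method = "t"` gives unadjusted
  pooled-variance t tests), but Tukey is the default because it is the
  standard generator of compact letter displays and controls the
  family-wise error rate.
* **KS reference.** The normal reference uses the sample mean and SD
  without a small-sample (Lilliefors) correction, matching the plain
  test the methodology names; the resulting p-values are conservative
  (biased upward) and the documentation says so.
* **Letters.** `compact_letters()` implements insert-and-absorb: start
  with one letter shared by all groups, split it on each significant
  pair, and absorb columns contained in others.  Two groups share a
  letter exactly when they are not significantly different — the test
  suite verifies this defining property against brute force over *all*
  significance patterns for up to four groups.  Letters are assigned in
  descending order of group mean (ties broken lexicographically),
  matching conventional table presentation.
* Published letter patterns of the source survey are not used as exact
  expectations, because the post-hoc procedure behind them is unstated.

`levene_mean()` returns W = 0 when every group shows the identical
deviation pattern (the 0/0 case of the F ratio is resolved to "no
evidence of heterogeneity"), and rejects all-constant groups outright.

# Synthetic studies

`generate_study()` draws a complete survey under minimal-assumption
distributions chosen once and documented here:

* cooked concentrations are lognormal across varieties (concentrations
  are positive and right-skewed; geometric mean defaults sit inside the
  packaged survey's cooked ranges under the ug/g reading: Al 2.3e-6,
  Cd 1.8e-8, Cr 4.5e-8, Pb 1.8e-8, As 3.6e-8 mg/g, geometric SD 1.15),
  with multiplicative replicate noise of CV 0.10;
* per-variety, per-element bioaccessibility is beta-distributed with
  means near the survey's per-element averages (Al 0.63, Cd 0.56,
  Cr 0.40, Pb 0.56, As 0.49) and precision kappa = 50;
* the non-digestible mass fraction is beta with mean 0.443 and SD 0.129,
  the survey's stated average; the beta shape parameters come from
  method of moments;
* composition profiles are normal around the survey's cooked average
  row with CV 0.10, truncated at zero.

Digestible concentrations are `cooked x bioaccessibility` and
non-digestible the exact remainder, so mass conservation holds by
construction for every record.  The generator is deterministic for a
fixed integer seed (Mersenne-Twister with inversion sampling), and
`recover_parameters()` provides method-of-moments estimates with
standard errors so recovery can be checked at any design size (the
default acceptance check uses 200 varieties x 10 replicates and asks for
agreement within 3 SE).

What passing tests on synthetic data do *not* show: the generator has no
between-element correlation, no soil-to-grain transfer structure, no
cooking losses, and replicate noise is purely multiplicative — so
closure tests demonstrate the pipeline's arithmetic and plumbing, not
the field realism of any particular dataset.

# Numerical choices and limitations

* Unit conversions are integer powers of ten, implemented with division
  on the downscale; same-exponent conversions are bitwise identities and
  cross-exponent round trips are exact to one ulp (decimal factors are
  not exactly representable in binary doubles).
* Problem sizes in the test suite are deliberately modest (the largest
  simulation is 200 varieties x 10 replicates); all checks are
  statistical properties, not timing-sensitive benchmarks.
* Tukey p-values below about 1e-10 saturate numerically; tests that
  compare adjusted and unadjusted p-values restrict themselves to the
  region where the studentized-range tail is accurate.
* The package models bioaccessibility, not bioavailability: epithelial
  absorption, mixture-interaction toxicology, and Monte-Carlo exposure
  distributions are out of scope, as are starch-digestibility kinetics
  and glycemic-index estimation.
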