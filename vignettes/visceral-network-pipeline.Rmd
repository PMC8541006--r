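---
title: "Quantifying the visceral network: models, parameters and design choices"
author: "viscnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the visceral network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscnet)
```

# The problem

After an intraperitoneal injection of ¹⁸F-FDG in a mouse, the tracer does not
enter the body through a vein. It sits in the peritoneal cavity and reaches
the splanchnic organs (gut wall, visceral fat, liver) by two distinct routes:
directly, through mesenteric and portal vessels, before ever touching the
general circulation (*pre-systemic*), and later from the blood pool like any
intravenous tracer (*post-systemic*). The first route dominates roughly the
first ten minutes of a 60-minute dynamic scan; integrating organ
time-activity curves separately over 0–10 and 10–60 minutes therefore splits
glucose handling into a portal-facing and a systemic-facing component. This
package implements that quantification, the liver histology composite used
to call steatohepatitis, a two-stage biomarker procedure for the
accompanying microbiome tables, and a correlation screen tying the three
data types together — plus a synthetic-cohort generator that makes the whole
chain testable without animal data.

# The tracer model

## Structure

The simulator is a linear, first-order compartment system:

- a peritoneal depot `P` that empties into blood (`kPA`) and directly into
  gut, visceral fat and liver (`kPG`, `kPV`, `kPL`; the pre-systemic routes);
- a blood pool `B` feeding the same tissues (`kBG`, `kBV`, `kBL`) and an
  irreversible loss pool (`kLoss`, renal excretion);
- tissue compartments that by default trap the tracer irreversibly (the FDG
  phosphorylation analogy); with `trapping = FALSE` each tissue exchanges
  back to blood at the rate constant that fills it.

Six auxiliary integral states record the cumulative amount delivered through
each route, so pre- vs post-systemic delivered fractions are exact by
construction rather than inferred. The system is closed: compartment amounts
plus loss equal the dose at every time, which the test suite asserts to
1e−8 for arbitrary parameter draws.

The solution is propagated with the matrix exponential of `A·dt` — exact for
a piecewise-uniform grid, with no step-size error to tune. An independent
stiff ODE integration (deSolve) agrees to 1e−6 in the tests; a closed-form
two-exponential solution of the trapping model is a second, hand-derived
oracle.

## Calibration, not mechanism

No kinetic model of i.p. FDG transport is given in the literature this
design follows; what is reported are arrival fractions: about 4% of the
blood pool's total 0–60 min exposure occurs within the first 10 minutes
(96% afterwards), while 15–20% of the injected dose reaches gut plus
visceral fat very rapidly through the pre-systemic routes. The default rate
constants

```{r}
kineticParams()
```

were calibrated once, numerically, to those two observations (yielding 4.08%
and 16.1% on the default grid) and then frozen. They are phenomenological:
the simulator reproduces the observed arrival pattern, not transport
mechanism, and no claim is made that individual rate constants correspond to
physiological conductances. The 15–20% figure is treated as a fraction *of
injected dose*; the source observation does not state the denominator, and
this reading is flagged as a choice rather than asserted as intent.

## Grid and integration

The default grid is 0.5-minute frames over 0–60 min: fine enough that
trapezoid integration of the default-magnitude exponentials is accurate to
better than 0.1%. Windowed integrals use the trapezoid rule on the sample
grid with linear interpolation at off-grid endpoints; the rule is exact for
piecewise-linear curves and exactly additive across adjacent windows sharing
a grid point, which makes `GE(0–10) + GE(10–60) = GE(0–60)` an identity
rather than an approximation. No extrapolation is ever performed: windows
outside the sampled support are an error.

# Quantification conventions

**%ID/g.** "Normalised to injected dose per gram of body weight" admits two
readings. The default is the SUV-like, dimensionless
`100 · C(t) · BW / D`; the alternative `100 · C(t) / D` (units 1/g) is
available behind `convention = "per_g"`. All downstream ratios are invariant
to the choice; absolute extraction values are not, which is why the switch
exists and the convention is recorded in the pipeline config.

**Windows as areas.** Extraction metrics are areas (value·min), not window
means. Both readings are defensible; areas were chosen because additivity
across windows then holds exactly.

**Glycemia** is a single fasting tail-blood value per subject, not a time
series; uptake is extraction × glycemia.

**EGP units.** Clearance (mL/min) × glycemia (mmol/L) = µmol/min, divided by
body weight in grams. Units are part of the column names
(`egp_umol_min_g`) so no silent convention can drift.

**Degenerate inputs.** Partitioning ratios are reported missing (`NA`) when
the denominator organ's 0–60 uptake is zero (including the glycemia = 0
case, where every uptake is zero); a zero blood integral makes clearance an
explicit error rather than `Inf`.

# The synthetic cohort

`studyDesign()` encodes the study conditions: four strata — weaning vs adult
age at scan crossed with maternal normal vs high-fat diet — of 11, 8, 10 and
9 animals (38 total), body weights near 17 g (weaning) and 31–33 g (adult),
dose 4 ± 0.4 MBq, fasting glycemia ~7.5 mmol/L, and triglycerides whose
below-range readings surface as the 70 mg/dl assay floor.

Stratum effects multiply the calibrated default rates before per-subject
log-normal jitter (sdlog 0.15): weaning strata carry the default (high)
gut/visceral-fat delivery and extraction — the arrival-fraction
observations typify the pooled cohort, which is weaning-dominated in
splanchnic avidity — while adult strata get one third of those rates,
reproducing the several-fold higher visceral-fat/liver and gut/liver uptake
ratios at weaning. The weaning-HFD stratum carries an extra 3× on the
visceral-fat rates (within the reported two-to-six-fold elevation), and the
adult-HFD stratum a 1.4× on post-systemic hepatic extraction. With these
choices the cohort-mean blood-exposure split stays at ~4%.

CT densities are Gaussian per stratum (negative HU for visceral fat,
positive for liver and gut, lower at weaning), with liver HU linearly
depressed by the subject's planted steatosis grade — a qualitative emulation
of the observed density–steatosis correlation only. Histology observations
are drawn from severity-driven distributions that worsen across the strata
in the order weaning-ND < weaning-HFD < adult-ND < adult-HFD. Measurement
noise on activities is multiplicative Gaussian (CV 5%, truncated at zero);
`noiseFree = TRUE` switches it off for calibration checks. Radioactive decay
is not simulated — inputs are declared decay-corrected.

Seeding uses one master seed with counter-based per-subject streams, so
enlarging one stratum never reshuffles another subject's draws, and the same
seed reproduces a cohort byte-identically through the whole pipeline.

**Taxa tables** are log-normal compositions: baseline log-abundances
`N(0, 1.5)` across taxa, within-class subject noise with sdlog 0.6, planted
taxa shifted by the requested log2-fold on the log scale before total-sum
scaling. The noise level was fixed at 0.6 — a realistic within-group spread
for dominant genera — so that a 4-fold planted effect at 10 vs 10 subjects
is recoverable by the biomarker stage in well over 90% of replicates, the
recoverability the generator is specified to provide. A `coupling` argument
ties one taxon's log-abundance to an external covariate to plant
taxon–metric associations.

What the generator does **not** emulate: compositional zero-inflation and
sequencing-depth effects, taxon–taxon correlation structure, arterial
input-function realism, partial-volume and spill-over effects, or any
image-space phenomenon. Passing tests therefore demonstrate correctness of
the estimators under a clean generative model, not robustness to every
artefact of real PET or 16S data.

# Histology composite

Grades follow the Kleiner-adapted scheme. Two decisions were genuinely open:

- *Cutoffs*: the steatosis percentage boundaries (<5, 5–33, >33–66, >66) are
  taken from the cited grading scheme since only "graded as the percentage
  of affected cells" is stated; boundaries are inclusive in the lower
  grade's upper bound.
- *Composite components*: the 0–3 lobular grade (not the binary flag) enters
  the sum — required for the stated maximum of 7 — and portal inflammation
  does not, per the printed component list. When micro- and macrovesicular
  steatosis are recorded separately the composite uses the worse grade
  (conservative; the source is silent).

The full 4×4×2 grade space is enumerated in the tests: NASH ⇔ sum ≥ 4,
minimum positive sum 4, maximum 7.

# Biomarker discovery

The two-stage procedure is reimplemented from its published logic rather
than wrapped: total-sum scaling, a nonparametric class screen, then a
linear-discriminant effect size on abundances rescaled to the 1–10⁶ range,
reported as log₁₀ and called strictly above 3.0.

Numerical decisions:

- **Screen test.** For two tie-free classes of fewer than 50 subjects the
  screen uses the exact Wilcoxon rank-sum distribution (the completely
  separated 4+4 case gives exactly p = 2/70, verified against full
  enumeration of all 70 labelings); ties or more than two classes fall back
  to the tie-corrected Kruskal–Wallis chi-square approximation. A feature
  constant across all subjects returns p = 1 by convention. Type-I
  calibration at α = 0.05 is verified over 1000 null features.
- **Effect size.** Per feature, the discriminant projection is scaled to
  unit pooled within-class variance (what a standard LDA fit returns for one
  variable, cross-checked against MASS::lda); the effect size averages the
  projected and raw class-mean differences. Zero between-class difference
  yields an NA score ("below threshold"), never an error; zero within-class
  variance with separated means degenerates to the raw difference.
- **Determinism.** The default is a single deterministic fit. A seeded
  bootstrap mode (`nBoot`) averaging 2/3-per-class subsamples reproduces the
  reference tool's averaging behaviour; the original's per-class pairwise
  consistency substage is available as `strict = TRUE`, off by default
  because the analysis this package follows does not mention it.
- **Multi-class** enrichment is one-vs-rest on the class with the largest
  mean.

# Association screen and group comparisons

Spearman's rho is the Pearson correlation of midranks (tie-corrected).
p-values use the t approximation for n ≥ 10 and full permutation enumeration
(all n! pairings) below that, where the approximation is poorest; the
enumeration matches `cor.test(..., exact = TRUE)` on tie-free cases. Pairs
with fewer than four complete observations are skipped with a warning, not
an error, and the per-pair n is reported. "FDR correction" is implemented as
Benjamini–Hochberg across all pairs of one screen — the adjustment family is
the whole metric × feature matrix, the most conservative reading of an
ambiguous statement. Two-group comparisons use Welch's unequal-variance t
(robust default); more than two groups use one-way ANOVA; groups identical
value-for-value return statistic 0, p = 1 instead of a degenerate error.

# Pipeline

`runPipeline()` chains simulate → quant → histology → lefse → associate.
Every stage reads the previous stage's files, so each is runnable standalone
on a directory of tables; all tables are plain CSV/TSV with numeric fields
written at 17 significant digits so a write–read round trip is bit-exact.
The manifest records the seed, a hash of the resolved config, per-stage row
counts and output hashes; a rerun with the same config and seed is verified
byte-identical in the tests.

# Problem sizes used in the checks

The packaged checks run at desk scale, chosen for statistical adequacy:
type-I calibration over 1000 null features (two classes of 20);
planted-biomarker power over 200 seeded replicates at 10 vs 10 subjects and
20 taxa; rate-multiplier recovery at 500 subjects per stratum
(law-of-large-numbers oracle, 2% Monte-Carlo band); a 20-point rate sweep
for metric–rate monotonicity; the default 38-subject cohort for everything
end-to-end.

# Known limitations

- The compartment model is a calibrated phenomenology; absolute rate
  constants are not physiological estimates, and no kinetic-model fitting
  (Patlak or compartmental estimation) is provided.
- The %ID/g convention and the area-vs-mean window reading are choices; both
  are surfaced as options rather than hidden.
- The biomarker stage reconstructs a published two-stage logic; the exact
  substage configuration of any particular historical run (per-stage α,
  bootstrap rounds) is not knowable and defaults are documented here.
- Group-level biological effect sizes from a 38-animal study are not
  reproducible from synthetic data; the package asserts orderings (e.g.
  weaning VF/liver partitioning exceeds adult) and rule-based constants, not
  the study's group means.
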