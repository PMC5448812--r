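---
title: "meiokit: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meiokit: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiokit)
```

meiokit implements the quantitative analyses behind a multi-assay dissection
of the yeast MutLγ (Mlh1–Mlh3) complex: tetrad-based crossover and
chromosome-missegregation genetics, hydroxyl-radical footprint mapping,
AFM particle volumetrics, and cooperative-binding / enzyme-kinetics fits,
with a shared layer of contingency statistics. Every data type has a seeded
generator with machine-readable ground truth, so the whole pipeline is
validated by recovery tests rather than by fixed fixtures. This vignette
records the models, their assumptions, and the choices made where the
design was genuinely open.

## Tetrad genetics

### Classification model

Each spore of a tetrad reports one chromatid of chromosome VIII through
three fluorescent markers: red near *CEN8* and green near *ARG4* on one
homolog, blue near *THR1* on the other. A chromatid is recombinant for the
*CEN8–ARG4* interval when red and green disagree, and for *ARG4–THR1* when
green and blue agree (both present or both absent). With 2:2 segregation of
every marker, each interval sees 0, 2 or 4 recombinant chromatids, giving
PD, TT or NPD.

Two scoring rules matter:

* **Ambiguity rule.** The pattern {RGB, RGB, ---, ---} arises from MI
  nondisjunction (both homologs to one pole, sisters split at MII) *and*
  from a four-chromatid double crossover in *ARG4–THR1* (a PD/NPD tetrad).
  Because double crossovers in the smaller interval are far rarer than
  missegregation in the strains of interest, the pattern is always counted
  as nondisjunction, with an `ambiguous` flag retained so sensitivity
  analyses can exclude these tetrads. The cost is a small, quantifiable
  deflation of the second interval's NPD tally (see *Known biases* below).
* **Aberrant rule.** Any other deviation from 2:2 segregation is flagged
  aberrant and excluded from every denominator.

### Map distance and its error

Distances use the Perkins equation, cM = 100(6·NPD + TT)/(2(PD + NPD + TT)).
The standard error treats (TT/n, NPD/n) as multinomial:
se = 50·sqrt((t(1−t) + 36p(1−p) − 12tp)/n). This is a delta-method
derivation rather than a reimplementation of any external tool; on a tally
of roughly 1,300 tetrads at 11–12 cM it yields a standard error of about
0.6 cM, the magnitude typical for assays of this size.

Strain comparisons run a G test on the 2×3 strain-by-(PD/TT/NPD) table per
interval. Whether such comparisons should instead use 2×2
recombinant-versus-parental chromatid counts is ambiguous in practice; both
are exposed (`crossover_table = "spores"`), with the 2×3 tetrad-type table
as the default because it uses the tetrad as the sampling unit, which is
what the assay actually counts. Nondisjunction is compared by two-tailed
Fisher's exact test on (nd, n − nd); when neither strain shows any
nondisjunction the test is reported as p = 1 with a note rather than an
error, and tetrad classes unobserved in both strains are dropped from the
G-test table (they carry no information and would make expected counts 0).

### The simulator

`simulate_tetrads()` draws, per meiosis, Poisson crossover counts per
interval with mean 2d/100 per bivalent (a map distance of d cM per
chromatid is d/100 Morgans; the bivalent of four chromatids accumulates
twice that), assigns each crossover one chromatid of each homolog uniformly
and independently — no chromatid interference and no crossover interference
— and propagates markers by walking each centromere outward through the
exchange points in positional order. The walk matters: exchanges compose as
transpositions of *original* chromatids, and a naive sequential swap of
current strand contents would couple the two intervals and distort
tetratype frequencies. Ground truth (interval types, nondisjunction) is
recorded from the walk itself, independently of the string-pattern
classifier that consumes the simulated spores.

Interference is deliberately not modelled: the Perkins estimator is the
standard no-interference correction, and the recovery tests are about the
estimator chain, not about interference biology. This is a realism limit:
real yeast meiosis shows positive interference, so simulated NPD counts at
a given distance are higher than real ones.

### Known biases, quantified

Two small deterministic offsets separate the expected Perkins estimate from
the generative distance, and the test suite checks the pipeline against the
analytically expected values (computed in the tests from the Poisson-Markov
tetrad-type distribution, not simulated):

1. The Perkins formula corrects for double but not triple-and-higher
   crossovers; under Poisson counts at 11.63 cM this biases the estimate by
   about −1.6%, within the ±2% envelope the recovery tests allow.
2. The ambiguity rule removes true PD/NPD tetrads from the second
   interval's tally, deflating its estimate by roughly 0.2 cM at wild-type
   distances — the same slight underestimate of the distal interval that
   the scoring convention produces on real data, where it is accepted
   because missegregation dominates in the crossover-deficient strains of
   interest.

## Footprint mapping

### From trace to residue

Lane traces are baseline-corrected with a wide running median,
smoothed with a Savitzky–Golay filter (quadratic, window 0.5% of the trace),
and peaks are local maxima above a prominence threshold (5% of the tallest
peak) with subsample centers from a three-point quadratic fit. Calibration
fits migration as a fourth-order polynomial of molecular weight — of MW
itself, not log MW — to ≥5 ladder markers. Because an unconstrained quartic
can oscillate, the fit is rejected unless strictly monotone over the marker
range, and inversion uses bisection on that range only; peaks migrating
outside it are flagged `out_of_range` rather than extrapolated.

Fragment masses convert to residue indices through the cumulative average
residue mass of the actual sequence plus the N-terminal tag mass (the tag
is what the blot detects, so fragments are N-terminal prefixes). Average
rather than monoisotopic masses are used, as appropriate for SDS-PAGE-scale
masses. Site uncertainty propagates the calibration residual RMS through
the local calibration slope and is floored at 5 residues, the assay's
stated precision class.

### Generator and resolution

`simulate_lane_set()` generates bands under a log-linear migration law,
migration = a − b·ln(MW), *deliberately different* from the quartic the
calibration fits. The quartic approximates the log law to a residual well
under 2% of lane length on a 9-marker ladder, and the mismatch keeps the
round-trip tests honest about model error: a noiseless round trip recovers
sites to ~3 residues (quartic-approximation error), not exactly.

The default band width is 0.4% of lane length. This was set from the
resolution the mapped fragment sets evidently require — neighbouring
cleavage sites ~9 residues (≈1 kDa) apart are reported as distinct
fragments, which demands bands narrower than ~0.5% of the lane at the
relevant masses. Bands closer than about twice their FWHM still merge into
a single reported peak whose position is the intensity-weighted blend; the
end-to-end tests therefore score recovery by nearest-match error, which
stays within the 10-residue precision bound even across merges.

Candidate DNA-binding residues are all K/R within ±12 residues of a mapped
site — the smallest window containing every reported site-to-mutation
pairing — optionally filtered by K/R conservation across a supplied
alignment (the filter is off by default since an alignment is an optional
input).

## AFM volumetrics

Background is removed as a least-squares plane plus the median of the
residual; the particle threshold is 3 robust SDs (MAD) of the corrected
background, with a relative floor (1% of the maximum corrected height) so
noise-free synthetic images do not threshold at numerical ripple. Components
are 8-connected; each particle's volume integrates corrected height over its
mask dilated by 3 px, which recovers the sub-threshold skirt of a particle
(without the dilation, 3–5% of a Gaussian-shaped particle's volume is lost
below threshold). Particles touching the image edge are flagged and excluded
from summaries. On noise-free simulated fields total measured volume matches
generated volume within 2%, and volumes are invariant to adding an arbitrary
plane.

Classification windows: dimers in [170, 350] nm³ with both bounds inclusive
(the stated dimer range), multimers above, monomers below down to a 40 nm³
floor that excludes noise speckles (the floor is a package choice; the
assay's custom analysis code is unpublished). The predicted hydrated volume
V_c = (M₀/N₀)(V₁ + d·V₂) with V₁ = 0.74 cm³/g, V₂ = 1 cm³/g, d = 0.4 g/g
evaluates to ≈331 nm³ for a 175 kDa heterodimer; the function evaluates the
equation as printed and makes no attempt to reproduce any separately quoted
number for it. Shape-based configuration scoring (extended, one-arm folded,
semi-condensed, condensed) is manual in the source assay, so configurations
enter only as pre-scored count tables compared by G test.

The field generator places Gaussian caps (volume 2πHσ²) by rejection with a
minimum separation of 8 lateral SDs, so simulated particles never overlap —
real fields contain touching particles that segmentation would merge; that
failure mode is out of the generators' scope.

## Binding and kinetics

The Hill fit parameterizes half-saturation directly, f(L) = Lⁿ/(Kⁿ + Lⁿ),
so K_D carries concentration units. Fits run on the scale the data arrive
in — EMSA quantifications are of the unbound substrate, so the default
response is unbound = 1 − f — by Levenberg–Marquardt least squares with
uniform weights. Starting values come from the data (K from the half-max
crossing by linear interpolation, n from the slope of the logit-log line
over points with 5–95% binding), with bounds n ∈ (0.001, 6], K > 0. The
saturating amplitude is fixed at 1 because the titrations run to >90%
completion, leaving the amplitude unidentifiable as a free parameter on
most series; `free_amplitude = TRUE` relaxes this. A series entirely on one
side of half-saturation is refused as non-identifiable rather than fitted.
Parameter standard errors come from the curvature of the least-squares
objective (the usual nls linearization), matching the mean ± SE convention
of the source quantifications; on noiseless data the fit recovers (K, n)
grids to ≥6 significant digits.

Michaelis–Menten fits are analogous (starting K_m from the half-V_max
crossing); k_cat is V_max itself when rates are already per-enzyme, or
V_max divided by a supplied enzyme concentration. A fit whose K_m exceeds
the largest substrate concentration warns that it is unsaturated — the
parameters then trade off along V_max/K_m, though the fitted curve (and
that ratio) remain well determined, degenerating to the line (V_max/K_m)·S.

Reversion frequencies are revertants per CFU per culture, aggregated by
mean (the source convention is mean ± SD over 3–6 cultures) with a
jackpot-robust median behind a flag. The generator draws Poisson counts at
frequency × CFU — a deliberate simplification that ignores Luria–Delbrück
jackpot skew, acceptable because frequencies, not mutation rates, are the
quantity of interest; real replicate-to-replicate spread is therefore
under-dispersed relative to real fluctuation data.

## Shared statistics

Fisher's exact test conditions on both margins and sums hypergeometric
probabilities of tables at most as probable as the observed one (the
probability-mass two-sided rule of standard implementations), with a 1e−7
relative tolerance for floating-point ties. The G test is
2·ΣO·ln(O/E) with no Williams or continuity correction (none is specified
for the source analyses); zero cells contribute nothing, and a zero row or
column margin is an error. Proportion intervals are Wald by default —
matching the symmetric "± 95% CI" presentation — with Wilson available;
Wald half-widths are zero at p̂ ∈ {0, 1}, which is the known cost of that
convention. No multiple-testing correction is applied anywhere, since raw
p-values are the reporting convention in this setting.

## Problem sizes and validation scale

The test suite and the acceptance script size their simulations for a
laptop-class single core: 200,000 tetrads for map-distance recovery
(Monte-Carlo SE ≈ 0.065 cM at 11.6 cM), 100,000 for classifier-truth
agreement and nondisjunction recovery, exhaustive Fisher-versus-enumeration
checks over all 2×2 tables with total ≤ 40, 10-point titrations, 40–90
particle AFM fields, and 6-culture reversion assays. The whole suite runs
in well under a minute; the acceptance script in seconds.

## Limitations

* No crossover or chromatid interference model (an interference hook would
  be a gamma-renewal process on crossover positions; not implemented).
* Footprint mapping starts from 1-D lane traces; blot image processing,
  lane registration and 2-D gel artefacts are upstream and out of scope.
* AFM analysis does not deconvolve tip geometry, so absolute volumes from
  real images carry the usual tip-convolution inflation; the volume windows
  are calibrated conventions, not physical constants.
* The Hill coefficient is treated as a fit parameter summarizing
  cooperativity, not interpreted thermodynamically.
* Synthetic generators are clean by construction (no gel smiling, no
  overlapping AFM particles, Poisson reversion counts); passing recovery
  tests demonstrates correctness of the estimator chain under the stated
  models, not robustness to every artefact of real data.
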