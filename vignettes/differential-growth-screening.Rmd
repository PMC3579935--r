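---
title: "Methods: differential growth-inhibition screening for SDH-deficient yeast"
author: "DiffGrowthScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential growth-inhibition screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiffGrowthScreen)
```

# The scientific problem

Loss of succinate dehydrogenase (SDH, mitochondrial Complex II) blocks the
TCA cycle and leaves a cell dependent on glycolysis for ATP. In yeast, an
*sdh2* null strain grows normally on fermentable carbon (glucose,
galactose) but cannot grow on non-fermentable carbon (glycerol), and on
mixed media it stops growing exactly where a wild-type culture undergoes
its diauxic shift into respiratory growth. This metabolic corner is a
therapeutic opportunity: a compound that is more toxic to the SDH-null
cell than to its wild-type parent leverages the tumour-defining lesion
itself.

`DiffGrowthScreen` implements the analysis side of a three-stage screen
for such compounds:

* **Stage I** — endpoint 384-well screening of the mutant strain alone:
  per-well percent inhibition, z-factor quality control, hit calling.
* **Stage II** — high-resolution growth curves of mutant and reference
  strain with and without each hit: multiphasic growth-model fitting and
  differential scoring of saturation, rate and lag.
* **Stage III** — the same comparison against a marker-control strain
  (wild-type physiology, same resistance cassette as the mutant) to
  exclude cassette artifacts.

Around the screen sit two dose-response components: four-parameter
log-logistic IC50 fitting for whole-cell growth, and an NADH-depletion
(A340) enzyme assay for alcohol dehydrogenase inhibition, whose initial
rates feed the same IC50 machinery. Because no screening dataset is
publicly deposited, a synthetic-data generator with known ground truth is
a first-class component: every analysis routine is validated by parameter
recovery against curves whose truth is known exactly.

# The growth model

A culture's optical density is modelled as a baseline plus one logistic
component per growth phase:

$$\mathrm{OD}(t) = b + \sum_{i} \frac{K_i}{1 + e^{-r_i (t - m_i)}}$$

Each phase is reported through three field-standard quantities:

* **saturation** $S_i = K_i$ — the asymptotic OD increment of the phase;
* **maximal rate** $R_i = r_i K_i / 4$ — the steepest slope, in OD/h
  (this is the slope of absorbance, not a per-cell exponential rate; the
  units matter and are stated everywhere);
* **lag** $L_i = \max(0,\, m_i - 2 / r_i)$ — the tangent-at-inflection
  intercept, the standard closed-form lag definition for a logistic.

A sum of logistics (rather than piecewise segments) is continuous and
differentiable and reproduces the plateaued diauxic shape; the visible
pause between phases is controlled in the generator by requiring the
second inflection to trail the first by at least a configurable gap
(default 1 h).

## Segmentation and fitting

`segmentPhases()` smooths the trace (moving median then moving mean,
5-point windows), takes the numeric derivative (additionally smoothed over
about 1.5 h when the read noise is appreciable), and proposes two phases
when two separated derivative maxima exist with an intervening minimum
below 30% of the smaller maximum. The peak positions, peak slopes and
plateau levels seed the nonlinear fit. A curve whose smoothed dynamic
range is under 0.05 OD is declared "no growth" and not fitted.

`fitGrowth()` runs bounded Levenberg–Marquardt least squares
(`minpack.lm`) from the segmentation guess plus four jittered restarts
(deterministic given a seed). In `auto` mode both the 1- and 2-phase
hypotheses are fitted and compared by small-sample-corrected AIC with a
2-point preference margin for the simpler model.

## Admissibility of a second phase

AICc alone occasionally (a few percent of curves at realistic noise)
accepts a second component that fits noise rather than biology, and a
spurious "phase 1" corrupts every downstream rate and lag ratio. A
2-phase candidate is therefore only admitted when both components are
bona fide observable growth phases:

* amplitude at least 0.005 OD and at least 5% of total growth;
* transition width no narrower than about two sampling intervals — the
  optimizer's shape-rate is bounded at $r \le 2.2/\Delta t$, and a
  noise-amplitude component pinned at that cap is rejected as a spike;
* inflection inside the recorded time window (an extrapolated tail is not
  an observed phase);
* enough separation between the components that a diauxic plateau
  actually exists between them (inflections further apart than the sum of
  the component half-widths $2.2/r_i$).

These criteria are the package's operational definition of "a second
growth phase is present", chosen so that phase-count selection is correct
on noise-free curves always and on noisy curves in well over 95% of
cases (asserted by the test suite over 100 simulated curves).

# Stage I: plate scoring

Percent inhibition places the no-compound control mean at 0% and the
media blank at 100%:

$$\mathrm{PI} = 100 \left(1 - \frac{\mathrm{test} - \mathrm{blank}}
{\mathrm{control} - \mathrm{blank}}\right)$$

Values outside $[0, 100]$ are passed through unclipped (they carry
information: growth stimulation, or absorbance below blank). Control and
blank means are always computed per plate and per read time. Assay
quality is summarized by the z-factor

$$z = 1 - \frac{3(\sigma_p + \sigma_n)}{|\mu_p - \mu_n|}$$

on the percent-inhibition values of positive (killer compound) and
negative controls, with sample ($n-1$) standard deviations; $z > 0.5$ is
the conventional screenable-assay bar. Control plates alternate full rows
of culture / culture+killer / media, mirroring the layout used for
instrument qualification.

The Stage-I hit threshold is deliberately a required, explicit parameter:
screening cutoffs belong in the run record, not in code defaults. The
shipped pipeline configuration uses PI ≥ 40% at the 48 h read, which at
the generator's noise level sits more than ten standard deviations above
the null distribution while catching partial inhibitors strong enough to
matter in Stage II.

## Dispensing arithmetic

`dispenseConcentration()` does exact mass-balance over the droplet
protocol (nanolitre DMSO droplets into pre-dispensed medium, media top-up,
culture inoculation) and reports both the exact accounting (droplet
volume included in the denominator) and the nominal convention a protocol
sheet quotes. With the default protocol (20 × 2.5 nL of 10 mM stock into
10 µL, +30 µL medium, +10 µL culture) the nominal stages are 50 µM (5×),
12.5 µM / 0.125% DMSO, and 10 µM / 0.1% DMSO final.

# Stage II: differential scoring

For each compound the matched quadruple — mutant ± drug, reference ±
drug, same concentration and media — is fitted and reduced to three
dimensionless differentials. With $S$ the total saturation above baseline
(summed across phases; baseline excluded so the ratios compare growth,
not optics), and $R$, $L$ the maximal rate and lag of the glycolytic
(first) phase:

$$\Delta S = \frac{S_{ref,drug}}{S_{ref,ctrl}} -
             \frac{S_{mut,drug}}{S_{mut,ctrl}}, \qquad
  \Delta R = \frac{R_{ref,drug}}{R_{ref,ctrl}} -
             \frac{R_{mut,drug}}{R_{mut,ctrl}}, \qquad
  \Delta L = \frac{L_{mut,drug}}{L_{mut,ctrl}} -
             \frac{L_{ref,drug}}{L_{ref,ctrl}}$$

The ratio-difference form is unitless and normalizes each strain to its
own untreated growth; the lag difference is orientation-flipped so that
**positive always means the mutant is hit harder** (inhibition shrinks
saturation and rate but lengthens lag). The sign convention is stated in
every output header. Two numerical conventions matter:

* a control lag below 0.25 h is replaced by that floor before the ratio
  (lags near zero make ratios explode without carrying information);
* when a drugged culture reaches less than 15% of its control saturation,
  its rate and lag ratios are suppressed (`NA`). The kinetics of a
  culture that barely grew are not quantifiable — fitted rate ratios in
  that regime have standard deviation around 0.5 with heavy tails — and
  the saturation delta already carries the inhibition signal.

## Classification thresholds

`classifyCall()` labels a compound mutant-selective when any differential
strictly exceeds its positive threshold, reference-selective below the
negative threshold, nonselective otherwise; exact threshold hits stay
nonselective, and opposite-direction conflicts are resolved by the
largest threshold-normalized magnitude. Thresholds are per metric and
must be explicit in the configuration. The shipped defaults are
$\Delta S, \Delta L: 0.3$ and $\Delta R: 0.7$. The asymmetry is
deliberate: saturation and lag ratios are precise (replicate sd ≈ 0.03
under the default retest design) while the maximal slope of a strongly
inhibited, steep, low-amplitude curve is intrinsically ill-determined
(delta sd ≈ 0.2, confirmed by refitting from true starting values), so
its threshold sits at roughly three times its noise floor. With the
generator's effect classes the true signals are ≈ +0.75 (mutant-
selective) and ≈ −0.40 (reference-selective) on $\Delta S$ — more than
ten standard deviations from the nonselective null.

A compound is reported differential if it is differential at one or more
tested concentrations.

# Stage III: marker concordance

The mutant differs from wild type in two ways: the deleted gene and the
resistance cassette (an acetyltransferase). The marker-control strain
carries the same cassette in a wild-type background; a true
mutation-linked compound must affect wild type and marker strain
identically. `markerConcordance()` forms each parameter's drug/control
ratio in both strains and flags a compound when any relative difference
exceeds the tolerance (default 20%). Near-complete inhibition can push
the rate-ratio difference past that tolerance by estimation noise alone,
so a discordance flag is a prompt for inspection, not an automatic
exclusion.

# Dose-response and enzyme kinetics

`fitIC50()` fits the four-parameter log-logistic
$y = bottom + (top - bottom) / (1 + (c/\mathrm{IC50})^{h})$ by bounded
least squares with a deterministic multi-start over an IC50 grid spanning
the tested dilution range. The Hill slope is free by default (switchable
to $h = 1$). Three asymptote modes reflect how the response was produced:
`free` for raw responses, `normalized` (top = 1, bottom = 0) for
fractional activities when the tested range does not reach the lower
plateau, and `bottom0` (bottom fixed at zero activity, top floating) —
the default for enzyme data, where responses are normalized to a
zero-inhibitor mean that itself carries estimation error, so the curve is
not forced through 1. An IC50 outside the tested span is flagged as
extrapolated; flat response sets return a diagnostic instead of a number.
A residual-resampling percentile bootstrap (default off, 200 resamples
when requested) provides the IC50 confidence interval.

`initialRate()` defines the initial rate of an A340 progress curve
operationally: ordinary least-squares slopes over expanding windows
anchored at $t = 0$, keeping the longest window whose $R^2 \ge 0.98$,
falling back to the minimum window (4 points) with a "curvature" flag.
The window rule is deterministic and reported; lowering the floor can
only lengthen the chosen window. Flat traces give $v_0 = 0$ ("flat");
rising traces are flagged ("increasing"). Conversion to µM NADH/min uses
$\varepsilon_{340} = 6.22\ \mathrm{mM^{-1}cm^{-1}}$ when a path length is
supplied.

`enzymeInhibitionIC50()` averages replicate rates per concentration,
normalizes to the zero-inhibitor mean and delegates to `fitIC50()`; with
a `run` column present it also fits each assay repetition separately and
reports the per-run IC50s and their mean, which is the quantity a
three-repetition assay reports.

# The synthetic-data generator

The generator is the package's study-condition definition; its defaults
were chosen once, as follows, and the tests inherit them.

**Strain archetypes.** Wild type: glycolytic phase (lag 4 h, maximal
rate 0.12 OD/h, saturation 0.55 OD) plus respiratory phase (lag 18 h,
0.05 OD/h, 0.50 OD); baseline 0.05 OD. The marker-control strain is
phenotypically identical to wild type. The SDH-null strain has no
respiratory phase. On pure glycerol it therefore stays at baseline; on
pure fermentable media only phase 1 appears for every strain. These
values reproduce the qualitative shape of mixed-media diauxic curves
(a fermentative rise over the first day, a visible plateau, and a slower
respiratory rise) at 6-min sampling over 48 h.

**Drug action.** A compound's effect on a strain is a saturable Hill
response per parameter: saturation and rate multipliers run from 1 (no
dose) to an asymptotic floor in (0, 1]; lag gains an added term. The
built-in screen classes use EC50 = 1 µM and Hill slope 2, so the 10 µM
primary dose and 50 µM retest both sit on the upper plateau:
mutant-selective (mutant floor 0.15, reference 0.9), reference-selective
(0.5 / 0.1 — the mutant partial effect lets such compounds surface in a
mutant-only primary screen, as observed screens require),
nonselective (0.2 everywhere), inert (no effect).

**Noise.** OD600 reads carry additive Gaussian noise, sd 0.01 OD —
typical culture-plate read scatter, and small enough that curve shapes
stay visually smooth at this scale. A340 kinetic reads use sd 0.003 AU;
photometric kinetic measurements are quieter than culture turbidity
reads. The enzyme signal is $A_0 = 1.24$ (200 µM NADH at 1 cm with
$\varepsilon = 6.22$), and the uninhibited rate 0.01 /min consumes about
15% of the NADH over the 20-min recording — an assay designed to stay in
its initial-rate regime, which is also the regime in which the
expanding-window estimator meets its accuracy contract (initial rates
within 10% of the analytic slope).

**Plates.** 384-well layout with columns 1, 2, 23 as negative controls,
24 as blanks, 320 compound wells; endpoint reads at 16 h and 48 h taken
from the same curve model; control plates alternate rows for z-factor
estimation.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: spatial plate effects (edge
evaporation, row/column gradients; the scoring deliberately applies no
spatial correction), instrument drift and carryover, substrate-depletion
mechanics (phases are phenomenological logistics, not Monod kinetics),
compound degradation over the 48 h incubation, and anything about the
actual chemical matter of a physical library. Parameter recovery on
synthetic data demonstrates correctness of the estimators under the
stated noise model, not robustness to artifacts the model excludes.

# Reproducibility and problem sizes

Every random draw descends deterministically from a single seed: the
generators draw noise under `withr::with_seed`, multi-starts jitter under
derived child seeds, and `runScreen()` derives all stage seeds from the
manifest seed, so two runs with the same configuration are bit-identical.
The test suite exercises the pipeline at sizes chosen to give tight
statistical assertions in tens of seconds per file: one 320-compound
plate per screen, 100-curve recovery ensembles, a 56-compound Stage-II
set (12 mutant-selective, 2 reference-selective, 42 nonselective), and
100-fit dose-response bias ensembles. `scripts/acceptance.R` re-runs the
whole analysis from scratch at the same sizes plus the full
three-repetition enzyme design.

# Known limitations

* At most two growth phases; triauxic growth or post-diauxic drift will
  be absorbed into the closest 2-phase description.
* The maximal rate of a strongly inhibited culture is reported but
  imprecise (see the threshold discussion); consumers should weight
  $\Delta S$ accordingly, as the default thresholds do.
* The enzyme initial-rate estimator carries a small negative bias
  (window-averaged slope of a convex decay); at the default assay design
  it stays within the stated 10% contract, and IC50s inherit a
  correspondingly small positive bias that three-repetition averaging
  keeps well inside a 25% envelope.
* Differential calls are made per concentration with no multiplicity
  control across compounds; the screen's own Stage-II/III retesting is
  the confirmation device, matching screening practice.
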