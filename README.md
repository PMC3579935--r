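# DiffGrowthScreen

Analytics for three-stage differential growth-inhibition screens using an
SDH-deficient yeast model.

## The problem

Cells that have lost succinate dehydrogenase (SDH, Complex II of the
mitochondrial respiratory chain) cannot run the TCA cycle and survive on
glycolysis alone — the metabolic state that defines SDH-mutant
paraganglioma. A haploid *sdh2*-null yeast strain reproduces this state:
it grows on fermentable carbon, stalls exactly at the diauxic shift on
mixed media, and cannot grow on glycerol. Compounds that inhibit the
mutant **more** than its wild-type parent exploit the tumour-defining
lesion and are candidate leads.

`DiffGrowthScreen` is the analysis pipeline for such a screen, for
screening facilities and chemical-genomics groups:

1. **Stage I — plate screening.** Per-well percent inhibition
   `PI = 100 (1 − (test − blank)/(control − blank))` from long-format
   plate-reader CSVs, z-factor QC
   `z = 1 − 3(σ_p + σ_n)/|µ_p − µ_n|` from alternating-row control
   plates, explicit-threshold hit calling, and exact mass-balance
   arithmetic for nanolitre droplet dispensing.
2. **Stage II — differential growth curves.** Mono/biphasic (diauxic)
   growth fitting `OD(t) = b + Σ K_i / (1 + exp(−r_i (t − m_i)))`
   reporting per phase the saturation `S = K`, maximal rate `R = rK/4`
   (OD/h) and lag `L = m − 2/r`; differential scores
   `ΔS = S_ref,drug/S_ref,ctrl − S_mut,drug/S_mut,ctrl` (likewise ΔR,
   and ΔL with the mutant first), positive = mutant hit harder; calls of
   mutant-selective / reference-selective / nonselective.
3. **Stage III — marker concordance.** Confirms that wild type and a
   marker-cassette control strain respond identically, excluding
   resistance-cassette artifacts.
4. **Dose-response.** Four-parameter log-logistic IC50 fitting for
   whole-cell growth and for alcohol-dehydrogenase inhibition measured as
   NADH-depletion (A340) initial rates, with serial-dilution design
   utilities and strain fold-ratios.

A synthetic-data generator with exact ground truth (strain archetypes,
Hill-model drug effects, 384-well plate layouts, enzyme progress curves)
drives validation end to end; no external data are required.

## Worked example

Run the full three-stage screen on a simulated 320-compound plate whose
truth table contains 12 mutant-selective, 2 reference-selective and 6
nonselective inhibitors:

```r
library(DiffGrowthScreen)
run <- runScreen(defaultScreenConfig(seed = 42))
screenReport(run)
```

```
=== Differential growth-inhibition screen ===

Screening funnel:
 count                              characteristic
   320          total compounds initially screened
    20  inhibit mutant at 10 uM (PI >= 40 at 48 h)
    14 differential effect on mutant vs. reference
    12        mutant inhibited more than reference
     2        reference inhibited more than mutant
    13     confirmed against marker-control strain

Plate QC (z-factors):
 plate_id read_time_h  z_factor n_pos n_neg suitable
    CTRL1          16 0.9024296   120   144     TRUE
    CTRL1          48 0.8854596   120   144     TRUE

Differential calls:
 compound_id  delta_S  delta_R  delta_L                call
    cmpd0193  0.74289  0.15959 -0.05784    mutant_selective
    cmpd0118  0.75087       NA       NA    mutant_selective
    ...
    cmpd0160 -0.40621       NA       NA reference_selective
    cmpd0216 -0.39756       NA       NA reference_selective
```

Reading this: all 20 true inhibitors clear the explicit PI ≥ 40% cutoff
(the null wells sit at 0 ± 2%), the control plate's z-factors ≈ 0.89 mark
the assay as comfortably screenable (> 0.5), and the quadruple growth
fits recover the 12/2 selective split exactly — a mutant-selective
compound shows ΔS ≈ +0.75 (the reference keeps ~90% of its growth, the
mutant ~15%), a reference-selective one ΔS ≈ −0.40. `NA` rate/lag deltas
mark cultures inhibited below 15% of control saturation, whose kinetics
are not reliably quantifiable; 13 of the 14 differential compounds are
concordant on the marker strain, the one flag being a near-complete
inhibition edge case noted in the report.

Single components are just as accessible:

```r
gc  <- genGrowthCurve(strainArchetype("wt"), cfg = simConfig(seed = 7))
fit <- fitGrowth(gc)           # 2 phases; S, R, L per phase
plot(gc, fit)

rec <- genEnzymeAssay(3.8, dilution = serialDilution(62.5, 5, 8),
                      replicates = 4,
                      cfg = simConfig(seed = 12, noise_sd = 0.003))
enzymeInhibitionIC50(rec)$fit  # IC50 back within a few percent
```

A command-line wrapper over the same functions is installed at
`system.file("scripts", "screen.R", package = "DiffGrowthScreen")`
(subcommands `simulate`, `score`, `fitgrowth`, `ic50`, `enzyme`, `run`,
`report`).

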