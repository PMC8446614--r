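# perfquant

Fully automated quantification of myocardial blood flow (MBF) from
dual-bolus, dynamic contrast-enhanced **stress perfusion cardiac MR**, for
cohorts in which coronary disease (e.g. aneurysms after Kawasaki disease,
stenoses, anomalous origins) may regionally limit hyperemic flow. The
package turns a multi-slice short-axis perfusion series plus LV-blood-pool /
myocardial / RV masks into pixel-wise MBF maps, AHA-segment and
coronary-territory scores, and nonparametric group statistics — and ships a
synthetic dual-bolus phantom and cohort generator with known ground truth so
every stage is testable without patient data.

## The model

Tissue enhancement is described by the **two-compartment exchange model
(2CXM)**: a plasma compartment (volume fraction *v*<sub>p</sub>) supplied by
plasma flow *F*<sub>p</sub> exchanges tracer with the interstitium
(*v*<sub>e</sub>) at permeability–surface-area product *PS*:

    vp dCp/dt = Fp (Ca − Cp) + PS (Ce − Cp)
    ve dCe/dt = PS (Cp − Ce),      Ct = vp Cp + ve Ce

The tissue residue function is biexponential,
*R*(*t*) = *A* e^(λ₊t) + (1−*A*) e^(λ₋t) with *R*(0) = 1 and
∫*R* = (*v*<sub>p</sub>+*v*<sub>e</sub>)/*F*<sub>p</sub>, and the model
tissue curve is *C*<sub>t</sub>(*t*) = *F*<sub>p</sub> · (*C*<sub>a</sub> ∗
*R*)(*t*). Each myocardial pixel's curve is fitted by bounded
Levenberg–Marquardt least squares with multi-start initialization; MBF in
ml/min/g is *F*<sub>p</sub>/ρ with myocardial density ρ = 1.05 g/ml.

The arterial input comes from a **dual-bolus** scheme: a diluted pre-bolus
(10% of the dose) measured in the linear signal regime is rescaled by the
inverse dose fraction and time-aligned to the main-bolus arrival, both
arrivals being detected automatically on the LV blood-pool curve. Pixels are
assigned to the 16 standard AHA segments from automatically detected RV
insertion points, segments map to LAD/RCA/LCx territories, and each
territory is scored as the **mean of its two lowest segment means**. Group
comparisons use median/IQR summaries and the Mann–Whitney U test (exact
enumeration for small samples, tie-corrected normal approximation
otherwise).

## Worked example

A noiseless phantom with the LAD territory hypoperfused at 1.3 ml/min/g
against a 2.5 ml/min/g background, run end to end, then a synthetic
territory cohort parameterized by the emulated study's group summaries:

```r
library(perfquant)

cfg    <- phantomConfig(gridSize = 64, noiseSd = 0, seed = 1)
report <- runPipeline(runConfig(cfg, seed = 1))
report
#> perfquant run: 1/1 scans completed (0.2 s, seed 1)
#> territory MBF (ml/min/g):
#>  scan_id territory territory_mbf n_segments
#>  scan001       LAD      1.292821          6
#>  scan001       RCA      2.446291          5
#>  scan001       LCx      2.489012          5

coh  <- generateCohort(cohortConfig(seed = 1))
compareGroups(coh)[, c("group_a", "group_b", "median_a", "median_b",
                       "U", "p_value", "significant")]
#>          group_a        group_b median_a median_b  U      p_value significant
#> 1       affected         normal 1.239959 2.633314 23 6.249554e-06        TRUE
#> 2       affected small_aneurysm 1.239959 2.508877  0 3.685685e-05        TRUE
#> 3 small_aneurysm         normal 2.508877 2.633314 67 8.155175e-01       FALSE
```

The territory table recovers the configured truth: the hypoperfused LAD
scores 1.29 ml/min/g (0.5% from its true 1.3 — the small deficit versus the
normal territories reflects the deliberately lower-tail two-lowest-segments
rule). In the cohort comparison, the affected group's flow deficit is highly
significant against both other groups while the small-aneurysm group is
indistinguishable from normal, mirroring the clinical contrast the
generator emulates.

## Command line

A thin wrapper over the package functions lives at
`inst/scripts/perfquant`:

```sh
perfquant simulate --out phantom/ --seed 1        # write a phantom (NIfTI + CSV)
perfquant run      --out run/     --seed 1        # end-to-end pipeline
perfquant cohort   --out cohort.csv               # synthetic cohort table
perfquant stats    --cohort cohort.csv            # group comparisons
```
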