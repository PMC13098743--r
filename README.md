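# rbctdo

Hybrid diffuse-optics analysis of red blood cell transfusion (RBCT)
sessions in critically ill patients.

Anemic ICU patients routinely receive red-cell transfusions, yet how a
transfusion changes oxygen delivery and consumption in the brain versus
peripheral muscle is hard to observe at the bedside. Hybrid diffuse optics
answers this non-invasively with two co-located instruments: time-resolved
near-infrared spectroscopy (TRS), which records photon time-of-flight
histograms at 690/830 nm and yields absolute absorption and scattering —
hence microvascular oxy-/deoxy-hemoglobin concentration and tissue oxygen
saturation StO₂ — and diffuse correlation spectroscopy (DCS), which turns
the temporal speckle fluctuations of 785 nm light into a microvascular
blood-flow index (BFI). `rbctdo` is a complete, tested re-implementation of
that analysis pipeline for researchers in biomedical optics and
neurocritical-care monitoring.

The chain, per subject:

1. **Forward models** — semi-infinite extrapolated-boundary time-domain
   diffusion for TRS and the Brownian correlation-diffusion solution for
   DCS (`td_reflectance()`, `dcs_g1()`, `siegert_g2()`).
2. **Inverse fitting** — Poisson-weighted fits of IRF-convolved DTOFs for
   (μa, μs′) and joint (BFI, β) fits of g₂ curves, via a compiled
   Levenberg–Marquardt core (`fit_dtof()`, `fit_g2()`,
   `chromophores_from_mua()`).
3. **Quality control** — TRS rejected at SNR ≤ 10; DCS below 10 kHz count
   rate or β < 0.4; event-marked artifact intervals removed
   (`trs_snr()`, `qc_trs()`, `qc_dcs()`, `apply_masks()`).
4. **Biomarkers** — 10-s binning, OEF from StO₂ via a venous-compartment
   estimate, and the hematocrit-corrected metabolic rate of oxygen
   `MRO₂ = BFI × OEF × CaO₂`, `CaO₂ = 1.36 × Hgb × SaO₂`,
   `Hgb = HCT/100 × MCHC/10`, with hematocrit held constant within each
   protocol period (`mro2_trace()`, `relative_trace()`, `delta_trace()`).
5. **Statistics** — per-subject pre/post window means, one-sided Wilcoxon
   signed-rank tests of the relative change (exact tied-rank null up to
   n = 25), paired pre/post and cerebral-vs-peripheral contrasts, and
   report tables (`signed_rank_test()`, `analyze_cohort()`).

A seeded synthetic-session generator (`make_ground_truth()`,
`simulate_raw()`, `generate_cohort()`) emulates the monitoring protocol
(30 min baseline, 2–3 h transfusion, 30 min post, three timed blood draws)
and the cohort effect sizes (peripheral blood flow +68%, OEF down 7–8% at
both sites, null deoxy-hemoglobin change, hematocrit 24.5 → 27.4%), so the
whole pipeline runs and is tested without any patient data. The clinical
table of the 15-subject pilot cohort is bundled
(`clinical_cohort()`) for the blood-gas statistics.

## Worked example

Blood-gas statistics of the bundled clinical cohort:

```r
library(rbctdo)
st <- clinical_cohort_stats()
print(st$hgb$test)
#> hgb [NA, paired_prepost]: n = 13, V = 91, p = <0.001 ↑
```

Hemoglobin rises from 8.1(0.48) to 9.1(0.56) g/dL (mean(SD), n = 13
subjects with blood data); all 13 paired differences are positive, so the
exact one-sided signed-rank p-value is 2⁻¹³ ≈ 1.2e-4, reported as
`<0.001`, and the median-based change is +0.9 g/dL.

A small synthetic study, end to end (6 subjects, shortened protocol):

```r
an <- run_synthetic_study(seed = 7, n_subjects = 6, missingness = FALSE,
  protocol = protocol_spec(baseline_min = 10, transfusion_min = 30,
                           post_min = 10, draw_offset_min = 3))
print(an)
#> Transfusion cohort analysis (n = 6 subjects)
#>
#> Blood-gas variables, pre vs post (paired Wilcoxon):
#>  variable        pre        post dir     p
#>       hgb 8.284(0.5) 9.675(0.72)   ↑ 0.031
#>       hct 24.26(1.8)   28.3(2.1)   ↑ 0.031
#>     paco2 40.81(5.2)    42.23(7)   -  0.22
#>
#> Post-transfusion tests (one-sided vs baseline; two-sided site contrast)
#>  variable cerebral_p cerebral_dir peripheral_p peripheral_dir cer_vs_per_p
#>      rbfi       0.84            -        0.016              ↑        0.031
#>      roef      0.016            ↓        0.016              ↓         0.69
#>     rmro2       0.16            -        0.016              ↑        0.031
#>     dhbo2      0.047            ↑        0.016              ↑            1
#>      dhhb       0.28            -         0.42              -         0.56
#>      dhbt       0.22            -        0.016              ↑            1
```

Reading the table: after the (simulated) transfusion, blood flow rises
significantly only in the peripheral muscle, the oxygen extraction fraction
falls at both sites, deoxy-hemoglobin does not change, and the metabolic
rate of oxygen increases more peripherally than cerebrally — the
physiological signature the generator is programmed to emulate. With six
subjects the exact one-sided signed-rank floor is 2⁻⁶ ≈ 0.016.

A command-line wrapper over the same functions lives in `inst/cli/rbctdo.R`
(`simulate` / `process` / `analyze` / `report` subcommands); session bundles
are plain-text directories (CSV + JSON) written and read by
`write_bundle()` / `read_bundle()`.

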