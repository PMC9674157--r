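# radpoi

Predicts the age at **premature ovarian insufficiency (POI)** for female
cancer patients from two inputs: the age at radiotherapy and the dose
received by the least-affected ovary. It is intended for clinicians and
medical physicists counselling young patients on fertility risk and comparing
photon versus proton treatment plans by their effect on the fertile window.

## The model

The ovarian reserve — the population of non-growing follicles (NGFs) — is
fixed at birth and declines until natural menopause, taken to occur when
fewer than 1,000 NGFs remain. The mean reserve at chronologic age *a* follows
the Wallace–Kelsey asymmetric double-Gaussian cumulative curve

    log10 NGF(a) = 5.56 · Φ((a − (25.6 − 52.72/2)) / 0.0742)
                        · [1 − Φ((a − (25.6 + 52.72/2)) / 24.52)]

(Φ = standard normal CDF), giving ≈292,000 NGFs at birth, ≈106,000 at age 20
and a menopause-threshold crossing at 49.5 years. Individual variation is a
z-score offset in log10 space, calibrated so the ±1.96 band reproduces a
4-year SD in age at natural menopause. Radiation kills NGFs by a single-hit
exponential, S(d) = 2^(−d/LD50) with LD50 = 2 Gy (overridable). After a dose,
the patient is mapped to the **equivalent age** at which a healthy ovary
holds the same count, then ages forward along the healthy curve:

    POI(a, d, z) = a + [ T_z − equivalent_age(a, d, z) ]

where T_z is the z-track's natural menopause age. The package also computes
the mean sterilizing dose (z = 0) and effective sterilizing dose
(ESD, z = +1.96), LD50 · log2(NGF(a, z)/1000), reads per-ovary dose-summary
tables, compares treatment plans, and draws calculator-style charts.

## Worked example

A 5-year-old receiving 0.8 / 1 / 1.4 Gy (min / mean / max) to the
least-affected ovary:

```r
library(radpoi)
w <- predict_window(exposure_scenario(5, 0.8, 1, 1.4))
w
#> POI prediction for treatment at age 5 y (photon, LD50 2 Gy)
#> Dose to least-affected ovary: min 0.8 / mean 1 / max 1.4 Gy
#> Predicted age at POI (mean dose, average reserve): 41.8 y
#> Dose range (z = 0): 39.6 - 43.0 y
#> 68% window (z = -1 to +1, mean dose): 37.7 - 45.8 y
#> Years of reproductive lifespan lost (mean dose, z = 0): 7.7
#> Caveat: concurrent chemotherapy is additive in an unquantified way;
#> predictions are an upper limit on the fertile window.
```

The mean-dose prediction says POI at 41.8 years — about 7.7 years of
reproductive lifespan lost relative to the model's natural menopause age of
49.5 — and the 68% window (37.7–45.8 y) spans the natural variation in
reserve. The same engine at 12 Gy predicts POI at age 11.8, i.e. essentially
at treatment, flagging fertility preservation. The same predictions are
available from the shell via the bundled script:

```sh
Rscript inst/exec/radpoi predict --age 5 --dose-min 0.8 --dose-mean 1 \
    --dose-max 1.4 --format text
Rscript inst/exec/radpoi esd --output esd.png
```

Plan comparison from a per-ovary dose table (CSV with columns
`patient_id,plan_label,ovary_side,modality,dose_min_gy,dose_mean_gy,dose_max_gy`):

```r
recs <- read_dose_summary("doses.csv")
compare_plans(recs, age = 3)   # best plan first; flags POI before age 30
```

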