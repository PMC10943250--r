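# holopolar

Simulation and analysis pipeline for **3D polarization-interference
holographic histology** of birefringent fibrillar tissue — the optical
method that records analyzer-resolved off-axis interferograms of a
histological section under circular laser probing, reconstructs the
complex object field by Fourier-sideband demodulation, isolates the
singly scattered light by phase-section scanning, and grades pathology
from scale-selective Mexican-hat wavelet markers of the polarization
azimuth and ellipticity maps.

For whom: researchers in tissue polarimetry and quantitative histology
who want a fully synthetic, reproducible testbed of the method — every
stage from the Mueller/Jones algebra of the birefringent layer to the
sensitivity/specificity report is implemented and tested against
independent oracles, with seeded phantoms standing in for the (not
publicly deposited) cadaveric specimens.

## The model in brief

A fibrous protein network is locally a linear retarder with axis
orientation ρ and retardance δ = 2πΔn·d/λ.  Probing with a right-circular
beam S₀ = (1, 0, 0, 1) yields, for single scattering,

    S' = (1, sin2ρ sinδ, cos2ρ sinδ, cosδ),
    α  = ½ atan2(s₃, s₂)          (azimuth of the polarization ellipse)
    β  = ½ asin(s₄ / s₁)          (ellipticity)

so α maps fibril orientation and, in the probe-referenced convention
β∘ = π/4 − β = δ/2, the ellipticity maps half the retardance.  Multiply
scattered light accumulates inter-component phase; the cumulative phase
sections δt select pixels by their deviation from the circular baseline
|atan2(s₃, s₄)|, and the single-scattering plane δt★ is the largest bound
below which the four statistical moments Z₁–Z₄ of both maps stop
changing.  Row-wise MHAT wavelet decomposition ψ(x) = (1−x²)e^(−x²/2) of
the maps gives per-scale markers Z₁(a), Z₂(a); the scales separating two
specimen groups are selected by a standardized between-group score, and a
leave-one-out midpoint classifier reports Se = A/N, Sp = B/H,
Ac = (A+B)/(N+H) with the five-level grading scale (≤80 Unsatisfactory …
>95 Excellent).

## Worked example

```r
library(holopolar)

## single-scatter algebra: a retarder with rho = pi/6, delta = pi/2
S <- apply_mueller(lb_mueller(pi / 6, pi / 2), stokes_circular())
round(as.numeric(S), 4)
#> [1] 1.000 0.866 0.500 0.000
stokes_to_polarization(S)
#> polarization state: alpha = 0.261799 rad, beta = 0.000000 rad
# alpha = pi/12, exactly 0.5*atan(cot(pi/3))

## full cohort benchmark: 12 + 12 synthetic myocardium specimens
## (ACI experimental vs CHD control), entire optical chain per specimen
cfg <- run_config(seed = 1, n_per_group = 12, size = 256)
res <- run_cohort(cfg)
res$selection$a_min
#> [1] 20
res$report
#> marker Z2@a=20/beta: Se 100.0%, Sp 100.0%, Ac 100.0% (Excellent) [balanced]
```

The selected small scale (≈15–20 px) matches the programmed 15–20 µm
fibril widths at 1.16 µm/px, and the small-scale variance of the
ellipticity map is the strongest marker — the same ranking the method
reports on real myocardium.  With `seed = 7` the same benchmark selects
a_min = 15 and reaches Ac = 95.8% ("Excellent").

## Command line

A thin launcher is shipped in `inst/cli/holopolar`:

```sh
holopolar simulate    --preset aci --seed 7 --size 256 --out phantom/
holopolar record      --field phantom/field_single --ref 2 --out pair/
holopolar reconstruct --in pair/ --out rec
holopolar scan        --field rec --dstep 0.0785 --tol 0.05 --out scan.json
holopolar wavelet     --map map.txt --scales 2:60 --out stats.csv
holopolar classify    --markers table.csv --marker Z2@a=15/beta --out report.json
holopolar pipeline    --preset aci --control chd --seed 1 --n 12 --out run/
```

Interferograms travel as plain-text PGM with a JSON sidecar; fields and
maps use a self-describing text array container; markers and scale
statistics are CSV.

## Package layout

- `R/polarization-optics.R` — Stokes/Mueller/Jones algebra of the
  linear-birefringence layer
- `R/phantom.R` — seeded fibrillar-tissue phantoms, scattering cascades,
  depolarized speckle background
- `R/holography.R` — off-axis recording and Fourier-sideband demodulation
- `R/phase-scan.R` — phase-section scanning, moments, δt★ detection
- `R/wavelet.R` — row-wise MHAT CWT, per-scale markers, scale selection
- `R/diagnostics.R` — Se/Sp/Ac, grading, leave-one-out classification
- `R/io.R`, `R/pipeline.R`, `R/cli.R` — formats, configuration, the
  end-to-end pipeline and the command line

The methods vignette (`vignettes/methods.Rmd`) documents the model, the
phantom's assumptions and limits, and every numerically consequential
design choice.
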