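# kiwitrts

Time-resolved transmittance spectroscopy (TRTS) analysis of fruit softening
during postharvest storage, built as an R package plus a small analysis
workflow.

## The problem

Kiwifruit soften dramatically after harvest while their skin color barely
changes, so conventional colorimetry is a poor ripeness monitor. TRTS sends
picosecond NIR laser pulses through the whole fruit and histograms the
arrival times of the transmitted photons (a time-resolved profile, TRP).
Because the shape of that histogram separates light *scattering* from light
*absorption*, it gives direct access to the reduced scattering coefficient
μs′ of the flesh — a quantity that tracks the mechanical breakdown of cell
walls during softening. This package implements the full analysis chain for
such experiments, for researchers in biophotonics and postharvest quality
assessment:

1. **Forward model** — time-domain transmittance of a homogeneous slab in
   the diffusion approximation, with extrapolated-boundary dipole image
   sources:

   T(ρ,t) = exp(−μa·v·t − ρ²/4Dvt) / (2(4πDv)^{3/2} t^{5/2}) ·
   Σₘ [ Z₁,ₘ exp(−Z₁,ₘ²/4Dvt) − Z₂,ₘ exp(−Z₂,ₘ²/4Dvt) ]

   with Z₁,ₘ = s(1−2m) − 4m·zₑ − z₀, Z₂,ₘ = s(1−2m) − (4m−2)·zₑ + z₀,
   z₀ = 1/μs′, D = 1/(3μs′), zₑ = 2AD, v = c/n, truncated at |m| ≤ 3
   (seven dipoles). Defaults: A = 2.58, n = 1.34, ρ = 0.
2. **Inverse fit** — bounded nonlinear least squares of the IRF-convolved
   model against a measured TRP, estimating (μa, μs′) with
   μs′ ∈ [0.1, 10] mm⁻¹ and μa ∈ [0.0001, 0.1] mm⁻¹ plus a free amplitude.
3. **Study analysis** — Savitzky–Golay smoothing (order 2, frame 5), day-0
   difference spectra, color indexes (Chroma, Hue, a*/b*), and per-sample
   Pearson correlations of every parameter with storage time.
4. **Staging** — PCA of the difference spectra, firmness-tertile softening
   classes (class 1 = firmest), and a five-fold cross-validated linear SVM.
5. **Synthetic studies** — a generator that renders complete two-condition
   storage trials (shelf life vs cold storage) as Poisson-sampled TRPs from
   latent μs′ trajectories, so the whole pipeline is testable end to end.

The package also bundles reference optical-property tables (ten fruit × 8
days per storage condition) from a published kiwifruit storage experiment,
so the storage-time correlation analysis can be reproduced from printed
data.

## Worked example

```r
library(kiwitrts)

# forward model + instrument
grid <- default_time_grid()                        # 0-5 ns, 10.3 ps bins
irf  <- make_gaussian_irf(grid, fwhm = 159.83)
geom <- slab_geometry(thickness_s = 51)            # fruit diameter, mm
model <- transmittance_curve(grid_times(grid),
                             optical_properties(mu_a = 0.010, mu_s_prime = 0.60),
                             geom)

# synthesize a measured TRP and fit it back
y <- trp(grid, simulate_counts(convolve_with_irf(model, irf, grid), 1e6, 42))
fit <- fit_optical_properties(y, irf, geom)
fit$props$mu_s_prime   # 0.6006029
fit$props$mu_a         # 0.01001933

# published storage series: correlation of scattering with storage time
shelf <- reference_optical_table("shelf")
s1 <- shelf[shelf$sample_id == 1, ]
correlate_with_time(s1$day, s1$mu_s_prime)   # -0.7375557
```

The fitted μs′ lands within 0.1% of the generating value at 10⁶ detected
photons, and the first reference fruit's scattering coefficient declines
with storage day at r ≈ −0.74: softening shows up as a steady loss of
light scattering.

The `analysis/` directory holds the narrative workflow over these
functions — run from the repository root, each writes tables under
`results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic study -> results/study/
Rscript analysis/02_fit.R         # per-TRP optical fits + truth benchmark
Rscript analysis/03_correlations.R
Rscript analysis/04_staging.R     # PCA + SVM softening stages
```

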