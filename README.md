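# recoilrange

Secondary-neutron range verification for proton therapy, end to end in
simulation: a fast synthetic Monte-Carlo generator of secondary-neutron
production and detection in a proton-recoil telescope, the iterative
acceptance/rejection back-projection reconstruction of the neutron
production depth distribution, and the range-landmark machinery that turns
it into a beam-range estimate with uncertainties.

## The problem and the method

The finite range of a therapeutic proton beam is its main selling point and
its main uncertainty: millimetres of range error force margins that
irradiate healthy tissue. One proposed way to verify the range *during*
delivery is to watch the secondary neutrons produced by nonelastic nuclear
interactions along the beam path in tissue. A hydrogen-rich converter slab
placed beside the phantom converts some of those neutrons to recoil protons
via (n,p) scattering; two tracking planes behind it measure each proton's
line of flight (a proton recoil telescope).

From the detected proton tracks, the reconstruction estimates where along
the beam axis the parent neutrons were produced:

1. back-project every track onto the *image plane* containing the beam
   axis; compute the ensemble mean (μ_u, μ_v) and standard deviations
   (σ_u, σ_v) of the projections;
2. define a sampling region of radius max_i d_i in the weighted metric
   d = √(((u−μ_u)/σ_u)² + ((v−μ_v)/σ_v)²);
3. for each track, sample M = 5000 candidate neutron directions (polar
   angle θ ~ U(0, π/2) off the proton direction, azimuth uniform), accept
   each against the empirical direction-cosine prior of detected neutrons
   (rejection sampling), back-project the survivors, keep those inside the
   region and the phantom's lateral extent, and average them;
4. summarize the estimated production depths u by the range landmark
   **β = μ_rec + σ_rec**, which increases linearly with the beam range R80
   (depth of distal 80% dose).

The repetition uncertainty σ_β (sample standard deviation of β over ten
independent runs) quantifies the precision at a given beam intensity.

All inputs are generated: the packaged 160/200/230 MeV beam configurations
reproduce calibrated per-primary neutron yields (0.08/0.13/0.18) and
detection rates (1.4/2.5/3.2 × 10⁻⁵), with forward-peaked angular
distributions, evaporation-plus-tail energy spectra bounded by the local
proton energy, and depth-dependent production that stops just proximal to
the Bragg peak. See `vignette("range-verification-methods")` for the full
model and its limitations.

## Worked example

```r
library(recoilrange)

beam <- beam_config("200MeV")
geom <- default_geometry(beam)

# dedicated calibration run -> direction-cosine prior of detected neutrons
calib <- simulate_run(beam, geom, 2e8, seed = 99, rate_based = TRUE)
prior <- estimate_prior(calib)
prior
#> <direction_prior> 50 bins, 5098 events, mode at u_x = 0.78, max density 2.30

# one treatment-spot-scale run (5e7 primaries) and its reconstruction
run <- simulate_run(beam, geom, 5e7, seed = 2, rate_based = TRUE)
rec <- reconstruct_all(run$events, prior, recon_options(seed = 3), geom)
rec$landmark
#> <landmark> beta = 17.710 cm (mu = 12.815, sigma = 4.895, n = 1243)
landmark(run$events$parent_x)   # ground truth for the same events
#> <landmark> beta = 18.067 cm (mu = 11.915, sigma = 6.151, n = 1243)
```

The reconstructed landmark (β = 17.71 cm) sits a few millimetres from the
ground-truth landmark of the same events (18.07 cm), both well proximal of
the 25.9 cm beam range; the reconstructed spread (4.90 cm) is smaller than
the true spread (6.15 cm) — the documented compression of the
prior-rejection step. Across beams, β rises strictly and almost linearly
with R80 (R² ≈ 0.99 over a 14–30 cm sweep, `range_sweep()`), which is what
makes it usable as a range proxy.

The whole pipeline (simulate → calibrate prior → reconstruct → analyze,
with artifacts and a JSON summary) runs from a YAML config:

```r
run_pipeline(default_config("200MeV"), "out/")
```

or from the shell via the thin CLI in `inst/cli/recoilrange`.

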