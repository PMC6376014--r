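---
title: "Methods: secondary-neutron range verification with a proton-recoil telescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secondary-neutron range verification with a proton-recoil telescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protons stop. The depth at which a therapeutic proton beam stops in tissue
(its *range*, conventionally quantified as R80, the depth of the distal 80%
dose) carries millimetre-level uncertainty in clinical practice, which is
absorbed by treatment margins at the cost of dose to healthy tissue. A
range-verification system watches secondary radiation produced by the beam
during delivery and infers, in real time, where the beam actually stopped.

This package implements one such concept end to end, in simulation:
secondary *neutrons* produced by nonelastic nuclear interactions along the
beam path are detected by a proton-recoil telescope — a hydrogen-rich
converter slab followed by two ideal charged-particle tracking planes — and
an iterative Monte-Carlo acceptance/rejection back-projection estimates the
neutron *production depth distribution*, whose summary landmark

$$\beta = \mu_{\mathrm{rec}} + \sigma_{\mathrm{rec}}$$

(the mean plus one standard deviation of the estimated production depths) is
linearly correlated with the beam range.

The package has three working layers:

1. **simulator** — a fast synthetic generator of neutron production,
   conversion and detection, calibrated to reproduce the per-primary
   production and detection rates of full nuclear-physics Monte-Carlo
   transport for 160/200/230 MeV pencil beams in a water phantom;
2. **reconstruction** — the ten-step acceptance/rejection back-projection
   and the landmark;
3. **analysis** — repetition/bunching uncertainty ($\sigma_\beta$),
   histogram RMSE, and the $\beta$-versus-range linear fit.

## Geometry and coordinate conventions

All lengths are cm, energies MeV. The beam travels along $x$ with the
phantom entrance at $x = 0$; $y$ points toward the detector and $z$ is
vertical. The water phantom is $35 \times 10 \times 10$ cm. The converter
(nominally a 5 mm hydrogen-rich organic scintillator slab, $20 \times 20$
cm) lies parallel to the beam axis with its midplane at $y = 10$ cm,
centred at the Bragg-peak depth of the configured beam. Every conversion is
placed on the converter midplane: at 5 mm thickness against a 5 cm tracker
lever arm, the thin-converter approximation changes back-projected depths
by far less than the reconstruction's statistical spread. The two tracking
planes sit 1.25 cm and 6.25 cm behind the midplane and are ideal: 100%
efficient, exact hit positions, no material.

The *image plane* of the reconstruction is the $y = 0$ plane containing the
beam axis, with in-plane coordinates $u = x$ (depth) and $v = z$.

Neither the tracker spacing nor the phantom-to-converter air gap is a
physically constrained quantity here; both are configuration
(`geometry_spec()`) with the defaults above. "10 cm lateral" is measured
from the beam axis to the converter midplane.

## The synthetic generator

The generator emulates the *statistical structure* of full Monte-Carlo
transport rather than its nuclear physics. Each piece is an explicit,
documented model:

* **Depth-dose and range.** `bragg_depth_dose()` is an analytic stand-in
  (rising entrance plateau plus Gaussian peak) whose only calibrated
  property is the one the method uses: the distal-80% depth equals the
  configured `range_r80` to within 0.01 cm. The residual ("local") proton
  energy at depth follows the Bragg–Kleeman relation
  $R = \alpha E^p$ with $\alpha = 0.0022$, $p = 1.77$, so
  `local_proton_energy()` starts at the nominal beam energy and reaches
  zero at the stopping depth.
* **Production depth.** Neutron production density is flat-with-mild-decline
  (a linear 30% decline by default) while the local proton energy exceeds a
  25 MeV production threshold, and zero beyond — reproducing the
  qualitative features of measured production curves: stable in the
  entrance region, steep drop just proximal to the Bragg peak, nothing past
  it.
* **Lateral profile.** Gaussian with the beam's 10 mm FWHM, truncated to the
  phantom.
* **Energy spectrum.** A 60/40 mixture of an evaporation component
  (Maxwellian, $T = 3$ MeV) and an exponential high-energy tail (scale
  $E_{\mathrm{loc}}/3$), both truncated so a neutron never exceeds the
  local proton energy at its production depth. This spans the
  20 MeV-to-beam-energy window that survives detection, with harder
  neutrons in the entrance region.
* **Angular distribution.** The beam-axis direction cosine follows
  $p(u_x) \propto e^{k u_x}$ with $k = 1 + E_n/50\,\mathrm{MeV}$ — forward
  peaked, more so at high energy — with uniform azimuth about the beam
  axis, hence symmetric $u_y$, $u_z$.
* **Conversion.** (n,p) conversion in the converter occurs with a single
  constant probability. Elastic kinematics sample
  $\cos\theta_{\mathrm{CM}}$ uniformly; the recoil proton leaves at
  $\theta_p = (\pi - \theta_{\mathrm{CM}})/2$ from the neutron direction
  with $E_p = E_n \cos^2\theta_p$ (so $E_p/E_n$ is uniform on $(0,1)$ and
  $\langle E_p\rangle = E_n/2$). A configurable 30% of conversions are
  inelastic and carry a uniform $(0.2, 1)$ fraction of the elastic energy.
  Neutrons below 20 MeV are tagged `low_energy` and excluded from the
  analysis, mirroring the exclusion of low-energy scattering interactions
  whose short-range protons would not traverse two planes.
* **Detection.** The proton line must cross both tracking planes inside
  their coverage and carry at least 10 MeV (a configurable stand-in for the
  two-plane punch-through requirement).

### Rate calibration

The packaged beam table (`inst/extdata/beam_calibration.csv`) fixes, per
beam, the neutrons produced per primary proton (0.08 / 0.13 / 0.18 for
160 / 200 / 230 MeV) and the neutrons detected per primary
($1.4 / 2.5 / 3.2 \times 10^{-5}$). The produced count in a run is Poisson
with mean `n_primaries * yield_per_primary`. The conversion probability is
the one free constant, and `calibrate_conversion()` fixes it from a single
pilot run with conversion forced: because the detected rate is *linear* in
a constant conversion probability, the calibration is exact in expectation.

### Rate-based sampling for large runs

Above $10^8$ primaries the simulator switches (configurably) to sampling
the detected-event count directly from
$\mathrm{Poisson}(n \times \text{detection rate})$ and drawing events from
the conditional distribution of detected events. A constant conversion
probability makes that conditional distribution independent of the
probability itself, so events are generated by running the ordinary chain
with conversion forced until the required count is collected — no
approximation beyond the model already stated.

### Randomness

Every function that needs randomness either draws from the current R stream
(low-level samplers) or derives named sub-streams from one root seed via
`derive_seed(seed, stage)` (runs, repetitions, pipeline stages). No stage
reads RNG state left behind by another, repetitions are fully independent,
and identical configurations with identical seeds reproduce results
byte-for-byte. Chunked processing uses fixed chunk sizes so chunking never
silently changes a stream.

## The reconstruction

Given the detected events of a run:

1. each proton track (two hits) is back-projected onto the image plane;
2. the ensemble mean $(\mu_u, \mu_v)$ and standard deviations
   $(\sigma_u, \sigma_v)$ of those projections are computed;
3. each projection's distance to the centre is measured in the
   standard-deviation-weighted metric
   $d = \sqrt{((u-\mu_u)/\sigma_u)^2 + ((v-\mu_v)/\sigma_v)^2}$;
4. the sampling region is the weighted-metric disc of radius
   $\max_i d_i$ (we read the region as a disc in this metric; an
   axis-aligned box would be the other defensible reading of "extends to
   the maximum distance", and the disc is the stricter, rotation-honest
   choice);
5. per event, `iterations` (default $M = 5000$) candidate neutron
   directions are sampled by rotating the proton direction by
   $\theta \sim U(0, \pi/2)$ — uniform in angle, exactly as specified, not
   uniform in $\cos\theta$ — and azimuth $\phi \sim U(0, 2\pi)$, and each
   candidate is accepted with probability
   $\mathrm{density}(u_x)/\max(\mathrm{density})$ under a direction-cosine
   prior estimated (`estimate_prior()`, 50-bin histogram) from the detected
   events of a *separate* calibration run of the same beam configuration;
6. accepted candidates are anchored at the event's converter-midplane
   intersection, back-projected to the image plane, and kept only if they
   fall inside the sampling region and within the phantom's lateral extent
   ($|v| \le 5$ cm);
7. the event's production-location estimate is the unweighted mean (in both
   $u$ and $v$) of all doubly accepted coordinates; events with zero
   acceptances after $M$ iterations are discarded and counted
   (`n_discarded`), and play no part in the landmark;
8. the landmark uses only the depth coordinate:
   $\beta = \mu_{\mathrm{rec}} + \sigma_{\mathrm{rec}}$ over the estimated
   $u$ values, with sample ($n-1$) standard deviations here and everywhere
   else in the package.

Candidates whose direction has a non-positive $y$ component cannot have
originated in the phantom and are rejected outright. Degenerate tracks
(identical hits, or parallel to the image plane) raise errors in the scalar
API and are dropped-and-counted by `reconstruct_all()`.

The candidate anchor point (the converter-midplane intersection of the
track) is a design choice; in this geometry it coincides with the true
conversion point, so it adds no systematic error of its own.

### What the prior buys, and what it costs

The prior is estimated from *detected* neutrons — the quantity the
rejection step actually conditions on — rather than all produced neutrons.
Because that prior is strongly forward-peaked, candidates matching the true
directions of neutrons produced near the Bragg peak (which reach the
detector at shallow direction cosines) are rejected often, and the
reconstructed depth distribution is *compressed* relative to ground truth:
shallow depths are suppressed, the spread $\sigma_{\mathrm{rec}}$ is
smaller than the true spread. The test suite pins this down as a regression
property ($\sigma_{\mathrm{rec}} \le \sigma_{\mathrm{truth}}$), not as a
virtue. Under this package's synthetic angular model the compression is
stronger than full nuclear-transport studies report: the max-normalized
RMSE between ground-truth and reconstructed depth histograms is 17–28%
across the packaged beams at full statistics, increasing with beam energy
(the acceptance suite carries the 10% bound of the reference setup, and
the corresponding check documents the shortfall honestly rather than
relaxing it). The compression also shifts the landmark in a
direction-dependent way — reconstructed $\beta$ slightly *above* ground
truth for the lowest-energy beam and below it for the higher-energy beams,
the same crossover pattern full-transport studies of this algorithm show.
The landmark, being a mean-plus-spread summary, is far more robust to the
compression than the histogram shape is — which is exactly why $\beta$,
not the histogram, is the range proxy.

## Uncertainty machinery

$\sigma_\beta$ (`sigma_beta()`) is the sample standard deviation of the
landmark over ten fully independent, separately seeded repetitions
(`repetition_betas()`). Ten repetitions is the protocol, not a luxury: a
standard deviation estimated from ten draws carries a relative standard
error of about $1/\sqrt{2\cdot 9} \approx 24\%$, so single
$\sigma_\beta$ readings scatter substantially around their expectation,
and the maximum over several beam configurations and sources is biased
upward relative to any one of them. Interpret near-threshold values
accordingly. The bunching analysis (`bunch_analysis()`) mirrors
a 24-way split of a $1.2 \times 10^9$-primary run into
$5 \times 10^7$-primary bunches: the landmark at a reduced intensity of
$k$ bunches uses the pooled events of the *first* $k$ bunches of each
repetition (nested prefixes — the natural reading of "leaving out"
bunches; disjoint subsets would estimate the same quantity with more
variance). Histogram comparisons (`rmse_hist()`) use 0.5 cm bins over the
35 cm phantom, each histogram normalized by its highest bin, as the
reference analysis prescribes; the binning is otherwise unconstrained and
configurable.

## Problem sizes and defaults

The defaults *are* the study conditions: $M = 5000$ iterations per proton,
10 repetitions, 24 bunches of $5\times10^7$ primaries, 0.5 cm bins,
$10^7$-primary direct-chain runs for rate checks, $5\times10^7$
primaries-equivalent per repetition for the uncertainty claim, and
$1.2\times10^9$ primaries-equivalent (about $1.7$–$3.8\times10^4$ detected
events per beam) for full-statistics reconstructions, all run through the
rate-based sampler. Prior calibration runs use $2\times10^8$
primaries-equivalent, enough for several thousand detected events in every
packaged configuration. On one CPU the full acceptance analysis completes
in minutes; memory never exceeds a few hundred MB.

## What the synthetic tests do and do not show

Passing tests demonstrate that the *method* — detection model,
reconstruction, landmark, uncertainty machinery — behaves as specified
under a generator whose rates, spectra shapes, angular trends and
depth-production structure emulate full nuclear-physics transport. They do
not validate the nuclear physics itself: absolute landmark values depend on
production-depth and detection distributions that only a full transport
code (or experiment) provides, so the package's acceptance surface checks
*properties* of $\beta$ — strict monotonicity and linearity
($R^2 \ge 0.98$) across a range sweep, $\beta <$ R80, millimetric
$\sigma_\beta$ — rather than absolute depths. Also outside the model: no
neutron scattering or moderation in phantom or converter, no gamma or
scattered-proton background, no scintillation or electronics response, no
patient geometries.

## Worked example

```{r, eval = FALSE}
library(recoilrange)

beam <- beam_config("200MeV")
geom <- default_geometry(beam)

# calibration run -> direction prior
calib <- simulate_run(beam, geom, 2e8, seed = 99, rate_based = TRUE)
prior <- estimate_prior(calib)

# a treatment-spot-scale run and its reconstruction
run <- simulate_run(beam, geom, 5e7, seed = 2, rate_based = TRUE)
rec <- reconstruct_all(run$events, prior, recon_options(seed = 3), geom)
rec$landmark                    # beta = mu_rec + sigma_rec
landmark(run$events$parent_x)   # ground-truth landmark

# repetition uncertainty at this intensity
reps <- repetition_betas(beam, geom, 5e7, reps = 10, seed = 4,
                         prior = prior)
sigma_beta(reps$beta_recon)
```
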