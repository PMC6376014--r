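# Bragg-Kleeman range-energy relation R = alpha * E^p (R in cm water, E in MeV)
.bk_alpha <- 0.0022
.bk_p <- 1.77

bk_range <- function(energy_mev) .bk_alpha * energy_mev^.bk_p
bk_energy <- function(range_cm) (range_cm / .bk_alpha)^(1 / .bk_p)

#' Define a proton pencil-beam configuration
#'
#' A beam is described by its nominal energy, its range `range_r80` (depth of
#' the distal 80% dose), the lateral Gaussian profile FWHM, and two calibrated
#' per-primary rates: the number of secondary neutrons produced in the phantom
#' per primary proton (`yield_per_primary`) and the number of neutrons
#' detected in both tracking planes per primary proton
#' (`detection_rate_per_primary`).
#'
#' The remaining arguments parameterize the synthetic neutron-production
#' model (see the methods vignette): the production-depth density declines
#' linearly by a fraction `production_decline` from the entrance to the depth
#' where the local proton energy falls below `production_threshold_mev`; the
#' neutron energy spectrum is a mixture of an evaporation (Maxwellian)
#' component and a high-energy tail, both bounded by the local proton energy;
#' the direction-cosine density along the beam axis is `p(u) ~ exp(k u)` with
#' `k = forward_k0 + energy / forward_k_scale_mev`.
#'
#' @param label Character tag, e.g. `"200MeV"`.
#' @param range_r80 Depth of distal 80% dose, cm.
#' @param yield_per_primary Neutrons produced per primary proton, in (0, 1).
#' @param detection_rate_per_primary Detected neutrons per primary proton;
#'   must be positive and smaller than `yield_per_primary`.
#' @param energy_mev Nominal beam energy, MeV. Defaults to the Bragg-Kleeman
#'   energy for `range_r80`.
#' @param fwhm Lateral Gaussian full width at half maximum, cm.
#' @param production_decline Fractional linear decline of the production-depth
#'   density over the production region (dimensionless, in `[0, 1)`).
#' @param production_threshold_mev Local proton energy below which neutron
#'   production stops, MeV.
#' @param evap_weight Mixture weight of the evaporation component.
#' @param evap_temperature_mev Evaporation temperature, MeV.
#' @param tail_scale_fraction The high-energy tail is exponential with scale
#'   `tail_scale_fraction * E_local`.
#' @param forward_k0,forward_k_scale_mev Forward-peaking parameters.
#' @param inelastic_fraction Fraction of converter (n,p) interactions that are
#'   inelastic.
#' @param min_proton_energy_mev Minimum recoil-proton energy required to cross
#'   both tracking planes, MeV.
#' @return An object of class `beam_spec`.
#' @seealso [beam_config()] for the packaged calibrated beams,
#'   [bragg_depth_dose()], [local_proton_energy()].
#' @export
#' @examples
#' b <- beam_spec("200MeV", range_r80 = 25.9, yield_per_primary = 0.13,
#'                detection_rate_per_primary = 2.5e-5, energy_mev = 200)
#' b$peak_depth
beam_spec <- function(label, range_r80, yield_per_primary,
                      detection_rate_per_primary,
                      energy_mev = bk_energy(range_r80), fwhm = 1.0,
                      production_decline = 0.3,
                      production_threshold_mev = 25,
                      evap_weight = 0.6, evap_temperature_mev = 3,
                      tail_scale_fraction = 1 / 3,
                      forward_k0 = 1, forward_k_scale_mev = 50,
                      inelastic_fraction = 0.3,
                      min_proton_energy_mev = 10) {
  stopifnot(range_r80 > 0, fwhm > 0, energy_mev > 0,
            0 <= production_decline, production_decline < 1)
  if (!(yield_per_primary > 0 && yield_per_primary < 1))
    stop("yield_per_primary must lie in (0, 1)")
  if (!(detection_rate_per_primary > 0 &&
        detection_rate_per_primary < yield_per_primary))
    stop("detection_rate_per_primary must lie in (0, yield_per_primary)")
  beam <- structure(list(
    label = as.character(label),
    energy_mev = energy_mev,
    range_r80 = range_r80,
    fwhm = fwhm,
    yield_per_primary = yield_per_primary,
    detection_rate_per_primary = detection_rate_per_primary,
    production_decline = production_decline,
    production_threshold_mev = production_threshold_mev,
    evap_weight = evap_weight,
    evap_temperature_mev = evap_temperature_mev,
    tail_scale_fraction = tail_scale_fraction,
    forward_k0 = forward_k0,
    forward_k_scale_mev = forward_k_scale_mev,
    inelastic_fraction = inelastic_fraction,
    min_proton_energy_mev = min_proton_energy_mev
  ), class = "beam_spec")
  beam$stopping_depth <- bk_range(energy_mev)
  beam$production_cutoff <- beam$stopping_depth -
    bk_range(production_threshold_mev)
  beam$bp_sigma <- 0.015 * range_r80 + 0.10
  beam$peak_depth <- calibrate_peak_depth(range_r80, beam$bp_sigma)
  beam
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %s: E0 = %.1f MeV, R80 = %.2f cm, FWHM = %.2f cm\n",
              x$label, x$energy_mev, x$range_r80, x$fwhm))
  cat(sprintf("  yield/primary = %.3g, detected/primary = %.3g\n",
              x$yield_per_primary, x$detection_rate_per_primary))
  cat(sprintf("  Bragg peak at %.2f cm, production cutoff at %.2f cm\n",
              x$peak_depth, x$production_cutoff))
  invisible(x)
}

# Raw depth-dose shape for a given peak position: a slowly rising entrance
# plateau, smoothly switched off past the peak, plus a Gaussian Bragg peak.
dose_shape <- function(depth, peak_depth, sigma, range_r80) {
  plateau <- 0.30 * (1 + 0.6 * depth / range_r80) *
    stats::plogis((peak_depth - depth) / 0.25)
  peak <- exp(-(depth - peak_depth)^2 / (2 * sigma^2))
  d <- plateau + peak
  d[depth > peak_depth + 6.5 * sigma] <- 0
  d
}

# Distal depth at which the dose falls to 80% of its maximum.
distal80 <- function(peak_depth, sigma, range_r80) {
  grid <- seq(0, peak_depth + 6 * sigma, length.out = 2000)
  dmax <- max(dose_shape(grid, peak_depth, sigma, range_r80))
  f <- function(d) dose_shape(d, peak_depth, sigma, range_r80) - 0.8 * dmax
  stats::uniroot(f, lower = peak_depth, upper = peak_depth + 6 * sigma,
                 tol = 1e-8)$root
}

# Choose the Gaussian peak position so the distal-80% depth equals range_r80.
calibrate_peak_depth <- function(range_r80, sigma) {
  f <- function(dp) distal80(dp, sigma, range_r80) - range_r80
  stats::uniroot(f, lower = range_r80 - 3 * sigma - 1, upper = range_r80,
                 tol = 1e-7)$root
}

#' Relative depth-dose of the pencil beam
#'
#' Analytic stand-in for a proton Bragg curve: a slowly rising entrance
#' plateau plus a Gaussian peak, calibrated at construction of the
#' [beam_spec()] so that the depth of the distal 80% dose equals
#' `beam$range_r80` (the working definition of beam range). Dose units are
#' arbitrary (maximum close to the peak amplitude).
#'
#' @param depth Depth(s) in the phantom along the beam axis, cm; must be
#'   non-negative.
#' @param beam A [beam_spec()].
#' @return Relative dose, same length as `depth`; zero beyond the distal
#'   falloff.
#' @export
#' @examples
#' b <- beam_config("160MeV")
#' bragg_depth_dose(c(0, 10, b$range_r80, 30), b)
bragg_depth_dose <- function(depth, beam) {
  stopifnot(inherits(beam, "beam_spec"))
  if (any(depth < 0)) stop("depth must be non-negative")
  dose_shape(depth, beam$peak_depth, beam$bp_sigma, beam$range_r80)
}

#' Local (residual) proton energy at depth
#'
#' Residual energy of the primary protons at a given depth, from the
#' Bragg-Kleeman relation `R = alpha E^p`: `E(d) = ((R0 - d)/alpha)^(1/p)`
#' where `R0` is the stopping depth of the nominal beam energy. Equals the
#' nominal energy at the surface, decreases monotonically, and is zero at and
#' beyond the stopping depth. It drives the depth dependence of the neutron
#' production model (harder neutrons in the entrance region).
#'
#' @inheritParams bragg_depth_dose
#' @return Energy in MeV, same length as `depth`.
#' @export
#' @examples
#' b <- beam_config("200MeV")
#' local_proton_energy(c(0, 10, 20), b)
local_proton_energy <- function(depth, beam) {
  stopifnot(inherits(beam, "beam_spec"))
  if (any(depth < 0)) stop("depth must be non-negative")
  e <- numeric(length(depth))
  inside <- depth < beam$stopping_depth
  e[inside] <- bk_energy(beam$stopping_depth - depth[inside])
  e
}

#' Packaged calibrated beam configurations
#'
#' Loads one of the three packaged pencil-beam configurations (160, 200,
#' 230 MeV) from the calibration table shipped in
#' `inst/extdata/beam_calibration.csv`, which records for each beam the range
#' (R80), the lateral FWHM, and the calibrated per-primary neutron yield and
#' detection rates the generator reproduces.
#'
#' @param label One of `"160MeV"`, `"200MeV"`, `"230MeV"`.
#' @param ... Passed on to [beam_spec()] to override model parameters.
#' @return A [beam_spec()].
#' @export
#' @examples
#' beam_config("230MeV")
beam_config <- function(label = c("160MeV", "200MeV", "230MeV"), ...) {
  label <- match.arg(label)
  tab <- beam_calibration_table()
  row <- tab[tab$label == label, ]
  beam_spec(label = row$label, energy_mev = row$energy_mev,
            range_r80 = row$range_r80_cm, fwhm = row$fwhm_cm,
            yield_per_primary = row$yield_per_primary,
            detection_rate_per_primary = row$detection_rate_per_primary, ...)
}

beam_calibration_table <- function() {
  path <- system.file("extdata", "beam_calibration.csv",
                      package = "recoilrange", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Interpolated beam configuration for an arbitrary range
#'
#' Builds a [beam_spec()] for any range R80 by linear interpolation (and mild
#' extrapolation) of the per-primary yield and detection rates of the three
#' packaged beams against their ranges; the nominal energy follows from the
#' Bragg-Kleeman relation. Used for range sweeps when studying the
#' landmark-versus-range correlation.
#'
#' @param range_r80 Target range (depth of distal 80% dose), cm.
#' @param ... Passed on to [beam_spec()].
#' @return A [beam_spec()].
#' @export
#' @examples
#' beam_for_range(22)$yield_per_primary
beam_for_range <- function(range_r80, ...) {
  stopifnot(range_r80 > 5, range_r80 < 40)
  tab <- beam_calibration_table()
  yfit <- stats::lm(yield_per_primary ~ range_r80_cm, data = tab)
  dfit <- stats::lm(detection_rate_per_primary ~ range_r80_cm, data = tab)
  nd <- data.frame(range_r80_cm = range_r80)
  beam_spec(label = sprintf("R80=%.1fcm", range_r80),
            range_r80 = range_r80,
            energy_mev = bk_energy(range_r80),
            yield_per_primary = unname(stats::predict(yfit, nd)),
            detection_rate_per_primary = unname(stats::predict(dfit, nd)),
            ...)
}
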