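# Repetition and bunching uncertainty analysis for the range landmark,
# histogram RMSE evaluation of the reconstruction, and the landmark-versus-
# range correlation.

#' Repetition uncertainty of the range landmark
#'
#' Sample standard deviation (divisor n - 1) of the landmark over independent
#' repetitions; for the canonical ten repetitions this is
#' `sqrt(1/9 * sum_i (beta_i - mean(beta))^2)`.
#'
#' @param betas Numeric vector of per-repetition landmark values, cm.
#' @return Standard deviation, cm.
#' @export
#' @examples
#' sigma_beta(c(1, 2, 3)) # 1
sigma_beta <- function(betas) {
  if (is.data.frame(betas)) betas <- betas$beta
  if (length(betas) < 2) stop("need at least 2 repetitions")
  stats::sd(betas)
}

#' Landmarks from independent seeded repetitions
#'
#' Runs `reps` fully independent simulations of `n_primaries` primaries each
#' (rate-based event sampling by default) and computes the range landmark per
#' repetition from the ground-truth production depths of the detected events
#' and, optionally, from the reconstruction.
#'
#' @param beam,geom Beam and geometry.
#' @param n_primaries Primaries (equivalent) per repetition.
#' @param reps Number of repetitions.
#' @param seed Root seed; each repetition and the prior calibration use
#'   derived streams.
#' @param reconstruct Also reconstruct each repetition?
#' @param prior Direction prior; if `NULL` and `reconstruct = TRUE`, one is
#'   calibrated from a dedicated run of `calib_primaries` primaries.
#' @param options [recon_options()]; the per-repetition reconstruction seed
#'   is derived from `seed`.
#' @param calib_primaries Primaries for the prior-calibration run.
#' @param rate_based,chunk_size Passed to [simulate_run()].
#' @return A data frame with columns `rep`, `n_events`, `beta_truth` and
#'   (if reconstructed) `beta_recon`.
#' @export
repetition_betas <- function(beam, geom = default_geometry(beam),
                             n_primaries, reps = 10, seed = 1L,
                             reconstruct = TRUE, prior = NULL,
                             options = recon_options(),
                             calib_primaries = 2e8, rate_based = TRUE,
                             chunk_size = 5e5) {
  if (reconstruct && is.null(prior)) {
    calib <- simulate_run(beam, geom, calib_primaries,
                          seed = derive_seed(seed, "prior-calibration"),
                          rate_based = TRUE)
    prior <- estimate_prior(calib)
  }
  out <- lapply(seq_len(reps), function(i) {
    run <- simulate_run(beam, geom, n_primaries,
                        seed = derive_seed(seed, paste0("repetition-", i)),
                        rate_based = rate_based, chunk_size = chunk_size)
    bt <- landmark(run$events$parent_x)$beta
    br <- NA_real_
    if (reconstruct) {
      opts <- options
      opts$seed <- derive_seed(seed, paste0("recon-repetition-", i))
      br <- reconstruct_all(run$events, prior, opts, geom)$landmark$beta
    }
    data.frame(rep = i, n_events = nrow(run$events),
               beta_truth = bt, beta_recon = br)
  })
  res <- do.call(rbind, out)
  if (!reconstruct) res$beta_recon <- NULL
  res
}

#' Bunching analysis of landmark uncertainty versus beam intensity
#'
#' Emulates splitting a full-statistics run into equal bunches of
#' `bunch_primaries` primaries each: per repetition, the landmark is computed
#' from the pooled events of the first `n_select` bunches (each bunch an
#' independently seeded sub-run), and the uncertainty is the repetition
#' spread [sigma_beta()]. The effective beam intensity of the point is
#' `n_select * bunch_primaries`.
#'
#' @inheritParams repetition_betas
#' @param n_select Number of bunches included (nested prefixes of the bunch
#'   sequence).
#' @param bunches Total bunches per repetition.
#' @param bunch_primaries Primaries per bunch.
#' @param chunk_size Passed to [simulate_run()]; smaller chunks speed up
#'   many small bunch runs.
#' @return An object of class `uncertainty_point`: a list with
#'   `n_primaries`, `sigma_beta_truth`, `sigma_beta_recon` (`NA` unless
#'   `reconstruct`), and the per-repetition `betas` data frame.
#' @export
bunch_analysis <- function(beam, geom = default_geometry(beam), n_select,
                           bunches = 24, reps = 10, bunch_primaries = 5e7,
                           seed = 1L, reconstruct = FALSE, prior = NULL,
                           options = recon_options(),
                           calib_primaries = 2e8, chunk_size = 5e5) {
  if (!(n_select >= 1 && n_select <= bunches))
    stop(sprintf("n_select must lie in [1, %d]", bunches))
  if (reconstruct && is.null(prior)) {
    calib <- simulate_run(beam, geom, calib_primaries,
                          seed = derive_seed(seed, "prior-calibration"),
                          rate_based = TRUE)
    prior <- estimate_prior(calib)
  }
  out <- lapply(seq_len(reps), function(r) {
    ev <- do.call(rbind, lapply(seq_len(n_select), function(b) {
      simulate_run(beam, geom, bunch_primaries,
                   seed = derive_seed(seed, sprintf("rep%d-bunch%d", r, b)),
                   rate_based = TRUE, chunk_size = chunk_size)$events
    }))
    bt <- landmark(ev$parent_x)$beta
    br <- NA_real_
    if (reconstruct) {
      opts <- options
      opts$seed <- derive_seed(seed, sprintf("recon-rep%d", r))
      br <- reconstruct_all(ev, prior, opts, geom)$landmark$beta
    }
    data.frame(rep = r, n_events = nrow(ev), beta_truth = bt,
               beta_recon = br)
  })
  betas <- do.call(rbind, out)
  structure(list(n_primaries = n_select * bunch_primaries,
                 sigma_beta_truth = sigma_beta(betas$beta_truth),
                 sigma_beta_recon = if (reconstruct)
                   sigma_beta(betas$beta_recon) else NA_real_,
                 betas = betas),
            class = "uncertainty_point")
}

#' @export
print.uncertainty_point <- function(x, ...) {
  cat(sprintf(paste0("<uncertainty_point> %.3g primaries: sigma_beta(truth) ",
                     "= %.3f cm, sigma_beta(recon) = %.3f cm\n"),
              x$n_primaries, x$sigma_beta_truth, x$sigma_beta_recon))
  invisible(x)
}

#' Max-normalized production-depth histogram
#'
#' Histogram of production depths with fixed-width bins, normalized by the
#' highest bin so the maximum bin height is exactly 1.
#'
#' @param positions Production depths, cm (non-empty).
#' @param bin_width Bin width, cm.
#' @param range Depth interval covered, cm.
#' @return An object of class `depth_histogram` with `breaks`, `mids`,
#'   `counts`, `height` (max-normalized), `bin_width`, `n`.
#' @export
depth_histogram <- function(positions, bin_width = 0.5, range = c(0, 35)) {
  if (length(positions) < 1) stop("empty input: no positions to histogram")
  stopifnot(bin_width > 0)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (utils::tail(breaks, 1) < range[2] - 1e-9)
    breaks <- c(breaks, range[2])
  x <- pmin(pmax(positions, range[1]), range[2])
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, mids = h$mids, counts = h$counts,
                 height = h$counts / max(h$counts),
                 bin_width = bin_width, n = length(positions)),
            class = "depth_histogram")
}

#' Root-mean-square error between two max-normalized histograms
#'
#' @param truth_hist,recon_hist [depth_histogram()]s on identical binning.
#' @return An object of class `rmse_report` with `rmse` (on the normalized
#'   0-1 scale), `n_bins`, `bin_width`.
#' @export
rmse_hist <- function(truth_hist, recon_hist) {
  stopifnot(inherits(truth_hist, "depth_histogram"),
            inherits(recon_hist, "depth_histogram"))
  if (length(truth_hist$breaks) != length(recon_hist$breaks) ||
      max(abs(truth_hist$breaks - recon_hist$breaks)) > 1e-9)
    stop("binning mismatch between histograms")
  structure(list(
    rmse = sqrt(mean((truth_hist$height - recon_hist$height)^2)),
    n_bins = length(truth_hist$counts),
    bin_width = truth_hist$bin_width), class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat(sprintf("<rmse_report> RMSE = %.2f%% (%d bins of %.2g cm)\n",
              100 * x$rmse, x$n_bins, x$bin_width))
  invisible(x)
}

#' Linear fit of the range landmark against beam range
#'
#' Ordinary least squares of `beta` on `range_R80`, with
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param betas Landmark values, cm.
#' @param ranges Beam ranges (R80), cm; same length, at least 3 points.
#' @return An object of class `range_fit` with `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_beta_vs_range <- function(betas, ranges) {
  stopifnot(length(betas) == length(ranges))
  if (length(betas) < 3) stop("need at least 3 points")
  fit <- stats::lm(betas ~ ranges)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((betas - mean(betas))^2)
  r2 <- if (ss_tot <= 1e-300) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = min(max(r2, 0), 1)),
            class = "range_fit")
}

#' @export
print.range_fit <- function(x, ...) {
  cat(sprintf("<range_fit> beta = %.3f + %.3f * R80 (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Landmark sweep over beam range
#'
#' Simulates and reconstructs one run per requested range (beams built by
#' [beam_for_range()], each with its own calibrated prior) and reports the
#' ground-truth and reconstructed landmarks, for studying the linear
#' correlation between the landmark and the beam range.
#'
#' @param r80_values Beam ranges to sweep, cm.
#' @param n_primaries Primaries-equivalent per point.
#' @param seed Root seed.
#' @param options [recon_options()].
#' @param calib_primaries Primaries for each prior-calibration run.
#' @return A data frame with `range_r80`, `n_events`, `beta_truth`,
#'   `beta_recon`.
#' @export
range_sweep <- function(r80_values = c(14, 18, 22, 26, 30),
                        n_primaries = 2e8, seed = 1L,
                        options = recon_options(),
                        calib_primaries = 2e8) {
  out <- lapply(r80_values, function(r80) {
    beam <- beam_for_range(r80)
    geom <- default_geometry(beam)
    tag <- sprintf("sweep-r80-%.3f", r80)
    calib <- simulate_run(beam, geom, calib_primaries,
                          seed = derive_seed(seed, paste0(tag, "-prior")),
                          rate_based = TRUE)
    prior <- estimate_prior(calib)
    run <- simulate_run(beam, geom, n_primaries,
                        seed = derive_seed(seed, tag), rate_based = TRUE)
    opts <- options
    opts$seed <- derive_seed(seed, paste0(tag, "-recon"))
    rec <- reconstruct_all(run$events, prior, opts, geom)
    data.frame(range_r80 = r80, n_events = nrow(run$events),
               beta_truth = landmark(run$events$parent_x)$beta,
               beta_recon = rec$landmark$beta)
  })
  do.call(rbind, out)
}
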