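# Configuration files, tabular event I/O, and the end-to-end pipeline
# (simulate -> calibrate prior -> reconstruct -> analyze).

config_schema <- list(
  beam = c("label", "energy_mev", "range_r80_cm", "fwhm_cm",
           "yield_per_primary", "detection_rate_per_primary"),
  geometry = c("phantom_extent_cm", "converter_center_cm",
               "converter_thickness_cm", "converter_area_cm",
               "tracker1_offset_cm", "tracker2_offset_cm"),
  recon = c("iterations"),
  run = c("n_primaries", "rate_based", "calib_primaries"),
  analysis = c("bunches", "reps", "bin_width_cm"),
  root_seed = NULL
)

#' Default pipeline configuration
#'
#' Fully resolved configuration for one of the packaged beams: converter
#' centred at the Bragg-peak depth 10 cm lateral to the beam axis, 5000
#' reconstruction iterations per detected proton, 24 bunches and 10
#' repetitions for the uncertainty analysis, 0.5 cm depth bins.
#'
#' @param label Packaged beam label.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(label = "200MeV") {
  beam <- beam_config(label)
  structure(list(
    beam = list(label = beam$label, energy_mev = beam$energy_mev,
                range_r80_cm = beam$range_r80, fwhm_cm = beam$fwhm,
                yield_per_primary = beam$yield_per_primary,
                detection_rate_per_primary = beam$detection_rate_per_primary),
    geometry = list(phantom_extent_cm = c(35, 10, 10),
                    converter_center_cm = c(beam$peak_depth, 10, 0),
                    converter_thickness_cm = 0.5,
                    converter_area_cm = c(20, 20),
                    tracker1_offset_cm = 1.25,
                    tracker2_offset_cm = 6.25),
    recon = list(iterations = 5000L),
    run = list(n_primaries = 5e7, rate_based = "auto",
               calib_primaries = 2e8),
    analysis = list(bunches = 24L, reps = 10L, bin_width_cm = 0.5),
    root_seed = 1L
  ), class = "pipeline_config")
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown) > 0)
    stop("unknown configuration key: ", unknown[1])
  for (sec in intersect(names(cfg), names(config_schema))) {
    keys <- config_schema[[sec]]
    if (is.null(keys)) next
    bad <- setdiff(names(cfg[[sec]]), keys)
    if (length(bad) > 0)
      stop(sprintf("unknown configuration key: %s.%s", sec, bad[1]))
  }
  invisible(cfg)
}

#' Load, validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills every missing
#' field from [default_config()] for the configured beam label, and resolves
#' derived defaults (e.g. the converter centre at the Bragg-peak depth).
#' `load_config(save_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param path YAML file. Only `beam.label` is mandatory.
#' @return A resolved `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname load_config
#' @param cfg A raw nested list or `pipeline_config`.
#' @export
as_pipeline_config <- function(cfg) {
  validate_config(cfg)
  label <- cfg$beam$label %||% "200MeV"
  def <- default_config(label)
  out <- def
  for (sec in names(config_schema)) {
    if (is.null(cfg[[sec]])) next
    if (is.null(config_schema[[sec]])) { # scalar key
      out[[sec]] <- cfg[[sec]]
    } else {
      for (k in names(cfg[[sec]])) out[[sec]][[k]] <- cfg[[sec]][[k]]
    }
  }
  # coerce numeric fields (YAML readers return plain-exponent literals like
  # "2.0e7" as strings)
  for (sec in c("beam", "geometry", "run", "analysis")) {
    for (k in names(out[[sec]])) {
      if (k %in% c("label", "rate_based")) next
      out[[sec]][[k]] <- as.numeric(out[[sec]][[k]])
    }
  }
  out$recon$iterations <- as.integer(out$recon$iterations)
  out$analysis$bunches <- as.integer(out$analysis$bunches)
  out$analysis$reps <- as.integer(out$analysis$reps)
  out$root_seed <- as.integer(out$root_seed)
  # re-resolve the converter centre if beam fields changed but the centre
  # was not given explicitly
  if (is.null(cfg$geometry$converter_center_cm)) {
    beam <- config_beam(out)
    out$geometry$converter_center_cm <- c(beam$peak_depth, 10, 0)
  }
  class(out) <- "pipeline_config"
  validate_config(out)
  out
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname load_config
#' @export
config_beam <- function(cfg) {
  b <- cfg$beam
  beam_spec(label = b$label, energy_mev = b$energy_mev,
            range_r80 = b$range_r80_cm, fwhm = b$fwhm_cm,
            yield_per_primary = b$yield_per_primary,
            detection_rate_per_primary = b$detection_rate_per_primary)
}

#' @rdname load_config
#' @export
config_geometry <- function(cfg) {
  g <- cfg$geometry
  geometry_spec(phantom_extent = g$phantom_extent_cm,
                converter_center = g$converter_center_cm,
                converter_thickness = g$converter_thickness_cm,
                converter_area = g$converter_area_cm,
                tracker1_offset = g$tracker1_offset_cm,
                tracker2_offset = g$tracker2_offset_cm)
}

# ---- tabular I/O ------------------------------------------------------------

signif_df <- function(df, digits = 6) {
  for (k in names(df)) if (is.numeric(df[[k]])) df[[k]] <- signif(df[[k]],
                                                                  digits)
  df
}

#' Read and write event lists
#'
#' Tab-separated event tables (one row per detected proton, the columns of
#' [simulate_run()]'s `events`), with a unit header comment; floats are
#' printed with 6 significant digits.
#'
#' @param events Event data frame.
#' @param path File path.
#' @return `read_events()`: the event data frame.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# recoilrange event list: lengths in cm, energies in MeV",
               "# hit1/hit2: tracker-plane hits; conv: converter midplane point; parent: neutron truth"),
             con)
  utils::write.table(signif_df(events), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname write_events
#' @param prior A [estimate_prior()] result.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "direction_prior"))
  df <- data.frame(bin_lo = utils::head(prior$bin_edges, -1),
                   bin_hi = prior$bin_edges[-1],
                   density = prior$density)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# direction-cosine prior (u_x along beam axis); %d events",
                     prior$n_events), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_prior <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  structure(list(bin_edges = c(df$bin_lo, df$bin_hi[nrow(df)]),
                 density = df$density, max_density = max(df$density),
                 n_events = NA_integer_),
            class = "direction_prior")
}

# ---- pipeline ---------------------------------------------------------------

pipeline_log <- function(stage, ...) {
  message(sprintf("[recoilrange:%s] %s", stage, sprintf(...)))
}

#' Run the full simulate/calibrate/reconstruct/analyze pipeline
#'
#' Executes the whole chain for one configuration and writes all artifacts
#' to `out_dir`: `events.tsv` (detected events), `prior.tsv` (direction
#' prior from a dedicated calibration run), `recon.tsv` (per-event
#' production estimates), and `summary.json` with the landmark (`beta`), its
#' repetition uncertainty (`sigma_beta`), the truth-vs-reconstruction
#' histogram `rmse`, counts, the root seed and a configuration hash. Rerun
#' with an identical configuration reproduces identical outputs.
#'
#' @param config A `pipeline_config` (see [load_config()]) or a path to a
#'   YAML file.
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage log lines.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else pipeline_log
  beam <- config_beam(config)
  geom <- config_geometry(config)
  seed <- config$root_seed
  cfg_hash <- rlang::hash(unclass(config))
  rate_based <- config$run$rate_based
  if (identical(rate_based, "auto")) rate_based <- NULL

  calib <- simulate_run(beam, geom, config$run$calib_primaries,
                        seed = derive_seed(seed, "prior-calibration"),
                        rate_based = TRUE)
  prior <- estimate_prior(calib)
  write_prior(prior, file.path(out_dir, "prior.tsv"))
  log("calibrate-prior", "%d events from %.3g primaries",
      nrow(calib$events), calib$n_primaries)

  run <- simulate_run(beam, geom, config$run$n_primaries, seed =
                        derive_seed(seed, "pipeline-run"),
                      rate_based = rate_based)
  write_events(run$events, file.path(out_dir, "events.tsv"))
  log("simulate", "%d neutrons produced, %d detected from %.3g primaries",
      run$n_produced, nrow(run$events), run$n_primaries)

  opts <- recon_options(iterations = config$recon$iterations,
                        seed = derive_seed(seed, "pipeline-recon"))
  rec <- reconstruct_all(run$events, prior, opts, geom)
  utils::write.table(signif_df(rec$points),
                     file.path(out_dir, "recon.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("reconstruct", "%d reconstructed, %d discarded, beta = %.3f cm",
      nrow(rec$points), rec$n_discarded, rec$landmark$beta)

  bw <- config$analysis$bin_width_cm
  ht <- depth_histogram(run$events$parent_x, bw,
                        range = c(0, geom$phantom_extent[1]))
  hr <- depth_histogram(rec$points$est_u, bw,
                        range = c(0, geom$phantom_extent[1]))
  rmse <- rmse_hist(ht, hr)
  reps <- repetition_betas(beam, geom, config$run$n_primaries,
                           reps = config$analysis$reps, seed =
                             derive_seed(seed, "pipeline-reps"),
                           reconstruct = TRUE, prior = prior,
                           options = opts)
  summary <- list(
    beam = beam$label,
    n_primaries = config$run$n_primaries,
    n_produced = run$n_produced,
    n_events = nrow(run$events),
    n_discarded = rec$n_discarded,
    iterations = rec$iterations,
    beta = rec$landmark$beta,
    mu_rec = rec$landmark$mu_rec,
    sigma_rec = rec$landmark$sigma_rec,
    beta_truth = landmark(run$events$parent_x)$beta,
    sigma_beta = sigma_beta(reps$beta_recon),
    sigma_beta_truth = sigma_beta(reps$beta_truth),
    rmse = rmse$rmse,
    seed = seed,
    config_hash = cfg_hash
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("analyze", "rmse = %.2f%%, sigma_beta = %.3f cm (truth %.3f cm)",
      100 * rmse$rmse, summary$sigma_beta, summary$sigma_beta_truth)
  invisible(summary)
}
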