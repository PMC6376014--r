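# Shared fixtures, built once per test session. All inputs are generated in
# code; runs use rate-based event sampling where only detected events matter.

.fix_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fix_env[[name]])) .fix_env[[name]] <- expr
  .fix_env[[name]]
}

beam200 <- function() fixture("beam200", beam_config("200MeV"))
geom200 <- function() fixture("geom200", default_geometry(beam200()))

# ~5000 detected events with parent truth
run200 <- function() fixture(
  "run200",
  simulate_run(beam200(), geom200(), 2e8, seed = 11, rate_based = TRUE))

# independent calibration run for prior estimation
prior200 <- function() fixture(
  "prior200",
  estimate_prior(simulate_run(beam200(), geom200(), 2e8, seed = 12,
                              rate_based = TRUE)))

# a small direct-chain run with full production truth kept
run200_direct <- function() fixture(
  "run200_direct",
  simulate_run(beam200(), geom200(), 2e6, seed = 13, keep_truth = TRUE))

# delta-like prior concentrated on the bin containing ux
delta_prior <- function(ux, bins = 50) {
  edges <- seq(-1, 1, length.out = bins + 1)
  dens <- rep(0, bins)
  i <- findInterval(ux, edges, rightmost.closed = TRUE, all.inside = TRUE)
  dens[i] <- 1 / (2 / bins)
  structure(list(bin_edges = edges, density = dens,
                 max_density = max(dens), n_events = NA_integer_),
            class = "direction_prior")
}

uniform_prior <- function(bins = 50) {
  edges <- seq(-1, 1, length.out = bins + 1)
  structure(list(bin_edges = edges, density = rep(0.5, bins),
                 max_density = 0.5, n_events = NA_integer_),
            class = "direction_prior")
}
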