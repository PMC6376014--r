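# Iterative Monte-Carlo acceptance/rejection back-projection. Detected
# proton tracks are back-projected onto the image plane (the y = 0 plane
# containing the beam axis; in-plane coordinates u = x along the beam,
# v = z). Candidate incident-neutron directions are sampled around each
# proton track, filtered by a direction-cosine prior and by a weighted-
# distance sampling region built from the ensemble of initial back
# projections, and the surviving back-projected coordinates are averaged
# into a per-event production-location estimate.

#' Reconstruction options
#'
#' @param iterations Candidate samples per detected proton (the algorithm's
#'   iteration count M).
#' @param theta_range Polar scattering-angle sampling interval, radians.
#' @param phi_range Azimuthal sampling interval, radians.
#' @param seed Integer seed for the reconstruction stream.
#' @return An object of class `recon_options`.
#' @export
recon_options <- function(iterations = 5000, theta_range = c(0, pi / 2),
                          phi_range = c(0, 2 * pi), seed = 1L) {
  stopifnot(iterations >= 1, length(theta_range) == 2, length(phi_range) == 2)
  structure(list(iterations = as.integer(iterations),
                 theta_range = theta_range, phi_range = phi_range,
                 seed = as.integer(seed)),
            class = "recon_options")
}

#' Back-project a proton track onto the image plane
#'
#' Intersects the line through the two tracker hits, extended backward, with
#' the image plane `y = 0`. The intersection's `x` coordinate is `u` (depth
#' along the beam axis) and its `z` coordinate is `v`.
#'
#' @param event Either a one-row event data frame (columns `hit1_*`,
#'   `hit2_*`, see [simulate_run()]) or a list with numeric length-3 `hit1`
#'   and `hit2`.
#' @param geom Unused (the image plane is fixed at `y = 0`); accepted for
#'   call-site uniformity.
#' @return Named numeric `c(u =, v =)` in cm.
#' @export
#' @examples
#' back_project(list(hit1 = c(14, 11.25, 0), hit2 = c(15, 16.25, 0)))
back_project <- function(event, geom = NULL) {
  h <- event_hits(event)
  d <- h$hit2 - h$hit1
  if (all(abs(d) < 1e-12)) stop("degenerate event: identical tracker hits")
  if (abs(d[2]) < 1e-12)
    stop("no intersection: proton track parallel to the image plane")
  t <- -h$hit1[2] / d[2]
  c(u = h$hit1[1] + t * d[1], v = h$hit1[3] + t * d[3])
}

event_hits <- function(event) {
  if (is.data.frame(event)) {
    stopifnot(nrow(event) == 1)
    list(hit1 = c(event$hit1_x, event$hit1_y, event$hit1_z),
         hit2 = c(event$hit2_x, event$hit2_y, event$hit2_z))
  } else {
    stopifnot(length(event$hit1) == 3, length(event$hit2) == 3)
    list(hit1 = as.numeric(event$hit1), hit2 = as.numeric(event$hit2))
  }
}

# Vectorized back projection of an event table; assumes non-degenerate
# tracks (use `backprojectable()` to pre-filter).
back_project_events <- function(events) {
  dx <- events$hit2_x - events$hit1_x
  dy <- events$hit2_y - events$hit1_y
  dz <- events$hit2_z - events$hit1_z
  t <- -events$hit1_y / dy
  data.frame(u = events$hit1_x + t * dx, v = events$hit1_z + t * dz)
}

backprojectable <- function(events) {
  dx <- events$hit2_x - events$hit1_x
  dy <- events$hit2_y - events$hit1_y
  dz <- events$hit2_z - events$hit1_z
  abs(dy) >= 1e-12 & (abs(dx) + abs(dy) + abs(dz)) >= 1e-12
}

#' Centre of gravity and spread of back-projected coordinates
#'
#' Unweighted means and sample standard deviations (divisor n - 1) of the
#' ensemble of image-plane coordinates, per dimension.
#'
#' @param coords A data frame or matrix with two columns (`u`, `v`).
#' @return An object of class `ensemble_stats` with `mu_u`, `mu_v`,
#'   `sigma_u`, `sigma_v`.
#' @export
#' @examples
#' ensemble_stats(data.frame(u = c(0, 2), v = c(0, 0)))
ensemble_stats <- function(coords) {
  coords <- as.data.frame(coords)
  if (nrow(coords) < 2)
    stop("insufficient data: need at least 2 coordinates")
  structure(list(mu_u = mean(coords[[1]]), mu_v = mean(coords[[2]]),
                 sigma_u = stats::sd(coords[[1]]),
                 sigma_v = stats::sd(coords[[2]])),
            class = "ensemble_stats")
}

wdist_term <- function(d, s) {
  if (s > 0) return((d / s)^2)
  if (all(abs(d) < 1e-12)) return(rep(0, length(d)))
  stop("degenerate ensemble: zero standard deviation with nonzero deviation")
}

#' Standard-deviation-weighted distance to the centre of gravity
#'
#' The Euclidean distance in the image plane with each dimension scaled by
#' the ensemble's standard deviation (a Mahalanobis distance without
#' covariances): `d = sqrt(((u - mu_u)/sigma_u)^2 + ((v - mu_v)/sigma_v)^2)`.
#' If a standard deviation is zero, that term is treated as 0 when the
#' deviation is also zero, and is an error otherwise.
#'
#' @param coord Numeric `c(u, v)`, or a two-column matrix/data frame.
#' @param stats An [ensemble_stats()].
#' @return Dimensionless distance(s).
#' @export
weighted_distance <- function(coord, stats) {
  stopifnot(inherits(stats, "ensemble_stats"))
  if (is.null(dim(coord))) coord <- matrix(coord, ncol = 2)
  coord <- as.data.frame(coord)
  sqrt(wdist_term(coord[[1]] - stats$mu_u, stats$sigma_u) +
         wdist_term(coord[[2]] - stats$mu_v, stats$sigma_v))
}

#' Build the acceptance sampling region
#'
#' The region is centred at the ensemble centre of gravity and extends, in
#' the weighted metric of [weighted_distance()], to the maximum distance
#' attained by any initial back-projected coordinate. Membership additionally
#' requires the in-plane lateral coordinate `v` to lie within the phantom's
#' lateral extent.
#'
#' @param coords Initial back-projected coordinates (two columns).
#' @param stats Their [ensemble_stats()].
#' @param geom A [geometry_spec()] (for the phantom bounds).
#' @return An object of class `sampling_region` with `half_width`,
#'   `u_bounds`, `v_bounds`.
#' @export
build_sampling_region <- function(coords, stats, geom) {
  d <- weighted_distance(coords, stats)
  structure(list(half_width = max(d),
                 u_bounds = c(0, geom$phantom_extent[1]),
                 v_bounds = c(-1, 1) * geom$phantom_extent[3] / 2),
            class = "sampling_region")
}

#' @rdname build_sampling_region
#' @param region A `sampling_region`.
#' @param u,v Candidate image-plane coordinates.
#' @return `region_contains()`: logical vector.
#' @export
region_contains <- function(region, stats, u, v) {
  d <- weighted_distance(cbind(u, v), stats)
  d <= region$half_width & v >= region$v_bounds[1] & v <= region$v_bounds[2]
}

#' Estimate the incident-direction prior from a calibration run
#'
#' Histogram density of the parent-neutron direction cosine along the beam
#' axis (`u_x`) over detected events, normalized to integrate to 1 over
#' `[-1, 1]`. This is the prior used in the acceptance/rejection step of the
#' reconstruction; for the packaged configurations it is strongly
#' forward-peaked.
#'
#' @param calibration_run A [simulate_run()] result (or an event data frame
#'   with a `parent_ux` column).
#' @param bins Number of histogram bins over `[-1, 1]`.
#' @param min_events Minimum number of detected events required.
#' @return An object of class `direction_prior` with `bin_edges`, `density`,
#'   `max_density`, `n_events`.
#' @export
estimate_prior <- function(calibration_run, bins = 50, min_events = 1000) {
  events <- if (inherits(calibration_run, "run_result"))
    calibration_run$events else calibration_run
  ux <- events$parent_ux
  if (length(ux) < min_events)
    stop(sprintf(paste0("insufficient statistics: %d detected events, need ",
                        "at least %d for prior estimation"),
                 length(ux), min_events))
  edges <- seq(-1, 1, length.out = bins + 1)
  counts <- graphics::hist(ux, breaks = edges, plot = FALSE)$counts
  bw <- 2 / bins
  density <- counts / (length(ux) * bw)
  structure(list(bin_edges = edges, density = density,
                 max_density = max(density), n_events = length(ux)),
            class = "direction_prior")
}

#' @export
print.direction_prior <- function(x, ...) {
  mode_bin <- which.max(x$density)
  cat(sprintf(paste0("<direction_prior> %d bins, %d events, mode at u_x = ",
                     "%.2f, max density %.2f\n"),
              length(x$density), x$n_events,
              mean(x$bin_edges[mode_bin + 0:1]), x$max_density))
  invisible(x)
}

prior_density_at <- function(prior, ux) {
  if (any(ux < -1 | ux > 1)) stop("direction cosine outside [-1, 1]")
  i <- findInterval(ux, prior$bin_edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  prior$density[i]
}

#' Sample a candidate incident-neutron direction
#'
#' Rotates the detected proton direction by a polar angle drawn uniformly
#' from `theta_range` (about an axis perpendicular to it) with azimuth drawn
#' uniformly from `phi_range`. The result is a unit candidate vector at an
#' angle exactly `theta` from the proton direction.
#'
#' Draws from the current RNG stream.
#'
#' @param proton_dir Unit direction of the detected proton.
#' @param options A [recon_options()].
#' @return A list with `direction` (unit vector), `theta`, `phi`.
#' @export
sample_candidate <- function(proton_dir, options = recon_options()) {
  stopifnot(abs(sum(proton_dir^2) - 1) < 1e-6)
  theta <- stats::runif(1, options$theta_range[1], options$theta_range[2])
  phi <- stats::runif(1, options$phi_range[1], options$phi_range[2])
  dir <- rotate_dirs(matrix(proton_dir, nrow = 1), theta, phi)
  list(direction = as.numeric(dir), theta = theta, phi = phi)
}

#' Accept or reject a candidate direction against the prior
#'
#' Standard rejection sampling: the candidate is accepted with probability
#' `density(u_x) / max_density`, where `u_x` is the candidate's direction
#' cosine along the beam axis. Over many proposals, accepted `u_x` values are
#' distributed as the prior.
#'
#' @param candidate Unit candidate direction (or a scalar `u_x`).
#' @param prior A [estimate_prior()] result.
#' @return Logical.
#' @export
accept_direction <- function(candidate, prior) {
  ux <- if (length(candidate) == 3) candidate[1] else candidate
  p <- prior_density_at(prior, ux) / prior$max_density
  stats::runif(1) < p
}

# Vectorized core: reconstruct a block of events (B x M candidates at once).
# h1, h2: B x 3 hit matrices. Returns per-event estimates and accepted
# counts; NA estimates mark events with zero accepted candidates.
reconstruct_batch <- function(h1, h2, prior, region, stats, geom, options) {
  b <- nrow(h1)
  m <- options$iterations
  d <- h2 - h1
  dn <- d / sqrt(rowSums(d^2))
  tt <- (geom$midplane_y - h1[, 2]) / d[, 2]
  cx <- h1[, 1] + tt * d[, 1]
  cy <- geom$midplane_y
  cz <- h1[, 3] + tt * d[, 3]
  idx <- rep(seq_len(b), each = m)
  theta <- stats::runif(b * m, options$theta_range[1], options$theta_range[2])
  phi <- stats::runif(b * m, options$phi_range[1], options$phi_range[2])
  cand <- rotate_dirs(dn[idx, , drop = FALSE], theta, phi)
  cux <- pmin(pmax(cand[, 1], -1), 1)
  pacc <- prior_density_at(prior, cux) / prior$max_density
  acc <- stats::runif(b * m) < pacc
  acc <- acc & cand[, 2] > 0
  s <- cy / cand[, 2]
  u <- cx[idx] - s * cand[, 1]
  v <- cz[idx] - s * cand[, 3]
  acc[acc] <- region_contains(region, stats, u[acc], v[acc])
  ia <- idx[acc]
  cnt <- tabulate(ia, nbins = b)
  est_u <- rep(NA_real_, b)
  est_v <- rep(NA_real_, b)
  if (length(ia) > 0) {
    rs <- rowsum(cbind(u[acc], v[acc]), ia)
    g <- as.integer(rownames(rs))
    est_u[g] <- rs[, 1] / cnt[g]
    est_v[g] <- rs[, 2] / cnt[g]
  }
  list(est_u = est_u, est_v = est_v, n_accepted = cnt)
}

#' Reconstruct the production location of one detected proton's parent
#'
#' Runs `iterations` candidate samples for the event: each candidate
#' direction (see [sample_candidate()]) is anchored at the event's
#' converter-midplane intersection, filtered by the direction prior
#' ([accept_direction()]), back-projected onto the image plane and filtered
#' by the sampling region. The estimate is the unweighted mean of all doubly
#' accepted coordinates; with zero acceptances the event is discarded.
#'
#' Draws from the current RNG stream; [reconstruct_all()] manages seeding.
#'
#' @param event A one-row event data frame or a list with `hit1`, `hit2`.
#' @param prior A [estimate_prior()] result.
#' @param region,stats Sampling region and ensemble statistics built from
#'   the full ensemble of initial back projections.
#' @param options A [recon_options()].
#' @param geom A [geometry_spec()].
#' @return A list with `coord` (`c(u, v)`) and `n_accepted`, or `NULL` if
#'   the event is discarded.
#' @export
reconstruct_event <- function(event, prior, region, stats,
                              options = recon_options(), geom) {
  h <- event_hits(event)
  res <- reconstruct_batch(matrix(h$hit1, nrow = 1),
                           matrix(h$hit2, nrow = 1),
                           prior, region, stats, geom, options)
  if (res$n_accepted[1] == 0) return(NULL)
  list(coord = c(u = res$est_u[1], v = res$est_v[1]),
       n_accepted = res$n_accepted[1])
}

#' Reconstruct all detected events and the range landmark
#'
#' Full reconstruction pipeline: back-projects all events onto the image
#' plane, builds the ensemble statistics and the weighted-distance sampling
#' region from those initial projections, then reconstructs each event by
#' acceptance/rejection sampling and assembles the range landmark
#' (see [landmark()]) from the estimated production depths.
#'
#' Events are processed in fixed-size blocks of candidates for speed; the
#' result is deterministic in `(events, prior, options, geom)`.
#'
#' @param events Event data frame (see [simulate_run()]) or a `run_result`.
#' @param prior A [estimate_prior()] result (typically from a separate
#'   calibration run of the same beam configuration).
#' @param options A [recon_options()].
#' @param geom A [geometry_spec()].
#' @return An object of class `recon_result`: `points` (data frame
#'   `event_id`, `est_u`, `est_v`, `n_accepted` for non-discarded events),
#'   `n_discarded`, `landmark`, plus the `stats` and `region` used.
#' @export
reconstruct_all <- function(events, prior, options = recon_options(), geom) {
  if (inherits(events, "run_result")) {
    geom <- events$geom
    events <- events$events
  }
  stopifnot(inherits(geom, "geometry_spec"))
  n_events <- nrow(events)
  if (n_events < 2) stop("insufficient events: need at least 2")
  ok <- backprojectable(events)
  good <- events[ok, , drop = FALSE]
  bp <- back_project_events(good)
  stats <- ensemble_stats(bp)
  region <- build_sampling_region(bp, stats, geom)
  m <- options$iterations
  block <- max(1L, as.integer(floor(2e5 / m)))
  h1 <- as.matrix(good[, c("hit1_x", "hit1_y", "hit1_z")])
  h2 <- as.matrix(good[, c("hit2_x", "hit2_y", "hit2_z")])
  n_good <- nrow(good)
  est_u <- numeric(n_good)
  est_v <- numeric(n_good)
  n_acc <- integer(n_good)
  withr::with_seed(derive_seed(options$seed, "reconstruction"), {
    i <- 1L
    while (i <= n_good) {
      j <- min(i + block - 1L, n_good)
      res <- reconstruct_batch(h1[i:j, , drop = FALSE],
                               h2[i:j, , drop = FALSE],
                               prior, region, stats, geom, options)
      est_u[i:j] <- res$est_u
      est_v[i:j] <- res$est_v
      n_acc[i:j] <- res$n_accepted
      i <- j + 1L
    }
  })
  keep <- n_acc > 0
  points <- data.frame(
    event_id = if ("event_id" %in% names(good)) good$event_id[keep]
               else which(ok)[keep],
    est_u = est_u[keep], est_v = est_v[keep], n_accepted = n_acc[keep])
  structure(list(points = points,
                 n_discarded = n_events - sum(keep),
                 landmark = landmark(points$est_u),
                 stats = stats, region = region,
                 iterations = m, seed = options$seed),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %d reconstructed events, %d discarded (M = %d)\n",
              nrow(x$points), x$n_discarded, x$iterations))
  print(x$landmark)
  invisible(x)
}

#' Range landmark of a set of reconstructed production depths
#'
#' Projects the reconstructed coordinates onto the beam axis and summarizes
#' them as `beta = mu_rec + sigma_rec`, the sample mean plus one sample
#' standard deviation (divisor n - 1) of the production depths. `beta` is
#' the scalar range landmark correlated with the primary beam range.
#'
#' @param points Numeric vector of production depths (the image-plane `u`
#'   coordinates), cm.
#' @return An object of class `landmark` with `mu_rec`, `sigma_rec`, `beta`
#'   (cm) and `n`.
#' @export
#' @examples
#' landmark(c(4, 6)) # mu = 5, sigma = sqrt(2)
landmark <- function(points) {
  if (is.data.frame(points)) points <- points$est_u
  if (length(points) < 2) stop("insufficient data: need at least 2 points")
  mu <- mean(points)
  sg <- stats::sd(points)
  structure(list(mu_rec = mu, sigma_rec = sg, beta = mu + sg,
                 n = length(points)),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark> beta = %.3f cm (mu = %.3f, sigma = %.3f, n = %d)\n",
              x$beta, x$mu_rec, x$sigma_rec, x$n))
  invisible(x)
}
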