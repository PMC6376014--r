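test_that("sampled neutrons respect symmetry, forward peaking and the local-energy bound", {
  b <- beam200()
  g <- geom200()
  nt <- withr::with_seed(21, sample_neutrons(1e5, b, g))
  se <- 1 / sqrt(3 * nrow(nt)) # SE of a direction-cosine mean (var <= 1/3)
  expect_lt(abs(mean(nt$uy)), 5 * se)
  expect_lt(abs(mean(nt$uz)), 5 * se)
  expect_gt(mean(nt$ux), 0)
  # unit directions
  norm2 <- nt$ux^2 + nt$uy^2 + nt$uz^2
  expect_lt(max(abs(norm2 - 1)), 1e-9)
  # energy bounded by the local proton energy at the production depth
  expect_true(all(nt$energy <= nt$e_local + 1e-9))
  expect_true(all(nt$energy > 0))
  # lateral positions inside the phantom
  expect_true(all(abs(nt$y) <= g$phantom_extent[2] / 2))
  expect_true(all(abs(nt$z) <= g$phantom_extent[3] / 2))
})

test_that("production depths follow the declining-density model and stop proximal to R80 + 1 cm", {
  b <- beam200()
  nt <- withr::with_seed(22, sample_neutrons(1e5, b, geom200()))
  expect_lt(max(nt$x), b$range_r80 + 1)
  expect_gte(min(nt$x), 0)
  # coarse-binned counts decline monotonically (linear decline + cutoff)
  counts <- table(cut(nt$x, seq(0, 25, by = 5)))
  expect_true(all(diff(as.numeric(counts)) < 0))
  # analytic inverse-CDF oracle for the linear production-depth density
  a <- b$production_decline
  dmax <- b$production_cutoff
  cdf <- function(x) {
    t <- pmin(pmax(x / dmax, 0), 1)
    (t - a * t^2 / 2) / (1 - a / 2)
  }
  ks <- suppressWarnings(stats::ks.test(nt$x, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("transport to the converter reproduces an independent line-plane intersection", {
  b <- beam200()
  g <- geom200()
  nt <- withr::with_seed(23, sample_neutrons(1e4, b, g))
  tr <- recoilrange:::transport_many(nt, g)
  # independent recomputation via the parametric plane equation
  # p = pos + t * dir with <p - c, n> = 0, n = (0, 1, 0)
  t_ind <- (g$midplane_y - nt$y) / nt$uy
  px_ind <- nt$x + t_ind * nt$ux
  pz_ind <- nt$z + t_ind * nt$uz
  ok <- tr$hit
  expect_true(any(ok))
  expect_lt(max(abs(tr$px[ok] - px_ind[ok])), 1e-9)
  expect_true(all(px_ind[ok] >= g$area_x[1] & px_ind[ok] <= g$area_x[2]))
  expect_true(all(pz_ind[ok] >= g$area_z[1] & pz_ind[ok] <= g$area_z[2]))
  # neutrons not travelling toward the detector never hit
  expect_true(all(nt$uy[ok] > 0))
})

test_that("transport handles perpendicular incidence and plane-parallel directions", {
  g <- geom200()
  xc <- g$converter_center[1]
  n <- neutron_truth(c(xc, 0, 0), c(0, 1, 0), 50)
  expect_equal(transport_to_converter(n, g), c(xc, g$midplane_y, 0))
  miss <- neutron_truth(c(xc, 0, 0), c(1, 0, 0), 50)
  expect_null(transport_to_converter(miss, g))
  away <- neutron_truth(c(xc, 0, 0), c(0, -1, 0), 50)
  expect_null(transport_to_converter(away, g))
})

test_that("elastic (n,p) kinematics match independent two-body sampling", {
  b <- beam200()
  en <- 100
  nt <- data.frame(ux = rep(1, 1e5), uy = 0, uz = 0, energy = en)
  cv <- withr::with_seed(24, recoilrange:::convert_many(
    nt, p_convert = 1, inelastic_fraction = 0))
  # E_p = E_n cos^2(theta_p) holds exactly per sample
  expect_lt(max(abs(cv$ep - en * cos(cv$theta_p)^2)), 1e-9)
  # mean proton energy is E_n / 2 (uniform cos(theta_CM))
  expect_lt(abs(mean(cv$ep) - en / 2), 0.2)
  # independent brute-force oracle: cos(theta_CM) uniform,
  # E_p = E_n (1 - cos(theta_CM)) / 2, theta_p = asin(sqrt(E_p / E_n))
  oracle <- withr::with_seed(25, {
    ccm <- runif(1e5, -1, 1)
    ep <- en * (1 - ccm) / 2
    list(ep = ep, theta = asin(sqrt(ep / en)))
  })
  expect_lt(abs(mean(oracle$ep) - en / 2), 0.2)
  ks_e <- suppressWarnings(stats::ks.test(cv$ep, oracle$ep))
  ks_t <- suppressWarnings(stats::ks.test(cv$theta_p, oracle$theta))
  expect_gt(ks_e$p.value, 0.01)
  expect_gt(ks_t$p.value, 0.01)
  # proton direction is at angle theta_p from the neutron direction
  ang <- acos(pmin(1, pmax(-1, cv$vx))) # neutron along +x
  expect_lt(max(abs(ang - cv$theta_p)), 1e-6)
})

test_that("scalar conversion handles energies below 20 MeV and inelastic scaling", {
  g <- geom200()
  n_low <- neutron_truth(c(10, 0, 0), c(0, 1, 0), 15)
  cv <- withr::with_seed(26, convert_neutron(n_low, g))
  expect_identical(cv$category, "low_energy")
  n_hi <- neutron_truth(c(10, 0, 0), c(0, 1, 0), 80)
  cvs <- withr::with_seed(27, replicate(200, {
    x <- convert_neutron(n_hi, g, inelastic_fraction = 0.5)
    c(x$energy, x$theta_p, x$category == "inelastic")
  }))
  el <- cvs[, cvs[3, ] == 0]
  inel <- cvs[, cvs[3, ] == 1]
  expect_lt(max(abs(el[1, ] - 80 * cos(el[2, ])^2)), 1e-9)
  # inelastic energies are a (0.2, 1) fraction of the elastic value
  expect_true(all(inel[1, ] <= 80 * cos(inel[2, ])^2 + 1e-9))
  expect_true(all(inel[1, ] >= 0.2 * 80 * cos(inel[2, ])^2 - 1e-9))
})

test_that("detection requires both planes, enough energy, and excludes low-energy conversions", {
  g <- geom200()
  parent <- neutron_truth(c(10, 0, 0), c(0, 1, 0), 60)
  center <- c(g$converter_center[1], g$midplane_y, 0)
  # low-energy category is never detected
  expect_null(detect_proton(list(point = center, direction = c(0, 1, 0),
                                 energy = 50, category = "low_energy",
                                 parent = parent), g))
  # below the two-plane punch-through minimum
  expect_null(detect_proton(list(point = center, direction = c(0, 1, 0),
                                 energy = 5, category = "elastic",
                                 parent = parent), g))
  # normal incidence from a central point shares in-plane coordinates
  ev <- detect_proton(list(point = center, direction = c(0, 1, 0),
                           energy = 50, category = "elastic",
                           parent = parent), g)
  expect_equal(c(ev$hit1_x, ev$hit1_z), c(center[1], 0))
  expect_equal(c(ev$hit2_x, ev$hit2_z), c(center[1], 0))
  expect_equal(ev$hit1_y, g$tracker_y[1])
  expect_equal(ev$hit2_y, g$tracker_y[2])
  # proton leaving parallel to the planes never reaches them
  expect_null(detect_proton(list(point = center, direction = c(1, 0, 0),
                                 energy = 50, category = "elastic",
                                 parent = parent), g))
})

test_that("detected hits are collinear with the conversion point", {
  ev <- run200()$events
  d1 <- cbind(ev$hit1_x - ev$conv_x, ev$hit1_y - ev$conv_y,
              ev$hit1_z - ev$conv_z)
  d2 <- cbind(ev$hit2_x - ev$conv_x, ev$hit2_y - ev$conv_y,
              ev$hit2_z - ev$conv_z)
  cross <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
                 d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
                 d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  expect_lt(max(abs(cross)), 1e-9)
})

test_that("detected events all stem from parents above 20 MeV within the converter area", {
  ev <- run200()$events
  g <- geom200()
  expect_true(all(ev$parent_e >= 20))
  expect_true(all(ev$category %in% c("elastic", "inelastic")))
  for (h in list(cbind(ev$hit1_x, ev$hit1_z), cbind(ev$hit2_x, ev$hit2_z))) {
    expect_true(all(h[, 1] >= g$area_x[1] & h[, 1] <= g$area_x[2]))
    expect_true(all(h[, 2] >= g$area_z[1] & h[, 2] <= g$area_z[2]))
  }
})

test_that("simulate_run is deterministic in the seed and handles edge inputs", {
  b <- beam200()
  g <- geom200()
  r1 <- simulate_run(b, g, 5e6, seed = 42)
  r2 <- simulate_run(b, g, 5e6, seed = 42)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$n_produced, r2$n_produced)
  r3 <- simulate_run(b, g, 5e6, seed = 43)
  expect_false(identical(r1$events, r3$events))
  # rate-based runs are deterministic too
  r4 <- simulate_run(b, g, 2e8, seed = 42, rate_based = TRUE)
  r5 <- simulate_run(b, g, 2e8, seed = 42, rate_based = TRUE)
  expect_identical(r4$events, r5$events)
  # empty and invalid runs
  r0 <- simulate_run(b, g, 0, seed = 1)
  expect_identical(nrow(r0$events), 0L)
  expect_identical(r0$n_produced, 0L)
  expect_error(simulate_run(b, g, -1, seed = 1), "non-negative")
})

test_that("empirical yield and detection rates are unbiased across independent seeds", {
  b <- beam200()
  g <- geom200()
  n <- 1e6
  runs <- lapply(1:20, function(s) simulate_run(b, g, n, seed = 1000 + s))
  prod_tot <- sum(vapply(runs, function(r) r$n_produced, numeric(1)))
  det_tot <- sum(vapply(runs, function(r) nrow(r$events), numeric(1)))
  lam_prod <- 20 * n * b$yield_per_primary
  lam_det <- 20 * n * b$detection_rate_per_primary
  expect_lt(abs(prod_tot - lam_prod) / sqrt(lam_prod), 4)
  expect_lt(abs(det_tot - lam_det) / sqrt(lam_det), 4)
})

test_that("rate-based event counts stay within the Poisson band of the configured rate", {
  r <- run200()
  lam <- r$n_primaries * r$beam$detection_rate_per_primary
  expect_lt(abs(nrow(r$events) - lam) / sqrt(lam), 5)
})
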