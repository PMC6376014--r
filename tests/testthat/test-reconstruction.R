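test_that("back projection intersects the image plane where expected", {
  bp <- back_project(list(hit1 = c(15, 11.25, 0), hit2 = c(15, 16.25, 0)))
  expect_equal(unname(bp), c(15, 0))
  bp2 <- back_project(list(hit1 = c(14, 11.25, 0), hit2 = c(15, 16.25, 0)))
  expect_equal(unname(bp2), c(11.75, 0))
  expect_error(back_project(list(hit1 = c(1, 2, 3), hit2 = c(1, 2, 3))),
               "degenerate")
  expect_error(back_project(list(hit1 = c(0, 11, 0), hit2 = c(5, 11, 0))),
               "parallel")
})

test_that("zero-scatter events back-project exactly to the parent production depth", {
  ev <- run200()$events
  # rebuild the tracker hits as if the proton continued along the parent
  # neutron's own direction (no scattering in the conversion)
  g <- geom200()
  t1 <- (g$tracker_y[1] - ev$parent_y) / ev$parent_uy
  t2 <- (g$tracker_y[2] - ev$parent_y) / ev$parent_uy
  zs <- data.frame(
    hit1_x = ev$parent_x + t1 * ev$parent_ux, hit1_y = g$tracker_y[1],
    hit1_z = ev$parent_z + t1 * ev$parent_uz,
    hit2_x = ev$parent_x + t2 * ev$parent_ux, hit2_y = g$tracker_y[2],
    hit2_z = ev$parent_z + t2 * ev$parent_uz)
  bp <- recoilrange:::back_project_events(zs)
  # the parent was produced at y ~ 0 (mm-scale beam width), so the
  # back-projected depth matches the production depth after removing the
  # small in-plane offset along the flight path
  u_expected <- ev$parent_x - ev$parent_y * ev$parent_ux / ev$parent_uy
  expect_lt(max(abs(bp$u - u_expected)), 1e-6)
})

test_that("ensemble statistics match closed forms and a streaming oracle", {
  st <- ensemble_stats(data.frame(u = c(0, 2), v = c(0, 0)))
  expect_equal(st$mu_u, 1)
  expect_equal(st$sigma_u, sqrt(2))
  expect_equal(st$sigma_v, 0)
  same <- ensemble_stats(data.frame(u = rep(3, 5), v = rep(-1, 5)))
  expect_equal(same$sigma_u, 0)
  expect_equal(same$sigma_v, 0)
  expect_error(ensemble_stats(data.frame(u = 1, v = 2)), "insufficient")
  # Welford streaming-moments oracle
  co <- withr::with_seed(31, data.frame(u = rnorm(1000), v = runif(1000)))
  st2 <- ensemble_stats(co)
  welford <- function(x) {
    m <- 0; s <- 0
    for (i in seq_along(x)) {
      d <- x[i] - m
      m <- m + d / i
      s <- s + d * (x[i] - m)
    }
    c(mean = m, sd = sqrt(s / (length(x) - 1)))
  }
  wu <- welford(co$u)
  expect_lt(abs(st2$mu_u - wu["mean"]), 1e-10)
  expect_lt(abs(st2$sigma_u - wu["sd"]), 1e-10)
})

test_that("weighted distance reduces to the expected closed forms", {
  st <- structure(list(mu_u = 0, mu_v = 0, sigma_u = 1, sigma_v = 1),
                  class = "ensemble_stats")
  expect_equal(weighted_distance(c(0, 0), st), 0)
  expect_equal(weighted_distance(c(3, 4), st), 5)
  st2 <- structure(list(mu_u = 1, mu_v = 2, sigma_u = 0.5, sigma_v = 2),
                   class = "ensemble_stats")
  expect_equal(weighted_distance(c(2, 2), st2), 2) # (2 sigma_u, 0)
  # degenerate sigma: zero deviation is fine, nonzero deviation errors
  st0 <- structure(list(mu_u = 0, mu_v = 0, sigma_u = 0, sigma_v = 1),
                   class = "ensemble_stats")
  expect_equal(weighted_distance(c(0, 2), st0), 2)
  expect_error(weighted_distance(c(1, 0), st0), "degenerate")
})

test_that("the sampling region contains all input coordinates and rejects out-of-phantom candidates", {
  g <- geom200()
  co <- withr::with_seed(32,
    data.frame(u = rnorm(200, 10, 4), v = runif(200, -4.5, 4.5)))
  st <- ensemble_stats(co)
  reg <- build_sampling_region(co, st, g)
  expect_true(all(region_contains(reg, st, co$u, co$v)))
  # two symmetric coordinates both sit on the boundary
  co2 <- data.frame(u = c(8, 12), v = c(1, -1))
  st2 <- ensemble_stats(co2)
  reg2 <- build_sampling_region(co2, st2, g)
  d <- weighted_distance(co2, st2)
  expect_equal(unname(d[1]), unname(d[2]))
  expect_equal(unname(max(d)), reg2$half_width)
  # lateral phantom bound overrides the distance criterion
  expect_false(region_contains(reg, st, st$mu_u, g$phantom_extent[3] / 2 + 1))
})

test_that("the direction prior is a normalized, forward-peaked density consistent across samples", {
  pr <- prior200()
  bw <- diff(pr$bin_edges[1:2])
  expect_lt(abs(sum(pr$density) * bw - 1), 1e-9)
  mode_ux <- pr$bin_edges[which.max(pr$density)] + bw / 2
  expect_gt(mode_ux, 0.5)
  expect_error(estimate_prior(run200()$events[1:100, ]), "insufficient")
  # two-sample KS against a fresh calibration run
  fresh <- simulate_run(beam200(), geom200(), 4e8, seed = 77,
                        rate_based = TRUE)
  ecdf_fresh <- stats::ecdf(fresh$events$parent_ux)
  cdf_prior <- cumsum(pr$density) * bw
  grid <- pr$bin_edges[-1]
  d_ks <- max(abs(cdf_prior - ecdf_fresh(grid)))
  n1 <- pr$n_events
  n2 <- nrow(fresh$events)
  crit <- 1.628 * sqrt((n1 + n2) / (n1 * n2)) # alpha = 0.01
  expect_lt(d_ks, crit)
})

test_that("candidate sampling is an exact rotation by the sampled polar angle", {
  pd <- c(0.3, 0.9, sqrt(1 - 0.3^2 - 0.9^2))
  cands <- withr::with_seed(33, replicate(1000, {
    s <- sample_candidate(pd)
    c(s$direction, s$theta)
  }))
  norms <- sqrt(colSums(cands[1:3, ]^2))
  expect_lt(max(abs(norms - 1)), 1e-9)
  ang <- acos(pmin(1, colSums(cands[1:3, ] * pd)))
  expect_lt(max(abs(ang - cands[4, ])), 1e-9)
  expect_true(all(cands[4, ] >= 0 & cands[4, ] <= pi / 2))
  # theta_range (0, 0) is the identity rotation
  id <- withr::with_seed(34,
    sample_candidate(pd, recon_options(theta_range = c(0, 0))))
  expect_equal(id$direction, pd, tolerance = 1e-12)
})

test_that("direction rejection sampling reproduces the prior", {
  pr <- prior200()
  # a candidate in a zero-density bin is always rejected
  zero_bin <- which(pr$density == 0)[1]
  ux0 <- mean(pr$bin_edges[zero_bin + 0:1])
  withr::with_seed(35, {
    for (i in 1:20)
      expect_false(accept_direction(c(ux0, sqrt(1 - ux0^2), 0), pr))
  })
  # a uniform prior accepts everything
  up <- uniform_prior()
  withr::with_seed(36, {
    for (i in 1:20)
      expect_true(accept_direction(runif(1, -1, 1), up))
  })
  expect_error(accept_direction(1.5, pr), "outside")
  # accepted samples from a uniform proposal are distributed as the prior
  acc <- withr::with_seed(37, {
    u <- runif(2e4, -1, 1)
    keep <- vapply(u, function(x) accept_direction(x, pr), logical(1))
    u[keep]
  })
  bw <- diff(pr$bin_edges[1:2])
  cdf_prior <- stats::stepfun(pr$bin_edges[-1],
                              c(0, cumsum(pr$density) * bw))
  d_ks <- max(abs(cdf_prior(pr$bin_edges[-1]) -
                    stats::ecdf(acc)(pr$bin_edges[-1])))
  crit <- 1.628 / sqrt(length(acc)) # alpha = 0.01, one-sample
  expect_lt(d_ks, crit)
})

test_that("a delta prior at the true direction recovers production depths", {
  ev <- run200()$events
  g <- geom200()
  sub <- ev[1:100, ]
  bp <- recoilrange:::back_project_events(ev)
  st <- ensemble_stats(bp)
  reg <- build_sampling_region(bp, st, g)
  errs <- withr::with_seed(38, vapply(seq_len(nrow(sub)), function(i) {
    e <- sub[i, ]
    res <- reconstruct_event(e, delta_prior(e$parent_ux), reg, st,
                             recon_options(iterations = 2000), g)
    if (is.null(res)) return(NA_real_)
    res$coord[["u"]] - e$parent_x
  }, numeric(1)))
  expect_lt(mean(abs(errs), na.rm = TRUE), 2)
})

test_that("events with no accepted candidates are discarded and counted", {
  ev <- run200()$events[1:20, ]
  g <- geom200()
  bp <- recoilrange:::back_project_events(ev)
  st <- ensemble_stats(bp)
  tiny <- structure(list(half_width = 1e-9, u_bounds = c(0, 35),
                         v_bounds = c(-5, 5)), class = "sampling_region")
  res <- withr::with_seed(39,
    reconstruct_event(ev[1, ], prior200(), tiny, st,
                      recon_options(iterations = 50), g))
  expect_null(res)
})

test_that("full reconstruction is deterministic, conserves events, and respects the region", {
  ev <- run200()$events[1:400, ]
  g <- geom200()
  pr <- prior200()
  opts <- recon_options(iterations = 1000, seed = 5)
  r1 <- reconstruct_all(ev, pr, opts, g)
  r2 <- reconstruct_all(ev, pr, opts, g)
  expect_identical(r1$points, r2$points)
  expect_identical(nrow(r1$points) + r1$n_discarded, nrow(ev))
  expect_true(all(region_contains(r1$region, r1$stats,
                                  r1$points$est_u, r1$points$est_v)))
  expect_equal(r1$landmark$beta,
               r1$landmark$mu_rec + r1$landmark$sigma_rec)
  expect_error(reconstruct_all(ev[1, ], pr, opts, g), "insufficient")
})

test_that("reconstructed depth distribution vanishes proximal to the Bragg peak and is compressed", {
  b <- beam200()
  rec <- fixture("rec200", reconstruct_all(
    run200()$events, prior200(),
    recon_options(iterations = 1000, seed = 6), geom200()))
  h <- depth_histogram(rec$points$est_u)
  # the distribution (not stray single-event estimates) falls to zero
  # proximal to the Bragg peak
  expect_true(all(h$height[h$mids > b$range_r80] <= 0.05))
  last_bulk <- max(h$mids[h$height >= 0.1])
  expect_lt(last_bulk, b$range_r80)
  # known compression artifact: reconstructed spread does not exceed the
  # ground-truth spread of production depths
  expect_lte(rec$landmark$sigma_rec,
             stats::sd(run200()$events$parent_x) * 1.02)
})

test_that("the landmark is the mean plus one standard deviation", {
  expect_equal(landmark(c(5, 5))$beta, 5)
  lm2 <- landmark(c(4, 6))
  expect_equal(lm2$mu_rec, 5)
  expect_equal(lm2$sigma_rec, sqrt(2))
  expect_equal(lm2$beta, 5 + sqrt(2))
  expect_error(landmark(3), "insufficient")
  big <- withr::with_seed(40, rnorm(1e6, 10, 2))
  expect_lt(abs(landmark(big)$beta - 12), 0.01)
})
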