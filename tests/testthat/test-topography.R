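# Posterior region selection, distance D, local sphere-fit curvature C and
# the gridded topography maps, validated against analytic shapes and
# independent nonlinear least-squares oracles.

test_that("posterior selection keeps the spherical-cap fraction", {
  set.seed(1)
  pts <- tibble::as_tibble(as.data.frame(runif_sphere(50000) * 12))
  names(pts) <- c("x", "y", "z")
  kept <- select_posterior_region(pts, span_deg = 120)
  # cap area fraction (1 - cos 60) / 2 = 0.25
  expect_equal(nrow(kept) / nrow(pts), 0.25, tolerance = 0.02)
  ang <- acos(kept$y / sqrt(kept$x^2 + kept$y^2 + kept$z^2)) * 180 / pi
  expect_lte(max(ang), 60 + 1e-9)

  expect_identical(nrow(select_posterior_region(pts, 360)), nrow(pts))
  expect_error(select_posterior_region(pts, 0), "insufficient sampling")
})

test_that("distance is the norm in eye coordinates with the D > 12 flag", {
  pc <- tibble::tibble(x = c(0, 3), y = c(18, 4), z = c(0, 0))
  out <- compute_distance(pc)
  expect_equal(out$D, c(18, 5))
  expect_identical(out$elongated, c(TRUE, FALSE))
})

test_that("sphere fit is exact on noiseless data and flags degeneracies", {
  cap <- fibonacci_sphere(4000) * 14
  cap <- cap[cap[, 2] > 13, ]
  fit <- fit_local_sphere(cap)
  expect_equal(fit$radius, 14, tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  expect_false(fit$flagged)

  expect_true(fit_local_sphere(cap[1:5, ])$flagged)

  # near-planar neighbourhood: clamped to the cap radius and flagged
  g <- expand.grid(x = seq(-1, 1, 0.2), y = 0, z = seq(-1, 1, 0.2))
  flat <- fit_local_sphere(as.matrix(g))
  expect_true(flat$flagged)
  expect_identical(flat$reason, "near_planar")
  expect_lte(1 / flat$radius, 1e-3)
})

test_that("a noisy sphere still fits to its radius", {
  set.seed(7)
  pts <- runif_sphere(1200) * 14
  pts <- pts + matrix(rnorm(length(pts), sd = 0.1), ncol = 3)
  fit <- fit_local_sphere(pts)
  expect_lt(abs(fit$radius - 14), 0.2)
  expect_lt(abs(fit$rms_residual - 0.1), 0.02)
})

test_that("algebraic fit matches a nonlinear least-squares oracle", {
  # noiseless ellipsoid cap, <= 200 points: radii agree within 0.1%
  u <- fibonacci_sphere(3000)
  p <- u / sqrt((u[, 1] / 11)^2 + (u[, 2] / 14)^2 + (u[, 3] / 11)^2)
  cap <- p[sqrt(rowSums(sweep(p, 2, c(0, 14, 0))^2)) <= 3, ]
  expect_lte(nrow(cap), 200)
  fit <- fit_local_sphere(cap)
  oracle <- function(th) {
    d <- sqrt((cap[, 1] - th[1])^2 + (cap[, 2] - th[2])^2 +
                (cap[, 3] - th[3])^2)
    sum((d - th[4])^2)
  }
  o <- optim(c(0, 6, 0, 8), oracle, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(abs(fit$radius - o$par[4]) / o$par[4], 0.001)
})

test_that("curvature of an analytic sphere is 1/R to 1e-6", {
  pc <- phantom_surface(phantom_spec("sphere"), n_points = 6000)
  post <- select_posterior_region(pc)
  crv <- compute_curvature(post, neighbors_from = pc)
  expect_false(any(crv$C_flagged))
  expect_equal(crv$C, rep(1 / 12, nrow(crv)), tolerance = 1e-6)

  # a 14.3 mm posterior radius lands in the observed C_mean magnitude range
  pc2 <- phantom_surface(phantom_spec("sphere", semi_axes = rep(14.3, 3)),
                         n_points = 6000)
  crv2 <- compute_curvature(select_posterior_region(pc2), neighbors_from = pc2)
  expect_equal(mean(crv2$C), 0.070, tolerance = 1e-3)
})

test_that("ellipsoid pole curvature matches a dense brute-force fit", {
  spec <- phantom_spec("type1", semi_axes = c(11, 14, 11), bump_amplitude = 0)
  pc <- phantom_surface(spec, n_points = 20000)
  post <- select_posterior_region(pc)
  crv <- compute_curvature(post, neighbors_from = pc)
  pole <- which.max(crv$y)
  # oracle: dense analytic cap around the pole, converged geometric fit
  u <- fibonacci_sphere(200000)
  p <- u / sqrt((u[, 1] / 11)^2 + (u[, 2] / 14)^2 + (u[, 3] / 11)^2)
  cap <- p[sqrt(rowSums(sweep(p, 2, c(0, 14, 0))^2)) <= 3, ]
  oracle <- function(th) {
    d <- sqrt((cap[, 1] - th[1])^2 + (cap[, 2] - th[2])^2 +
                (cap[, 3] - th[3])^2)
    sum((d - th[4])^2)
  }
  o <- optim(c(0, 6, 0, 8), oracle, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(crv$C[pole], 1 / o$par[4], tolerance = 0.01)
})

test_that("scaling points scales D, inverts C and leaves C*D unchanged", {
  pc <- phantom_surface(phantom_spec("sphere"), n_points = 6000)
  s <- 1.37
  t1 <- compute_topography(pc)
  scaled <- pc
  scaled$x <- pc$x * s; scaled$y <- pc$y * s; scaled$z <- pc$z * s
  t2 <- compute_topography(scaled)
  expect_equal(t2$D, t1$D * s, tolerance = 1e-9)
  expect_equal(t2$C, t1$C / s, tolerance = 1e-9)
  expect_equal(t2$CD, t1$CD, tolerance = 1e-9)
})

test_that("D and C are invariant under joint rigid transforms", {
  spec <- phantom_spec("type1")
  pc <- phantom_surface(spec, n_points = 6000)
  tr <- phantom_truth(pc)
  fr <- build_eye_frame(tr$center, tr$vertex, radius = tr$inscribed_radius)
  topo0 <- compute_topography(to_eye_coordinates(pc, fr))

  pose <- random_rigid_pose(21)
  pc2 <- apply_pose(pc, pose)
  fr2 <- transform_frame(fr, pose)
  topo1 <- compute_topography(to_eye_coordinates(pc2, fr2))
  expect_equal(topo1$D, topo0$D, tolerance = 1e-9)
  expect_equal(topo1$C, topo0$C, tolerance = 1e-9)
})

test_that("topography maps are constant for a sphere and peak at bumps", {
  run <- sphere_surface_run()
  m <- run$map[run$map$n_points > 0, ]
  expect_lt(diff(range(m$D_mm)), 0.01)
  expect_lt(diff(range(m$C_per_mm)), 1e-4)
  # empty cells are missing, not zero
  expect_true(anyNA(run$map$D_mm))
  expect_false(any(run$map$D_mm == 0, na.rm = TRUE))

  # Type 1: central protrusion, map maximum within 10 degrees of the pole
  t1 <- type1_volume_run()
  m1 <- t1$map[!is.na(t1$map$D_mm), ]
  expect_lte(m1$polar_deg[which.max(m1$D_mm)], 10)

  # Type 2: off-axis protrusion; the map maximum sits at the analytic
  # max-D direction (from the origin) within 5 degrees
  spec2 <- phantom_spec("type2")
  th <- seq(0, 60, by = 0.1) * pi / 180
  u <- cbind(sin(th), cos(th), 0)
  r <- u * as.numeric(scleratopo:::phantom_radius(u, spec2))
  org <- phantom_truth(phantom_surface(spec2, 100))$origin
  rel <- sweep(r, 2, org)
  D <- sqrt(rowSums(rel^2))
  truth_polar <- atan2(sqrt(rel[, 1]^2 + rel[, 3]^2), rel[, 2])[which.max(D)] * 180 / pi
  r2 <- run_pipeline(phantom_volume(spec2), NULL, write_png = FALSE)
  m2 <- r2$map[!is.na(r2$map$D_mm), ]
  mx <- m2[which.max(m2$D_mm), ]
  expect_lt(abs(mx$polar_deg - truth_polar), 5)
  expect_lt(abs(mx$azimuth_deg), 10)  # bump lies in the temporal meridian
})

test_that("map CSV export round-trips the grid schema", {
  run <- sphere_surface_run()
  f <- withr::local_tempfile(fileext = ".csv")
  write_topography(run$map, f)
  back <- read_topography(f)
  expect_identical(names(back),
                   c("polar_deg", "azimuth_deg", "D_mm", "C_per_mm", "CD",
                     "n_points"))
  expect_equal(back$D_mm, run$map$D_mm, tolerance = 1e-9)
})
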