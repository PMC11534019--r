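# Pupillary-foveal frame: inscribed sphere, corneal vertex, frame
# construction and the insensitivity of the axis to posterior protrusions.

test_that("a voxelized ball is its own inscribed sphere", {
  sph <- find_inscribed_sphere(sphere_volume())
  expect_lt(vnorm_test(sph$center), 0.5)
  expect_lt(abs(sph$radius - 12), 0.5)
})

test_that("the inscribed sphere of a prolate spheroid has the minor radius", {
  # analytic: an interior axis point (0, y, 0) of the spheroid (a, b, a)
  # has boundary distance a * sqrt(1 - y^2 / (b^2 - a^2)), maximal at the
  # centre with value a = the minor semi-axis
  vol <- phantom_volume(phantom_spec("type1", semi_axes = c(11, 14, 11),
                                     bump_amplitude = 0))
  sph <- find_inscribed_sphere(vol)
  expect_lt(abs(sph$radius - 11), 0.5)
  expect_lt(abs(sph$center[1]), 0.5)  # on the long (Y) axis
  expect_lt(abs(sph$center[3]), 0.5)
})

test_that("a posterior bump does not move the inscribed sphere", {
  base <- phantom_spec("type1", semi_axes = c(11, 14, 11), bump_amplitude = 0)
  bumped <- phantom_spec("type1", semi_axes = c(11, 14, 11), bump_amplitude = 3)
  s0 <- find_inscribed_sphere(phantom_volume(base))
  s1 <- find_inscribed_sphere(phantom_volume(bumped))
  expect_lt(abs(s0$radius - s1$radius), 0.1)
  expect_lt(vnorm_test(s0$center - s1$center), 0.5)
})

test_that("inscribed sphere radius equals the min distance to the surface", {
  vol <- sphere_volume()
  sph <- find_inscribed_sphere(vol)
  pc <- extract_surface(vol, sigma = 0)
  d <- sqrt((pc$x - sph$center[1])^2 + (pc$y - sph$center[2])^2 +
              (pc$z - sph$center[3])^2)
  expect_lt(abs(min(d) - sph$radius), 0.25)
})

test_that("degenerate inscribed-sphere inputs error", {
  expect_error(find_inscribed_sphere(eye_volume(array(0L, c(8, 8, 8)), 0.5)),
               "empty foreground")
  thin <- array(0L, c(16, 16, 16)); thin[4:12, 8, 8] <- 1L
  expect_error(find_inscribed_sphere(eye_volume(thin, 0.5)), "degenerate")
})

test_that("corneal vertex lands on the anterior pole", {
  # exact sphere: any anterior point is maximal; result is deterministic
  pc <- phantom_surface(phantom_spec("sphere"), n_points = 5000)
  v1 <- find_corneal_vertex(pc, c(0, 0, 0), c(0, -1, 0))
  expect_equal(sqrt(sum(v1^2)), 12, tolerance = 0.5)
  expect_lt(v1[2], 0)
  expect_identical(v1, find_corneal_vertex(pc, c(0, 0, 0), c(0, -1, 0)))

  # elongated ellipsoid: unique anterior pole, recovered within 1 mm
  pe <- phantom_surface(phantom_spec("type1", semi_axes = c(11, 14, 11),
                                     bump_amplitude = 0), n_points = 20000)
  ve <- find_corneal_vertex(pe, c(0, 0, 0), c(0, -1, 0))
  expect_lt(vnorm_test(ve - c(0, -14, 0)), 1)

  # hint orthogonal to the true axis on a sphere: tie-break is deterministic
  v2 <- find_corneal_vertex(pc, c(0, 0, 0), c(1, 0, 0))
  expect_identical(v2, find_corneal_vertex(pc, c(0, 0, 0), c(1, 0, 0)))
  expect_gt(v2[1], 0)
  expect_error(find_corneal_vertex(pc, c(0, 0, 0), c(0, 1, 0) * NA),
               "zero-length|finite")
})

test_that("frame construction follows the stated geometry exactly", {
  fr <- build_eye_frame(c(0, 0, 0), c(0, -12, 0))
  expect_equal(fr$axis, c(0, 1, 0))
  expect_equal(fr$origin, c(0, 0, 0))
  # offset 12 gives ||origin - vertex|| = 12 exactly, any geometry
  set.seed(3)
  for (i in 1:5) {
    ctr <- rnorm(3); vtx <- ctr + unit_fixture(rnorm(3)) * runif(1, 5, 15)
    fr2 <- build_eye_frame(ctr, vtx, offset = 12)
    expect_equal(vnorm_test(fr2$origin - fr2$corneal_vertex), 12)
    expect_equal(vnorm_test(fr2$axis), 1, tolerance = 1e-12)
    # right-handed orthonormal rotation
    expect_equal(crossprod(fr2$rotation), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(det(fr2$rotation), 1, tolerance = 1e-12)
  }
  expect_error(build_eye_frame(c(0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("eye-coordinate transform is rigid and mirrors left eyes", {
  pc <- phantom_surface(phantom_spec("type1"), n_points = 2000)
  fr <- build_eye_frame(c(1, 2, 3), c(1, -10, 3), x_hint = c(1, 0, 0))
  out <- to_eye_coordinates(pc, fr)
  m0 <- as.matrix(pc[, c("x", "y", "z")])
  m1 <- as.matrix(out[, c("x", "y", "z")])
  i <- seq(1, 1900, by = 97); j <- i + 41
  d0 <- sqrt(rowSums((m0[i, ] - m0[j, ])^2))
  d1 <- sqrt(rowSums((m1[i, ] - m1[j, ])^2))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  # frame-aligned input: identity
  id_fr <- build_eye_frame(c(0, 5, 0), c(0, -7, 0), offset = 7)
  aligned <- tibble::tibble(x = c(1, 2), y = c(3, -1), z = c(0, 4))
  expect_equal(as.data.frame(to_eye_coordinates(aligned, id_fr))[, 1:3],
               as.data.frame(aligned), tolerance = 1e-12)

  # OS mirroring flips X and records chirality
  fr_os <- build_eye_frame(c(0, 5, 0), c(0, -7, 0), offset = 7,
                           laterality = "OS")
  mir <- to_eye_coordinates(aligned, fr_os)
  expect_equal(mir$x, -aligned$x)
  expect_true(surface_meta(mir)$chirality_mirrored)
})

test_that("axis recovery survives rigid poses within the stated bounds", {
  tol <- c(type0 = 3, type1 = 3, type2 = 5)
  for (ty in names(tol)) {
    pose <- random_rigid_pose(seed = match(ty, names(tol)) + 10)
    vol <- phantom_volume(phantom_spec(ty, rigid_pose = pose),
                          pose_in = "grid")
    tr <- phantom_truth(vol)$posed
    res <- run_pipeline(vol, output_dir = NULL, write_png = FALSE,
                        anterior_hint = tr$anterior_hint)
    expect_lt(angle_between_deg(res$frame$axis, tr$axis), tol[[ty]])
  }
})

test_that("a 4 mm posterior bump barely moves the recovered axis", {
  base <- phantom_spec("type1", semi_axes = c(11, 14.5, 11),
                       bump_amplitude = 0)
  bumped <- phantom_spec("type1", semi_axes = c(11, 14.5, 11),
                         bump_amplitude = 4)
  r0 <- run_pipeline(phantom_volume(base), NULL, write_png = FALSE)
  r1 <- run_pipeline(phantom_volume(bumped), NULL, write_png = FALSE)
  expect_lt(angle_between_deg(r0$frame$axis, r1$frame$axis), 1.5)
})

test_that("frame estimation is deterministic", {
  pc <- phantom_surface(phantom_spec("type1"), n_points = 4000)
  f1 <- estimate_eye_frame(pc, anterior_hint = c(0, -1, 0))
  f2 <- estimate_eye_frame(pc, anterior_hint = c(0, -1, 0))
  expect_identical(f1, f2)
})
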