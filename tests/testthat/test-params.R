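# The seven shape parameters: closed-form checks on toy vectors, exact
# sphere limits, monotonicity in protrusion amplitude and scaling laws.

test_that("parameters match closed-form order statistics on a toy vector", {
  topo <- toy_topography(c(10, 10, 14, 14))
  p <- compute_parameters(topo, min_points = 4)
  expect_equal(p$d_mean, 12)
  expect_equal(p$d_var, 4)   # population variance: mean of {4,4,4,4}
  # linear-interpolation percentile (type 7): h = 1 + 3 * 0.95 = 3.85,
  # x[3] + 0.85 * (x[4] - x[3]) = 14
  expect_equal(p$d_max, 14)
  expect_equal(p$cd_mean, 1)
  expect_equal(p$c_mean, 1 / 12)

  p2 <- compute_parameters(topo, min_points = 4, var_denominator = "sample")
  expect_equal(p2$d_var, 16 / 3)

  p80 <- compute_parameters(toy_topography(1:10), min_points = 4,
                            percentile = 80)
  expect_equal(p80$d_max, quantile(1:10, 0.8, names = FALSE))
})

test_that("an exact sphere gives the analytic limit values", {
  p <- sphere_surface_run()$parameters
  expect_equal(p$d_mean, 12, tolerance = 1e-6)
  expect_lt(p$d_var, 1e-10)
  expect_equal(p$c_mean, 1 / 12, tolerance = 1e-6)
  expect_equal(p$cd_mean, 1, tolerance = 1e-6)
  expect_equal(p$cd_max, 1, tolerance = 1e-6)
})

test_that("a displaced spherical posterior raises CD_max but not D_var", {
  # elongated eye whose posterior surface is still a 12 mm sphere, centred
  # 2 mm posterior to the pre-elongation origin
  u <- fibonacci_sphere(20000)
  pc <- tibble::as_tibble(as.data.frame(u * 12))
  names(pc) <- c("x", "y", "z")
  pc$y <- pc$y + 2
  topo <- compute_topography(pc)
  p <- compute_parameters(topo)
  expect_gt(p$cd_max, 1.1)
  expect_lt(p$d_var, 0.2)
})

test_that("ordering invariants hold on arbitrary topographies", {
  set.seed(5)
  for (i in 1:10) {
    D <- runif(300, 10, 20)
    C <- runif(300, 0.05, 0.2)
    p <- compute_parameters(toy_topography(D, C), min_points = 100)
    expect_gte(p$d_max, p$d_mean)
    expect_gte(p$c_max, p$c_mean)
    expect_gte(p$cd_max, p$cd_mean)
    expect_gte(p$d_var, 0)
  }
})

test_that("flagged points are excluded and scarcity errors", {
  topo <- toy_topography(c(rep(12, 300), rep(50, 10)))
  topo$flagged[301:310] <- TRUE
  p <- compute_parameters(topo)
  expect_equal(p$d_mean, 12)
  expect_identical(p$n_flagged, 10L)
  expect_error(compute_parameters(toy_topography(rep(12, 50))),
               "insufficient points")
})

test_that("D_var, D_max and CD_max increase strictly with bump amplitude", {
  vals <- amplitude_series()
  expect_true(all(diff(vals$d_var) > 0))
  expect_true(all(diff(vals$d_max) > 0))
  expect_true(all(diff(vals$cd_max) > 0))
})

test_that("uniform scaling acts as s on D, s^2 on D_var, identity on C*D", {
  pc <- phantom_surface(phantom_spec("type1"), n_points = 8000)
  tr <- phantom_truth(pc)
  fr <- build_eye_frame(tr$center, tr$vertex)
  eye <- to_eye_coordinates(pc, fr)
  s <- 1.25
  scaled <- eye
  scaled$x <- eye$x * s; scaled$y <- eye$y * s; scaled$z <- eye$z * s
  p1 <- compute_parameters(compute_topography(eye))
  # neighbourhood co-scales: C is defined relative to the surface scale
  p2 <- compute_parameters(compute_topography(scaled,
                                              neighborhood_radius = 3 * s))
  expect_equal(p2$d_mean, p1$d_mean * s, tolerance = 1e-6)
  expect_equal(p2$d_max, p1$d_max * s, tolerance = 1e-6)
  expect_equal(p2$d_var, p1$d_var * s^2, tolerance = 1e-6)
  expect_equal(p2$cd_mean, p1$cd_mean, tolerance = 1e-6)
  expect_equal(p2$cd_max, p1$cd_max, tolerance = 1e-6)
})

test_that("parameter tables pivot long and summarise per group", {
  eyes <- dplyr::bind_rows(purrr::map(1:3, function(i) {
    p <- compute_parameters(toy_topography(rnorm(300, 12, i / 10)),
                            min_points = 100)
    dplyr::bind_cols(tibble::tibble(eye_id = paste0("eye", i),
                                    group = c("0", "1", "2")[i]), p)
  }))
  tab <- parameters_table(eyes)
  expect_identical(nrow(tab$values), 21L)  # 3 eyes x 7 parameters
  expect_identical(names(tab$values), c("eye_id", "group", "parameter", "value"))
  # single-eye groups report SD as missing, not zero
  expect_true(all(is.na(tab$summary$sd)))
  dup <- eyes; dup$eye_id <- "same"
  expect_error(parameters_table(dup), "duplicate eye ids")
  expect_error(parameters_table(eyes[, -1]), "missing columns")
})
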