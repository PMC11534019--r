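# Shared fixtures, built once per session and cached: phantom pipelines are
# the expensive part of the suite, and several files interrogate the same
# runs.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

sphere_surface_run <- function() cached("sphere_surface_run", {
  run_pipeline(phantom_surface(phantom_spec("sphere"), n_points = 20000),
               output_dir = NULL, write_png = FALSE)
})

sphere_volume <- function() cached("sphere_volume", {
  phantom_volume(phantom_spec("sphere"))
})

sphere_volume_run <- function() cached("sphere_volume_run", {
  run_pipeline(sphere_volume(), output_dir = NULL, write_png = FALSE)
})

type1_volume <- function() cached("type1_volume", {
  phantom_volume(phantom_spec("type1"))
})

type1_volume_run <- function() cached("type1_volume_run", {
  run_pipeline(type1_volume(), output_dir = NULL, write_png = FALSE)
})

# full volume-path cohort with per-eye parameters and axis recovery errors
cohort_run <- function(n_per_type = 10, seed = 42L) cached("cohort_run", {
  cohort <- phantom_cohort(n_per_type = n_per_type, seed = seed,
                           output = "volume")
  rows <- purrr::pmap(cohort, function(eye_id, type, object) {
    res <- run_pipeline(object, output_dir = NULL, write_png = FALSE)
    tr <- phantom_truth(object)
    dplyr::bind_cols(
      tibble::tibble(
        eye_id = eye_id, group = type,
        axis_error_deg = angle_between_deg(res$frame$axis, tr$posed$axis)
      ),
      tibble::as_tibble(res$parameters)
    )
  })
  dplyr::bind_rows(rows)
})

vnorm_test <- function(v) sqrt(sum(v^2))
unit_fixture <- function(v) v / sqrt(sum(v^2))

# parameters along a bump-amplitude series (analytic surface path)
amplitude_series <- function() cached("amplitude_series", {
  purrr::map(c(0, 1, 2, 3, 4), function(A) {
    spec <- phantom_spec("type1", semi_axes = c(11, 14.5, 11),
                         bump_amplitude = A, seed = 1L)
    run_pipeline(phantom_surface(spec, n_points = 12000),
                 output_dir = NULL, write_png = FALSE)$parameters
  }) |> dplyr::bind_rows()
})

new_surface_fixture <- function() {
  tibble::tibble(
    x = c(1.123456, -2.5, 0), y = c(0.654321, 3.25, -1),
    z = c(12.111111, -0.125, 4)
  )
}

# uniform random directions on the unit sphere
runif_sphere <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# minimal hand-built topography tibble for closed-form parameter checks
toy_topography <- function(D, C = rep(1 / 12, length(D))) {
  tibble::tibble(
    x = 0, y = D, z = 0, D = D, C = C, CD = C * D,
    flagged = FALSE
  )
}
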