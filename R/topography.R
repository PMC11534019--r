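# Posterior scleral topography: 120-degree posterior region selection,
# per-point distance D to the pre-elongation centre, local sphere-fit
# curvature C (3 mm neighbourhoods), their product, and gridded maps.

#' Select the posterior region
#'
#' Keeps points whose direction from the origin makes an angle of at most
#' `span_deg / 2` with the posterior axis `+Y`. Points must already be in
#' eye coordinates ([to_eye_coordinates()]).
#'
#' @param pc data frame of eye-frame points (x/y/z mm).
#' @param span_deg full angular span of the cone (default 120, i.e. a
#'   60-degree half-angle about the posterior pole).
#' @param min_points minimum surviving points (default 200) below which the
#'   sampling is deemed insufficient.
#' @return filtered `eye_surface` tibble.
#' @export
select_posterior_region <- function(pc, span_deg = 120, min_points = 200) {
  if (!is.numeric(span_deg) || span_deg < 0) abort("span_deg must be >= 0")
  m <- as_points_matrix(pc)
  d <- row_norms(m)
  ok <- d > 0
  cosang <- ifelse(ok, m[, 2] / d, -1)
  keep <- ok & cosang >= cos(min(span_deg, 360) / 2 * pi / 180)
  if (sum(keep) < max(min_points, 1)) {
    abort(paste0("insufficient sampling: only ", sum(keep),
                 " points fall in the ", span_deg, "-degree posterior region"))
  }
  out <- tibble::as_tibble(as.data.frame(pc)[keep, , drop = FALSE])
  new_eye_surface(out, meta = c(surface_meta(pc), list(span_deg = span_deg)))
}

#' Per-point distance to the pre-elongation eye centre
#'
#' Adds `D` (mm), the Euclidean distance of each eye-frame point to the
#' origin, and `elongated`, the predicate `D > normal_radius_mm` flagging
#' surface farther out than the posterior sphere of a normal 24 mm eye.
#'
#' @param pc data frame of eye-frame points.
#' @param normal_radius_mm radius of the reference normal eye (default 12).
#' @return input tibble with `D` and `elongated` columns.
#' @export
compute_distance <- function(pc, normal_radius_mm = 12) {
  m <- as_points_matrix(pc)
  out <- tibble::as_tibble(as.data.frame(pc))
  out$D <- row_norms(m)
  out$elongated <- out$D > normal_radius_mm
  new_eye_surface(out, meta = surface_meta(pc))
}

#' Fit a sphere to a local surface neighbourhood
#'
#' Algebraic least-squares sphere fit (linearised: minimise
#' `||p||^2 - 2 c.p - d` over centre `c` and `d`), refined by Gauss-Newton
#' iteration on the geometric (orthogonal) residuals, which removes the
#' algebraic fit's radius-shrinking noise bias. Neighbourhoods with
#' fewer than `min_neighbors` points are flagged; near-planar fits (radius
#' above `max_radius`) are clamped to `max_radius` and flagged.
#'
#' @param points data frame or matrix of surface points (mm).
#' @param center_point optional centre of the neighbourhood ball; when
#'   given, only points within `neighborhood_radius` of it are fitted.
#' @param neighborhood_radius Euclidean ball radius in mm (default 3).
#' @param min_neighbors minimum usable neighbours (default 10).
#' @param max_radius planarity cap in mm (default 1000).
#' @param refine refine the algebraic solution by iterated Gauss-Newton on
#'   the orthogonal residuals (default TRUE).
#' @return list with `radius` (mm), `center`, `rms_residual` (mm),
#'   `n_neighbors`, `flagged`, `reason`.
#' @export
fit_local_sphere <- function(points, center_point = NULL,
                             neighborhood_radius = 3, min_neighbors = 10,
                             max_radius = 1000, refine = TRUE) {
  m <- as_points_matrix(points)
  if (!is.null(center_point)) {
    q <- as.numeric(center_point)
    d2 <- (m[, 1] - q[1])^2 + (m[, 2] - q[2])^2 + (m[, 3] - q[3])^2
    m <- m[d2 <= neighborhood_radius^2, , drop = FALSE]
  }
  sphere_fit_algebraic(m, min_neighbors = min_neighbors,
                       max_radius = max_radius, refine = refine)
}

sphere_fit_algebraic <- function(m, min_neighbors = 10, max_radius = 1000,
                                 refine = TRUE) {
  n <- nrow(m)
  flagged_out <- function(reason) {
    list(radius = NA_real_, center = rep(NA_real_, 3),
         rms_residual = NA_real_, n_neighbors = n, flagged = TRUE,
         reason = reason)
  }
  planar_out <- function() {
    list(radius = max_radius, center = rep(NA_real_, 3),
         rms_residual = NA_real_, n_neighbors = n, flagged = TRUE,
         reason = "near_planar")
  }
  if (n < min_neighbors) return(flagged_out("too_few_neighbors"))
  A <- cbind(2 * m, 1)
  b <- rowSums(m^2)
  beta <- tryCatch(unname(qr.solve(A, b)), error = function(e) NULL)
  # a rank-deficient system means the neighbourhood carries no resolvable
  # curvature (coplanar/collinear points): clamp to the planarity cap
  if (is.null(beta)) return(planar_out())
  ctr <- beta[1:3]
  r2 <- beta[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) return(planar_out())
  r <- as.numeric(sqrt(r2))
  if (refine && r <= max_radius) {
    # Gauss-Newton on the geometric residuals ||p - c|| - r, iterated to
    # convergence: the one-shot algebraic solution underestimates the
    # radius badly on shallow noisy caps, the orthogonal fit does not
    for (it in seq_len(20)) {
      rel <- sweep(m, 2, ctr)
      dist <- row_norms(rel)
      J <- cbind(-rel / pmax(dist, 1e-12), -1)
      res <- dist - r
      step <- tryCatch(unname(qr.solve(J, -res)),
                       error = function(e) rep(0, 4))
      if (!all(is.finite(step)) || r + step[4] <= 0) break
      ctr <- ctr + step[1:3]; r <- r + step[4]
      if (sqrt(sum(step^2)) < 1e-10 || r > max_radius) break
    }
  }
  rel <- sweep(m, 2, ctr)
  dist <- row_norms(rel)
  rms <- sqrt(mean((dist - r)^2))
  if (r > max_radius) {
    return(list(radius = max_radius, center = as.numeric(ctr),
                rms_residual = rms, n_neighbors = n, flagged = TRUE,
                reason = "near_planar"))
  }
  list(radius = r, center = as.numeric(ctr), rms_residual = rms,
       n_neighbors = n, flagged = FALSE, reason = NA_character_)
}

#' Per-point local sphere-fit curvature
#'
#' `C_i = 1 / R_i` with `R_i` the radius of the least-squares sphere fitted
#' to all surface points within `neighborhood_radius` of point `i`.
#' Curvature is unsigned (a sphere fit carries no orientation). Flagged
#' points (too few neighbours, degenerate or near-planar fits) carry `NA`
#' curvature and `C_flagged = TRUE`; they are excluded from downstream
#' statistics rather than imputed.
#'
#' @param pc data frame of points at which to evaluate curvature.
#' @param neighbors_from optional larger cloud supplying the neighbourhoods
#'   (e.g. the full surface when `pc` is the posterior region), so that fits
#'   near the region edge are not truncated.
#' @inheritParams fit_local_sphere
#' @return `pc` with columns `C` (1/mm), `C_flagged`, `n_neighbors`.
#' @export
compute_curvature <- function(pc, neighbors_from = NULL,
                              neighborhood_radius = 3, min_neighbors = 10,
                              max_radius = 1000, refine = TRUE) {
  m <- as_points_matrix(pc)
  ref <- if (is.null(neighbors_from)) m else as_points_matrix(neighbors_from)
  idx <- cell_index_build(ref, neighborhood_radius)
  n <- nrow(m)
  C <- rep(NA_real_, n); flag <- logical(n); nn <- integer(n)
  for (i in seq_len(n)) {
    ids <- cell_index_query(idx, m[i, ], neighborhood_radius)
    fit <- sphere_fit_algebraic(ref[ids, , drop = FALSE],
                                min_neighbors = min_neighbors,
                                max_radius = max_radius, refine = refine)
    nn[i] <- fit$n_neighbors
    if (fit$flagged && is.na(fit$radius)) {
      flag[i] <- TRUE
    } else {
      C[i] <- 1 / fit$radius
      flag[i] <- fit$flagged
    }
  }
  out <- tibble::as_tibble(as.data.frame(pc))
  out$C <- C
  out$C_flagged <- flag
  out$n_neighbors <- nn
  new_eye_surface(out, meta = surface_meta(pc))
}

#' Compute the posterior scleral topography
#'
#' Full per-point topography over the posterior region: selects the
#' `span_deg` cone, computes distance `D` to the pre-elongation centre,
#' local sphere-fit curvature `C` with `neighborhood_radius` mm
#' neighbourhoods drawn from the full surface, and the per-point product
#' `CD = C * D`.
#'
#' @param pc surface in eye coordinates ([to_eye_coordinates()]).
#' @param span_deg posterior cone span in degrees (default 120).
#' @param neighborhood_radius curvature neighbourhood in mm (default 3).
#' @param min_points minimum posterior points (default 200).
#' @inheritParams fit_local_sphere
#' @return an `eye_topography` tibble with columns `x, y, z, D, elongated,
#'   C, C_flagged, n_neighbors, CD, flagged`.
#' @export
compute_topography <- function(pc, span_deg = 120, neighborhood_radius = 3,
                               min_points = 200, min_neighbors = 10,
                               max_radius = 1000, refine = TRUE) {
  post <- select_posterior_region(pc, span_deg = span_deg,
                                  min_points = min_points)
  post <- compute_distance(post)
  post <- compute_curvature(post, neighbors_from = pc,
                            neighborhood_radius = neighborhood_radius,
                            min_neighbors = min_neighbors,
                            max_radius = max_radius, refine = refine)
  post$CD <- post$C * post$D
  post$flagged <- post$C_flagged | !is.finite(post$D) | !is.finite(post$C)
  out <- tibble::as_tibble(as.data.frame(post))
  class(out) <- c("eye_topography", class(tibble::tibble()))
  attr(out, "meta") <- c(surface_meta(pc),
                         list(span_deg = span_deg,
                              neighborhood_radius = neighborhood_radius))
  out
}

#' Grid the topography onto an azimuthal-equidistant map
#'
#' Projects posterior points onto a polar grid centred on the posterior
#' pole: polar angle from the pole (degrees, radial coordinate) by azimuth
#' (degrees, measured from `+X` temporal towards `+Z` superior). Each cell
#' holds the mean `D`, `C` and `CD` of its member points; cells with no
#' supporting points are kept as missing (`NA`), never zero.
#'
#' @param topo an `eye_topography` from [compute_topography()].
#' @param grid_res_deg angular cell size in degrees (default 1).
#' @return an `eye_topography_map` tibble with columns `polar_deg,
#'   azimuth_deg, D_mm, C_per_mm, CD, n_points`.
#' @export
build_topography_map <- function(topo, grid_res_deg = 1) {
  stopifnot(is.data.frame(topo), all(c("D", "C", "CD") %in% names(topo)))
  meta <- attr(topo, "meta") %||% list()
  span <- meta$span_deg %||% 120
  res <- grid_res_deg
  polar <- acos(pmin(1, pmax(-1, topo$y / topo$D))) * 180 / pi
  azim <- atan2(topo$z, topo$x) * 180 / pi
  pb <- pmin(floor(polar / res), ceiling(span / 2 / res) - 1)
  ab <- pmin(floor((azim + 180) / res), ceiling(360 / res) - 1)
  df <- tibble::tibble(
    polar_deg = (pb + 0.5) * res,
    azimuth_deg = (ab + 0.5) * res - 180,
    D = topo$D, C = topo$C, CD = topo$CD, flagged = topo$flagged
  )
  grid <- df |>
    dplyr::group_by(.data$polar_deg, .data$azimuth_deg) |>
    dplyr::summarise(
      D_mm = mean(.data$D, na.rm = TRUE),
      C_per_mm = mean(.data$C[!.data$flagged], na.rm = TRUE),
      CD = mean(.data$CD[!.data$flagged], na.rm = TRUE),
      n_points = dplyr::n(),
      .groups = "drop"
    )
  full <- tidyr::expand_grid(
    polar_deg = seq(res / 2, span / 2 - res / 2 + 1e-9, by = res),
    azimuth_deg = seq(res / 2 - 180, 180 - res / 2 + 1e-9, by = res)
  )
  out <- dplyr::left_join(full, grid, by = c("polar_deg", "azimuth_deg")) |>
    dplyr::mutate(n_points = tidyr::replace_na(.data$n_points, 0L),
                  dplyr::across(c("D_mm", "C_per_mm", "CD"),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
  class(out) <- c("eye_topography_map", class(tibble::tibble()))
  attr(out, "meta") <- c(meta, list(grid_res_deg = res))
  out
}

#' Write a topography map to CSV
#' @param map an `eye_topography_map`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_topography <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Read a topography map CSV back
#' @param path CSV written by [write_topography()].
#' @return an `eye_topography_map` tibble.
#' @export
read_topography <- function(path) {
  out <- tibble::as_tibble(read.csv(path))
  class(out) <- c("eye_topography_map", class(tibble::tibble()))
  out
}

#' @export
autoplot.eye_topography_map <- function(object, what = c("D", "C", "CD"), ...) {
  what <- match.arg(what)
  col <- switch(what, D = "D_mm", C = "C_per_mm", CD = "CD")
  lab <- switch(what, D = "D (mm)", C = expression(C ~ (mm^-1)), CD = "C·D")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$azimuth_deg, y = .data$polar_deg,
                               fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(theta = "x", start = pi) +
    ggplot2::scale_fill_viridis_c(na.value = "grey92", name = lab) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(
      x = "azimuth (deg, from temporal)",
      y = "polar angle from posterior pole (deg)",
      title = paste("Posterior scleral topography:", what)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eye_topography <- function(object, what = c("D", "C", "CD"),
                                    grid_res_deg = 1, ...) {
  autoplot(build_topography_map(object, grid_res_deg = grid_res_deg),
           what = match.arg(what), ...)
}

#' Plot a topography map
#' @param x an `eye_topography_map`.
#' @param ... passed to [autoplot.eye_topography_map()].
#' @return a ggplot, invisibly (after printing).
#' @export
plot.eye_topography_map <- function(x, ...) {
  p <- autoplot(x, ...)
  print(p)
  invisible(p)
}
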