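# Synthetic eyeball phantoms with analytic ground truth: a base ellipsoid
# plus an optional Gaussian angular protrusion, as analytic point clouds
# (Fibonacci-sphere sampling) or voxelised masks. The three default
# morphologies mirror the qualitative staphyloma classes: Type 0 (no
# apparent protrusion), Type 1 (elongated, symmetric conical posterior
# protrusion), Type 2 (elongated, sharp off-axis protrusion).

phantom_defaults <- list(
  sphere = list(semi_axes = c(12, 12, 12), bump_amplitude = 0,
                bump_direction = c(0, 1, 0), bump_angular_sigma = 25),
  type0 = list(semi_axes = c(11.5, 12.5, 11.5), bump_amplitude = 0,
               bump_direction = c(0, 1, 0), bump_angular_sigma = 25),
  type1 = list(semi_axes = c(11, 14.5, 11), bump_amplitude = 1.5,
               bump_direction = c(0, 1, 0), bump_angular_sigma = 25),
  type2 = list(semi_axes = c(11, 16, 11), bump_amplitude = 3,
               bump_direction = c(sin(25 * pi / 180), cos(25 * pi / 180), 0),
               bump_angular_sigma = 15)
)

#' Specify a synthetic eyeball phantom
#'
#' The radial model is `r(u) = r_ellipsoid(u) + A exp(-psi^2 / (2 sigma^2))`
#' where `u` is a unit direction from the ellipsoid centre, `psi` its angle
#' to `bump_direction`, `A = bump_amplitude` (mm) and `sigma =
#' bump_angular_sigma` (degrees). The phantom frame has `+Y` posterior;
#' anterior is `-Y`.
#'
#' @param type `"sphere"`, `"type0"`, `"type1"` or `"type2"`; sets defaults
#'   that the remaining arguments override.
#' @param semi_axes ellipsoid semi-axes `(a_x, a_y, a_z)` in mm.
#' @param bump_amplitude protrusion amplitude `A` in mm (`>= 0`).
#' @param bump_direction unit direction of the protrusion (phantom frame).
#' @param bump_angular_sigma angular width of the protrusion in degrees.
#' @param noise_sigma per-coordinate Gaussian noise sigma in mm (surfaces).
#' @param rigid_pose optional [rigid_pose()] applied last.
#' @param voxel_spacing voxel size in mm for [phantom_volume()]; scalar or
#'   length 3.
#' @param seed integer seed fixing all randomness.
#' @param laterality `"OD"` or `"OS"`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(type = c("sphere", "type0", "type1", "type2"),
                         semi_axes = NULL, bump_amplitude = NULL,
                         bump_direction = NULL, bump_angular_sigma = NULL,
                         noise_sigma = 0, rigid_pose = NULL,
                         voxel_spacing = 0.5, seed = 1L,
                         laterality = c("OD", "OS")) {
  type <- match.arg(type)
  laterality <- match.arg(laterality)
  def <- phantom_defaults[[type]]
  spec <- list(
    type = type,
    semi_axes = as.numeric(semi_axes %||% def$semi_axes),
    bump_amplitude = as.numeric(bump_amplitude %||% def$bump_amplitude),
    bump_direction = unit_vec(as.numeric(bump_direction %||% def$bump_direction)),
    bump_angular_sigma = as.numeric(bump_angular_sigma %||% def$bump_angular_sigma),
    noise_sigma = noise_sigma, rigid_pose = rigid_pose,
    voxel_spacing = rep(as.numeric(voxel_spacing), length.out = 3),
    seed = as.integer(seed), laterality = laterality
  )
  if (length(spec$semi_axes) != 3 || any(spec$semi_axes <= 0)) {
    abort("semi_axes must be three positive lengths (mm)")
  }
  if (spec$bump_amplitude < 0) abort("bump_amplitude must be >= 0")
  if (spec$bump_amplitude > 0 && spec$bump_angular_sigma <= 0) {
    abort("bump_angular_sigma must be positive when the bump has amplitude")
  }
  if (spec$bump_amplitude >= min(spec$semi_axes)) {
    abort("bump too large: the radial model would self-intersect")
  }
  structure(spec, class = "phantom_spec")
}

# radial model evaluated at unit directions (n x 3 matrix)
phantom_radius <- function(dirs, spec) {
  a <- spec$semi_axes
  r_ell <- 1 / sqrt((dirs[, 1] / a[1])^2 + (dirs[, 2] / a[2])^2 +
                      (dirs[, 3] / a[3])^2)
  if (spec$bump_amplitude > 0) {
    cosp <- pmin(1, pmax(-1, dirs %*% spec$bump_direction))
    psi <- acos(cosp)
    sb <- spec$bump_angular_sigma * pi / 180
    r_ell <- r_ell + spec$bump_amplitude * exp(-psi^2 / (2 * sb^2))
  }
  as.numeric(r_ell)
}

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(x = s * cos(th), y = z, z = s * sin(th))
}

#' Generate an analytic phantom surface with ground truth
#'
#' Samples the radial model on a Fibonacci lattice, adds seeded Gaussian
#' coordinate noise, and applies the rigid pose last. Ground truth (eye
#' centre, corneal vertex, pupillary-foveal axis, pre-elongation origin and
#' per-point analytic D) is emitted for the pre-noise, pre-pose surface;
#' posed copies of the landmark truth are included for convenience.
#'
#' @param spec a [phantom_spec()].
#' @param n_points number of surface points (default 20000).
#' @param offset_mm vertex-to-origin offset used for the ground-truth origin
#'   (default 12).
#' @return an `eye_surface` tibble; `phantom_truth()` retrieves the truth.
#' @export
phantom_surface <- function(spec, n_points = 20000, offset_mm = 12) {
  stopifnot(inherits(spec, "phantom_spec"))
  dirs <- fibonacci_sphere(n_points)
  r <- phantom_radius(dirs, spec)
  if (any(r <= 0)) abort("bump too large: the radial model would self-intersect")
  pts <- dirs * r

  u_ant <- c(0, -1, 0)
  vertex <- as.numeric(phantom_radius(matrix(u_ant, 1, 3), spec)) * u_ant
  axis <- c(0, 1, 0)
  origin <- vertex + offset_mm * axis
  truth <- list(
    center = c(0, 0, 0),
    inscribed_radius = min(spec$semi_axes),
    vertex = vertex, axis = axis, origin = origin,
    D = sqrt((pts[, 1] - origin[1])^2 + (pts[, 2] - origin[2])^2 +
               (pts[, 3] - origin[3])^2),
    anterior_hint = u_ant
  )

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    pts <- pts + matrix(rnorm(3 * n_points, sd = spec$noise_sigma),
                        n_points, 3)
  }
  if (!is.null(spec$rigid_pose)) {
    P <- spec$rigid_pose
    pts <- as.matrix(apply_pose(pts, P))
    mv <- function(p) as.numeric(P$rotation %*% p + P$translation)
    truth$posed <- list(center = mv(truth$center), vertex = mv(truth$vertex),
                        axis = as.numeric(P$rotation %*% truth$axis),
                        origin = mv(truth$origin),
                        anterior_hint = as.numeric(P$rotation %*% u_ant))
  } else {
    truth$posed <- truth[c("center", "vertex", "axis", "origin", "anterior_hint")]
  }
  colnames(pts) <- c("x", "y", "z")
  out <- new_eye_surface(tibble::as_tibble(as.data.frame(pts)),
                         meta = list(source = paste0("phantom:", spec$type),
                                     laterality = spec$laterality))
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  out
}

#' Ground truth attached to a phantom
#' @param x a phantom surface or volume.
#' @return the ground-truth list (centre, vertex, axis, origin, analytic D).
#' @export
phantom_truth <- function(x) attr(x, "truth")

#' Voxelise a phantom into a labeled volume
#'
#' Inside-test voxelisation of the radial model at `spec$voxel_spacing`.
#' With `pose_in = "affine"` the mask is built in the phantom frame and the
#' header affine encodes the rigid pose; with `"grid"` the phantom is
#' rotated into an axis-aligned world grid (re-discretised), which is the
#' harder test of pose invariance.
#'
#' @param spec a [phantom_spec()].
#' @param fov_mm cubic field of view in mm (default 44).
#' @param pose_in `"affine"` or `"grid"`.
#' @return an [eye_volume()] with the phantom truth attached.
#' @export
phantom_volume <- function(spec, fov_mm = 44, pose_in = c("affine", "grid")) {
  stopifnot(inherits(spec, "phantom_spec"))
  pose_in <- match.arg(pose_in)
  sp <- spec$voxel_spacing
  rmax <- max(spec$semi_axes) + spec$bump_amplitude
  if (2 * (rmax + max(sp)) > fov_mm) abort("phantom exceeds fov")
  dims <- as.integer(ceiling(fov_mm / sp))
  ax_coords <- lapply(1:3, function(a) (0:(dims[a] - 1)) * sp[a] - (dims[a] - 1) * sp[a] / 2)
  X <- rep(ax_coords[[1]], times = dims[2] * dims[3])
  Y <- rep(rep(ax_coords[[2]], each = dims[1]), times = dims[3])
  Z <- rep(ax_coords[[3]], each = dims[1] * dims[2])
  P <- spec$rigid_pose

  if (pose_in == "grid" && !is.null(P)) {
    # world grid centred on the posed phantom centre; map back to phantom frame
    ctr <- P$translation
    Xw <- X + ctr[1]; Yw <- Y + ctr[2]; Zw <- Z + ctr[3]
    Q <- cbind(Xw - P$translation[1], Yw - P$translation[2], Zw - P$translation[3]) %*% P$rotation
    Xp <- Q[, 1]; Yp <- Q[, 2]; Zp <- Q[, 3]
  } else {
    Xp <- X; Yp <- Y; Zp <- Z
  }
  nrm <- sqrt(Xp^2 + Yp^2 + Zp^2)
  u <- cbind(Xp, Yp, Zp) / pmax(nrm, 1e-12)
  inside <- nrm <= phantom_radius(u, spec)
  vox <- array(as.integer(inside), dim = dims)

  affine <- diag(4)
  grid_origin <- vapply(ax_coords, function(v) v[1], numeric(1))
  if (pose_in == "affine" && !is.null(P)) {
    affine[1:3, 1:3] <- P$rotation %*% diag(sp)
    affine[1:3, 4] <- as.numeric(P$rotation %*% grid_origin + P$translation)
  } else if (pose_in == "grid" && !is.null(P)) {
    affine[1:3, 1:3] <- diag(sp)
    affine[1:3, 4] <- grid_origin + P$translation
  } else {
    affine[1:3, 1:3] <- diag(sp)
    affine[1:3, 4] <- grid_origin
  }
  out <- eye_volume(vox, sp, affine)
  truth <- phantom_truth(phantom_surface(spec, n_points = 1000))
  attr(out, "truth") <- truth
  attr(out, "spec") <- spec
  out
}

#' Generate a seeded phantom cohort
#'
#' Per-type parameter jitter (semi-axes +/-5%, bump amplitude +/-20%,
#' uniform, seeded) produces within-type variability; the result is
#' deterministic given the seed.
#'
#' @param n_per_type phantoms per type (default 10).
#' @param types character vector of phantom types.
#' @param seed cohort seed.
#' @param output `"volume"` or `"surface"`.
#' @param n_points surface points per phantom when `output = "surface"`.
#' @param fov_mm field of view for volumes.
#' @return tibble with columns `eye_id`, `type` and a list-column `object`
#'   holding the phantoms (truth attached to each).
#' @export
phantom_cohort <- function(n_per_type = 10,
                           types = c("type0", "type1", "type2"),
                           seed = 42L, output = c("volume", "surface"),
                           n_points = 20000, fov_mm = 44) {
  output <- match.arg(output)
  stopifnot(n_per_type >= 1)
  set.seed(seed)
  rows <- list()
  for (ty in types) {
    for (i in seq_len(n_per_type)) {
      def <- phantom_defaults[[ty]]
      sa <- def$semi_axes * runif(3, 0.95, 1.05)
      amp <- def$bump_amplitude * runif(1, 0.8, 1.2)
      sub_seed <- sample.int(.Machine$integer.max, 1)
      spec <- phantom_spec(ty, semi_axes = sa, bump_amplitude = amp,
                           seed = sub_seed)
      obj <- if (output == "volume") phantom_volume(spec, fov_mm = fov_mm)
             else phantom_surface(spec, n_points = n_points)
      rows[[length(rows) + 1]] <- tibble::tibble(
        eye_id = sprintf("%s_%02d", ty, i), type = ty, object = list(obj)
      )
    }
  }
  dplyr::bind_rows(rows)
}
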