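# The pupillary-foveal coordinate frame: maximally inscribed sphere,
# corneal vertex, axis, and the hypothetical pre-elongation eye centre
# placed `offset` (default 12) mm posterior to the vertex.

#' Find the maximally inscribed sphere
#'
#' Locates the largest ball fully inside the eyeball. For volumes the search
#' is the argmax of the Euclidean distance transform of the foreground,
#' refined to sub-voxel precision by continuous maximisation of the distance
#' to the surface point cloud; for surface point clouds the continuous
#' search starts at the centroid. The inscribed-sphere centre is what makes
#' the axis estimate insensitive to posterior protrusions: a bump only adds
#' volume far from the centre and cannot move the distance-transform
#' maximum.
#'
#' @param x an [eye_volume()] or a data frame of surface points (x/y/z, mm).
#' @param refine run the continuous sub-voxel refinement (volumes only).
#' @param ... unused.
#' @return list with `center` (mm) and `radius` (mm).
#' @export
find_inscribed_sphere <- function(x, ...) UseMethod("find_inscribed_sphere")

#' @rdname find_inscribed_sphere
#' @export
find_inscribed_sphere.eye_volume <- function(x, refine = TRUE, ...) {
  if (sum(x$voxels) == 0) abort("empty foreground")
  D2 <- edt_squared(x$voxels, x$spacing)
  mx <- max(D2)
  if (sqrt(mx) < 2 * min(x$spacing)) {
    abort("degenerate mask: inscribed radius below two voxels")
  }
  # centroid of the near-maximal plateau, in world coords, as the start
  thr <- (sqrt(mx) - 0.5 * min(x$spacing))^2
  lin <- which(D2 >= thr)
  d <- dim(x$voxels)
  vox <- cbind(
    (lin - 1L) %% d[1],
    ((lin - 1L) %/% d[1]) %% d[2],
    (lin - 1L) %/% (d[1] * d[2])
  )
  w <- vox %*% t(x$affine[1:3, 1:3])
  w <- sweep(w, 2, x$affine[1:3, 4], "+")
  start <- colMeans(w)

  surf <- iso_vertices(x$voxels + 0, x$affine, normals = FALSE)
  pts <- as_points_matrix(surf)
  if (!refine) {
    r <- min_dist_to(pts, start)
    return(list(center = as.numeric(start), radius = r))
  }
  refine_inscribed(pts, start)
}

#' @rdname find_inscribed_sphere
#' @export
find_inscribed_sphere.data.frame <- function(x, ...) {
  pts <- as_points_matrix(x)
  if (nrow(pts) < 10) abort("too few surface points for an inscribed sphere")
  res <- refine_inscribed(pts, colMeans(pts))
  if (res$radius < 1) abort("degenerate surface: inscribed radius below 1 mm")
  res
}

min_dist_to <- function(pts, center) {
  sqrt(min((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
             (pts[, 3] - center[3])^2))
}

refine_inscribed <- function(pts, start) {
  fn <- function(c3) -min_dist_to(pts, c3)
  opt <- optim(start, fn, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  # polish: restart once from the optimum (Nelder-Mead on a kinked max)
  opt <- optim(opt$par, fn, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  list(center = as.numeric(opt$par), radius = -opt$value)
}

#' Find the corneal vertex
#'
#' The corneal vertex is the anterior surface point most distant from the
#' inscribed-sphere centre. Among anterior-hemisphere points (positive dot
#' product with `anterior_hint`) whose distance is within `tie_tol` of the
#' maximum, the vertex is placed along the candidates' mean direction at
#' the maximal distance. Averaging over the near-maximal cap makes the
#' estimate stable when the anterior surface is locally flat relative to
#' the sampling grid (a plain argmax is forced onto a lattice point and
#' flutters by half a voxel between discretisations); on an exact-tie
#' surface (a sphere) the hint side selects the hemisphere and the result
#' stays deterministic.
#'
#' @param pc data frame of surface points (x/y/z mm).
#' @param center inscribed-sphere centre (length 3, mm).
#' @param anterior_hint unit vector roughly indicating anterior (from image
#'   orientation metadata or a user flag).
#' @param tie_tol near-maximum tolerance in mm (default 0.25, half a voxel).
#' @return length-3 vertex coordinates (mm).
#' @export
find_corneal_vertex <- function(pc, center, anterior_hint,
                                tie_tol = 0.25) {
  pts <- as_points_matrix(pc)
  hint <- unit_vec(as.numeric(anterior_hint))
  rel <- sweep(pts, 2, as.numeric(center))
  keep <- (rel %*% hint)[, 1] > 0
  if (!any(keep)) abort("no surface points in the anterior hemisphere; check anterior_hint")
  rel <- rel[keep, , drop = FALSE]
  pts <- pts[keep, , drop = FALSE]
  d <- row_norms(rel)
  cand <- which(d >= max(d) - tie_tol)
  dirs <- rel[cand, , drop = FALSE] / d[cand]
  mdir <- colMeans(dirs)
  if (vnorm(mdir) < 1e-8) mdir <- hint else mdir <- mdir / vnorm(mdir)
  as.numeric(center) + max(d) * mdir
}

#' Build the pupillary-foveal eye frame
#'
#' The axis runs from the corneal vertex through the inscribed-sphere
#' centre (anterior to posterior); the origin — the hypothetical
#' pre-elongation eye centre — sits `offset` mm posterior to the vertex
#' along the axis. The frame is right-handed with `+Y` posterior along the
#' axis, `+X` the naso-temporal image direction projected orthogonal to the
#' axis, and `Z = X x Y`.
#'
#' @param center inscribed-sphere centre (mm).
#' @param vertex corneal vertex (mm).
#' @param offset distance from vertex to origin in mm (default 12, the
#'   radius-equivalent centre of a normal 24 mm eye).
#' @param radius inscribed-sphere radius (carried as metadata).
#' @param x_hint world direction whose projection defines `+X` (temporal).
#' @param laterality `"OD"` (right) or `"OS"` (left); left eyes are mirrored
#'   in X by [to_eye_coordinates()] so `+X` is temporal for all eyes.
#' @return an `eye_frame` object.
#' @export
build_eye_frame <- function(center, vertex, offset = 12, radius = NA_real_,
                            x_hint = c(1, 0, 0), laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  center <- as.numeric(center); vertex <- as.numeric(vertex)
  sep <- vnorm(center - vertex)
  if (sep < 1) abort("degenerate geometry: corneal vertex within 1 mm of the sphere centre")
  axis <- (center - vertex) / sep
  x <- as.numeric(x_hint) - sum(x_hint * axis) * axis
  if (vnorm(x) < 1e-6) {
    # hint parallel to the axis: pick any orthogonal direction
    alt <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    x <- alt - sum(alt * axis) * axis
  }
  x <- x / vnorm(x)
  z <- cross3(x, axis)
  origin <- vertex + offset * axis
  structure(
    list(sphere_center = center, sphere_radius = radius,
         corneal_vertex = vertex, axis = axis, origin = origin,
         offset = offset, rotation = cbind(x = x, y = axis, z = z),
         laterality = laterality),
    class = "eye_frame"
  )
}

#' @export
print.eye_frame <- function(x, ...) {
  cat("<eye_frame>\n",
      "  sphere centre : ", paste(signif(x$sphere_center, 5), collapse = ", "), " mm\n",
      "  sphere radius : ", signif(x$sphere_radius, 5), " mm\n",
      "  corneal vertex: ", paste(signif(x$corneal_vertex, 5), collapse = ", "), " mm\n",
      "  axis (post.)  : ", paste(signif(x$axis, 5), collapse = ", "), "\n",
      "  origin        : ", paste(signif(x$origin, 5), collapse = ", "),
      " mm (", x$offset, " mm posterior to vertex)\n",
      "  laterality    : ", x$laterality, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.eye_frame <- function(x, ...) {
  tibble::tibble(
    component = c("sphere_center", "corneal_vertex", "axis", "origin"),
    x = c(x$sphere_center[1], x$corneal_vertex[1], x$axis[1], x$origin[1]),
    y = c(x$sphere_center[2], x$corneal_vertex[2], x$axis[2], x$origin[2]),
    z = c(x$sphere_center[3], x$corneal_vertex[3], x$axis[3], x$origin[3])
  )
}

#' Estimate the full eye frame from a surface (and optionally its volume)
#'
#' Convenience wrapper: inscribed sphere (from the volume when given,
#' otherwise from the surface), corneal vertex, then [build_eye_frame()].
#'
#' @param pc surface point cloud in world mm.
#' @param anterior_hint world direction roughly pointing anterior.
#' @param volume optional [eye_volume()] for the inscribed-sphere search.
#' @inheritParams build_eye_frame
#' @return an `eye_frame`.
#' @export
estimate_eye_frame <- function(pc, anterior_hint, volume = NULL, offset = 12,
                               x_hint = c(1, 0, 0), laterality = "OD") {
  sph <- if (is.null(volume)) find_inscribed_sphere(as.data.frame(pc))
         else find_inscribed_sphere(volume)
  vert <- find_corneal_vertex(pc, sph$center, anterior_hint)
  build_eye_frame(sph$center, vert, offset = offset, radius = sph$radius,
                  x_hint = x_hint, laterality = laterality)
}

#' Transform surface points into eye coordinates
#'
#' Rigid transform placing the pre-elongation origin at `(0,0,0)` with the
#' pupillary-foveal axis along `+Y` (posterior positive). Left eyes (`OS`)
#' are mirrored in X (when `mirror = TRUE`) so `+X` is temporal for all
#' eyes; the chirality flip is recorded in the surface metadata. Pairwise
#' distances are preserved exactly (up to the optional mirror).
#'
#' @param pc data frame of surface points in world mm.
#' @param frame an `eye_frame`.
#' @param mirror mirror left eyes in X (default TRUE).
#' @return an `eye_surface` tibble in eye coordinates.
#' @export
to_eye_coordinates <- function(pc, frame, mirror = TRUE) {
  stopifnot(inherits(frame, "eye_frame"))
  m <- as_points_matrix(pc)
  R <- frame$rotation
  out <- sweep(m, 2, frame$origin) %*% R
  mirrored <- frame$laterality == "OS" && mirror
  if (mirrored) out[, 1] <- -out[, 1]
  colnames(out) <- c("x", "y", "z")
  df <- tibble::as_tibble(as.data.frame(out))
  if (is.data.frame(pc) && all(c("nx", "ny", "nz") %in% names(pc))) {
    nm <- as.matrix(pc[, c("nx", "ny", "nz")]) %*% R
    if (mirrored) nm[, 1] <- -nm[, 1]
    df$nx <- nm[, 1]; df$ny <- nm[, 2]; df$nz <- nm[, 3]
  }
  meta <- if (is.data.frame(pc)) surface_meta(pc) else list()
  meta$chirality_mirrored <- mirrored
  meta$frame <- frame
  new_eye_surface(df, meta = meta)
}

#' Apply a rigid pose to an eye frame
#'
#' Moves every frame component (centre, vertex, origin, axes) through the
#' same world-frame rigid transform, so that topography computed from
#' jointly transformed points and frame is identical.
#'
#' @param frame an `eye_frame`.
#' @param pose a [rigid_pose()].
#' @return the transformed `eye_frame`.
#' @export
transform_frame <- function(frame, pose) {
  R <- pose$rotation; t <- pose$translation
  mv <- function(p) as.numeric(R %*% p + t)
  rot <- R %*% frame$rotation
  structure(
    list(sphere_center = mv(frame$sphere_center),
         sphere_radius = frame$sphere_radius,
         corneal_vertex = mv(frame$corneal_vertex),
         axis = as.numeric(R %*% frame$axis),
         origin = mv(frame$origin),
         offset = frame$offset,
         rotation = rot,
         laterality = frame$laterality),
    class = "eye_frame"
  )
}
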