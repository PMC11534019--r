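# Small geometry helpers shared across modules. Points travel as N x 3
# matrices internally and as tibbles with x/y/z columns at the interface.

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    abort("cannot normalise a zero-length or non-finite vector")
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Angle between two vectors in degrees
#' @param a,b numeric vectors of length 3.
#' @return angle in degrees in `[0, 180]`.
#' @export
angle_between_deg <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  acos(min(1, max(-1, ca))) * 180 / pi
}

# Accept a data frame with x/y/z columns or an N x 3 matrix.
as_points_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) abort("point matrix must have 3 columns")
    colnames(x) <- c("x", "y", "z")
    return(x)
  }
  if (is.data.frame(x)) {
    need <- c("x", "y", "z")
    if (!all(need %in% names(x))) {
      abort("point data frame must have columns x, y, z (mm)")
    }
    m <- as.matrix(x[, need])
    storage.mode(m) <- "double"
    return(m)
  }
  if (is.numeric(x) && length(x) == 3) return(matrix(x, 1, 3, dimnames = list(NULL, c("x", "y", "z"))))
  abort("points must be a data frame with x/y/z columns or an N x 3 matrix")
}

row_norms <- function(m) sqrt(rowSums(m^2))

#' Construct a rigid pose (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation in mm.
#' @return a `rigid_pose` list.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    abort("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_pose")
}

#' Rotation matrix about an axis
#' @param axis rotation axis (length 3, need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit_vec(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' A reproducible random rigid pose
#' @param seed integer seed.
#' @param max_translation_mm translation bound per axis.
#' @return a `rigid_pose`.
#' @export
random_rigid_pose <- function(seed = 1L, max_translation_mm = 5) {
  old <- .Random.seed_exists()
  set.seed(seed)
  ax <- rnorm(3)
  ang <- runif(1, 0, 360)
  tr <- runif(3, -max_translation_mm, max_translation_mm)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  rigid_pose(rotation_about_axis(ax, ang), tr)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' Apply a rigid pose to points
#' @param points data frame with x/y/z or N x 3 matrix.
#' @param pose a [rigid_pose()].
#' @param inverse apply the inverse transform instead.
#' @return tibble with transformed x/y/z (other columns preserved when the
#'   input is a data frame; normal columns nx/ny/nz are rotated).
#' @export
apply_pose <- function(points, pose, inverse = FALSE) {
  m <- as_points_matrix(points)
  R <- pose$rotation
  t <- pose$translation
  out <- if (inverse) {
    sweep(m, 2, t) %*% R          # R^T applied from the left == %*% R
  } else {
    m %*% t(R) + matrix(t, nrow(m), 3, byrow = TRUE)
  }
  colnames(out) <- c("x", "y", "z")
  if (is.data.frame(points)) {
    res <- points
    res$x <- out[, 1]; res$y <- out[, 2]; res$z <- out[, 3]
    if (all(c("nx", "ny", "nz") %in% names(points))) {
      nm <- as.matrix(points[, c("nx", "ny", "nz")])
      nr <- if (inverse) nm %*% R else nm %*% t(R)
      res$nx <- nr[, 1]; res$ny <- nr[, 2]; res$nz <- nr[, 3]
    }
    tibble::as_tibble(res)
  } else {
    tibble::as_tibble(as.data.frame(out))
  }
}

# Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
# Coordinates outside the grid sample as `outside`.
trilinear_sample <- function(arr, coords, outside = 0) {
  d <- dim(arr)
  cx <- coords[, 1]; cy <- coords[, 2]; cz <- coords[, 3]
  i0 <- floor(cx); j0 <- floor(cy); k0 <- floor(cz)
  fx <- cx - i0; fy <- cy - j0; fz <- cz - k0
  get_at <- function(i, j, k) {
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    v <- rep(outside, length(i))
    if (any(ok)) {
      lin <- i[ok] + d[1] * (j[ok] + d[2] * k[ok]) + 1
      v[ok] <- arr[lin]
    }
    v
  }
  v000 <- get_at(i0, j0, k0);     v100 <- get_at(i0 + 1, j0, k0)
  v010 <- get_at(i0, j0 + 1, k0); v110 <- get_at(i0 + 1, j0 + 1, k0)
  v001 <- get_at(i0, j0, k0 + 1); v101 <- get_at(i0 + 1, j0, k0 + 1)
  v011 <- get_at(i0, j0 + 1, k0 + 1); v111 <- get_at(i0 + 1, j0 + 1, k0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}
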