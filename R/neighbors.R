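# Fixed-radius neighbour queries via a uniform cell list (grid hash with
# cell edge = query radius): exact, O(1) expected per query, and the natural
# structure for the 3 mm curvature neighbourhoods.

cell_index_build <- function(points, cell_size) {
  m <- as_points_matrix(points)
  lo <- apply(m, 2, min)
  key <- floor(sweep(m, 2, lo) / cell_size)
  dims <- apply(key, 2, max) + 1
  lin <- key[, 1] + dims[1] * (key[, 2] + dims[2] * key[, 3]) + 1
  ord <- order(lin)
  structure(
    list(points = m, lo = lo, cell = cell_size, dims = dims,
         lin_sorted = lin[ord], ord = ord),
    class = "cell_index"
  )
}

# ids (row numbers into the indexed cloud) within `radius` of point q
cell_index_query <- function(index, q, radius) {
  key0 <- floor((q - index$lo) / index$cell)
  cand <- integer(0)
  dims <- index$dims
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- key0 + c(dx, dy, dz)
    if (any(k < 0) || any(k >= dims)) next
    lin <- k[1] + dims[1] * (k[2] + dims[2] * k[3]) + 1
    rng <- findInterval(c(lin - 1, lin), index$lin_sorted)
    if (rng[2] > rng[1]) cand <- c(cand, index$ord[(rng[1] + 1):rng[2]])
  }
  if (length(cand) == 0) return(integer(0))
  p <- index$points[cand, , drop = FALSE]
  d2 <- (p[, 1] - q[1])^2 + (p[, 2] - q[2])^2 + (p[, 3] - q[3])^2
  cand[d2 <= radius^2]
}
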