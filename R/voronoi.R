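# Bounded Voronoi tessellation of a test-location grid.
#
# Each cell is obtained by clipping the boundary polygon against the
# perpendicular-bisector half-plane of every other generator
# (Sutherland-Hodgman). O(n^2) in the number of locations, which is ample
# for perimetric grids (54-100 points). Cells are convex by construction.

# Clip convex/simple polygon (matrix nx2) by half-plane a.(p) + b <= 0.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- poly %*% a + b
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    din <- d[i] <= 0; djn <- d[j] <= 0
    if (din) out <- rbind(out, p)
    if (xor(din, djn)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  i <- seq_len(n); j <- c(2:n, 1)
  abs(sum(poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2])) / 2
}

# Convex point-in-polygon with tolerance (polygon vertices in consistent
# orientation not required; uses sign consistency of cross products).
point_in_convex <- function(pt, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) -
          (poly[j, 2] - poly[i, 2]) * (pt[1] - poly[i, 1])
    if (cr > tol) { if (s < 0) return(FALSE); s <- 1 }
    else if (cr < -tol) { if (s > 0) return(FALSE); s <- -1 }
  }
  TRUE
}

#' Default clip boundary for a grid
#'
#' The convex hull of the locations, dilated outward by half the median
#' nearest-neighbor distance, so edge locations get finite tiles. For
#' degenerate (collinear) grids the dilated bounding box is used.
#'
#' @param grid a `vf_grid`.
#' @return a matrix with columns x, y: the boundary polygon vertices.
#' @export
default_clip_boundary <- function(grid) {
  pts <- as.matrix(grid$locations[, c("x", "y")])
  n <- nrow(pts)
  if (n == 1) {
    r <- 3
    return(cbind(pts[1, 1] + c(-r, r, r, -r), pts[1, 2] + c(-r, -r, r, r)))
  }
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  r <- stats::median(apply(dm, 1, min)) / 2
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  if (polygon_area(hull) < 1e-9) {  # collinear: dilated bounding box
    return(cbind(c(min(pts[, 1]) - r, max(pts[, 1]) + r, max(pts[, 1]) + r, min(pts[, 1]) - r),
                 c(min(pts[, 2]) - r, min(pts[, 2]) - r, max(pts[, 2]) + r, max(pts[, 2]) + r)))
  }
  # chull returns clockwise order; offset each edge outward by r and
  # intersect the half-planes starting from an enlarged bounding box.
  pad <- r + max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  box <- cbind(c(min(pts[, 1]) - pad, max(pts[, 1]) + pad,
                 max(pts[, 1]) + pad, min(pts[, 1]) - pad),
               c(min(pts[, 2]) - pad, min(pts[, 2]) - pad,
                 max(pts[, 2]) + pad, max(pts[, 2]) + pad))
  cen <- colMeans(hull)
  poly <- box
  m <- nrow(hull)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    nrm <- c(-e[2], e[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    if (sum(nrm * (cen - hull[i, ])) > 0) nrm <- -nrm  # outward normal
    # keep points with nrm.(p - (v + r*nrm)) <= 0
    poly <- clip_halfplane(poly, nrm, -sum(nrm * (hull[i, ] + r * nrm)))
  }
  poly
}

#' Voronoi tessellation of a grid, clipped to a boundary
#'
#' Partitions the clip region into one convex tile per test location such
#' that every point of a tile is closer to its generating location than to
#' any other (the defining Voronoi property). Used both for plotting
#' irregular grids and to derive the neighbor graph that drives the growth
#' pattern and normative smoothing.
#'
#' @param grid a `vf_grid` with at least 2 locations.
#' @param clip_boundary optional convex boundary polygon (matrix with columns
#'   x, y) containing every location; defaults to [default_clip_boundary()].
#' @return an object of class `vf_tessellation`: list with `polygons` (one
#'   nx2 vertex matrix per location), `clip_boundary`, and the generating
#'   `points`.
#' @examples
#' g <- build_standard_grid("24-2")
#' tess <- voronoi_tessellate(g)
#' length(tess$polygons)  # one tile per location
#' @export
voronoi_tessellate <- function(grid, clip_boundary = NULL) {
  pts <- as.matrix(grid$locations[, c("x", "y")])
  n <- nrow(pts)
  if (n < 2) stop_perisim("tessellation needs at least 2 locations")
  if (is.null(clip_boundary)) clip_boundary <- default_clip_boundary(grid)
  clip_boundary <- as.matrix(clip_boundary)
  for (i in seq_len(n)) {
    if (!point_in_convex(pts[i, ], clip_boundary, tol = 1e-7))
      stop_perisim("location ", i, " (", pts[i, 1], ", ", pts[i, 2],
                   ") lies outside the clip boundary")
  }
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- clip_boundary
    for (j in seq_len(n)) {
      if (i == j) next
      dir <- pts[j, ] - pts[i, ]
      mid <- (pts[i, ] + pts[j, ]) / 2
      # keep the side nearer to i: dir.(p - mid) <= 0
      poly <- clip_halfplane(poly, dir, -sum(dir * mid))
      if (nrow(poly) == 0) break
    }
    polys[[i]] <- poly
  }
  structure(list(polygons = polys, clip_boundary = clip_boundary, points = pts),
            class = "vf_tessellation")
}

#' @export
print.vf_tessellation <- function(x, ...) {
  cat(sprintf("Voronoi tessellation: %d tiles, clip area %.3f deg^2\n",
              length(x$polygons), polygon_area(x$clip_boundary)))
  invisible(x)
}

#' Tile areas of a tessellation
#'
#' @param tess a `vf_tessellation`.
#' @return numeric vector of tile areas in squared degrees.
#' @export
tessellation_areas <- function(tess) {
  vapply(tess$polygons, polygon_area, numeric(1))
}

#' Neighbor graph from a tessellation
#'
#' Two locations are adjacent when their Voronoi tiles share a boundary
#' segment of positive length. The graph is symmetric and irreflexive; it is
#' the adjacency used by the growth pattern and by normative smoothing, and
#' it works identically for regular and irregular grids.
#'
#' @param tess a `vf_tessellation`.
#' @param min_edge minimum shared-segment length in degrees (default 1e-9).
#' @return a list with `pairs` (two-column matrix of location indices, i < j)
#'   and `neighbors` (per-location integer vector of adjacent indices).
#' @export
adjacency_from_tessellation <- function(tess, min_edge = 1e-9) {
  pts <- tess$points
  n <- nrow(pts)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n - 1)) {
    pi_ <- tess$polygons[[i]]
    if (nrow(pi_) < 2) next
    for (j in (i + 1):n) {
      len <- shared_bisector_length(pi_, pts[i, ], pts[j, ])
      if (len > min_edge) pairs <- rbind(pairs, c(i, j))
    }
  }
  neighbors <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
  }
  neighbors <- lapply(neighbors, function(v) sort(unique(v %||% integer(0))))
  list(pairs = pairs, neighbors = neighbors)
}

# Total length of polygon i's edges lying on the perpendicular bisector of
# generators pi/pj (these are exactly the tile faces shared with j).
shared_bisector_length <- function(poly, pi_, pj, tol = 1e-7) {
  n <- nrow(poly)
  if (n < 2) return(0)
  total <- 0
  on_bis <- function(p) {
    abs(sqrt(sum((p - pi_)^2)) - sqrt(sum((p - pj)^2))) < tol
  }
  for (k in seq_len(n)) {
    l <- if (k == n) 1L else k + 1L
    if (on_bis(poly[k, ]) && on_bis(poly[l, ]))
      total <- total + sqrt(sum((poly[l, ] - poly[k, ])^2))
  }
  total
}
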