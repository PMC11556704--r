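#' Keypoint sets
#'
#' An ordered set of 2-D pixel coordinates with role tags. Coordinates are
#' 0-based, `x` = column and `y` = row, pixel-center convention. Interior
#' keypoints are cell centroids and are the only points that ever move;
#' border keypoints form the fixed lattice along the image frame.
#'
#' @param points Numeric `n x 2` matrix of `(x, y)` coordinates.
#' @param roles Character vector, `"interior"` or `"border"`, one per point.
#' @return An object of class `keypoint_set`.
#' @export
keypoint_set <- function(points, roles) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  roles <- as.character(roles)
  if (nrow(points) != length(roles))
    stop("points and roles lengths differ", call. = FALSE)
  if (!all(roles %in% c("interior", "border")))
    stop_field("roles", "must be 'interior' or 'border'")
  if (anyDuplicated(points))
    stop("duplicate keypoints are not allowed", call. = FALSE)
  structure(list(points = points, roles = roles), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %d points (%d interior, %d border)\n",
              nrow(x$points), sum(x$roles == "interior"),
              sum(x$roles == "border")))
  invisible(x)
}

#' @export
length.keypoint_set <- function(x) nrow(x$points)

#' Extract cell-centroid keypoints from a label mask
#'
#' One interior keypoint per region id `k >= 1`, at the region's pixel-area
#' centroid rounded to the nearest pixel (round-half-to-even), in ascending
#' id order. Centroids that coincide after rounding are merged with a
#' warning.
#'
#' @param x A [labeled_pair()] or an integer label matrix. A logical/0-255
#'   binary boundary mask is first converted via [labels_from_boundary()].
#' @return A [keypoint_set()] with all roles `"interior"`.
#' @export
extract_centroids <- function(x) {
  lab <- if (inherits(x, "labeled_pair")) x$label_mask else x
  if (is.logical(lab) || identical(sort(unique(as.vector(lab))), c(0L, 255L)))
    lab <- labels_from_boundary(lab != 0)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0) stop("no cells found", call. = FALSE)
  pts <- t(vapply(ids, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(round(mean(idx[, 2] - 1)), round(mean(idx[, 1] - 1)))
  }, numeric(2)))
  dup <- duplicated(pts)
  if (any(dup)) {
    warning(sum(dup), " centroid(s) merged after rounding", call. = FALSE)
    pts <- pts[!dup, , drop = FALSE]
  }
  keypoint_set(pts, rep("interior", nrow(pts)))
}

#' Fixed border lattice of keypoints
#'
#' Points at fractions 0, 1/8, 1/4, 3/8, 1/2, 5/8, 3/4, 7/8, 1 of each edge
#' of the image rectangle (corners, centers, quarters, eighths), mapped to
#' pixels by `round(f * (size - 1))` with shared corners deduplicated: 32
#' points in total. These points anchor the warp so the deformed mesh still
#' tiles the full image, preventing out-of-frame (black-triangle) artefacts.
#'
#' @param width,height Image size in pixels, each `>= 8`.
#' @return A [keypoint_set()] with all roles `"border"`.
#' @export
border_lattice <- function(width, height) {
  if (width < 8 || height < 8)
    stop("image must be at least 8 px per side for the border lattice",
         call. = FALSE)
  f <- (0:8) / 8
  xs <- round(f * (width - 1))
  ys <- round(f * (height - 1))
  pts <- rbind(cbind(xs, 0),               # top edge
               cbind(xs, height - 1),      # bottom edge
               cbind(0, ys),               # left edge
               cbind(width - 1, ys))       # right edge
  pts <- unique(pts)
  keypoint_set(pts, rep("border", nrow(pts)))
}

#' Minimum pairwise keypoint distance (per-axis-min metric)
#'
#' The distance between two keypoints is `min(|xa - xb|, |ya - yb|)`: the
#' smaller of the per-axis absolute differences. The returned value is the
#' minimum over all unordered pairs of the selected set. Because any two
#' points sharing an x or y coordinate are at distance 0 under this metric
#' (always true of the axis-aligned border lattice), the default policy
#' restricts to interior-interior pairs whenever at least two interior
#' points exist; callers that scale shifts apply a 1 px floor on top
#' (see [sample_shifts()]).
#'
#' @param K A [keypoint_set()] with `>= 2` points.
#' @param pairs `"auto"` (interior pairs when possible, else all),
#'   `"interior"` or `"all"`.
#' @return Non-negative scalar distance in pixels (0 is possible).
#' @export
min_pairwise_distance <- function(K, pairs = c("auto", "interior", "all")) {
  stopifnot(inherits(K, "keypoint_set"))
  pairs <- match.arg(pairs)
  pts <- K$points
  if (pairs == "interior" ||
      (pairs == "auto" && sum(K$roles == "interior") >= 2))
    pts <- pts[K$roles == "interior", , drop = FALSE]
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points in the selected pair set",
                  call. = FALSE)
  dx <- abs(outer(pts[, 1], pts[, 1], "-"))
  dy <- abs(outer(pts[, 2], pts[, 2], "-"))
  d <- pmin(dx, dy)
  min(d[upper.tri(d)])
}

# signed area (positive = counter-clockwise in x-right / y-down raster axes)
triangle_signed_area <- function(p1, p2, p3) {
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

mesh_areas <- function(points, triangles) {
  triangle_signed_area(points[triangles[, 1], , drop = FALSE],
                       points[triangles[, 2], , drop = FALSE],
                       points[triangles[, 3], , drop = FALSE])
}

#' Delaunay triangulation of a keypoint set
#'
#' Index triples into `K`, oriented counter-clockwise (positive signed
#' area). The triangulation maximizes the minimum angle; when `K` includes
#' the border lattice the triangle union tiles the whole image rectangle.
#' For cocircular quadruples any valid Delaunay triangulation is accepted.
#'
#' @param K A [keypoint_set()] with at least 3 non-collinear points.
#' @return An object of class `triangle_mesh`: list with `triangles`
#'   (`m x 3` integer matrix) and `n_points`.
#' @export
delaunay <- function(K) {
  stopifnot(inherits(K, "keypoint_set"))
  pts <- K$points
  if (nrow(pts) < 3) stop("need at least 3 points", call. = FALSE)
  tm <- tryCatch(interp::tri.mesh(pts[, 1], pts[, 2]),
                 error = function(e)
                   stop("Delaunay triangulation failed: ",
                        conditionMessage(e), call. = FALSE))
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  if (nrow(tri) == 0) stop("all points are collinear", call. = FALSE)
  # normalize orientation to CCW (positive signed area)
  ar <- mesh_areas(pts, tri)
  flip <- ar < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  storage.mode(tri) <- "integer"
  structure(list(triangles = tri, n_points = nrow(pts)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d triangles over %d points\n",
              nrow(x$triangles), x$n_points))
  invisible(x)
}

#' Export keypoints as CSV
#'
#' Columns `x`, `y`, `role`; 0-based pixel coordinates.
#' @param K A [keypoint_set()].
#' @param path Output CSV path.
#' @export
write_keypoints_csv <- function(K, path) {
  stopifnot(inherits(K, "keypoint_set"))
  write.csv(data.frame(x = K$points[, 1], y = K$points[, 2], role = K$roles),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a mesh as an OFF-style text listing
#'
#' Plain-text OFF format (vertices as x y 0, faces as triangles) for
#' inspection in standard mesh viewers.
#' @param K A [keypoint_set()].
#' @param mesh A `triangle_mesh` over `K`.
#' @param path Output path.
#' @export
write_mesh_off <- function(K, mesh, path) {
  stopifnot(inherits(K, "keypoint_set"), inherits(mesh, "triangle_mesh"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(K$points), nrow(mesh$triangles)), con)
  writeLines(sprintf("%g %g 0", K$points[, 1], K$points[, 2]), con)
  t0 <- mesh$triangles - 1L
  writeLines(sprintf("3 %d %d %d", t0[, 1], t0[, 2], t0[, 3]), con)
  invisible(path)
}
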