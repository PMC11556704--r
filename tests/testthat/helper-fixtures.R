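# shared fixture builders; everything is generated in code

clean_mosaic <- function(n_cells = 20, seed = 7, size = 96) {
  generate_mosaic(mosaic_spec(size, size, n_cells = n_cells, seed = seed,
                              noise_sd = 0, blur_sigma = 0,
                              illumination_amplitude = 0))
}

default_mosaic <- function(n_cells = 20, seed = 7, size = 96, ...) {
  generate_mosaic(mosaic_spec(size, size, n_cells = n_cells, seed = seed, ...))
}

# full keypoint set (centroids + border lattice) of a pair
pair_keypoints <- function(pair) {
  cents <- extract_centroids(pair)
  lat <- border_lattice(ncol(pair$image), nrow(pair$image))
  keypoint_set(rbind(cents$points, lat$points), c(cents$roles, lat$roles))
}

zero_shifts <- function(K) {
  structure(list(deltas = matrix(0, nrow(K$points), 2),
                 s = 1, d_min_used = 1),
            class = "shift_field")
}

# circumcenter and radius of a triangle given a 3 x 2 coordinate matrix
circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# worst empty-circumcircle violation of a mesh (positive = point strictly
# inside some circumcircle by that margin)
circumcircle_violation <- function(points, triangles) {
  worst <- -Inf
  for (t in seq_len(nrow(triangles))) {
    i <- triangles[t, ]
    cc <- circumcircle(points[i, , drop = FALSE])
    others <- points[-i, , drop = FALSE]
    if (nrow(others) == 0) next
    dmin <- min(sqrt((others[, 1] - cc$center[1])^2 +
                       (others[, 2] - cc$center[2])^2))
    worst <- max(worst, cc$radius - dmin)
  }
  worst
}

# brute-force forward warp oracle: locate the containing source triangle by
# point-in-triangle tests, then barycentric interpolation of the vertex
# displacements
oracle_forward <- function(map, pts) {
  tri <- map$triangles; src <- map$src; dst <- map$dst
  out <- matrix(NA_real_, nrow(pts), 2)
  for (j in seq_len(nrow(pts))) {
    for (t in seq_len(nrow(tri))) {
      i <- tri[t, ]
      p1 <- src[i[1], ]; p2 <- src[i[2], ]; p3 <- src[i[3], ]
      det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
             (p3[1] - p1[1]) * (p2[2] - p1[2])
      l2 <- ((pts[j, 1] - p1[1]) * (p3[2] - p1[2]) -
               (pts[j, 2] - p1[2]) * (p3[1] - p1[1])) / det
      l3 <- ((pts[j, 2] - p1[2]) * (p2[1] - p1[1]) -
               (pts[j, 1] - p1[1]) * (p2[2] - p1[2])) / det
      l1 <- 1 - l2 - l3
      if (l1 >= -1e-12 && l2 >= -1e-12 && l3 >= -1e-12) {
        out[j, ] <- l1 * dst[i[1], ] + l2 * dst[i[2], ] + l3 * dst[i[3], ]
        break
      }
    }
  }
  out
}

quiet_warp <- function(...) suppressMessages(warp_pair(...))
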