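#' Sample a bounded random shift field for a keypoint set
#'
#' Each interior keypoint is shifted by `(dx, dy) = (R1, R2) * d_min / s`
#' with `R1`, `R2` independent uniform(-1, 1) draws; border keypoints stay
#' fixed. `d_min` is the minimum pairwise keypoint distance under the
#' per-axis-min metric over interior pairs ([min_pairwise_distance()]),
#' floored at 1 px when degenerate (two interior points sharing a row or
#' column make the raw minimum 0). The strain parameter `s` inversely
#' controls deformation strength: `s = 2` gives strong warps, `s = 3` mild
#' ones.
#'
#' @param K A [keypoint_set()] with at least one interior point.
#' @param s Strain parameter, `> 0`.
#' @param d_min Optional override of the distance floor; computed from `K`
#'   when `NULL`.
#' @return An object of class `shift_field`: list with `deltas` (`n x 2`),
#'   `s` and `d_min_used`. Draws come from the caller's RNG stream.
#' @export
sample_shifts <- function(K, s, d_min = NULL) {
  stopifnot(inherits(K, "keypoint_set"))
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop_field("s", "must be a positive scalar")
  interior <- K$roles == "interior"
  if (!any(interior)) stop("K has no interior keypoint", call. = FALSE)
  if (is.null(d_min)) {
    raw <- if (sum(interior) >= 2)
      min_pairwise_distance(K, pairs = "interior")
    else min_pairwise_distance(K, pairs = "all")
    d_min <- raw
    if (raw < 1) {
      d_min <- 1
      message("degenerate d_min (", signif(raw, 3), " px): floored at 1 px")
    }
  }
  n <- nrow(K$points)
  deltas <- matrix(0, n, 2, dimnames = list(NULL, c("dx", "dy")))
  idx <- which(interior)
  for (i in idx) deltas[i, ] <- runif(2, -1, 1) * d_min / s
  structure(list(deltas = deltas, s = s, d_min_used = d_min),
            class = "shift_field")
}

#' @export
print.shift_field <- function(x, ...) {
  cat(sprintf("<shift_field> %d keypoints, s = %g, d_min = %g, max|d| = %.3g px\n",
              nrow(x$deltas), x$s, x$d_min_used, max(abs(x$deltas))))
  invisible(x)
}

# exact affine T mapping the 3 source vertices onto the 3 target vertices:
# [x' y'] = [x y 1] %*% A, A is 3 x 2. Returns NULL when degenerate.
solve_affine <- function(src, dst) {
  S <- cbind(src, 1)
  A <- tryCatch(solve(S, dst), error = function(e) NULL)
  A
}

#' Build the piecewise affine map between a keypoint set and its shifts
#'
#' The target set `K' = K + deltas` is triangulated (Delaunay); the same
#' index triples are imposed on the source points so each triangle carries
#' one exact affine transform (solved from its 3 vertex correspondences)
#' and its inverse. The map is flagged invalid — not an error — when the
#' triangulation fails, any triangle on either side degenerates, or a
#' triangle folds over (non-positive signed area), since fold-over breaks
#' bijectivity on the image rectangle.
#'
#' @param K A [keypoint_set()].
#' @param shifts A [sample_shifts()] result aligned with `K`.
#' @param connectivity_side Triangulate the shifted points (`"target"`,
#'   default, matching re-triangulation of the modified set) or the source
#'   points (`"source"`).
#' @return An object of class `piecewise_affine_map` with elements
#'   `src`, `dst` (point matrices), `triangles`, `fwd`/`inv` (lists of
#'   3 x 2 affine coefficient matrices), `valid` and `reason`.
#' @export
build_map <- function(K, shifts, connectivity_side = c("target", "source")) {
  stopifnot(inherits(K, "keypoint_set"), inherits(shifts, "shift_field"))
  connectivity_side <- match.arg(connectivity_side)
  if (nrow(shifts$deltas) != nrow(K$points))
    stop("K and shifts are not aligned", call. = FALSE)
  src <- K$points
  dst <- src + shifts$deltas

  invalid <- function(reason)
    structure(list(src = src, dst = dst, triangles = NULL,
                   fwd = NULL, inv = NULL, valid = FALSE, reason = reason,
                   shifts = shifts, roles = K$roles),
              class = "piecewise_affine_map")

  base_pts <- if (connectivity_side == "target") dst else src
  if (anyDuplicated(base_pts)) return(invalid("duplicate keypoints"))
  mesh <- tryCatch(
    delaunay(keypoint_set(base_pts, K$roles)),
    error = function(e) NULL)
  if (is.null(mesh)) return(invalid("triangulation failed"))
  tri <- mesh$triangles

  area_eps <- 1e-9
  if (any(mesh_areas(dst, tri) <= area_eps))
    return(invalid("fold-over (target triangle)"))
  if (any(mesh_areas(src, tri) <= area_eps))
    return(invalid("fold-over (source triangle)"))

  m <- nrow(tri)
  fwd <- vector("list", m); inv <- vector("list", m)
  for (t in seq_len(m)) {
    i <- tri[t, ]
    fwd[[t]] <- solve_affine(src[i, , drop = FALSE], dst[i, , drop = FALSE])
    inv[[t]] <- solve_affine(dst[i, , drop = FALSE], src[i, , drop = FALSE])
    if (is.null(fwd[[t]]) || is.null(inv[[t]]))
      return(invalid("degenerate triangle"))
  }
  structure(list(src = src, dst = dst, triangles = tri, fwd = fwd,
                 inv = inv, valid = TRUE, reason = NULL,
                 shifts = shifts, roles = K$roles),
            class = "piecewise_affine_map")
}

#' @export
print.piecewise_affine_map <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<piecewise_affine_map> %d triangles over %d keypoints, valid\n",
                nrow(x$triangles), nrow(x$src)))
  else
    cat(sprintf("<piecewise_affine_map> invalid: %s\n", x$reason))
  invisible(x)
}

# evaluate the map at arbitrary points. pts: n x 2; side "fwd" maps source
# coordinates to warped coordinates, "inv" the reverse. Containing triangles
# are located on the matching side by barycentric point-in-triangle tests.
evaluate_map <- function(map, pts, side = c("fwd", "inv")) {
  side <- match.arg(side)
  if (!map$valid) stop("map is invalid (", map$reason,
                       "); resample shifts", call. = FALSE)
  dom <- if (side == "fwd") map$src else map$dst
  aff <- if (side == "fwd") map$fwd else map$inv
  tri <- map$triangles
  n <- nrow(pts)
  out <- matrix(NA_real_, n, 2)
  assigned <- rep(FALSE, n)
  eps <- 1e-9
  for (t in seq_len(nrow(tri))) {
    if (all(assigned)) break
    i <- tri[t, ]
    p1 <- dom[i[1], ]; p2 <- dom[i[2], ]; p3 <- dom[i[3], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
           (p3[1] - p1[1]) * (p2[2] - p1[2])
    cand <- which(!assigned)
    vx <- pts[cand, 1] - p1[1]; vy <- pts[cand, 2] - p1[2]
    l2 <- (vx * (p3[2] - p1[2]) - vy * (p3[1] - p1[1])) / det
    l3 <- (vy * (p2[1] - p1[1]) - vx * (p2[2] - p1[2])) / det
    inside <- l2 >= -eps & l3 >= -eps & (l2 + l3) <= 1 + eps
    if (!any(inside)) next
    sel <- cand[inside]
    out[sel, ] <- cbind(pts[sel, 1], pts[sel, 2], 1) %*% aff[[t]]
    assigned[sel] <- TRUE
  }
  if (!all(assigned))
    stop(sum(!assigned), " point(s) outside the triangulated domain",
         call. = FALSE)
  out
}

#' Evaluate the forward warping function at arbitrary points
#'
#' @param map A valid [build_map()] result.
#' @param pts `n x 2` matrix of 0-based `(x, y)` coordinates inside the
#'   source domain.
#' @return `n x 2` matrix of warped coordinates.
#' @export
forward_map <- function(map, pts) evaluate_map(map, pts, "fwd")

#' Evaluate the inverse warping function at arbitrary points
#'
#' @inheritParams forward_map
#' @param pts `n x 2` matrix of coordinates inside the warped domain.
#' @return `n x 2` matrix of source coordinates.
#' @export
inverse_map <- function(map, pts) evaluate_map(map, pts, "inv")

# bilinear sampling of matrix `img` at 0-based coordinates (clamped)
sample_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 0, w - 1); y <- clamp(y, 0, h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]; i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}

sample_nearest <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(round(x), 0, w - 1); y <- clamp(round(y), 0, h - 1)
  img[cbind(y + 1, x + 1)]
}

#' Warp an image/mask pair through a piecewise affine map
#'
#' Every output pixel is pulled back through the inverse map; intensities
#' are sampled bilinearly and labels by nearest neighbour (labels are never
#' blended, so no new ids can appear). With `mask_warp = "boundary"` the
#' binary boundary raster is warped by nearest neighbour instead and labels
#' are re-derived from it; the default label path avoids the broken 1-px
#' boundaries that nearest-neighbour warping of thin rasters produces.
#'
#' @param pair A [labeled_pair()] whose dimensions match the map's domain.
#' @param map A valid [build_map()] result.
#' @param mask_warp `"labels"` (default) or `"boundary"`.
#' @return The warped [labeled_pair()].
#' @export
apply_warp <- function(pair, map, mask_warp = c("labels", "boundary")) {
  stopifnot(inherits(pair, "labeled_pair"),
            inherits(map, "piecewise_affine_map"))
  mask_warp <- match.arg(mask_warp)
  if (!map$valid)
    stop("map is invalid (", map$reason, "); resample shifts", call. = FALSE)
  h <- nrow(pair$image); w <- ncol(pair$image)
  g <- pixel_grid(h, w)
  srcxy <- inverse_map(map, cbind(g$x, g$y))
  # snap to the pixel grid within numerical noise so that an identity map
  # reproduces the input bit-exactly
  near <- abs(srcxy - round(srcxy)) < 1e-6
  srcxy[near] <- round(srcxy[near])
  img_w <- matrix(sample_bilinear(pair$image, srcxy[, 1], srcxy[, 2]), h, w)
  img_w <- clamp(img_w, 0, 1)
  if (mask_warp == "labels") {
    lab_w <- matrix(sample_nearest(pair$label_mask, srcxy[, 1], srcxy[, 2]),
                    h, w)
  } else {
    bnd_w <- matrix(sample_nearest(pair$boundary_mask * 1L,
                                   srcxy[, 1], srcxy[, 2]), h, w)
    lab_w <- labels_from_boundary(bnd_w != 0)
  }
  storage.mode(lab_w) <- "integer"
  labeled_pair(img_w, lab_w, regions = pair$regions)
}

# do all region ids survive without new fragmentation? A region must keep
# at least one pixel and must not split into more 4-connected components
# than it had in the input (regions that arrive 4-connected must stay so).
regions_intact <- function(lab_in, lab_out) {
  ids_in <- setdiff(sort(unique(as.vector(lab_in))), 0L)
  ids_out <- setdiff(sort(unique(as.vector(lab_out))), 0L)
  if (!identical(ids_in, ids_out)) return(FALSE)
  for (k in ids_out) {
    n_out <- max(cc_label(lab_out == k, connectivity = 4L))
    n_in <- max(cc_label(lab_in == k, connectivity = 4L))
    if (n_out > n_in) return(FALSE)
  }
  TRUE
}

#' Warp an image/mask pair with resampling until plausible
#'
#' Full augmentation of a single pair: cell centroids are extracted from
#' the mask and combined with the fixed border lattice; bounded random
#' shifts are drawn; the piecewise affine map is built and applied. A draw
#' is rejected — and redrawn, up to `retry_budget` times — when the mesh
#' folds over or the warped mask loses or fragments a region, an automated
#' stand-in for manual curation of plausible deformations.
#'
#' @param pair A [labeled_pair()].
#' @param s Strain parameter, `> 0` (2 = strong, 3 = mild deformation).
#' @param seed Optional integer seed; `NULL` uses the caller's RNG stream.
#' @param retry_budget Maximum number of redraws.
#' @param connectivity_side,mask_warp Passed to [build_map()] and
#'   [apply_warp()].
#' @return A list of class `warp_result`: `pair` (warped), `shifts`
#'   (accepted [sample_shifts()] field), `keypoints`, `map`, `n_retries`,
#'   `s`, `seed`, `d_min_used`.
#' @export
warp_pair <- function(pair, s, seed = NULL, retry_budget = 20,
                      connectivity_side = c("target", "source"),
                      mask_warp = c("labels", "boundary")) {
  stopifnot(inherits(pair, "labeled_pair"))
  connectivity_side <- match.arg(connectivity_side)
  mask_warp <- match.arg(mask_warp)
  if (!is.numeric(s) || s <= 0) stop_field("s", "must be > 0")

  cents <- extract_centroids(pair)
  lat <- border_lattice(ncol(pair$image), nrow(pair$image))
  keep <- !(paste(cents$points[, 1], cents$points[, 2]) %in%
              paste(lat$points[, 1], lat$points[, 2]))
  if (!all(keep))
    warning(sum(!keep), " centroid(s) coincide with border lattice points ",
            "and were dropped", call. = FALSE)
  K <- keypoint_set(rbind(cents$points[keep, , drop = FALSE], lat$points),
                    c(cents$roles[keep], lat$roles))

  # d_min is a property of K, not of the draw: compute once
  raw <- if (sum(K$roles == "interior") >= 2)
    min_pairwise_distance(K, pairs = "interior")
  else min_pairwise_distance(K, pairs = "all")
  d_min <- raw
  if (raw < 1) {
    d_min <- 1
    message("degenerate d_min (", signif(raw, 3), " px): floored at 1 px")
  }

  with_seed(seed, {
    failures <- c(fold_over = 0L, region_loss = 0L)
    for (attempt in 0:retry_budget) {
      shifts <- sample_shifts(K, s, d_min = d_min)
      map <- build_map(K, shifts, connectivity_side)
      if (!map$valid) {
        failures["fold_over"] <- failures["fold_over"] + 1L
        next
      }
      warped <- apply_warp(pair, map, mask_warp)
      if (mask_warp == "labels" &&
          !regions_intact(pair$label_mask, warped$label_mask)) {
        failures["region_loss"] <- failures["region_loss"] + 1L
        next
      }
      return(structure(list(pair = warped, shifts = shifts, keypoints = K,
                            map = map, n_retries = attempt, s = s,
                            seed = seed, d_min_used = shifts$d_min_used),
                       class = "warp_result"))
    }
    stop(sprintf(
      "retry budget (%d) exhausted at s = %g: %d fold-over, %d region-loss rejections",
      retry_budget, s, failures["fold_over"], failures["region_loss"]),
      call. = FALSE)
  })
}

#' @export
print.warp_result <- function(x, ...) {
  cat(sprintf("<warp_result> s = %g, d_min = %g, %d retries, max|d| = %.3g px\n",
              x$s, x$d_min_used, x$n_retries, max(abs(x$shifts$deltas))))
  invisible(x)
}
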