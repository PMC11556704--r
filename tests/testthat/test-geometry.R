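test_that("centroids are region means rounded half-to-even", {
  # 10x10 square region, top-left pixel (x = 20, y = 30): centroid (24.5, 34.5)
  lab <- matrix(0L, 96, 96)
  lab[31:40, 21:30] <- 1L
  K <- extract_centroids(lab)
  expect_equal(nrow(K$points), 1)
  expect_equal(K$points[1, ], c(x = 24, y = 34)) # round-half-to-even
  expect_identical(K$roles, "interior")
})

test_that("one centroid per region, matching the brute-force mean", {
  pair <- default_mosaic(n_cells = 20, seed = 9)
  K <- extract_centroids(pair)
  expect_equal(nrow(K$points), 20)
  for (k in 1:20) {
    idx <- which(pair$label_mask == k, arr.ind = TRUE)
    expect_equal(K$points[k, ],
                 c(x = round(mean(idx[, 2] - 1)), y = round(mean(idx[, 1] - 1))))
  }
})

test_that("centroid extraction ignores region id relabeling up to order", {
  pair <- default_mosaic(n_cells = 12, seed = 3)
  lab <- pair$label_mask
  perm <- sample(12)
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (k in 1:12) relab[lab == k] <- perm[k]
  a <- extract_centroids(lab)$points
  b <- extract_centroids(relab)$points
  expect_identical(a[order(a[, 1], a[, 2]), ], b[order(b[, 1], b[, 2]), ])
})

test_that("empty masks are rejected", {
  expect_error(extract_centroids(matrix(0L, 16, 16)), "no cells found")
})

test_that("border lattice holds 32 points on the eighth-fraction grid", {
  L <- border_lattice(96, 96)
  expect_equal(nrow(L$points), 32)
  expect_true(all(L$roles == "border"))
  top <- sort(L$points[L$points[, 2] == 0, 1])
  expect_equal(top, round((0:8) / 8 * 95)) # 0 12 24 36 48 59 71 83 95
  corners <- rbind(c(0, 0), c(95, 0), c(0, 95), c(95, 95))
  expect_true(all(apply(corners, 1, function(p)
    any(L$points[, 1] == p[1] & L$points[, 2] == p[2]))))
  expect_error(border_lattice(7, 96), "8 px")

  # symmetric under horizontal and vertical flips up to the 1-px rounding
  # slack of the half-edge point (x.5 has no mirror-exact pixel on an
  # even-sized grid)
  nearest <- function(q, P) max(apply(q, 1, function(p)
    min(pmax(abs(P[, 1] - p[1]), abs(P[, 2] - p[2])))))
  for (wh in list(c(96, 96), c(128, 64), c(97, 33))) {
    P <- border_lattice(wh[1], wh[2])$points
    expect_lte(nearest(cbind(wh[1] - 1 - P[, 1], P[, 2]), P), 1)
    expect_lte(nearest(cbind(P[, 1], wh[2] - 1 - P[, 2]), P), 1)
  }
  # odd sizes have a pixel-exact midpoint: symmetry is exact there
  P <- border_lattice(97, 97)$points
  key <- paste(P[, 1], P[, 2])
  expect_setequal(paste(96 - P[, 1], P[, 2]), key)
  expect_setequal(paste(P[, 1], 96 - P[, 2]), key)
})

test_that("minimum pairwise distance follows the per-axis-min metric", {
  K <- keypoint_set(rbind(c(0, 0), c(3, 5)), rep("interior", 2))
  expect_equal(min_pairwise_distance(K), 3)
  # shared x-coordinate: degenerate 0 under the printed metric
  K0 <- keypoint_set(rbind(c(0, 0), c(0, 7)), rep("interior", 2))
  expect_equal(min_pairwise_distance(K0), 0)
  expect_error(min_pairwise_distance(
    keypoint_set(cbind(1, 1), "interior")), "at least 2")

  # brute-force oracle over all 45 pairs of 10 random points
  set.seed(42)
  pts <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  K10 <- keypoint_set(pts, rep("interior", 10))
  brute <- Inf
  for (a in 1:9) for (b in (a + 1):10)
    brute <- min(brute, min(abs(pts[a, 1] - pts[b, 1]),
                            abs(pts[a, 2] - pts[b, 2])))
  expect_equal(min_pairwise_distance(K10), brute)
})

test_that("interior-only pair policy excludes the degenerate border lattice", {
  pair <- default_mosaic(n_cells = 10, seed = 5)
  K <- pair_keypoints(pair)
  expect_equal(min_pairwise_distance(K, pairs = "all"), 0) # collinear lattice
  expect_gte(min_pairwise_distance(K, pairs = "auto"), 0)
})

test_that("delaunay meets its basic contracts", {
  tri3 <- delaunay(keypoint_set(rbind(c(0, 0), c(10, 0), c(5, 8)),
                                rep("interior", 3)))
  expect_equal(nrow(tri3$triangles), 1)
  sq <- delaunay(keypoint_set(rbind(c(0, 0), c(9, 0), c(0, 9), c(9, 9)),
                              rep("border", 4)))
  expect_equal(nrow(sq$triangles), 2)
  expect_error(delaunay(keypoint_set(cbind(1:5, 2 * (1:5)),
                                     rep("interior", 5))),
               "triangulation failed|collinear")
})

test_that("delaunay satisfies the empty-circumcircle property", {
  set.seed(7)
  for (rep in 1:5) {
    pts <- cbind(runif(15, 0, 95), runif(15, 0, 95))
    m <- delaunay(keypoint_set(pts, rep("interior", 15)))
    expect_lt(circumcircle_violation(pts, m$triangles), 1e-9)
  }
})

test_that("mesh triangles are CCW, tile the hull, and use every point", {
  pair <- default_mosaic(n_cells = 20, seed = 1)
  K <- pair_keypoints(pair)
  m <- delaunay(K)
  areas <- endowarp:::mesh_areas(K$points, m$triangles)
  expect_true(all(areas > 0))
  # triangle areas sum to the convex hull area (the full 96x96 rectangle
  # since the lattice corners are in K)
  expect_equal(sum(areas), 95 * 95, tolerance = 1e-6)
  expect_setequal(as.vector(m$triangles), seq_len(nrow(K$points)))
})

test_that("keypoint and mesh exports are readable text", {
  K <- pair_keypoints(default_mosaic(n_cells = 8, seed = 2))
  m <- delaunay(K)
  td <- withr::local_tempdir()
  write_keypoints_csv(K, file.path(td, "k.csv"))
  tab <- read.csv(file.path(td, "k.csv"))
  expect_identical(nrow(tab), nrow(K$points))
  expect_named(tab, c("x", "y", "role"))
  write_mesh_off(K, m, file.path(td, "m.off"))
  lines <- readLines(file.path(td, "m.off"))
  expect_identical(lines[1], "OFF")
  expect_length(lines, 2 + nrow(K$points) + nrow(m$triangles))
})
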