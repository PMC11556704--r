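test_that("shift sampling obeys the delta = R * d_min / s law", {
  K <- pair_keypoints(default_mosaic(n_cells = 15, seed = 3))
  expect_error(sample_shifts(K, s = 0), "s")
  expect_error(sample_shifts(K, s = -2), "s")

  # same RNG stream: sample_shifts must equal a hand-rolled draw
  n_int <- sum(K$roles == "interior")
  set.seed(123)
  sf <- sample_shifts(K, s = 2, d_min = 8)
  set.seed(123)
  manual <- t(vapply(seq_len(n_int), function(i) runif(2, -1, 1) * 8 / 2,
                     numeric(2)))
  expect_equal(unname(sf$deltas[K$roles == "interior", ]), manual)
  expect_true(all(sf$deltas[K$roles == "border", ] == 0))
  expect_true(all(abs(sf$deltas) <= 8 / 2))

  # s -> large is numerically the identity
  set.seed(5)
  tiny <- sample_shifts(K, s = 1e6, d_min = 8)
  expect_true(all(abs(tiny$deltas) <= 8e-6))
})

test_that("mean shift magnitude scales as 1/s (s = 2 vs s = 3)", {
  K <- pair_keypoints(default_mosaic(n_cells = 25, seed = 8))
  n_int <- sum(K$roles == "interior")
  draw_mean <- function(s, reps) {
    set.seed(99 + s) # independent streams per strain level
    v <- replicate(reps, {
      sf <- sample_shifts(K, s = s, d_min = 8)
      mean(abs(sf$deltas[K$roles == "interior", ]))
    })
    mean(v)
  }
  reps <- ceiling(1e4 / (2 * n_int))
  ratio <- draw_mean(2, reps) / draw_mean(3, reps)
  expect_equal(ratio, 1.5, tolerance = 0.05)
})

test_that("zero shifts build an exact identity map", {
  pair <- default_mosaic(n_cells = 12, seed = 6)
  K <- pair_keypoints(pair)
  map <- build_map(K, zero_shifts(K))
  expect_true(map$valid)
  for (A in map$fwd)
    expect_equal(A, rbind(diag(2), 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
  w <- apply_warp(pair, map)
  expect_identical(w$image, pair$image)
  expect_identical(w$label_mask, pair$label_mask)
})

test_that("vertex correspondences are reproduced exactly", {
  pair <- default_mosaic(n_cells = 20, seed = 2)
  K <- pair_keypoints(pair)
  set.seed(4)
  sf <- sample_shifts(K, s = 2, d_min = 6)
  map <- build_map(K, sf)
  expect_true(map$valid)
  expect_lt(max(abs(forward_map(map, K$points) - map$dst)), 1e-9)

  # a single interior point shifted by (4, 0) maps exactly to its target
  lat <- border_lattice(64, 64)
  K1 <- keypoint_set(rbind(c(30, 30), lat$points),
                     c("interior", lat$roles))
  sf1 <- zero_shifts(K1)
  sf1$deltas[1, ] <- c(4, 0)
  m1 <- build_map(K1, sf1)
  expect_true(m1$valid)
  expect_equal(forward_map(m1, rbind(c(30, 30)))[1, ], c(34, 30))
})

test_that("forward map agrees with the barycentric brute-force oracle", {
  pair <- default_mosaic(n_cells = 20, seed = 2)
  r <- quiet_warp(pair, s = 2, seed = 3)
  set.seed(11)
  pts <- cbind(runif(200, 0, 95), runif(200, 0, 95))
  expect_lt(max(abs(forward_map(r$map, pts) - oracle_forward(r$map, pts))),
            1e-6)
})

test_that("warping preserves label vocabulary and constant images", {
  pair <- default_mosaic(n_cells = 18, seed = 5)
  r <- quiet_warp(pair, s = 2, seed = 7)
  expect_true(all(unique(as.vector(r$pair$label_mask)) %in%
                    unique(as.vector(pair$label_mask))))

  const <- labeled_pair(matrix(0.5, 96, 96), pair$label_mask)
  wc <- apply_warp(const, r$map)
  expect_lt(max(abs(wc$image - 0.5)), 1e-6)
})

test_that("invalid maps are flagged, not thrown, and rejected by apply_warp", {
  lat <- border_lattice(64, 64)
  K <- keypoint_set(rbind(c(30, 30), c(33, 35), lat$points),
                    c("interior", "interior", lat$roles))
  sf <- zero_shifts(K)
  sf$deltas[1, ] <- c(3, 5) # collide the two interior targets
  m <- build_map(K, sf)
  expect_false(m$valid)
  pair <- default_mosaic(n_cells = 6, seed = 1, size = 64)
  expect_error(apply_warp(pair, m), "resample")
})

test_that("warp_pair is deterministic and respects the shift bound", {
  pair <- default_mosaic(n_cells = 20, seed = 7)
  a <- quiet_warp(pair, s = 2, seed = 31)
  b <- quiet_warp(pair, s = 2, seed = 31)
  expect_identical(a$pair, b$pair)
  expect_identical(a$shifts, b$shifts)
  bound <- a$d_min_used / a$s
  expect_true(all(abs(a$shifts$deltas) <= bound + 1e-12))
})

test_that("border pixels are fixed points of accepted maps", {
  pair <- default_mosaic(n_cells = 15, seed = 4)
  r <- quiet_warp(pair, s = 2, seed = 9)
  edge <- rbind(cbind(0:95, 0), cbind(0:95, 95), cbind(0, 0:95), cbind(95, 0:95))
  expect_lt(max(abs(forward_map(r$map, edge) - edge)), 1e-9)
})

test_that("accepted warps keep every region present and unfragmented", {
  pair <- default_mosaic(n_cells = 30, seed = 12)
  for (seed in 1:5) {
    r <- quiet_warp(pair, s = 2, seed = seed)
    expect_identical(sort(setdiff(unique(as.vector(r$pair$label_mask)), 0L)),
                     sort(setdiff(unique(as.vector(pair$label_mask)), 0L)))
    for (k in unique(pair$regions$id)) {
      comp <- endowarp:::cc_label(r$pair$label_mask == k, 4L)
      expect_identical(max(comp), 1L)
    }
  }
})

test_that("boundary-raster warping is supported as an alternative path", {
  pair <- clean_mosaic(n_cells = 10, seed = 3)
  r <- quiet_warp(pair, s = 3, seed = 21, mask_warp = "boundary")
  ids <- setdiff(unique(as.vector(r$pair$label_mask)), 0L)
  expect_gt(length(ids), 0)
})

test_that("exhausting the retry budget reports the failure mode", {
  pair <- default_mosaic(n_cells = 6, seed = 1, size = 64)
  fake <- pair
  # a mask whose only region is 1 px: any resampling drift loses it
  lab <- matrix(0L, 64, 64)
  lab[2, 2] <- 1L; lab[40, 40] <- 2L
  fake <- labeled_pair(pair$image, lab)
  expect_error(suppressMessages(warp_pair(fake, s = 1.01, seed = 2,
                                          retry_budget = 3)),
               "retry budget|region-loss")
})
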