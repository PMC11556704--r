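#' Configuration of the batch augmentation pipeline
#'
#' Defaults reproduce the operating regime of endothelium augmentation:
#' strain `s` drawn uniformly from `[2, 3]`, where `s = 2` gives strong and
#' `s = 3` mild deformations.
#'
#' @param s_range Length-2 interval for the strain parameter, lower bound
#'   `> 0`. A single value fixes `s`.
#' @param n_outputs_per_input Augmented outputs requested per input pair.
#' @param seed Integer master seed; per-output seeds and strains are derived
#'   from it, making whole runs bit-reproducible.
#' @param retry_budget Redraw budget per output ([warp_pair()]).
#' @param refine A [refine_config()], or `NULL` to skip refinement.
#' @param connectivity_side,mask_warp Passed to [warp_pair()].
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(s_range = c(2, 3), n_outputs_per_input = 1,
                           seed = 1, retry_budget = 20,
                           refine = refine_config(),
                           connectivity_side = c("target", "source"),
                           mask_warp = c("labels", "boundary")) {
  if (length(s_range) == 1) s_range <- c(s_range, s_range)
  if (length(s_range) != 2 || s_range[1] <= 0 || s_range[2] < s_range[1])
    stop_field("s_range", "must be an interval with lower bound > 0")
  if (n_outputs_per_input < 1)
    stop_field("n_outputs_per_input", "must be >= 1")
  if (!is.null(refine) && !inherits(refine, "refine_config"))
    stop_field("refine", "must be a refine_config() or NULL")
  structure(list(s_range = as.numeric(s_range),
                 n_outputs_per_input = as.integer(n_outputs_per_input),
                 seed = as.integer(seed),
                 retry_budget = as.integer(retry_budget),
                 refine = refine,
                 connectivity_side = match.arg(connectivity_side),
                 mask_warp = match.arg(mask_warp)),
            class = "augment_config")
}

# one augmented pair + its reproducibility sidecar
augment_one <- function(pair, s, seed, cfg) {
  res <- warp_pair(pair, s = s, seed = seed,
                   retry_budget = cfg$retry_budget,
                   connectivity_side = cfg$connectivity_side,
                   mask_warp = cfg$mask_warp)
  out_pair <- res$pair
  if (!is.null(cfg$refine)) {
    lab <- refine_mask(out_pair$image, out_pair$label_mask, cfg$refine)
    out_pair <- labeled_pair(out_pair$image, lab, regions = out_pair$regions)
  }
  list(pair = out_pair, result = res)
}

sidecar_list <- function(res, image_src, mask_src) {
  list(source_image = image_src, source_mask = mask_src,
       s = res$s, seed = res$seed, d_min_used = res$d_min_used,
       n_retries = res$n_retries,
       keypoints = cbind(res$keypoints$points,
                         role = res$keypoints$roles),
       deltas = res$shifts$deltas)
}

#' Augment a dataset of image/mask pairs
#'
#' For every input pair, `n_outputs_per_input` strains are drawn uniformly
#' from `s_range`; each output runs [warp_pair()] (with automated rejection
#' and retry) followed by watershed refinement, and is written alongside a
#' JSON sidecar recording the strain, seed, `d_min`, keypoints and shifts
#' for exact replay. The run is fully deterministic given `cfg$seed`.
#'
#' @param manifest Data frame with columns `image` and `mask`, or the path
#'   of a CSV with those columns.
#' @param out_dir Output directory (created if missing).
#' @param cfg An [augment_config()].
#' @return Invisibly, the run report: counts of inputs, successes,
#'   rejections and retries, and the achieved dataset multiplier
#'   (originals + accepted outputs, relative to originals). Also written to
#'   `out_dir/report.json`.
#' @export
augment_dataset <- function(manifest, out_dir, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  if (is.character(manifest)) manifest <- read.csv(manifest)
  if (!all(c("image", "mask") %in% names(manifest)))
    stop("manifest needs columns 'image' and 'mask'", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  n_in <- nrow(manifest)
  n_total <- n_in * cfg$n_outputs_per_input
  # derive all per-output draws up front from the master seed
  draws <- with_seed(cfg$seed, list(
    s = runif(n_total, cfg$s_range[1], cfg$s_range[2]),
    seed = sample.int(.Machine$integer.max - 1L, n_total)))

  n_success <- 0L; n_rejected <- 0L; n_skipped <- 0L; total_retries <- 0L
  log_lines <- character(0)
  for (i in seq_len(n_in)) {
    pair <- tryCatch(read_pair(manifest$image[i], manifest$mask[i]),
                     error = function(e) {
                       message("skipping pair ", i, ": ", conditionMessage(e))
                       NULL
                     })
    if (is.null(pair)) { n_skipped <- n_skipped + 1L; next }
    stem <- tools::file_path_sans_ext(basename(manifest$image[i]))
    for (j in seq_len(cfg$n_outputs_per_input)) {
      k <- (i - 1L) * cfg$n_outputs_per_input + j
      out <- tryCatch(
        augment_one(pair, draws$s[k], draws$seed[k], cfg),
        error = function(e) {
          message("rejected ", stem, " output ", j, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(out)) { n_rejected <- n_rejected + 1L; next }
      n_success <- n_success + 1L
      total_retries <- total_retries + out$result$n_retries
      base <- sprintf("%s_aug%02d", stem, j)
      write_pair(out$pair,
                 file.path(out_dir, paste0(base, "_image.tif")),
                 file.path(out_dir, paste0(base, "_mask.tif")))
      jsonlite::write_json(
        sidecar_list(out$result, manifest$image[i], manifest$mask[i]),
        file.path(out_dir, paste0(base, ".json")),
        auto_unbox = TRUE, digits = NA)
      log_lines <- c(log_lines, sprintf(
        "%s s=%.4f seed=%d retries=%d ok", base,
        draws$s[k], draws$seed[k], out$result$n_retries))
    }
  }
  if (n_success == 0) stop("all pairs failed to augment", call. = FALSE)
  report <- list(n_inputs = n_in,
                 n_outputs_requested = n_total,
                 n_success = n_success,
                 n_rejected = n_rejected,
                 n_inputs_skipped = n_skipped,
                 total_retries = total_retries,
                 multiplier = (n_in + n_success) / n_in,
                 seed = cfg$seed, s_range = cfg$s_range)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(report)
}

#' Replay one augmentation from its sidecar
#'
#' Re-runs [warp_pair()] with the strain and seed recorded in a sidecar
#' JSON, reproducing that output bit-exactly.
#'
#' @param pair The source [labeled_pair()].
#' @param sidecar_path Path to the sidecar JSON written by
#'   [augment_dataset()].
#' @param cfg The [augment_config()] used for the original run.
#' @return The re-created warped (and refined, if configured) pair.
#' @export
replay_sidecar <- function(pair, sidecar_path, cfg = augment_config()) {
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  augment_one(pair, s = sc$s, seed = sc$seed, cfg)$pair
}

# draw a 1-px line into an rgb array (Bresenham-free dense sampling)
draw_line <- function(rgb, x0, y0, x1, y1, col = c(1, 0.85, 0)) {
  n <- max(2, ceiling(2 * max(abs(x1 - x0), abs(y1 - y0))))
  xs <- clamp(round(seq(x0, x1, length.out = n)), 0, dim(rgb)[2] - 1)
  ys <- clamp(round(seq(y0, y1, length.out = n)), 0, dim(rgb)[1] - 1)
  for (ch in 1:3) rgb[cbind(ys + 1, xs + 1, ch)] <- col[ch]
  rgb
}

gray_to_rgb <- function(img) array(rep(img, 3), c(dim(img), 3))

overlay_mesh <- function(img, points, triangles) {
  rgb <- gray_to_rgb(img)
  for (t in seq_len(nrow(triangles))) {
    i <- triangles[t, ]
    for (e in list(c(1, 2), c(2, 3), c(3, 1)))
      rgb <- draw_line(rgb, points[i[e[1]], 1], points[i[e[1]], 2],
                       points[i[e[2]], 1], points[i[e[2]], 2])
  }
  rgb
}

#' Demonstration run: original vs mild vs strong deformation
#'
#' Generates a small synthetic mosaic, augments it at `s = 3` (mild) and
#' `s = 2` (strong), and writes the pairs plus a side-by-side panel
#' (original, mild, strong — top row images with the warped mesh overlaid,
#' bottom row boundary masks).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, a list with the original pair and the two
#'   `warp_result`s.
#' @export
endowarp_demo <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- generate_mosaic(mosaic_spec(96, 96, n_cells = 20, seed = seed))
  write_pair(pair, file.path(out_dir, "original_image.tif"),
             file.path(out_dir, "original_mask.tif"))
  res <- list()
  for (s in c(3, 2)) {
    r <- warp_pair(pair, s = s, seed = seed + s)
    write_pair(r$pair,
               file.path(out_dir, sprintf("warped_s%g_image.tif", s)),
               file.path(out_dir, sprintf("warped_s%g_mask.tif", s)))
    res[[sprintf("s%g", s)]] <- r
  }
  h <- nrow(pair$image); w <- ncol(pair$image); gap <- 4
  panel <- array(1, c(2 * h + gap, 3 * w + 2 * gap, 3))
  put <- function(panel, rgb, row, col) {
    r0 <- (row - 1) * (h + gap); c0 <- (col - 1) * (w + gap)
    panel[r0 + seq_len(h), c0 + seq_len(w), ] <- rgb
    panel
  }
  K <- res$s3$keypoints
  mesh0 <- delaunay(K)
  panel <- put(panel, overlay_mesh(pair$image, K$points, mesh0$triangles), 1, 1)
  panel <- put(panel, overlay_mesh(res$s3$pair$image, res$s3$map$dst,
                                   res$s3$map$triangles), 1, 2)
  panel <- put(panel, overlay_mesh(res$s2$pair$image, res$s2$map$dst,
                                   res$s2$map$triangles), 1, 3)
  panel <- put(panel, gray_to_rgb(1 - pair$boundary_mask), 2, 1)
  panel <- put(panel, gray_to_rgb(1 - res$s3$pair$boundary_mask), 2, 2)
  panel <- put(panel, gray_to_rgb(1 - res$s2$pair$boundary_mask), 2, 3)
  png::writePNG(panel, file.path(out_dir, "panel.png"))
  invisible(c(list(original = pair), res))
}
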