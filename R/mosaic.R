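#' Specification of a synthetic endothelium mosaic
#'
#' Parameters of the synthetic specular-microscopy-like generator. Cells are
#' laid out as a Voronoi partition of random seed points, giving convex-ish
#' polygonal regions with dark borders like a healthy endothelial mosaic; a
#' fraction of regions can be rendered as dark guttae blobs to emulate Fuchs
#' dystrophy. Degradations (illumination gradient, blur, noise) mimic the
#' acquisition artefacts of in-vivo specular microscopy.
#'
#' @param height,width Image size in pixels.
#' @param n_cells Number of regions (cells + guttae), `>= 1`.
#' @param guttae_fraction Fraction in `[0, 1]` of regions rendered as dark
#'   guttae blobs.
#' @param border_width Width of the dark intercellular border in pixels
#'   (`>= 1`; the base two-sided interface is already 2 px wide).
#' @param illumination_amplitude Relative amplitude in `[0, 1]` of a smooth
#'   multiplicative illumination gradient.
#' @param blur_sigma Gaussian blur sigma in pixels (`>= 0`).
#' @param noise_sd Additive Gaussian noise standard deviation in intensity
#'   units (image range is `[0, 1]`), `>= 0`.
#' @param seed Integer RNG seed; a fixed spec renders bit-identically.
#' @return An object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(height = 96, width = 96, n_cells = 20,
                        guttae_fraction = 0, border_width = 1,
                        illumination_amplitude = 0.15, blur_sigma = 0.7,
                        noise_sd = 0.02, seed = 1) {
  if (!is.numeric(height) || height < 8) stop_field("height", "must be >= 8")
  if (!is.numeric(width) || width < 8) stop_field("width", "must be >= 8")
  if (!is.numeric(n_cells) || n_cells < 1) stop_field("n_cells", "must be >= 1")
  if (n_cells > height * width)
    stop_field("n_cells", "cannot exceed height*width (seeds must be distinct pixels)")
  if (guttae_fraction < 0 || guttae_fraction > 1)
    stop_field("guttae_fraction", "must lie in [0, 1]")
  if (border_width < 1) stop_field("border_width", "must be >= 1")
  if (illumination_amplitude < 0 || illumination_amplitude > 1)
    stop_field("illumination_amplitude", "must lie in [0, 1]")
  if (blur_sigma < 0) stop_field("blur_sigma", "must be >= 0")
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 guttae_fraction = guttae_fraction,
                 border_width = as.integer(border_width),
                 illumination_amplitude = illumination_amplitude,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mosaic_spec")
}

# intensity levels of the rendered mosaic (fractions of full scale)
.mosaic_levels <- list(cell = 0.85, gutta = 0.35, border = 0.15)

# sample n distinct seed pixels with a soft minimum separation so no
# Voronoi cell degenerates to a sliver; deterministic under the caller's RNG
sample_seed_points <- function(height, width, n) {
  min_sep <- max(3, floor(0.45 * sqrt(height * width / n)))
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; cap <- 500L * n
  while (length(xs) < n && attempts < cap) {
    attempts <- attempts + 1L
    cx <- sample.int(width, 1) - 1
    cy <- sample.int(height, 1) - 1
    if (length(xs) == 0 ||
        min(pmax(abs(xs - cx), abs(ys - cy))) >= min_sep) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  while (length(xs) < n) { # fallback: any unused pixel
    cx <- sample.int(width, 1) - 1
    cy <- sample.int(height, 1) - 1
    if (!any(xs == cx & ys == cy)) { xs <- c(xs, cx); ys <- c(ys, cy) }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic cell-mosaic image/mask pair
#'
#' Renders a Voronoi partition of `n_cells` seed points as a bright cell
#' mosaic with dark borders; a `guttae_fraction` share of regions is drawn
#' as dark guttae blobs. The intensity image is the base mosaic multiplied
#' by a smooth illumination field, plus Gaussian noise, then Gaussian blur,
#' quantized to the 8-bit grid. Deterministic for a fixed spec.
#'
#' @param spec A [mosaic_spec()].
#' @return A [labeled_pair()] whose `regions` table records, per region id,
#'   the seed point, the guttae flag and the pixel area.
#' @examples
#' pair <- generate_mosaic(mosaic_spec(n_cells = 12, seed = 42))
#' pair
#' @export
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  h <- spec$height; w <- spec$width; n <- spec$n_cells
  with_seed(spec$seed, {
    seeds <- sample_seed_points(h, w, n)

    # nearest-seed assignment (squared Euclidean, ties -> lowest id)
    g <- pixel_grid(h, w)
    d2 <- matrix(0, h * w, n)
    for (k in seq_len(n))
      d2[, k] <- (g$x - seeds[k, 1])^2 + (g$y - seeds[k, 2])^2
    voronoi <- matrix(max.col(-d2, ties.method = "first"), h, w)
    storage.mode(voronoi) <- "integer"

    n_guttae <- round(spec$guttae_fraction * n)
    gutta_ids <- if (n_guttae > 0) sort(sample.int(n, n_guttae)) else integer(0)

    # carve the intercellular border: two-sided interface, dilated if wider
    border <- boundary_from_labels(voronoi)
    if (spec$border_width > 1) {
      brush <- EBImage::makeBrush(2 * (spec$border_width - 1) + 1, "disc")
      border <- EBImage::dilate(border * 1, brush) > 0
    }
    label_mask <- voronoi
    label_mask[border] <- 0L
    # guarantee every region keeps at least its seed pixel
    for (k in seq_len(n)) {
      if (!any(label_mask == k))
        label_mask[seeds[k, 2] + 1, seeds[k, 1] + 1] <- k
    }
    # enforce 4-connected regions: carving can pinch a cell at triple
    # junctions; stray fragments are reassigned to the border
    for (k in seq_len(n)) {
      comp <- cc_label(label_mask == k, connectivity = 4L)
      if (max(comp) > 1L) {
        sizes <- tabulate(comp[comp > 0L])
        label_mask[comp > 0L & comp != which.max(sizes)] <- 0L
      }
    }

    base <- matrix(.mosaic_levels$cell, h, w)
    base[label_mask == 0L] <- .mosaic_levels$border
    for (k in gutta_ids) base[voronoi == k] <- .mosaic_levels$gutta

    # smooth multiplicative illumination: tilted plane in a random direction
    theta <- runif(1, 0, 2 * pi)
    u <- (matrix(g$x, h, w) / max(1, w - 1) - 0.5) * cos(theta) +
         (matrix(g$y, h, w) / max(1, h - 1) - 0.5) * sin(theta)
    illum <- 1 + spec$illumination_amplitude * 2 * u

    img <- base * illum
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    if (spec$blur_sigma > 0)
      img <- EBImage::gblur(img, sigma = spec$blur_sigma)
    img <- quantize_intensity(clamp(img, 0, 1), 8L)

    areas <- tabulate(label_mask[label_mask > 0L], nbins = n)
    regions <- data.frame(id = seq_len(n),
                          seed_x = seeds[, 1], seed_y = seeds[, 2],
                          is_gutta = seq_len(n) %in% gutta_ids,
                          area = areas)
    labeled_pair(img, label_mask, regions = regions)
  })
}
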