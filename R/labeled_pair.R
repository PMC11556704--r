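#' Image/mask pair kept in lockstep
#'
#' A `labeled_pair` bundles a grayscale intensity raster with its integer
#' label mask. Intensities live in `[0, 1]` internally regardless of the
#' on-disk bit depth; the label mask assigns `0` to boundary/background
#' pixels and an id `k >= 1` to each cell or gutta region. A binary
#' boundary mask is derived from the labels, never stored independently.
#'
#' @param image Numeric matrix (rows = height, cols = width), values in
#'   `[0, 1]`.
#' @param label_mask Integer matrix of the same dimensions; `0` marks
#'   boundary/background pixels.
#' @param regions Optional data frame describing the regions (used by
#'   [generate_mosaic()] to record guttae flags and seed points).
#' @return An object of class `labeled_pair` with elements `image`,
#'   `label_mask`, `boundary_mask` and optionally `regions`.
#' @seealso [generate_mosaic()], [write_pair()], [read_pair()]
#' @export
labeled_pair <- function(image, label_mask, regions = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_field("image", "must be a numeric matrix")
  if (!is.matrix(label_mask))
    stop_field("label_mask", "must be an integer matrix")
  if (!identical(dim(image), dim(label_mask)))
    stop("image and label_mask dimensions differ: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(label_mask), collapse = "x"), call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop_field("image", "intensities must lie in [0, 1]")
  storage.mode(label_mask) <- "integer"
  if (min(label_mask) < 0)
    stop_field("label_mask", "ids must be >= 0")
  structure(
    list(image = image,
         label_mask = label_mask,
         boundary_mask = boundary_from_labels(label_mask),
         regions = regions),
    class = "labeled_pair")
}

#' @export
print.labeled_pair <- function(x, ...) {
  d <- dim(x$image)
  ids <- setdiff(unique(as.vector(x$label_mask)), 0L)
  cat(sprintf("<labeled_pair> %d x %d, %d regions, %d boundary px\n",
              d[1], d[2], length(ids), sum(x$boundary_mask)))
  invisible(x)
}

#' @export
dim.labeled_pair <- function(x) dim(x$image)

#' Boundary mask from a label raster
#'
#' A pixel belongs to the boundary when any of its 8 neighbours carries a
#' different label id (including id 0). This two-sided rule marks both
#' flanks of every region interface, so a 1-px interface yields a 2-px
#' boundary band. Pixels on the image frame are not flagged merely for
#' touching the frame (`include_frame = FALSE`, the default).
#'
#' @param label_mask Integer matrix of region ids.
#' @param include_frame Flag image-frame pixels as boundary regardless of
#'   their neighbours.
#' @return Logical matrix of the same dimensions.
#' @export
boundary_from_labels <- function(label_mask, include_frame = FALSE) {
  nr <- nrow(label_mask); nc <- ncol(label_mask)
  b <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    c0 <- c1 - dc
    b[r0, c0] <- b[r0, c0] | (label_mask[r0, c0] != label_mask[r1, c1])
  }
  if (include_frame) {
    b[c(1, nr), ] <- TRUE
    b[, c(1, nc)] <- TRUE
  }
  b
}

#' Recover a label mask from a binary boundary mask
#'
#' Non-boundary pixels are grouped by 4-connectivity; each component becomes
#' a region. A component touching the image frame is treated as background
#' (excluded, id not assigned) only when its area exceeds half the image,
#' which discards a surrounding background sheet while keeping frame-touching
#' cells. Components below `min_area` pixels — interstitial slivers inside
#' wide boundary bands at cell junctions — are absorbed into the boundary.
#'
#' @param boundary_mask Logical or 0/1 matrix, `TRUE`/1 = boundary pixel.
#' @param min_area Smallest component kept as a region.
#' @return Integer label matrix; boundary pixels keep id 0.
#' @export
labels_from_boundary <- function(boundary_mask, min_area = 4) {
  bm <- boundary_mask != 0
  lab <- cc_label(!bm, connectivity = 4L)
  nr <- nrow(lab); nc <- ncol(lab)
  frame_ids <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  frame_ids <- setdiff(frame_ids, 0L)
  for (id in frame_ids) {
    if (sum(lab == id) > 0.5 * nr * nc) lab[lab == id] <- 0L
  }
  sizes <- tabulate(lab[lab > 0L])
  for (id in which(sizes > 0 & sizes < min_area)) lab[lab == id] <- 0L
  # renumber compactly
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  out <- matrix(0L, nr, nc)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# quantize intensities to the grid representable at `bits` depth
quantize_intensity <- function(image, bits = 8L) {
  mx <- 2^bits - 1
  round(image * mx) / mx
}

#' Write an image/mask pair to disk
#'
#' Images are written as single-channel TIF or PNG at the requested bit
#' depth (PNG is 8-bit; 16-bit requires TIF). Label masks are written as
#' integer-valued rasters; binary boundary masks as 0/255.
#'
#' @param pair A [labeled_pair()].
#' @param image_path,mask_path Output paths ending in `.tif`/`.tiff` or
#'   `.png`.
#' @param bits Bit depth for the image file (8 or 16).
#' @param mask_kind Write the integer label mask (`"labels"`, default) or
#'   the binary boundary mask as 0/255 (`"boundary"`).
#' @return Invisibly, the two paths.
#' @export
write_pair <- function(pair, image_path, mask_path, bits = 8L,
                       mask_kind = c("labels", "boundary")) {
  stopifnot(inherits(pair, "labeled_pair"))
  mask_kind <- match.arg(mask_kind)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop_field("bits", "must be 8 or 16")
  img <- quantize_intensity(pair$image, bits)
  write_raster(img, image_path, bits)
  if (mask_kind == "boundary") {
    write_raster(ifelse(pair$boundary_mask, 255, 0) / 255, mask_path, 8L)
  } else {
    maxid <- max(pair$label_mask)
    mbits <- if (maxid > 255 || grepl("\\.tiff?$", mask_path, ignore.case = TRUE)) 16L else 8L
    if (maxid > 255 && !grepl("\\.tiff?$", mask_path, ignore.case = TRUE))
      stop("label ids exceed 255; write the mask as TIF", call. = FALSE)
    write_raster(pair$label_mask / (2^mbits - 1), mask_path, mbits)
  }
  invisible(c(image_path, mask_path))
}

write_raster <- function(values, path, bits) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(values, path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (bits != 8L)
      stop("PNG output is 8-bit; use TIF for 16-bit rasters", call. = FALSE)
    png::writePNG(values, path)
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(v)) == 3) {
    warning("multi-channel raster in ", basename(path),
            ": keeping channel 1", call. = FALSE)
    v <- v[, , 1]
  }
  v
}

read_mask_int <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE))
    if (length(dim(v)) == 3) {
      warning("multi-channel mask in ", basename(path),
              ": keeping channel 1", call. = FALSE)
      v <- v[, , 1]
    }
    m <- v
  } else if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3) {
      warning("multi-channel mask in ", basename(path),
              ": keeping channel 1", call. = FALSE)
      v <- v[, , 1]
    }
    m <- round(v * 255) # PNG masks follow the 8-bit convention
  } else stop("unsupported mask format: .", ext, call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Read an image/mask pair from disk
#'
#' Intensities are normalized to `[0, 1]` at their native bit depth. A mask
#' holding exactly the values 0 and 255 is interpreted as a binary boundary
#' mask (the 0/255 on-disk convention) and converted to labels via
#' [labels_from_boundary()]; anything else is taken as an integer label
#' mask. Multi-channel inputs are reduced to channel 1 with a warning.
#'
#' @param image_path,mask_path Paths to TIF or PNG rasters of equal size.
#' @return A [labeled_pair()].
#' @export
read_pair <- function(image_path, mask_path) {
  img <- read_gray(image_path)
  msk <- read_mask_int(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop("image (", paste(dim(img), collapse = "x"), ") and mask (",
         paste(dim(msk), collapse = "x"), ") dimensions differ",
         call. = FALSE)
  vals <- sort(unique(as.vector(msk)))
  if (identical(vals, c(0L, 255L))) {
    msk <- labels_from_boundary(msk != 0)
  }
  labeled_pair(img, msk)
}
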