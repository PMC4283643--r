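# Neuron detection in the NeuN channel. Stand-in for the black-box
# segmentation step of the original pipeline: Gaussian smoothing, Otsu (or
# absolute) thresholding, connected components, distance-transform
# watershed to split touching somata, and a minimum-area filter.

#' Wrap a raster as a section image
#'
#' @param pixels height x width x channels array, 8-bit values (0-255).
#'   Higher-depth rasters are linearly rescaled to 0-255 with a message.
#' @param channel_roles Named integer vector mapping role ("neun",
#'   "tracer_red", "tracer_yellow", ...) to channel index; must cover
#'   "neun" and at least one tracer role.
#' @param pixel_size Micrometers per pixel.
#' @return A list of class `"section_image"`.
#' @export
section_image <- function(pixels, channel_roles = CHANNEL_ROLES,
                          pixel_size = 0.23) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  if (!"neun" %in% names(channel_roles)) {
    stop_cf("channel_roles must include 'neun'")
  }
  if (!any(grepl("^tracer", names(channel_roles)))) {
    stop_cf("channel_roles must include at least one tracer role")
  }
  if (max(channel_roles) > dim(pixels)[3]) {
    stop_cf("channel_roles index %d exceeds channel count %d",
            max(channel_roles), dim(pixels)[3])
  }
  mx <- max(pixels)
  if (mx > 255) {
    message(sprintf("rescaling raster from max %g to 8-bit (factor %.4g)",
                    mx, 255 / mx))
    pixels <- round(pixels * (255 / mx))
  }
  if (min(pixels) < 0) stop_cf("negative pixel values")
  structure(list(pixels = pixels, channel_roles = channel_roles,
                 pixel_size = pixel_size),
            class = "section_image")
}

as_section_image <- function(x) {
  if (inherits(x, "section_image")) return(x)
  if (inherits(x, "section_bundle")) {
    if (is.null(x$image)) stop_cf("section bundle has no rendered image")
    return(section_image(x$image, x$channel_roles, x$pixel_size))
  }
  if (is.array(x) && length(dim(x)) == 3) return(section_image(x))
  stop_cf("cannot interpret input as a section image")
}

# Separable Gaussian blur (kernel clipped at 3 sigma, renormalised;
# replicate padding) of a single-channel matrix.
gaussian_blur <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1), n)
  conv_cols <- function(mm) {
    # convolve down each column
    pp <- mm[pad_idx(nrow(mm)), , drop = FALSE]
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k)) {
      out <- out + k[i] * pp[seq_len(nrow(mm)) + (i - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

# Otsu threshold on an 8-bit single-channel matrix: the cut maximising
# between-class variance of the 256-bin histogram.
otsu_threshold <- function(m) {
  h <- tabulate(as.integer(round(m)) + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h) / n
  mu <- cumsum(h * lev) / n
  mu_t <- mu[256]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  lev[which.max(between)]
}

#' Split an image into overlapping tiles
#'
#' Tiles cover the raster completely; offsets give the global pixel
#' coordinate (0-based x, y) of each tile's top-left corner so detections
#' can be mapped back exactly.
#'
#' @param image A [section_image()] (or raw array / `section_bundle`).
#' @param tile_size Tile edge length in pixels; must exceed `2 * overlap`.
#' @param overlap Overlap between adjacent tiles in pixels.
#' @return List of elements `list(image = <section_image>, offset = c(x, y))`.
#' @export
tile_image <- function(image, tile_size, overlap = 0) {
  img <- as_section_image(image)
  check_number(tile_size, "tile_size", min = 1)
  check_number(overlap, "overlap", min = 0)
  if (tile_size <= 2 * overlap) {
    stop_cf("tile_size (%g) must exceed 2 * overlap (%g)", tile_size, 2 * overlap)
  }
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  starts <- function(n) {
    if (tile_size >= n) return(0L)
    s <- seq(0L, n - tile_size, by = tile_size - overlap)
    unique(c(s, n - tile_size))
  }
  out <- list()
  for (y0 in starts(H)) {
    for (x0 in starts(W)) {
      h <- min(tile_size, H - y0); w <- min(tile_size, W - x0)
      sub <- img$pixels[y0 + seq_len(h), x0 + seq_len(w), , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        image = section_image(sub, img$channel_roles, img$pixel_size),
        offset = c(x0, y0)
      )
    }
  }
  out
}

#' Segment neurons in the NeuN channel
#'
#' Gaussian smoothing (sigma 1 px), Otsu threshold (or an absolute
#' override), 8-connected components, marker-based watershed on the
#' chamfer distance transform to split touching somata, and a minimum
#' object size filter.
#'
#' @param image A [section_image()] (or array / `section_bundle`).
#' @param threshold Absolute NeuN threshold overriding Otsu, or `NULL`.
#' @param min_area Minimum component area in pixels.
#' @param sigma Smoothing sigma in pixels.
#' @param split_touching Run the watershed split.
#' @param min_peak_dist Minimum distance (px) between watershed markers.
#' @return Integer label matrix (0 background, 1..n objects), with
#'   attribute `unreliable = TRUE` (plus a warning) when the NeuN channel
#'   is fully saturated.
#' @export
segment_neurons <- function(image, threshold = NULL, min_area = 20,
                            sigma = 1, split_touching = TRUE,
                            min_peak_dist = 5) {
  img <- as_section_image(image)
  neun <- img$pixels[, , img$channel_roles[["neun"]]]
  if (all(neun >= 255)) {
    warning("NeuN channel fully saturated; returning a single region flagged unreliable")
    lab <- matrix(1L, nrow(neun), ncol(neun))
    attr(lab, "unreliable") <- TRUE
    return(lab)
  }
  sm <- gaussian_blur(neun, sigma)
  thr <- threshold %||% otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(neun), ncol(neun)))
  lab <- cpp_label_components(mask)
  if (split_touching) {
    dt <- cpp_chamfer_distance(mask)
    lab <- cpp_watershed_split(dt, lab, min_peak_dist)
  }
  # area filter + sequential relabel
  a <- tabulate(lab[lab > 0L])
  keep <- which(a >= min_area)
  remap <- integer(length(a))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Extract per-cell intensity features
#'
#' One row per label: area, intensity-weighted centroid (weights from the
#' NeuN channel; 0-based pixel-center coordinates), and for every channel
#' the integrated intensity (sum of pixel values over the segmented
#' footprint), maximum and minimum pixel value.
#'
#' @param image A [section_image()] (or array / `section_bundle`).
#' @param labels Label matrix from [segment_neurons()] on the same raster.
#' @param section_id Identifier copied into the table.
#' @return Tibble with columns `section_id`, `cell_id`, `x`, `y`, `area`
#'   and `<role>_integrated` / `<role>_max` / `<role>_min` per channel
#'   role.
#' @export
extract_features <- function(image, labels, section_id = "sec01") {
  img <- as_section_image(image)
  d <- dim(img$pixels)
  if (!all(dim(labels) == d[1:2])) {
    stop_cf("label map %dx%d does not match raster %dx%d",
            nrow(labels), ncol(labels), d[1], d[2])
  }
  idx <- which(labels > 0L)
  n <- max(labels)
  if (n == 0L || length(idx) == 0L) {
    out <- tibble::tibble(section_id = character(0), cell_id = integer(0),
                          x = numeric(0), y = numeric(0), area = integer(0))
    for (role in names(img$channel_roles)) {
      out[[paste0(role, "_integrated")]] <- numeric(0)
      out[[paste0(role, "_max")]] <- numeric(0)
      out[[paste0(role, "_min")]] <- numeric(0)
    }
    return(out)
  }
  lab <- labels[idx]
  rows <- ((idx - 1L) %% d[1])      # 0-based y
  cols <- ((idx - 1L) %/% d[1])     # 0-based x
  area <- tabulate(lab, nbins = n)
  neun_v <- as.numeric(img$pixels[, , img$channel_roles[["neun"]]][idx])
  w <- neun_v
  wsum <- rowsum_vec(w, lab, n)
  # fall back to unweighted centroid where the footprint is NeuN-dark
  zero_w <- wsum <= 0
  if (any(zero_w)) {
    w_adj <- ifelse(wsum[lab] <= 0, 1, w)
    wsum <- rowsum_vec(w_adj, lab, n)
    w <- w_adj
  }
  cx <- rowsum_vec(w * cols, lab, n) / wsum
  cy <- rowsum_vec(w * rows, lab, n) / wsum
  out <- tibble::tibble(
    section_id = section_id,
    cell_id = seq_len(n),
    x = cx, y = cy,
    area = area
  )
  sp <- split(seq_along(lab), lab)
  for (role in names(img$channel_roles)) {
    v <- as.numeric(img$pixels[, , img$channel_roles[[role]]][idx])
    out[[paste0(role, "_integrated")]] <- rowsum_vec(v, lab, n)
    out[[paste0(role, "_max")]] <-
      unname(vapply(sp, function(ii) max(v[ii]), numeric(1)))
    out[[paste0(role, "_min")]] <-
      unname(vapply(sp, function(ii) min(v[ii]), numeric(1)))
  }
  out
}

rowsum_vec <- function(v, g, n) {
  out <- numeric(n)
  rs <- rowsum(v, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Detect cells in a section, optionally tile by tile
#'
#' Convenience wrapper chaining [segment_neurons()] and
#' [extract_features()]. With a `tile_size`, the raster is processed in
#' overlapping tiles, per-tile detections are mapped back to global
#' coordinates and duplicates in the overlap bands are resolved by
#' keeping, of any pair of detections from different tiles closer than
#' `dedup_dist`, the one whose centroid lies farthest from its own tile's
#' border.
#'
#' @inheritParams segment_neurons
#' @param section_id Identifier copied into the feature table.
#' @param tile_size Optional tile edge (pixels); `NULL` processes the
#'   whole raster at once.
#' @param overlap Tile overlap in pixels.
#' @param dedup_dist Radius (px) within which two detections from
#'   different tiles are considered the same cell.
#' @return Feature tibble as from [extract_features()].
#' @export
detect_cells <- function(image, section_id = "sec01", threshold = NULL,
                         min_area = 20, sigma = 1, split_touching = TRUE,
                         min_peak_dist = 5, tile_size = NULL, overlap = 64,
                         dedup_dist = 3) {
  img <- as_section_image(image)
  if (is.null(tile_size)) {
    lab <- segment_neurons(img, threshold = threshold, min_area = min_area,
                           sigma = sigma, split_touching = split_touching,
                           min_peak_dist = min_peak_dist)
    return(extract_features(img, lab, section_id = section_id))
  }
  tiles <- tile_image(img, tile_size, overlap)
  feats <- list()
  for (tl in tiles) {
    lab <- segment_neurons(tl$image, threshold = threshold,
                           min_area = min_area, sigma = sigma,
                           split_touching = split_touching,
                           min_peak_dist = min_peak_dist)
    f <- extract_features(tl$image, lab, section_id = section_id)
    if (nrow(f) == 0) next
    th <- dim(tl$image$pixels)[1]; tw <- dim(tl$image$pixels)[2]
    # distance of each centroid to its own tile border (tile-local coords)
    f$border_dist <- pmin(f$x, f$y, tw - 1 - f$x, th - 1 - f$y)
    f$x <- f$x + tl$offset[1]
    f$y <- f$y + tl$offset[2]
    feats[[length(feats) + 1L]] <- f
  }
  if (length(feats) == 0) {
    return(extract_features(img, matrix(0L, dim(img$pixels)[1],
                                        dim(img$pixels)[2]),
                            section_id = section_id))
  }
  all_f <- dplyr::bind_rows(feats)
  # resolve duplicates: order by border distance (desc), greedily keep
  # detections not within dedup_dist of an already-kept one
  ord <- order(-all_f$border_dist, all_f$x, all_f$y)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) > 0) {
      d2 <- (all_f$x[kept] - all_f$x[i])^2 + (all_f$y[kept] - all_f$y[i])^2
      if (min(d2) < dedup_dist^2) next
    }
    kept <- c(kept, i)
  }
  out <- all_f[sort(kept), ]
  out$border_dist <- NULL
  out$cell_id <- seq_len(nrow(out))
  out
}
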