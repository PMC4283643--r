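# Synthetic histology generator: NeuN-stained coronal sections carrying
# planted neurons of known position and tracer intensity on a curved
# cortical ribbon, with ROI polygons, a cingulum-border arc origin, a
# rhinal-sulcus landmark and an injection site. Every downstream stage is
# validated against the ground truth produced here.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic-section generator
#'
#' Bundles and validates every knob of the synthetic histology world:
#' raster size, pixel scale, the cortical ribbon (a spline through control
#' points standing in for the layer IV/V boundary), cell number and size,
#' tracer intensity ranges for planted positive and negative neurons,
#' background noise, ROI arc breakpoints, and the injection site.
#'
#' Defaults describe a scaled-down coronal section: 1200 x 400 px at
#' 0.23 um/px, 150 neurons of paint radius 4-6 px (Gaussian profile,
#' sigma = radius/3, clipped at 3 sigma) of which 40 carry retrograde
#' tracer with peak amplitude in 150-255 against a negative range of 0-30,
#' on a shallow-arc ribbon split into six named ROIs.
#'
#' @param image_width,image_height Raster size in pixels.
#' @param pixel_size Pixel pitch in micrometers per pixel.
#' @param n_cells Number of planted neurons per section.
#' @param n_tracer_positive How many of them carry retrograde tracer.
#' @param cell_radius_range Length-2 range of paint radii (pixels).
#' @param min_separation Minimum center-to-center distance between planted
#'   cells (pixels); must exceed twice the maximum radius so painted
#'   footprints never overlap.
#' @param neun_intensity_range Peak NeuN-channel amplitude range (0-255).
#' @param tracer_intensity_range_positive,tracer_intensity_range_negative
#'   Peak tracer-channel amplitude ranges for positive / negative cells.
#' @param background_noise_sd Gaussian noise sd added to every channel.
#' @param ribbon_control_points n x 2 matrix of pixel coordinates the
#'   ribbon spline passes through (medial end first).
#' @param ribbon_halfwidth Half-width of the cortical ribbon (pixels).
#' @param roi_arc_breakpoints Named numeric vector: for each ROI, the arc
#'   position (um from the cingulum anchor) where it starts; ROIs run from
#'   each breakpoint to the next (the last to the end of the ribbon).
#'   `NULL` splits the ribbon into six equal ROIs.
#' @param injection_arc_fraction Position of the injection center along
#'   the ribbon, as a fraction of total arc length.
#' @param injection_extent_um Injection-site diameter (um).
#' @param tracer_role Channel the tracer signal is painted into
#'   (`"tracer_red"` or `"tracer_yellow"`).
#' @param line_noise_sd Gaussian jitter (pixels) applied to reference-line
#'   vertices handed to the pipeline; the truth always uses the noiseless
#'   curve.
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @return A validated list of class `"synth_params"`.
#' @export
synth_params <- function(image_width = 1200L,
                         image_height = 400L,
                         pixel_size = 0.23,
                         n_cells = 150L,
                         n_tracer_positive = 40L,
                         cell_radius_range = c(4, 6),
                         min_separation = 13,
                         neun_intensity_range = c(120, 220),
                         tracer_intensity_range_positive = c(150, 255),
                         tracer_intensity_range_negative = c(0, 30),
                         background_noise_sd = 2,
                         ribbon_control_points = NULL,
                         ribbon_halfwidth = 40,
                         roi_arc_breakpoints = NULL,
                         injection_arc_fraction = 0.45,
                         injection_extent_um = 40,
                         tracer_role = "tracer_red",
                         line_noise_sd = 0,
                         seed = 1L) {
  check_number(image_width, "image_width", min = 32)
  check_number(image_height, "image_height", min = 32)
  check_number(pixel_size, "pixel_size", min = 1e-6)
  check_number(n_cells, "n_cells", min = 0)
  check_number(n_tracer_positive, "n_tracer_positive", min = 0)
  if (n_tracer_positive > n_cells) {
    stop_cf("n_tracer_positive (%d) exceeds n_cells (%d)",
            n_tracer_positive, n_cells)
  }
  check_number(cell_radius_range, "cell_radius_range", min = 1, len = 2L)
  check_number(min_separation, "min_separation", min = 0)
  if (n_cells > 1 && min_separation <= 2 * max(cell_radius_range)) {
    stop_cf("min_separation must exceed 2 * max cell radius (%g)",
            2 * max(cell_radius_range))
  }
  for (nm in c("neun_intensity_range", "tracer_intensity_range_positive",
               "tracer_intensity_range_negative")) {
    check_number(get(nm), nm, min = 0, max = 255, len = 2L)
  }
  check_number(background_noise_sd, "background_noise_sd", min = 0)
  check_number(ribbon_halfwidth, "ribbon_halfwidth", min = 2)
  check_number(injection_arc_fraction, "injection_arc_fraction",
               min = 0, max = 1)
  check_number(injection_extent_um, "injection_extent_um", min = 1e-6)
  if (!tracer_role %in% c("tracer_red", "tracer_yellow")) {
    stop_cf("tracer_role must be 'tracer_red' or 'tracer_yellow'")
  }
  if (is.null(ribbon_control_points)) {
    # shallow arc spanning the raster, bulging upward in the middle
    xs <- seq(40, image_width - 40, length.out = 6)
    mid <- image_height / 2
    amp <- image_height / 5
    ys <- mid - amp * sin(seq(0, pi, length.out = 6))
    ribbon_control_points <- cbind(xs, ys)
  }
  stopifnot(is.matrix(ribbon_control_points),
            ncol(ribbon_control_points) == 2,
            nrow(ribbon_control_points) >= 2)
  if (!is.null(roi_arc_breakpoints)) {
    if (is.null(names(roi_arc_breakpoints)) ||
        any(!nzchar(names(roi_arc_breakpoints)))) {
      stop_cf("roi_arc_breakpoints must be a fully named numeric vector")
    }
    if (is.unsorted(roi_arc_breakpoints)) {
      stop_cf("roi_arc_breakpoints must be nondecreasing")
    }
  }
  structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    pixel_size = pixel_size,
    n_cells = as.integer(n_cells),
    n_tracer_positive = as.integer(n_tracer_positive),
    cell_radius_range = cell_radius_range,
    min_separation = min_separation,
    neun_intensity_range = neun_intensity_range,
    tracer_intensity_range_positive = tracer_intensity_range_positive,
    tracer_intensity_range_negative = tracer_intensity_range_negative,
    background_noise_sd = background_noise_sd,
    ribbon_control_points = ribbon_control_points,
    ribbon_halfwidth = ribbon_halfwidth,
    roi_arc_breakpoints = roi_arc_breakpoints,
    injection_arc_fraction = injection_arc_fraction,
    injection_extent_um = injection_extent_um,
    tracer_role = tracer_role,
    line_noise_sd = line_noise_sd,
    seed = as.integer(seed)
  ), class = "synth_params")
}

# Default six-ROI split of a ribbon of `total_um` arc length, named
# medial-to-lateral with plausible rat cortical areas.
default_roi_breakpoints <- function(total_um) {
  nms <- c("Cg", "RSD", "PtA", "S1", "V2L", "TeA")
  setNames(seq(0, total_um, length.out = 7)[1:6], nms)
}

roi_intervals <- function(params, total_um) {
  bp <- params$roi_arc_breakpoints %||% default_roi_breakpoints(total_um)
  tibble::tibble(
    roi = names(bp),
    arc_start = unname(bp),
    arc_end = c(unname(bp)[-1], total_um)
  )
}

# Band polygon between two arc positions: outer edge offset +halfwidth
# along the leftward normal, inner edge -halfwidth, joined into a ring.
ribbon_band_polygon <- function(curve, arc_from_px, arc_to_px, halfwidth) {
  a <- seq(arc_from_px, arc_to_px, length.out =
             max(8L, ceiling((arc_to_px - arc_from_px) / 4)))
  pa <- polyline_point_at(curve, a)
  outer <- pa$point + halfwidth * pa$normal
  inner <- pa$point - halfwidth * pa$normal
  rbind(outer, inner[rev(seq_len(nrow(inner))), , drop = FALSE])
}

paint_gaussian <- function(acc, cx, cy, r, peak) {
  sigma <- r / 3
  x0 <- max(0L, floor(cx - r)); x1 <- min(ncol(acc) - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(nrow(acc) - 1L, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  g <- peak * exp(-d2 / (2 * sigma^2))
  g[d2 > r^2] <- 0
  acc[ys + 1L, xs + 1L] <- acc[ys + 1L, xs + 1L] + g
  acc
}

footprint_sum <- function(img_channel, cx, cy, r) {
  x0 <- max(0L, floor(cx - r)); x1 <- min(ncol(img_channel) - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(nrow(img_channel) - 1L, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  block <- img_channel[ys + 1L, xs + 1L, drop = FALSE]
  sum(block[d2 <= r^2])
}

#' Generate one synthetic section with ground truth
#'
#' Plants `n_cells` Gaussian-profile somata (sigma = radius/3, clipped at
#' 3 sigma, additive with saturation at 255) inside the cortical ribbon by
#' rejection sampling at the configured minimum separation; the first
#' `n_tracer_positive` of a random permutation also receive tracer-channel
#' signal drawn from the positive amplitude range, the rest from the
#' negative range. Gaussian background noise is added last, and the final
#' raster is 8-bit (0-255) per channel.
#'
#' The ground-truth table stores, per cell, the true center, positivity,
#' per-channel integrated intensity summed over the painted footprint of
#' the noise-free raster, the ROI containing it, and the arc position (um)
#' of its nearest point on the noiseless reference curve relative to the
#' cingulum anchor.
#'
#' @param params A [synth_params()] object.
#' @param section_id Identifier stored with the section.
#' @param section_order_index Position of the section in its series.
#' @param ap_position Anterior-posterior coordinate label (mm analog).
#' @param render_image If `FALSE`, skip rasterisation: geometry and
#'   position truth are produced but the image is `NULL` and intensity
#'   truth is `NA` (used for unmapped series sections).
#' @return A list of class `"section_bundle"`: `image` (height x width x 3
#'   integer array, channels neun / tracer_red / tracer_yellow),
#'   `channel_roles`, `pixel_size`, `reference_line`, `rois`, `truth`
#'   (tibble), `section_id`, `section_order_index`, `ap_position`.
#' @export
generate_section <- function(params, section_id = "sec01",
                             section_order_index = 1L,
                             ap_position = 0,
                             render_image = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  with_seed(params$seed, {
    W <- params$image_width; H <- params$image_height
    curve <- spline_through(params$ribbon_control_points, spacing = 1)
    total_px <- cumulative_arc(curve)
    total_px <- total_px[length(total_px)]
    total_um <- total_px * params$pixel_size
    ivals <- roi_intervals(params, total_um)

    # landmarks: cingulum anchor at the medial (first) vertex, rhinal
    # sulcus at the vertex nearest 95% of arc length
    rhinal_idx <- which.min(abs(cumulative_arc(curve) - 0.95 * total_px))
    line_vertices <- curve
    if (params$line_noise_sd > 0) {
      line_vertices <- curve +
        matrix(rnorm(length(curve), 0, params$line_noise_sd), ncol = 2)
    }
    ref_line <- reference_line(line_vertices,
                               cingulum_anchor = 1L,
                               rhinal_sulcus = rhinal_idx,
                               pixel_size = params$pixel_size)

    rois <- lapply(seq_len(nrow(ivals)), function(i) {
      poly <- ribbon_band_polygon(curve,
                                  ivals$arc_start[i] / params$pixel_size,
                                  ivals$arc_end[i] / params$pixel_size,
                                  params$ribbon_halfwidth)
      roi_polygon(ivals$roi[i], section_id, poly, compartment = "cortical",
                  check_simple = FALSE)
    })

    # --- cell placement by rejection sampling -------------------------
    n <- params$n_cells
    rmax <- max(params$cell_radius_range)
    vmax <- params$ribbon_halfwidth - rmax - 1
    if (n > 0 && vmax <= 0) {
      stop_cf("ribbon_halfwidth too small for the configured cell radii")
    }
    cx <- numeric(n); cy <- numeric(n); rr <- numeric(n); arc_px <- numeric(n)
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        u <- runif(1, 0, total_px)
        v <- runif(1, -vmax, vmax)
        r <- runif(1, params$cell_radius_range[1], params$cell_radius_range[2])
        pa <- polyline_point_at(curve, u)
        x <- pa$point[1, 1] + v * pa$normal[1, 1]
        y <- pa$point[1, 2] + v * pa$normal[1, 2]
        if (x < rmax + 1 || x > W - rmax - 2 ||
            y < rmax + 1 || y > H - rmax - 2) next
        if (placed > 0L) {
          d2 <- (cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2
          if (min(d2) < params$min_separation^2) next
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop_cf(paste0("placement failure: could not place cell %d of %d at ",
                       "min_separation %g within 1000 retries"),
                placed + 1L, n, params$min_separation)
      }
      placed <- placed + 1L
      cx[placed] <- x; cy[placed] <- y; rr[placed] <- r
    }

    positive <- rep(FALSE, n)
    if (params$n_tracer_positive > 0 && n > 0) {
      positive[sample.int(n, params$n_tracer_positive)] <- TRUE
    }
    neun_peak <- runif(n, params$neun_intensity_range[1],
                       params$neun_intensity_range[2])
    tr_peak <- numeric(n)
    tr_peak[positive] <- runif(sum(positive),
                               params$tracer_intensity_range_positive[1],
                               params$tracer_intensity_range_positive[2])
    tr_peak[!positive] <- runif(sum(!positive),
                                params$tracer_intensity_range_negative[1],
                                params$tracer_intensity_range_negative[2])

    # truth arc position on the noiseless curve
    if (n > 0) {
      proj <- project_onto_polyline(cbind(cx, cy), curve)
      arc_um <- proj$arc * params$pixel_size
      roi_idx <- findInterval(arc_um, c(ivals$arc_start, total_um),
                              rightmost.closed = TRUE)
      roi_idx <- pmin(pmax(roi_idx, 1L), nrow(ivals))
      true_roi <- ivals$roi[roi_idx]
    } else {
      arc_um <- numeric(0); true_roi <- character(0)
    }

    image <- NULL
    int_neun <- rep(NA_real_, n); int_tracer <- rep(NA_real_, n)
    if (render_image) {
      tracer_ch <- CHANNEL_ROLES[[params$tracer_role]]
      chans <- list(matrix(0, H, W), matrix(0, H, W), matrix(0, H, W))
      for (i in seq_len(n)) {
        chans[[CHANNEL_ROLES[["neun"]]]] <-
          paint_gaussian(chans[[CHANNEL_ROLES[["neun"]]]],
                         cx[i], cy[i], rr[i], neun_peak[i])
        if (tr_peak[i] > 0) {
          chans[[tracer_ch]] <-
            paint_gaussian(chans[[tracer_ch]], cx[i], cy[i], rr[i], tr_peak[i])
        }
      }
      noiseless <- lapply(chans, function(m) round(pmin(m, 255)))
      for (i in seq_len(n)) {
        int_neun[i] <- footprint_sum(noiseless[[CHANNEL_ROLES[["neun"]]]],
                                     cx[i], cy[i], rr[i])
        int_tracer[i] <- footprint_sum(noiseless[[tracer_ch]],
                                       cx[i], cy[i], rr[i])
      }
      img <- array(unlist(chans, use.names = FALSE), dim = c(H, W, 3))
      if (params$background_noise_sd > 0) {
        img <- img + array(rnorm(length(img), 0, params$background_noise_sd),
                           dim = dim(img))
      }
      image <- array(as.integer(round(pmin(pmax(img, 0), 255))),
                     dim = c(H, W, 3))
    }

    truth <- tibble::tibble(
      cell_id = seq_len(n),
      true_x = cx, true_y = cy, radius = rr,
      true_positive = positive,
      true_integrated_neun = int_neun,
      true_integrated_tracer = int_tracer,
      tracer_peak = tr_peak,
      true_roi = true_roi,
      true_arc_um = arc_um
    )

    structure(list(
      image = image,
      channel_roles = CHANNEL_ROLES,
      pixel_size = params$pixel_size,
      reference_line = ref_line,
      curve = curve,
      rois = rois,
      truth = truth,
      roi_intervals = ivals,
      total_arc_um = total_um,
      section_id = section_id,
      section_order_index = as.integer(section_order_index),
      ap_position = ap_position,
      tracer_role = params$tracer_role
    ), class = "section_bundle")
  })
}

#' Generate a synthetic brain as a sampled series of sections
#'
#' Emulates the sectioning and sampling scheme of the source preparation:
#' cut sections are collected in three parallel series, the NeuN series is
#' every third cut section, and a flat map is made for every other NeuN
#' section, so the mapped fraction is exactly 1/6 of cut sections when
#' `n_cut_sections` is divisible by 6. Sections carry a strictly
#' increasing anterior-posterior position on a 0.05 mm grid (50 um cut
#' thickness analog).
#'
#' @param params A [synth_params()] object; per-section seeds are derived
#'   deterministically from `params$seed`.
#' @param n_cut_sections Total number of cut sections; must be >= 6, and
#'   divisible by 6 for the mapped fraction to be exactly 1/6.
#' @param render `"mapped"` rasterises only the mapped sections (unmapped
#'   NeuN-series sections keep geometry and position truth with a `NULL`
#'   image); `"all"` rasterises every NeuN-series section.
#' @return A list of class `"synthetic_brain"`: `sections` (NeuN-series
#'   [generate_section()] bundles), `mapped` (logical sampling mask over
#'   the NeuN series), `n_cut_sections`, `injection` (an
#'   [injection_site()]), `params`.
#' @export
generate_brain <- function(params, n_cut_sections,
                           render = c("mapped", "all")) {
  stopifnot(inherits(params, "synth_params"))
  render <- match.arg(render)
  check_number(n_cut_sections, "n_cut_sections", min = 1)
  if (n_cut_sections < 6) {
    stop_cf("n_cut_sections must be at least 6 (got %d)", n_cut_sections)
  }
  if (n_cut_sections %% 6 != 0) {
    warning("n_cut_sections not divisible by 6; mapped fraction will not be exactly 1/6")
  }
  cut_idx <- seq(1L, as.integer(n_cut_sections), by = 3L)  # NeuN series
  mapped <- rep(c(TRUE, FALSE), length.out = length(cut_idx))
  sections <- vector("list", length(cut_idx))
  for (k in seq_along(cut_idx)) {
    p_k <- params
    p_k$seed <- as.integer((params$seed * 1009 + cut_idx[k] * 7919) %% 2147483647L)
    sections[[k]] <- generate_section(
      p_k,
      section_id = sprintf("sec%02d", cut_idx[k]),
      section_order_index = k,
      ap_position = (cut_idx[k] - 1L) * 0.05,
      render_image = render == "all" || mapped[k]
    )
  }
  # injection metadata: center on the ribbon of the mapped section nearest
  # the middle of the brain, at the configured arc fraction
  mid <- which(mapped)[ceiling(sum(mapped) / 2)]
  sec <- sections[[mid]]
  inj_arc_um <- params$injection_arc_fraction * sec$total_arc_um
  pa <- polyline_point_at(sec$curve, inj_arc_um / params$pixel_size)
  half <- params$injection_extent_um / 2
  iv <- sec$roi_intervals
  covered <- iv$roi[iv$arc_end > inj_arc_um - half &
                      iv$arc_start < inj_arc_um + half]
  if (length(covered) > 2) {
    # keep the two with the largest overlap
    ov <- pmin(iv$arc_end[match(covered, iv$roi)], inj_arc_um + half) -
      pmax(iv$arc_start[match(covered, iv$roi)], inj_arc_um - half)
    covered <- covered[order(-ov)][1:2]
  }
  injection <- injection_site(
    center = c(pa$point[1, 1], pa$point[1, 2]),
    section_id = sec$section_id,
    extent_um = params$injection_extent_um,
    covered_rois = covered,
    arc_um = inj_arc_um,
    ap_mm = sec$ap_position
  )
  structure(list(
    sections = sections,
    mapped = mapped,
    n_cut_sections = as.integer(n_cut_sections),
    injection = injection,
    params = params
  ), class = "synthetic_brain")
}

#' Generate a paired manual/automated count fixture
#'
#' Emulates the systematic undercounting of automated tracer-positive cell
#' counts relative to manual counts: `manual = true_counts` and
#' `automated = max(0, true - offset + noise)`, so a regression of manual
#' on automated counts has a planted x-intercept of `-offset` that the
#' calibration module should recover.
#'
#' @param true_counts Nonnegative per-ROI true counts (optionally named).
#' @param offset Nonnegative undercount planted in the automated counts.
#' @param noise_sd Gaussian noise sd added to the automated counts.
#' @param seed Integer seed.
#' @return Tibble with columns `roi`, `manual`, `automated`.
#' @export
generate_count_fixture <- function(true_counts, offset, noise_sd = 0,
                                   seed = 1L) {
  if (any(true_counts < 0)) stop_cf("true_counts must be nonnegative")
  check_number(offset, "offset", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    noise <- rnorm(length(true_counts), 0, noise_sd)
    tibble::tibble(
      roi = names(true_counts) %||% sprintf("roi%02d", seq_along(true_counts)),
      manual = as.numeric(true_counts),
      automated = pmax(0, as.numeric(true_counts) - offset + noise)
    )
  })
}
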