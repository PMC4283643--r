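# Flat-map construction: smooth the layer IV/V reference polyline, express
# every tracer-positive cell as a signed arc-length position relative to
# the cingulum-border anchor, and stack sections into an unrolled 2D map.

#' Layer IV/V reference polyline with landmark anchors
#'
#' @param vertices n x 2 matrix of ordered pixel coordinates tracing the
#'   layer IV/V boundary, medial end first.
#' @param cingulum_anchor Vertex index of the lateral cingulate border;
#'   the arc-length origin of the flat map.
#' @param rhinal_sulcus Optional vertex index of the rhinal sulcus, the
#'   lateral reference landmark.
#' @param extra_marks Named integer vector of additional landmark vertex
#'   indices (e.g. V1 borders).
#' @param pixel_size Micrometers per pixel.
#' @return A list of class `"reference_line"`.
#' @export
reference_line <- function(vertices, cingulum_anchor = 1L,
                           rhinal_sulcus = NULL, extra_marks = integer(),
                           pixel_size = 0.23) {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  if (nrow(vertices) < 2) stop_cf("reference line needs at least 2 vertices")
  dup <- which(rowSums(abs(diff(vertices))) == 0)
  if (length(dup) > 0) {
    stop_cf("reference line has identical consecutive vertices (first at %d)",
            dup[1])
  }
  n <- nrow(vertices)
  chk_idx <- function(i, name) {
    if (!is.null(i) && (i < 1 || i > n)) {
      stop_cf("%s index %d outside 1..%d", name, i, n)
    }
  }
  chk_idx(cingulum_anchor, "cingulum_anchor")
  chk_idx(rhinal_sulcus, "rhinal_sulcus")
  for (nm in names(extra_marks)) chk_idx(extra_marks[[nm]], nm)
  structure(list(
    vertices = unname(vertices),
    cingulum_anchor = as.integer(cingulum_anchor),
    rhinal_sulcus = if (is.null(rhinal_sulcus)) NULL else as.integer(rhinal_sulcus),
    extra_marks = extra_marks,
    pixel_size = pixel_size
  ), class = "reference_line")
}

# Map landmark indices of `line` onto the polyline `new_v` by nearest
# vertex (in position, not index).
remap_landmarks <- function(line, new_v) {
  nearest <- function(idx) {
    p <- line$vertices[idx, ]
    which.min((new_v[, 1] - p[1])^2 + (new_v[, 2] - p[2])^2)
  }
  reference_line(
    new_v,
    cingulum_anchor = nearest(line$cingulum_anchor),
    rhinal_sulcus = if (is.null(line$rhinal_sulcus)) NULL else nearest(line$rhinal_sulcus),
    extra_marks = if (length(line$extra_marks))
      setNames(vapply(line$extra_marks, nearest, integer(1)),
               names(line$extra_marks)) else integer(),
    pixel_size = line$pixel_size
  )
}

#' Smooth a reference line by moving-window line regression
#'
#' Reimplements the "runline" smoother: the polyline is first resampled to
#' uniform arc spacing of `step` pixels, then each vertex is replaced by
#' the center-point evaluation of a least-squares line fit (x and y
#' against vertex index) over the `window` vertices centered on it, with
#' shrunken one-sided windows at the endpoints. Landmarks are re-attached
#' to the nearest smoothed vertex. Defaults match the published smoothing
#' scale: a 5-pixel (1.15 um) window advanced in 1-pixel (0.23 um) steps.
#'
#' @param line A [reference_line()].
#' @param window Odd window size in vertices (= pixels after resampling).
#' @param step Resampling spacing in pixels.
#' @return A smoothed [reference_line()].
#' @export
smooth_reference_line <- function(line, window = 5, step = 1) {
  stopifnot(inherits(line, "reference_line"))
  check_number(window, "window", min = 1)
  check_number(step, "step", min = 1e-9)
  if (window %% 2 != 1) stop_cf("window must be odd (got %g)", window)
  rs <- resample_polyline(line$vertices, spacing = step)
  line <- remap_landmarks(line, rs)
  n <- nrow(rs)
  if (window > n) {
    warning(sprintf("window %d larger than vertex count %d; clamped", window, n))
    window <- if (n %% 2 == 1) n else n - 1L
  }
  if (window == 1) return(line)
  h <- (window - 1) / 2
  sm <- matrix(0, n, 2)
  t <- seq_len(n)
  for (d in 1:2) {
    x <- rs[, d]
    cs_x <- cumsum(x); cs_xt <- cumsum(x * t)
    cs_t <- cumsum(t); cs_t2 <- cumsum(t^2)
    a <- pmax(1, t - h); b <- pmin(n, t + h)
    m <- b - a + 1
    lo <- pmax(a - 1, 1); has_lo <- a > 1
    Sx <- cs_x[b] - cs_x[lo] * has_lo
    Sxt <- cs_xt[b] - cs_xt[lo] * has_lo
    St <- cs_t[b] - cs_t[lo] * has_lo
    St2 <- cs_t2[b] - cs_t2[lo] * has_lo
    var_t <- St2 - St^2 / m
    slope <- ifelse(var_t > 1e-12, (Sxt - Sx * St / m) / var_t, 0)
    sm[, d] <- Sx / m + slope * (t - St / m)
  }
  # guard against numerically coincident consecutive vertices
  keep <- c(TRUE, rowSums(abs(diff(sm))) > 1e-12)
  sm <- sm[keep, , drop = FALSE]
  remap_landmarks(line, sm)
}

arc_of_vertex <- function(line, idx) {
  cumulative_arc(line$vertices)[idx]
}

#' Project points onto a reference line
#'
#' Each point is dropped perpendicularly onto the nearest polyline segment
#' (clamped to segment ends, so positions beyond the line ends clamp to
#' the ends rather than extrapolating). The arc position is the signed
#' arc length from the cingulum anchor to the foot point, in micrometers:
#' negative medial of the anchor, positive lateral. Ties between
#' equidistant segments break toward the smaller arc position.
#'
#' @param points n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @param line A (typically smoothed) [reference_line()].
#' @return Tibble with `arc_um` and `normal_um` per point.
#' @export
project_cells <- function(points, line) {
  stopifnot(inherits(line, "reference_line"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (is.data.frame(points)) points <- as.matrix(points)
  total <- cumulative_arc(line$vertices)
  if (total[length(total)] <= 0) stop_cf("degenerate zero-length reference line")
  pr <- project_onto_polyline(points, line$vertices)
  anchor_arc <- arc_of_vertex(line, line$cingulum_anchor)
  tibble::tibble(
    arc_um = (pr$arc - anchor_arc) * line$pixel_size,
    normal_um = pr$distance * line$pixel_size
  )
}

#' @rdname project_cells
#' @param point A single (x, y) pixel coordinate.
#' @export
project_cell <- function(point, line) {
  project_cells(matrix(point, ncol = 2), line)
}

#' Arc coordinate frame of a section
#'
#' Reports every landmark of the line as an arc position relative to the
#' cingulum anchor (which is 0 by construction). Arc positions are
#' invariant under rigid transforms of the section.
#'
#' @param line A [reference_line()] with its cingulum anchor set.
#' @return A list of class `"arc_frame"`: `cingulum_arc_um` (always 0),
#'   `rhinal_arc_um` (or `NA`), `extra_marks_um`, `length_um`.
#' @export
align_to_landmarks <- function(line) {
  stopifnot(inherits(line, "reference_line"))
  if (is.null(line$cingulum_anchor)) stop_cf("cingulum anchor missing")
  s <- cumulative_arc(line$vertices)
  anchor <- s[line$cingulum_anchor]
  arc_um <- function(idx) (s[idx] - anchor) * line$pixel_size
  structure(list(
    cingulum_arc_um = 0,
    rhinal_arc_um = if (is.null(line$rhinal_sulcus)) NA_real_
                    else arc_um(line$rhinal_sulcus),
    extra_marks_um = if (length(line$extra_marks))
      setNames(vapply(line$extra_marks, arc_um, numeric(1)),
               names(line$extra_marks)) else setNames(numeric(0), character(0)),
    length_um = (s[length(s)] - anchor) * line$pixel_size,
    medial_extent_um = -anchor * line$pixel_size
  ), class = "arc_frame")
}

#' Assemble a whole-brain flat map
#'
#' Stacks mapped sections into an unrolled 2D map: one row per section,
#' ordered rostral to caudal by anterior-posterior position, with every
#' tracer-positive cell placed at its arc position on that section's
#' smoothed reference line. Cells lying in the injection ROI(s) stay on
#' the map (rendered distinctly) but are flagged out of the
#' quantification layer.
#'
#' @param entries List of per-section entries, each a list with `section`
#'   (a `section_bundle` or any list providing `section_id`,
#'   `ap_position` and `reference_line`) and `cells` (tibble of
#'   tracer-positive cells with columns `x`, `y`, `cell_id`, optionally
#'   `roi` and `tracer_role`).
#' @param injection Optional [injection_site()]; its covered ROIs define
#'   the excluded cells, and its center is marked on the map.
#' @param window,step Smoothing parameters passed to
#'   [smooth_reference_line()].
#' @return A list of class `"flat_map"`: `cells` (tibble: `section_id`,
#'   `ap_position`, `arc_um`, `normal_um`, `tracer_role`, `cell_id`,
#'   `roi`, `in_injection`), `rows` (per-section landmark arcs), and
#'   `injection_mark`.
#' @export
assemble_flatmap <- function(entries, injection = NULL, window = 5, step = 1) {
  if (length(entries) < 1) stop_cf("need at least one mapped section")
  ids <- vapply(entries, function(e) e$section$section_id, character(1))
  if (anyDuplicated(ids)) {
    stop_cf("duplicate section ids: %s", paste(ids[duplicated(ids)], collapse = ", "))
  }
  ap <- vapply(entries, function(e) e$section$ap_position, numeric(1))
  entries <- entries[order(ap)]
  rows <- list(); cells <- list()
  inj_rois <- if (is.null(injection)) character(0) else injection$covered_rois
  inj_mark <- NULL
  for (e in entries) {
    sec <- e$section
    sl <- smooth_reference_line(sec$reference_line, window = window, step = step)
    frame <- align_to_landmarks(sl)
    rows[[sec$section_id]] <- tibble::tibble(
      section_id = sec$section_id,
      ap_position = sec$ap_position,
      rhinal_arc_um = frame$rhinal_arc_um,
      length_um = frame$length_um
    )
    cl <- e$cells
    if (!is.null(cl) && nrow(cl) > 0) {
      pr <- project_cells(cbind(cl$x, cl$y), sl)
      roi <- if ("roi" %in% names(cl)) cl$roi else NA_character_
      cells[[sec$section_id]] <- tibble::tibble(
        section_id = sec$section_id,
        ap_position = sec$ap_position,
        arc_um = pr$arc_um,
        normal_um = pr$normal_um,
        tracer_role = if ("tracer_role" %in% names(cl)) cl$tracer_role
                      else NA_character_,
        cell_id = cl$cell_id,
        roi = roi,
        in_injection = !is.na(roi) & roi %in% inj_rois
      )
    }
    if (!is.null(injection) && identical(sec$section_id, injection$section_id)) {
      prm <- project_cells(matrix(injection$center, ncol = 2), sl)
      inj_mark <- tibble::tibble(
        section_id = sec$section_id,
        ap_position = sec$ap_position,
        arc_um = prm$arc_um
      )
    }
  }
  structure(list(
    cells = if (length(cells)) dplyr::bind_rows(cells) else
      tibble::tibble(section_id = character(0), ap_position = numeric(0),
                     arc_um = numeric(0), normal_um = numeric(0),
                     tracer_role = character(0), cell_id = integer(0),
                     roi = character(0), in_injection = logical(0)),
    rows = dplyr::bind_rows(rows),
    injection_mark = inj_mark
  ), class = "flat_map")
}

#' @export
print.flat_map <- function(x, ...) {
  cat(sprintf("<flat_map> %d sections, %d cells (%d in injection ROI)\n",
              nrow(x$rows), nrow(x$cells), sum(x$cells$in_injection)))
  invisible(x)
}

#' Render a flat map
#'
#' One row per section (anterior-posterior position on the vertical axis),
#' tracer-positive cells at their arc positions, the cingulum anchor as
#' the zero line, rhinal-sulcus landmarks, and the injection center mark.
#'
#' @param x A `flat_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.flat_map <- function(x, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = 0, color = "blue", linewidth = 0.3) +
    ggplot2::geom_point(
      data = x$rows,
      ggplot2::aes(x = .data$rhinal_arc_um, y = .data$ap_position),
      color = "red", size = 2
    ) +
    ggplot2::geom_point(
      data = x$cells,
      ggplot2::aes(x = .data$arc_um, y = .data$ap_position,
                   shape = .data$in_injection),
      color = "darkgreen", size = 0.8, alpha = 0.7
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "arc position from cingulum border (um)",
                  y = "anterior-posterior position (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(x$injection_mark)) {
    p <- p + ggplot2::geom_point(
      data = x$injection_mark,
      ggplot2::aes(x = .data$arc_um, y = .data$ap_position),
      color = "orange", size = 4, alpha = 0.6
    )
  }
  p
}
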