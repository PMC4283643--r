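# ROI counting and normalisation: assign tracer-positive cells to hand-
# drawn ROI polygons, zero the injected ROI(s), normalise to proportions,
# aggregate into cortical networks / thalamic groups, and quantify
# injection placement and anterograde intensity proportions.

#' A named ROI polygon on one section
#'
#' @param name ROI name.
#' @param section_id Section the polygon belongs to.
#' @param vertices n x 2 matrix of pixel coordinates (open ring, >= 3
#'   vertices, simple polygon).
#' @param compartment `"cortical"` or `"thalamic"`.
#' @param check_simple Verify the polygon is non-self-intersecting
#'   (O(n^2); disable for dense generated band polygons known simple).
#' @return A list of class `"roi_polygon"`.
#' @export
roi_polygon <- function(name, section_id, vertices,
                        compartment = c("cortical", "thalamic"),
                        check_simple = TRUE) {
  compartment <- match.arg(compartment)
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  if (nrow(vertices) < 3) stop_cf("ROI '%s' needs >= 3 vertices", name)
  if (check_simple && !polygon_is_simple(vertices)) {
    stop_cf("ROI '%s' polygon is self-intersecting", name)
  }
  structure(list(name = name, section_id = section_id,
                 vertices = unname(vertices), compartment = compartment),
            class = "roi_polygon")
}

#' Injection-site metadata
#'
#' @param center (x, y) pixel coordinates of the injection center.
#' @param section_id Section holding the center.
#' @param extent_um Injection diameter in micrometers.
#' @param covered_rois The 1-2 ROI names containing the deposit; these are
#'   zeroed in all quantification.
#' @param arc_um Optional arc position of the center (um from the cingulum
#'   anchor).
#' @param ap_mm Optional anterior-posterior estimate (mm-from-bregma
#'   analog).
#' @param ml_distance_um,ml_class,rc_class Optional placement metrics,
#'   normally filled in by [injection_metrics()].
#' @return A list of class `"injection_site"`.
#' @export
injection_site <- function(center, section_id, extent_um, covered_rois,
                           arc_um = NA_real_, ap_mm = NA_real_,
                           ml_distance_um = NA_real_,
                           ml_class = NA_character_,
                           rc_class = NA_character_) {
  check_number(center, "center", len = 2L)
  check_number(extent_um, "extent_um", min = 1e-12)
  if (length(covered_rois) < 1 || length(covered_rois) > 2) {
    stop_cf("covered_rois must name 1 or 2 ROIs (got %d)", length(covered_rois))
  }
  structure(list(center = center, section_id = section_id,
                 extent_um = extent_um, covered_rois = covered_rois,
                 arc_um = arc_um, ap_mm = ap_mm,
                 ml_distance_um = ml_distance_um,
                 ml_class = ml_class, rc_class = rc_class),
            class = "injection_site")
}

#' Assign cells to ROIs and count
#'
#' Each cell is counted in exactly one ROI: polygons are visited in
#' deterministic name-sorted order and the first containing polygon wins
#' (boundary points count as inside). Overlapping polygons trigger a
#' warning. Cells inside no ROI land in the unassigned bucket.
#'
#' @param cells Tibble with columns `x`, `y` (pixel coordinates).
#' @param rois List of [roi_polygon()]s from the same coordinate frame.
#' @return A list: `counts` (tibble `roi`, `count`, including zero-count
#'   ROIs), `cell_roi` (per-cell ROI name, `NA` if unassigned),
#'   `unassigned` (count).
#' @export
assign_cells_to_rois <- function(cells, rois) {
  nms <- vapply(rois, function(r) r$name, character(1))
  rois <- rois[order(nms)]
  nms <- sort(nms)
  n <- nrow(cells)
  assigned <- rep(NA_character_, n)
  multi <- rep(FALSE, n)
  if (n > 0) {
    pts <- cbind(cells$x, cells$y)
    for (i in seq_along(rois)) {
      inside <- points_in_polygon(pts, rois[[i]]$vertices)
      multi <- multi | (inside & !is.na(assigned))
      take <- inside & is.na(assigned)
      assigned[take] <- nms[i]
    }
  }
  if (any(multi)) {
    warning(sprintf("%d cell(s) fell inside overlapping ROI polygons; first name-sorted ROI kept",
                    sum(multi)))
  }
  counts <- tibble::tibble(
    roi = unique(nms),
    count = as.numeric(tabulate(match(assigned, unique(nms)),
                                nbins = length(unique(nms))))
  )
  list(counts = counts, cell_roi = assigned,
       unassigned = sum(is.na(assigned)))
}

#' Zero the injection-site ROI(s)
#'
#' The ROI (or two, when the deposit straddles a border) containing the
#' injection center is set to zero on every section for that animal; all
#' other ROIs are untouched. Idempotent.
#'
#' @param counts Tibble with columns `roi` and a count column.
#' @param injection An [injection_site()] (or character vector of ROI
#'   names).
#' @param col Name of the count column to zero.
#' @return `counts` with the injected ROI(s) zeroed in `col`.
#' @export
zero_injection_rois <- function(counts, injection, col = "count") {
  rois <- if (inherits(injection, "injection_site")) injection$covered_rois
          else as.character(injection)
  missing <- setdiff(rois, counts$roi)
  if (length(missing) > 0) {
    stop_cf("unknown injection ROI(s): %s", paste(missing, collapse = ", "))
  }
  counts[[col]][counts$roi %in% rois] <- 0
  counts
}

#' Normalise counts to proportions of the total
#'
#' @param counts Tibble with `roi` and a count column (already
#'   injection-zeroed).
#' @param included_rois ROIs entering the denominator; defaults to all.
#' @param col Count column name.
#' @return `counts` restricted to `included_rois` with a `proportion`
#'   column summing to 1.
#' @export
counts_to_proportions <- function(counts, included_rois = NULL,
                                  col = "count") {
  included_rois <- included_rois %||% counts$roi
  sub <- counts[counts$roi %in% included_rois, , drop = FALSE]
  total <- sum(sub[[col]])
  if (total <= 0) {
    stop_cf("total count over included ROIs is zero; proportions undefined")
  }
  sub$proportion <- sub[[col]] / total
  sub
}

#' Aggregate ROI proportions into networks / groups
#'
#' @param proportions Tibble with `roi` and `proportion`.
#' @param grouping Named character vector mapping every ROI to its group
#'   (cortical network or thalamic group).
#' @return Tibble `group`, `proportion` (sum of member proportions),
#'   ordered by first appearance in `grouping`.
#' @export
aggregate_groups <- function(proportions, grouping) {
  unmapped <- setdiff(proportions$roi, names(grouping))
  if (length(unmapped) > 0) {
    stop_cf("ROIs missing from the grouping map: %s",
            paste(unmapped, collapse = ", "))
  }
  g <- unname(grouping[proportions$roi])
  lev <- unique(unname(grouping))
  agg <- rowsum(proportions$proportion, factor(g, levels = lev))
  tibble::tibble(group = rownames(agg), proportion = unname(agg[, 1]))
}

#' Default cortical network map
#'
#' A 21-ROI assignment into the four cortical networks (medial, lateral,
#' somatic, claustrum/entorhinal). The published membership lists are not
#' exhaustive, so this table is a package default meant to be overridden
#' per study; `"V2M/PtA"` is the composite of remaining parietal
#' subregions outside the injection site.
#'
#' @return Named character vector, ROI -> network.
#' @export
default_cortical_networks <- function() {
  c(
    RSD = "medial", RSG = "medial", Cg = "medial", mPFC = "medial",
    oFC = "medial", `V2M/PtA` = "medial", V1 = "medial",
    M1 = "somatic", M2 = "somatic", S1 = "somatic", S1BF = "somatic",
    S2 = "somatic", FL = "somatic",
    V2L = "lateral", AuD = "lateral", Au1 = "lateral", TeA = "lateral",
    Cl = "claustrum/entorhinal", LEC = "claustrum/entorhinal",
    PrH = "claustrum/entorhinal", Ect = "claustrum/entorhinal"
  )
}

#' Default thalamic group map
#'
#' Seven-level grouping of thalamic nuclei: motor, sensory, the
#' associative group split into anterior / lateral / mediodorsal, the
#' intralaminar and the midline nuclei.
#'
#' @return Named character vector, nucleus -> group.
#' @export
default_thalamic_groups <- function() {
  c(
    VA = "motor", VL = "motor",
    VPM = "sensory", VPL = "sensory", Po = "sensory",
    AV = "anterior-associative", AM = "anterior-associative",
    AD = "anterior-associative",
    LD = "lateral-associative", LPMR = "lateral-associative",
    LPLR = "lateral-associative",
    MD = "mediodorsal-associative",
    CL = "intralaminar", CM = "intralaminar",
    Re = "midline", Rh = "midline"
  )
}

#' Complete injection placement metrics
#'
#' Measures the medial-lateral distance of the injection center from the
#' medial cingulate border along the flat-map frame (the arc position of
#' the center projected on the border-anchored reference line) and
#' classifies the injection as medial/lateral and rostral/caudal against
#' configured boundaries. A center exactly on the medial-lateral boundary
#' classifies as medial (tie rule).
#'
#' @param injection An [injection_site()] with `center` and `ap_mm` set.
#' @param border_line [reference_line()] of the same section whose
#'   cingulum anchor sits on the medial cingulate border.
#' @param ml_boundary_um Arc distance splitting medial from lateral
#'   injections (um).
#' @param rc_boundary_mm Anterior-posterior position splitting rostral
#'   from caudal injections (mm analog; larger = more caudal).
#' @return The completed [injection_site()].
#' @export
injection_metrics <- function(injection, border_line,
                              ml_boundary_um, rc_boundary_mm = NA_real_) {
  stopifnot(inherits(injection, "injection_site"))
  if (is.null(border_line)) stop_cf("border polyline missing")
  stopifnot(inherits(border_line, "reference_line"))
  pr <- project_cells(matrix(injection$center, ncol = 2), border_line)
  injection$ml_distance_um <- pr$arc_um[1]
  injection$arc_um <- pr$arc_um[1]
  injection$ml_class <- if (injection$ml_distance_um <= ml_boundary_um)
    "medial" else "lateral"
  if (!is.na(rc_boundary_mm) && !is.na(injection$ap_mm)) {
    injection$rc_class <- if (injection$ap_mm <= rc_boundary_mm)
      "rostral" else "caudal"
  }
  injection
}

#' Anterograde terminal-labeling proportions
#'
#' For anterograde experiments the measure is each ROI's integrated
#' tracer intensity as a proportion of the total; the injected ROI(s) are
#' zeroed before the total is formed.
#'
#' @param intensities Tibble with `roi` and `intensity` (>= 0).
#' @param injection [injection_site()] or character vector of injected
#'   ROI names; `NULL` for no zeroing.
#' @return Tibble with `roi`, `intensity` (post-zeroing), `proportion`.
#' @export
anterograde_proportions <- function(intensities, injection = NULL) {
  if (!all(c("roi", "intensity") %in% names(intensities))) {
    stop_cf("intensities must have columns 'roi' and 'intensity'")
  }
  if (any(intensities$intensity < 0)) stop_cf("intensities must be >= 0")
  if (!is.null(injection)) {
    intensities <- zero_injection_rois(intensities, injection,
                                       col = "intensity")
  }
  total <- sum(intensities$intensity)
  if (total <= 0) {
    stop_cf("all intensities are zero after injection zeroing")
  }
  intensities$proportion <- intensities$intensity / total
  intensities
}

#' Keep only cells ipsilateral to the injection
#'
#' @param cells Tibble with a `hemisphere` column.
#' @param injection_hemisphere `"left"` or `"right"`.
#' @return `cells` restricted to the injection hemisphere.
#' @export
filter_ipsilateral <- function(cells, injection_hemisphere) {
  if (!"hemisphere" %in% names(cells)) return(cells)
  cells[cells$hemisphere == injection_hemisphere, , drop = FALSE]
}
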