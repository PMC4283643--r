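# Plain-text serialisation of sections and geometry. No TIFF library is
# assumed: each channel is written as an ASCII PGM (P2) raster next to a
# channels.json sidecar, geometry (polylines, ROI polygons, landmarks,
# injection metadata) as JSON, and tables as CSV.

write_pgm <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
  apply_rows <- apply(m, 1, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop_cf("%s: not an ASCII PGM (P2) file", path)
  vals <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
  w <- vals[1]; h <- vals[2]
  matrix(as.integer(vals[-(1:3)]), nrow = h, ncol = w, byrow = TRUE)
}

#' Write / read a section bundle
#'
#' Serialises a synthetic section to a directory: one ASCII PGM per
#' channel, `geometry.json` (reference line, landmarks, ROI polygons,
#' pixel size, section metadata) and `truth.csv`.
#'
#' @param bundle A `section_bundle` from [generate_section()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`write_section_bundle`); the rebuilt bundle
#'   (`read_section_bundle`).
#' @export
write_section_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "section_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roles <- bundle$channel_roles
  if (!is.null(bundle$image)) {
    for (role in names(roles)) {
      write_pgm(bundle$image[, , roles[[role]]],
                file.path(dir, paste0(role, ".pgm")))
    }
  }
  geom <- list(
    section_id = bundle$section_id,
    section_order_index = bundle$section_order_index,
    ap_position = bundle$ap_position,
    pixel_size = bundle$pixel_size,
    tracer_role = bundle$tracer_role,
    channels = as.list(roles),
    reference_line = list(
      vertices = bundle$reference_line$vertices,
      cingulum_anchor = bundle$reference_line$cingulum_anchor,
      rhinal_sulcus = bundle$reference_line$rhinal_sulcus,
      extra_marks = as.list(bundle$reference_line$extra_marks)
    ),
    rois = lapply(bundle$rois, function(r) {
      list(name = r$name, compartment = r$compartment, vertices = r$vertices)
    })
  )
  jsonlite::write_json(geom, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_section_bundle
#' @export
read_section_bundle <- function(dir) {
  geom <- jsonlite::read_json(file.path(dir, "geometry.json"),
                              simplifyVector = TRUE)
  roles <- unlist(geom$channels)
  image <- NULL
  pgms <- file.path(dir, paste0(names(roles), ".pgm"))
  if (all(file.exists(pgms))) {
    mats <- lapply(pgms, read_pgm)
    image <- array(0L, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
    for (i in seq_along(mats)) image[, , roles[[i]]] <- mats[[i]]
  }
  rl <- geom$reference_line
  ref <- reference_line(
    matrix(unlist(rl$vertices), ncol = 2),
    cingulum_anchor = rl$cingulum_anchor,
    rhinal_sulcus = rl$rhinal_sulcus,
    extra_marks = if (length(rl$extra_marks)) unlist(rl$extra_marks)
                  else integer(),
    pixel_size = geom$pixel_size
  )
  rois <- lapply(seq_len(length(geom$rois$name)), function(i) {
    roi_polygon(geom$rois$name[i], geom$section_id,
                matrix(unlist(geom$rois$vertices[i]), ncol = 2),
                compartment = geom$rois$compartment[i],
                check_simple = FALSE)
  })
  truth <- tibble::as_tibble(read.csv(file.path(dir, "truth.csv")))
  structure(list(
    image = image, channel_roles = roles, pixel_size = geom$pixel_size,
    reference_line = ref, rois = rois, truth = truth,
    section_id = geom$section_id,
    section_order_index = geom$section_order_index,
    ap_position = geom$ap_position, tracer_role = geom$tracer_role
  ), class = "section_bundle")
}

#' Write a flat map to CSV
#'
#' @param fm A `flat_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flatmap_csv <- function(fm, path) {
  stopifnot(inherits(fm, "flat_map"))
  write.csv(fm$cells, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model A [fit_calibration()] model.
#' @param path JSON path.
#' @return `path` invisibly; `read_calibration_json()` returns the model.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "calibration_model")
}
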