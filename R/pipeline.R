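# Pipeline orchestration: simulate -> segment -> classify -> calibrate ->
# flatmap -> quantify -> stats, driven by one JSON-serialisable config,
# with a manifest recording parameters, seeds and output checksums so
# runs are reproducible and resumable.

PIPELINE_STAGES <- c("simulate", "segment", "classify", "calibrate",
                     "flatmap", "quantify", "stats")

#' Build and validate a pipeline configuration
#'
#' @param out_dir Directory all stage artifacts are written to.
#' @param seed Master seed; all stochastic stages derive their seeds from
#'   it.
#' @param n_animals Number of synthetic animals.
#' @param n_cut_sections Cut sections per brain (divisible by 6).
#' @param synth Named list of [synth_params()] overrides.
#' @param segment Named list: `threshold`, `min_area`, `sigma`,
#'   `tile_size`, `overlap`.
#' @param classify Named list: `integrated_threshold`,
#'   `max_pixel_threshold`, `tracer_channel`. The demo default thresholds
#'   (1200 / 75) sit between the planted positive and negative integrated
#'   ranges of the default synthetic world; for full-scale somata use the
#'   published 250,000 / 150.
#' @param stats Named list: `alpha`.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_animals = 4L,
                            n_cut_sections = 12L, synth = list(),
                            segment = list(), classify = list(),
                            stats = list()) {
  fail <- function(path, msg) stop_cf("config error at %s: %s", path, msg)
  if (!is.character(out_dir) || length(out_dir) != 1) {
    fail("out_dir", "must be a single path")
  }
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be one integer")
  if (!is.numeric(n_animals) || n_animals < 1) {
    fail("n_animals", "must be >= 1")
  }
  if (!is.numeric(n_cut_sections) || n_cut_sections < 6) {
    fail("n_cut_sections", "must be >= 6")
  }
  for (nm in names(synth)) {
    if (!nm %in% names(formals(synth_params))) {
      fail(paste0("synth.", nm), "unknown synth_params field")
    }
  }
  seg_fields <- c("threshold", "min_area", "sigma", "tile_size", "overlap")
  for (nm in names(segment)) {
    if (!nm %in% seg_fields) fail(paste0("segment.", nm), "unknown field")
  }
  cls_fields <- c("integrated_threshold", "max_pixel_threshold",
                  "tracer_channel")
  for (nm in names(classify)) {
    if (!nm %in% cls_fields) fail(paste0("classify.", nm), "unknown field")
  }
  segment <- utils::modifyList(
    list(threshold = NULL, min_area = 12, sigma = 1, tile_size = NULL,
         overlap = 64), segment)
  classify <- utils::modifyList(
    list(integrated_threshold = 1200, max_pixel_threshold = 75,
         tracer_channel = "tracer_red"), classify)
  stats <- utils::modifyList(list(alpha = 0.05), stats)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    n_animals = as.integer(n_animals),
    n_cut_sections = as.integer(n_cut_sections),
    synth = synth, segment = segment, classify = classify, stats = stats
  ), class = "pipeline_config")
}

#' Read a pipeline config from JSON
#'
#' @param path JSON file with fields matching [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

config_fingerprint <- function(config, stage) {
  sub <- switch(stage,
    simulate = config[c("seed", "n_animals", "n_cut_sections", "synth")],
    segment = config["segment"],
    classify = config["classify"],
    calibrate = list(),
    flatmap = list(),
    quantify = list(),
    stats = config["stats"]
  )
  jsonlite::toJSON(sub, auto_unbox = TRUE, digits = NA, null = "null")
}

manifest_path <- function(config) file.path(config$out_dir, "manifest.json")

read_manifest <- function(config) {
  p <- manifest_path(config)
  if (!file.exists(p)) return(list())
  jsonlite::read_json(p, simplifyVector = FALSE)
}

update_manifest <- function(config, stage, outputs) {
  man <- read_manifest(config)
  man[[stage]] <- list(
    fingerprint = as.character(config_fingerprint(config, stage)),
    seed = config$seed,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)), outputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(man, manifest_path(config), auto_unbox = TRUE)
  invisible(man)
}

animal_ids <- function(config) sprintf("animal%02d", seq_len(config$n_animals))

stage_outputs <- function(config, stage) {
  od <- config$out_dir
  ids <- animal_ids(config)
  switch(stage,
    simulate = file.path(od, "sim", ids, "brain.json"),
    segment = file.path(od, "features", paste0(ids, "_features.csv")),
    classify = file.path(od, "classified", paste0(ids, "_classified.csv")),
    calibrate = file.path(od, "calibration", paste0(ids, "_calibration.json")),
    flatmap = file.path(od, "flatmap", paste0(ids, "_flatmap.csv")),
    quantify = file.path(od, "counts", "proportions.csv"),
    stats = file.path(od, "stats", "anova.csv")
  )
}

stage_deps <- function(stage) {
  i <- match(stage, PIPELINE_STAGES)
  if (is.na(i)) stop_cf("unknown stage '%s'", stage)
  if (i == 1) character(0) else PIPELINE_STAGES[i - 1]
}

check_upstream <- function(config, stage) {
  dep <- stage_deps(stage)
  if (length(dep) == 0) return(invisible(TRUE))
  missing <- !file.exists(stage_outputs(config, dep))
  if (any(missing)) {
    stop_cf("stage '%s' needs artifacts from stage '%s'; run that stage first",
            stage, dep)
  }
  invisible(TRUE)
}

animal_seed <- function(config, a) {
  as.integer((config$seed * 10007 + a * 104729) %% 2147483647L)
}

mapped_section_dirs <- function(config, id) {
  meta <- jsonlite::read_json(file.path(config$out_dir, "sim", id,
                                        "brain.json"),
                              simplifyVector = TRUE)
  file.path(config$out_dir, "sim", id, meta$mapped_sections)
}

run_simulate <- function(config) {
  for (a in seq_len(config$n_animals)) {
    id <- animal_ids(config)[a]
    adir <- file.path(config$out_dir, "sim", id)
    dir.create(adir, showWarnings = FALSE, recursive = TRUE)
    sp <- do.call(synth_params,
                  utils::modifyList(config$synth,
                                    list(seed = animal_seed(config, a))))
    brain <- generate_brain(sp, config$n_cut_sections)
    mapped_ids <- character(0)
    for (k in seq_along(brain$sections)) {
      if (!brain$mapped[k]) next
      sec <- brain$sections[[k]]
      write_section_bundle(sec, file.path(adir, sec$section_id))
      mapped_ids <- c(mapped_ids, sec$section_id)
    }
    jsonlite::write_json(list(
      animal_id = id, seed = sp$seed,
      n_cut_sections = config$n_cut_sections,
      mapped_sections = mapped_ids,
      tracer_role = sp$tracer_role,
      injection = unclass(brain$injection)
    ), file.path(adir, "brain.json"), auto_unbox = TRUE, digits = NA)
  }
}

run_segment <- function(config) {
  dir.create(file.path(config$out_dir, "features"), showWarnings = FALSE,
             recursive = TRUE)
  sg <- config$segment
  for (id in animal_ids(config)) {
    feats <- list()
    for (sdir in mapped_section_dirs(config, id)) {
      sec <- read_section_bundle(sdir)
      feats[[sec$section_id]] <- detect_cells(
        sec, section_id = sec$section_id, threshold = sg$threshold,
        min_area = sg$min_area, sigma = sg$sigma,
        tile_size = sg$tile_size, overlap = sg$overlap
      )
    }
    write.csv(dplyr::bind_rows(feats),
              stage_outputs(config, "segment")[match(id, animal_ids(config))],
              row.names = FALSE)
  }
}

run_classify <- function(config) {
  dir.create(file.path(config$out_dir, "classified"), showWarnings = FALSE,
             recursive = TRUE)
  cl <- config$classify
  cp <- classifier_params(cl$integrated_threshold, cl$max_pixel_threshold,
                          cl$tracer_channel)
  ids <- animal_ids(config)
  for (i in seq_along(ids)) {
    f <- tibble::as_tibble(read.csv(stage_outputs(config, "segment")[i]))
    f$tracer_positive <- classify_tracer_positive(f, cp)
    write.csv(f, stage_outputs(config, "classify")[i], row.names = FALSE)
  }
}

# Per-section, per-ROI (manual, automated) pairs: manual from the planted
# truth, automated from the classified detections.
calibration_pairs <- function(config, id, classified) {
  pairs <- list()
  for (sdir in mapped_section_dirs(config, id)) {
    sec <- read_section_bundle(sdir)
    truth_pos <- sec$truth[sec$truth$true_positive, , drop = FALSE]
    manual <- table(factor(truth_pos$true_roi,
                           levels = vapply(sec$rois, `[[`, "", "name")))
    det <- classified[classified$section_id == sec$section_id &
                        classified$tracer_positive, , drop = FALSE]
    auto <- assign_cells_to_rois(det, sec$rois)$counts
    pairs[[sec$section_id]] <- tibble::tibble(
      section_id = sec$section_id,
      roi = auto$roi,
      manual = as.numeric(manual[auto$roi]),
      automated = auto$count
    )
  }
  dplyr::bind_rows(pairs)
}

run_calibrate <- function(config) {
  dir.create(file.path(config$out_dir, "calibration"), showWarnings = FALSE,
             recursive = TRUE)
  ids <- animal_ids(config)
  for (i in seq_along(ids)) {
    cls <- tibble::as_tibble(read.csv(stage_outputs(config, "classify")[i]))
    pairs <- calibration_pairs(config, ids[i], cls)
    model <- fit_calibration(pairs)
    write_calibration_json(model, stage_outputs(config, "calibrate")[i])
  }
}

run_flatmap <- function(config) {
  dir.create(file.path(config$out_dir, "flatmap"), showWarnings = FALSE,
             recursive = TRUE)
  ids <- animal_ids(config)
  for (i in seq_along(ids)) {
    id <- ids[i]
    meta <- jsonlite::read_json(file.path(config$out_dir, "sim", id,
                                          "brain.json"),
                                simplifyVector = TRUE)
    inj <- meta$injection
    injection <- injection_site(unlist(inj$center), inj$section_id,
                                inj$extent_um, unlist(inj$covered_rois),
                                arc_um = inj$arc_um, ap_mm = inj$ap_mm)
    cls <- tibble::as_tibble(read.csv(stage_outputs(config, "classify")[i]))
    entries <- list()
    for (sdir in mapped_section_dirs(config, id)) {
      sec <- read_section_bundle(sdir)
      pos <- cls[cls$section_id == sec$section_id & cls$tracer_positive, ,
                 drop = FALSE]
      pos$roi <- assign_cells_to_rois(pos, sec$rois)$cell_roi
      pos$tracer_role <- meta$tracer_role
      entries[[sec$section_id]] <- list(section = sec, cells = pos)
    }
    fm <- assemble_flatmap(entries, injection = injection)
    write_flatmap_csv(fm, stage_outputs(config, "flatmap")[i])
  }
}

run_quantify <- function(config) {
  dir.create(file.path(config$out_dir, "counts"), showWarnings = FALSE,
             recursive = TRUE)
  ids <- animal_ids(config)
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    meta <- jsonlite::read_json(file.path(config$out_dir, "sim", id,
                                          "brain.json"),
                                simplifyVector = TRUE)
    cls <- tibble::as_tibble(read.csv(stage_outputs(config, "classify")[i]))
    model <- read_calibration_json(stage_outputs(config, "calibrate")[i])
    total <- NULL
    for (sdir in mapped_section_dirs(config, id)) {
      sec <- read_section_bundle(sdir)
      pos <- cls[cls$section_id == sec$section_id & cls$tracer_positive, ,
                 drop = FALSE]
      cnt <- assign_cells_to_rois(pos, sec$rois)$counts
      total <- if (is.null(total)) cnt else {
        total$count <- total$count + cnt$count[match(total$roi, cnt$roi)]
        total
      }
    }
    adj <- apply_calibration(total, model)
    adj$count <- adj$adjusted
    zeroed <- zero_injection_rois(adj, unlist(meta$injection$covered_rois))
    props <- counts_to_proportions(zeroed)
    props$animal_id <- id
    rows[[id]] <- props[, c("animal_id", "roi", "count", "proportion")]
  }
  write.csv(dplyr::bind_rows(rows), stage_outputs(config, "quantify"),
            row.names = FALSE)
}

run_stats <- function(config) {
  dir.create(file.path(config$out_dir, "stats"), showWarnings = FALSE,
             recursive = TRUE)
  props <- tibble::as_tibble(read.csv(stage_outputs(config, "quantify")))
  wide <- tidyr_pivot(props)
  des <- rm_design(wide, alpha = config$stats$alpha)
  res <- one_way_rm_anova(des)
  write.csv(as.data.frame(res$table), stage_outputs(config, "stats"),
            row.names = FALSE)
}

# minimal long -> wide pivot (animals x ROI) without a tidyr dependency
tidyr_pivot <- function(props) {
  ids <- unique(props$animal_id)
  rois <- sort(unique(props$roi))
  m <- matrix(0, length(ids), length(rois),
              dimnames = list(ids, rois))
  for (r in seq_len(nrow(props))) {
    m[props$animal_id[r], props$roi[r]] <- props$proportion[r]
  }
  m
}

#' Run one pipeline stage
#'
#' Verifies that upstream artifacts exist (naming the stage to run first
#' if not), executes the stage, and records parameters, seed and output
#' checksums in the manifest.
#'
#' @param name Stage name, one of `simulate`, `segment`, `classify`,
#'   `calibrate`, `flatmap`, `quantify`, `stats`.
#' @param config A [pipeline_config()].
#' @return Character vector of output paths, invisibly.
#' @export
run_stage <- function(name, config) {
  stopifnot(inherits(config, "pipeline_config"))
  name <- match.arg(name, PIPELINE_STAGES)
  check_upstream(config, name)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
    simulate = run_simulate(config),
    segment = run_segment(config),
    classify = run_classify(config),
    calibrate = run_calibrate(config),
    flatmap = run_flatmap(config),
    quantify = run_quantify(config),
    stats = run_stats(config)
  )
  outs <- stage_outputs(config, name)
  update_manifest(config, name, outs)
  invisible(outs)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order. A stage is skipped when its
#' outputs already exist and the manifest records the same configuration
#' fingerprint, so deleting one stage's outputs reruns only that stage
#' (and any later stage whose outputs are also missing or stale).
#'
#' @param config A [pipeline_config()].
#' @param force Rerun every stage regardless of the manifest.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  for (stage in PIPELINE_STAGES) {
    outs <- stage_outputs(config, stage)
    man <- read_manifest(config)
    fresh <- !force && all(file.exists(outs)) &&
      !is.null(man[[stage]]) &&
      identical(man[[stage]]$fingerprint,
                as.character(config_fingerprint(config, stage)))
    if (fresh) next
    message(sprintf("[cortexflat] running stage '%s'", stage))
    run_stage(stage, config)
  }
  invisible(read_manifest(config))
}
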