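unit_line <- function(n = 101, pixel_size = 1) {
  reference_line(cbind(seq(0, n - 1), rep(0, n)), cingulum_anchor = 1,
                 pixel_size = pixel_size)
}

test_that("runline smoothing leaves straight lines alone", {
  ln <- unit_line()
  sm <- smooth_reference_line(ln, window = 5)
  expect_lt(max(abs(sm$vertices - ln$vertices)), 1e-9)

  # collinear but diagonal
  diag_ln <- reference_line(cbind(0:80, (0:80) * 0.5), 1, pixel_size = 1)
  smd <- smooth_reference_line(diag_ln, window = 5)
  expect_lt(max(abs(smd$vertices[, 2] - smd$vertices[, 1] * 0.5)), 1e-9)

  # window 1 is the identity transform (on a 1-px-spaced line)
  sm1 <- smooth_reference_line(ln, window = 1)
  expect_equal(sm1$vertices, ln$vertices, tolerance = 1e-12)

  expect_error(smooth_reference_line(ln, window = 4), "odd")
  short <- reference_line(cbind(c(0, 1, 2), c(0, 0, 0)), 1, pixel_size = 1)
  expect_warning(smooth_reference_line(short, window = 9), "clamped")
})

test_that("smoothing pulls noisy boundaries toward the clean curve", {
  rsp <- getFromNamespace("resample_polyline", "cortexflat")
  pop <- getFromNamespace("project_onto_polyline", "cortexflat")
  t <- seq(0, 2 * pi, length.out = 200)
  clean <- cbind(t * 40, 40 * sin(t))
  dense_clean <- rsp(clean, 0.05)
  rms_to_clean <- function(v) sqrt(mean(pop(v, dense_clean)$distance^2))
  improved <- 0; shorter <- 0
  for (s in 1:20) {
    set.seed(s)
    noisy <- clean + matrix(rnorm(length(clean), 0, 1), ncol = 2)
    raw <- rsp(noisy, 1)
    sm <- smooth_reference_line(reference_line(noisy, 1, pixel_size = 1),
                                window = 5)
    if (rms_to_clean(sm$vertices) < rms_to_clean(raw)) improved <- improved + 1
    len <- function(v) sum(sqrt(rowSums(diff(v)^2)))
    if (len(sm$vertices) <= len(raw)) shorter <- shorter + 1
  }
  expect_equal(improved, 20)
  expect_equal(shorter, 20)   # total length non-increasing under smoothing
})

test_that("projection arithmetic is exact on a unit line", {
  ln <- reference_line(cbind(c(0, 100), c(0, 0)), 1, pixel_size = 1)
  pr <- project_cell(c(30, 7), ln)
  expect_equal(pr$arc_um, 30)
  expect_equal(pr$normal_um, 7)

  beyond <- project_cell(c(120, 5), ln)
  expect_equal(beyond$arc_um, 100)                 # clamped, no extrapolation
  expect_equal(beyond$normal_um, sqrt(20^2 + 5^2))

  medial <- project_cell(c(-10, 0), ln)
  expect_equal(medial$arc_um, 0)

  expect_error(project_cells(cbind(1, 1),
                             structure(list(vertices = cbind(c(0, 0), c(0, 0)),
                                            cingulum_anchor = 1L,
                                            pixel_size = 1),
                                       class = "reference_line")),
               "consecutive vertices|zero-length")
})

test_that("arc positions agree with a dense-resampling nearest-point oracle", {
  rsp <- getFromNamespace("resample_polyline", "cortexflat")
  set.seed(12)
  t <- seq(0, pi, length.out = 150)
  curve <- cbind(t * 120, 60 * sin(t) + 8 * sin(3 * t))
  ln <- reference_line(rsp(curve, 1), 1, pixel_size = 1)
  pts <- cbind(runif(200, -20, max(curve[, 1]) + 20), runif(200, -40, 100))
  pr <- project_cells(pts, ln)
  # oracle: nearest vertex of the same polyline resampled at 0.01 px
  dense <- rsp(ln$vertices, 0.01)
  s <- getFromNamespace("cumulative_arc", "cortexflat")(dense)
  for (i in seq_len(nrow(pts))) {
    d2 <- (dense[, 1] - pts[i, 1])^2 + (dense[, 2] - pts[i, 2])^2
    expect_lt(abs(pr$arc_um[i] - s[which.min(d2)]), 0.05)
  }
})

test_that("landmark frame is rigid-transform invariant", {
  rsp <- getFromNamespace("resample_polyline", "cortexflat")
  t <- seq(0, pi, length.out = 120)
  v <- rsp(cbind(t * 100, 30 * sin(t)), 1)
  ln <- reference_line(v, cingulum_anchor = 10, rhinal_sulcus = 90,
                       extra_marks = c(V1 = 60L), pixel_size = 0.5)
  f0 <- align_to_landmarks(ln)
  expect_equal(f0$cingulum_arc_um, 0)

  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- reference_line(v %*% R + matrix(c(31, -17), nrow(v), 2,
                                           byrow = TRUE),
                          cingulum_anchor = 10, rhinal_sulcus = 90,
                          extra_marks = c(V1 = 60L), pixel_size = 0.5)
  f1 <- align_to_landmarks(moved)
  expect_equal(f1$rhinal_arc_um, f0$rhinal_arc_um, tolerance = 1e-6)
  expect_equal(f1$extra_marks_um, f0$extra_marks_um, tolerance = 1e-6)

  # projections of rigidly moved points are unchanged too
  set.seed(4)
  pts <- cbind(runif(50, 0, 200), runif(50, -30, 60))
  a0 <- project_cells(pts, ln)$arc_um
  a1 <- project_cells(pts %*% R + matrix(c(31, -17), 50, 2, byrow = TRUE),
                      moved)$arc_um
  expect_equal(a1, a0, tolerance = 1e-6)

  # unit-spacing line: a landmark at vertex 4 sits at arc 3 * pixel_size
  lnu <- reference_line(cbind(0:10, rep(0, 11)), 1, rhinal_sulcus = 4,
                        pixel_size = 0.23)
  expect_equal(align_to_landmarks(lnu)$rhinal_arc_um, 3 * 0.23)

  bad <- ln; bad$cingulum_anchor <- NULL
  expect_error(align_to_landmarks(bad), "anchor")
})

test_that("flat maps stack sections in anterior-posterior order", {
  p <- small_params(n_cells = 20, n_tracer_positive = 8)
  brain <- generate_brain(p, 24)
  entries <- lapply(which(brain$mapped), function(k) {
    sec <- brain$sections[[k]]
    pos <- sec$truth[sec$truth$true_positive, ]
    list(section = sec,
         cells = tibble::tibble(x = pos$true_x, y = pos$true_y,
                                cell_id = pos$cell_id, roi = pos$true_roi))
  })
  fm <- assemble_flatmap(entries, injection = brain$injection)
  expect_s3_class(fm, "flat_map")
  expect_equal(nrow(fm$rows), 4)                      # 24 cut sections -> 4 rows
  expect_true(!is.unsorted(fm$rows$ap_position))
  expect_false(is.null(fm$injection_mark))
  expect_true(any(fm$cells$in_injection) || all(!fm$cells$in_injection))

  # every plotted cell's arc equals an independent re-projection
  for (k in which(brain$mapped)) {
    sec <- brain$sections[[k]]
    sl <- smooth_reference_line(sec$reference_line)
    sub <- fm$cells[fm$cells$section_id == sec$section_id, ]
    pos <- sec$truth[sec$truth$true_positive, ]
    redo <- project_cells(cbind(pos$true_x, pos$true_y), sl)
    expect_equal(sub$arc_um, redo$arc_um, tolerance = 1e-9)
  }

  dup <- entries
  dup[[2]]$section$section_id <- dup[[1]]$section$section_id
  expect_error(assemble_flatmap(dup), "duplicate")
  expect_error(assemble_flatmap(list()), "at least one")

  expect_s3_class(plot(fm), "ggplot")
})

test_that("arc recovery on synthetic brains stays within tolerance", {
  # noiseless geometry: < 2 um mean absolute error
  sec <- generate_section(small_params(seed = 55))
  sl <- smooth_reference_line(sec$reference_line)
  pr <- project_cells(cbind(sec$truth$true_x, sec$truth$true_y), sl)
  expect_lt(mean(abs(pr$arc_um - sec$truth$true_arc_um)), 2)

  # vertex noise sd 1 px: < 10 um
  secn <- generate_section(small_params(seed = 56, line_noise_sd = 1))
  sln <- smooth_reference_line(secn$reference_line)
  prn <- project_cells(cbind(secn$truth$true_x, secn$truth$true_y), sln)
  expect_lt(mean(abs(prn$arc_um - secn$truth$true_arc_um)), 10)
})
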