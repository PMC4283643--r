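square_roi <- function(name = "sq", x0 = 0, y0 = 0, side = 10) {
  roi_polygon(name, "s1", rbind(c(x0, y0), c(x0 + side, y0),
                                c(x0 + side, y0 + side), c(x0, y0 + side)))
}

test_that("cell-to-ROI counting handles interior, boundary and unassigned cells", {
  rois <- list(square_roi("A", 0, 0), square_roi("B", 20, 0))
  cells <- tibble::tibble(x = c(5, 25, 50, 10), y = c(5, 5, 5, 5))
  res <- assign_cells_to_rois(cells, rois)
  expect_equal(res$counts$count[res$counts$roi == "A"], 2)  # boundary inside
  expect_equal(res$counts$count[res$counts$roi == "B"], 1)
  expect_equal(res$unassigned, 1)
  expect_equal(res$cell_roi, c("A", "B", NA, "A"))

  # overlap resolved by name order with a warning
  over <- list(square_roi("Z", 0, 0), square_roi("A", 5, 0))
  expect_warning(res2 <- assign_cells_to_rois(tibble::tibble(x = 7, y = 5),
                                              over),
                 "overlapping")
  expect_equal(res2$cell_roi, "A")

  bad <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(roi_polygon("bowtie", "s1", bad), "bowtie")
})

test_that("point-in-polygon matches an independent ray-casting oracle", {
  set.seed(8)
  # irregular star-ish simple polygon
  ang <- sort(runif(9, 0, 2 * pi))
  rad <- runif(9, 5, 20)
  poly <- cbind(25 + rad * cos(ang), 25 + rad * sin(ang))
  roi <- roi_polygon("star", "s1", poly)
  pts <- cbind(runif(500, 0, 50), runif(500, 0, 50))
  mine <- getFromNamespace("points_in_polygon", "cortexflat")(pts, poly)
  oracle <- pip_oracle(pts[, 1], pts[, 2], poly)
  expect_equal(mine, oracle)
  res <- assign_cells_to_rois(tibble::tibble(x = pts[, 1], y = pts[, 2]),
                              list(roi))
  expect_equal(res$counts$count, sum(oracle))
})

test_that("injection zeroing is targeted and idempotent", {
  counts <- tibble::tibble(roi = c("MPtA", "LPtA", "RSD"),
                           count = c(40, 12, 7))
  z1 <- zero_injection_rois(counts, "MPtA")
  expect_equal(z1$count, c(0, 12, 7))
  z2 <- zero_injection_rois(counts, c("MPtA", "LPtA"))  # straddled border
  expect_equal(z2$count, c(0, 0, 7))
  expect_equal(zero_injection_rois(z2, c("MPtA", "LPtA"))$count, z2$count)
  expect_error(zero_injection_rois(counts, "nope"), "unknown")
})

test_that("proportions normalise, invert and refuse empty totals", {
  counts <- tibble::tibble(roi = c("a", "b", "c"), count = c(2, 3, 5))
  pr <- counts_to_proportions(counts)
  expect_equal(pr$proportion, c(0.2, 0.3, 0.5))
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)
  expect_equal(pr$proportion * sum(counts$count), counts$count,
               tolerance = 1e-9)

  single <- counts_to_proportions(tibble::tibble(roi = c("a", "b"),
                                                 count = c(0, 4)))
  expect_equal(single$proportion, c(0, 1))

  expect_error(counts_to_proportions(tibble::tibble(roi = "a", count = 0)),
               "zero")
})

test_that("group aggregation partitions proportions", {
  pr <- tibble::tibble(roi = c("RSD", "RSG", "S1", "Cl"),
                       proportion = c(0.3, 0.2, 0.4, 0.1))
  g <- c(RSD = "medial", RSG = "medial", S1 = "somatic",
         Cl = "claustrum/entorhinal")
  agg <- aggregate_groups(pr, g)
  expect_equal(agg$proportion[agg$group == "medial"], 0.5)
  expect_equal(sum(agg$proportion), 1, tolerance = 1e-9)
  expect_error(aggregate_groups(pr, g[-1]), "RSD")

  # thalamic map yields the 7-level grouping
  th <- default_thalamic_groups()
  expect_equal(length(unique(th)), 7)
  prt <- tibble::tibble(roi = names(th),
                        proportion = rep(1 / length(th), length(th)))
  expect_equal(nrow(aggregate_groups(prt, th)), 7)

  cn <- default_cortical_networks()
  expect_equal(length(cn), 21)
  expect_setequal(unique(cn),
                  c("medial", "lateral", "somatic", "claustrum/entorhinal"))
})

test_that("injection placement metrics use the flat-map frame", {
  # border line with anchor at the medial end; pixel_size 0.5 um/px
  ln <- reference_line(cbind(0:2000, rep(0, 2001)), 1, pixel_size = 0.5)
  inj <- injection_site(center = c(1000, 30), section_id = "s1",
                        extent_um = 300, covered_rois = "MPtA",
                        ap_mm = -4.0)
  done <- injection_metrics(inj, ln, ml_boundary_um = 400,
                            rc_boundary_mm = -4.5)
  expect_equal(done$ml_distance_um, 500)     # 1000 px * 0.5 um
  expect_equal(done$ml_class, "lateral")
  expect_equal(done$rc_class, "caudal")

  # a center exactly on the boundary classifies medial (tie rule)
  tie <- injection_metrics(injection_site(c(800, 0), "s1", 300, "MPtA",
                                          ap_mm = -5),
                           ln, ml_boundary_um = 400, rc_boundary_mm = -4.5)
  expect_equal(tie$ml_distance_um, 400)
  expect_equal(tie$ml_class, "medial")
  expect_equal(tie$rc_class, "rostral")

  expect_error(injection_metrics(inj, NULL, 400), "missing")

  # planted synthetic injections recovered within one pixel
  p <- small_params(n_cells = 5, n_tracer_positive = 2)
  brain <- generate_brain(p, 12)
  sec <- brain$sections[[which(vapply(brain$sections, `[[`, "", "section_id") ==
                                 brain$injection$section_id)]]
  sl <- smooth_reference_line(sec$reference_line)
  got <- injection_metrics(brain$injection, sl, ml_boundary_um = 60)
  expect_lt(abs(got$ml_distance_um - brain$injection$arc_um), 1 * p$pixel_size)
})

test_that("anterograde intensity proportions zero the injected region first", {
  ints <- tibble::tibble(roi = c("a", "b"), intensity = c(100, 300))
  pr <- anterograde_proportions(ints)
  expect_equal(pr$proportion, c(0.25, 0.75))
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-9)

  with_inj <- anterograde_proportions(
    tibble::tibble(roi = c("a", "b", "inj"), intensity = c(100, 300, 900)),
    injection = "inj")
  expect_equal(with_inj$proportion, c(0.25, 0.75, 0))

  expect_error(anterograde_proportions(
    tibble::tibble(roi = "a", intensity = 5), injection = "a"), "zero")
  expect_error(anterograde_proportions(
    tibble::tibble(roi = "a", intensity = -2)), ">= 0")
})

test_that("counting is blind to tracer intensities and hemisphere filtering works", {
  sec <- generate_section(small_params(seed = 61))
  pos <- sec$truth[sec$truth$true_positive, ]
  cells <- tibble::tibble(x = pos$true_x, y = pos$true_y)
  before <- assign_cells_to_rois(cells, sec$rois)
  # permuting tracer intensities of negative cells cannot reach counting,
  # which sees coordinates only
  after <- assign_cells_to_rois(cells[sample(nrow(cells)), ], sec$rois)
  expect_equal(sort(before$cell_roi), sort(after$cell_roi))

  mixed <- tibble::tibble(x = 1:4, y = 1:4,
                          hemisphere = c("left", "right", "left", "right"))
  expect_equal(nrow(filter_ipsilateral(mixed, "left")), 2)
})
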