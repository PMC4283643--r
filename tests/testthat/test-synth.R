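test_that("empty and single-cell sections behave as stated", {
  empty <- generate_section(small_params(n_cells = 0, n_tracer_positive = 0,
                                         background_noise_sd = 3))
  expect_equal(nrow(empty$truth), 0)
  expect_equal(dim(empty$image), c(300, 600, 3))
  # pure background noise: nothing approaches a soma peak
  expect_lt(max(empty$image), 30)

  one <- generate_section(straight_params(n_cells = 1, n_tracer_positive = 0,
                                          background_noise_sd = 0))
  neun <- one$image[, , 1]
  expect_gt(max(neun), 50)
  lab <- cpp_label_components_wrap(neun > 10)
  expect_equal(max(lab), 1)
  # intensity centroid of the single blob sits on the planted center
  idx <- which(lab == 1)
  w <- neun[idx]
  ys <- (idx - 1) %% nrow(neun); xs <- (idx - 1) %/% nrow(neun)
  expect_lt(abs(sum(w * xs) / sum(w) - one$truth$true_x), 0.5)
  expect_lt(abs(sum(w * ys) / sum(w) - one$truth$true_y), 0.5)
})

test_that("generation is bit-reproducible for a fixed seed", {
  p <- small_params(seed = 99)
  a <- generate_section(p)
  b <- generate_section(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)

  ba <- generate_brain(small_params(seed = 5), 12)
  bb <- generate_brain(small_params(seed = 5), 12)
  expect_identical(ba$sections[[1]]$image, bb$sections[[1]]$image)
})

test_that("stored integrated-intensity truth matches brute-force pixel sums", {
  sec <- generate_section(small_params(background_noise_sd = 0, seed = 31))
  neun <- sec$image[, , sec$channel_roles[["neun"]]]
  tracer <- sec$image[, , sec$channel_roles[["tracer_red"]]]
  for (i in seq_len(nrow(sec$truth))) {
    cx <- sec$truth$true_x[i]; cy <- sec$truth$true_y[i]
    r <- sec$truth$radius[i]
    s_neun <- 0; s_tr <- 0
    for (x in floor(cx - r):ceiling(cx + r)) {
      for (y in floor(cy - r):ceiling(cy + r)) {
        if ((x - cx)^2 + (y - cy)^2 <= r^2) {
          s_neun <- s_neun + neun[y + 1, x + 1]
          s_tr <- s_tr + tracer[y + 1, x + 1]
        }
      }
    }
    expect_lt(abs(s_neun - sec$truth$true_integrated_neun[i]), 1)
    expect_lt(abs(s_tr - sec$truth$true_integrated_tracer[i]), 1)
  }
})

test_that("every planted cell lies inside the ribbon and truth arc agrees with the curve", {
  sec <- generate_section(small_params(seed = 41))
  pr <- getFromNamespace("project_onto_polyline", "cortexflat")(
    cbind(sec$truth$true_x, sec$truth$true_y), sec$curve)
  expect_true(all(pr$distance <= small_params()$ribbon_halfwidth))
  expect_equal(pr$arc * sec$pixel_size, sec$truth$true_arc_um,
               tolerance = 1e-8)
})

test_that("sectioning and 1-in-6 sampling follow the series scheme", {
  p <- small_params(n_cells = 5, n_tracer_positive = 2)
  b24 <- generate_brain(p, 24)
  expect_length(b24$sections, 8)          # every 3rd cut section
  expect_equal(sum(b24$mapped), 4)        # every other NeuN section
  expect_equal(sum(b24$mapped) / b24$n_cut_sections, 1 / 6)

  b6 <- generate_brain(p, 6)
  expect_equal(sum(b6$mapped), 1)

  ap <- vapply(b24$sections[b24$mapped], function(s) s$ap_position, numeric(1))
  expect_true(all(diff(ap) > 0))

  expect_error(generate_brain(p, 3), "at least 6")
  expect_warning(generate_brain(p, 8), "divisible by 6")
})

test_that("unmapped sections carry geometry but no raster by default", {
  b <- generate_brain(small_params(n_cells = 5, n_tracer_positive = 2), 12)
  unmapped <- b$sections[!b$mapped]
  expect_true(all(vapply(unmapped, function(s) is.null(s$image), logical(1))))
  expect_true(all(vapply(unmapped, function(s) nrow(s$truth) == 5, logical(1))))
  b_all <- generate_brain(small_params(n_cells = 5, n_tracer_positive = 2),
                          12, render = "all")
  expect_false(any(vapply(b_all$sections, function(s) is.null(s$image),
                          logical(1))))
})

test_that("count fixtures encode the planted undercount offset", {
  f0 <- generate_count_fixture(c(10, 20, 30), offset = 0, noise_sd = 0)
  expect_equal(f0$automated, f0$manual)

  f3 <- generate_count_fixture(c(10, 20, 30), offset = 3, noise_sd = 0)
  expect_equal(f3$automated, c(7, 17, 27))

  expect_error(generate_count_fixture(c(-1, 5), offset = 1), "nonnegative")

  # planted offset is recoverable by the calibration fit
  set.seed(77)
  true_counts <- 10 + round(rexp(50, 1 / 40))
  fx <- generate_count_fixture(true_counts, offset = 3, noise_sd = 1,
                               seed = 123)
  model <- fit_calibration(fx)
  expect_gt(model$x_intercept, -3.5)
  expect_lt(model$x_intercept, -2.5)
})

test_that("infeasible packing raises a placement error", {
  p <- small_params(image_width = 80, image_height = 80, n_cells = 60,
                    n_tracer_positive = 0, min_separation = 20,
                    cell_radius_range = c(4, 6),
                    ribbon_control_points = cbind(c(10, 70), c(40, 40)),
                    ribbon_halfwidth = 20)
  expect_error(generate_section(p), "placement failure")
})
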