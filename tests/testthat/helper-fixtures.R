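# Shared fixtures: scaled-down synthetic worlds that keep tests fast while
# exercising the same code paths as full-size sections.

small_params <- function(...) {
  defaults <- list(
    image_width = 600L, image_height = 300L,
    n_cells = 60L, n_tracer_positive = 20L,
    seed = 11L
  )
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}

# straight horizontal ribbon: arc position equals x offset, which makes
# projection arithmetic checkable by hand
straight_params <- function(...) {
  defaults <- list(
    image_width = 600L, image_height = 200L,
    ribbon_control_points = cbind(c(20, 580), c(100, 100)),
    ribbon_halfwidth = 40,
    n_cells = 30L, n_tracer_positive = 10L,
    seed = 21L
  )
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}

CHANNEL_ROLES_test <- c(neun = 1L, tracer_red = 2L, tracer_yellow = 3L)

cpp_label_components_wrap <- function(mask) {
  getFromNamespace("cpp_label_components", "cortexflat")(mask)
}

# independent even-odd ray-casting point-in-polygon oracle (per-point
# scalar loop, boundary treated as inside), distinct from the package's
# vectorised implementation
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  on_boundary <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_boundary(x, y)) return(TRUE)
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- poly[i, 2]; y2 <- poly[j, 2]
      if ((y1 <= y) != (y2 <= y)) {
        xint <- poly[i, 1] + (y - y1) / (y2 - y1) * (poly[j, 1] - poly[i, 1])
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# nearest-neighbour matching of detections to planted truth; returns the
# per-truth-cell distance to its closest detection
match_to_truth <- function(features, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    sqrt(min((features$x - truth$true_x[i])^2 +
               (features$y - truth$true_y[i])^2))
  }, numeric(1))
}
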