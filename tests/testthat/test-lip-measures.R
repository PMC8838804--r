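test_that("lip splines share the commissures and interpolate the midpoints", {
  f <- worked_lip_frame()
  sp <- lip_splines(f)
  expect_equal(sp$upper[1, ], c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(sp$upper[100, ], c(x = 40, y = 0), tolerance = 1e-12)
  expect_equal(sp$lower[1, ], c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(sp$lower[100, ], c(x = 40, y = 0), tolerance = 1e-12)
  # upper passes through C, lower through D (checked at dense sampling so
  # the sample-to-sample distance is not limited by the 100-point default)
  spd <- lip_splines(f, 2000)
  tol <- arc_length(spd$upper) / 2000 # half the sample spacing, with margin
  expect_lt(nearest_distance(c(20, 10), spd$upper)$distance, tol)
  expect_lt(nearest_distance(c(20, -10), spd$lower)$distance, tol)
  # degenerate closed mouth: both splines are the same straight segment
  flat <- lip_frame(rbind(
    A = c(0, 0), B = c(40, 0), C = c(20, 0), D = c(20, 0),
    E = c(10, 0), F = c(10, 0), G = c(30, 0), H = c(30, 0)
  ))
  spf <- lip_splines(flat)
  expect_equal(spf$upper, spf$lower)
  expect_equal(max(abs(spf$upper[, "y"])), 0)
})

test_that("lip width is the commissure distance", {
  f <- worked_lip_frame()
  expect_equal(lip_width(f), 40)
  rot <- f
  xy <- rotate_points(cbind(f$x, f$y), 0.6, c(3, 3))
  rot$x <- xy[, 1]
  rot$y <- xy[, 2]
  expect_equal(lip_width(rot), 40, tolerance = 1e-9)
  expect_error(
    lip_rounding(lip_frame(rbind(
      A = c(0, 0), B = c(0, 0), C = c(0, 1), D = c(0, -1),
      E = c(0, 1), F = c(0, -1), G = c(0, 1), H = c(0, -1)
    ))),
    "zero lip width"
  )
})

test_that("aperture of an elliptical mouth approximates pi*a*b", {
  f <- gen_lip_frame(
    lip_shape_params(width_mm = 40, upper_height_mm = 5, lower_height_mm = 5)
  )
  expect_equal(lip_aperture(f), pi * 20 * 5, tolerance = 0.05 * pi * 20 * 5)
  closed <- gen_lip_frame(
    lip_shape_params(width_mm = 40, upper_height_mm = 0, lower_height_mm = 0)
  )
  expect_equal(lip_aperture(closed), 0)
})

test_that("aperture matches a rasterized point-in-polygon oracle", {
  set.seed(171)
  for (rep in 1:5) {
    f <- gen_lip_frame(lip_shape_params(
      width_mm = runif(1, 35, 60),
      upper_height_mm = runif(1, 4, 12),
      lower_height_mm = runif(1, 5, 14),
      asymmetry = 2, seed = NULL
    ))
    area <- lip_aperture(f)
    # rasterize on a fine grid and count interior points by ray casting
    sp <- lip_splines(f, 200)
    poly <- rbind(sp$upper, sp$lower[199:2, ])
    h <- 0.05
    gx <- seq(min(poly[, 1]), max(poly[, 1]), by = h)
    gy <- seq(min(poly[, 2]), max(poly[, 2]), by = h)
    grid <- expand.grid(x = gx, y = gy)
    px <- poly[, 1]
    py <- poly[, 2]
    nxt <- c(2:nrow(poly), 1)
    inside <- rep(FALSE, nrow(grid))
    for (s in seq_len(nrow(poly))) {
      x1 <- px[s]; y1 <- py[s]; x2 <- px[nxt[s]]; y2 <- py[nxt[s]]
      crosses <- ((y1 > grid$y) != (y2 > grid$y))
      if (any(crosses)) {
        xin <- x1 + (grid$y[crosses] - y1) / (y2 - y1) * (x2 - x1)
        flip <- xin > grid$x[crosses]
        inside[crosses][flip] <- !inside[crosses][flip]
      }
    }
    raster_area <- sum(inside) * h * h
    expect_equal(area, raster_area, tolerance = 0.01 * raster_area)
  }
})

test_that("aperture is invariant under rotation and scales quadratically", {
  f <- gen_lip_frame(lip_shape_params(
    width_mm = 50, upper_height_mm = 8, lower_height_mm = 10
  ))
  a0 <- lip_aperture(f)
  rot <- f
  xy <- rotate_points(cbind(f$x, f$y), 1.1, c(-4, 9))
  rot$x <- xy[, 1]
  rot$y <- xy[, 2]
  expect_equal(lip_aperture(rot), a0, tolerance = 1e-6)
  for (s in c(0.5, 2, 3.7)) {
    g <- f
    g$x <- f$x * s
    g$y <- f$y * s
    expect_equal(lip_aperture(g), a0 * s^2, tolerance = 1e-6)
    expect_equal(lip_width(g), lip_width(f) * s, tolerance = 1e-9)
    expect_equal(lip_rounding(g), lip_rounding(f), tolerance = 1e-9)
  }
})

test_that("the rounding index reproduces the worked configuration", {
  f <- worked_lip_frame()
  expect_equal(lip_rounding(f), 0.15)
  # index doubles when the width halves with separations fixed
  half <- lip_frame(rbind(
    A = c(0, 0), B = c(20, 0), C = c(20, 10), D = c(20, -10),
    E = c(10, 7), F = c(10, -7), G = c(30, 7), H = c(30, -7)
  ))
  expect_equal(lip_rounding(half), 0.30)
  # a flat closed mouth scores zero
  flat <- lip_frame(rbind(
    A = c(0, 0), B = c(40, 0), C = c(20, 0), D = c(20, 0),
    E = c(10, 0), F = c(10, 0), G = c(30, 0), H = c(30, 0)
  ))
  expect_equal(lip_rounding(flat), 0)
  # vertical-distance convention ignores horizontal offsets
  skew <- lip_frame(rbind(
    A = c(0, 0), B = c(40, 0), C = c(25, 10), D = c(15, -10),
    E = c(10, 7), F = c(10, -7), G = c(30, 7), H = c(30, -7)
  ))
  expect_equal(lip_rounding(skew, distance = "vertical"), 0.15)
  expect_gt(lip_rounding(skew), 0.15) # euclidean includes the skew
})

test_that("rounding is monotone in midline separation and in width", {
  base <- function(cd, w) {
    lip_frame(rbind(
      A = c(0, 0), B = c(w, 0), C = c(w / 2, cd / 2), D = c(w / 2, -cd / 2),
      E = c(w / 4, 3), F = c(w / 4, -3), G = c(3 * w / 4, 3), H = c(3 * w / 4, -3)
    ))
  }
  r_cd <- vapply(c(10, 14, 18, 22), function(cd) lip_rounding(base(cd, 40)),
    numeric(1)
  )
  expect_true(all(diff(r_cd) > 0))
  r_w <- vapply(c(30, 40, 50, 60), function(w) lip_rounding(base(18, w)),
    numeric(1)
  )
  expect_true(all(diff(r_w) < 0))
})

test_that("lip evaluation reports zero deltas for identical frames", {
  f <- gen_lip_frame(lip_shape_params(seed = 5))
  ev <- evaluate_lips(f, f)
  expect_equal(ev$msd_upper_mm, 0)
  expect_equal(ev$msd_lower_mm, 0)
  expect_equal(ev$width_diff, 0)
  expect_equal(ev$aperture_diff, 0)
})

test_that("a rigid vertical shift moves both lip MSDs but not the width", {
  # shallow arcs: the 1 mm shift is nearly normal to the curve everywhere,
  # so the MSD recovers it; steep arcs would report slightly less because
  # nearest-point matching absorbs the tangential component
  f <- gen_lip_frame(
    lip_shape_params(upper_height_mm = 2, lower_height_mm = 2.5, seed = 6)
  )
  g <- f
  g$y <- f$y + 1
  ev <- evaluate_lips(f, g)
  expect_equal(ev$msd_upper_mm, 1, tolerance = 0.02)
  expect_equal(ev$msd_lower_mm, 1, tolerance = 0.02)
  expect_equal(ev$width_diff, 0, tolerance = 1e-9)
  curved <- gen_lip_frame(lip_shape_params(seed = 6))
  gcurved <- curved
  gcurved$y <- curved$y + 1
  evc <- evaluate_lips(curved, gcurved)
  expect_lte(evc$msd_upper_mm, 1 + 1e-9)
  expect_gt(evc$msd_upper_mm, 0.8)
  # sign convention: smaller estimated mouth gives negative aperture diff
  small <- f
  small$y <- f$y * 0.8
  expect_lt(evaluate_lips(f, small)$aperture_diff, 0)
})
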