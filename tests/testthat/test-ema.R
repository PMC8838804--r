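test_that("bite-plane alignment maps the trace onto y = 0 rigidly", {
  pl <- bite_plane(c(0, 0), c(1, 1))
  p <- align_to_bite_plane(c(1, 1), pl)
  expect_equal(p, c(sqrt(2), 0), tolerance = 1e-12)
  # an already-horizontal plane through the origin changes nothing
  pl0 <- bite_plane(c(0, 0), c(10, 0))
  set.seed(181)
  cloud <- cbind(runif(20, -5, 5), runif(20, -5, 5))
  expect_equal(align_to_bite_plane(cloud, pl0), cloud, ignore_attr = TRUE)
  # arbitrary plane: rigid, and both trace points land on y = 0
  pl2 <- bite_plane(c(2, 3), c(-1, 7))
  al <- align_to_bite_plane(cloud, pl2)
  expect_equal(as.numeric(dist(al)), as.numeric(dist(cloud)), tolerance = 1e-9)
  expect_equal(align_to_bite_plane(c(2, 3), pl2)[2], 0, tolerance = 1e-12)
  expect_equal(align_to_bite_plane(c(-1, 7), pl2)[2], 0, tolerance = 1e-12)
  expect_error(bite_plane(c(1, 1), c(1, 1)), "distinct")
})

test_that("trajectory resampling is exact on affine signals", {
  tr <- sensor_trajectory("TT", 0:10, rep(4, 11), rep(-2, 11))
  out <- resample_to_frames(tr, c(0.5, 3.25, 9.9))
  expect_equal(out[, "x"], rep(4, 3))
  expect_equal(out[, "y"], rep(-2, 3))
  ramp <- sensor_trajectory("TT", 0:10, 0:10, 2 * (0:10) + 1)
  out2 <- resample_to_frames(ramp, c(0.5, 7.25))
  expect_equal(out2[, "x"], c(0.5, 7.25))
  expect_equal(out2[, "y"], 2 * c(0.5, 7.25) + 1)
  expect_error(
    resample_to_frames(ramp, c(5, 11.5)),
    "11.5.*outside"
  )
})

test_that("resampling error on a sinusoid is second order in the step", {
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  f <- 3
  tr <- sensor_trajectory("TT", t, sin(2 * pi * f * t), cos(2 * pi * f * t))
  tq <- seq(0.005, 1.995, by = 0.013)
  out <- resample_to_frames(tr, tq)
  bound <- (2 * pi * f)^2 * dt^2 / 8 # max |x''| h^2 / 8
  expect_lt(max(abs(out[, "x"] - sin(2 * pi * f * tq))), bound * 1.01)
})

test_that("pearson correlation matches the textbook formula and guards input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(191)
  a <- rnorm(200)
  b <- 0.5 * a + rnorm(200)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), num / den, tolerance = 1e-12)
  expect_error(pearson_r(a, b[1:10]), "equal lengths")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("a noiseless session correlates perfectly on every coordinate", {
  s <- gen_ema_session(motion_params(duration_s = 5, seed = 11))
  tab <- correlate_sensors(session_pairs(s))
  expect_equal(nrow(tab), 6)
  expect_true(all(abs(tab$r - 1) < 1e-6))
})

test_that("keypoint noise attenuates correlation per the analytic formula", {
  target_r <- 0.9
  p <- motion_params(duration_s = 2000 / 81.25, seed = 12)
  v <- sum(p$latent_amplitudes^2) / 2
  sigma_kp <- sqrt(v * (1 / target_r^2 - 1))
  s <- gen_ema_session(motion_params(
    duration_s = 2000 / 81.25, sigma_kp_mm = sigma_kp, seed = 12
  ))
  tab <- correlate_sensors(session_pairs(s))
  expect_equal(length(s$keypoints$frames), 2000)
  expect_true(all(abs(tab$r - target_r) < 0.05))
})

test_that("decoupled horizontal motion reproduces the high-y low-x pattern", {
  s <- gen_ema_session(motion_params(
    duration_s = 2000 / 81.25, sigma_kp_mm = 1, decouple_x = TRUE, seed = 13
  ))
  tab <- correlate_sensors(session_pairs(s))
  ry <- tab$r[tab$coord == "y"]
  rx <- tab$r[tab$coord == "x"]
  expect_true(all(ry > 0.9))
  expect_true(all(abs(rx) < 0.15))
  expect_true(all(ry - abs(rx) > 0.5))
})

test_that("pooled correlation reduces to per-recording for one recording", {
  s <- gen_ema_session(motion_params(duration_s = 5, sigma_kp_mm = 2, seed = 14))
  pairs <- session_pairs(s)
  pooled <- correlate_sensors(pairs)
  per <- correlate_sensors(pairs, per_recording = TRUE)
  m <- merge(pooled, per, by = c("sensor", "coord"))
  expect_equal(m$r.x, m$r.y, tolerance = 1e-12)
  one <- pairs[[1]]
  expect_equal(
    pooled$r[pooled$sensor == one$sensor & pooled$coord == "x"],
    pearson_r(one$ema_xy[, 1], one$kp_xy[, 1])
  )
})

test_that("correlation survives a common pre-rotation once bite-aligned", {
  base <- motion_params(duration_s = 8, sigma_kp_mm = 1.5, seed = 15)
  s0 <- gen_ema_session(base)
  rot <- motion_params(
    duration_s = 8, sigma_kp_mm = 1.5, rotation_deg = 20, seed = 15
  )
  s1 <- gen_ema_session(rot)
  ev0 <- run_ema_eval(
    list(a = s0$ema), list(a = s0$keypoints),
    list(ema = s0$bite_plane_ema, kp = s0$bite_plane_kp)
  )
  ev1 <- run_ema_eval(
    list(a = s1$ema), list(a = s1$keypoints),
    list(ema = s1$bite_plane_ema, kp = s1$bite_plane_kp)
  )
  expect_equal(ev1$pooled$r, ev0$pooled$r, tolerance = 1e-6)
  # without alignment the rotated session correlates worse on average
  # (rotation mixes the coordinates, so individual channels may move
  # either way, but the coordinate-frame mismatch costs correlation overall)
  tab_raw <- correlate_sensors(session_pairs(s1))
  expect_gt(mean(ev1$pooled$r), mean(tab_raw$r))
})

test_that("EMA tables round trip through the on-disk format", {
  s <- gen_ema_session(motion_params(duration_s = 2, seed = 16))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ema_table(list(rec1 = s$ema), path)
  back <- read_ema_table(path)
  expect_named(back, "rec1")
  expect_named(back$rec1, c("TT", "TBl", "TD"))
  expect_equal(back$rec1$TT$x, s$ema$TT$x, tolerance = 1e-12)
  expect_equal(back$rec1$TD$times, s$ema$TD$times, tolerance = 1e-12)
})
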