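test_that("blood pool is fully enclosed by the myocardial shell", {
  geom <- phantom_geometry(grid_shape = c(64, 64, 64), voxel_mm = 4)
  labs <- build_labels(geom)
  blood <- which(labs == 4L, arr.ind = TRUE)
  d <- dim(labs)
  for (ax in 1:3) {
    for (s in c(-1, 1)) {
      nb <- blood
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1 & nb[, ax] <= d[ax]
      neigh <- labs[nb[ok, , drop = FALSE]]
      expect_true(all(neigh %in% c(3L, 4L)))
    }
  }
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_geometry(wall_mm = 0), "thickness")
  expect_error(phantom_geometry(heart = list(center = c(0, -20, 10),
                                             semi = c(200, 36, 30))),
               "inside the torso")
  expect_error(phantom_geometry(torso = list(center = c(0, 0, 0),
                                             semi = c(-1, 85, 105))),
               "positive")
})

test_that("myocardial voxel count matches direct point-in-ellipsoid count", {
  geom <- small_geometry()
  labs <- build_labels(geom)
  # independent enumeration over voxel centres
  n <- geom$grid_shape
  cnt <- 0L
  hc <- geom$heart$center
  so <- geom$heart$semi
  si <- geom$heart$semi - geom$wall_mm
  for (i in 0:(n[1] - 1)) {
    x <- (i - n[1] / 2) * geom$voxel_mm
    for (j in 0:(n[2] - 1)) {
      y <- (j - n[2] / 2) * geom$voxel_mm
      for (k in 0:(n[3] - 1)) {
        z <- (k - n[3] / 2) * geom$voxel_mm
        qo <- ((x - hc[1]) / so[1])^2 + ((y - hc[2]) / so[2])^2 +
          ((z - hc[3]) / so[3])^2
        qi <- ((x - hc[1]) / si[1])^2 + ((y - hc[2]) / si[2])^2 +
          ((z - hc[3]) / si[3])^2
        if (qo <= 1 && qi > 1) cnt <- cnt + 1L
      }
    }
  }
  expect_identical(sum(labs == 3L), cnt)
})

test_that("respiratory state displaces the heart by the stated excursion", {
  geom <- phantom_geometry(grid_shape = c(64, 64, 64), voxel_mm = 4)
  mot <- motion_params()
  l0 <- phantom_state(geom, mot, 0, mode = "resp")
  expect_identical(unclass(l0)[TRUE], unclass(build_labels(geom))[TRUE])
  lmid <- phantom_state(geom, mot, 1.8, mode = "resp")
  cen <- function(l) {
    idx <- which(l == 4L, arr.ind = TRUE)
    colMeans(idx) * attr(l, "voxel_mm")
  }
  d <- cen(lmid) - cen(l0)
  expect_lt(abs(d[1] - 18.4), 4 + 1e-9)  # within one voxel
  expect_lt(abs(d[2] - 2.4), 4 + 1e-9)
  expect_lt(abs(d[3]), 1e-9)
  # periodicity
  lper <- phantom_state(geom, mot, 1.8 + 3.6, mode = "resp")
  expect_identical(unclass(lper)[TRUE], unclass(lmid)[TRUE])
})

test_that("compartment volumes are conserved under respiratory motion", {
  # fine grid: nearest-voxel discretization jitter stays below 2%
  geom <- phantom_geometry(grid_shape = c(128, 128, 128), voxel_mm = 2)
  mot <- motion_params()
  ref <- tabulate(build_labels(geom), 4)
  for (t in c(0.48, 1.2, 1.8, 2.64)) {
    cnt <- tabulate(phantom_state(geom, mot, t, "resp"), 4)
    expect_true(all(abs(cnt - ref) / ref < 0.02),
                label = sprintf("volume conservation at t=%.2f", t))
  }
})

test_that("cardiac contraction scales the blood pool as (1 - cf)^3", {
  geom <- phantom_geometry(grid_shape = c(128, 128, 128), voxel_mm = 2)
  mot <- motion_params(contraction_fraction = 0.25)
  vdia <- sum(phantom_state(geom, mot, 0, "cardiac") == 4L)
  # peak systole at the end of the systolic ramp (t = 0.36 on the 60 ms
  # grid is the state closest to full contraction)
  vsys <- min(vapply(c(0.36, 0.36 + 0.06), function(t)
    sum(phantom_state(geom, mot, t, "cardiac") == 4L), numeric(1)))
  expect_lt(vsys, vdia)
  p_peak <- naheart:::contraction_profile(mot, 0.36)
  expected <- (1 - 0.25 * p_peak)^3
  expect_lt(abs(vsys / vdia - expected) / expected, 0.05)
})

test_that("respiratory motion-state grid has 60 periodic states", {
  mot <- motion_params()
  expect_identical(naheart:::n_motion_states(mot, "resp"), 60L)
  geom <- small_geometry()
  a <- phantom_state(geom, mot, 0.13, "resp")
  b <- phantom_state(geom, mot, 0.13 + 3.6 * 5, "resp")
  expect_identical(unclass(a)[TRUE], unclass(b)[TRUE])
})

test_that("coil sensitivities are deterministic and anatomically plausible", {
  geom <- small_geometry()
  c1 <- coil_sensitivities(geom, 4, seed = 7)
  c2 <- coil_sensitivities(geom, 4, seed = 7)
  expect_identical(unclass(c1)[TRUE], unclass(c2)[TRUE])
  # single central lobe is near-uniform over the heart
  c0 <- coil_sensitivities(geom, 1, seed = 1)
  labs <- build_labels(geom)
  heart <- labs == 3L | labs == 4L
  mag <- Mod(array(c0[, , , 1], dim = dim(labs)))[heart]
  expect_lt(max(mag) / min(mag), 2)
  # an anterior channel sees the anterior heart half at least 2x stronger
  # than a posterior channel does
  pos <- attr(c1, "positions")
  ant_ch <- which.min(pos[, 2])
  post_ch <- which.max(pos[, 2])
  co <- naheart:::grid_coords(dim(labs), geom$voxel_mm)
  ap <- array(rep(rep(co$y, each = dim(labs)[1]), times = dim(labs)[3]),
              dim = dim(labs))
  ant_half <- heart & ap < geom$heart$center[2]
  m_ant <- mean(Mod(array(c1[, , , ant_ch], dim = dim(labs)))[ant_half])
  m_post <- mean(Mod(array(c1[, , , post_ch], dim = dim(labs)))[ant_half])
  expect_gt(m_ant / m_post, 2)
})

test_that("synthetic bias field has the requested smoothness and limits", {
  geom <- small_geometry()
  f_inf <- synthetic_bias_field(geom, seed = 1, smoothness_mm = Inf)
  expect_equal(max(abs(f_inf - 1)), 0)
  f <- synthetic_bias_field(geom, seed = 2, smoothness_mm = 48)
  expect_true(all(f > 0))
  labs <- build_labels(geom)
  heart <- labs == 3L | labs == 4L
  expect_lt(abs(mean(f[heart]) - 1), 1e-6)
  # shifted copy equals the original sampled at the offset (interior)
  fs <- shift_field(f, c(16, 0, 0))
  expect_equal(fs[3:28, , ], unclass(f)[1:26, , ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # empirical autocorrelation scale of the stochastic part ~ smoothness
  fn <- synthetic_bias_field(geom, seed = 3, smoothness_mm = 48,
                             poly_amp = 0, falloff_mm = Inf)
  g <- fn - mean(fn)
  ac <- function(lag) {
    a <- g[1:(32 - lag), , ]
    b <- g[(1 + lag):32, , ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  lags <- 0:8
  acs <- vapply(lags, ac, numeric(1))
  # fit a Gaussian: filtered white noise has autocorrelation scale
  # sigma * sqrt(2)
  fit_sigma <- sqrt(-0.5 * 1 / coef(lm(log(pmax(acs, 1e-6)) ~
                                         I(lags^2) - 1))[1])
  est_mm <- fit_sigma * geom$voxel_mm / sqrt(2)
  expect_lt(abs(est_mm - 48) / 48, 0.25)
})
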