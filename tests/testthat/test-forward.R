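test_that("DC sample equals concentration times volume in the ideal limit", {
  # full-grid compartment, TE = 0, TR >> T1, FA = 90: weight reduces to c
  geom <- small_geometry(16, 16)
  labs <- build_labels(geom)
  labs[] <- 1L
  tis <- data.frame(label = 1L, name = "x", c = 7, T1 = 10, T2s = 1e9,
                    T2l = 1e9, r = 0)
  traj <- radial_trajectory(10, n_samples = 8, dwell_us = 25, TE_ms = 0,
                            nominal_mm = 16)
  plan <- nufft_plan(rep(16L, 3), width = 7)
  ks <- forward_signal(labs, tis, traj, FA_deg = 90, TR_ms = 1e6,
                       plan = plan)
  expect_equal(Mod(ks[1, 1, 1]), 7 * 16^3, tolerance = 1e-6)
})

test_that("two-compartment signal matches the brute-force Fourier sum", {
  geom <- small_geometry(16, 16)
  labs <- build_labels(geom)
  tis <- tissue_params("23Na")
  traj <- radial_trajectory(5, n_samples = 6, dwell_us = 25, TE_ms = 1.15,
                            nominal_mm = 16)
  ks <- forward_signal(labs, tis, traj, 82, 60,
                       plan = nufft_plan(rep(16L, 3), width = 7))
  W <- signal_weight(tis, traj$t_ms, 82, 60)
  freq <- naheart:::traj_freq(traj, 16)
  ref <- 0
  for (i in seq_len(nrow(tis))) {
    ind <- array(as.numeric(labs == tis$label[i]), dim = dim(labs))
    ref <- ref + dft_direct(ind, freq) * rep(W[, i], 5)
  }
  expect_lt(max(Mod(as.vector(ks[, , 1]) - ref)) / max(Mod(ref)), 1e-5)
  # at k = 0 specifically the NUFFT is accurate to much better than 1e-6
  expect_lt(Mod(ks[1, 1, 1] - ref[1]) / Mod(ref[1]), 1e-6)
})

test_that("T2* decay scales the late-readout signal as predicted", {
  geom <- small_geometry(16, 16)
  labs <- build_labels(geom)
  labs[] <- 1L
  traj <- radial_trajectory(3, n_samples = 16, dwell_us = 50, TE_ms = 1,
                            nominal_mm = 16)
  mk <- function(T2) data.frame(label = 1L, name = "x", c = 1, T1 = 50,
                                T2s = T2, T2l = T2, r = 1)
  k1 <- forward_signal(labs, mk(3), traj, 82, 60)
  k2 <- forward_signal(labs, mk(6), traj, 82, 60)
  tlast <- traj$t_ms[16]
  expected <- exp(-tlast / 6) / exp(-tlast / 3)
  expect_equal(Mod(k2[16, 1, 1]) / Mod(k1[16, 1, 1]), expected,
               tolerance = 1e-9)
})

test_that("forward model is linear over disjoint compartments", {
  geom <- small_geometry(16, 16)
  labs <- build_labels(geom)
  tis <- tissue_params("23Na")
  traj <- radial_trajectory(4, n_samples = 6, nominal_mm = 16)
  full <- forward_signal(labs, tis, traj, 82, 60)
  parts <- 0
  for (i in 1:4) {
    sub <- tis
    sub$c[-i] <- 0
    parts <- parts + forward_signal(labs, sub, traj, 82, 60)
  }
  expect_lt(max(Mod(full - parts)), 1e-10 * max(Mod(full)))
})

test_that("composite assembly reduces to the single-state simulation", {
  geom <- small_geometry()
  seqp <- test_sequence()
  mot0 <- motion_params(resp_excursion_mm = c(0, 0, 0))
  sim_static <- assemble_composite_kspace(geom, mot0, seqp, 12,
                                          mode = "static")
  sim_resp0 <- assemble_composite_kspace(geom, mot0, seqp, 12,
                                         mode = "resp")
  expect_equal(sim_resp0$na$data, sim_static$na$data, tolerance = 1e-12)
})

test_that("respiratory motion blurs the reconstruction", {
  geom <- small_geometry()
  seqp <- test_sequence()
  sim_mov <- assemble_composite_kspace(geom, motion_params(), seqp, 36,
                                       mode = "resp")
  sim_sta <- assemble_composite_kspace(geom, motion_params(), seqp, 36,
                                       mode = "static")
  gt <- reconstruct(sim_sta$na, 32, 8)
  img <- reconstruct(sim_mov$na, 32, 8)
  masks <- naheart:::gt_masks(geom, 32, 8)
  expect_gt(nrmse(img, gt, masks$heart), nrmse(gt, gt, masks$heart))
  expect_gt(nrmse(img, gt, masks$heart), 0.05)
})

test_that("navigator reflects the physiological modulation", {
  geom <- small_geometry()
  seqp <- test_sequence()
  coil <- coil_sensitivities(geom, 2, seed = 1)
  # static: constant navigator per channel
  sim0 <- assemble_composite_kspace(geom, motion_params(), seqp, 12,
                                    mode = "static", coil = coil)
  expect_lt(diff(range(Mod(sim0$nav$values[, 1]))), 1e-9)
  # cardiac-only: dominant spectral peak at 1 Hz (60 bpm)
  simc <- assemble_composite_kspace(geom, motion_params(), seqp, 30,
                                    mode = "cardiac", coil = coil)
  nav <- resample_navigator(simc$nav)
  x <- Mod(nav$values[, 1])
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  fr <- (0:(n - 1)) / (n * nav$dt)
  band <- fr > 0.2 & fr < 5
  expect_equal(fr[band][which.max(p[band])], 1.0, tolerance = 0.1)
  # respiratory-only: periodic with 3.6 s
  simr <- assemble_composite_kspace(geom, motion_params(), seqp, 36,
                                    mode = "resp", coil = coil)
  navr <- resample_navigator(simr$nav)
  xr <- Mod(navr$values[, 1]) - mean(Mod(navr$values[, 1]))
  pr <- Mod(fft(xr))^2
  frr <- (0:(length(xr) - 1)) / (length(xr) * navr$dt)
  bandr <- frr > 0.05 & frr < 2
  expect_equal(frr[bandr][which.max(pr[bandr])], 1 / 3.6, tolerance = 0.05)
})

test_that("noise injection is unbiased, seeded, and pure", {
  geom <- small_geometry(16, 16)
  traj <- radial_trajectory(200, n_samples = 32, nominal_mm = 16)
  ks <- new_kspace_set(array(0 + 0i, dim = c(32, 200, 1)), traj,
                       seq_len(200) * 0.06, "23Na")
  expect_identical(add_noise(ks, 0, 1)$data, ks$data)
  k1 <- add_noise(ks, 2, 5)
  expect_equal(sd(Re(k1$data)), 2, tolerance = 0.02)
  expect_equal(sd(Im(k1$data)), 2, tolerance = 0.02)
  k2 <- add_noise(ks, 2, 6)
  expect_false(identical(k1$data, k2$data))
  expect_identical(ks$data, array(0 + 0i, dim = c(32, 200, 1)))
  expect_identical(add_noise(ks, 2, 5)$data, k1$data)
})

test_that("SNR of the reconstruction scales with the projection count", {
  traj <- radial_trajectory(1600, n_samples = 24, nominal_mm = 8)
  ks <- new_kspace_set(array(0 + 0i, dim = c(24, 1600, 1)), traj,
                       seq_len(1600) * 0.06, "23Na")
  ks <- add_noise(ks, 1, 3)
  i1 <- reconstruct(ks, 24, 8, proj_idx = 1:400)
  i4 <- reconstruct(ks, 24, 8)
  # pure-noise magnitude images: the noise floor scales as 1/sqrt(n)
  expect_equal(mean(i1) / mean(i4), 2, tolerance = 0.1)
})
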