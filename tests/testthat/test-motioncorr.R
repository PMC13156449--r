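test_that("identity transform leaves k-space bit-identical", {
  sim <- static_sim()
  out <- apply_rigid_kspace(sim$na, rigid_transform())
  expect_identical(out$data, sim$na$data)
  expect_identical(out$traj$dirs, sim$na$traj$dirs)
})

test_that("rigid k-space correction conserves sample energy", {
  sim <- static_sim()
  tf <- rigid_transform(c(7, -3, 2), c(4, -2, 1))
  out <- apply_rigid_kspace(sim$na, tf)
  expect_lt(max(abs(Mod(out$data) - Mod(sim$na$data))),
            1e-12 * max(Mod(sim$na$data)))
  expect_equal(unname(sqrt(rowSums(out$traj$dirs^2))),
               rep(1, nrow(out$traj$dirs)), tolerance = 1e-12)
})

test_that("successive k-space corrections equal the composed transform", {
  sim <- static_sim()
  t1 <- rigid_transform(c(3, 1, -2), c(2, -1, 0.5))
  t2 <- rigid_transform(c(-1, 2, 4), c(0, 3, -1))
  seqd <- apply_rigid_kspace(apply_rigid_kspace(sim$na, t1), t2)
  once <- apply_rigid_kspace(sim$na, compose_rigid(t1, t2))
  expect_lt(max(Mod(seqd$data - once$data)), 1e-10 * max(Mod(once$data)))
  expect_lt(max(abs(seqd$traj$dirs - once$traj$dirs)), 1e-10)
})

test_that("correct-then-reconstruct matches the static simulation", {
  # the k-space correction oracle: simulate a displaced phantom, apply the
  # known rigid transform in k-space, and compare with the static truth
  geom <- phantom_geometry(grid_shape = rep(48L, 3), voxel_mm = 5)
  seqp <- test_sequence(5)
  mot <- motion_params()
  labs0 <- phantom_state(geom, mot, 0, "resp")
  labs1 <- phantom_state(geom, mot, 1.8, "resp")  # d = (18.4, 2.4, 0)
  tis <- tissue_params("23Na")
  traj <- radial_trajectory(2000, seqp$na_samples, seqp$na_dwell_us,
                            seqp$TE_23Na, 5)
  ks0 <- new_kspace_set(forward_signal(labs0, tis, traj, 82, 60), traj,
                        seq_len(2000), "23Na")
  ks1 <- new_kspace_set(forward_signal(labs1, tis, traj, 82, 60), traj,
                        seq_len(2000), "23Na")
  # heart and lungs moved by d, the body did not; restrict the comparison
  # to the heart region where the rigid model holds
  tf <- rigid_transform(c(18.4, 2.4, 0))
  corr <- apply_rigid_kspace(ks1, tf)
  img0 <- reconstruct(ks0, 48, 5)
  imgc <- reconstruct(corr, 48, 5)
  masks <- naheart:::gt_masks(geom, 48, 5)
  expect_lt(nrmse(imgc, img0, masks$heart_tight), 0.05)
  # and the correction direction is right: without it the error is large
  img1 <- reconstruct(ks1, 48, 5)
  expect_gt(nrmse(img1, img0, masks$heart_tight), 0.2)
})

test_that("respiratory correction keeps every projection", {
  geom <- small_geometry()
  seqp <- test_sequence()
  coil <- coil_sensitivities(geom, 2, seed = 1)
  sim <- cached("resp_sim_small", assemble_composite_kspace(
    geom, motion_params(), seqp, 45, mode = "resp", coil = coil))
  masks <- naheart:::gt_masks(geom, 32, 8)
  gate <- self_gate(sim, 32, 8, masks$heart, cardiac = FALSE)
  rc <- respiratory_correction(sim$na, sim$h, gate$resp_na, gate$resp_h,
                               32, 8, masks$heart)
  expect_identical(dim(rc$kspace_na$data), dim(sim$na$data))
  expect_identical(dim(rc$kspace_h$data), dim(sim$h$data))
  # per-nucleus bin counts are balanced
  expect_lte(diff(range(tabulate(gate$resp_na, 8))), 1)
  expect_lte(diff(range(tabulate(gate$resp_h, 8))), 1)
})

test_that("static phantom yields near-identity bin transforms", {
  geom <- small_geometry()
  seqp <- test_sequence()
  coil <- coil_sensitivities(geom, 2, seed = 1)
  mot0 <- motion_params(resp_excursion_mm = c(1e-3, 0, 0))
  sim <- assemble_composite_kspace(geom, mot0, seqp, 45, mode = "resp",
                                   coil = coil)
  masks <- naheart:::gt_masks(geom, 32, 8)
  nav <- resample_navigator(sim$nav)
  filt <- respiratory_signal(nav)
  b_h <- bin_respiratory(filt$values[, 1], filt$timestamps,
                         sim$h$timestamps, 8)
  b_na <- bin_respiratory(filt$values[, 1], filt$timestamps,
                          sim$na$timestamps, 8)
  rc <- respiratory_correction(sim$na, sim$h, b_na, b_h, 32, 8,
                               masks$heart)
  # transforms stay below the streak-noise level of the bin images
  # (a fraction of a voxel) and the corrected image matches the
  # uncorrected one
  for (tf in rc$transforms) {
    expect_lt(sqrt(sum(tf$translation^2)), 3)
  }
  img_u <- reconstruct(sim$na, 32, 8)
  img_c <- reconstruct(rc$kspace_na, 32, 8)
  expect_lt(nrmse(img_c, img_u, masks$heart), 0.03)
})

test_that("cardiac correction averages diastole with warped systole", {
  geom <- small_geometry()
  d <- c(32L, 32L, 32L)
  img <- array(runif(prod(d)), dim = d)
  attr(img, "voxel_mm") <- 8
  zero_field <- array(0, dim = c(d, 3))
  attr(zero_field, "voxel_mm") <- 8
  out <- cardiac_correction(img, img, zero_field, 60, 40)
  expect_equal(unclass(out), img, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(out, "frame"), "diastole")
  bad <- array(0, dim = c(16, 16, 16, 3))
  expect_error(cardiac_correction(img, img, bad, 1, 1), "mismatch")
})
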