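na_row <- function(name) {
  tis <- tissue_params("23Na")
  tis[tis$name == name, , drop = FALSE]
}

test_that("compartment PSF reflects the T2* weighting of the readout", {
  traj <- radial_trajectory(1500, n_samples = 24, nominal_mm = 8)
  long <- na_row("myocardium")
  long$T2s <- long$T2l <- 1e9
  psf0 <- compartment_psf(traj, long, 32, 8, hamming = FALSE)
  ctr <- c(17, 17, 17)
  expect_equal(psf0[ctr[1], ctr[2], ctr[3]], 1)
  expect_equal(max(psf0), psf0[ctr[1], ctr[2], ctr[3]])
  # symmetry of the pure sampling PSF
  prof_lo <- psf0[16:12, 17, 17]
  prof_hi <- psf0[18:22, 17, 17]
  expect_equal(prof_lo, prof_hi, tolerance = 0.05, ignore_attr = TRUE)
  # shorter short-T2* widens the PSF
  fwhm <- function(T2s) {
    row <- na_row("myocardium")
    row$T2s <- T2s
    psf <- compartment_psf(traj, row, 32, 8)
    prof <- psf[, 17, 17]
    sum(prof > max(prof) / 2)
  }
  w24 <- fwhm(2.4)
  w36 <- fwhm(3.6)
  expect_gte(w24, w36)
  # finer profile via central second moment
  mom <- function(T2s) {
    row <- na_row("myocardium")
    row$T2s <- T2s
    psf <- pmax(compartment_psf(traj, row, 32, 8), 0)
    x <- (1:32) - 17
    sum(x^2 * psf[, 17, 17]) / sum(psf[, 17, 17])
  }
  expect_gt(mom(2.4), mom(3.6))
})

test_that("PSF integral equals its DC transfer", {
  # Parseval-type check: the image-domain sum of the adjoint equals the
  # weighted sum of the lattice Dirichlet kernels of all samples, computed
  # here by an independent direct summation
  traj <- radial_trajectory(400, n_samples = 16, nominal_mm = 8)
  row <- na_row("blood")
  psf <- compartment_psf(traj, row, 32, 8, normalize = "none")
  dec <- row$r * exp(-traj$t_ms / row$T2s) +
    (1 - row$r) * exp(-traj$t_ms / row$T2l)
  dec <- dec / dec[1]
  w <- naheart:::dcf_weights(traj, 8, 400) * naheart:::hamming_weights(traj)
  freq <- naheart:::traj_freq(traj, 8)
  dirichlet <- function(f) {
    # sum over centred integer lattice positions -16..15
    x <- (-16):15
    Re(sum(exp(2i * pi * f * x)))
  }
  D <- vapply(seq_len(nrow(freq)), function(j)
    dirichlet(freq[j, 1]) * dirichlet(freq[j, 2]) * dirichlet(freq[j, 3]),
    numeric(1))
  expected <- sum(rep(w * dec, 400) * D)
  # the image-domain sum cancels heavily, so the per-sample accuracy of
  # the gridding kernel bounds this identity at the percent level
  expect_equal(sum(psf), expected, tolerance = 0.02)
})

test_that("region spread functions behave like convolutions", {
  geom <- small_geometry()
  labs <- build_labels(geom)
  mask <- labs == 4L
  d <- dim(labs)
  delta <- array(0, dim = d)
  delta[d[1] / 2 + 1, d[2] / 2 + 1, d[3] / 2 + 1] <- 1
  expect_equal(region_spread_function(mask, delta), mask + 0,
               tolerance = 1e-10, ignore_attr = TRUE)
  traj <- radial_trajectory(800, n_samples = 24, nominal_mm = 8)
  psf <- compartment_psf(traj, na_row("blood"), 32, 8, normalize = "none")
  full <- array(1, dim = d)
  rsf_full <- region_spread_function(full, psf)
  expect_lt(diff(range(rsf_full)), 1e-9 * max(abs(rsf_full)))
  rsf <- region_spread_function(mask, psf)
  expect_equal(sum(rsf), sum(mask) * sum(psf), tolerance = 1e-9)
})

test_that("partial-volume correction inverts RSF mixtures exactly", {
  geom <- small_geometry()
  labs <- build_labels(geom)
  masks <- list(labs == 3L, labs == 4L)
  d <- dim(labs)
  delta <- array(0, dim = d)
  delta[d[1] / 2 + 1, d[2] / 2 + 1, d[3] / 2 + 1] <- 1
  ident <- partial_volume_correct(
    0.7 * masks[[1]] + 1.3 * masks[[2]],
    masks, list(region_spread_function(masks[[1]], delta),
                region_spread_function(masks[[2]], delta)))
  expect_equal(unname(ident), c(0.7, 1.3), tolerance = 1e-10)
  traj <- radial_trajectory(800, n_samples = 24, nominal_mm = 8)
  rsfs <- lapply(1:2, function(i) region_spread_function(
    masks[[i]], compartment_psf(traj, na_row(c("myocardium", "blood")[i]),
                                32, 8, normalize = "none")))
  synth <- 0.5 * rsfs[[1]] + 1.0 * rsfs[[2]]
  got <- partial_volume_correct(synth, masks, rsfs)
  expect_equal(unname(got), c(0.5, 1.0), tolerance = 1e-6)
})

test_that("synthetic prior is linear in the assumed ratio", {
  geom <- small_geometry()
  labs <- build_labels(geom)
  a <- array(runif(prod(dim(labs))), dim = dim(labs))
  b <- array(runif(prod(dim(labs))), dim = dim(labs))
  expect_equal(synthetic_prior(0, a, b), b)
  expect_equal(synthetic_prior(1, a, b), a + b)
  expect_equal(synthetic_prior(0.5, a, b),
               (synthetic_prior(0.3, a, b) + synthetic_prior(0.7, a, b)) / 2)
})

test_that("bias-field estimation recovers smooth multiplicative fields", {
  geom <- small_geometry()
  labs <- build_labels(geom)
  mask <- labs == 3L | labs == 4L
  prior <- naheart:::gauss_filter3(array(1 + (labs == 4L), dim = dim(labs)),
                                   1)
  attr(prior, "voxel_mm") <- 8
  f1 <- estimate_bias_field(prior, prior, mask, sigma_mm = 10,
                            voxel_mm = 8)
  expect_lt(max(abs(f1[mask] - 1)), 1e-9)
  g <- synthetic_bias_field(geom, seed = 5, smoothness_mm = 80,
                            noise_amp = 0.1, poly_amp = 0.2)
  biased <- array(prior * g, dim = dim(labs))
  attr(biased, "voxel_mm") <- 8
  fhat <- estimate_bias_field(biased, prior, mask, sigma_mm = 10,
                              voxel_mm = 8)
  gn <- g
  gn[mask] <- gn[mask] / mean(g[mask])
  expect_lt(nrmse(array(fhat, dim = dim(g)), array(gn, dim = dim(g)),
                  mask), 0.05)
  # round trip: correcting the biased image recovers the prior
  rec <- apply_bias_correction(biased, fhat)
  expect_lt(nrmse(array(rec, dim = dim(g)), array(prior, dim = dim(g)),
                  mask), 0.05)
  # the field contains no structure below the filter scale (evaluated
  # away from the mask boundary where the plain filter sees the cutoff)
  hp <- fhat - naheart:::gauss_filter3(array(fhat, dim = dim(g)), 10 / 8)
  core <- morph_mask(mask, 2, "erode")
  expect_lt(sum(hp[core]^2) / sum((fhat[core] - mean(fhat[core]))^2), 0.05)
})

test_that("bias application is a masked voxel-wise division", {
  img <- array(runif(16^3, 1, 2), rep(16, 3))
  mask <- array(FALSE, rep(16, 3))
  mask[5:12, 5:12, 5:12] <- TRUE
  f2 <- array(2, rep(16, 3))
  out <- apply_bias_correction(img, f2, mask)
  expect_equal(out[mask], img[mask] / 2)
  expect_equal(out[!mask], img[!mask])
  f0 <- array(1, rep(16, 3))
  expect_equal(apply_bias_correction(img, f0, mask), img,
               ignore_attr = TRUE)
  fneg <- f2
  fneg[6, 6, 6] <- -1
  expect_error(apply_bias_correction(img, fneg, mask), "positive")
})

test_that("the estimated field carries no anatomy", {
  geom <- small_geometry()
  seqp <- test_sequence()
  sim <- static_sim()
  img <- reconstruct(sim$na, 32, 8)
  masks <- naheart:::gt_masks(geom, 32, 8)
  g <- synthetic_bias_field(geom, seed = 6)
  biased <- array(abs_or_re(img) * g, dim = dim(img))
  attr(biased, "voxel_mm") <- 8
  tis <- tissue_params("23Na")
  rsfs <- rsf_pair(list(masks$myo, masks$blood), sim$na$traj, tis, 82,
                   1.15, 60, 8)
  it <- iterate_ratio(biased, rsfs, list(masks$myo, masks$blood),
                      masks$heart_tight)
  fld <- it$field[masks$heart_tight]
  anat <- (masks$myo - mean(masks$myo[masks$heart_tight]))[masks$heart_tight]
  expect_lt(abs(cor(fld, anat)), 0.3)
})

test_that("1H support-region correction flattens smooth bias", {
  geom <- small_geometry()
  labs <- build_labels(geom)
  body <- labs > 0
  img <- array(1.0 * body, dim = dim(labs))
  attr(img, "voxel_mm") <- 8
  out <- h1_bias_correction(img, body_mask = body)
  expect_lt(diff(range(out[body])), 1e-6)
  g <- synthetic_bias_field(geom, seed = 7, smoothness_mm = 80)
  biased <- array(img * g, dim = dim(labs))
  attr(biased, "voxel_mm") <- 8
  corr <- h1_bias_correction(biased, body_mask = body)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(biased[body]) / cv(corr[body]), 5)
  # on a structured image the myo-blood contrast is reduced but not gone
  seqp <- test_sequence()
  simh <- cached("static_h_2ch", {
    coil <- coil_sensitivities(geom, 2, seed = 1)
    assemble_composite_kspace(geom, motion_params(), seqp, 24,
                              mode = "static", coil = coil)
  })
  himg <- reconstruct(simh$h, 32, 8)
  masks <- naheart:::gt_masks(geom, 32, 8)
  hc <- h1_bias_correction(himg)
  contrast <- function(x) mean(x[masks$blood]) / mean(x[masks$myo])
  expect_gt(contrast(hc), 1.05)
  expect_lt(contrast(hc), contrast(himg) + 0.5)
})

test_that("AFI estimator and its T1 bias model are consistent", {
  expect_equal(afi_flip_angle(array(2, c(4, 4, 4)), array(2, c(4, 4, 4)),
                              sigma_mm = 0, voxel_mm = 4)$fa_map[1], 0)
  # ideal limit: T1 -> infinity removes the bias
  expect_lt(abs(afi_t1_bias(60, 12, 48, 1e6) - 60), 0.01)
  # forward-simulate the AFI steady state and recover the flip angle
  mz <- naheart:::afi_steady_state(60, 12, 48, 1e6)
  S1 <- array(sin(pi / 3) * mz[1], c(4, 4, 4))
  S2 <- array(sin(pi / 3) * mz[2], c(4, 4, 4))
  fa <- afi_flip_angle(S1, S2, sigma_mm = 0, voxel_mm = 4)
  expect_lt(abs(fa$fa_map[1] - 60), 0.1)
  # at T1 = 30 ms the measurement is biased exactly as modelled
  mz30 <- naheart:::afi_steady_state(60, 12, 48, 30)
  fa30 <- afi_flip_angle(array(sin(pi / 3) * mz30[1], c(4, 4, 4)),
                         array(sin(pi / 3) * mz30[2], c(4, 4, 4)),
                         sigma_mm = 0, voxel_mm = 4)
  expect_equal(fa30$fa_map[1], afi_t1_bias(60, 12, 48, 30),
               tolerance = 1e-6)
  # bias magnitude decreases with T1
  b <- vapply(c(20, 30, 50, 100, 300), function(T1)
    abs(afi_t1_bias(60, 12, 48, T1) - 60), numeric(1))
  expect_true(all(diff(b) < 0))
  # numerical inversion round trip
  for (fa_true in c(40, 60, 82)) {
    fam <- afi_t1_bias(fa_true, 12, 48, 30)
    expect_lt(abs(afi_t1_bias_correct(fam, 12, 48, 30) - fa_true), 0.05)
  }
})

test_that("relaxation correction obeys its closed-form limits", {
  row <- na_row("myocardium")
  # TE = 0 and TR >> T1: no correction
  expect_equal(relaxation_correction(5, row, 82, 0, 1e9), 5,
               tolerance = 1e-9)
  # r = 1, TE = T2s, TR >> T1: multiply by e
  r1 <- row
  r1$r <- 1
  expect_equal(relaxation_correction(5, r1, 82, r1$T2s, 1e9), 5 * exp(1),
               tolerance = 1e-9)
  # self-consistency with the forward signal model (sin(FA) excluded)
  W <- signal_weight(row, 1.15, 82, 60)
  rec <- relaxation_correction(W[1, 1], row, 82, 1.15, 60)
  expect_equal(rec, row$c * sin(82 * pi / 180), tolerance = 1e-9)
  bad <- row
  bad$T1 <- -60  # saturation factor becomes negative
  expect_error(relaxation_correction(5, bad, 82, 1.15, 60),
               "non-positive")
})

test_that("blood mask truncation and morphology utilities work", {
  m <- array(FALSE, c(10, 6, 6))
  myo <- m
  myo[3:6, 2:4, 2:4] <- TRUE
  blood <- m
  blood[2:9, 3, 3] <- TRUE
  out <- truncate_blood_mask(blood, myo)
  expect_true(all(which(out, arr.ind = TRUE)[, 1] <= 6))
  expect_identical(sum(out), 5L)
  sq <- array(FALSE, c(8, 8, 8))
  sq[4:5, 4:5, 4:5] <- TRUE
  expect_gt(sum(morph_mask(sq, 1, "dilate")), sum(sq))
  expect_lt(sum(morph_mask(sq, 1, "erode")), sum(sq))
  expect_true(all(sq[morph_mask(sq, 1, "erode")]))
})
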