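#' B1 bias correction configuration
#'
#' Gaussian filter scales of the bias-field estimation (10 mm for 23Na,
#' 12 mm for the 1H support-region correction, 14 mm for AFI flip-angle
#' maps) and the assumed myo-blood ratio grid `[0.3, 0.7]` in steps of
#' 0.005 searched by [iterate_ratio()].
#'
#' @param sigma_23Na,sigma_1H,sigma_AFI Gaussian standard deviations (mm).
#' @param r_grid assumed-ratio search grid.
#' @param heart_dilate_mm dilation of the myocardium+blood union that
#'   defines the heart mask.
#' @export
b1_config <- function(sigma_23Na = 10, sigma_1H = 12, sigma_AFI = 14,
                      r_grid = seq(0.3, 0.7, by = 0.005),
                      heart_dilate_mm = 10) {
  stopifnot(all(r_grid > 0), all(r_grid < 1))
  structure(list(sigma_23Na = sigma_23Na, sigma_1H = sigma_1H,
                 sigma_AFI = sigma_AFI, r_grid = r_grid,
                 heart_dilate_mm = heart_dilate_mm), class = "b1_config")
}

#' Point-spread function of the apodized radial acquisition
#'
#' Reconstructs the readout weighting of a unit impulse: each k-space
#' sample is weighted by the compartment's biexponential T2* decay along
#' the readout (relative to the echo time) and the usual density
#' compensation and Hamming filter, then transformed to image space.
#' A shorter short-component T2* makes the k-space weighting fall off
#' faster and hence widens the PSF.
#'
#' @param traj a [radial_trajectory()].
#' @param tissue_row single row of [tissue_params()].
#' @param grid,voxel_mm image grid of the PSF volume.
#' @param hamming include the Hamming filter.
#' @param normalize `"center"` (unit central value) or `"none"` (DC gain
#'   equals the true relative signal attenuation; used for quantitative
#'   RSF modelling).
#' @return real PSF volume.
#' @export
compartment_psf <- function(traj, tissue_row, grid, voxel_mm,
                            hamming = TRUE,
                            normalize = c("center", "none")) {
  normalize <- match.arg(normalize)
  if (length(grid) == 1) grid <- rep(grid, 3)
  p <- tissue_row
  dec <- p$r * exp(-traj$t_ms / p$T2s) + (1 - p$r) * exp(-traj$t_ms / p$T2l)
  dec <- dec / dec[1]
  n_psf_proj <- min(nrow(traj$dirs), 2000L)
  w <- dcf_weights(traj, voxel_mm, n_psf_proj)
  if (hamming) w <- w * hamming_weights(traj)
  plan <- nufft_plan(grid, width = 5)
  freq <- traj_freq(traj, voxel_mm, seq_len(n_psf_proj))
  vals <- rep(dec * w, n_psf_proj)
  psf <- Re(nufft_adjoint(plan, vals, freq))
  if (normalize == "center") {
    ctr <- grid / 2 + 1
    psf <- psf / psf[ctr[1], ctr[2], ctr[3]]
  }
  structure(psf, voxel_mm = voxel_mm)
}

#' Region-spread function: compartment mask convolved with its PSF
#'
#' Circular convolution via the Fourier domain; the result is real.
#' @param mask binary/logical compartment mask.
#' @param psf PSF volume on the same grid ([compartment_psf()]).
#' @export
region_spread_function <- function(mask, psf) {
  if (!all(dim(mask) == dim(psf))) stop("mask/PSF grid mismatch")
  m <- array(as.numeric(mask), dim = dim(mask))
  # center the PSF kernel at the array origin for circular convolution
  k <- cfft3(psf + 0i)
  M <- cfft3(m + 0i)
  out <- Re(cfft3(M * k, inverse = TRUE)) / prod(dim(mask))
  structure(array(out, dim = dim(mask)), voxel_mm = attr(psf, "voxel_mm"))
}

#' Partial-volume correction of compartment means
#'
#' Unmixes the spillover between myocardium and blood by solving the
#' 2x2 system `M c = s`, where `M_ij` is the mean of RSF_j over mask_i
#' and `s_i` the measured mean over mask_i; `c` are the unmixed
#' compartment intensities.
#'
#' @param image measured image (or `NULL` if `means` given).
#' @param masks list of two logical masks (myocardium, blood).
#' @param rsfs list of two RSFs matching the masks.
#' @param means optional length-2 measured means (replaces `image`).
#' @return named numeric: unmixed `myo` and `blood` intensities.
#' @export
partial_volume_correct <- function(image, masks, rsfs, means = NULL) {
  stopifnot(length(masks) == 2, length(rsfs) == 2)
  M <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) M[i, j] <- mean(rsfs[[j]][masks[[i]]])
  if (abs(det(M)) < 1e-12 * prod(diag(M)))
    stop("PVC system singular: RSF means not separable")
  s <- if (is.null(means)) {
    c(mean(image[masks[[1]]]), mean(image[masks[[2]]]))
  } else means
  c(stats::setNames(solve(M, s), c("myo", "blood")))
}

#' Synthetic prior image from RSFs and an assumed myo-blood ratio
#'
#' `prior = r_assumed * RSF_myo + RSF_blood`.
#' @param r_assumed assumed myocardium-to-blood ratio in (0, 1].
#' @param rsf_myo,rsf_blood region-spread functions.
#' @export
synthetic_prior <- function(r_assumed, rsf_myo, rsf_blood) {
  r_assumed * rsf_myo + rsf_blood
}

# Gaussian filtering restricted to a mask (normalized convolution):
# G*(x m) / G*(m), defined inside the mask; avoids the edge bias of
# filtering across the mask boundary
masked_gauss <- function(x, mask, sigma_vox) {
  m <- array(as.numeric(mask), dim = dim(x))
  num <- gauss_filter3(x * m, sigma_vox)
  den <- gauss_filter3(m, sigma_vox)
  out <- num / pmax(den, 1e-12)
  out[!mask] <- NA_real_
  out
}

#' Estimate the multiplicative B1 bias field from a prior image
#'
#' Both the measured and the prior image are masked to the heart and
#' low-pass filtered with a mask-normalized Gaussian; their quotient is
#' the estimated smooth bias field
#' \deqn{B_{1,bias}(x) = S_{orig,filt}(x) / S_{prior,filt}(x)
#'   \approx \sin(FA(x)) B_1^-(x)}
#' defined inside the mask (1 outside, flagged by the `mask` attribute).
#'
#' @param original measured image.
#' @param prior synthetic prior ([synthetic_prior()]).
#' @param heart_mask logical mask.
#' @param sigma_mm Gaussian standard deviation in mm.
#' @param voxel_mm voxel size.
#' @return `bias_field` array with attributes `mask`, `provenance`.
#' @export
estimate_bias_field <- function(original, prior, heart_mask, sigma_mm = 10,
                                voxel_mm = attr(original, "voxel_mm")) {
  stopifnot(any(heart_mask))
  sf <- masked_gauss(abs_or_re(original), heart_mask, sigma_mm / voxel_mm)
  pf <- masked_gauss(abs_or_re(prior), heart_mask, sigma_mm / voxel_mm)
  if (any(pf[heart_mask] <= 0))
    stop("filtered prior not positive inside the mask")
  field <- array(1, dim = dim(original))
  field[heart_mask] <- sf[heart_mask] / pf[heart_mask]
  # the absolute scale of the quotient is arbitrary (the prior is defined
  # up to a calibration constant); normalize to mean 1 over the mask so
  # corrected images keep the scale of the input
  field[heart_mask] <- field[heart_mask] / mean(field[heart_mask])
  structure(field, mask = heart_mask, provenance = "estimated",
            voxel_mm = voxel_mm, class = c("bias_field", "array"))
}

#' Divide out a bias field inside a mask
#'
#' `S_corr = S_uncorr / field` inside the mask; voxels outside are left
#' unchanged and flagged via the `corrected_mask` attribute.
#'
#' @param image image to correct.
#' @param field positive bias field.
#' @param mask logical mask (defaults to the field's own mask).
#' @export
apply_bias_correction <- function(image, field, mask = attr(field, "mask")) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(image))
  if (any(field[mask] <= 0)) stop("bias field not positive inside the mask")
  out <- abs_or_re(image)
  out[mask] <- out[mask] / field[mask]
  out <- array(out, dim = dim(image))
  attributes(out) <- attributes(image)
  attr(out, "corrected_mask") <- mask
  out
}

#' Iterative anatomy-based B1 bias correction
#'
#' For every assumed myo-blood ratio on the grid a synthetic prior is
#' built, the bias field estimated, the image corrected, and the measured
#' ratio recovered by partial-volume correction (and relaxation
#' correction, so the ratio is on the concentration scale of
#' `r_assumed`); the ratio whose measurement best reproduces the
#' assumption is selected.  Ties take the smaller ratio.
#'
#' @param original uncorrected 23Na image.
#' @param rsfs list of two RSFs (myocardium, blood), each scaled by its
#'   compartment's relaxation/saturation factor so that the prior models
#'   the measured image of a unit-blood-concentration object (see
#'   [rsf_pair()]).
#' @param masks list of two logical masks (myocardium, blood).
#' @param heart_mask logical heart mask used for filtering/correction.
#' @param config a [b1_config()].
#' @param relax_factors length-2 factors (myo, blood) dividing the PVC
#'   means; leave at `c(1, 1)` when the RSFs already carry the
#'   relaxation/saturation scaling ([rsf_pair()] does), or pass the
#'   factors explicitly when using raw mask-convolved RSFs.
#' @param voxel_mm voxel size.
#' @return list: `r_opt`, corrected `image`, `field`, and the full
#'   diagnostic `trace` (`r_assumed`, `r_measured`).
#' @export
iterate_ratio <- function(original, rsfs, masks, heart_mask,
                          config = b1_config(), relax_factors = c(1, 1),
                          voxel_mm = attr(original, "voxel_mm")) {
  stopifnot(all(dim(rsfs[[1]]) == dim(original)))
  sig <- config$sigma_23Na / voxel_mm
  orig <- abs_or_re(original)
  filt_orig <- masked_gauss(orig, heart_mask, sig)
  filt_m <- masked_gauss(abs_or_re(rsfs[[1]]), heart_mask, sig)
  filt_b <- masked_gauss(abs_or_re(rsfs[[2]]), heart_mask, sig)
  r_meas <- rep(NA_real_, length(config$r_grid))
  for (i in seq_along(config$r_grid)) {
    r <- config$r_grid[i]
    ok <- try({
      pf <- r * filt_m + filt_b
      field <- array(1, dim = dim(orig))
      field[heart_mask] <- filt_orig[heart_mask] / pf[heart_mask]
      corr <- orig
      corr[heart_mask] <- corr[heart_mask] / field[heart_mask]
      cm <- partial_volume_correct(corr, masks, rsfs)
      r_meas[i] <- (cm[1] / relax_factors[1]) / (cm[2] / relax_factors[2])
    }, silent = TRUE)
  }
  if (all(is.na(r_meas))) stop("B1 ratio iteration failed at every grid point")
  dif <- abs(r_meas - config$r_grid)
  r_opt <- config$r_grid[which.min(dif)]  # which.min takes the first = smaller r
  prior <- synthetic_prior(r_opt, rsfs[[1]], rsfs[[2]])
  field <- estimate_bias_field(original, prior, heart_mask,
                               config$sigma_23Na, voxel_mm)
  corrected <- apply_bias_correction(original, field)
  list(r_opt = r_opt, image = corrected, field = field,
       trace = data.frame(r_assumed = config$r_grid, r_measured = r_meas))
}

#' 1H bias correction with a homogeneous support region
#'
#' The support-region variant of the bias correction: the object support
#' (air/tissue threshold of the image if not supplied; low-signal lung
#' must stay inside the support or the shading around the heart is left
#' uncorrected) serves as a homogeneous prior; the field is the
#' mask-normalized Gaussian filtered image
#' (normalized to mean 1 over the mask) and is divided out inside the
#' mask.  This flattens the low-frequency bias but also reduces genuine
#' myocardium-blood contrast, which is acceptable for images used only
#' for segmentation and motion-field estimation.
#'
#' @param image 1H magnitude image.
#' @param body_mask optional logical support mask.
#' @param sigma_mm Gaussian standard deviation (mm).
#' @param voxel_mm voxel size.
#' @return corrected image with attributes `field` and `body_mask`.
#' @export
h1_bias_correction <- function(image, body_mask = NULL, sigma_mm = 12,
                               voxel_mm = attr(image, "voxel_mm")) {
  img <- abs_or_re(image)
  if (is.null(body_mask))
    body_mask <- img > 0.05 * quantile(img, 0.99)
  if (!any(body_mask)) stop("empty body mask")
  f <- masked_gauss(img, body_mask, sigma_mm / voxel_mm)
  f <- f / mean(f[body_mask])
  out <- img
  out[body_mask] <- out[body_mask] / f[body_mask]
  out <- array(out, dim = dim(image))
  attributes(out) <- attributes(image)
  attr(out, "field") <- f
  attr(out, "body_mask") <- body_mask
  out
}

# Otsu's threshold on a 256-bin histogram
otsu_threshold <- function(x) {
  v <- as.vector(x)
  br <- seq(min(v), max(v), length.out = 257)
  h <- as.numeric(tabulate(findInterval(v, br, all.inside = TRUE), 256))
  w <- cumsum(h)
  m <- cumsum(h * seq_len(256))
  mt <- m[256]
  between <- (mt * w - m * w[256])^2 / (w * (w[256] - w) + 1e-12)
  br[which.max(between)]
}

#' AFI flip-angle map from a dual-TR acquisition
#'
#' Actual flip-angle imaging estimator: with `n = TR2/TR1` and
#' `rho = S2/S1`, `FA = arccos((rho n - 1)/(n - rho))` per voxel,
#' smoothed with a Gaussian (sigma 14 mm); voxels whose argument falls
#' outside `[-1, 1]` are flagged invalid and excluded from the reported
#' blood-pool median.
#'
#' @param S1,S2 steady-state magnitude images of the two TR slots.
#' @param TR1,TR2 repetition times (ms).
#' @param sigma_mm smoothing scale (mm); 0 disables smoothing.
#' @param voxel_mm voxel size.
#' @param blood_mask optional mask for the reported median.
#' @return list: `fa_map` (deg, NA where invalid), `valid`,
#'   `blood_median_deg` (NA without a mask).
#' @export
afi_flip_angle <- function(S1, S2, TR1 = 12, TR2 = 48, sigma_mm = 14,
                           voxel_mm = attr(S1, "voxel_mm"),
                           blood_mask = NULL) {
  stopifnot(all(dim(S1) == dim(S2)))
  if (any(S1 < 0, na.rm = TRUE)) stop("S1 must be a magnitude image")
  n <- TR2 / TR1
  rho <- abs_or_re(S2) / pmax(abs_or_re(S1), 1e-300)
  arg <- (rho * n - 1) / (n - rho)
  valid <- is.finite(arg) & arg >= -1 & arg <= 1
  fa <- array(NA_real_, dim = dim(S1))
  fa[valid] <- acos(arg[valid]) * 180 / pi
  if (sigma_mm > 0 && any(valid)) {
    sm <- masked_gauss(ifelse(valid, fa, 0), valid, sigma_mm / voxel_mm)
    fa[valid] <- sm[valid]
  }
  med <- if (!is.null(blood_mask)) {
    median(fa[blood_mask & valid], na.rm = TRUE)
  } else NA_real_
  list(fa_map = fa, valid = valid, blood_median_deg = med)
}

# exact two-TR AFI steady state under perfect spoiling: longitudinal
# magnetization before each of the two pulses
afi_steady_state <- function(FA_deg, TR1, TR2, T1) {
  a <- cos(FA_deg * pi / 180)
  e1 <- exp(-TR1 / T1)
  e2 <- exp(-TR2 / T1)
  den <- 1 - a^2 * e1 * e2
  mz1 <- (1 - e2 + (1 - e1) * a * e2) / den  # before pulse of the TR1 slot
  mz2 <- (1 - e1 + (1 - e2) * a * e1) / den  # before pulse of the TR2 slot
  c(mz1 = mz1, mz2 = mz2)
}

#' Flip angle measured by AFI at finite T1
#'
#' The AFI estimator assumes `TR1, TR2 << T1`; at the short sodium T1
#' values this is violated and the measured flip angle is biased.  This
#' computes the exact two-TR steady state and applies the AFI estimator,
#' returning the biased measurement; [afi_t1_bias_correct()] inverts it.
#'
#' @param FA_true true flip angle (deg).
#' @param TR1,TR2 repetition times (ms).
#' @param T1 longitudinal relaxation time (ms).
#' @return measured flip angle (deg).
#' @export
afi_t1_bias <- function(FA_true, TR1 = 12, TR2 = 48, T1 = 30) {
  vapply(FA_true, function(fa) {
    mz <- afi_steady_state(fa, TR1, TR2, T1)
    rho <- mz[2] / mz[1]
    n <- TR2 / TR1
    acos(pmin(pmax((rho * n - 1) / (n - rho), -1), 1)) * 180 / pi
  }, numeric(1))
}

#' Invert the AFI T1 bias numerically
#'
#' @param FA_measured measured flip angle (deg).
#' @inheritParams afi_t1_bias
#' @return corrected (true) flip angle (deg).
#' @export
afi_t1_bias_correct <- function(FA_measured, TR1 = 12, TR2 = 48, T1 = 30) {
  vapply(FA_measured, function(fam) {
    stats::uniroot(function(fa) afi_t1_bias(fa, TR1, TR2, T1) - fam,
                   c(1e-3, 179.9), tol = 1e-8)$root
  }, numeric(1))
}

# Relaxation/saturation attenuation factor of a compartment at the scan's
# TE/TR/FA; this is the denominator of the relaxation correction
relaxation_factor <- function(tissue_row, FA_deg, TE_ms, TR_ms) {
  p <- tissue_row
  dec <- p$r * exp(-TE_ms / p$T2s) + (1 - p$r) * exp(-TE_ms / p$T2l)
  e1 <- exp(-TR_ms / p$T1)
  dec * (1 - e1) / (1 - cos(FA_deg * pi / 180) * e1)
}

#' Relaxation correction of 23Na signals
#'
#' Divides out the echo-time T2* decay and the T1/flip-angle saturation:
#' \deqn{S_{corr} = S \Big/ \left\{ \left[r e^{-TE/T2^*_s} + (1-r)
#' e^{-TE/T2^*_l}\right] \frac{1 - e^{-TR/T_1}}{1 - \cos(FA)
#' e^{-TR/T_1}} \right\}}
#' with the subject's blood-pool median flip angle and the compartment's
#' literature relaxation times.
#'
#' @param S signal (scalar, vector or image).
#' @param tissue_row compartment row of [tissue_params()].
#' @param FA_deg flip angle (deg; blood-pool AFI median in vivo).
#' @param TE_ms,TR_ms sequence timing (ms).
#' @export
relaxation_correction <- function(S, tissue_row, FA_deg, TE_ms, TR_ms) {
  f <- relaxation_factor(tissue_row, FA_deg, TE_ms, TR_ms)
  if (f <= 0) stop("non-positive relaxation correction denominator")
  S / f
}

#' Quantitative RSF pair for the PVC / B1 machinery
#'
#' Builds the myocardium and blood region-spread functions used by
#' [iterate_ratio()] and [partial_volume_correct()]: each compartment's
#' PSF (readout T2* decay, Hamming filter) convolved with its mask and
#' scaled by the compartment's relaxation/saturation factor, so the pair
#' models the measured image of unit compartment concentrations.
#'
#' @param masks list of two logical masks (myo, blood).
#' @param traj the 23Na [radial_trajectory()].
#' @param tissue 23Na [tissue_params()].
#' @param FA_deg,TE_ms,TR_ms sequence parameters.
#' @param voxel_mm image voxel size.
#' @param hamming include the Hamming filter.
#' @return list of two RSFs with attribute `relax_factors`.
#' @export
rsf_pair <- function(masks, traj, tissue, FA_deg, TE_ms, TR_ms, voxel_mm,
                     hamming = TRUE) {
  rows <- list(tissue[tissue$name == "myocardium", ],
               tissue[tissue$name == "blood", ])
  rf <- vapply(rows, relaxation_factor, numeric(1), FA_deg = FA_deg,
               TE_ms = TE_ms, TR_ms = TR_ms)
  rsfs <- lapply(1:2, function(i) {
    psf <- compartment_psf(traj, rows[[i]], dim(masks[[i]]), voxel_mm,
                           hamming = hamming, normalize = "none")
    region_spread_function(masks[[i]], psf) * rf[i]
  })
  attr(rsfs, "relax_factors") <- rf
  rsfs
}

#' Truncate a blood-pool mask at the top of the myocardium
#'
#' Removes blood voxels superior to the most superior myocardial voxel
#' (excluding the great vessels from the evaluation); a post-processing
#' utility for supplied segmentations.
#'
#' @param blood_mask,myo_mask logical masks (axis 1 = SI, increasing
#'   index = superior).
#' @export
truncate_blood_mask <- function(blood_mask, myo_mask) {
  top <- max(which(apply(myo_mask, 1, any)))
  if (top < dim(blood_mask)[1]) {
    blood_mask[(top + 1):dim(blood_mask)[1], , ] <- FALSE
  }
  blood_mask
}

#' Morphological erosion/dilation of a mask with a spherical element
#'
#' @param mask logical 3D mask.
#' @param radius_vox sphere radius in voxels.
#' @param op `"dilate"` or `"erode"`.
#' @export
morph_mask <- function(mask, radius_vox = 1, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(mask)
  r <- ceiling(radius_vox)
  off <- expand.grid(-r:r, -r:r, -r:r)
  off <- off[rowSums(off^2) <= radius_vox^2 + 1e-9, , drop = FALSE]
  m <- if (op == "erode") !mask else mask
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(off))) {
    sx <- pmin(pmax(seq_len(d[1]) - off[i, 1], 1), d[1])
    sy <- pmin(pmax(seq_len(d[2]) - off[i, 2], 1), d[2])
    sz <- pmin(pmax(seq_len(d[3]) - off[i, 3], 1), d[3])
    out <- out | m[sx, sy, sz]
  }
  if (op == "erode") !out else out
}
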