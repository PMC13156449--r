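#' Background-noise SNR estimate for magnitude images
#'
#' \deqn{SNR = \frac{\mathrm{mean}(S_{roi})}{\mathrm{std}(noise)}
#'   \sqrt{(4-\pi)/2}}
#' The \eqn{\sqrt{(4-\pi)/2} \approx 0.655} factor converts the standard
#' deviation of Rayleigh-distributed magnitude background noise to the
#' underlying Gaussian component sigma.
#'
#' @param image magnitude image.
#' @param signal_mask logical mask of the tissue of interest.
#' @param noise_roi logical mask of a background (air) region.
#' @export
snr_background <- function(image, signal_mask, noise_roi) {
  sdn <- sd(image[noise_roi])
  if (!is.finite(sdn) || sdn == 0) stop("noise ROI has zero variance")
  mean(image[signal_mask]) / sdn * sqrt((4 - pi) / 2)
}

#' Normalized root mean square error within a mask
#'
#' RMSE over the mask divided by the mean of the reference over the mask.
#' @param image,reference same-size arrays.
#' @param mask logical mask (default: everywhere).
#' @export
nrmse <- function(image, reference, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(reference))
  if (!any(mask)) stop("empty mask")
  stopifnot(all(dim(image) == dim(reference)))
  sqrt(mean((image[mask] - reference[mask])^2)) / mean(reference[mask])
}

#' Mean structural similarity index over a mask
#'
#' Standard SSIM with a Gaussian window (sigma 1.5 voxels) and stabilizing
#' constants K1 = 0.01, K2 = 0.03; the dynamic range is taken from the
#' joint 1st-99th percentile of both images, which is robust to isolated
#' reconstruction outliers.
#'
#' @param a,b images on a common grid and intensity scale.
#' @param mask logical mask for averaging (default: everywhere).
#' @param sigma Gaussian window standard deviation in voxels.
#' @param K stabilizing constants `c(K1, K2)`.
#' @export
ssim <- function(a, b, mask = NULL, sigma = 1.5, K = c(0.01, 0.03)) {
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(a))
  if (!any(mask)) stop("empty mask")
  q <- quantile(c(a[mask], b[mask]), c(0.01, 0.99))
  L <- max(q[2] - q[1], .Machine$double.eps)
  c1 <- (K[1] * L)^2
  c2 <- (K[2] * L)^2
  mu_a <- gauss_filter3(a, sigma)
  mu_b <- gauss_filter3(b, sigma)
  va <- gauss_filter3(a * a, sigma) - mu_a^2
  vb <- gauss_filter3(b * b, sigma) - mu_b^2
  cab <- gauss_filter3(a * b, sigma) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s[mask])
}

#' Whole-blood sodium concentration from serum and hematocrit
#'
#' `c_blood = (1 - hematocrit) * c_serum`.
#' @param c_serum serum sodium concentration (mM).
#' @param hematocrit hematocrit fraction in `[0, 1)`.
#' @export
blood_concentration <- function(c_serum, hematocrit) {
  if (any(hematocrit >= 1) || any(hematocrit < 0))
    stop("hematocrit must be in [0, 1)")
  (1 - hematocrit) * c_serum
}

#' Apparent tissue sodium concentration by blood calibration
#'
#' `aTSC = c_blood * mean_myo / mean_blood` (linear calibration against
#' the ventricular blood pool as internal reference).
#' @param mean_myo,mean_blood mean compartment signals.
#' @param c_blood whole-blood sodium concentration (mM).
#' @export
atsc <- function(mean_myo, mean_blood, c_blood) {
  if (any(mean_blood <= 0)) stop("blood mean must be positive")
  c_blood * mean_myo / mean_blood
}

#' Convert tissue sodium content to a concentration
#'
#' Multiplies umol/g by the tissue specific gravity (g/mL), e.g.
#' 41 umol/g at 1.05 g/mL gives 43.05 mM.
#' @param umol_per_g content in micromoles per gram.
#' @param specific_gravity tissue density in g/mL.
#' @export
content_to_concentration <- function(umol_per_g, specific_gravity = 1.05) {
  umol_per_g * specific_gravity
}

#' Coefficient of repeatability for a test-retest table
#'
#' \deqn{CR = 2.77 \sqrt{\frac{1}{n}\sum_i \sum_k (x_{ik} - \bar x_i)^2}}
#' over n subjects with two measurements each; the relative CR divides by
#' the grand mean.
#'
#' @param x numeric matrix or data.frame with two columns (measurement 1
#'   and 2, one row per subject).
#' @return list with `CR` and `rCR`.
#' @export
coefficient_of_repeatability <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2 || nrow(x) < 2 || anyNA(x))
    stop("need a complete n x 2 table with n >= 2 subjects")
  dev2 <- (x - rowMeans(x))^2
  cr <- 2.77 * sqrt(mean(rowSums(dev2)))
  list(CR = cr, rCR = cr / mean(x))
}

#' Bland-Altman agreement statistics
#'
#' Per-subject difference against mean, the bias (mean difference) and the
#' 95% limits of agreement `bias +/- 1.96 sd(differences)`.
#'
#' @inheritParams coefficient_of_repeatability
#' @return list with `bias`, `loa` (length 2), `sd`, and a `data`
#'   data.frame (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2)
  d <- x[, 1] - x[, 2]
  m <- rowMeans(x)
  s <- if (length(d) > 1) sd(d) else 0
  bias <- mean(d)
  list(bias = bias, sd = s, loa = bias + c(-1.96, 1.96) * s,
       data = data.frame(mean = m, diff = d))
}

#' Plot Bland-Altman agreement data
#'
#' @param ba result of [bland_altman()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_bland_altman <- function(ba, ...) {
  graphics::plot(ba$data$mean, ba$data$diff, xlab = "mean of measurements",
                 ylab = "difference", ...)
  graphics::abline(h = c(ba$bias, ba$loa), lty = c(1, 2, 2))
  invisible(ba)
}
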