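#' Apply a rigid transform directly in k-space
#'
#' A rigid motion of the object is corrected without regridding the data:
#' rotations rotate each projection's trajectory direction, and the
#' translation becomes a per-sample phase ramp
#' \deqn{G(R^T k) = S(k)\, e^{+2\pi i\, k \cdot t}}
#' so that the reconstructed image appears at the reference (fixed)
#' position.  The transform is the output of [register_rigid()] with the
#' bin image as moving and the reference-bin image as fixed; the rotation
#' centre is the image centre.  Sample magnitudes are untouched.
#'
#' @param kspace a `kspace_set`.
#' @param transform a [rigid_transform()].
#' @param proj_idx projections to correct (default all).
#' @return the corrected `kspace_set`.
#' @export
apply_rigid_kspace <- function(kspace, transform, proj_idx = NULL) {
  if (is.null(proj_idx)) proj_idx <- seq_len(dim(kspace$data)[2])
  R <- rotation_matrix(transform$rotation)
  dirs <- kspace$traj$dirs
  kt <- dirs[proj_idx, , drop = FALSE] %*% transform$translation
  phase <- exp(2i * pi * outer(kspace$traj$radii, as.vector(kt)))
  for (ch in seq_len(dim(kspace$data)[3])) {
    kspace$data[, proj_idx, ch] <- kspace$data[, proj_idx, ch] * phase
  }
  kspace$traj$dirs[proj_idx, ] <- dirs[proj_idx, , drop = FALSE] %*% R
  kspace
}

#' Respiratory motion correction in k-space
#'
#' The pipeline of the respiratory correction: reconstruct the 1H image of
#' every respiratory bin, rigidly register each to the exhaled reference
#' bin within the heart region, and apply each bin's transform to the
#' bin's k-space subsets of both nuclei.  All projections are kept; the
#' merged corrected k-space is reconstructed in the exhaled state.
#'
#' @param kspace_na,kspace_h composite `kspace_set`s.
#' @param bins_na,bins_h integer respiratory bin per projection (oriented
#'   so that `ref_bin` is the exhaled state).
#' @param grid,voxel_mm 1H reconstruction grid for the bin images.
#' @param heart_mask logical registration mask on that grid.
#' @param ref_bin reference (exhaled) bin.
#' @return list: corrected `kspace_na`, `kspace_h`, per-bin `transforms`.
#' @export
respiratory_correction <- function(kspace_na, kspace_h, bins_na, bins_h,
                                   grid, voxel_mm, heart_mask,
                                   ref_bin = max(bins_h),
                                   rot_penalty = 1e-3) {
  n_bins <- max(bins_h)
  ref_img <- h1_bias_correction(
    reconstruct(kspace_h, grid, voxel_mm,
                proj_idx = which(bins_h == ref_bin), frame = "exhaled"))
  body <- attr(ref_img, "body_mask")
  transforms <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    if (b == ref_bin) {
      transforms[[b]] <- rigid_transform()
      next
    }
    # the support-region bias correction flattens the static receive
    # shading that would otherwise bias the registration of the moving
    # heart through the coil profile
    img_b <- h1_bias_correction(
      reconstruct(kspace_h, grid, voxel_mm, proj_idx = which(bins_h == b),
                  frame = sprintf("bin%d", b)), body_mask = body)
    transforms[[b]] <- register_rigid(img_b, ref_img, heart_mask,
                                      rot_penalty = rot_penalty)
    kspace_na <- apply_rigid_kspace(kspace_na, transforms[[b]],
                                    which(bins_na == b))
    kspace_h <- apply_rigid_kspace(kspace_h, transforms[[b]],
                                   which(bins_h == b))
  }
  list(kspace_na = kspace_na, kspace_h = kspace_h, transforms = transforms)
}

#' Cardiac motion correction by deformation and averaging
#'
#' Warps the systolic images into the diastolic frame with the 1H-derived
#' deformation field and averages diastole and warped systole with weights
#' proportional to the projection counts of the two clusters, so the
#' result approximates an all-data reconstruction in the diastolic frame.
#' Warping operates on magnitude images.
#'
#' @param diastolic,systolic images (same grid).
#' @param field [register_nonrigid()] output (systole onto diastole).
#' @param n_dia,n_sys projection counts behind the two images.
#' @return corrected magnitude image tagged `frame = "diastole"`.
#' @export
cardiac_correction <- function(diastolic, systolic, field, n_dia, n_sys) {
  if (!all(dim(diastolic) == dim(systolic)) ||
      !all(dim(field)[1:3] == dim(diastolic)))
    stop("image/field grid mismatch")
  wsys <- warp_image(systolic, field)
  out <- (n_dia * abs_or_re(diastolic) + n_sys * abs_or_re(wsys)) /
    (n_dia + n_sys)
  out <- array(out, dim = dim(diastolic))
  attributes(out) <- attributes(diastolic)
  attr(out, "frame") <- "diastole"
  attr(out, "n_proj") <- n_dia + n_sys
  out
}
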