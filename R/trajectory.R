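#' 3D double golden-angle projection directions
#'
#' Unit vectors following the 3D golden-means scheme: for projection index
#' i, the polar coordinate is `z = 1 - 2 frac(i phi1)` and the azimuth
#' `theta = 2 pi frac(i phi2)` with `phi1 = 0.4656...`, `phi2 = 0.6823...`
#' (the two 3D golden means).  Any contiguous subset covers the sphere
#' near-uniformly, which is what makes motion-sorted reconstruction of
#' subsets possible.
#'
#' @param n_projections number of directions.
#' @return `n x 3` matrix of unit vectors (SI, AP, LR components).
#' @export
golden_angle_directions <- function(n_projections) {
  stopifnot(n_projections >= 1)
  phi1 <- 0.4656010700
  phi2 <- 0.6823278038
  i <- seq_len(n_projections) - 1
  z <- 1 - 2 * ((i * phi1) %% 1)
  th <- 2 * pi * ((i * phi2) %% 1)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(z, rho * cos(th), rho * sin(th), deparse.level = 0)
}

#' Radial readout description
#'
#' Uniform radial sampling from the k-space centre to `kmax = 0.5 /
#' nominal_mm` cycles/mm with an analytic `|k|^2` density compensation
#' (capped at DC).  Sample times are `TE + j * dwell`.
#'
#' @param n_projections number of projections (golden-angle ordered).
#' @param n_samples samples per projection.
#' @param dwell_us readout dwell time (microseconds).
#' @param TE_ms echo time of the first sample (ms).
#' @param nominal_mm nominal resolution; sets `kmax`.
#' @return `radial_trajectory` list: `dirs`, `radii` (cycles/mm),
#'   `t_ms` (per-sample time since excitation), `kmax`, `nominal_mm`.
#' @export
radial_trajectory <- function(n_projections, n_samples = 64, dwell_us = 25,
                              TE_ms = 1.15, nominal_mm = 6) {
  stopifnot(n_samples >= 2)
  kmax <- 0.5 / nominal_mm
  radii <- seq(0, kmax, length.out = n_samples)
  structure(list(dirs = golden_angle_directions(n_projections),
                 radii = radii,
                 t_ms = TE_ms + (seq_len(n_samples) - 1) * dwell_us * 1e-3,
                 kmax = kmax, nominal_mm = nominal_mm),
            class = "radial_trajectory")
}

# frequency coordinates (cycles/voxel) for a projection subset, ordered
# sample-fastest; M = n_samples * length(proj_idx)
traj_freq <- function(traj, voxel_mm, proj_idx = NULL) {
  if (is.null(proj_idx)) proj_idx <- seq_len(nrow(traj$dirs))
  f <- traj$radii * voxel_mm
  d <- traj$dirs[proj_idx, , drop = FALSE]
  cbind(rep(d[, 1], each = length(f)) * f,
        rep(d[, 2], each = length(f)) * f,
        rep(d[, 3], each = length(f)) * f)
}

# analytic quadrature (density compensation) weights in cycles/voxel units
# for one projection; total over all samples of all projections integrates
# the sampled k-space ball, so reconstructed intensities are on the scale
# of the underlying voxel values independent of the projection count.
dcf_weights <- function(traj, voxel_mm, n_proj) {
  rf <- traj$radii * voxel_mm
  dr <- rf[2] - rf[1]
  w <- rf^2 * dr * 4 * pi
  w[1] <- 4 * pi / 3 * (dr / 2)^3
  w / n_proj
}

# radial Hamming apodization over the acquired k-range
hamming_weights <- function(traj) {
  0.54 + 0.46 * cos(pi * traj$radii / traj$kmax)
}
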