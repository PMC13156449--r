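#' Rigid transform (translation + Euler rotation)
#'
#' Parameters map points of the fixed frame into the moving frame for
#' resampling: `x_mov = R (x_fix) + t` with world coordinates in mm about
#' the image centre and Euler order SI-AP-LR (rotations about the SI, AP
#' and LR axes applied in that order).
#'
#' @param translation length-3 translation (mm, SI/AP/LR).
#' @param rotation length-3 Euler angles (degrees).
#' @param reference tag of the fixed frame.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation = c(0, 0, 0), reference = "fixed") {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            all(rotation > -180), all(rotation <= 180))
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation), reference = reference),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: t = (%.2f, %.2f, %.2f) mm, r = (%.2f, %.2f, %.2f) deg>\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3]))
  invisible(x)
}

# rotation matrix for Euler angles (deg) about axes 1 (SI), 2 (AP), 3 (LR)
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  r1 <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])),
               3, 3)
  r2 <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])),
               3, 3)
  r3 <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1),
               3, 3)
  r1 %*% r2 %*% r3
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `t1` then `t2` as
#' resampling maps (`x -> R2(R1 x + t1) + t2` read right to left in the
#' fixed-to-moving direction).
#' @param t2,t1 `rigid_transform`s.
#' @export
compose_rigid <- function(t2, t1) {
  R1 <- rotation_matrix(t1$rotation)
  R2 <- rotation_matrix(t2$rotation)
  R <- R2 %*% R1
  tt <- as.vector(R2 %*% t1$translation) + t2$translation
  ang <- euler_from_matrix(R)
  rigid_transform(tt, ang, reference = t1$reference)
}

# recover SI-AP-LR Euler angles (deg) from a rotation matrix
# (R = R1(a) R2(b) R3(c) gives R[1,3] = sin b, R[2,3] = -sin a cos b,
#  R[3,3] = cos a cos b, R[1,2] = -cos b sin c, R[1,1] = cos b cos c)
euler_from_matrix <- function(R) {
  b <- asin(pmin(pmax(R[1, 3], -1), 1))
  a <- atan2(-R[2, 3], R[3, 3])
  c <- atan2(-R[1, 2], R[1, 1])
  c(a, b, c) * 180 / pi
}

# world coordinates (mm) of every voxel of a grid, M x 3
world_points <- function(grid, voxel_mm) {
  co <- grid_coords(grid, voxel_mm)
  cbind(rep(co$x, times = prod(grid[2:3])),
        rep(rep(co$y, each = grid[1]), times = grid[3]),
        rep(co$z, each = prod(grid[1:2])))
}

# sample a real volume at world points (mm) with trilinear interpolation
sample_world <- function(vol, voxel_mm, pts_mm, outside = 0) {
  d <- dim(vol)
  idx <- sweep(pts_mm / voxel_mm, 2, d / 2, "+")
  cpp_trilinear(as.vector(vol), d, idx, outside)
}

#' Resample an image through a rigid transform
#'
#' `out(x) = img(R x + t)` with trilinear interpolation (zero outside).
#' @param img 3D array with `voxel_mm` attribute (or supply `voxel_mm`).
#' @param transform a [rigid_transform()].
#' @param voxel_mm voxel size override.
#' @export
apply_rigid_image <- function(img, transform,
                              voxel_mm = attr(img, "voxel_mm")) {
  d <- dim(img)
  pts <- world_points(d, voxel_mm) %*% t(rotation_matrix(transform$rotation))
  pts <- sweep(pts, 2, transform$translation, "+")
  out <- array(sample_world(unclass(img), voxel_mm, pts), dim = d)
  attributes(out) <- attributes(img)
  out
}

# masked negative normalized cross-correlation between fixed values and
# moving image sampled at transformed points; optionally with the analytic
# gradient w.r.t. the six rigid parameters
ncc_cost <- function(par, mov, voxel_mm, pts_fix, fvals, grad_mov = NULL,
                     rot_penalty = 1e-6) {
  R <- rotation_matrix(par[4:6])
  pts <- pts_fix %*% t(R)
  pts <- sweep(pts, 2, par[1:3], "+")
  mvals <- sample_world(mov, voxel_mm, pts)
  n <- length(fvals)
  fc <- fvals - mean(fvals)
  mc <- mvals - mean(mvals)
  sf <- sqrt(sum(fc^2))
  sm <- sqrt(sum(mc^2))
  if (sm < .Machine$double.eps) return(list(value = 1, grad = rep(0, 6)))
  ncc <- sum(fc * mc) / (sf * sm)
  val <- -ncc + rot_penalty * sum(par[4:6]^2)
  if (is.null(grad_mov)) return(list(value = val, grad = NULL))
  dcost_dm <- -(fc / (sf * sm) - ncc * mc / sm^2)
  # gradient of the moving image (per mm) at the transformed points
  G <- vapply(1:3, function(a)
    sample_world(grad_mov[[a]], voxel_mm, pts) / voxel_mm, numeric(n))
  gt <- colSums(dcost_dm * G)
  gr <- vapply(1:3, function(k) {
    dR <- rotation_deriv(par[4:6], k)
    dp <- pts_fix %*% t(dR)
    sum(dcost_dm * rowSums(G * dp))
  }, numeric(1))
  list(value = val, grad = c(gt, gr + 2 * rot_penalty * par[4:6]))
}

# derivative of the rotation matrix w.r.t. Euler angle k (per degree)
rotation_deriv <- function(angles_deg, k, h = 1e-4) {
  ap <- am <- angles_deg
  ap[k] <- ap[k] + h
  am[k] <- am[k] - h
  (rotation_matrix(ap) - rotation_matrix(am)) / (2 * h)
}

# block-mean downsampling by an integer factor (crops to a multiple)
downsample3 <- function(x, f) {
  if (f == 1) return(x)
  d <- dim(x) %/% f * f
  x <- x[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  dd <- d %/% f
  a <- array(x, dim = c(f, dd[1], f, dd[2], f, dd[3]))
  apply(a, c(2, 4, 6), mean)
}

#' Rigid registration by masked normalized cross-correlation
#'
#' Multi-resolution (3 levels) Nelder-Mead maximization of the NCC between
#' the fixed image and the moving image resampled over the heart mask.
#' Returns the transform that maps fixed-frame points into the moving
#' image, i.e. `apply_rigid_image(moving, transform)` aligns the moving
#' image to the fixed one.
#'
#' @param moving,fixed images on the same grid (`voxel_mm` attribute).
#' @param mask logical mask defining the registration region.
#' @param levels downsampling factors, coarse to fine.
#' @param max_rot rotation search bound (deg).
#' @param rot_penalty quadratic penalty weight on the Euler angles; a
#'   firmer prior (e.g. `1e-3`) stabilizes registration of structures
#'   with little rotational information.
#' @return a [rigid_transform()] with attribute `ncc` (final correlation).
#' @export
register_rigid <- function(moving, fixed, mask, levels = c(4, 2, 1),
                           max_rot = 20, rot_penalty = 1e-6) {
  stopifnot(all(dim(moving) == dim(fixed)), any(mask))
  voxel_mm <- attr(fixed, "voxel_mm")
  if (is.null(voxel_mm)) stop("fixed image needs a voxel_mm attribute")
  mov <- abs_or_re(moving)
  fix <- abs_or_re(fixed)
  levels <- levels[vapply(levels, function(f) all(dim(fix) %/% f >= 16),
                          logical(1))]
  if (!length(levels)) levels <- 1
  # initialize the translation by a coarse exhaustive search (the capture
  # range of the gradient-based refinement is about one voxel)
  f0 <- levels[1]
  mv0 <- gauss_filter3(downsample3(mov, f0), 1.0)
  fx0 <- gauss_filter3(downsample3(fix, f0), 1.0)
  mk0 <- downsample3(mask + 0, f0) > 0.25
  if (!any(mk0)) mk0 <- downsample3(mask + 0, f0) > 0
  pts0 <- world_points(dim(fx0), voxel_mm * f0)[as.vector(mk0), ,
                                                drop = FALSE]
  fv0 <- fx0[mk0]
  step <- voxel_mm * f0
  cand <- as.matrix(expand.grid(seq(-3, 3) * step, seq(-3, 3) * step,
                                seq(-3, 3) * step))
  cc <- apply(cand, 1, function(tr)
    ncc_cost(c(tr, 0, 0, 0), mv0, voxel_mm * f0, pts0, fv0,
             rot_penalty = rot_penalty)$value)
  par <- c(cand[which.min(cc), ], 0, 0, 0)
  for (f in levels) {
    # equal smoothing of both images removes the asymmetric interpolation
    # blur that otherwise biases the metric toward the identity
    mv <- gauss_filter3(downsample3(mov, f), 1.0)
    fx <- gauss_filter3(downsample3(fix, f), 1.0)
    mk <- downsample3(mask + 0, f) > 0.25
    if (!any(mk)) mk <- downsample3(mask + 0, f) > 0
    vm <- voxel_mm * f
    pts <- world_points(dim(fx), vm)[as.vector(mk), , drop = FALSE]
    fvals <- fx[mk]
    gm <- lapply(1:3, function(a) central_diff(mv, a))
    env <- new.env()
    fn <- function(p) {
      r <- ncc_cost(p, mv, vm, pts, fvals, grad_mov = gm,
                    rot_penalty = rot_penalty)
      env$g <- r$grad
      r$value
    }
    gr <- function(p) env$g
    opt <- optim(par, fn, gr, method = "BFGS",
                 control = list(maxit = 150, reltol = 1e-10))
    # simplex polish: the sampled-gradient line search stalls once the
    # cost differences reach the interpolation noise floor
    opt <- optim(opt$par, function(p)
      ncc_cost(p, mv, vm, pts, fvals, rot_penalty = rot_penalty)$value,
      method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-11,
                     parscale = c(rep(1, 3), rep(0.5, 3))))
    par <- opt$par
  }
  if (any(abs(par[4:6]) > max_rot))
    stop("rigid registration did not converge (rotation out of bounds)")
  structure(rigid_transform(par[1:3], par[4:6]), ncc = -opt$value)
}

abs_or_re <- function(x) {
  if (is.complex(x)) array(Mod(x), dim = dim(x)) else unclass(x)
}
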