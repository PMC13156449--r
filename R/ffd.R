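#' Nonrigid B-spline registration and deformation fields
#'
#' Free-form deformation on a cubic B-spline control grid, optimized by
#' L-BFGS with an analytic gradient of the masked normalized
#' cross-correlation plus a bending-energy penalty on the control
#' coefficients.  The estimated field maps the fixed frame into the moving
#' image: `warp_image(moving, field)` aligns the moving image to the fixed
#' one (for cardiac correction: fixed = diastole, moving = systole).
#'
#' @name ffd
NULL

# cubic B-spline basis value, support |s| < 2
bspline3 <- function(s) {
  s <- abs(s)
  ifelse(s < 1, (4 - 6 * s^2 + 3 * s^3) / 6,
         ifelse(s < 2, (2 - s)^3 / 6, 0))
}

# dense per-axis basis matrix: positions 0..(n-1) against knots spaced
# `delta` voxels starting at -delta
bspline_basis <- function(n, delta) {
  K <- ceiling((n - 1) / delta) + 3
  knots <- ((seq_len(K)) - 2) * delta
  outer((0:(n - 1)), knots, function(x, k) bspline3((x - k) / delta))
}

# mode-n tensor product: apply matrix B (n x K) along dimension a of C
ttm <- function(C, B, a) {
  d <- dim(C)
  perm <- c(a, setdiff(1:3, a))
  M <- matrix(aperm(C, perm), nrow = d[a])
  out <- B %*% M
  aperm(array(out, dim = c(nrow(B), d[perm[2]], d[perm[3]])),
        order(perm))
}

# evaluate the displacement field (voxels) from control coefficients
ffd_field <- function(coef3, Bs) {
  lapply(1:3, function(dd)
    ttm(ttm(ttm(coef3[[dd]], Bs[[1]], 1), Bs[[2]], 2), Bs[[3]], 3))
}

# adjoint projection of a voxel-wise field onto control space
ffd_project <- function(vol3, Bs) {
  lapply(vol3, function(v)
    ttm(ttm(ttm(v, t(Bs[[1]]), 1), t(Bs[[2]]), 2), t(Bs[[3]]), 3))
}

second_diff_penalty <- function(C) {
  pen <- 0
  grad <- array(0, dim = dim(C))
  for (a in 1:3) {
    if (dim(C)[a] < 3) next
    perm <- c(a, setdiff(1:3, a))
    M <- matrix(aperm(C, perm), nrow = dim(C)[a])
    D <- diff(M, differences = 2)
    pen <- pen + sum(D^2)
    G <- matrix(0, nrow(M), ncol(M))
    n <- nrow(M)
    G[1:(n - 2), ] <- G[1:(n - 2), ] + D
    G[2:(n - 1), ] <- G[2:(n - 1), ] - 2 * D
    G[3:n, ] <- G[3:n, ] + D
    grad <- grad + aperm(array(G, dim = dim(C)[perm]), order(perm))
  }
  list(pen = pen, grad = 2 * grad)
}

#' Upsample a deformation field to a finer grid
#'
#' Trilinear interpolation of each displacement component onto a grid
#' refined by an integer factor (matching [zero_fill()] of the image it
#' will warp); displacements stay in mm.
#'
#' @param field `deformation_field` array (nx, ny, nz, 3).
#' @param factor integer refinement factor.
#' @export
resample_field <- function(field, factor = 2) {
  d <- dim(field)[1:3]
  voxel_mm <- attr(field, "voxel_mm")
  df <- d * factor
  idx <- as.matrix(expand.grid(0:(df[1] - 1), 0:(df[2] - 1),
                               0:(df[3] - 1)))
  # fine voxel centre in coarse 0-based index coordinates
  pts <- cbind((idx[, 1] - df[1] / 2) / factor + d[1] / 2,
               (idx[, 2] - df[2] / 2) / factor + d[2] / 2,
               (idx[, 3] - df[3] / 2) / factor + d[3] / 2)
  pts <- pmin(pmax(pts, 0), matrix(rep(d - 1, each = nrow(pts)), ncol = 3))
  out <- array(0, dim = c(df, 3))
  for (dd in 1:3) {
    out[, , , dd] <- array(cpp_trilinear(as.vector(field[, , , dd]), d,
                                         pts, 0), dim = df)
  }
  attr(out, "voxel_mm") <- voxel_mm / factor
  class(out) <- c("deformation_field", "array")
  out
}

#' Warp an image through a deformation field
#'
#' `out(x) = img(x + u(x))` with trilinear interpolation; complex images
#' are warped on their magnitude (phase is not preserved by nonrigid
#' resampling).
#'
#' @param img 3D array.
#' @param field `deformation_field` (mm) from [register_nonrigid()].
#' @param voxel_mm voxel size override.
#' @export
warp_image <- function(img, field, voxel_mm = attr(field, "voxel_mm")) {
  d <- dim(img)
  stopifnot(all(dim(field)[1:3] == d))
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  u <- matrix(field, ncol = 3) / voxel_mm
  pts <- idx + u
  vol <- abs_or_re(img)
  out <- array(cpp_trilinear(as.vector(vol), d, pts, 0), dim = d)
  attributes(out) <- attributes(img)
  out
}

# central-difference derivative of a 3D array along axis a
central_diff <- function(u, a) {
  d <- dim(u)
  g <- array(0, dim = d)
  n <- d[a]
  if (a == 1) g[2:(n - 1), , ] <- (u[3:n, , ] - u[1:(n - 2), , ]) / 2
  if (a == 2) g[, 2:(n - 1), ] <- (u[, 3:n, ] - u[, 1:(n - 2), ]) / 2
  if (a == 3) g[, , 2:(n - 1)] <- (u[, , 3:n] - u[, , 1:(n - 2)]) / 2
  g
}

# minimum Jacobian determinant of x + u(x) over a mask (finite differences)
field_min_jacobian <- function(field, voxel_mm, mask) {
  d <- dim(field)[1:3]
  g <- function(dd, a) central_diff(array(field[, , , dd] / voxel_mm,
                                          dim = d), a)
  g11 <- g(1, 1); g12 <- g(1, 2); g13 <- g(1, 3)
  g21 <- g(2, 1); g22 <- g(2, 2); g23 <- g(2, 3)
  g31 <- g(3, 1); g32 <- g(3, 2); g33 <- g(3, 3)
  J <- (1 + g11) * ((1 + g22) * (1 + g33) - g23 * g32) -
    g12 * (g21 * (1 + g33) - g23 * g31) +
    g13 * (g21 * g32 - (1 + g22) * g31)
  min(J[mask])
}

#' Nonrigid B-spline registration
#'
#' Multi-resolution free-form deformation maximizing the masked normalized
#' cross-correlation with a bending-energy penalty; see [ffd].  Errors if
#' the resulting map folds (non-positive Jacobian) inside the mask.
#'
#' @param moving,fixed images on one grid (`voxel_mm` attribute on fixed).
#' @param mask logical mask (metric region).
#' @param spacing_vox control-point spacings in voxels, coarse to fine.
#' @param lambda bending-energy weight.
#' @param maxit L-BFGS iterations per level.
#' @return `deformation_field`: array `dim(fixed) x 3` of displacements in
#'   mm with attributes `voxel_mm` and `ncc`.
#' @export
register_nonrigid <- function(moving, fixed, mask, spacing_vox = c(8, 4),
                              lambda = 1e-3, maxit = 40, margin_vox = 8) {
  stopifnot(all(dim(moving) == dim(fixed)), any(mask))
  voxel_mm <- attr(fixed, "voxel_mm")
  if (is.null(voxel_mm)) stop("fixed image needs a voxel_mm attribute")
  full_dim <- dim(fixed)
  # optimize on the mask bounding box (plus margin); the field is zero
  # outside, where the metric carries no information anyway
  bb <- lapply(1:3, function(a) {
    r <- range(which(apply(mask, a, any)))
    max(1, r[1] - margin_vox):min(full_dim[a], r[2] + margin_vox)
  })
  crop <- function(x) x[bb[[1]], bb[[2]], bb[[3]]]
  mov <- crop(abs_or_re(moving))
  fix <- crop(abs_or_re(fixed))
  mask <- crop(mask)
  d <- dim(fix)
  sc <- max(abs(fix))
  mov <- mov / sc
  fix <- fix / sc
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  mvec <- as.vector(mask)
  f <- fix[mask]
  fc <- f - mean(f)
  sf <- sqrt(sum(fc^2))
  # image gradients of the moving image (central differences, voxel units)
  grad_m <- lapply(1:3, function(a) central_diff(mov, a))
  coef3 <- NULL
  for (sp in spacing_vox) {
    Bs <- lapply(1:3, function(a) bspline_basis(d[a], sp))
    Kd <- vapply(Bs, ncol, integer(1))
    if (is.null(coef3)) {
      coef3 <- lapply(1:3, function(i) array(0, dim = Kd))
    } else {
      # resample previous field onto the new control grid by projection
      u_prev <- ffd_field(coef3_prev, Bs_prev)
      coef3 <- fit_coefficients(u_prev, Bs)
    }
    npar <- prod(Kd)
    unpack <- function(p) lapply(1:3, function(i)
      array(p[((i - 1) * npar + 1):(i * npar)], dim = Kd))
    cost_grad <- function(p) {
      cf <- unpack(p)
      u <- ffd_field(cf, Bs)
      pts <- idx + cbind(as.vector(u[[1]]), as.vector(u[[2]]),
                         as.vector(u[[3]]))
      w <- cpp_trilinear(as.vector(mov), d, pts, 0)
      wm <- w[mvec]
      wc <- wm - mean(wm)
      sw <- sqrt(sum(wc^2))
      if (sw < 1e-12) return(list(value = 1, grad = rep(0, 3 * npar)))
      ncc <- sum(fc * wc) / (sf * sw)
      dmetric_dw <- -(fc / (sf * sw) - ncc * wc / sw^2)
      dvol <- numeric(prod(d))
      dvol[mvec] <- dmetric_dw
      dvol <- array(dvol, dim = d)
      gval <- -ncc
      gvec <- numeric(3 * npar)
      for (dd in 1:3) {
        gs <- cpp_trilinear(as.vector(grad_m[[dd]]), d, pts, 0)
        gfield <- array(dvol * array(gs, dim = d), dim = d)
        proj <- ffd_project(list(gfield), Bs)[[1]]
        pen <- second_diff_penalty(cf[[dd]])
        gval <- gval + lambda * pen$pen
        gvec[((dd - 1) * npar + 1):(dd * npar)] <-
          as.vector(proj) + lambda * as.vector(pen$grad)
      }
      list(value = gval, grad = gvec)
    }
    env <- new.env()
    fn <- function(p) {
      r <- cost_grad(p)
      env$g <- r$grad
      r$value
    }
    gr <- function(p) env$g
    p0 <- unlist(coef3)
    opt <- optim(p0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e10))
    coef3 <- unpack(opt$par)
    coef3_prev <- coef3
    Bs_prev <- Bs
  }
  u <- ffd_field(coef3, Bs_prev)
  field <- array(0, dim = c(full_dim, 3))
  for (dd in 1:3) {
    sub <- array(0, dim = full_dim)
    sub[bb[[1]], bb[[2]], bb[[3]]] <- u[[dd]] * voxel_mm
    field[, , , dd] <- sub
  }
  attr(field, "voxel_mm") <- voxel_mm
  attr(field, "ncc") <- -opt$value
  class(field) <- c("deformation_field", "array")
  full_mask <- array(FALSE, dim = full_dim)
  full_mask[bb[[1]], bb[[2]], bb[[3]]] <- mask
  mj <- field_min_jacobian(field, voxel_mm, full_mask)
  attr(field, "min_jacobian") <- mj
  if (mj <= 0)
    stop("deformation field folds inside the mask (Jacobian <= 0)")
  field
}

# least-squares fit of control coefficients to a voxelwise field
# (separable normal equations per axis)
fit_coefficients <- function(u, Bs) {
  P <- lapply(Bs, function(B) solve(crossprod(B) + 1e-8 * diag(ncol(B)),
                                    t(B)))
  lapply(u, function(v) ttm(ttm(ttm(v, P[[1]], 1), P[[2]], 2), P[[3]], 3))
}
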