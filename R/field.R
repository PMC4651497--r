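#' Dense nonlinear displacement field
#'
#' Per-voxel 3-component displacement vectors in mm, stored as a 4D array
#' (x, y, z, component) on the same axis-aligned grid convention as
#' [sq_volume()]. Fields act in the pull (backward-sampling) convention used by
#' standard resamplers: the resampled image takes, at output voxel `v`, the
#' input value sampled at `v + d(v)`. This is stated explicitly because image
#' registration literature uses both conventions interchangeably.
#'
#' @param vectors 4D numeric array, last dimension of length 3 (mm).
#' @param spacing,origin Grid geometry as in [sq_volume()].
#' @return An object of class `sq_field`.
#' @export
sq_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L) {
    stop_bad_arg("`vectors` must be a 4D array with 3 components on the last axis")
  }
  if (any(!is.finite(vectors))) stop_bad_arg("displacements must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop_bad_arg("voxel spacing must be positive")
  structure(list(vectors = vectors, spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "sq_field")
}

#' @export
print.sq_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<sq_field> %s, spacing %s mm, |d| max %.3g mm, RMS %.3g mm\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              max(mag), sqrt(mean(mag^2))))
  invisible(x)
}

#' @rdname sq_field
#' @param dims Grid dimensions (length 3) for the constructors.
#' @export
zero_field <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  sq_field(array(0, c(dims, 3L)), spacing = spacing, origin = origin)
}

#' @rdname sq_field
#' @param shift_mm Length-3 constant displacement in mm.
#' @export
constant_field <- function(dims, shift_mm, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  v <- array(0, c(dims, 3L))
  for (a in 1:3) v[, , , a] <- shift_mm[a]
  sq_field(v, spacing = spacing, origin = origin)
}

# ---- low-level samplers -----------------------------------------------------

# x, y, z: fractional 1-based voxel coordinates (equal-length vectors).
# Returns sampled values with `fill` wherever the sample point falls outside
# [1, n] on any axis. Compiled kernels; logical/integer arrays are coerced.
sample_trilinear <- function(data, x, y, z, fill = 0) {
  storage.mode(data) <- "double"
  cpp_sample_trilinear(data, as.integer(dim(data)), as.double(x), as.double(y),
                       as.double(z), as.double(fill))
}

sample_nearest <- function(data, x, y, z, fill = 0) {
  was_logical <- is.logical(data)
  storage.mode(data) <- "double"
  out <- cpp_sample_nearest(data, as.integer(dim(data)), as.double(x),
                            as.double(y), as.double(z), as.double(fill))
  if (was_logical) out <- out != 0
  out
}

# Full-grid 1-based voxel coordinate vectors for a given dim.
grid_coords <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  list(x = rep.int(seq_len(nx), ny * nz),
       y = rep.int(rep(seq_len(ny), each = nx), nz),
       z = rep(seq_len(nz), each = nx * ny))
}

# Sample a field's three components (linearly) at fractional voxel coords;
# returns a list of three vectors in mm. Coordinates are clamped to the grid
# (a displacement field extends continuously to the border; zero-filling would
# create artificial discontinuities that destabilise composition/inversion).
sample_field_at <- function(field, x, y, z) {
  dn <- dim(field$vectors)[1:3]
  x <- pmin(pmax(x, 1), dn[1])
  y <- pmin(pmax(y, 1), dn[2])
  z <- pmin(pmax(z, 1), dn[3])
  lapply(1:3, function(a) {
    sample_trilinear(field$vectors[, , , a], x, y, z, fill = 0)
  })
}

# ---- resampling -------------------------------------------------------------

#' Resample a volume through a displacement field
#'
#' Pull convention: output voxel `v` takes the input value sampled at
#' `v + d(v)` (displacement converted from mm to voxel units per axis). Sample
#' points outside the input domain take `fill`. Mask volumes must use nearest
#' neighbour interpolation; requesting linear interpolation for a mask is an
#' error, protecting the binarity and pairwise disjointness of tissue masks.
#'
#' @param vol Input `sq_volume`.
#' @param field `sq_field` on the same grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Value for out-of-domain samples.
#' @return A resampled `sq_volume` on the field's grid.
#' @export
apply_displacement <- function(vol, field, interpolation = c("linear", "nearest"),
                               fill = 0) {
  interpolation <- match.arg(interpolation)
  check_same_grid(vol, field, "volume and field")
  if (is_mask(vol) && interpolation == "linear") {
    stop_bad_arg("linear interpolation would break mask binarity; use nearest")
  }
  dims <- dim(vol$data)
  g <- grid_coords(dims)
  x <- g$x + as.vector(field$vectors[, , , 1]) / vol$spacing[1]
  y <- g$y + as.vector(field$vectors[, , , 2]) / vol$spacing[2]
  z <- g$z + as.vector(field$vectors[, , , 3]) / vol$spacing[3]
  dat <- if (interpolation == "linear") {
    sample_trilinear(vol$data, x, y, z, fill = fill)
  } else {
    sample_nearest(vol$data, x, y, z, fill = fill)
  }
  dim(dat) <- dims
  sq_volume(dat, spacing = vol$spacing, origin = vol$origin, type = vol$type)
}

resample_seg <- function(seg, field) {
  sq_seg(apply_displacement(seg$wm, field, "nearest", fill = 0),
         apply_displacement(seg$gm, field, "nearest", fill = 0),
         apply_displacement(seg$csf, field, "nearest", fill = 0))
}

#' Compose two displacement fields
#'
#' Returns the field whose application equals applying `inner` first and
#' `outer` second, i.e. `apply(compose(outer, inner), V) ==
#' apply(outer, apply(inner, V))` up to interpolation error. In the pull
#' convention this is `d(v) = outer(v) + inner(v + outer(v))`.
#'
#' @param outer,inner `sq_field`s on one grid.
#' @return The composite `sq_field`.
#' @export
compose_fields <- function(outer, inner) {
  check_same_grid(outer, inner, "fields")
  dims <- dim(outer$vectors)[1:3]
  g <- grid_coords(dims)
  x <- g$x + as.vector(outer$vectors[, , , 1]) / outer$spacing[1]
  y <- g$y + as.vector(outer$vectors[, , , 2]) / outer$spacing[2]
  z <- g$z + as.vector(outer$vectors[, , , 3]) / outer$spacing[3]
  s <- sample_field_at(inner, x, y, z)
  v <- array(0, c(dims, 3L))
  for (a in 1:3) v[, , , a] <- outer$vectors[, , , a] + s[[a]]
  sq_field(v, spacing = outer$spacing, origin = outer$origin)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `inv` with `(id + inv) = (id + field)^{-1}`, so that
#' `compose_fields(field, inv)` is (numerically) the zero field. Valid for
#' smooth, non-folding fields (positive Jacobian determinant of `id + field`).
#'
#' @param field `sq_field` to invert.
#' @param tol Acceptance tolerance on the residual displacement of
#'   `compose(field, inverse)`, in voxel units. The default 0.1 voxel reflects
#'   the accuracy attainable by a grid-sampled inverse under trilinear
#'   interpolation for fields of a few mm at a few-voxel smoothness scale;
#'   the residual is interpolation-limited, not iteration-limited.
#' @param max_iter Maximum fixed-point iterations.
#' @param mask Optional `sq_volume` mask; the residual criterion is evaluated
#'   inside the mask only (the inverse is still computed everywhere).
#' @return The inverse `sq_field`.
#' @export
invert_field <- function(field, tol = 0.1, max_iter = 50, mask = NULL) {
  dims <- dim(field$vectors)[1:3]
  g <- grid_coords(dims)
  inv <- -field$vectors
  sel <- if (is.null(mask)) TRUE else as.vector(mask$data)
  min_sp <- min(field$spacing)
  # damped fixed point: inv <- (1-a) inv + a (-f(v + inv)); plain iteration
  # (a = 1) is only contractive for |grad d| < 1, damping extends the range
  alpha <- 0.5
  for (iter in seq_len(max_iter)) {
    x <- g$x + as.vector(inv[, , , 1]) / field$spacing[1]
    y <- g$y + as.vector(inv[, , , 2]) / field$spacing[2]
    z <- g$z + as.vector(inv[, , , 3]) / field$spacing[3]
    s <- sample_field_at(field, x, y, z)
    delta <- pmax(abs(s[[1]] + as.vector(inv[, , , 1])),
                  abs(s[[2]] + as.vector(inv[, , , 2])),
                  abs(s[[3]] + as.vector(inv[, , , 3])))
    inv[, , , 1] <- (1 - alpha) * inv[, , , 1] - alpha * s[[1]]
    inv[, , , 2] <- (1 - alpha) * inv[, , , 2] - alpha * s[[2]]
    inv[, , , 3] <- (1 - alpha) * inv[, , , 3] - alpha * s[[3]]
    if (max(delta[sel]) / min_sp < tol / 4) break
  }
  invf <- sq_field(inv, spacing = field$spacing, origin = field$origin)
  comp <- compose_fields(field, invf)
  resid <- pmax(abs(as.vector(comp$vectors[, , , 1])) / field$spacing[1],
                abs(as.vector(comp$vectors[, , , 2])) / field$spacing[2],
                abs(as.vector(comp$vectors[, , , 3])) / field$spacing[3])
  resid <- max(resid[sel])
  if (resid > tol) {
    stop_bad_arg(sprintf(
      "field inversion did not converge: residual %.4f voxels after %d iterations (tol %.3f)",
      resid, max_iter, tol))
  }
  invf
}

# ---- smooth random fields ---------------------------------------------------

# Zero-padded separable Gaussian smoothing of a 3D array.
gaussian_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, axis)
  }
  arr
}

# 1D convolution along `axis` with zero padding, FFT-based ("same" part of the
# full linear convolution).
convolve_axis <- function(arr, kernel, axis) {
  dn <- dim(arr)
  n <- dn[axis]
  r <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dim(a) <- c(n, prod(dn[perm][2:3]))
  L <- stats::nextn(n + length(kernel) - 1L)
  kf <- stats::fft(c(kernel, rep(0, L - length(kernel))))
  af <- stats::mvfft(rbind(a, matrix(0, L - n, ncol(a))))
  conv <- Re(stats::mvfft(af * kf, inverse = TRUE)) / L
  out <- conv[(r + 1):(r + n), , drop = FALSE]
  dim(out) <- dn[perm]
  aperm(out, order(perm))
}

# Cosine taper to zero over `margin` voxels at both ends of each axis; keeps
# random deformations from pushing sample points across the grid border, where
# a deformation of head anatomy has no physical meaning anyway.
edge_taper <- function(dims, margin = 4L) {
  w1 <- function(n) {
    w <- rep(1, n)
    m <- min(margin, floor(n / 2))
    if (m > 0) {
      # exact zero at the outermost voxel
      ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / m))
      w[seq_len(m)] <- ramp
      w[n + 1 - seq_len(m)] <- ramp
    }
    w
  }
  wx <- w1(dims[1]); wy <- w1(dims[2]); wz <- w1(dims[3])
  outer(outer(wx, wy), wz)
}

#' Random smooth displacement field
#'
#' I.i.d. Gaussian vector noise smoothed with a Gaussian kernel of the given
#' spatial scale, then rescaled so that the root-mean-square displacement
#' magnitude (over `mask` if given, else the whole grid) equals
#' `amplitude_mm`. This is the package's model of smooth anatomical
#' variability and of residual registration error.
#'
#' @param dims Grid dimensions.
#' @param spacing,origin Grid geometry (mm).
#' @param amplitude_mm Target RMS displacement magnitude in mm (0 gives the
#'   zero field).
#' @param smoothness_mm Gaussian smoothing scale in mm (> 0).
#' @param mask Optional `sq_volume` mask over which the RMS is normalised.
#' @param seed Integer seed (deterministic output).
#' @return An `sq_field`.
#' @export
random_smooth_field <- function(dims, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                                amplitude_mm = 1, smoothness_mm = 6,
                                mask = NULL, seed = 1L) {
  if (smoothness_mm <= 0) stop_bad_arg("`smoothness_mm` must be > 0")
  if (amplitude_mm < 0) stop_bad_arg("`amplitude_mm` must be >= 0")
  if (amplitude_mm == 0) return(zero_field(dims, spacing, origin))
  sigma_vox <- smoothness_mm / rep_len(as.numeric(spacing), 3L)
  v <- with_seed(seed, array(stats::rnorm(prod(dims) * 3), c(dims, 3L)))
  # taper the noise before smoothing (preserves the smoothness scale) and the
  # result gently after, so displacements vanish at the grid border without
  # introducing gradients steeper than the smoothing scale allows
  pre <- edge_taper(dims, margin = 6L)
  post <- edge_taper(dims, margin = 4L)
  for (a in 1:3) {
    v[, , , a] <- gaussian_smooth3(v[, , , a] * pre, sigma_vox) * post
  }
  mag2 <- v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2
  sel <- if (is.null(mask)) TRUE else mask$data
  rms <- sqrt(mean(mag2[sel]))
  if (rms == 0) stop_bad_arg("degenerate random field (zero RMS)")
  sq_field(v * (amplitude_mm / rms), spacing = spacing, origin = origin)
}

# Minimum Jacobian determinant of (id + field) over the grid, displacement in
# voxel units, central differences. Non-positive values indicate grid folding.
min_jacobian <- function(field) {
  dims <- dim(field$vectors)[1:3]
  J <- vector("list", 9)
  for (a in 1:3) {
    da <- field$vectors[, , , a] / field$spacing[a]
    for (b in 1:3) {
      g <- central_diff(da, b)
      J[[(a - 1) * 3 + b]] <- g + (a == b)
    }
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
         J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
         J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  min(det)
}

central_diff <- function(arr, axis) {
  dn <- dim(arr)
  n <- dn[axis]
  idx <- lapply(dn, seq_len)
  ip <- idx; im <- idx
  ip[[axis]] <- pmin(seq_len(n) + 1L, n)
  im[[axis]] <- pmax(seq_len(n) - 1L, 1L)
  # step is 2 in the interior, 1 at the borders (one-sided differences)
  h <- pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L)
  num <- arr[ip[[1]], ip[[2]], ip[[3]]] - arr[im[[1]], im[[2]], im[[3]]]
  sweep(num, axis, h, "/")
}

# ---- point tracking ---------------------------------------------------------

#' Track a voxel through a transform
#'
#' Maps a labeled voxel to its location under a (forward) displacement field:
#' `world-style` continuous coordinates `v + d(v)/spacing` plus the nearest
#' voxel index. Note the pull-convention fields used for resampling map target
#' voxels to source locations; to follow a source voxel into target space,
#' pass the inverted field (see [invert_field()]).
#'
#' @param voxel Length-3 (1-based) voxel index, inside the grid.
#' @param field An `sq_field`.
#' @return A list with `position` (fractional voxel coordinates), `index`
#'   (nearest voxel index), `world_mm`, and `out_of_domain` flag.
#' @export
track_voxel <- function(voxel, field) {
  dims <- dim(field$vectors)[1:3]
  voxel <- as.numeric(voxel)
  if (length(voxel) != 3L || any(voxel < 1) || any(voxel > dims)) {
    stop_bad_arg("`voxel` must be a length-3 index inside the grid")
  }
  d <- vapply(sample_field_at(field, voxel[1], voxel[2], voxel[3]), identity,
              numeric(1))
  pos <- voxel + d / field$spacing
  idx <- round(pos)
  out <- any(idx < 1) || any(idx > dims)
  list(position = pos,
       index = pmin(pmax(idx, 1), dims),
       world_mm = field$origin + (pos - 1) * field$spacing,
       out_of_domain = out)
}

# ---- I/O --------------------------------------------------------------------

#' Read / write displacement fields as 4D NIfTI
#'
#' The vector component is stored on the 4th axis, values in mm.
#'
#' @param field An `sq_field`.
#' @param path File path.
#' @return `read_field()` returns an `sq_field`.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  sq_field(array(as.numeric(img), dim = dim(img)), spacing = spacing)
}
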