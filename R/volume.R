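#' 3D scalar volume
#'
#' A minimal array-backed image container: a 3D numeric (or logical, for masks)
#' array plus per-axis voxel spacing in mm and a world-space origin. The
#' voxel-to-world mapping is `world = origin + (index - 1) * spacing` with
#' 1-based voxel indices, i.e. an axis-aligned affine; oblique orientations are
#' out of scope for the phantom pipeline.
#'
#' @param data 3D array (numeric, or logical/0-1 for masks).
#' @param spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin Numeric length-3, world coordinates of voxel (1,1,1) in mm.
#' @param type `"scalar"` for intensity images, `"mask"` for binary masks.
#'   Masks refuse linear interpolation during resampling.
#' @return An object of class `sq_volume`.
#' @export
#' @examples
#' v <- sq_volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' dim(v)
sq_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      type = c("scalar", "mask")) {
  type <- match.arg(type)
  if (length(dim(data)) != 3L) stop_bad_arg("`data` must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_bad_arg("voxel spacing must be finite and positive")
  }
  if (type == "mask") {
    storage.mode(data) <- "logical"
    data[is.na(data)] <- FALSE
  }
  structure(list(data = data, spacing = spacing, origin = origin, type = type),
            class = "sq_volume")
}

#' @export
dim.sq_volume <- function(x) dim(x$data)

#' @export
print.sq_volume <- function(x, ...) {
  cat(sprintf("<sq_volume %s> %s, spacing %s mm, range [%.4g, %.4g]\n",
              x$type, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE))))
  invisible(x)
}

is_mask <- function(vol) inherits(vol, "sq_volume") && vol$type == "mask"

# Shared-grid check used by every pairwise volume/field operation.
same_grid <- function(a, b) {
  identical(dim(a$data %||% a$vectors)[1:3], dim(b$data %||% b$vectors)[1:3]) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop_bad_arg("grid mismatch between ", what)
  invisible(TRUE)
}

#' Convert voxel indices to world coordinates
#'
#' @param vol An `sq_volume` (or any object with `spacing` and `origin`).
#' @param voxel Numeric vector of length 3 or an n-by-3 matrix of (possibly
#'   fractional) 1-based voxel indices.
#' @return World coordinates in mm, same shape as `voxel`.
#' @export
world_from_voxel <- function(vol, voxel) {
  v <- rbind(voxel)
  w <- sweep(sweep(v - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  if (is.null(dim(voxel))) drop(w) else w
}

#' Convert world coordinates to (fractional) voxel indices
#'
#' @inheritParams world_from_voxel
#' @param world World coordinates in mm (length 3 or n-by-3 matrix).
#' @return 1-based fractional voxel indices.
#' @export
voxel_from_world <- function(vol, world) {
  w <- rbind(world)
  v <- sweep(sweep(w, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  if (is.null(dim(world))) drop(v) else v
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. `write_volume()` stores masks as
#' unsigned 8-bit integers; `read_volume()` restores the container class.
#'
#' @param vol An `sq_volume`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param type Passed to [sq_volume()] on read.
#' @return `read_volume()` returns an `sq_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (is_mask(vol)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::asNifti(dat, reference = img)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, type = c("scalar", "mask")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  dat <- array(as.numeric(img), dim = dim(img)[1:3])
  sq_volume(dat, spacing = spacing, type = type)
}

#' Tissue segmentation (disjoint WM/GM/CSF masks)
#'
#' @param wm,gm,csf Binary `sq_volume` masks on one grid.
#' @return An object of class `sq_seg`.
#' @export
sq_seg <- function(wm, gm, csf) {
  for (m in list(wm, gm, csf)) {
    if (!is_mask(m)) stop_bad_arg("segmentation components must be mask volumes")
  }
  check_same_grid(wm, gm, "segmentation masks")
  check_same_grid(wm, csf, "segmentation masks")
  if (any(wm$data & gm$data) || any(wm$data & csf$data) || any(gm$data & csf$data)) {
    stop_bad_arg("tissue masks must be pairwise disjoint")
  }
  structure(list(wm = wm, gm = gm, csf = csf), class = "sq_seg")
}

#' @export
print.sq_seg <- function(x, ...) {
  cat(sprintf("<sq_seg> WM %d, GM %d, CSF %d voxels\n",
              sum(x$wm$data), sum(x$gm$data), sum(x$csf$data)))
  invisible(x)
}

brain_mask <- function(seg) {
  sq_volume(seg$wm$data | seg$gm$data | seg$csf$data,
            spacing = seg$wm$spacing, origin = seg$wm$origin, type = "mask")
}
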