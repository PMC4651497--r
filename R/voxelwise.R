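#' Default voxelwise analysis parameters
#'
#' One-tailed (low-FA) voxel threshold p < 0.005 with a minimum cluster extent
#' of 100 contiguous voxels; 26-connectivity is the package default for
#' contiguity (common in neuroimaging cluster software, configurable).
#'
#' @return A list with `alpha`, `min_size`, `connectivity`.
#' @export
voxelwise_defaults <- function() {
  list(alpha = 0.005, min_size = 100L, connectivity = 26L)
}

#' Single-case voxelwise t map (one subject vs a control group)
#'
#' At each analysis-mask voxel, the subject's FA value `x` is compared to the
#' control sample (mean `m`, sd `s`, size `n`) with the single-case t
#' statistic
#' \deqn{t = (x - m) / (s \sqrt{1 + 1/n}), \quad df = n - 1,}
#' algebraically the two-sample t with a group of one (Crawford-Howell form).
#' The variance inflation `1 + 1/n` accounts for the subject being a single
#' draw rather than a mean. p is the lower-tail probability (low-FA
#' direction). Voxels with zero control variance are flagged invalid rather
#' than raising: they occur naturally on synthetic mask borders.
#'
#' @param subject_fa `sq_volume` of subject FA.
#' @param control_fas List of control FA `sq_volume`s (>= 2) on the same grid.
#' @param mask Binary `sq_volume`: the analysis mask (template WM).
#' @return An `sq_statmap`: `t` and `p` volumes (NA outside mask / invalid),
#'   `valid` mask, `n_controls`, `df`.
#' @export
single_case_t_map <- function(subject_fa, control_fas, mask) {
  n <- length(control_fas)
  if (n < 2) stop_bad_arg("need at least 2 controls")
  if (!is_mask(mask)) stop_bad_arg("`mask` must be a mask volume")
  check_same_grid(subject_fa, mask, "subject and mask")
  for (cf in control_fas) check_same_grid(subject_fa, cf, "subject and control")
  if (!any(mask$data)) stop_bad_arg("empty analysis mask")
  dims <- dim(subject_fa$data)
  sel <- which(mask$data)
  x <- subject_fa$data[sel]
  s1 <- numeric(length(sel))
  s2 <- numeric(length(sel))
  for (cf in control_fas) {
    v <- cf$data[sel]
    s1 <- s1 + v
    s2 <- s2 + v * v
  }
  m <- s1 / n
  var_c <- pmax((s2 - n * m^2) / (n - 1), 0)
  s <- sqrt(var_c)
  valid <- s > 0
  tval <- rep(NA_real_, length(sel))
  tval[valid] <- (x[valid] - m[valid]) / (s[valid] * sqrt(1 + 1 / n))
  pval <- rep(NA_real_, length(sel))
  pval[valid] <- stats::pt(tval[valid], df = n - 1)
  t_arr <- array(NA_real_, dims); t_arr[sel] <- tval
  p_arr <- array(NA_real_, dims); p_arr[sel] <- pval
  v_arr <- array(FALSE, dims); v_arr[sel] <- valid
  structure(list(t = sq_volume(t_arr, subject_fa$spacing, subject_fa$origin),
                 p = sq_volume(p_arr, subject_fa$spacing, subject_fa$origin),
                 valid = sq_volume(v_arr, subject_fa$spacing, subject_fa$origin,
                                   type = "mask"),
                 n_controls = n, df = n - 1L),
            class = "sq_statmap")
}

#' @export
print.sq_statmap <- function(x, ...) {
  cat(sprintf("<sq_statmap> %s, n_controls %d, df %d, %d valid voxels\n",
              paste(dim(x$t$data), collapse = "x"), x$n_controls, x$df,
              sum(x$valid$data)))
  invisible(x)
}

# 3D neighbour offsets for a given connectivity, as index offsets into an
# array padded by one voxel on every side.
neighbour_offsets <- function(dims_padded, connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop_bad_arg("`connectivity` must be 6, 18 or 26")
  }
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  off <- off[keep, ]
  off$dx + dims_padded[1] * off$dy + dims_padded[1] * dims_padded[2] * off$dz
}

# Connected-component labelling of a logical 3D array by frontier expansion.
# Returns an integer array of labels (0 = background).
label_components <- function(bin, connectivity = 26L) {
  dims <- dim(bin)
  dp <- dims + 2L
  padded <- array(FALSE, dp)
  padded[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- bin
  offs <- neighbour_offsets(dp, connectivity)
  labels <- array(0L, dp)
  todo <- which(padded)
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[padded[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1), drop = FALSE]
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Connected components (6/18/26-connectivity) of the voxels inside `mask`
#' with valid `p < alpha`; components of at least `min_size` voxels are
#' returned sorted by size (descending), ties broken by most negative peak t,
#' then by lexicographically smallest first voxel.
#'
#' @param stat An `sq_statmap`.
#' @param mask Binary analysis mask (`sq_volume`).
#' @param alpha Voxelwise threshold in (0, 1).
#' @param min_size Minimum cluster extent in voxels (>= 1); a cluster of
#'   exactly `min_size` voxels is retained ("at least" semantics).
#' @param connectivity 6, 18 or 26.
#' @return A tibble with one row per cluster: `cluster_id`, `size`, `peak_t`,
#'   `centroid_x/y/z` (mm), `misreg_overlap_pct` (NA until filled by
#'   [cluster_overlap_percent()]), and a `voxels` list-column of n-by-3 index
#'   matrices. The labelled cluster volume is attached as attribute
#'   `label_volume`.
#' @export
extract_clusters <- function(stat, mask, alpha = 0.005, min_size = 100L,
                             connectivity = 26L) {
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("`alpha` must be in (0, 1)")
  if (min_size < 1) stop_bad_arg("`min_size` must be >= 1")
  check_same_grid(stat$p, mask, "stat map and mask")
  dims <- dim(stat$p$data)
  bin <- mask$data & stat$valid$data & !is.na(stat$p$data) & stat$p$data < alpha
  labels <- label_components(bin, connectivity)
  empty <- cluster_tibble(list(), stat)
  if (!any(bin)) return(empty)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_size)
  if (!length(keep)) return(empty)
  clusters <- lapply(keep, function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    tv <- stat$t$data[labels == k]
    list(voxels = idx, size = nrow(idx), peak_t = min(tv),
         centroid = colMeans(idx))
  })
  # sort: size desc, most negative peak t, then first voxel lexicographic
  first_vox <- vapply(clusters, function(cl) {
    v <- cl$voxels[order(cl$voxels[, 1], cl$voxels[, 2], cl$voxels[, 3]), ,
                   drop = FALSE][1, ]
    sum((v - 1) * c(1, dims[1], dims[1] * dims[2]))
  }, numeric(1))
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"),
               vapply(clusters, `[[`, numeric(1), "peak_t"),
               first_vox)
  clusters <- clusters[ord]
  out <- cluster_tibble(clusters, stat)
  relab <- array(0L, dims)
  for (i in seq_along(clusters)) relab[clusters[[i]]$voxels] <- i
  attr(out, "label_volume") <- sq_volume(relab, stat$p$spacing, stat$p$origin)
  out
}

cluster_tibble <- function(clusters, stat) {
  if (!length(clusters)) {
    out <- tibble::tibble(cluster_id = integer(), size = integer(),
                          peak_t = numeric(), centroid_x = numeric(),
                          centroid_y = numeric(), centroid_z = numeric(),
                          misreg_overlap_pct = numeric(), voxels = list())
    attr(out, "label_volume") <- sq_volume(array(0L, dim(stat$p$data)),
                                           stat$p$spacing, stat$p$origin)
    return(out)
  }
  cent <- t(vapply(clusters, function(cl) {
    world_from_voxel(stat$p, cl$centroid)
  }, numeric(3)))
  tibble::tibble(cluster_id = seq_along(clusters),
                 size = vapply(clusters, `[[`, numeric(1), "size"),
                 peak_t = vapply(clusters, `[[`, numeric(1), "peak_t"),
                 centroid_x = cent[, 1], centroid_y = cent[, 2],
                 centroid_z = cent[, 3],
                 misreg_overlap_pct = NA_real_,
                 voxels = lapply(clusters, `[[`, "voxels"))
}

#' Write a statistic map as NIfTI t/p volumes
#'
#' @param stat An `sq_statmap`.
#' @param prefix Output path prefix; writes `<prefix>_tmap.nii.gz` and
#'   `<prefix>_pmap.nii.gz`.
#' @return The two paths, invisibly.
#' @export
write_stat_map <- function(stat, prefix) {
  t_path <- paste0(prefix, "_tmap.nii.gz")
  p_path <- paste0(prefix, "_pmap.nii.gz")
  write_volume(stat$t, t_path)
  write_volume(stat$p, p_path)
  invisible(c(t_path, p_path))
}

#' Write clusters as TSV (plus the labelled-cluster NIfTI)
#'
#' @param clusters Tibble from [extract_clusters()].
#' @param path TSV output path.
#' @param label_path Optional NIfTI path for the labelled-cluster volume.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, label_path = NULL) {
  tab <- clusters[, c("cluster_id", "size", "peak_t", "centroid_x",
                      "centroid_y", "centroid_z", "misreg_overlap_pct")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path) && !is.null(attr(clusters, "label_volume"))) {
    write_volume(attr(clusters, "label_volume"), label_path)
  }
  invisible(path)
}
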