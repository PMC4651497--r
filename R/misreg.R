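#' Misregistration mask: registered GM/CSF on template WM
#'
#' Voxels where the registered subject's non-white-matter (GM union CSF)
#' lands on white matter of the template -- the locations at which a
#' voxelwise FA comparison against a WM normative sample is comparing the
#' wrong tissue.
#'
#' @param registered_seg `sq_seg` of the registered subject.
#' @param template_wm Binary `sq_volume`: template WM mask.
#' @return Binary `sq_volume` mask.
#' @export
misregistration_mask <- function(registered_seg, template_wm) {
  check_same_grid(registered_seg$wm, template_wm, "segmentation and template WM")
  sq_volume((registered_seg$gm$data | registered_seg$csf$data) & template_wm$data,
            template_wm$spacing, template_wm$origin, type = "mask")
}

#' Misregistered-voxel percentage of template WM
#'
#' `100 * |mask| / |template WM|`, reported to one decimal (half away from
#' zero). The denominator is the *template's* WM voxel count -- the number of
#' voxels entering the voxelwise analysis -- not the subject's.
#'
#' @param mask Binary misregistration mask.
#' @param template_wm Binary template WM mask (non-empty).
#' @return Percentage (one decimal).
#' @export
misregistration_percent <- function(mask, template_wm) {
  check_same_grid(mask, template_wm, "mask and template WM")
  n_wm <- sum(template_wm$data)
  if (n_wm == 0) stop_bad_arg("empty template WM mask")
  round_half_away(100 * sum(mask$data) / n_wm, 1)
}

#' Overlap of cluster voxels with the misregistration mask
#'
#' Percentage of detected abnormally-low-FA cluster voxels that fall inside
#' the misregistration mask, overall and per cluster. With no clusters the
#' ratio is undefined and reported as `NA`.
#'
#' @param clusters Cluster tibble from [extract_clusters()].
#' @param misreg_mask Binary `sq_volume`.
#' @return List with `overall_pct` (one decimal, or `NA`), `per_cluster_pct`,
#'   and the input `clusters` tibble with `misreg_overlap_pct` filled in.
#' @export
cluster_overlap_percent <- function(clusters, misreg_mask) {
  if (nrow(clusters) == 0) {
    return(list(overall_pct = NA_real_, per_cluster_pct = numeric(0),
                clusters = clusters))
  }
  in_mask <- vapply(clusters$voxels, function(v) sum(misreg_mask$data[v]),
                    numeric(1))
  per <- round_half_away(100 * in_mask / clusters$size, 1)
  overall <- round_half_away(100 * sum(in_mask) / sum(clusters$size), 1)
  clusters$misreg_overlap_pct <- per
  list(overall_pct = overall, per_cluster_pct = per, clusters = clusters)
}

#' Assemble a misregistration report
#'
#' @param registered_seg `sq_seg` of the registered subject (or `NULL` in
#'   subject-based mode, where the subject is never resampled and the mask is
#'   empty by construction).
#' @param template_wm Binary template WM mask.
#' @param clusters Optional cluster tibble to compute overlaps for.
#' @return List of class `sq_misreg_report`: `n_template_wm`, `n_misreg`,
#'   `pct_misreg`, `cluster_overlap_pct`, `per_cluster_pct`, `mask`.
#' @export
misreg_report <- function(registered_seg, template_wm, clusters = NULL) {
  if (is.null(registered_seg)) {
    mask <- sq_volume(array(FALSE, dim(template_wm$data)), template_wm$spacing,
                      template_wm$origin, type = "mask")
  } else {
    mask <- misregistration_mask(registered_seg, template_wm)
  }
  rep <- list(n_template_wm = sum(template_wm$data),
              n_misreg = sum(mask$data),
              pct_misreg = misregistration_percent(mask, template_wm),
              cluster_overlap_pct = NA_real_,
              per_cluster_pct = numeric(0),
              mask = mask)
  if (!is.null(clusters)) {
    ov <- cluster_overlap_percent(clusters, mask)
    # subject-based mode: the subject cannot be misregistered, overlap is 0
    rep$cluster_overlap_pct <- if (is.null(registered_seg) && nrow(clusters) > 0) {
      0
    } else {
      ov$overall_pct
    }
    rep$per_cluster_pct <- ov$per_cluster_pct
  }
  structure(rep, class = "sq_misreg_report")
}

#' @export
print.sq_misreg_report <- function(x, ...) {
  cat(sprintf("<sq_misreg_report> %d/%d template-WM voxels misregistered (%.1f%%)%s\n",
              x$n_misreg, x$n_template_wm, x$pct_misreg,
              if (!is.na(x$cluster_overlap_pct)) {
                sprintf(", cluster overlap %.1f%%", x$cluster_overlap_pct)
              } else ""))
  invisible(x)
}

#' Write a misregistration report as JSON
#'
#' @param report An `sq_misreg_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_misreg_report <- function(report, path) {
  jsonlite::write_json(
    list(n_template_wm = report$n_template_wm,
         n_misreg = report$n_misreg,
         pct_misreg = report$pct_misreg,
         cluster_overlap_pct = report$cluster_overlap_pct,
         per_cluster_pct = report$per_cluster_pct),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
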