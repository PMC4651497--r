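#' Analysis parameters for a single-subject study run
#'
#' Collects the voxelwise thresholds and the simulated-registration error
#' settings. `residual_amplitude_mm` applies to every registration unless a
#' side-specific override is given; `subject_residual_mm` only matters in
#' atlas-based mode (in subject-based mode the subject is never registered).
#'
#' @param alpha Voxelwise one-tailed threshold (default 0.005).
#' @param min_size Minimum cluster extent in voxels (default 100).
#' @param connectivity Cluster connectivity, 6/18/26 (default 26).
#' @param residual_amplitude_mm RMS residual registration error, mm.
#' @param residual_smoothness_mm Spatial scale of the residual error, mm.
#' @param subject_residual_mm,control_residual_mm Optional side-specific
#'   overrides of `residual_amplitude_mm`.
#' @param seed Integer seed; per-registration seeds derive from it.
#' @return A list of class `sq_params`.
#' @export
analysis_params <- function(alpha = 0.005, min_size = 100L, connectivity = 26L,
                            residual_amplitude_mm = 0,
                            residual_smoothness_mm = 6,
                            subject_residual_mm = NULL,
                            control_residual_mm = NULL,
                            seed = 1L) {
  structure(list(alpha = alpha, min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity),
                 residual_amplitude_mm = residual_amplitude_mm,
                 residual_smoothness_mm = residual_smoothness_mm,
                 subject_residual_mm = subject_residual_mm %||% residual_amplitude_mm,
                 control_residual_mm = control_residual_mm %||% residual_amplitude_mm,
                 seed = as.integer(seed)),
            class = "sq_params")
}

#' Run one single-subject-vs-group voxelwise analysis
#'
#' The workhorse of the package. In atlas-based mode (`"abr"`) every brain --
#' subject included -- is registered to the supplied template and the
#' comparison runs inside the template's WM mask. In subject-based mode
#' (`"sbr"`) the subject *is* the template: the controls are registered to
#' the subject, the subject's own volumes are used untouched (bit-identical
#' to the input), and its misregistration mask is empty by construction.
#'
#' @param subject `sq_subject` record.
#' @param controls List of `sq_subject` records (>= 2).
#' @param mode `"sbr"` or `"abr"`.
#' @param template Template `sq_subject` for `"abr"` mode; must be `NULL`
#'   (or the subject itself) in `"sbr"` mode.
#' @param params [analysis_params()].
#' @param registered_control_fas Optional list of control FA volumes already
#'   registered to the template (atlas-based mode only) -- controls are
#'   registered to a fixed atlas once per study, so large simulations reuse
#'   them across subjects.
#' @return An `sq_analysis`: `subject_id`, `mode`, `template_id`, `stat`
#'   (`sq_statmap`), `clusters` (tibble), `misreg` (`sq_misreg_report`),
#'   `n_abnormal_voxels`, `subject_fa` (the subject volume actually compared:
#'   bit-identical to the input in subject-based mode), `registered_subject`
#'   (abr only), `params`.
#' @export
run_analysis <- function(subject, controls, mode = c("sbr", "abr"),
                         template = NULL, params = analysis_params(),
                         registered_control_fas = NULL) {
  mode <- match.arg(mode)
  if (length(controls) < 2) stop_bad_arg("need at least 2 controls")
  if (mode == "sbr") {
    if (!is.null(template) && !identical(template$id, subject$id)) {
      stop_bad_arg("subject-based mode uses the subject as template; do not pass a different template")
    }
    template <- subject
    mask <- subject$seg$wm
    control_fas <- lapply(seq_along(controls), function(i) {
      simulate_registration(controls[[i]], subject,
                            residual_amplitude_mm = params$control_residual_mm,
                            residual_smoothness_mm = params$residual_smoothness_mm,
                            seed = derive_seed(params$seed, i),
                            what = "fa")$registered$fa
    })
    subject_fa <- subject$fa   # never resampled
    registered_subject <- NULL
  } else {
    if (is.null(template)) stop_bad_arg("atlas-based mode needs a template record")
    mask <- template$seg$wm
    if (is.null(registered_control_fas)) {
      registered_control_fas <- lapply(seq_along(controls), function(i) {
        simulate_registration(controls[[i]], template,
                              residual_amplitude_mm = params$control_residual_mm,
                              residual_smoothness_mm = params$residual_smoothness_mm,
                              seed = derive_seed(params$seed, i),
                              what = "fa")$registered$fa
      })
    }
    control_fas <- registered_control_fas
    registered_subject <- simulate_registration(
      subject, template,
      residual_amplitude_mm = params$subject_residual_mm,
      residual_smoothness_mm = params$residual_smoothness_mm,
      seed = derive_seed(params$seed, 100003L),
      what = c("fa", "seg", "lesion"))$registered
    subject_fa <- registered_subject$fa
  }
  stat <- single_case_t_map(subject_fa, control_fas, mask)
  clusters <- extract_clusters(stat, mask, alpha = params$alpha,
                               min_size = params$min_size,
                               connectivity = params$connectivity)
  misreg <- misreg_report(if (mode == "abr") registered_subject$seg else NULL,
                          mask, clusters)
  clusters$misreg_overlap_pct <- misreg$per_cluster_pct %||% numeric(0)
  if (nrow(clusters) && !length(misreg$per_cluster_pct)) {
    clusters$misreg_overlap_pct <- NA_real_
  }
  structure(list(subject_id = subject$id, mode = mode,
                 template_id = template$id,
                 stat = stat, clusters = clusters, misreg = misreg,
                 n_abnormal_voxels = sum(clusters$size),
                 subject_fa = subject_fa,
                 registered_subject = registered_subject,
                 params = params),
            class = "sq_analysis")
}

#' @export
print.sq_analysis <- function(x, ...) {
  cat(sprintf("<sq_analysis> %s vs %d controls [%s, template %s]: %d clusters, %d abnormal voxels, misreg %.1f%%\n",
              x$subject_id, x$stat$n_controls, x$mode, x$template_id,
              nrow(x$clusters), x$n_abnormal_voxels, x$misreg$pct_misreg))
  invisible(x)
}

#' One-row summary of an analysis
#'
#' @param x An `sq_analysis`.
#' @param ... Unused.
#' @return A tibble with id, mode, cluster/voxel counts and misregistration
#'   percentages.
#' @export
glance.sq_analysis <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, mode = x$mode,
                 template_id = x$template_id,
                 n_clusters = nrow(x$clusters),
                 n_abnormal_voxels = x$n_abnormal_voxels,
                 pct_misreg = x$misreg$pct_misreg,
                 cluster_overlap_pct = x$misreg$cluster_overlap_pct)
}

#' Generic one-row model summary
#'
#' @param x Object to summarise.
#' @param ... Passed on to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Generic tidy summary
#'
#' @param x Object to tidy.
#' @param ... Passed on to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

# Map subject-space cluster voxels into template-space labels: a subject
# voxel v corresponds to template location v + truth(v).
clusters_overlap_count <- function(sbr_clusters, subject, abr_label_vol) {
  if (nrow(sbr_clusters) == 0) return(0L)
  lab <- abr_label_vol$data
  dims <- dim(lab)
  hits <- vapply(sbr_clusters$voxels, function(vox) {
    d <- sample_field_at(subject$truth_field, vox[, 1], vox[, 2], vox[, 3])
    x <- round(vox[, 1] + d[[1]] / subject$truth_field$spacing[1])
    y <- round(vox[, 2] + d[[2]] / subject$truth_field$spacing[2])
    z <- round(vox[, 3] + d[[3]] / subject$truth_field$spacing[3])
    ok <- x >= 1 & x <= dims[1] & y >= 1 & y <= dims[2] & z >= 1 & z <= dims[3]
    any(lab[cbind(x[ok], y[ok], z[ok])] > 0)
  }, logical(1))
  sum(hits)
}

#' Compare subject-based and atlas-based analyses across a cohort
#'
#' Runs, for every subject of a phantom cohort, the subject-based analysis
#' and the atlas-based analysis against the cohort's template phantom (the
#' atlas stand-in: an anatomy none of the individuals equals), and tabulates
#' per-subject cluster counts, abnormal-voxel counts and the number of
#' subject-based clusters that overlap an atlas-based cluster after mapping
#' through the subject's ground-truth deformation. Controls are registered
#' to the atlas once and reused across subjects, as in a standard
#' atlas-centred workflow. A paired one-sided Wilcoxon signed-rank test
#' compares the two modes.
#'
#' @param cohort List from [generate_cohort()].
#' @param params [analysis_params()].
#' @param adjust_voxels_to_subject If `TRUE`, atlas-based abnormal-voxel
#'   counts are rescaled by the ratio of the subject's native WM voxel count
#'   to the template's (one plausible reading of a "volume adjusted to
#'   patient volume" correction; no canonical formula exists, hence off by
#'   default).
#' @return List with `table` (per-subject tibble), `wilcoxon_clusters`,
#'   `wilcoxon_voxels` (class `sq_wilcoxon`, or `NULL` when all differences
#'   are zero), and `results` (list of per-subject `(sbr, abr)` pairs of
#'   [glance.sq_analysis()] rows).
#' @export
compare_modes <- function(cohort, params = analysis_params(),
                          adjust_voxels_to_subject = FALSE) {
  template <- cohort$template
  reg_ctrl <- lapply(seq_along(cohort$controls), function(i) {
    simulate_registration(cohort$controls[[i]], template,
                          residual_amplitude_mm = params$control_residual_mm,
                          residual_smoothness_mm = params$residual_smoothness_mm,
                          seed = derive_seed(params$seed, i),
                          what = "fa")$registered$fa
  })
  rows <- lapply(seq_along(cohort$subjects), function(j) {
    subj <- cohort$subjects[[j]]
    p_j <- params
    p_j$seed <- derive_seed(params$seed, 5000L + j)
    sbr <- run_analysis(subj, cohort$controls, "sbr", params = p_j)
    abr <- run_analysis(subj, cohort$controls, "abr", template = template,
                        params = p_j, registered_control_fas = reg_ctrl)
    overlap <- clusters_overlap_count(sbr$clusters, subj,
                                      attr(abr$clusters, "label_volume"))
    abr_vox <- abr$n_abnormal_voxels
    if (adjust_voxels_to_subject) {
      abr_vox <- abr_vox * sum(subj$seg$wm$data) / sum(template$seg$wm$data)
    }
    tibble::tibble(id = subj$id,
                   sbr_clusters = nrow(sbr$clusters),
                   abr_clusters = nrow(abr$clusters),
                   sbr_voxels = sbr$n_abnormal_voxels,
                   abr_voxels = abr_vox,
                   overlap_clusters = overlap,
                   abr_pct_misreg = abr$misreg$pct_misreg,
                   abr_cluster_overlap_pct = abr$misreg$cluster_overlap_pct)
  })
  tab <- do.call(rbind, rows)
  wil <- function(a, b) {
    if (all(b - a == 0)) return(NULL)
    wilcoxon_signed_rank(a, b, alternative = "greater")
  }
  list(table = tab,
       wilcoxon_clusters = wil(tab$sbr_clusters, tab$abr_clusters),
       wilcoxon_voxels = wil(tab$sbr_voxels, tab$abr_voxels))
}

#' Cluster-size threshold calibration (false-positive base rate)
#'
#' Leave-one-out over a set of healthy controls: each control in turn is
#' analysed as the "subject" against the remaining ones, and for every
#' cluster-size threshold the fraction of pseudo-subjects showing at least
#' one suprathreshold cluster is reported -- the empirical base rate of
#' abnormal findings in healthy individuals, as a function of the extent
#' threshold.
#'
#' @param controls List of `sq_subject` records (>= 3).
#' @param thresholds Positive, strictly increasing cluster-size thresholds.
#' @param mode `"sbr"` or `"abr"`; atlas-based mode needs `template` and
#'   registers every control to it once (with the configured residual
#'   error), mirroring an atlas-centred workflow.
#' @param template Template record for `"abr"`.
#' @param params [analysis_params()].
#' @param max_subjects Cap on the number of pseudo-subjects analysed
#'   (default: all controls).
#' @return Tibble with `threshold`, `n_subjects`, `n_with_cluster`, `rate`.
#' @export
calibrate_cluster_threshold <- function(controls,
                                        thresholds = c(50L, 100L, 150L, 200L),
                                        mode = c("sbr", "abr"),
                                        template = NULL,
                                        params = analysis_params(),
                                        max_subjects = NULL) {
  mode <- match.arg(mode)
  if (length(controls) < 3) stop_bad_arg("need at least 3 controls")
  if (any(thresholds <= 0) || any(diff(thresholds) <= 0)) {
    stop_bad_arg("`thresholds` must be positive and strictly increasing")
  }
  n_sub <- min(max_subjects %||% length(controls), length(controls))
  p_all <- params
  p_all$min_size <- 1L   # collect every cluster once, filter by size after
  if (mode == "abr") {
    if (is.null(template)) stop_bad_arg("atlas-based mode needs a template")
    reg_fas <- lapply(seq_along(controls), function(i) {
      simulate_registration(controls[[i]], template,
                            residual_amplitude_mm = params$control_residual_mm,
                            residual_smoothness_mm = params$residual_smoothness_mm,
                            seed = derive_seed(params$seed, i),
                            what = "fa")$registered$fa
    })
    reg_segs <- lapply(seq_len(n_sub), function(i) {
      simulate_registration(controls[[i]], template,
                            residual_amplitude_mm = params$subject_residual_mm,
                            residual_smoothness_mm = params$residual_smoothness_mm,
                            seed = derive_seed(params$seed, 200000L + i),
                            what = c("fa", "seg"))$registered
    })
  }
  max_sizes <- vapply(seq_len(n_sub), function(i) {
    if (mode == "sbr") {
      p_i <- p_all
      p_i$seed <- derive_seed(params$seed, 300000L + i)
      res <- run_analysis(controls[[i]], controls[-i], "sbr", params = p_i)
    } else {
      stat <- single_case_t_map(reg_segs[[i]]$fa, reg_fas[-i], template$seg$wm)
      cl <- extract_clusters(stat, template$seg$wm, alpha = p_all$alpha,
                             min_size = 1L,
                             connectivity = p_all$connectivity)
      res <- list(clusters = cl)
    }
    if (nrow(res$clusters)) max(res$clusters$size) else 0L
  }, numeric(1))
  tibble::tibble(threshold = as.integer(thresholds),
                 n_subjects = as.integer(n_sub),
                 n_with_cluster = vapply(thresholds, function(thr) {
                   sum(max_sizes >= thr)
                 }, numeric(1)),
                 rate = vapply(thresholds, function(thr) {
                   mean(max_sizes >= thr)
                 }, numeric(1)))
}

#' Probe the effect of the extra interpolation step
#'
#' In subject-based mode the subject undergoes one less interpolation than in
#' atlas-based mode. This experiment isolates that difference from
#' misregistration bias: the subject-based analysis is run twice, once
#' normally and once after resampling the subject's FA through an identity
#' warp (`interpolation = "nearest"`, bit-identical by construction) or
#' through a constant sub-voxel shift and back (`interpolation = "linear"`,
#' two trilinear resamples, pure interpolation smoothing, no displacement).
#'
#' @param subject,controls Cohort members.
#' @param params [analysis_params()].
#' @param interpolation `"nearest"` or `"linear"`.
#' @param shift_vox Sub-voxel shift (in voxels) used for the linear probe.
#' @return List with `baseline` and `perturbed` analyses plus a `comparison`
#'   tibble of cluster/voxel-count differences.
#' @export
interpolation_impact <- function(subject, controls, params = analysis_params(),
                                 interpolation = c("nearest", "linear"),
                                 shift_vox = 0.5) {
  interpolation <- match.arg(interpolation)
  baseline <- run_analysis(subject, controls, "sbr", params = params)
  dims <- dim(subject$fa$data)
  sp <- subject$fa$spacing
  subject2 <- subject
  if (interpolation == "nearest") {
    f0 <- zero_field(dims, sp, subject$fa$origin)
    subject2$fa <- apply_displacement(subject$fa, f0, "nearest", fill = 0)
  } else {
    fwd <- constant_field(dims, c(shift_vox * sp[1], 0, 0), sp, subject$fa$origin)
    bwd <- constant_field(dims, c(-shift_vox * sp[1], 0, 0), sp, subject$fa$origin)
    once <- apply_displacement(subject$fa, fwd, "linear", fill = 0)
    subject2$fa <- apply_displacement(once, bwd, "linear", fill = 0)
  }
  perturbed <- run_analysis(subject2, controls, "sbr", params = params)
  list(baseline = baseline, perturbed = perturbed,
       comparison = tibble::tibble(
         interpolation = interpolation,
         clusters_baseline = nrow(baseline$clusters),
         clusters_perturbed = nrow(perturbed$clusters),
         cluster_diff = nrow(perturbed$clusters) - nrow(baseline$clusters),
         voxels_baseline = baseline$n_abnormal_voxels,
         voxels_perturbed = perturbed$n_abnormal_voxels,
         voxel_diff = perturbed$n_abnormal_voxels - baseline$n_abnormal_voxels,
         fa_identical = identical(subject2$fa$data, subject$fa$data)))
}
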