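#' Simulation experiments shipped with the package
#'
#' These functions run the package's standard phantom-cohort experiments:
#' null calibration of the voxelwise test, the registration-target bias
#' comparison, misregistration monotonicity in residual error, ground-truth
#' lesion recovery, and cluster-size-threshold base-rate calibration. Each is
#' deterministic given its seed and sized to run in minutes on one CPU; the
#' defaults are the package's study conditions (64 voxel cube at 2 mm,
#' 48-control normative group, 20-subject reference-group experiments).
#'
#' @name experiments
NULL

#' Null calibration of the voxelwise rejection rate
#'
#' Identity phantom cohort (no anatomical variability, no registration
#' error): every brain shares one grid, so the single-case t test is exactly
#' calibrated and the empirical rejection rate at `alpha` must match `alpha`.
#' The rate is evaluated on a stride-`stride` voxel lattice: FA measurement
#' noise has a short spatial correlation, and subsampling beyond its
#' correlation length makes the voxel tests approximately independent so
#' that the binomial standard error model for the empirical rate holds.
#'
#' @param seed Integer seed.
#' @param n_controls Controls in the normative group.
#' @param n_subjects Lesion-free subjects pooled into the rate estimate.
#' @param alpha Voxelwise threshold.
#' @param stride Lattice stride in voxels.
#' @param spec Phantom spec (variability is forced to zero).
#' @return A list: `rate`, `alpha`, `n_tests`, `binomial_se`, and the
#'   per-subject rates.
#' @export
experiment_null_rejection <- function(seed = 1L, n_controls = 48,
                                      n_subjects = 20, alpha = 0.005,
                                      stride = 3L, spec = phantom_spec()) {
  spec$variability_amplitude_mm <- 0
  cohort <- generate_cohort(spec, n_controls = n_controls,
                            subjects = rep(list(NULL), n_subjects),
                            seed = derive_seed(seed, 17L))
  dims <- spec$grid_shape
  lattice <- array(FALSE, dims)
  lattice[seq(1, dims[1], stride), seq(1, dims[2], stride),
          seq(1, dims[3], stride)] <- TRUE
  par <- analysis_params(residual_amplitude_mm = 0, alpha = alpha,
                         seed = derive_seed(seed, 23L))
  hits <- 0; tests <- 0; per_subject <- numeric(n_subjects)
  for (j in seq_len(n_subjects)) {
    res <- run_analysis(cohort$subjects[[j]], cohort$controls, "sbr",
                        params = par)
    sel <- res$stat$valid$data & lattice
    p <- res$stat$p$data[sel]
    hits <- hits + sum(p < alpha)
    tests <- tests + length(p)
    per_subject[j] <- mean(p < alpha)
  }
  list(rate = hits / tests, alpha = alpha, n_tests = tests,
       binomial_se = sqrt(alpha * (1 - alpha) / tests),
       per_subject = per_subject)
}

#' Null cluster runs: lesion-free subjects under subject-based analysis
#'
#' Full-variability phantom cohort, zero residual registration error,
#' default thresholds: healthy subjects analysed against the normative group
#' should essentially never show a suprathreshold cluster of the default
#' 100-voxel extent.
#'
#' @inheritParams experiment_null_rejection
#' @param n_runs Number of lesion-free subjects analysed.
#' @param cohort Optional pre-built cohort (>= `n_runs` subjects); built from
#'   `spec` when missing.
#' @return Tibble with one row per run: `run`, `n_clusters` (at the default
#'   100-voxel extent), `max_component` (largest suprathreshold component of
#'   any size), `rejection_rate`.
#' @export
experiment_null_clusters <- function(seed = 1L, n_controls = 48, n_runs = 20,
                                     spec = phantom_spec(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec, n_controls = n_controls,
                              subjects = rep(list(NULL), n_runs),
                              seed = derive_seed(seed, 29L))
  }
  par <- analysis_params(residual_amplitude_mm = 0,
                         seed = derive_seed(seed, 31L))
  rows <- lapply(seq_len(n_runs), function(j) {
    res <- run_analysis(cohort$subjects[[j]], cohort$controls, "sbr",
                        params = par)
    all_cl <- extract_clusters(res$stat, cohort$subjects[[j]]$seg$wm,
                               alpha = par$alpha, min_size = 1L,
                               connectivity = par$connectivity)
    v <- res$stat$valid$data
    tibble::tibble(run = j, n_clusters = nrow(res$clusters),
                   max_component = if (nrow(all_cl)) max(all_cl$size) else 0,
                   rejection_rate = mean(res$stat$p$data[v] < par$alpha))
  })
  do.call(rbind, rows)
}

#' Registration-target bias experiment
#'
#' For each lesion-free subject, the atlas-based analysis (everything,
#' subject included, registered to the template phantom with the given
#' residual error) is paired with the subject-based analysis (controls
#' registered to the subject with the same residual error; the subject
#' untouched). The only systematic difference is the subject-side
#' registration error, so any excess of atlas-based cluster or voxel counts
#' is the bias attributable to registering the subject of interest. Controls
#' are registered to the atlas once and reused, as in an atlas-centred
#' workflow.
#'
#' @inheritParams experiment_null_clusters
#' @param n_subjects Number of paired analyses.
#' @param residual_amplitude_mm Residual registration error (all
#'   registrations).
#' @return List: `table` (per-subject paired counts and the subject-side
#'   misregistration voxel count under sBR, which is structurally zero),
#'   `wilcoxon_clusters`, `wilcoxon_voxels` (one-sided, atlas > subject).
#' @export
experiment_bias <- function(seed = 1L, n_controls = 20, n_subjects = 20,
                            residual_amplitude_mm = 2,
                            spec = phantom_spec(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec, n_controls = n_controls,
                              subjects = rep(list(NULL), n_subjects),
                              seed = derive_seed(seed, 37L))
  }
  controls <- cohort$controls[seq_len(min(n_controls, length(cohort$controls)))]
  template <- cohort$template
  par <- analysis_params(residual_amplitude_mm = residual_amplitude_mm,
                         seed = derive_seed(seed, 41L))
  reg_ctrl <- lapply(seq_along(controls), function(i) {
    simulate_registration(controls[[i]], template,
                          residual_amplitude_mm = residual_amplitude_mm,
                          residual_smoothness_mm = par$residual_smoothness_mm,
                          seed = derive_seed(seed, 43L + i),
                          what = "fa")$registered$fa
  })
  rows <- lapply(seq_len(n_subjects), function(j) {
    subj <- cohort$subjects[[j]]
    p_j <- par
    p_j$seed <- derive_seed(seed, 5000L + j)
    sbr <- run_analysis(subj, controls, "sbr", params = p_j)
    abr <- run_analysis(subj, controls, "abr", template = template,
                        params = p_j, registered_control_fas = reg_ctrl)
    tibble::tibble(id = subj$id,
                   sbr_clusters = nrow(sbr$clusters),
                   abr_clusters = nrow(abr$clusters),
                   sbr_voxels = sbr$n_abnormal_voxels,
                   abr_voxels = abr$n_abnormal_voxels,
                   sbr_misreg_voxels = sbr$misreg$n_misreg,
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

#' Misregistration monotonicity in residual amplitude
#'
#' Registers each subject's segmentation to the template at several residual
#' error amplitudes and reports the percentage of template WM covered by
#' misregistered GM/CSF: the expectation is non-decreasing in amplitude.
#'
#' @inheritParams experiment_null_clusters
#' @param amplitudes Residual amplitudes in mm (increasing).
#' @param n_subjects Subjects averaged per amplitude.
#' @return Tibble `amplitude_mm`, `mean_pct`, plus per-subject percentages in
#'   the `pct` list-column.
#' @export
experiment_misreg_monotonicity <- function(seed = 1L,
                                           amplitudes = c(0, 1, 2),
                                           n_subjects = 20,
                                           spec = phantom_spec(),
                                           cohort = NULL) {
  if (is.null(cohort)) {
    spec$seed <- derive_seed(seed, 47L)
    template <- make_template_phantom(spec)
    subjects <- lapply(seq_len(n_subjects), function(j) {
      sample_individual(template, spec, sprintf("s%02d", j),
                        seed = derive_seed(seed, 53L + j))
    })
  } else {
    template <- cohort$template
    subjects <- cohort$subjects[seq_len(min(n_subjects, length(cohort$subjects)))]
  }
  rows <- lapply(amplitudes, function(amp) {
    pct <- vapply(seq_along(subjects), function(j) {
      r <- simulate_registration(subjects[[j]], template,
                                 residual_amplitude_mm = amp,
                                 seed = derive_seed(seed, 7000L + j),
                                 what = "seg")
      misreg_report(r$registered$seg, template$seg$wm)$pct_misreg
    }, numeric(1))
    tibble::tibble(amplitude_mm = amp, mean_pct = mean(pct), pct = list(pct))
  })
  do.call(rbind, rows)
}

#' Ground-truth lesion recovery under subject-based analysis
#'
#' Inserts a spherical WM lesion of known extent into a fresh subject and
#' checks that the subject-based analysis recovers it: the best cluster's
#' Dice overlap with the true lesion mask is reported.
#'
#' @inheritParams experiment_null_clusters
#' @param lesion A [lesion_spec()]; the default is a sphere of roughly 400
#'   WM voxels at an FA reduction of 0.2.
#' @return List: `dice` (best cluster), `n_lesion_voxels`, `n_clusters`,
#'   `clusters`.
#' @export
experiment_lesion_recovery <- function(seed = 1L, n_controls = 48,
                                       lesion = lesion_spec(c(45, 33, 33),
                                                            radius_mm = 9.2,
                                                            fa_delta = 0.2),
                                       spec = phantom_spec(), cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec, n_controls = n_controls,
                              subjects = list(), seed = derive_seed(seed, 59L))
  }
  subj <- sample_individual(cohort$template, spec, "lesioned",
                            seed = derive_seed(seed, 61L))
  subj <- insert_lesion(subj, lesion)
  par <- analysis_params(residual_amplitude_mm = 0,
                         seed = derive_seed(seed, 67L))
  res <- run_analysis(subj, cohort$controls, "sbr", params = par)
  dice <- if (nrow(res$clusters)) {
    max(vapply(res$clusters$voxels, function(v) {
      m <- array(FALSE, dim(subj$fa$data)); m[v] <- TRUE
      2 * sum(m & subj$lesion_mask$data) /
        (sum(m) + sum(subj$lesion_mask$data))
    }, numeric(1)))
  } else 0
  list(dice = dice, n_lesion_voxels = sum(subj$lesion_mask$data),
       n_clusters = nrow(res$clusters), clusters = res$clusters)
}

#' Cluster-size-threshold base-rate calibration (atlas-based)
#'
#' Runs [calibrate_cluster_threshold()] in atlas-based mode on a healthy
#' reference group with subject-side residual registration error: the
#' false-positive base rate as a function of the extent threshold.
#'
#' @inheritParams experiment_null_clusters
#' @param thresholds Cluster-size thresholds.
#' @param residual_amplitude_mm Residual error for all registrations.
#' @param n_pseudo Number of pseudo-subjects (leave-one-out).
#' @return The calibration tibble from [calibrate_cluster_threshold()].
#' @export
experiment_threshold_calibration <- function(seed = 1L, n_controls = 16,
                                             thresholds = c(50L, 100L, 150L, 200L),
                                             residual_amplitude_mm = 2,
                                             n_pseudo = NULL,
                                             spec = phantom_spec(),
                                             cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec, n_controls = n_controls,
                              subjects = list(), seed = derive_seed(seed, 71L))
  }
  controls <- cohort$controls[seq_len(min(n_controls, length(cohort$controls)))]
  par <- analysis_params(residual_amplitude_mm = residual_amplitude_mm,
                         seed = derive_seed(seed, 73L))
  calibrate_cluster_threshold(controls, thresholds = thresholds,
                              mode = "abr", template = cohort$template,
                              params = par, max_subjects = n_pseudo)
}
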