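# Desk-scale cohort for the orchestration tests (32 voxel grid, mild
# anatomical variability, 6 controls).
study_spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_mm = 2,
                           brain_radii_vox = c(11, 13, 10), shell_vox = 2,
                           ventricle_radii_vox = c(3, 4, 3),
                           variability_amplitude_mm = 1.5,
                           variability_smoothness_mm = 10, seed = 21L)
study_cohort <- generate_cohort(study_spec, n_controls = 6,
                                subjects = list(NULL), seed = 11)

test_that("subject-based analysis never resamples the subject", {
  par <- analysis_params(residual_amplitude_mm = 1, min_size = 5, seed = 2)
  res <- run_analysis(study_cohort$subjects[[1]], study_cohort$controls,
                      "sbr", params = par)
  expect_identical(res$subject_fa$data, study_cohort$subjects[[1]]$fa$data)
  expect_identical(res$misreg$n_misreg, 0L)
  expect_identical(res$template_id, res$subject_id)
  expect_error(run_analysis(study_cohort$subjects[[1]], study_cohort$controls,
                            "sbr", template = study_cohort$template),
               "template")
})

test_that("atlas-based analysis registers the subject and quantifies misregistration", {
  par <- analysis_params(residual_amplitude_mm = 2, min_size = 5, seed = 2)
  res <- run_analysis(study_cohort$subjects[[1]], study_cohort$controls,
                      "abr", template = study_cohort$template, params = par)
  expect_false(identical(res$subject_fa$data, study_cohort$subjects[[1]]$fa$data))
  expect_gt(res$misreg$n_misreg, 0)
  expect_identical(res$template_id, "template")
  expect_error(run_analysis(study_cohort$subjects[[1]], study_cohort$controls,
                            "abr"), "template")
  g <- glance(res)
  expect_identical(g$mode, "abr")
  expect_identical(g$n_clusters, nrow(res$clusters))
})

test_that("analyses are reproducible from the seed", {
  par <- analysis_params(residual_amplitude_mm = 1, seed = 9)
  a <- run_analysis(study_cohort$subjects[[1]], study_cohort$controls, "sbr",
                    params = par)
  b <- run_analysis(study_cohort$subjects[[1]], study_cohort$controls, "sbr",
                    params = par)
  expect_identical(a$stat$t$data, b$stat$t$data)
  expect_identical(a$clusters$size, b$clusters$size)
})

test_that("a WM lesion is recovered by the subject-based analysis", {
  les <- lesion_spec(c(22, 16, 16), radius_mm = 5, fa_delta = 0.2)
  subj <- insert_lesion(study_cohort$subjects[[1]], les)
  par <- analysis_params(residual_amplitude_mm = 0, min_size = 20, seed = 3)
  res <- run_analysis(subj, study_cohort$controls, "sbr", params = par)
  expect_gte(nrow(res$clusters), 1)
  dice <- vapply(res$clusters$voxels, function(v) {
    m <- array(FALSE, dim(subj$fa$data)); m[v] <- TRUE
    2 * sum(m & subj$lesion_mask$data) /
      (sum(m) + sum(subj$lesion_mask$data))
  }, numeric(1))
  expect_gte(max(dice), 0.5)
})

test_that("mode comparison tabulates both analyses with the expected columns", {
  coh <- study_cohort
  coh$subjects <- rep(coh$subjects, 3)
  for (j in 1:3) coh$subjects[[j]]$id <- sprintf("s%d", j)
  par <- analysis_params(residual_amplitude_mm = 1.5, min_size = 10, seed = 4)
  cmp <- compare_modes(coh, par)
  expect_identical(names(cmp$table),
                   c("id", "sbr_clusters", "abr_clusters", "sbr_voxels",
                     "abr_voxels", "overlap_clusters", "abr_pct_misreg",
                     "abr_cluster_overlap_pct"))
  expect_identical(nrow(cmp$table), 3L)
  expect_true(all(cmp$table$overlap_clusters <= cmp$table$sbr_clusters))
  adj <- compare_modes(coh, par, adjust_voxels_to_subject = TRUE)
  ratio <- vapply(coh$subjects[1:3], function(s) {
    sum(s$seg$wm$data) / sum(coh$template$seg$wm$data)
  }, numeric(1))
  expect_equal(adj$table$abr_voxels, cmp$table$abr_voxels * ratio)
  if (!is.null(cmp$wilcoxon_clusters)) {
    expect_s3_class(cmp$wilcoxon_clusters, "sq_wilcoxon")
  }
})

test_that("threshold calibration validates inputs and yields monotone rates", {
  expect_error(calibrate_cluster_threshold(study_cohort$controls,
                                           thresholds = c(10, 5)),
               "increasing")
  expect_error(calibrate_cluster_threshold(study_cohort$controls[1:2]),
               "3 controls")
  par <- analysis_params(residual_amplitude_mm = 2, seed = 6)
  cal <- calibrate_cluster_threshold(study_cohort$controls,
                                     thresholds = c(5L, 20L, 80L),
                                     mode = "abr",
                                     template = study_cohort$template,
                                     params = par, max_subjects = 4)
  expect_identical(nrow(cal), 3L)
  expect_true(all(diff(cal$rate) <= 0))
  expect_true(all(cal$rate >= 0 & cal$rate <= 1))
  expect_identical(cal$n_subjects, rep(4L, 3)[seq_len(3)])
})

test_that("a vanishingly small alpha yields a zero base rate", {
  par <- analysis_params(alpha = 1e-12, residual_amplitude_mm = 0, seed = 6)
  cal <- calibrate_cluster_threshold(study_cohort$controls,
                                     thresholds = c(5L, 50L),
                                     mode = "sbr", params = par,
                                     max_subjects = 3)
  expect_identical(cal$rate, c(0, 0))
})

test_that("identity-warp nearest resampling leaves the analysis bit-identical", {
  par <- analysis_params(residual_amplitude_mm = 0, min_size = 5, seed = 7)
  imp <- interpolation_impact(study_cohort$subjects[[1]],
                              study_cohort$controls, params = par,
                              interpolation = "nearest")
  expect_true(imp$comparison$fa_identical)
  expect_identical(imp$comparison$cluster_diff, 0L)
  expect_identical(imp$comparison$voxel_diff, 0L)
  expect_identical(imp$baseline$stat$t$data, imp$perturbed$stat$t$data)
})

test_that("sub-voxel linear shift-and-back smooths without shifting results far", {
  par <- analysis_params(residual_amplitude_mm = 0, min_size = 5, seed = 8)
  imp <- interpolation_impact(study_cohort$subjects[[1]],
                              study_cohort$controls, params = par,
                              interpolation = "linear", shift_vox = 0.5)
  expect_false(imp$comparison$fa_identical)
  # smoothing perturbs the FA map but in a bounded way
  expect_lt(max(abs(imp$perturbed$subject_fa$data -
                    imp$baseline$subject_fa$data)), 0.2)
})
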