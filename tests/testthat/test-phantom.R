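# A desk-scale spec reused across phantom tests.
small_spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_mm = 2,
                           brain_radii_vox = c(11, 13, 10), shell_vox = 2,
                           ventricle_radii_vox = c(3, 4, 3),
                           variability_amplitude_mm = 1.5,
                           variability_smoothness_mm = 10, seed = 7L)

test_that("template generation is deterministic and geometrically consistent", {
  a <- make_template_phantom(small_spec)
  b <- make_template_phantom(small_spec)
  expect_identical(a$fa$data, b$fa$data)
  expect_identical(a$structural$data, b$structural$data)
  wm <- a$seg$wm$data; gm <- a$seg$gm$data; csf <- a$seg$csf$data
  expect_false(any(wm & gm) || any(wm & csf) || any(gm & csf))
  # union of tissues covers the brain ellipsoid exactly
  brain <- wm | gm | csf
  expect_true(all(a$fa$data[!brain] == 0))
  expect_gt(sum(wm), 500)
  expect_true(all(a$fa$data >= 0 & a$fa$data <= 1))
})

test_that("WM FA matches the requested distribution", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), seed = 11L)
  tpl <- make_template_phantom(spec)
  wm_fa <- tpl$fa$data[tpl$seg$wm$data]
  expect_equal(mean(wm_fa), 0.50, tolerance = 0.01)
  expect_equal(sd(wm_fa), sqrt(0.05^2 + 0.02^2), tolerance = 0.01)
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_spec(brain_radii_vox = c(5, 5, 5), shell_vox = 6),
               "degenerate")
  expect_error(phantom_spec(ventricle_radii_vox = c(30, 30, 30)), "nest")
  expect_error(phantom_spec(fa_params = list(wm = c(1.5, 0.05),
                                             gm = c(0.15, 0.03),
                                             csf = c(0.05, 0.02))),
               "\\[0, 1\\]")
  expect_error(phantom_spec(variability_smoothness_mm = 0), "smoothness")
})

test_that("zero-variability individuals equal the template up to fresh noise", {
  tpl <- make_template_phantom(small_spec)
  spec0 <- small_spec
  spec0$variability_amplitude_mm <- 0
  ind <- sample_individual(tpl, spec0, "c1", seed = 3)
  expect_identical(ind$seg$wm$data, tpl$seg$wm$data)
  expect_identical(ind$seg$csf$data, tpl$seg$csf$data)
  diff <- ind$fa$data - tpl$fa$data
  brain <- tpl$seg$wm$data | tpl$seg$gm$data | tpl$seg$csf$data
  expect_true(all(diff[!brain] == 0))
  # difference is two independent noise draws: sd ~ sqrt(2) * noise_sd (the
  # spatially correlated noise leaves the brain-restricted sd a few % loose)
  expect_equal(sd(diff[brain]), sqrt(2) * small_spec$noise_sd, tolerance = 0.05)
})

test_that("different seeds give distinct deformations; RMS matches amplitude", {
  tpl <- make_template_phantom(small_spec)
  i1 <- sample_individual(tpl, small_spec, "c1", seed = 1)
  i2 <- sample_individual(tpl, small_spec, "c2", seed = 2)
  expect_gt(max(abs(i1$truth_field$vectors - i2$truth_field$vectors)), 0)
  brain <- tpl$seg$wm$data | tpl$seg$gm$data | tpl$seg$csf$data
  mag2 <- i1$truth_field$vectors[, , , 1]^2 + i1$truth_field$vectors[, , , 2]^2 +
    i1$truth_field$vectors[, , , 3]^2
  rms <- sqrt(mean(mag2[brain]))
  expect_lt(abs(rms - small_spec$variability_amplitude_mm) /
              small_spec$variability_amplitude_mm, 0.3)
})

test_that("folding deformations are rejected with an informative error", {
  tpl <- make_template_phantom(small_spec)
  wild <- small_spec
  wild$variability_amplitude_mm <- 12
  wild$variability_smoothness_mm <- 6
  expect_error(sample_individual(tpl, wild, "x", seed = 1), "12")
})

test_that("lesion insertion reduces FA by exactly fa_delta inside sphere-in-WM", {
  tpl <- make_template_phantom(small_spec)
  expect_error(lesion_spec(c(16, 16, 16), 5, 0), "fa_delta")
  expect_error(lesion_spec(c(16, 16, 16), -1, 0.2), "radius")
  les <- lesion_spec(c(16, 21, 16), radius_mm = 5, fa_delta = 0.2)
  rec <- insert_lesion(tpl, les)
  mask <- rec$lesion_mask$data
  expect_gt(sum(mask), 10)
  # WM FA ~0.5, delta 0.2: no clipping, so the reduction is exact
  expect_equal(tpl$fa$data[mask] - rec$fa$data[mask], rep(0.2, sum(mask)))
  expect_identical(rec$fa$data[!mask], tpl$fa$data[!mask])
  expect_true(all(mask[!tpl$seg$wm$data] == FALSE))
})

test_that("lesion mask equals the brute-force sphere-and-WM voxel scan", {
  tpl <- make_template_phantom(small_spec)
  # near cortex: sphere pokes out of WM and must be clipped to it
  center <- c(24, 16, 16); r_mm <- 6
  les <- lesion_spec(center, r_mm, 0.1)
  rec <- insert_lesion(tpl, les)
  dims <- dim(tpl$fa$data)
  count <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    d2 <- sum(((c(i, j, k) - center) * 2)^2)
    if (d2 <= r_mm^2 && tpl$seg$wm$data[i, j, k]) count <- count + 1L
  }
  expect_identical(sum(rec$lesion_mask$data), count)
  expect_lt(count, sum(tpl$seg$wm$data))
})

test_that("lesions entirely outside WM are rejected", {
  tpl <- make_template_phantom(small_spec)
  expect_error(insert_lesion(tpl, lesion_spec(c(2, 2, 2), 2, 0.2)),
               "WM")
})

test_that("cohort generation writes a reproducible manifest and volumes", {
  dir1 <- file.path(tempdir(), "coh1"); dir2 <- file.path(tempdir(), "coh2")
  man1 <- make_cohort(small_spec, n_controls = 3,
                      subjects = list(NULL, lesion_spec(c(16, 21, 16), 5, 0.2)),
                      seed = 5, dir = dir1)
  man2 <- make_cohort(small_spec, n_controls = 3,
                      subjects = list(NULL, lesion_spec(c(16, 21, 16), 5, 0.2)),
                      seed = 5, dir = dir2)
  expect_equal(nrow(man1), 1 + 3 + 2)
  expect_equal(sum(man1$role == "control"), 3)
  expect_identical(man1$id, man2$id)
  expect_identical(names(man1),
                   c("id", "role", "fa_path", "struct_path", "wm_path",
                     "gm_path", "csf_path", "lesion_path"))
  # lesion-free subject has no lesion file; lesioned subject does
  expect_identical(man1$lesion_path[man1$id == "subj01"], "")
  expect_true(nzchar(man1$lesion_path[man1$id == "subj02"]))
  v1 <- read_volume(man1$fa_path[2]); v2 <- read_volume(man2$fa_path[2])
  expect_equal(v1$data, v2$data, tolerance = 1e-7)
  coh <- read_cohort(file.path(dir1, "manifest.tsv"))
  expect_length(coh$controls, 3)
  expect_s3_class(coh$subjects[[2]]$lesion_mask, "sq_volume")
  expect_error(generate_cohort(small_spec, n_controls = 1), "n_controls")
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("phantom specs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(small_spec, path)
  spec2 <- read_phantom_spec(path)
  expect_equal(unclass(spec2), unclass(small_spec))
})
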