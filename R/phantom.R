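#' Phantom generation parameters
#'
#' Defines the synthetic brain phantom used throughout the package: nested
#' ellipsoids (a cortical gray-matter shell around a white-matter interior
#' with central CSF ventricles), tissue-specific FA distributions, voxelwise
#' measurement noise, and the smooth random deformation model that turns the
#' template into individual anatomies.
#'
#' FA values are unitless in \[0, 1\]. The defaults (WM 0.50 +/- 0.05,
#' GM 0.15 +/- 0.03, CSF 0.05 +/- 0.02, measurement noise 0.02) give plausible
#' tissue contrast; they are artifact defaults, configurable, not measured
#' values. The per-tissue spread is realised as a *smooth* spatial texture
#' (fixed texture scale of 2 voxels) shared by all individuals through their
#' anatomical warps; on top of it, measurement noise with per-voxel sd
#' `noise_sd` and a short spatial correlation (0.8 voxel) is drawn fresh for
#' every individual: the texture models anatomy, the noise models the
#' acquisition chain, whose resampling steps leave FA noise slightly smooth
#' rather than white.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param brain_radii_vox Semi-axes of the outer brain ellipsoid, voxels.
#' @param shell_vox Cortical GM shell thickness, voxels.
#' @param ventricle_radii_vox Semi-axes of the central CSF ellipsoid, voxels.
#' @param fa_params Named list `wm`, `gm`, `csf`, each `c(mean, sd)`.
#' @param noise_sd Voxelwise FA measurement noise (sd).
#' @param variability_amplitude_mm RMS displacement of per-individual
#'   anatomical variability, mm.
#' @param variability_smoothness_mm Spatial scale of that variability, mm
#'   (> 0). Keep the ratio amplitude/smoothness well below ~0.3 or the
#'   deformations start to fold.
#' @param seed Integer seed for the template.
#' @return A validated `sq_phantom_spec` list.
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 32, 32))
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = 2,
                         brain_radii_vox = c(22, 26, 20),
                         shell_vox = 3,
                         ventricle_radii_vox = c(5, 8, 5),
                         fa_params = list(wm = c(0.50, 0.05),
                                          gm = c(0.15, 0.03),
                                          csf = c(0.05, 0.02)),
                         noise_sd = 0.02,
                         variability_amplitude_mm = 2,
                         variability_smoothness_mm = 10,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_size_mm = as.numeric(voxel_size_mm),
               brain_radii_vox = as.numeric(brain_radii_vox),
               shell_vox = as.numeric(shell_vox),
               ventricle_radii_vox = as.numeric(ventricle_radii_vox),
               fa_params = fa_params,
               noise_sd = as.numeric(noise_sd),
               variability_amplitude_mm = as.numeric(variability_amplitude_mm),
               variability_smoothness_mm = as.numeric(variability_smoothness_mm),
               seed = as.integer(seed))
  class(spec) <- "sq_phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L)) {
    stop_bad_arg("`grid_shape` must be three values >= 8")
  }
  if (spec$voxel_size_mm <= 0) stop_bad_arg("`voxel_size_mm` must be > 0")
  fa <- spec$fa_params
  for (t in c("wm", "gm", "csf")) {
    if (is.null(fa[[t]]) || length(fa[[t]]) != 2L) {
      stop_bad_arg("`fa_params$", t, "` must be c(mean, sd)")
    }
    if (fa[[t]][1] < 0 || fa[[t]][1] > 1) {
      stop_bad_arg("FA means must lie in [0, 1]")
    }
    if (fa[[t]][2] < 0) stop_bad_arg("FA sds must be >= 0")
  }
  if (spec$noise_sd < 0) stop_bad_arg("`noise_sd` must be >= 0")
  if (spec$variability_smoothness_mm <= 0) {
    stop_bad_arg("`variability_smoothness_mm` must be > 0")
  }
  if (spec$variability_amplitude_mm < 0) {
    stop_bad_arg("`variability_amplitude_mm` must be >= 0")
  }
  if (spec$shell_vox >= min(spec$brain_radii_vox)) {
    stop_bad_arg("degenerate geometry: GM shell thickness (", spec$shell_vox,
                 ") must be smaller than the smallest brain radius (",
                 min(spec$brain_radii_vox), ")")
  }
  inner <- spec$brain_radii_vox - spec$shell_vox
  if (any(spec$ventricle_radii_vox >= inner)) {
    stop_bad_arg("degenerate geometry: ventricles must nest inside the WM compartment")
  }
  if (any(spec$brain_radii_vox >= spec$grid_shape / 2)) {
    stop_bad_arg("brain ellipsoid must fit inside the grid with a border margin")
  }
  invisible(spec)
}

ellipsoid_mask <- function(dims, center, radii) {
  g <- grid_coords(dims)
  inside <- ((g$x - center[1]) / radii[1])^2 +
            ((g$y - center[2]) / radii[2])^2 +
            ((g$z - center[3]) / radii[3])^2 <= 1
  array(inside, dims)
}

# Smooth unit-variance texture field (Gaussian noise smoothed at a fixed
# 2-voxel scale, re-standardised).
texture_field <- function(dims) {
  f <- gaussian_smooth3(array(stats::rnorm(prod(dims)), dims), c(2, 2, 2))
  (f - mean(f)) / stats::sd(f)
}

# Measurement noise: Gaussian with a short spatial correlation (sigma 0.8
# voxel), per-voxel sd = `sd`. FA maps inherit smoothing from tensor fitting
# and distortion/alignment preprocessing, so their noise is not white; white
# noise would also exaggerate the variance lost to a single resampling step.
measurement_noise <- function(dims, sd) {
  if (sd == 0) return(array(0, dims))
  f <- gaussian_smooth3(array(stats::rnorm(prod(dims)), dims), c(0.8, 0.8, 0.8))
  f / stats::sd(f) * sd
}

#' Generate the template phantom brain
#'
#' Builds the canonical synthetic anatomy: disjoint WM/GM/CSF masks from
#' nested ellipsoids, an FA map with tissue-specific means, smooth per-tissue
#' texture and voxelwise noise (clipped to \[0, 1\]), and a structural volume
#' with distinct per-tissue intensity levels. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A subject record (class `sq_subject`): list with `id`, `fa`,
#'   `structural`, `seg`, `truth_field` (zero for the template),
#'   `truth_field_inv`, `lesion_mask` (`NULL`), plus internal noise-free
#'   intensity fields reused when individuals are sampled.
#' @export
make_template_phantom <- function(spec) {
  validate_phantom_spec(spec)
  dims <- spec$grid_shape
  sp <- rep(spec$voxel_size_mm, 3)
  center <- (dims + 1) / 2
  brain <- ellipsoid_mask(dims, center, spec$brain_radii_vox)
  inner <- ellipsoid_mask(dims, center, spec$brain_radii_vox - spec$shell_vox)
  csf <- ellipsoid_mask(dims, center, spec$ventricle_radii_vox)
  gm <- brain & !inner
  wm <- inner & !csf

  with_seed(spec$seed, {
    fa_clean <- array(0, dims)
    struct_clean <- array(0, dims)
    levels <- c(wm = 0.9, gm = 0.6, csf = 0.2)  # T1-like contrast, arbitrary units
    masks <- list(wm = wm, gm = gm, csf = csf)
    for (t in names(masks)) {
      tex <- texture_field(dims)
      fa_clean[masks[[t]]] <- spec$fa_params[[t]][1] +
        spec$fa_params[[t]][2] * tex[masks[[t]]]
      struct_clean[masks[[t]]] <- levels[[t]]
    }
    fa_clean <- pmin(pmax(fa_clean, 0), 1)
    fa <- fa_clean
    noise <- measurement_noise(dims, spec$noise_sd)
    fa[brain] <- fa[brain] + noise[brain]
    fa <- array(pmin(pmax(fa, 0), 1), dims)
    structural <- struct_clean
    snoise <- measurement_noise(dims, 0.02)
    structural[brain] <- structural[brain] + snoise[brain]
    structural <- array(structural, dims)

    seg <- sq_seg(sq_volume(array(wm, dims), sp, type = "mask"),
                  sq_volume(array(gm, dims), sp, type = "mask"),
                  sq_volume(array(csf, dims), sp, type = "mask"))
    new_subject(id = "template",
                fa = sq_volume(fa, sp),
                structural = sq_volume(structural, sp),
                seg = seg,
                truth_field = zero_field(dims, sp),
                truth_field_inv = zero_field(dims, sp),
                fa_clean = sq_volume(array(fa_clean, dims), sp),
                struct_clean = sq_volume(array(struct_clean, dims), sp))
  })
}

new_subject <- function(id, fa, structural, seg, truth_field = NULL,
                        truth_field_inv = NULL, lesion_mask = NULL,
                        fa_clean = NULL, struct_clean = NULL) {
  structure(list(id = id, fa = fa, structural = structural, seg = seg,
                 truth_field = truth_field, truth_field_inv = truth_field_inv,
                 lesion_mask = lesion_mask, fa_clean = fa_clean,
                 struct_clean = struct_clean),
            class = "sq_subject")
}

#' @export
print.sq_subject <- function(x, ...) {
  cat(sprintf("<sq_subject> id %s, grid %s%s%s\n", x$id,
              paste(dim(x$fa$data), collapse = "x"),
              if (!is.null(x$truth_field)) ", truth field known" else "",
              if (!is.null(x$lesion_mask)) sprintf(", lesion %d voxels",
                                                   sum(x$lesion_mask$data)) else ""))
  invisible(x)
}

#' Sample an individual anatomy from the template
#'
#' Warps the template by a random smooth deformation (the individual's ground
#' truth), resamples masks with nearest neighbour and noise-free intensities
#' with trilinear interpolation, then adds fresh voxelwise noise. The record
#' stores both the generating deformation (`truth_field`, pull convention:
#' individual sampled from template at `v + d(v)`) and its cached inverse,
#' which downstream registration simulation needs.
#'
#' @param template Record from [make_template_phantom()].
#' @param spec The [phantom_spec()] (variability and noise parameters).
#' @param id Subject identifier.
#' @param seed Integer seed for this individual.
#' @return An `sq_subject` record.
#' @export
sample_individual <- function(template, spec, id = "subject", seed = 1L) {
  dims <- spec$grid_shape
  sp <- rep(spec$voxel_size_mm, 3)
  brain <- brain_mask(template$seg)
  field <- random_smooth_field(dims, spacing = sp,
                               amplitude_mm = spec$variability_amplitude_mm,
                               smoothness_mm = spec$variability_smoothness_mm,
                               mask = brain, seed = seed)
  if (spec$variability_amplitude_mm > 0) {
    mj <- min_jacobian(field)
    if (mj <= 0) {
      stop_bad_arg(sprintf(
        "deformation folds the grid (min Jacobian %.3f <= 0) at amplitude %.2f mm; reduce variability_amplitude_mm or increase variability_smoothness_mm",
        mj, spec$variability_amplitude_mm))
    }
    # cached for registration simulation; 0.25-voxel accuracy is ample (a
    # 0.5 mm misalignment is far below the 2-voxel anatomy texture scale)
    # and holds across grid sizes where the 0.1-voxel default can be
    # interpolation-limited on small grids
    inv <- invert_field(field, tol = 0.25, max_iter = 100, mask = brain)
  } else {
    inv <- field
  }
  seg <- resample_seg(template$seg, field)
  ind_brain <- brain_mask(seg)
  fa_clean <- apply_displacement(template$fa_clean, field, "linear", fill = 0)
  struct_clean <- apply_displacement(template$struct_clean, field, "linear", fill = 0)
  fa <- fa_clean$data
  struct <- struct_clean$data
  with_seed(derive_seed(seed, 1L), {
    noise <- measurement_noise(dims, spec$noise_sd)
    fa[ind_brain$data] <- fa[ind_brain$data] + noise[ind_brain$data]
    snoise <- measurement_noise(dims, 0.02)
    struct[ind_brain$data] <- struct[ind_brain$data] + snoise[ind_brain$data]
  })
  fa[!ind_brain$data] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  new_subject(id = id,
              fa = sq_volume(array(fa, dims), sp),
              structural = sq_volume(array(struct, dims), sp),
              seg = seg,
              truth_field = field,
              truth_field_inv = inv,
              fa_clean = fa_clean,
              struct_clean = struct_clean)
}

#' Lesion specification
#'
#' A spherical focal FA reduction, the ground-truth analogue of a region of
#' abnormally low FA: `fa_delta` is subtracted inside (sphere intersect WM),
#' clipped at zero.
#'
#' @param center Length-3 voxel coordinates of the lesion center (1-based).
#' @param radius_mm Sphere radius in mm (> 0).
#' @param fa_delta FA reduction, in (0, 1].
#' @return An `sq_lesion_spec`.
#' @export
lesion_spec <- function(center, radius_mm, fa_delta) {
  if (radius_mm <= 0) stop_bad_arg("`radius_mm` must be > 0")
  if (fa_delta <= 0 || fa_delta > 1) stop_bad_arg("`fa_delta` must be in (0, 1]")
  structure(list(center = as.numeric(center), radius_mm = as.numeric(radius_mm),
                 fa_delta = as.numeric(fa_delta)),
            class = "sq_lesion_spec")
}

#' Insert a ground-truth lesion into a subject record
#'
#' @param record An `sq_subject`.
#' @param lesion An [lesion_spec()].
#' @return The record with reduced FA inside the lesion and `lesion_mask` set.
#' @export
insert_lesion <- function(record, lesion) {
  if (!inherits(lesion, "sq_lesion_spec")) stop_bad_arg("`lesion` must be a lesion_spec()")
  dims <- dim(record$fa$data)
  sp <- record$fa$spacing
  g <- grid_coords(dims)
  r_vox <- lesion$radius_mm / sp
  sphere <- ((g$x - lesion$center[1]) / r_vox[1])^2 +
            ((g$y - lesion$center[2]) / r_vox[2])^2 +
            ((g$z - lesion$center[3]) / r_vox[3])^2 <= 1
  mask <- array(sphere, dims) & record$seg$wm$data
  if (!any(mask)) {
    stop_bad_arg("lesion sphere does not intersect the WM mask; nothing to detect")
  }
  fa <- record$fa$data
  fa[mask] <- pmax(fa[mask] - lesion$fa_delta, 0)
  record$fa <- sq_volume(fa, sp, record$fa$origin)
  record$lesion_mask <- sq_volume(mask, sp, record$fa$origin, type = "mask")
  record
}

#' Generate a phantom cohort in memory
#'
#' Template, `n_controls` control anatomies, and one record per entry of
#' `subjects` (each `NULL` for a lesion-free subject or an [lesion_spec()]).
#' Mirrors a single-site normative study: every brain is an independent draw
#' from the same anatomical distribution.
#'
#' @param spec A [phantom_spec()].
#' @param n_controls Number of controls (>= 2; 48 matches the package's
#'   default normative-cohort size).
#' @param subjects List of `NULL`-or-[lesion_spec()], one per test subject.
#' @param seed Integer seed; all member seeds derive from it.
#' @return List with `template`, `controls` (list), `subjects` (list), `spec`.
#' @export
generate_cohort <- function(spec, n_controls = 48, subjects = list(NULL),
                            seed = 1L) {
  if (n_controls < 2) {
    stop_bad_arg("`n_controls` must be >= 2 (control variance undefined otherwise)")
  }
  spec$seed <- derive_seed(seed, 0L)
  template <- make_template_phantom(spec)
  controls <- lapply(seq_len(n_controls), function(i) {
    sample_individual(template, spec, id = sprintf("ctrl%02d", i),
                      seed = derive_seed(seed, i))
  })
  subj <- lapply(seq_along(subjects), function(j) {
    rec <- sample_individual(template, spec, id = sprintf("subj%02d", j),
                             seed = derive_seed(seed, 1000L + j))
    if (!is.null(subjects[[j]])) rec <- insert_lesion(rec, subjects[[j]])
    rec
  })
  list(template = template, controls = controls, subjects = subj, spec = spec)
}

#' Write a phantom cohort to disk (NIfTI volumes + TSV manifest)
#'
#' @inheritParams generate_cohort
#' @param dir Output directory (created if needed).
#' @return The manifest as a tibble (columns `id role fa_path struct_path
#'   wm_path gm_path csf_path lesion_path`), invisibly also written to
#'   `manifest.tsv` in `dir`.
#' @export
make_cohort <- function(spec, n_controls = 48, subjects = list(NULL),
                        seed = 1L, dir = ".") {
  cohort <- generate_cohort(spec, n_controls, subjects, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  dump <- function(rec, role) {
    base <- file.path(dir, rec$id)
    paths <- list(fa = paste0(base, "_fa.nii.gz"),
                  struct = paste0(base, "_struct.nii.gz"),
                  wm = paste0(base, "_wm.nii.gz"),
                  gm = paste0(base, "_gm.nii.gz"),
                  csf = paste0(base, "_csf.nii.gz"))
    write_volume(rec$fa, paths$fa)
    write_volume(rec$structural, paths$struct)
    write_volume(rec$seg$wm, paths$wm)
    write_volume(rec$seg$gm, paths$gm)
    write_volume(rec$seg$csf, paths$csf)
    lesion_path <- ""
    if (!is.null(rec$lesion_mask)) {
      lesion_path <- paste0(base, "_lesion.nii.gz")
      write_volume(rec$lesion_mask, lesion_path)
    }
    tibble::tibble(id = rec$id, role = role,
                   fa_path = paths$fa, struct_path = paths$struct,
                   wm_path = paths$wm, gm_path = paths$gm,
                   csf_path = paths$csf, lesion_path = lesion_path)
  }
  rows <- c(list(dump(cohort$template, "template")),
            lapply(cohort$controls, dump, role = "control"),
            lapply(cohort$subjects, dump, role = "subject"))
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a cohort written by [make_cohort()]
#'
#' Volumes are reloaded from NIfTI; truth fields are not serialised by
#' [make_cohort()], so reloaded cohorts support analyses that do not require
#' them (or attach fields kept elsewhere).
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @return A cohort list as from [generate_cohort()] (without truth fields).
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  load_rec <- function(row) {
    seg <- sq_seg(read_volume(row$wm_path, "mask"),
                  read_volume(row$gm_path, "mask"),
                  read_volume(row$csf_path, "mask"))
    lesion <- NULL
    if (nzchar(row$lesion_path %||% "")) {
      lesion <- read_volume(row$lesion_path, "mask")
    }
    new_subject(id = row$id, fa = read_volume(row$fa_path),
                structural = read_volume(row$struct_path), seg = seg,
                lesion_mask = lesion)
  }
  recs <- lapply(seq_len(nrow(man)), function(i) load_rec(man[i, ]))
  list(template = recs[[which(man$role == "template")[1]]],
       controls = recs[man$role == "control"],
       subjects = recs[man$role == "subject"],
       manifest = tibble::as_tibble(man))
}

#' Read / write a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec()` returns a validated spec.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$fa_params <- lapply(vals$fa_params, as.numeric)
  do.call(phantom_spec, vals)
}
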