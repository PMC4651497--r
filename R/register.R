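#' Exact phantom-truth registration map between two cohort members
#'
#' Both records were generated from one template by known deformations, so
#' the exact moving-to-target resampling field is the composition of the
#' target's generating deformation with the inverse of the moving record's
#' deformation: sampling the moving image through it reproduces the target's
#' anatomy (up to interpolation).
#'
#' @param moving,target `sq_subject` records carrying `truth_field` /
#'   `truth_field_inv` (phantom cohorts only).
#' @return The exact pull-convention `sq_field`.
#' @export
exact_registration_map <- function(moving, target) {
  if (is.null(moving$truth_field_inv) || is.null(target$truth_field)) {
    stop_bad_arg("truth deformation fields are required; for real images plug ",
                 "in an external deformable registration (out of scope here)")
  }
  compose_fields(target$truth_field, moving$truth_field_inv)
}

#' Simulate registration of one brain onto another
#'
#' Models an imperfect deformable registration as the exact phantom-truth map
#' corrupted by a fresh random smooth residual field of controlled RMS
#' amplitude: `residual_amplitude_mm = 0` reproduces the exact map, larger
#' amplitudes emulate the persistent limitations of real registration
#' algorithms. FA/structural volumes are resampled with trilinear
#' interpolation, tissue masks (and lesion masks) with nearest neighbour.
#'
#' @param moving,target `sq_subject` records from one phantom cohort.
#' @param residual_amplitude_mm RMS of the residual error field, mm (>= 0).
#' @param residual_smoothness_mm Spatial scale of the residual, mm.
#' @param seed Integer seed for the residual draw.
#' @param what Character vector of record components to resample, any of
#'   `"fa"`, `"structural"`, `"seg"`, `"lesion"`; trimming this saves time in
#'   large simulations.
#' @return List with `registered` (an `sq_subject` on the target grid, truth
#'   fields dropped) and `recovered` (the simulated registration `sq_field`).
#' @export
simulate_registration <- function(moving, target, residual_amplitude_mm = 0,
                                  residual_smoothness_mm = 6, seed = 1L,
                                  what = c("fa", "structural", "seg", "lesion")) {
  d_exact <- exact_registration_map(moving, target)
  if (residual_amplitude_mm > 0) {
    resid <- random_smooth_field(dim(d_exact$vectors)[1:3],
                                 spacing = d_exact$spacing,
                                 origin = d_exact$origin,
                                 amplitude_mm = residual_amplitude_mm,
                                 smoothness_mm = residual_smoothness_mm,
                                 mask = brain_mask(target$seg), seed = seed)
    recovered <- compose_fields(resid, d_exact)
  } else {
    recovered <- d_exact
  }
  fa <- if ("fa" %in% what) {
    apply_displacement(moving$fa, recovered, "linear", fill = 0)
  }
  structural <- if ("structural" %in% what) {
    apply_displacement(moving$structural, recovered, "linear", fill = 0)
  }
  seg <- if ("seg" %in% what) resample_seg(moving$seg, recovered)
  lesion <- if ("lesion" %in% what && !is.null(moving$lesion_mask)) {
    apply_displacement(moving$lesion_mask, recovered, "nearest", fill = 0)
  }
  list(registered = new_subject(id = moving$id, fa = fa,
                                structural = structural, seg = seg,
                                lesion_mask = lesion),
       recovered = recovered)
}
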