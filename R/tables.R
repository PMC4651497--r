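#' Template white-matter voxel counts of the two atlas templates
#'
#' The MNI- and JHU-template white-matter mask sizes used as denominators of
#' the misregistration percentages in the packaged cohort table
#' (`table3.tsv`).
#'
#' @format Named integer vector with entries `mni` and `jhu`.
#' @export
atlas_wm_voxels <- c(mni = 607633L, jhu = 567402L)

#' Load a packaged cohort table
#'
#' The four per-patient summary tables of the mTBI-vs-controls cohort study
#' ship with the package as TSV fixtures: (1) abnormally-low-FA cluster
#' counts per registration approach and their overlaps, (2) abnormal voxel
#' counts within clusters, (3) GM/CSF-onto-template-WM misregistration
#' counts and percentages, (4) percent overlap of cluster voxels with
#' misregistered voxels.
#'
#' @param which Table number, 1-4.
#' @return A tibble.
#' @export
paper_table <- function(which) {
  if (!which %in% 1:4) stop_bad_arg("`which` must be 1, 2, 3 or 4")
  path <- system.file("extdata", sprintf("table%d.tsv", which),
                      package = "surequant", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Summaries of the cluster-count table (Table 1 shape)
#'
#' Column sums, per-subject mean excess of atlas-based over subject-based
#' cluster counts, subject-based cluster recovery percentages, and the
#' number of subjects with at least one cluster per method.
#'
#' @param t1 Tibble with the six cluster-count columns of `paper_table(1)`.
#' @return One-row tibble of summary statistics.
#' @export
summarize_table1 <- function(t1) {
  need <- c("sbr_clusters", "abr_mni_clusters", "abr_jhu_clusters",
            "overlap_sbr_mni", "overlap_sbr_jhu", "overlap_mni_jhu")
  check_columns(t1, need)
  n <- nrow(t1)
  sum_sbr <- sum(t1$sbr_clusters)
  tibble::tibble(
    sum_sbr = sum_sbr,
    sum_abr_mni = sum(t1$abr_mni_clusters),
    sum_abr_jhu = sum(t1$abr_jhu_clusters),
    sum_overlap_sbr_mni = sum(t1$overlap_sbr_mni),
    sum_overlap_sbr_jhu = sum(t1$overlap_sbr_jhu),
    sum_overlap_mni_jhu = sum(t1$overlap_mni_jhu),
    excess_per_subject_mni = round_half_away(
      (sum(t1$abr_mni_clusters) - sum_sbr) / n, 1),
    excess_per_subject_jhu = round_half_away(
      (sum(t1$abr_jhu_clusters) - sum_sbr) / n, 1),
    subjects_with_sbr = sum(t1$sbr_clusters > 0),
    subjects_with_abr_mni = sum(t1$abr_mni_clusters > 0),
    subjects_with_abr_jhu = sum(t1$abr_jhu_clusters > 0),
    recovery_pct_mni = if (sum_sbr > 0) {
      round_half_away(100 * sum(t1$overlap_sbr_mni) / sum_sbr, 1)
    } else NA_real_,
    recovery_pct_jhu = if (sum_sbr > 0) {
      round_half_away(100 * sum(t1$overlap_sbr_jhu) / sum_sbr, 1)
    } else NA_real_)
}

#' Summaries of the abnormal-voxel-count table (Table 2 shape)
#'
#' Mean voxel increase per atlas template and, over the subjects with a
#' nonzero subject-based voxel count, the mean per-subject percentage
#' `100 * abr / sbr`. The published text phrases this quantity as "% more
#' voxels"; the mean-of-ratios reading implemented here is the one that
#' reproduces the printed values. Subjects with zero subject-based voxels
#' are excluded from the ratio mean (division guard, matching the published
#' restriction to subjects with subject-based clusters).
#'
#' @param t2 Tibble with the columns of `paper_table(2)`.
#' @return One-row tibble.
#' @export
summarize_table2 <- function(t2) {
  need <- c("sbr_voxels", "abr_mni_voxels", "abr_jhu_voxels")
  check_columns(t2, need)
  pos <- t2$sbr_voxels > 0
  tibble::tibble(
    mean_increase_mni = round_half_away(
      mean(t2$abr_mni_voxels - t2$sbr_voxels), 1),
    mean_increase_jhu = round_half_away(
      mean(t2$abr_jhu_voxels - t2$sbr_voxels), 1),
    n_sbr_positive = sum(pos),
    ratio_mean_mni = round_half_away(
      mean(100 * t2$abr_mni_voxels[pos] / t2$sbr_voxels[pos]), 1),
    ratio_mean_jhu = round_half_away(
      mean(100 * t2$abr_jhu_voxels[pos] / t2$sbr_voxels[pos]), 1))
}

#' Summaries of the misregistration table (Table 3 shape)
#'
#' Recomputes every per-patient percentage from the misregistered-voxel
#' counts and the template WM totals ([atlas_wm_voxels]), and reports the
#' column means. The denominator is the template WM count: this is the
#' convention that reproduces the printed percentages.
#'
#' @param t3 Tibble with the columns of `paper_table(3)`.
#' @return List with `summary` (one-row tibble) and `recomputed` (per-row
#'   tibble with recomputed percentages).
#' @export
summarize_table3 <- function(t3) {
  need <- c("misreg_mni", "misreg_jhu", "pct_mni", "pct_jhu")
  check_columns(t3, need)
  rec <- tibble::tibble(
    patient = t3$patient,
    pct_mni_recomputed = round_half_away(
      100 * t3$misreg_mni / atlas_wm_voxels[["mni"]], 1),
    pct_jhu_recomputed = round_half_away(
      100 * t3$misreg_jhu / atlas_wm_voxels[["jhu"]], 1))
  list(summary = tibble::tibble(
         mean_pct_mni = round_half_away(mean(t3$pct_mni), 1),
         mean_pct_jhu = round_half_away(mean(t3$pct_jhu), 1),
         all_recomputed_match = all(rec$pct_mni_recomputed == t3$pct_mni) &&
           all(rec$pct_jhu_recomputed == t3$pct_jhu)),
       recomputed = rec)
}

#' Summaries of the cluster/misregistration overlap table (Table 4 shape)
#'
#' Column means excluding `NA` entries (a patient with no clusters under a
#' method has an undefined overlap ratio), and verification that the
#' subject-based column is identically zero -- the subject cannot be
#' misregistered when it is itself the registration template.
#'
#' @param t4 Tibble with the columns of `paper_table(4)`.
#' @return One-row tibble.
#' @export
summarize_table4 <- function(t4) {
  need <- c("pct_sbr", "pct_mni", "pct_jhu")
  check_columns(t4, need)
  tibble::tibble(
    mean_pct_sbr = round_half_away(mean(t4$pct_sbr, na.rm = TRUE), 1),
    mean_pct_mni = round_half_away(mean(t4$pct_mni, na.rm = TRUE), 1),
    mean_pct_jhu = round_half_away(mean(t4$pct_jhu, na.rm = TRUE), 1),
    n_valid_mni = sum(!is.na(t4$pct_mni)),
    n_valid_jhu = sum(!is.na(t4$pct_jhu)),
    sbr_all_zero = all(t4$pct_sbr == 0))
}

check_columns <- function(tab, need) {
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_bad_arg("malformed table: missing column(s) ",
                 paste(missing, collapse = ", "))
  }
  for (col in need) {
    if (any(tab[[col]] < 0, na.rm = TRUE) && !grepl("increase", col)) {
      stop_bad_arg("malformed table: negative entries in ", col)
    }
  }
  invisible(TRUE)
}
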