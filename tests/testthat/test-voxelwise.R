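test_that("single-case t statistic matches the hand-evaluated formula", {
  dims <- c(2, 2, 1)
  mk <- function(val) sq_volume(array(val, dims))
  subject <- mk(0.30)
  controls <- list(mk(0.45), mk(0.50), mk(0.55))
  stat <- single_case_t_map(subject, controls, full_mask(dims))
  # x = 0.30, controls {0.45, 0.50, 0.55}: m = 0.50, s = 0.05, n = 3
  # t = -0.20 / (0.05 * sqrt(4/3)) = -3.4641, df = 2
  expect_equal(stat$t$data[1, 1, 1], -0.20 / (0.05 * sqrt(4 / 3)),
               tolerance = 1e-6)
  expect_equal(stat$t$data[1, 1, 1], -3.4641, tolerance = 1e-4)
  expect_identical(stat$df, 2L)
  expect_equal(stat$p$data[1, 1, 1], pt(-3.4641016, df = 2), tolerance = 1e-6)
})

test_that("subject at the control mean gives t = 0, p = 0.5", {
  dims <- c(2, 2, 1)
  subject <- sq_volume(array(0.5, dims))
  controls <- list(sq_volume(array(0.4, dims)), sq_volume(array(0.6, dims)))
  stat <- single_case_t_map(subject, controls, full_mask(dims))
  expect_equal(stat$t$data[1, 1, 1], 0)
  expect_equal(stat$p$data[1, 1, 1], 0.5)
})

test_that("zero control variance flags voxels invalid without raising", {
  dims <- c(2, 1, 1)
  subject <- sq_volume(array(0.3, dims))
  c1 <- array(0.5, dims); c2 <- array(0.5, dims); c3 <- array(0.5, dims)
  c2[2, 1, 1] <- 0.45; c3[2, 1, 1] <- 0.55
  controls <- list(sq_volume(c1), sq_volume(c2), sq_volume(c3))
  stat <- single_case_t_map(subject, controls, full_mask(dims))
  expect_false(stat$valid$data[1, 1, 1])
  expect_true(stat$valid$data[2, 1, 1])
  expect_true(is.na(stat$p$data[1, 1, 1]))
})

test_that("input contracts are enforced", {
  dims <- c(2, 2, 2)
  v <- sq_volume(array(0.5, dims))
  expect_error(single_case_t_map(v, list(v), full_mask(dims)), "2 controls")
  expect_error(single_case_t_map(v, list(v, sq_volume(array(0.5, c(3, 3, 3)))),
                                 full_mask(dims)), "mismatch")
  empty <- sq_volume(array(FALSE, dims), type = "mask")
  expect_error(single_case_t_map(v, list(v, v), empty), "empty")
})

test_that("cluster extraction handles empty, L-shaped, and boundary cases", {
  # nothing below threshold
  p1 <- array(0.5, c(5, 5, 1))
  s1 <- fake_statmap(p1)
  expect_identical(nrow(extract_clusters(s1, full_mask(c(5, 5, 1)),
                                         alpha = 0.005, min_size = 1)), 0L)
  # one 3-voxel L-shaped component and one isolated voxel, min_size 2
  p2 <- array(0.5, c(5, 5, 1))
  p2[2, 2, 1] <- 1e-4; p2[3, 2, 1] <- 1e-4; p2[3, 3, 1] <- 1e-4
  p2[5, 5, 1] <- 1e-4
  s2 <- fake_statmap(p2)
  cl <- extract_clusters(s2, full_mask(c(5, 5, 1)), alpha = 0.005,
                         min_size = 2, connectivity = 26)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$size, 3)
  # a straight line of exactly 100 voxels survives min_size = 100
  p3 <- array(0.5, c(102, 3, 3))
  p3[2:101, 2, 2] <- 1e-4
  s3 <- fake_statmap(p3)
  cl3 <- extract_clusters(s3, full_mask(c(102, 3, 3)), alpha = 0.005,
                          min_size = 100)
  expect_identical(nrow(cl3), 1L)
  expect_identical(cl3$size, 100)
  expect_error(extract_clusters(s3, full_mask(c(102, 3, 3)),
                                connectivity = 10), "connectivity")
  expect_error(extract_clusters(s3, full_mask(c(102, 3, 3)), alpha = 1.5),
               "alpha")
})

test_that("connectivity changes which voxels are contiguous", {
  p <- array(0.5, c(4, 4, 1))
  p[1, 1, 1] <- 1e-4; p[2, 2, 1] <- 1e-4   # diagonal neighbours
  s <- fake_statmap(p)
  cl26 <- extract_clusters(s, full_mask(c(4, 4, 1)), min_size = 2,
                           connectivity = 26)
  cl6 <- extract_clusters(s, full_mask(c(4, 4, 1)), min_size = 2,
                          connectivity = 6)
  expect_identical(nrow(cl26), 1L)
  expect_identical(nrow(cl6), 0L)
})

test_that("clusters are sorted by size then peak t, and are disjoint", {
  set.seed(42)
  p <- array(runif(512, 0.1, 1), c(8, 8, 8))
  p[1:3, 1:2, 1] <- 1e-4           # 6 voxels
  p[6:8, 6:8, 6:8] <- 1e-5         # 27 voxels
  s <- fake_statmap(p)
  cl <- extract_clusters(s, full_mask(c(8, 8, 8)), min_size = 2)
  expect_identical(cl$size, c(27, 6))
  expect_true(all(diff(cl$size) <= 0))
  allv <- do.call(rbind, cl$voxels)
  expect_identical(nrow(allv), nrow(unique(as.data.frame(allv))))
  lab <- attr(cl, "label_volume")
  expect_identical(sum(lab$data == 1), 27L)
})

test_that("cluster extraction agrees with the brute-force flood-fill oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    conn <- sample(c(6L, 18L, 26L), 1)
    p <- array(ifelse(runif(512) < 0.25, 1e-4, 0.5), c(8, 8, 8))
    s <- fake_statmap(p)
    cl <- extract_clusters(s, full_mask(c(8, 8, 8)), alpha = 0.005,
                           min_size = 1, connectivity = conn)
    comps <- oracle_components(p < 0.005, conn)
    expect_identical(nrow(cl), length(comps))
    expect_setequal(cl$size, vapply(comps, nrow, integer(1)))
    expect_identical(as.integer(sum(cl$size)), sum(p < 0.005))
  }
})

test_that("default analysis parameters are the published thresholds", {
  d <- voxelwise_defaults()
  expect_identical(d$alpha, 0.005)
  expect_identical(d$min_size, 100L)
  expect_identical(d$connectivity, 26L)
})

test_that("stat maps and cluster tables serialize to NIfTI/TSV", {
  dims <- c(6, 6, 6)
  subject <- sq_volume(array(0.3, dims))
  set.seed(1)
  controls <- lapply(1:5, function(i) sq_volume(array(rnorm(216, 0.5, 0.05), dims)))
  stat <- single_case_t_map(subject, controls, full_mask(dims))
  prefix <- tempfile()
  paths <- write_stat_map(stat, prefix)
  expect_true(all(file.exists(paste0(prefix, c("_tmap.nii.gz", "_pmap.nii.gz")))))
  cl <- extract_clusters(stat, full_mask(dims), min_size = 1)
  tsv <- tempfile(fileext = ".tsv")
  write_clusters(cl, tsv)
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), nrow(cl))
})
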