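test_that("object volumes are voxel counts times voxel volume", {
  lab <- array(0L, c(10, 10, 4))
  lab[1:5, 1:5, 1:4] <- 1L  # 100 voxels
  out <- object_volumes(lab, c(0.5, 0.1, 0.1))
  expect_equal(out$volume_um3, 0.5)
  expect_identical(out$voxel_count, 100L)
  empty <- object_volumes(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_identical(nrow(empty), 0L)
})

test_that("volume is invariant to axis permutation with permuted spacing", {
  mv <- make_mito_volume(5, seed = 21)
  lab <- segment_mito_3d(mv$image, "tomm20")
  v1 <- object_volumes(lab, mv$image$spacing)
  perm <- aperm(lab, c(3, 1, 2))
  sp <- unname(mv$image$spacing)  # (dz, dy, dx)
  v2 <- object_volumes(perm, sp[c(3, 1, 2)])  # same spacings in permuted slots
  expect_equal(sort(v1$volume_um3), sort(v2$volume_um3))
})

test_that("segmentation conserves labelled voxels and recovers known volumes", {
  mv <- make_mito_volume(20, seed = 3)
  lab <- segment_mito_3d(mv$image, "tomm20")
  vols <- object_volumes(lab, mv$image$spacing)
  expect_identical(nrow(vols), 20L)
  expect_identical(sum(vols$voxel_count), sum(lab > 0L))
  rel <- (sort(vols$volume_um3) - sort(mv$truth$objects$volume_um3)) /
    sort(mv$truth$objects$volume_um3)
  expect_true(all(abs(rel) <= 0.10))

  blank <- volume_image(array(0.2, c(16, 16, 8)), c(0.2, 0.1, 0.1), "tomm20")
  expect_error(segment_mito_3d(blank), class = "fiberquant_error_degenerate")
})

test_that("diagonal contact merges objects under 26-connectivity", {
  m <- array(FALSE, c(6, 6, 6))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE  # touches only diagonally
  lab <- label_components(m)
  expect_identical(max(lab), 1L)
  m[5, 5, 5] <- TRUE  # separated
  expect_identical(max(label_components(m)), 2L)
})

test_that("circularity behaves for canonical shapes", {
  disk <- make_disk_mask(50)
  sq <- make_rect_mask(70, 70, 50, 50)
  rod <- make_rect_mask(20, 120, 3, 100)
  res <- shape_metrics_2d(
    matrix(as.integer(disk), nrow(disk)), c(0.1, 0.1)
  )
  expect_gt(res$circularity, 0.95)
  expect_lt(res$circularity, 1.05)
  res_sq <- shape_metrics_2d(matrix(as.integer(sq), 70), c(0.1, 0.1))
  expect_equal(res_sq$circularity, pi / 4, tolerance = 0.05 / (pi / 4))
  res_rod <- shape_metrics_2d(matrix(as.integer(rod), 20), c(0.1, 0.1))
  expect_lt(res_rod$circularity, 0.3)
  # convex shapes never exceed 1 by more than the discretization tolerance
  for (r in c(8, 20, 35)) {
    d <- make_disk_mask(r)
    cc <- shape_metrics_2d(matrix(as.integer(d), nrow(d)), c(1, 1))$circularity
    expect_lt(cc, 1.1)
  }
  expect_error(
    shape_metrics_2d(matrix(1L, 5, 5), c(0.1, 0.2)),
    class = "fiberquant_error_validation"
  )
})

test_that("volume distribution summary uses midpoint median and a proper CDF", {
  expect_equal(volume_distribution_summary(c(1, 2, 3))$median_um3, 2)
  expect_equal(volume_distribution_summary(c(1, 2, 3, 4))$median_um3, 2.5)
  s <- volume_distribution_summary(withr::with_seed(5, rlnorm(100)))
  expect_equal(s$cdf$cum_fraction[nrow(s$cdf)], 1)
  expect_true(all(diff(s$cdf$cum_fraction) >= 0))
  expect_error(volume_distribution_summary(numeric()), class = "fiberquant_error_validation")
  expect_s3_class(autoplot(s), "ggplot")
  expect_equal(glance(s)$n_objects, 100L)
})

test_that("KS comparison flags a 2-fold median shift and honours edge cases", {
  same <- c(1, 2, 3, 4, 5)
  kt <- compare_distributions(same, same)
  expect_equal(kt$statistic, 0)
  expect_equal(kt$p_value, 1)
  expect_error(compare_distributions(1, c(1, 2)), class = "fiberquant_error_validation")

  hits <- withr::with_seed(6, {
    sum(replicate(20, {
      a <- rlnorm(500, meanlog = log(0.35), sdlog = 0.8)
      b <- rlnorm(500, meanlog = log(0.70), sdlog = 0.8)
      compare_distributions(a, b)$p_value < 0.01
    }))
  })
  expect_gte(hits, 19)
})
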