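test_that("fiber-frame generator produces exact stratified bin counts", {
  ff <- make_fiber_frame(1000, c(0.05, 0.065, 0.885), fiber_angle_deg = 35, seed = 9)
  expect_identical(unname(ff$truth$bin_counts), c(50L, 65L, 885L))
  expect_identical(sum(ff$truth$bin_counts), 1000L)
  # true relative angles lie inside their assigned bins
  obj <- ff$truth$objects
  lo <- c(`0-30` = 0, `30-60` = 30, `60-90` = 60)[obj$bin]
  expect_true(all(obj$rel_angle_true >= lo & obj$rel_angle_true < lo + 30))
  expect_error(
    make_fiber_frame(10, c(0.5, 0.5, 0.5), 0, seed = 1),
    class = "fiberquant_error_validation"
  )
  expect_error(
    make_fiber_frame(5000, c(1, 0, 0), 0, seed = 1, image_size = 300),
    class = "fiberquant_error_capacity"
  )
})

test_that("largest-remainder apportionment is exact for awkward fractions", {
  expect_identical(largest_remainder(1000, c(0.05, 0.065, 0.885)), c(50L, 65L, 885L))
  expect_identical(sum(largest_remainder(7, c(1, 1, 1) / 3)), 7L)
  expect_identical(largest_remainder(10, c(0.34, 0.33, 0.33)), c(4L, 3L, 3L))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- make_fiber_frame(40, c(0.2, 0.3, 0.5), 10, seed = 5)
  b <- make_fiber_frame(40, c(0.2, 0.3, 0.5), 10, seed = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$objects, b$truth$objects)

  mv1 <- make_mito_volume(5, seed = 2)
  mv2 <- make_mito_volume(5, seed = 2)
  expect_identical(mv1$image$voxels, mv2$image$voxels)

  ni1 <- make_nuclei_image(4, 2, noise_sd = 0.02, seed = 3)
  ni2 <- make_nuclei_image(4, 2, noise_sd = 0.02, seed = 3)
  expect_identical(ni1$image$voxels, ni2$image$voxels)

  ep1 <- make_endplate(0.4, 3, seed = 4)
  ep2 <- make_endplate(0.4, 3, seed = 4)
  expect_identical(ep1$image$voxels, ep2$image$voxels)

  dt1 <- make_deg_table(c(AIN_In = 3, AD_De_neg = 2), seed = 6)
  dt2 <- make_deg_table(c(AIN_In = 3, AD_De_neg = 2), seed = 6)
  expect_identical(dt1$records, dt2$records)
})

test_that("mito-volume ground truth is the voxelized volume", {
  mv <- make_mito_volume(
    3, volume_distribution = list(family = "fixed", values = 0.5),
    spacing = c(0.5, 0.1, 0.1), seed = 7
  )
  expect_equal(
    mv$truth$objects$volume_um3,
    mv$truth$objects$voxel_count * 0.5 * 0.1 * 0.1
  )
  # a 100-voxel object at (0.5, 0.1, 0.1) has volume 0.5 um^3 by arithmetic
  expect_equal(100 * prod(c(0.5, 0.1, 0.1)), 0.5)
  expect_error(
    make_mito_volume(
      1, volume_distribution = list(family = "fixed", values = 0.01),
      spacing = c(0.5, 0.1, 0.1), seed = 1
    ),
    class = "fiberquant_error_validation"
  )
})

test_that("nuclei generator injects the N/C ratio exactly before noise", {
  for (r in c(1, 2)) {
    ni <- make_nuclei_image(6, nc_ratio = r, noise_sd = 0, seed = 8)
    sig <- get_channel(ni$image, "ctbp1")
    nuc <- ni$truth$nuclei > 0L
    cyto <- ni$truth$fiber_mask & !nuc
    expect_equal(mean(sig[nuc]) / mean(sig[cyto]), r, tolerance = 1e-12)
  }
})

test_that("endplate generator realizes the dominance fraction and fragments exactly", {
  ep <- make_endplate(0.3, n_fragments = 4, seed = 10)
  M <- ep$truth$n_mask_voxels
  expect_identical(ep$truth$n_new, round(0.3 * M))
  expect_identical(sum(ep$truth$new_mask), as.integer(round(0.3 * M)))
  expect_identical(length(ep$truth$fragment_sizes), 4L)
  expect_true(all(ep$truth$fragment_sizes > 0L))

  ep0 <- make_endplate(0, n_fragments = 5, seed = 11)
  dom <- pixel_dominance(
    get_channel(ep0$image, "old"), get_channel(ep0$image, "new"), ep0$truth$mask
  )
  expect_equal(dom$new_fraction, 0)
  expect_equal(dom$old_fraction, 1)
  expect_equal(dom$tie_fraction, 0)
  expect_error(make_endplate(0.001, 3, seed = 1), class = "fiberquant_error_validation")
  expect_error(make_endplate(0.5, 40, seed = 1), class = "fiberquant_error_capacity")
})

test_that("deg-table generator round trips through classification", {
  counts <- c(AIN_InDe = 5, AD_De_pos = 7, AD_untouched = 11)
  dt <- make_deg_table(counts, seed = 12)
  cl <- classify_table(dt$records)
  got <- cl$class_counts$n[match(names(counts), cl$class_counts$class)]
  expect_identical(got, unname(as.integer(counts)))
  # per-gene agreement with the generator's own labels
  merged <- merge(tidy(cl), dt$truth$assignments, by = "gene")
  expect_identical(merged$class.x, merged$class.y)

  empty <- make_deg_table(c())
  expect_identical(nrow(empty$records), 0L)
  expect_error(
    make_deg_table(c(not_a_class = 3)),
    class = "fiberquant_error_validation"
  )
})
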