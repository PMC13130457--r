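test_that("relative_angle folds axial differences into [0, 90]", {
  expect_equal(relative_angle(45, 45), 0)
  expect_equal(relative_angle(150, 0), 30)
  expect_equal(relative_angle(10, 170), 20)
  expect_error(relative_angle(180, 0), class = "fiberquant_error_validation")
  expect_error(relative_angle(10, -1), class = "fiberquant_error_validation")

  # brute-force fold over a 1-degree grid, symmetry, and 180-periodicity
  grid <- seq(0, 179, by = 1)
  for (f in c(0, 17, 89, 135.5)) {
    got <- relative_angle(grid, rep(f, length(grid)))
    want <- vapply(grid, function(a) oracle_fold(a, f), numeric(1))
    expect_equal(got, want)
    expect_equal(got, relative_angle(rep(f, length(grid)), grid))  # symmetry
  }
})

test_that("bin_angles uses half-open edges with 90 closing the last bin", {
  s <- bin_angles(c(10, 45, 80))
  expect_identical(unname(s$counts), c(1L, 1L, 1L))
  expect_equal(unname(s$proportions), rep(1 / 3, 3))
  expect_identical(unname(bin_angles(30)$counts), c(0L, 1L, 0L))
  expect_equal(unname(bin_angles(c(90, 90))$proportions[3]), 1)
  expect_error(bin_angles(numeric()), class = "fiberquant_error_validation")
  expect_error(bin_angles(91), class = "fiberquant_error_validation")

  withr::with_seed(1, {
    for (i in 1:20) {
      s <- bin_angles(runif(50, 0, 90))
      expect_equal(sum(s$proportions), 1)
      expect_identical(sum(s$counts), s$n_total)
    }
  })
})

test_that("object orientation matches moment geometry and an eigen oracle", {
  horiz <- make_rect_mask(40, 40, 3, 20)
  vert <- make_rect_mask(40, 40, 20, 3)
  oh <- object_orientation(matrix(as.integer(horiz), 40, 40))
  ov <- object_orientation(matrix(as.integer(vert), 40, 40))
  expect_lt(min(oh$orientation_deg, 180 - oh$orientation_deg), 0.5)
  expect_equal(ov$orientation_deg, 90, tolerance = 0.5)
  expect_gt(oh$eccentricity, 0.9)

  diag45 <- outer(1:60, 1:60, function(i, j) abs(i - j) <= 1)
  od <- object_orientation(matrix(as.integer(diag45), 60, 60))
  expect_equal(od$orientation_deg, 45, tolerance = 2)
  expect_equal(od$orientation_deg, oracle_axis_angle(diag45), tolerance = 1)

  expect_identical(nrow(object_orientation(matrix(0L, 5, 5))), 0L)
})

test_that("bilateral filter denoises flat regions without moving edges", {
  ny <- 60L; nx <- 80L
  step <- matrix(rep(c(0.2, 0.8), each = ny * nx / 2), ny, nx)
  noisy <- withr::with_seed(2, step + matrix(rnorm(ny * nx, sd = 0.05), ny, nx))
  frame <- plane_image(noisy, c(0.1, 0.1))
  out <- preprocess_frame(frame, sigma_spatial = 2, sigma_range = 0.1)
  v_in <- var(as.vector(noisy[5:55, 5:30]))
  v_out <- var(as.vector(out$pixels[5:55, 5:30]))
  expect_lt(v_out, 0.5 * v_in)
  # half-max crossing of the mean profile stays within 1 px of the true edge
  prof <- colMeans(out$pixels)
  cross <- which(prof >= 0.5)[1]
  expect_lte(abs(cross - (nx / 2 + 1)), 1)
  # a constant image is a fixed point
  const <- plane_image(matrix(0.4, 20, 20), c(1, 1))
  expect_equal(preprocess_frame(const, 2, 0.1)$pixels, const$pixels, tolerance = 1e-12)
  expect_error(preprocess_frame(frame, 0, 0.1), class = "fiberquant_error_validation")
})

test_that("fiber segmentation recovers the band axis", {
  ff <- make_fiber_frame(30, c(1, 0, 0), fiber_angle_deg = 30, seed = 3)
  pre <- preprocess_frame(ff$image)
  fib <- segment_fiber(pre)
  expect_equal(fib$angle_deg, 30, tolerance = 2)

  band <- matrix(0.05, 120, 120)
  band[50:70, ] <- 0.8
  fib2 <- segment_fiber(plane_image(band, c(0.1, 0.1)))
  expect_lt(min(fib2$angle_deg, 180 - fib2$angle_deg), 1)

  expect_error(
    segment_fiber(plane_image(matrix(0.5, 50, 50), c(1, 1))),
    class = "fiberquant_error_degenerate"
  )
})

test_that("Frangi enhancement is bounded and selective for tubular structures", {
  blank <- plane_image(matrix(0.3, 50, 50), c(1, 1))
  expect_true(all(enhance_tubular(blank, 1:3)$pixels == 0))

  img <- matrix(0.05, 60, 120)
  img[29:33, 10:110] <- 1  # rod of radius ~2 px
  v <- enhance_tubular(plane_image(img, c(1, 1)), scales = 1:3)$pixels
  expect_true(all(v >= 0 & v <= 1))
  centerline <- mean(v[31, 15:105])
  background <- mean(v[c(1:15, 45:60), ])
  expect_gt(centerline, 5 * background)

  rnd <- withr::with_seed(4, matrix(runif(900), 30, 30))
  vr <- enhance_tubular(plane_image(rnd, c(1, 1)), c(1, 2))$pixels
  expect_true(all(vr >= 0 & vr <= 1))
  expect_error(enhance_tubular(blank, numeric()), class = "fiberquant_error_validation")
})

test_that("mitochondria segmentation counts separated rods and filters speckle", {
  v <- matrix(0, 60, 60)
  v[10:12, 5:50] <- 0.9
  v[30:32, 5:50] <- 0.9
  v[50:52, 5:50] <- 0.9
  mask <- matrix(TRUE, 60, 60)
  lab <- segment_mitochondria(plane_image(v, c(1, 1)), mask, min_area_px = 10)
  expect_identical(max(lab), 3L)

  v2 <- matrix(0, 40, 60)
  v2[20:22, 5:50] <- 0.9
  v2[5, 5:6] <- 0.9  # 2-px speckle
  lab2 <- segment_mitochondria(plane_image(v2, c(1, 1)), matrix(TRUE, 40, 60), 10)
  expect_identical(max(lab2), 1L)

  blank <- plane_image(matrix(0, 30, 30), c(1, 1))
  expect_identical(max(segment_mitochondria(blank, matrix(TRUE, 30, 30), 10)), 0L)
})

test_that("pipeline recovers pure single-bin mixtures", {
  for (cse in list(list(fr = c(1, 0, 0), bin = 1), list(fr = c(0, 0, 1), bin = 3))) {
    ff <- make_fiber_frame(300, cse$fr, fiber_angle_deg = 25, seed = 13)
    res <- run_orientation_pipeline(plane_to_volume(ff$image))
    expect_false(res$unreliable)
    expect_gte(res$summary$proportions[cse$bin], 0.95)
  }
})

test_that("a blank stack yields zero objects flagged unreliable", {
  blank <- volume_image(array(0.2, c(64, 64, 3)), c(0.5, 0.1, 0.1), "tomm20")
  res <- run_orientation_pipeline(blank)
  expect_true(res$unreliable)
  expect_identical(res$n_objects, 0L)
  expect_null(res$summary)
})

test_that("recovered relative angles are equivariant under frame rotation", {
  f1 <- make_fiber_frame(150, c(0.3, 0.3, 0.4), fiber_angle_deg = 20, seed = 14)
  f2 <- make_fiber_frame(150, c(0.3, 0.3, 0.4), fiber_angle_deg = 35, seed = 14)
  r1 <- run_orientation_pipeline(plane_to_volume(f1$image))
  r2 <- run_orientation_pipeline(plane_to_volume(f2$image))
  a1 <- sort(r1$objects$relative_angle_deg[r1$objects$used_in_summary])
  a2 <- sort(r2$objects$relative_angle_deg[r2$objects$used_in_summary])
  n <- min(length(a1), length(a2))
  expect_lt(median(abs(a1[seq_len(n)] - a2[seq_len(n)])), 3)
})

test_that("glance and tidy expose the pipeline result as tibbles", {
  ff <- make_fiber_frame(60, c(0, 0, 1), fiber_angle_deg = 10, seed = 15)
  res <- run_orientation_pipeline(plane_to_volume(ff$image))
  g <- glance(res)
  expect_identical(nrow(g), 1L)
  expect_equal(g$prop_0_30 + g$prop_30_60 + g$prop_60_90, 1)
  expect_true(all(c("relative_angle_deg", "eccentricity") %in% names(tidy(res))))
  expect_s3_class(autoplot(res), "ggplot")
})
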