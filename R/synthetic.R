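# Seeded generators producing every input class with exact ground truth.
# Ground-truth quantities are exact by construction (stratified counts,
# voxelized volumes, exact dominance counts), never estimated, and every
# generator is a pure function of its arguments including the seed.

#' Promote a plane to a single-channel volume
#'
#' Convenience for feeding generated frames to stack-level pipelines.
#'
#' @param plane A [plane_image()].
#' @param channel_name Channel label (default `"tomm20"`).
#' @param dz Out-of-plane spacing in micrometres (default 0.5).
#' @return A [volume_image()] with one z-plane.
#' @export
plane_to_volume <- function(plane, channel_name = "tomm20", dz = 0.5) {
  stopifnot(inherits(plane, "plane_image"))
  volume_image(
    array(plane$pixels, c(dim(plane$pixels), 1L)),
    spacing = c(dz, plane$spacing),
    channel_names = channel_name
  )
}

# Distance from grid points to the segment AB (all in pixel coordinates).
dist_to_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx^2 + vy^2
  t <- if (l2 > 0) pmin(pmax(((px - ax) * vx + (py - ay) * vy) / l2, 0), 1) else 0
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Synthetic central frame with rods at a controlled angle mixture
#'
#' Renders one bright fiber band at `fiber_angle_deg` containing
#' `n_objects` non-overlapping rods (tubular mitochondria). Per-bin object
#' counts are EXACT stratified counts via [largest_remainder()]; within its
#' assigned bin each rod's true fiber-relative angle is uniform. Rods are
#' rendered by distance-to-segment thresholding with 1-pixel Gaussian edge
#' softening; additive Gaussian noise of `noise_sd` is applied last.
#' Identical seeds give bit-identical output.
#'
#' @param n_objects Number of rods (>= 1).
#' @param bin_fractions Length-3 fractions for the 0-30 / 30-60 / 60-90
#'   degree bins; non-negative, summing to 1 within 1e-9.
#' @param fiber_angle_deg Fiber axis angle in `[0, 180)`.
#' @param noise_sd Additive Gaussian noise sd (intensity units; peak = 1).
#' @param seed Integer seed.
#' @param spacing `(dy, dx)` in micrometres (isotropic).
#' @param image_size Side of the square frame in pixels; `NULL` scales with
#'   `n_objects`.
#' @param rod_length,rod_radius Ranges (px) for rod dimensions.
#' @param gap_px Minimum clearance between rods (px).
#' @param band_width_frac Fiber band width as a fraction of the image side.
#' @param band_margin_px Clearance between rods and the band edge (px).
#' @param peak,band_level,background Intensity levels of rods, fiber band and
#'   surround.
#' @param max_tries Placement retries per rod before a capacity error.
#' @return List with `image` (a [plane_image()]) and `truth`: per-object
#'   tibble (`id`, `bin`, `rel_angle_true`, `angle_abs_deg`, position and
#'   size), exact `bin_counts`, `fiber_angle_deg`, `seed` and parameters.
#' @export
make_fiber_frame <- function(n_objects, bin_fractions, fiber_angle_deg,
                             noise_sd = 0.05, seed = 1L,
                             spacing = c(0.1, 0.1), image_size = NULL,
                             rod_length = c(8, 14), rod_radius = c(1.2, 1.8),
                             gap_px = 4, band_width_frac = 0.45,
                             band_margin_px = 14, peak = 1,
                             band_level = 0.35, background = 0.05,
                             max_tries = 500L) {
  n_objects <- assert_count(n_objects, "n_objects", min = 1L)
  if (length(bin_fractions) != 3L) stop_validation("`bin_fractions` must have length 3")
  if (!is.finite(fiber_angle_deg) || fiber_angle_deg < 0 || fiber_angle_deg >= 180) {
    stop_validation("`fiber_angle_deg` must lie in [0, 180)")
  }
  if (noise_sd < 0) stop_validation("`noise_sd` must be non-negative")
  counts <- largest_remainder(n_objects, bin_fractions)  # validates fractions
  side <- image_size %||% max(512L, ceiling(sqrt(n_objects * 1250)))

  withr::with_seed(seed, {
    # assigned bins and true relative angles (uniform within each bin)
    bin <- rep.int(1:3, counts)
    lo <- c(0, 30, 60)[bin]
    rel <- lo + runif(n_objects) * 30
    ord <- sample.int(n_objects)  # placement order independent of bin order
    bin <- bin[ord]; rel <- rel[ord]
    sgn <- sample(c(-1, 1), n_objects, replace = TRUE)
    phi <- (fiber_angle_deg + sgn * rel) %% 180

    theta <- fiber_angle_deg * pi / 180
    nvec <- c(-sin(theta), cos(theta))   # band normal in (x, y)
    c0 <- (side + 1) / 2
    halfw <- band_width_frac * side / 2
    img <- matrix(background, side, side)
    colx <- matrix(rep(seq_len(side), each = side), side, side)  # x = column
    rowy <- matrix(rep(seq_len(side), side), side, side)         # y = row
    band <- abs((colx - c0) * nvec[1] + (rowy - c0) * nvec[2]) <= halfw
    img[band] <- band_level
    occupied <- matrix(FALSE, side, side)

    L <- runif(n_objects, rod_length[1], rod_length[2])
    R <- runif(n_objects, rod_radius[1], rod_radius[2])
    cxs <- cys <- numeric(n_objects)
    inner <- halfw - band_margin_px
    if (inner <= 0) stop_validation("band too narrow for `band_margin_px`")

    for (o in seq_len(n_objects)) {
      u <- c(cos(phi[o] * pi / 180), sin(phi[o] * pi / 180))
      half <- L[o] / 2
      reach <- half + R[o] + gap_px + 2
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- runif(1, 1 + reach, side - reach)
        cy <- runif(1, 1 + reach, side - reach)
        ends_x <- cx + c(-half, half) * u[1]
        ends_y <- cy + c(-half, half) * u[2]
        perp <- abs((c(ends_x, cx) - c0) * nvec[1] + (c(ends_y, cy) - c0) * nvec[2])
        if (max(perp) > inner - R[o]) next
        x0 <- floor(cx - reach); x1 <- ceiling(cx + reach)
        y0 <- floor(cy - reach); y1 <- ceiling(cy + reach)
        gx <- x0:x1; gy <- y0:y1
        pxm <- matrix(rep(gx, each = length(gy)), length(gy), length(gx))
        pym <- matrix(rep(gy, length(gx)), length(gy), length(gx))
        d <- dist_to_segment(pxm, pym, ends_x[1], ends_y[1], ends_x[2], ends_y[2])
        stamp <- d <= R[o] + gap_px
        occ <- occupied[gy, gx]
        if (any(occ & stamp)) next
        soft <- exp(-pmax(0, d - R[o])^2 / 2)
        patch <- img[gy, gx]
        img[gy, gx] <- pmax(patch, band_level + (peak - band_level) * soft * (soft > 0.01))
        occupied[gy, gx] <- occ | stamp
        cxs[o] <- cx; cys[o] <- cy
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_capacity(sprintf(
          "could not place rod %d of %d after %d tries; reduce n_objects or enlarge the frame",
          o, n_objects, max_tries
        ))
      }
    }
    if (noise_sd > 0) img <- pmax(img + rnorm(length(img), sd = noise_sd), 0)

    truth <- list(
      objects = tibble(
        id = seq_len(n_objects),
        bin = c("0-30", "30-60", "60-90")[bin],
        rel_angle_true = rel,
        angle_abs_deg = phi,
        cx = cxs, cy = cys, length_px = L, radius_px = R
      ),
      bin_counts = stats::setNames(counts, c("0-30", "30-60", "60-90")),
      fiber_angle_deg = fiber_angle_deg,
      n_objects = n_objects,
      seed = seed,
      params = list(
        noise_sd = noise_sd, image_size = side, band_width_frac = band_width_frac,
        peak = peak, band_level = band_level, background = background
      )
    )
    list(image = plane_image(img, validate_spacing(spacing, 2L)), truth = truth)
  })
}

#' Synthetic 3D stack of ellipsoidal mitochondria with known volumes
#'
#' Places non-touching ellipsoids whose target volumes are drawn from a named
#' distribution family; the recorded ground-truth volume of each object is
#' its voxelized volume (rendered voxel count times the voxel volume), not
#' the continuous target.
#'
#' @param n_objects Number of ellipsoids (>= 1).
#' @param volume_distribution List: `family` one of `"lognormal"`
#'   (`meanlog`, `sdlog`), `"uniform"` (`min`, `max`) or `"fixed"`
#'   (`values`, recycled); volumes in um^3.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @param seed Integer seed.
#' @param dims Optional `(nz, ny, nx)`; `NULL` scales with the requested
#'   total volume.
#' @param gap_vox Minimum clearance between objects, voxels.
#' @param intensity,background,noise_sd Intensity model.
#' @param max_tries Placement retries per object.
#' @return List with `image` (a [volume_image()], channel `"tomm20"`) and
#'   `truth`: per-object tibble (`id`, `voxel_count`, `volume_um3`,
#'   `target_um3`, centre), `seed`, `spacing`.
#' @export
make_mito_volume <- function(n_objects,
                             volume_distribution = list(
                               family = "lognormal", meanlog = log(0.35), sdlog = 0.8
                             ),
                             spacing = c(0.2, 0.1, 0.1), seed = 1L, dims = NULL,
                             gap_vox = 2, intensity = 1, background = 0.05,
                             noise_sd = 0.02, max_tries = 500L) {
  n_objects <- assert_count(n_objects, "n_objects", min = 1L)
  spacing <- validate_spacing(spacing, 3L)
  voxvol <- prod(spacing)

  withr::with_seed(seed, {
    targets <- switch(volume_distribution$family,
      lognormal = rlnorm(n_objects, volume_distribution$meanlog, volume_distribution$sdlog),
      uniform = runif(n_objects, volume_distribution$min, volume_distribution$max),
      fixed = rep_len(volume_distribution$values, n_objects),
      stop_validation(sprintf("unknown volume family '%s'", volume_distribution$family))
    )
    if (any(targets / voxvol < 8)) {
      stop_validation("every requested volume must cover at least 8 voxels at this spacing")
    }
    est_total <- sum(targets) / voxvol
    if (is.null(dims)) {
      base <- (est_total * 20)^(1 / 3)
      dims <- c(max(24, ceiling(base)), max(64, ceiling(1.6 * base)), max(64, ceiling(1.6 * base)))
    }
    dims <- as.integer(dims)  # (nz, ny, nx)
    nzv <- dims[1]; nyv <- dims[2]; nxv <- dims[3]
    arr <- array(background, c(nyv, nxv, nzv))
    occupied <- array(FALSE, c(nyv, nxv, nzv))

    vox_counts <- integer(n_objects)
    centres <- matrix(NA_real_, n_objects, 3)
    for (o in seq_len(n_objects)) {
      r0 <- (3 * targets[o] / (4 * pi))^(1 / 3)  # um
      f1 <- runif(1, 0.75, 1.3); f2 <- runif(1, 0.75, 1.3)
      ax_um <- c(r0 * f1, r0 * f2, r0 / (f1 * f2))  # (z, y, x) semi-axes
      ext <- ceiling(ax_um / spacing) + gap_vox + 1L  # (z, y, x)
      if (any(2L * ext + 1L >= dims)) {
        stop_capacity("an object is too large for the volume; enlarge `dims`")
      }
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ctr <- runif(3, 1 + ext, dims - ext)  # (z, y, x)
        zi <- floor(ctr[1] - ext[1]):ceiling(ctr[1] + ext[1])
        yi <- floor(ctr[2] - ext[2]):ceiling(ctr[2] + ext[2])
        xi <- floor(ctr[3] - ext[3]):ceiling(ctr[3] + ext[3])
        dz2 <- ((zi - ctr[1]) * spacing[1])
        dy2 <- ((yi - ctr[2]) * spacing[2])
        dx2 <- ((xi - ctr[3]) * spacing[3])
        # (y, x, z) block to match array layout
        q <- outer(outer((dy2 / ax_um[2])^2, (dx2 / ax_um[3])^2, "+"), (dz2 / ax_um[1])^2, "+")
        inside <- q <= 1
        gpad <- gap_vox * max(spacing)
        stamp <- outer(
          outer((dy2 / (ax_um[2] + gpad))^2, (dx2 / (ax_um[3] + gpad))^2, "+"),
          (dz2 / (ax_um[1] + gpad))^2, "+"
        ) <= 1
        occ <- occupied[yi, xi, zi]
        if (any(occ & stamp)) next
        blk <- arr[yi, xi, zi]
        blk[inside] <- intensity
        arr[yi, xi, zi] <- blk
        occupied[yi, xi, zi] <- occ | stamp
        vox_counts[o] <- sum(inside)
        centres[o, ] <- ctr
        placed <- TRUE
        break
      }
      if (!placed) stop_capacity(sprintf("could not place object %d of %d", o, n_objects))
    }
    if (noise_sd > 0) arr <- pmax(arr + rnorm(length(arr), sd = noise_sd), 0)
    list(
      image = volume_image(arr, spacing = spacing, channel_names = "tomm20"),
      truth = list(
        objects = tibble(
          id = seq_len(n_objects),
          voxel_count = vox_counts,
          volume_um3 = vox_counts * voxvol,
          target_um3 = targets,
          cz = centres[, 1], cy = centres[, 2], cx = centres[, 3]
        ),
        seed = seed, spacing = spacing
      )
    )
  })
}

#' Synthetic two-channel nucleus/cytoplasm stack with an injected N/C ratio
#'
#' Two channels, `"dapi"` (bright only inside nuclei) and `"ctbp1"` (mean
#' `nc_ratio * cyto_level` inside nuclei, `cyto_level` in the fiber
#' cytoplasm, near-zero outside the fiber), before additive noise. Nuclei are
#' disjoint ellipsoids fully inside the fiber region.
#'
#' @param n_nuclei Number of nuclei (>= 1).
#' @param nc_ratio Injected nuclear/cytoplasmic mean-intensity ratio (> 0).
#' @param cyto_level Cytoplasmic mean intensity.
#' @param noise_sd Additive Gaussian noise sd (both channels).
#' @param seed Integer seed.
#' @param dims `(nz, ny, nx)` array dimensions.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @param nucleus_semiaxes Nucleus ellipsoid semi-axes `(z, y, x)` in voxels.
#' @return List with `image` (a [volume_image()]) and `truth`: `nuclei`
#'   (exact label array), `fiber_mask`, `nc_ratio`, per-nucleus voxel counts,
#'   `seed`.
#' @export
make_nuclei_image <- function(n_nuclei, nc_ratio, cyto_level = 0.4,
                              noise_sd = 0, seed = 1L,
                              dims = c(14, 140, 280), spacing = c(0.3, 0.2, 0.2),
                              nucleus_semiaxes = c(3, 7, 7)) {
  n_nuclei <- assert_count(n_nuclei, "n_nuclei", min = 1L)
  assert_positive_scalar(nc_ratio, "nc_ratio")
  assert_positive_scalar(cyto_level, "cyto_level")
  if (noise_sd < 0) stop_validation("`noise_sd` must be non-negative")
  spacing <- validate_spacing(spacing, 3L)
  dims <- as.integer(dims)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]

  withr::with_seed(seed, {
    fiber <- array(FALSE, c(ny, nx, nz))
    yr <- round(0.15 * ny):round(0.85 * ny)
    zr <- 2:(nz - 1)
    fiber[yr, , zr] <- TRUE

    lab <- array(0L, c(ny, nx, nz))
    semi <- nucleus_semiaxes  # (z, y, x)
    margin <- 5L
    for (o in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        cz <- runif(1, min(zr) + semi[1] + 1, max(zr) - semi[1] - 1)
        cy <- runif(1, min(yr) + semi[2] + margin, max(yr) - semi[2] - margin)
        cx <- runif(1, 1 + semi[3] + margin, nx - semi[3] - margin)
        zi <- floor(cz - semi[1]):ceiling(cz + semi[1])
        yi <- floor(cy - semi[2] - 2):ceiling(cy + semi[2] + 2)
        xi <- floor(cx - semi[3] - 2):ceiling(cx + semi[3] + 2)
        q <- outer(
          outer(((yi - cy) / semi[2])^2, ((xi - cx) / semi[3])^2, "+"),
          ((zi - cz) / semi[1])^2, "+"
        )
        inside <- q <= 1
        # keep a 2-voxel in-plane clearance between nuclei
        stamp <- outer(
          outer(((yi - cy) / (semi[2] + 2))^2, ((xi - cx) / (semi[3] + 2))^2, "+"),
          ((zi - cz) / (semi[1] + 1))^2, "+"
        ) <= 1
        blk <- lab[yi, xi, zi]
        if (any(blk[stamp] > 0L)) next
        blk[inside] <- o
        lab[yi, xi, zi] <- blk
        placed <- TRUE
        break
      }
      if (!placed) stop_capacity(sprintf("could not place nucleus %d of %d", o, n_nuclei))
    }

    nucmask <- lab > 0L
    ctbp1 <- array(0.02, c(ny, nx, nz))
    ctbp1[fiber] <- cyto_level
    ctbp1[nucmask] <- nc_ratio * cyto_level
    dapi <- array(0.02, c(ny, nx, nz))
    dapi[nucmask] <- 0.9
    if (noise_sd > 0) {
      ctbp1 <- pmax(ctbp1 + rnorm(length(ctbp1), sd = noise_sd), 0)
      dapi <- pmax(dapi + rnorm(length(dapi), sd = noise_sd), 0)
    }
    vox <- array(0, c(ny, nx, nz, 2L))
    vox[, , , 1L] <- dapi
    vox[, , , 2L] <- ctbp1
    list(
      image = volume_image(vox, spacing = spacing, channel_names = c("dapi", "ctbp1")),
      truth = list(
        nuclei = lab, fiber_mask = fiber, nc_ratio = nc_ratio,
        cyto_level = cyto_level,
        voxel_counts = tabulate(lab[lab > 0L], nbins = n_nuclei),
        seed = seed
      )
    )
  })
}

#' Synthetic dual-label endplate with exact pixel dominance
#'
#' A pretzel-like ring of `n_fragments` tube-shaped arcs. Exactly
#' `round(new_fraction * n_mask_voxels)` mask voxels are new-dominant after
#' the package's 99th-percentile normalization (and the rest old-dominant
#' with no ties): dominant voxels carry intensity 1 in their channel and
#' `low_level` in the other; at `new_fraction` 0 (or 1) the new (old) channel
#' is identically zero. Channels are noiseless so the dominance counts are
#' exact by construction.
#'
#' @param new_fraction Fraction of new-dominant mask voxels in `[0, 1]`.
#'   Intermediate fractions must leave each channel at least 2% of the mask
#'   (so its 99th-percentile anchor is a dominant voxel).
#' @param n_fragments Number of connected endplate fragments (>= 1).
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @param seed Integer seed.
#' @param dims `(nz, ny, nx)` array dimensions.
#' @param ring_radius,tube_radius,tube_radius_z,wobble Geometry in pixels.
#' @param low_level Non-dominant channel intensity at dominant voxels.
#' @return List with `image` (a [volume_image()], channels `"old"`, `"new"`)
#'   and `truth`: `mask`, `new_mask`, `n_mask_voxels`, `n_new`,
#'   `fragment_sizes`, `seed`.
#' @export
make_endplate <- function(new_fraction, n_fragments, spacing = c(0.3, 0.15, 0.15),
                          seed = 1L, dims = c(20, 128, 128), ring_radius = 40,
                          tube_radius = 7, tube_radius_z = 4, wobble = 3,
                          low_level = 0.2) {
  if (!is.finite(new_fraction) || new_fraction < 0 || new_fraction > 1) {
    stop_validation("`new_fraction` must lie in [0, 1]")
  }
  n_fragments <- assert_count(n_fragments, "n_fragments", min = 1L)
  spacing <- validate_spacing(spacing, 3L)
  dims <- as.integer(dims)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  circ <- 2 * pi * ring_radius
  gap_len <- 2 * tube_radius + 4
  if (n_fragments * gap_len > 0.55 * circ) {
    stop_capacity("too many fragments for the ring circumference")
  }

  withr::with_seed(seed, {
    cy <- (ny + 1) / 2; cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
    ymat <- matrix(rep(seq_len(ny), nx), ny, nx) - cy
    xmat <- matrix(rep(seq_len(nx), each = ny), ny, nx) - cx
    rho <- sqrt(ymat^2 + xmat^2)
    ang <- atan2(xmat, ymat) %% (2 * pi)
    phase <- runif(1, 0, 2 * pi)
    r_eff <- ring_radius + wobble * sin(3 * ang + phase)

    arc_span <- (circ - n_fragments * gap_len) / n_fragments / ring_radius
    gap_span <- gap_len / ring_radius
    offset <- runif(1, 0, 2 * pi)
    frag2d <- matrix(0L, ny, nx)
    for (k in seq_len(n_fragments)) {
      start <- (offset + (k - 1) * (arc_span + gap_span)) %% (2 * pi)
      delta <- (ang - start) %% (2 * pi)
      frag2d[delta <= arc_span & frag2d == 0L] <- k
    }

    mask <- array(FALSE, c(ny, nx, nz))
    fragvox <- array(0L, c(ny, nx, nz))
    for (z in seq_len(nz)) {
      zterm <- ((z - cz) / tube_radius_z)^2
      if (zterm > 1) next
      radial <- ((rho - r_eff) / tube_radius)^2 <= 1 - zterm
      sl <- radial & frag2d > 0L
      mask[, , z] <- sl
      fz <- frag2d; fz[!sl] <- 0L
      fragvox[, , z] <- fz
    }
    M <- sum(mask)
    if (M == 0L) stop_capacity("endplate geometry produced an empty mask")
    k_new <- round(new_fraction * M)
    if (k_new > 0L && k_new < M && (k_new < 0.02 * M || M - k_new < 0.02 * M)) {
      stop_validation(
        "`new_fraction` too extreme for exact dominance under percentile normalization; use 0, 1, or a fraction in [0.02, 0.98]"
      )
    }
    idx <- which(mask)
    new_idx <- if (k_new > 0L) sample(idx, k_new) else integer()
    old_idx <- setdiff(idx, new_idx)

    old <- array(0, c(ny, nx, nz))
    new <- array(0, c(ny, nx, nz))
    if (length(old_idx)) {
      old[old_idx] <- 1
      if (length(new_idx)) new[old_idx] <- low_level
    }
    if (length(new_idx)) {
      new[new_idx] <- 1
      if (length(old_idx)) old[new_idx] <- low_level
    }
    new_mask <- array(FALSE, c(ny, nx, nz))
    new_mask[new_idx] <- TRUE

    vox <- array(0, c(ny, nx, nz, 2L))
    vox[, , , 1L] <- old
    vox[, , , 2L] <- new
    list(
      image = volume_image(vox, spacing = spacing, channel_names = c("old", "new")),
      truth = list(
        mask = mask, new_mask = new_mask, n_mask_voxels = M, n_new = k_new,
        fragment_sizes = tabulate(fragvox[fragvox > 0L], nbins = n_fragments),
        seed = seed
      )
    )
  })
}

#' Synthetic three-contrast DE table realizing requested class counts
#'
#' For each requested class, emits genes whose `(log2FC, p)` triples satisfy
#' exactly that class's definition under `(fc_thresh, p_thresh)`: DE log2FC
#' magnitudes at least `log2(fc_thresh) + 0.1`, non-DE genes strictly below
#' the fold threshold or with p strictly above the p threshold.
#'
#' @param class_counts Named vector/list mapping class names (see the classes
#'   of [classify_table()]) to non-negative counts; empty input gives an
#'   empty table.
#' @param fc_thresh,p_thresh Thresholds as in [flag_de()].
#' @param seed Integer seed.
#' @return List with `records` (tibble in the [classify_gene()] layout, rows
#'   shuffled) and `truth`: tibble (`gene`, `class`), `seed`, thresholds.
#' @export
make_deg_table <- function(class_counts, fc_thresh = 1.5, p_thresh = 0.05, seed = 1L) {
  class_counts <- unlist(class_counts)
  if (length(class_counts) > 0) {
    bad <- setdiff(names(class_counts), DEG_CLASSES)
    if (length(bad) || is.null(names(class_counts))) {
      stop_validation(paste(
        "unknown class name(s):",
        paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")
      ))
    }
    if (any(class_counts < 0) || any(class_counts != round(class_counts))) {
      stop_validation("class counts must be non-negative integers")
    }
  }
  lfc_margin <- log2(fc_thresh) + 0.1

  empty <- tibble(
    gene = character(), log2fc_den = double(), p_den = double(),
    log2fc_sh_in = double(), p_sh_in = double(),
    log2fc_sh_de = double(), p_sh_de = double()
  )
  if (length(class_counts) == 0 || sum(class_counts) == 0) {
    return(list(records = empty, truth = list(
      assignments = tibble(gene = character(), class = character()),
      seed = seed, fc_thresh = fc_thresh, p_thresh = p_thresh
    )))
  }

  withr::with_seed(seed, {
    de_lfc <- function(n, sgn = NULL) {
      s <- sgn %||% sample(c(-1, 1), n, replace = TRUE)
      s * (lfc_margin + runif(n, 0, 1.2))
    }
    de_p <- function(n) runif(n, p_thresh * 0.02, p_thresh * 0.9)
    non_de <- function(n) {
      mode <- runif(n) < 0.5
      lfc <- ifelse(
        mode,
        runif(n, -1, 1) * pmax(log2(fc_thresh) - 0.1, 0.02),
        de_lfc(n)
      )
      p <- ifelse(mode, runif(n), runif(n, min(p_thresh + 0.02, 0.99), 1))
      list(lfc = lfc, p = p)
    }

    gen_class <- function(cls, n) {
      d <- i <- e <- list(lfc = rep(0, n), p = rep(1, n))
      de <- function() list(lfc = de_lfc(n), p = de_p(n))
      de_sgn <- function(sgn) list(lfc = de_lfc(n, sgn), p = de_p(n))
      switch(cls,
        none = { d <- non_de(n); i <- non_de(n); e <- non_de(n) },
        AIN_In = { d <- non_de(n); i <- de(); e <- non_de(n) },
        AIN_De = { d <- non_de(n); i <- non_de(n); e <- de() },
        AIN_InDe = { d <- non_de(n); i <- de(); e <- de() },
        AD_untouched = { d <- de(); i <- non_de(n); e <- non_de(n) },
        AD_In_pos = { d <- de(); i <- de_sgn(sign(d$lfc)); e <- non_de(n) },
        AD_In_neg = { d <- de(); i <- de_sgn(-sign(d$lfc)); e <- non_de(n) },
        AD_De_pos = { d <- de(); i <- non_de(n); e <- de_sgn(sign(d$lfc)) },
        AD_De_neg = { d <- de(); i <- non_de(n); e <- de_sgn(-sign(d$lfc)) },
        AD_InDe = { d <- de(); i <- de(); e <- de_sgn(sign(i$lfc)) },
        AD_InDe_inverse = { d <- de(); i <- de(); e <- de_sgn(-sign(i$lfc)) }
      )
      tibble(
        class = cls,
        log2fc_den = d$lfc, p_den = d$p,
        log2fc_sh_in = i$lfc, p_sh_in = i$p,
        log2fc_sh_de = e$lfc, p_sh_de = e$p
      )
    }

    rows <- purrr::imap_dfr(
      class_counts[class_counts > 0],
      function(n, cls) gen_class(cls, as.integer(n))
    )
    rows <- rows[sample.int(nrow(rows)), ]
    rows$gene <- sprintf("gene%05d", seq_len(nrow(rows)))
    records <- dplyr::select(
      rows, "gene", "log2fc_den", "p_den", "log2fc_sh_in", "p_sh_in",
      "log2fc_sh_de", "p_sh_de"
    )
    list(
      records = records,
      truth = list(
        assignments = dplyr::select(rows, "gene", "class"),
        seed = seed, fc_thresh = fc_thresh, p_thresh = p_thresh
      )
    )
  })
}
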