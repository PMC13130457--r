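# Low-level image operations shared by the pipelines: bilateral filtering,
# Frangi vesselness, Otsu thresholding, separable 3D Gaussian smoothing, and
# connected-component labelling (2D 8-connectivity / 3D 26-connectivity via
# compiled code).

# Otsu threshold computed from a vector of intensities (256-level histogram,
# maximizing between-class variance via EBImage's implementation).
otsu_from_values <- function(values) {
  rng <- range(values)
  if (diff(rng) <= 0) stop_degenerate("cannot threshold: intensities are constant")
  x <- (values - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(x, nrow = 1L), range = c(0, 1), levels = 256L)
  rng[1] + thr * diff(rng)
}

# Replicate-padded shift of a matrix by (dy, dx).
shift_matrix <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) + dy, 1L), n)
  ci <- pmin(pmax(seq_len(p) + dx, 1L), p)
  m[ri, ci, drop = FALSE]
}

#' Edge-preserving Gaussian bilateral filter
#'
#' Smooths a plane while preserving intensity edges: each output pixel is a
#' weighted mean of its neighbourhood, the weights being the product of a
#' spatial Gaussian (`sigma_spatial`, pixels) and a range Gaussian on the
#' intensity difference (`sigma_range`, intensity units). Used to preprocess
#' the central frame before fiber and mitochondria segmentation.
#'
#' @param frame A [plane_image()].
#' @param sigma_spatial Spatial standard deviation in pixels (> 0).
#' @param sigma_range Range standard deviation in intensity units (> 0).
#' @return A [plane_image()] of the same shape; the output range is contained
#'   in the input range (weighted means cannot extrapolate).
#' @export
preprocess_frame <- function(frame, sigma_spatial = 2, sigma_range = 0.1) {
  stopifnot(inherits(frame, "plane_image"))
  assert_positive_scalar(sigma_spatial, "sigma_spatial")
  assert_positive_scalar(sigma_range, "sigma_range")
  img <- frame$pixels
  r <- ceiling(2 * sigma_spatial)
  num <- matrix(0, nrow(img), ncol(img))
  den <- num
  inv2ss <- 1 / (2 * sigma_spatial^2)
  inv2sr <- 1 / (2 * sigma_range^2)
  for (dy in -r:r) {
    for (dx in -r:r) {
      ws <- exp(-(dy^2 + dx^2) * inv2ss)
      sh <- shift_matrix(img, dy, dx)
      w <- ws * exp(-(sh - img)^2 * inv2sr)
      num <- num + w * sh
      den <- den + w
    }
  }
  plane_image(num / den, frame$spacing)
}

# Analytic Gaussian second-derivative kernels at scale sigma, already
# scale-normalized (multiplied by sigma^2).
gauss_hessian_kernels <- function(sigma) {
  h <- max(2L, ceiling(3 * sigma))
  x <- -h:h
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  gxx <- ((x^2 - sigma^2) / sigma^4) * g  # 1D second derivative
  gxx <- gxx - sum(gxx) / length(gxx)     # exact zero response to constants
  gx1 <- (-x / sigma^2) * g               # 1D first derivative
  list(
    # column-major: rows = y, cols = x
    yy = sigma^2 * outer(gxx, g),
    xx = sigma^2 * outer(g, gxx),
    xy = sigma^2 * outer(gx1, gx1)
  )
}

#' Multiscale Frangi vesselness enhancement of tubular structures
#'
#' Hessian-eigenvalue ridge filter: at each scale the scale-normalized
#' Hessian is computed with Gaussian-derivative kernels; for bright ridges
#' (large negative second eigenvalue) the response combines the blobness
#' ratio `|l1|/|l2|` (beta = 0.5) and the Frobenius structure norm (gamma =
#' half its per-scale maximum). The output is the per-pixel maximum over
#' scales, bounded in `[0, 1]`.
#'
#' @param frame A [plane_image()].
#' @param scales Positive vesselness scales in pixels (non-empty).
#' @param beta Blobness sensitivity (default 0.5).
#' @return A [plane_image()] with vesselness response in `[0, 1]`.
#' @export
enhance_tubular <- function(frame, scales = c(1, 2, 3, 4), beta = 0.5) {
  stopifnot(inherits(frame, "plane_image"))
  if (length(scales) < 1L || any(!is.finite(scales)) || any(scales <= 0)) {
    stop_validation("`scales` must be non-empty and positive")
  }
  img <- frame$pixels
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    k <- gauss_hessian_kernels(s)
    hyy <- EBImage::filter2(img, k$yy, boundary = "replicate")
    hxx <- EBImage::filter2(img, k$xx, boundary = "replicate")
    hxy <- EBImage::filter2(img, k$xy, boundary = "replicate")
    tr2 <- (hxx + hyy) / 2
    disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    e1 <- tr2 + disc
    e2 <- tr2 - disc
    swap <- abs(e1) > abs(e2)
    lam1 <- ifelse(swap, e2, e1)  # smaller magnitude
    lam2 <- ifelse(swap, e1, e2)  # larger magnitude
    s2 <- lam1^2 + lam2^2
    smax <- sqrt(max(s2))
    # floor against FFT round-off: a (near-)constant image has no structure,
    # and gamma-normalizing by a round-off-level maximum would amplify noise
    if (smax <= 1e-8 * (max(abs(img)) + 1e-12)) next
    cc <- smax / 2
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[lam2 >= 0] <- 0
    out <- pmax(out, v)
  }
  plane_image(out, frame$spacing)
}

#' Connected-component labelling
#'
#' 8-connectivity in 2D, 26-connectivity in 3D; labels are `1..K` with no
#' gaps, in scan order.
#'
#' @param mask Logical (or 0/1 numeric) matrix or 3D array.
#' @return Integer array of the same shape.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    stop_validation("`mask` must be a matrix or a 3D array")
  }
  if (length(d) == 2L) d <- c(d, 1L)
  lab <- label_components_cpp(as.logical(mask), as.integer(d))
  dim(lab) <- dim(mask)
  lab
}

# Separable Gaussian smoothing of a 3D array (replicate boundary). `sigma`
# may be a scalar or per-axis (y, x, z) vector in voxels; 0 skips an axis.
gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0 || d[ax] == 1L) next
    h <- max(1L, ceiling(3 * s))
    w <- dnorm(-h:h, sd = s)
    w <- w / sum(w)
    acc <- array(0, d)
    n <- d[ax]
    for (j in seq_along(w)) {
      off <- j - h - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      acc <- acc + w[j] * switch(ax,
        arr[idx, , , drop = FALSE],
        arr[, idx, , drop = FALSE],
        arr[, , idx, drop = FALSE]
      )
    }
    arr <- acc
  }
  arr
}

# Chebyshev (box) dilation of a logical 3D array by `r` voxels per axis.
dilate_mask <- function(mask, r) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  r <- assert_count(r, "r", min = 0L)
  if (r == 0L) return(mask)
  out <- mask
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    acc <- out
    n <- d[ax]
    for (off in c(-r:-1, 1:r)) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      acc <- acc | switch(ax,
        out[idx, , , drop = FALSE],
        out[, idx, , drop = FALSE],
        out[, , idx, drop = FALSE]
      )
    }
    out <- acc
  }
  out
}

# Binary erosion of a 2D mask by a disc of radius r (via EBImage).
erode_disc_2d <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::erode(mask * 1, k) > 0.5
}
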