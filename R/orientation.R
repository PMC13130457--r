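# The 2D mitochondria-orientation pipeline: fiber segmentation and axis
# estimation, tubular enhancement and segmentation, per-object orientation
# relative to the fiber, and binning into 0-30 / 30-60 / 60-90 degrees.

# Per-label second central moments. Angles use the (x = column, y = row)
# frame; orientation is measured from the +x axis, reported in [0, 180).
label_moments <- function(labels) {
  pos <- which(labels > 0L)
  if (length(pos) == 0L) {
    return(tibble(
      label = integer(), area_px = integer(), cx = double(), cy = double(),
      orientation_deg = double(), eccentricity = double()
    ))
  }
  lab <- labels[pos]
  ny <- nrow(labels)
  y <- ((pos - 1L) %% ny) + 1L
  x <- ((pos - 1L) %/% ny) + 1L
  n <- as.vector(rowsum(rep(1, length(lab)), lab))
  ulab <- as.integer(rownames(rowsum(rep(1, length(lab)), lab)))
  sx <- as.vector(rowsum(as.numeric(x), lab)); sy <- as.vector(rowsum(as.numeric(y), lab))
  sxx <- as.vector(rowsum(as.numeric(x)^2, lab)); syy <- as.vector(rowsum(as.numeric(y)^2, lab))
  sxy <- as.vector(rowsum(as.numeric(x) * y, lab))
  cx <- sx / n; cy <- sy / n
  mu20 <- sxx / n - cx^2
  mu02 <- syy / n - cy^2
  mu11 <- sxy / n - cx * cy
  theta <- (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
  tr2 <- (mu20 + mu02) / 2
  disc <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + disc
  l2 <- pmax(tr2 - disc, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  tibble(
    label = ulab, area_px = as.integer(n), cx = cx, cy = cy,
    orientation_deg = theta, eccentricity = ecc
  )
}

#' Segment the muscle fiber and estimate its axis
#'
#' Morphological closing (disc of `closing_radius` pixels) followed by Otsu
#' thresholding; the fiber mask is the largest 8-connected foreground
#' component and the fiber angle is the principal direction of its second
#' central moments, mapped to `[0, 180)` degrees.
#'
#' @param frame A [plane_image()] (typically bilateral-filtered).
#' @param closing_radius Closing disc radius in pixels.
#' @return A `fiber_axis` object: list with `angle_deg` and logical `mask`.
#' @export
segment_fiber <- function(frame, closing_radius = 5) {
  stopifnot(inherits(frame, "plane_image"))
  img <- frame$pixels
  if (sd(img) < 1e-9) stop_degenerate("frame has (near-)zero intensity variance")
  k <- EBImage::makeBrush(2L * as.integer(closing_radius) + 1L, shape = "disc")
  closed <- EBImage::closing(img, k)
  thr <- otsu_from_values(as.vector(closed))
  bw <- closed > thr
  if (!any(bw)) stop_degenerate("fiber segmentation produced an empty foreground")
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  # Principal axis from pixels inside the centred inscribed circle: a square
  # field clips an oblique fiber asymmetrically and biases the raw moment
  # axis by several degrees; a rotation-symmetric window removes that bias.
  ny <- nrow(mask); nx <- ncol(mask)
  r2 <- (min(ny, nx) / 2)^2
  circ <- outer(
    (seq_len(ny) - (ny + 1) / 2)^2, (seq_len(nx) - (nx + 1) / 2)^2, "+"
  ) <= r2
  sel <- mask & circ
  if (sum(sel) < 100L) sel <- mask
  mom <- label_moments(matrix(as.integer(sel), ny, nx))
  structure(
    list(angle_deg = mom$orientation_deg[1], mask = mask),
    class = "fiber_axis"
  )
}

#' @export
print.fiber_axis <- function(x, ...) {
  cat(sprintf(
    "<fiber_axis> angle %.2f deg, mask %d px\n", x$angle_deg, sum(x$mask)
  ))
  invisible(x)
}

#' Segment mitochondrial objects from a vesselness response
#'
#' Otsu threshold computed on vesselness values inside the fiber mask;
#' 8-connected components of the thresholded response (restricted to the
#' mask) with at least `min_area_px` pixels, relabelled `1..K`.
#'
#' @param vesselness A [plane_image()] with response in `[0, 1]`
#'   (from [enhance_tubular()]).
#' @param fiber_mask Logical matrix of the same shape.
#' @param min_area_px Minimum object area in pixels.
#' @return Integer label matrix (`0` = background). All-zero vesselness gives
#'   an empty label map, not an error.
#' @export
segment_mitochondria <- function(vesselness, fiber_mask, min_area_px = 10) {
  stopifnot(inherits(vesselness, "plane_image"))
  v <- vesselness$pixels
  if (min(v) < 0 || max(v) > 1) stop_validation("vesselness must lie in [0, 1]")
  if (!identical(dim(v), dim(fiber_mask))) stop_validation("mask shape mismatch")
  vals <- v[fiber_mask]
  if (length(vals) == 0L || max(vals) <= 0) {
    return(matrix(0L, nrow(v), ncol(v)))
  }
  thr <- tryCatch(otsu_from_values(vals), fiberquant_error_degenerate = function(e) NA_real_)
  if (is.na(thr)) return(matrix(0L, nrow(v), ncol(v)))
  bw <- (v > thr) & fiber_mask
  filter_labels(label_components(bw), as.integer(min_area_px))
}

#' Per-object orientation and eccentricity
#'
#' Principal-axis angle of each labelled object from its second central
#' moments, in `[0, 180)` degrees (measured from the image x axis), plus the
#' eccentricity of the moment ellipse.
#'
#' @param labels Integer label matrix.
#' @return Tibble with `label`, `area_px`, centroid (`cx`, `cy`, pixels),
#'   `orientation_deg`, `eccentricity`. Empty label map gives an empty tibble.
#' @export
object_orientation <- function(labels) {
  if (!is.matrix(labels)) stop_validation("`labels` must be a matrix")
  label_moments(labels)
}

#' Angle between an object and the fiber axis
#'
#' Axial (orientation) angles are periodic with period 180 degrees; the
#' relative angle folds the difference into `[0, 90]`:
#' `min(|a - b|, 180 - |a - b|)`.
#'
#' @param object_deg,fiber_deg Orientation angles in `[0, 180)` (vectorized).
#' @return Relative angles in `[0, 90]` degrees.
#' @export
#' @examples
#' relative_angle(150, 0)  # 30
#' relative_angle(10, 170) # 20
relative_angle <- function(object_deg, fiber_deg) {
  if (any(!is.finite(object_deg)) || any(object_deg < 0) || any(object_deg >= 180) ||
      any(!is.finite(fiber_deg)) || any(fiber_deg < 0) || any(fiber_deg >= 180)) {
    stop_validation("orientation angles must lie in [0, 180)")
  }
  d <- abs(object_deg - fiber_deg)
  pmin(d, 180 - d)
}

#' Bin fiber-relative angles into 0-30, 30-60 and 60-90 degrees
#'
#' Half-open edges `[0, 30)`, `[30, 60)`, `[60, 90]`; 90 closes the last bin
#' so the bins partition `[0, 90]`.
#'
#' @param angles Non-empty vector of relative angles in `[0, 90]`.
#' @return An `angle_bin_summary`: counts and proportions per bin plus
#'   `n_total`.
#' @export
bin_angles <- function(angles) {
  if (length(angles) == 0L) stop_validation("`angles` must be non-empty")
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles > 90)) {
    stop_validation("relative angles must lie in [0, 90]")
  }
  counts <- c(
    `0-30`  = sum(angles < 30),
    `30-60` = sum(angles >= 30 & angles < 60),
    `60-90` = sum(angles >= 60)
  )
  structure(
    list(counts = counts, proportions = counts / length(angles), n_total = length(angles)),
    class = "angle_bin_summary"
  )
}

#' @export
print.angle_bin_summary <- function(x, ...) {
  cat(sprintf("<angle_bin_summary> n = %d\n", x$n_total))
  print(round(x$proportions, 4))
  invisible(x)
}

#' @rdname bin_angles
#' @param x An `angle_bin_summary`.
#' @param ... Unused.
#' @export
tidy.angle_bin_summary <- function(x, ...) {
  tibble(
    bin = names(x$counts),
    count = as.integer(x$counts),
    proportion = as.numeric(x$proportions)
  )
}

#' Run the full mitochondria-orientation pipeline on a stack
#'
#' Composition of [central_frame()], [preprocess_frame()], [segment_fiber()],
#' [enhance_tubular()], [segment_mitochondria()] (restricted to the eroded
#' fiber mask), [object_orientation()] (objects below the eccentricity floor
#' are kept in the table but excluded from angle statistics),
#' [relative_angle()] and [bin_angles()].
#'
#' A frame with (near-)zero variance yields zero objects and an unreliable
#' summary rather than an error; the summary is also flagged unreliable below
#' `min_objects`.
#'
#' @param stack A [volume_image()] containing the mitochondria channel.
#' @param config Configuration list (see [default_config()]); only the
#'   `orientation` group is used.
#' @param channel Channel override; defaults to `config$orientation$channel`.
#' @return An `orientation_result`: list with `summary`
#'   (an `angle_bin_summary` or `NULL`), `objects` (per-object tibble),
#'   `fiber_angle_deg`, `n_objects` (used in the summary), and `unreliable`.
#' @export
run_orientation_pipeline <- function(stack, config = default_config(), channel = NULL) {
  stopifnot(inherits(stack, "volume_image"))
  validate_config(config)
  cfg <- utils::modifyList(default_config(), config)$orientation
  channel <- channel %||% cfg$channel
  sp <- stack$spacing
  if (abs(sp["dy"] - sp["dx"]) > 1e-9 * sp["dx"]) {
    stop_validation("in-plane spacing must be isotropic for orientation analysis")
  }
  frame <- central_frame(stack, channel)

  empty <- function() {
    structure(list(
      summary = NULL,
      objects = tibble(
        label = integer(), centroid_x_um = double(), centroid_y_um = double(),
        area_px = integer(), area_um2 = double(), orientation_deg = double(),
        eccentricity = double(), relative_angle_deg = double(),
        used_in_summary = logical()
      ),
      fiber_angle_deg = NA_real_, n_objects = 0L, unreliable = TRUE,
      config = cfg
    ), class = "orientation_result")
  }
  if (sd(frame$pixels) < 1e-9) return(empty())

  pre <- preprocess_frame(frame, cfg$sigma_spatial, cfg$sigma_range)
  fiber <- segment_fiber(pre, cfg$closing_radius)
  mask <- erode_disc_2d(fiber$mask, cfg$fiber_erosion_px)
  if (!any(mask)) return(empty())
  vess <- enhance_tubular(pre, cfg$frangi_scales)
  labels <- segment_mitochondria(vess, mask, cfg$min_area_px)
  mom <- object_orientation(labels)
  if (nrow(mom) == 0L) return(empty())

  px <- unname(sp["dx"])
  py <- unname(sp["dy"])
  objects <- mom |>
    dplyr::mutate(
      centroid_x_um = .data$cx * px,
      centroid_y_um = .data$cy * py,
      area_um2 = .data$area_px * py * px,
      relative_angle_deg = relative_angle(.data$orientation_deg, fiber$angle_deg),
      used_in_summary = .data$eccentricity >= cfg$eccentricity_min
    ) |>
    dplyr::select(
      "label", "centroid_x_um", "centroid_y_um", "area_px", "area_um2",
      "orientation_deg", "eccentricity", "relative_angle_deg", "used_in_summary"
    )
  used <- objects$relative_angle_deg[objects$used_in_summary]
  summary <- if (length(used) > 0L) bin_angles(used) else NULL
  structure(list(
    summary = summary,
    objects = objects,
    fiber_angle_deg = fiber$angle_deg,
    n_objects = length(used),
    unreliable = length(used) < cfg$min_objects,
    config = cfg
  ), class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf(
    "<orientation_result> fiber axis %.2f deg, %d object(s) in summary%s\n",
    x$fiber_angle_deg, x$n_objects, if (x$unreliable) " [unreliable]" else ""
  ))
  if (!is.null(x$summary)) print(round(x$summary$proportions, 4))
  invisible(x)
}

#' @rdname run_orientation_pipeline
#' @param x An `orientation_result`.
#' @param ... Unused.
#' @export
tidy.orientation_result <- function(x, ...) x$objects

#' @rdname run_orientation_pipeline
#' @export
glance.orientation_result <- function(x, ...) {
  p <- if (is.null(x$summary)) rep(NA_real_, 3) else as.numeric(x$summary$proportions)
  tibble(
    n_objects = x$n_objects, fiber_angle_deg = x$fiber_angle_deg,
    prop_0_30 = p[1], prop_30_60 = p[2], prop_60_90 = p[3],
    unreliable = x$unreliable
  )
}

#' @rdname run_orientation_pipeline
#' @param object An `orientation_result` (for `autoplot`).
#' @export
autoplot.orientation_result <- function(object, ...) {
  if (is.null(object$summary)) stop_validation("no summary to plot")
  autoplot(object$summary)
}

#' @rdname bin_angles
#' @param object An `angle_bin_summary` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.angle_bin_summary <- function(object, ...) {
  df <- tidy(object)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "angle to fiber axis (deg)", y = "proportion of mitochondria"
    ) +
    ggplot2::theme_minimal()
}
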