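#' Multichannel 3D voxel grid with physical spacing
#'
#' The universal microscopy container of the package: a non-negative voxel
#' grid stored as a 4D array in R-native column-major order `(y, x, z, c)`,
#' together with its physical voxel spacing `(dz, dy, dx)` in micrometres and
#' ordered channel labels. All readers normalize to this one layout.
#'
#' @param voxels Numeric array: 2D `(y, x)`, 3D `(y, x, z)` or 4D
#'   `(y, x, z, c)`. Lower-dimensional inputs are promoted (a 2D image becomes
#'   a single-channel, single-plane volume).
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in micrometres, all
#'   strictly positive.
#' @param channel_names Character vector of channel labels, one per channel;
#'   defaults to `"ch1"`, `"ch2"`, ...
#' @return An object of class `volume_image` with elements `voxels` (4D
#'   array), `spacing` (named numeric) and `channel_names`.
#' @export
#' @examples
#' vi <- volume_image(array(runif(4 * 4 * 3), c(4, 4, 3)), spacing = c(0.5, 0.1, 0.1))
#' dim(vi$voxels)
volume_image <- function(voxels, spacing, channel_names = NULL) {
  if (!is.numeric(voxels) && !is.logical(voxels)) {
    stop_validation("`voxels` must be a numeric array")
  }
  nd <- length(dim(voxels) %||% c(NA, NA))
  if (is.null(dim(voxels))) stop_validation("`voxels` must have dimensions")
  if (nd == 2L) {
    dim(voxels) <- c(dim(voxels), 1L, 1L)
  } else if (nd == 3L) {
    dim(voxels) <- c(dim(voxels), 1L)
  } else if (nd != 4L) {
    stop_format(sprintf("voxel arrays with %d axes are not supported", nd))
  }
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    stop_validation("voxel intensities must be finite and non-negative")
  }
  spacing <- validate_spacing(spacing, 3L)
  nc <- dim(voxels)[4L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop_validation("`channel_names` length must match the channel axis")
  }
  structure(
    list(voxels = voxels, spacing = spacing, channel_names = as.character(channel_names)),
    class = "volume_image"
  )
}

#' Single-plane image with in-plane spacing
#'
#' @param pixels Numeric matrix `(y, x)`, at least 2x2.
#' @param spacing Length-2 vector `(dy, dx)` in micrometres, strictly positive.
#' @return An object of class `plane_image`.
#' @export
plane_image <- function(pixels, spacing) {
  if (!is.matrix(pixels) || nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop_validation("`pixels` must be a matrix of at least 2x2")
  }
  spacing <- validate_spacing(spacing, 2L)
  structure(list(pixels = pixels, spacing = spacing), class = "plane_image")
}

validate_spacing <- function(spacing, n) {
  if (!is.numeric(spacing) || length(spacing) != n || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_validation(sprintf("`spacing` must be %d positive values (micrometres)", n))
  }
  names(spacing) <- if (n == 3L) c("dz", "dy", "dx") else c("dy", "dx")
  spacing
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_image> %d x %d x %d (y,x,z), %d channel(s): %s\n  spacing (dz,dy,dx) um: %s\n",
    d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", "),
    paste(signif(x$spacing, 4), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf(
    "<plane_image> %d x %d (y,x), spacing (dy,dx) um: %s\n",
    nrow(x$pixels), ncol(x$pixels), paste(signif(x$spacing, 4), collapse = ", ")
  ))
  invisible(x)
}

# Resolve a channel given by name or index; returns the integer index.
channel_index <- function(volume, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > length(volume$channel_names)) {
      stop_lookup(sprintf("channel index %d out of range", ch))
    }
    return(ch)
  }
  ch <- match(channel, volume$channel_names)
  if (is.na(ch)) {
    stop_lookup(sprintf(
      "unknown channel '%s' (available: %s)",
      channel, paste(volume$channel_names, collapse = ", ")
    ))
  }
  ch
}

#' Extract one channel of a volume as a 3D array
#'
#' @param volume A [volume_image()].
#' @param channel Channel name or index.
#' @return 3D numeric array `(y, x, z)`.
#' @export
get_channel <- function(volume, channel) {
  stopifnot(inherits(volume, "volume_image"))
  volume$voxels[, , , channel_index(volume, channel), drop = FALSE] |>
    (\(a) { dim(a) <- dim(a)[1:3]; a })()
}

#' Central frame of an image stack
#'
#' Returns the plane at z-index `floor(nz / 2)` (0-based; the documented
#' convention for even-depth stacks) of the requested channel, with spacing
#' reduced to `(dy, dx)`.
#'
#' @param stack A [volume_image()].
#' @param channel Channel name or index (default: first channel).
#' @return A [plane_image()].
#' @export
central_frame <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "volume_image"))
  arr <- get_channel(stack, channel)
  nz <- dim(arr)[3L]
  z <- floor(nz / 2) + 1L  # 0-based floor(nz/2) -> 1-based
  plane_image(arr[, , z], spacing = stack$spacing[c("dy", "dx")])
}

#' Read a TIFF stack into a volume_image
#'
#' Reads single- or multi-page TIFF (8/16-bit integer or float) and normalizes
#' to the package's `(y, x, z, c)` layout. Integer intensities are preserved
#' bit-exact. Physical spacing is required input: TIFF metadata is not
#' trusted. Multi-page files with `k > 1` channel names are interpreted as
#' channel-blocked pages (all z-planes of channel 1, then channel 2, ...),
#' the layout written by [write_volume()]. Pages with a samples-per-pixel
#' axis (e.g. RGB) use that axis as the channel axis instead.
#'
#' @param path Path to a TIFF file.
#' @param spacing `(dz, dy, dx)` voxel spacing in micrometres.
#' @param channel_names Optional channel labels.
#' @return A [volume_image()].
#' @export
load_volume <- function(path, spacing, channel_names = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop_io(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  fmt <- attr(pages[[1]], "sample.format") %||% "uint"
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  is_float <- identical(fmt, "float") || bits > 16L
  if (!is_float) {
    # integer samples: re-read unscaled so intensities stay bit-exact
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  nd <- vapply(pages, function(p) length(dim(p) %||% c(1L)), integer(1))
  if (any(nd > 3L) || any(nd < 2L)) {
    stop_format("TIFF pages must have 2 or 3 axes")
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p)[1:2], d1[1:2]), logical(1)))) {
    stop_format("all TIFF pages must share the same extent")
  }
  has_samples <- nd[1] == 3L
  if (has_samples) {
    nc <- d1[3L]
    nz <- length(pages)
    arr <- array(0, c(d1[1L], d1[2L], nz, nc))
    for (z in seq_len(nz)) arr[, , z, ] <- pages[[z]]
  } else {
    npage <- length(pages)
    k <- if (is.null(channel_names)) 1L else length(channel_names)
    if (npage %% k != 0L) {
      stop_format(sprintf("%d pages cannot be split into %d channel blocks", npage, k))
    }
    nz <- npage %/% k
    arr <- array(0, c(d1[1L], d1[2L], nz, k))
    for (i in seq_len(npage)) {
      cidx <- (i - 1L) %/% nz + 1L
      zidx <- (i - 1L) %% nz + 1L
      arr[, , zidx, cidx] <- pages[[i]]
    }
  }
  volume_image(arr, spacing = spacing, channel_names = channel_names)
}

#' Write a volume_image to a multi-page TIFF
#'
#' Pages are written channel-blocked (all z of channel 1, then channel 2, ...),
#' the layout [load_volume()] reads back. Whole-number intensities up to 65535
#' are written as 16-bit (lossless round trip); anything else as 32-bit float.
#'
#' @param volume A [volume_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  v <- volume$voxels
  d <- dim(v)
  pages <- vector("list", d[3L] * d[4L])
  i <- 1L
  for (ch in seq_len(d[4L])) {
    for (z in seq_len(d[3L])) {
      pages[[i]] <- v[, , z, ch]
      i <- i + 1L
    }
  }
  integerish <- all(v == round(v)) && max(v) <= 65535
  res <- tryCatch({
    if (integerish) {
      tiff::writeTIFF(lapply(pages, function(p) p / 65535), path, bits.per.sample = 16L)
    } else {
      tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    }
  }, error = function(e) stop_io(sprintf("cannot write TIFF '%s': %s", path, conditionMessage(e))))
  invisible(path)
}
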