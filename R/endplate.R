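# Endplate morphometry (volume, fragmentation) and dual-label old/new AChR
# turnover by pixel dominance. The two bungarotoxin channels are normalized
# to their own 99th-percentile intensity inside the endplate mask, removing
# acquisition-gain differences; each voxel is then assigned to the channel
# with the higher normalized intensity, with a tie band.

#' Segment the endplate from the two bungarotoxin channels
#'
#' Otsu threshold on the smoothed sum of the old and new channels; connected
#' components smaller than `min_voxels` are removed.
#'
#' @param volume A [volume_image()].
#' @param old_channel,new_channel Channel names or indices.
#' @param smooth_sigma Gaussian sigma in voxels.
#' @param min_voxels Minimum component size retained.
#' @return Logical 3D array.
#' @export
endplate_mask <- function(volume, old_channel = "old", new_channel = "new",
                          smooth_sigma = 1, min_voxels = 64) {
  stopifnot(inherits(volume, "volume_image"))
  tot <- get_channel(volume, old_channel) + get_channel(volume, new_channel)
  if (sd(tot) < 1e-9) stop_degenerate("combined channels have (near-)zero variance")
  sm <- gaussian_smooth_3d(tot, smooth_sigma)
  thr <- otsu_from_values(as.vector(sm))
  filter_labels(label_components(sm > thr), as.integer(min_voxels)) > 0L
}

#' Endplate volume in cubic micrometres
#'
#' @param mask Logical 3D array.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @return Voxel count times voxel volume; 0 (with a warning) for an empty
#'   mask.
#' @export
endplate_volume <- function(mask, spacing) {
  spacing <- validate_spacing(spacing, 3L)
  n <- sum(mask)
  if (n == 0L) {
    warn("endplate mask is empty; volume is 0")
    return(0)
  }
  n * prod(spacing)
}

#' Number of endplate fragments
#'
#' 26-connected components of the mask with at least `min_fragment_voxels`
#' voxels.
#'
#' @param mask Logical 3D array.
#' @param min_fragment_voxels Minimum voxels for a counted fragment.
#' @return Integer count (0 for an empty mask).
#' @export
fragment_count <- function(mask, min_fragment_voxels = 27) {
  if (!any(mask)) return(0L)
  lab <- label_components(mask)
  sum(tabulate(lab[lab > 0L]) >= min_fragment_voxels)
}

#' Old/new pixel dominance within the endplate
#'
#' Each channel is normalized to its own 99th-percentile intensity within the
#' mask (robust to hot pixels); a voxel is new-dominant when normalized new
#' exceeds normalized old by more than `tie_delta`, old-dominant in the
#' opposite case, and a tie otherwise. A channel that is identically zero in
#' the mask carries no label and normalizes to zero; a channel with nonzero
#' values but a zero 99th percentile has no defined normalization and errors.
#'
#' @param old,new Numeric 3D arrays (raw channel intensities).
#' @param mask Logical 3D array, non-empty.
#' @param tie_delta Tie band on normalized intensities (default 0.05).
#' @return One-row tibble: `new_fraction`, `old_fraction`, `tie_fraction`
#'   (summing to 1 exactly), `turnover_index` (= new / (new + old), the
#'   tie-excluded turnover measure; `NaN` if every voxel ties) and
#'   `n_mask_voxels`.
#' @export
pixel_dominance <- function(old, new, mask, tie_delta = 0.05) {
  if (!identical(dim(old), dim(new)) || !identical(dim(old), dim(mask))) {
    stop_validation("channel and mask shapes must match")
  }
  if (!any(mask)) stop_validation("mask must be non-empty")
  if (tie_delta < 0) stop_validation("`tie_delta` must be non-negative")
  ov <- old[mask]
  nv <- new[mask]
  norm_vals <- function(v, label) {
    p99 <- unname(quantile(v, 0.99, names = FALSE))
    if (p99 <= 0) {
      if (max(v) <= 0) return(v * 0)
      stop_computation(sprintf(
        "99th percentile of the %s channel is zero but the channel is not", label
      ))
    }
    v / p99
  }
  on <- norm_vals(ov, "old")
  nn <- norm_vals(nv, "new")
  d <- nn - on
  m <- length(d)
  new_n <- sum(d > tie_delta)
  old_n <- sum(d < -tie_delta)
  tie_n <- m - new_n - old_n
  tibble(
    new_fraction = new_n / m,
    old_fraction = old_n / m,
    tie_fraction = tie_n / m,
    turnover_index = if (new_n + old_n > 0L) new_n / (new_n + old_n) else NaN,
    n_mask_voxels = m
  )
}

#' Full endplate analysis for one acquisition
#'
#' Composes [endplate_mask()], [endplate_volume()], [fragment_count()] and
#' [pixel_dominance()].
#'
#' @param volume A [volume_image()] with the two bungarotoxin channels.
#' @param old_channel,new_channel Channel labels.
#' @param config Configuration list; only the `endplate` group is used.
#' @return One-row tibble: `volume_um3`, `fragment_count`, `n_mask_voxels`,
#'   `new_fraction`, `old_fraction`, `tie_fraction`, `turnover_index`.
#' @export
run_endplate_pipeline <- function(volume, old_channel = "old", new_channel = "new",
                                  config = default_config()) {
  validate_config(config)
  cfg <- utils::modifyList(default_config(), config)$endplate
  mask <- endplate_mask(
    volume, old_channel, new_channel,
    smooth_sigma = cfg$smooth_sigma, min_voxels = cfg$min_voxels
  )
  dom <- pixel_dominance(
    get_channel(volume, old_channel), get_channel(volume, new_channel),
    mask, tie_delta = cfg$tie_delta
  )
  dplyr::bind_cols(
    tibble(
      volume_um3 = endplate_volume(mask, volume$spacing),
      fragment_count = fragment_count(mask, cfg$min_fragment_voxels)
    ),
    dom
  )
}
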