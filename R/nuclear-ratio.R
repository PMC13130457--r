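# Per-nucleus nuclear-to-cytoplasmic mean-intensity ratio with nested
# per-muscle aggregation and normalization to a control group. The ratio is
# the mean signal inside each segmented nucleus divided by one global
# cytoplasmic mean per image (the biological replicate is the muscle, so
# statistics downstream run on muscle-level means).

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, Otsu threshold, 26-connected components, minimum-size
#' filter; optionally drops nuclei touching the y/x image border (partial
#' nuclei bias intensity means).
#'
#' @param volume A [volume_image()].
#' @param channel DAPI channel name or index.
#' @param min_voxels Minimum nucleus size in voxels.
#' @param smooth_sigma Gaussian sigma in voxels.
#' @param exclude_border Drop border-touching nuclei (default `TRUE`).
#' @return Integer 3D label array.
#' @export
segment_nuclei <- function(volume, channel = "dapi", min_voxels = 64,
                           smooth_sigma = 1, exclude_border = TRUE) {
  stopifnot(inherits(volume, "volume_image"))
  arr <- get_channel(volume, channel)
  if (sd(arr) < 1e-9) stop_degenerate("DAPI channel has (near-)zero variance")
  sm <- gaussian_smooth_3d(arr, smooth_sigma)
  thr <- otsu_from_values(as.vector(sm))
  lab <- filter_labels(label_components(sm > thr), as.integer(min_voxels))
  if (exclude_border && max(lab) > 0L) {
    d <- dim(lab)
    border <- unique(c(
      lab[c(1L, d[1L]), , ], lab[, c(1L, d[2L]), ]
    ))
    border <- border[border > 0L]
    if (length(border)) {
      lab[lab %in% border] <- 0L
      lab <- relabel_sequential(lab)
    }
  }
  lab
}

#' Cytoplasmic mask: fiber minus dilated nuclei
#'
#' @param fiber_mask Logical 3D array of the fiber region.
#' @param nuclei Integer 3D nucleus label array (same shape).
#' @param margin_px Chebyshev dilation margin around nuclei, voxels.
#' @return Logical 3D array, disjoint from every dilated nucleus.
#' @export
cytoplasm_mask <- function(fiber_mask, nuclei, margin_px = 2) {
  if (!identical(dim(fiber_mask), dim(nuclei))) stop_validation("shape mismatch")
  excl <- dilate_mask(nuclei > 0L, margin_px)
  out <- fiber_mask & !excl
  if (!any(out)) stop_degenerate("cytoplasmic mask is empty (fiber covered by nuclei)")
  out
}

#' Per-nucleus nuclear/cytoplasmic intensity ratios
#'
#' Each nucleus's mean signal intensity divided by the global cytoplasmic
#' mean of the same image.
#'
#' @param volume A [volume_image()] carrying the signal channel.
#' @param channel Signal channel name or index.
#' @param nuclei Integer 3D nucleus label array.
#' @param cytoplasm Logical 3D cytoplasmic mask.
#' @param muscle_id Muscle (biological replicate) identifier.
#' @param group Experimental group label.
#' @return Tibble with one row per nucleus: `nucleus`, `muscle_id`, `group`,
#'   `mean_nuclear`, `mean_cytoplasmic`, `ratio`.
#' @export
nucleus_ratios <- function(volume, channel, nuclei, cytoplasm, muscle_id, group) {
  stopifnot(inherits(volume, "volume_image"))
  sig <- get_channel(volume, channel)
  if (!identical(dim(sig), dim(nuclei)) || !identical(dim(sig), dim(cytoplasm))) {
    stop_validation("shape mismatch between signal, nuclei and cytoplasm")
  }
  if (!any(cytoplasm)) stop_validation("cytoplasmic mask is empty")
  cyto_mean <- mean(sig[cytoplasm])
  if (cyto_mean <= 0) stop_computation("cytoplasmic mean intensity is not positive")
  pos <- nuclei > 0L
  if (!any(pos)) {
    return(tibble(
      nucleus = integer(), muscle_id = character(), group = character(),
      mean_nuclear = double(), mean_cytoplasmic = double(), ratio = double()
    ))
  }
  means <- as.vector(rowsum(sig[pos], nuclei[pos])) /
    as.vector(rowsum(rep(1, sum(pos)), nuclei[pos]))
  ids <- sort(unique(nuclei[pos]))
  tibble(
    nucleus = as.integer(ids),
    muscle_id = as.character(muscle_id),
    group = as.character(group),
    mean_nuclear = means,
    mean_cytoplasmic = cyto_mean,
    ratio = means / cyto_mean
  )
}

#' Aggregate nucleus records to per-muscle means
#'
#' The muscle is the unit of analysis: each muscle contributes the arithmetic
#' mean of its nuclei's ratios.
#'
#' @param records Tibble from [nucleus_ratios()] (rows from several images
#'   may be bound together).
#' @return Tibble with `muscle_id`, `group`, `mean_ratio`, `n_nuclei`.
#' @export
aggregate_by_muscle <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_validation("`records` must be a non-empty data frame")
  }
  chk <- records |>
    dplyr::distinct(.data$muscle_id, .data$group) |>
    dplyr::count(.data$muscle_id)
  if (any(chk$n > 1L)) {
    stop_validation("a muscle_id appears under more than one group label")
  }
  records |>
    dplyr::group_by(.data$muscle_id, .data$group) |>
    dplyr::summarise(
      mean_ratio = mean(.data$ratio), n_nuclei = dplyr::n(), .groups = "drop"
    )
}

#' Normalize muscle summaries to a control group
#'
#' Divides every muscle's mean ratio by the grand mean of the control group's
#' muscle means, so the control group's normalized mean is exactly 1.
#'
#' @param summaries Tibble from [aggregate_by_muscle()].
#' @param control_group Group label of the control condition.
#' @return `summaries` with an added `normalized_ratio` column.
#' @export
normalize_to_control <- function(summaries, control_group) {
  if (!control_group %in% summaries$group) {
    stop_validation(sprintf("control group '%s' not present", control_group))
  }
  ctrl <- mean(summaries$mean_ratio[summaries$group == control_group])
  if (ctrl <= 0) stop_computation("control-group mean ratio is not positive")
  dplyr::mutate(summaries, normalized_ratio = .data$mean_ratio / ctrl)
}

#' Full nuclear/cytoplasmic ratio pipeline for one image
#'
#' Fiber region from an Otsu threshold on the smoothed signal channel, nuclei
#' from the DAPI channel, cytoplasm as fiber minus dilated nuclei; nuclear
#' masks are eroded by `measure_erosion_px` before intensity measurement
#' (boundary voxels mix nuclear and cytoplasmic signal).
#'
#' @param volume A [volume_image()] with DAPI and signal channels.
#' @param muscle_id,group Identifiers carried into the records.
#' @param dapi_channel,signal_channel Channel labels.
#' @param config Configuration list; only the `nuclei` group is used.
#' @param exclude_mask Optional logical 3D array of regions to exclude from
#'   nucleus analysis (e.g. sub-synaptic regions).
#' @return Tibble of nucleus records (see [nucleus_ratios()]).
#' @export
run_nc_pipeline <- function(volume, muscle_id, group,
                            dapi_channel = "dapi", signal_channel = "ctbp1",
                            config = default_config(), exclude_mask = NULL) {
  validate_config(config)
  cfg <- utils::modifyList(default_config(), config)$nuclei
  sig <- get_channel(volume, signal_channel)
  sm <- gaussian_smooth_3d(sig, cfg$smooth_sigma)
  fiber <- sm > otsu_from_values(as.vector(sm))
  nuc <- segment_nuclei(
    volume, dapi_channel,
    min_voxels = cfg$min_voxels, smooth_sigma = cfg$smooth_sigma,
    exclude_border = cfg$exclude_border
  )
  if (!is.null(exclude_mask)) {
    drop <- unique(nuc[exclude_mask & nuc > 0L])
    if (length(drop)) {
      nuc[nuc %in% drop] <- 0L
      nuc <- relabel_sequential(nuc)
    }
  }
  cyto <- cytoplasm_mask(fiber, nuc, cfg$margin_px)
  meas <- nuc
  if (cfg$measure_erosion_px > 0L) {
    keep <- !dilate_mask(nuc == 0L, cfg$measure_erosion_px)
    meas[!keep] <- 0L
    # erosion may null small nuclei entirely; fall back to the uneroded mask
    gone <- setdiff(unique(nuc[nuc > 0L]), unique(meas[meas > 0L]))
    if (length(gone)) meas[nuc %in% gone] <- nuc[nuc %in% gone]
  }
  nucleus_ratios(volume, signal_channel, meas, cyto, muscle_id, group)
}
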