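#' Write a per-object or per-gene table to delimited text
#'
#' Comma-delimited, header row, UTF-8; numeric columns at full precision so a
#' write-then-read round trip reproduces values bit-exact.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param allow_empty Permit writing a zero-row table (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, allow_empty = FALSE) {
  if (!is.data.frame(records)) stop_validation("`records` must be a data frame")
  if (nrow(records) == 0L && !allow_empty) {
    stop_validation("refusing to write an empty table (set `allow_empty = TRUE`)")
  }
  # doubles are serialized with 17 significant digits so that re-reading
  # reproduces them bit-exact
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)
  ))
  tryCatch(
    readr::write_csv(out, path),
    error = function(e) stop_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read a table written by write_records
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  # base read.csv: its strtod-based double parser is correctly rounded, so
  # the 17-digit serialization of write_records round trips bit-exact
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Default analysis configuration
#'
#' One named list per pipeline, every parameter validated against its
#' documented range by [validate_config()]. Lengths are in pixels/voxels,
#' intensities on the image's own scale.
#'
#' @return Nested named list of parameter groups.
#' @export
default_config <- function() {
  list(
    orientation = list(
      channel = "tomm20",        # mitochondria channel label
      sigma_spatial = 2,         # bilateral spatial sigma, px
      sigma_range = 0.1,         # bilateral range sigma, intensity units
      closing_radius = 5,        # fiber-segmentation closing disc radius, px
      frangi_scales = c(1, 2, 3, 4),  # vesselness scales, px
      fiber_erosion_px = 8,      # fiber-mask erosion before restricting objects
      min_area_px = 10,          # minimum mitochondrial object area
      eccentricity_min = 0.3,    # orientation ill-defined below this
      min_objects = 10           # below this the summary is flagged unreliable
    ),
    morphology3d = list(
      smooth_sigma = 0.7,        # 3D Gaussian sigma, voxels
      min_voxels = 8             # discard components smaller than this
    ),
    nuclei = list(
      smooth_sigma = 1,
      min_voxels = 64,
      margin_px = 2,             # nuclear dilation margin excluded from cytoplasm
      measure_erosion_px = 1,    # erosion of nuclear masks before intensity means
      exclude_border = TRUE      # drop nuclei touching the y/x image border
    ),
    endplate = list(
      smooth_sigma = 1,
      min_voxels = 64,
      min_fragment_voxels = 27,
      tie_delta = 0.05           # dominance tie band on normalized intensities
    ),
    deg = list(
      fc_thresh = 1.5,           # linear fold-change threshold, boundary inclusive
      p_thresh = 0.05            # raw p-value threshold, strict
    )
  )
}

#' Validate an analysis configuration
#'
#' @param config Nested list as returned by [default_config()]; unknown groups
#'   or parameters, and values outside their documented ranges, are rejected.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  if (!is.list(config)) stop_validation("`config` must be a list")
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) stop_validation(paste("unknown config group(s):", paste(extra, collapse = ", ")))
  for (grp in names(config)) {
    bad <- setdiff(names(config[[grp]]), names(ref[[grp]]))
    if (length(bad)) {
      stop_validation(sprintf("unknown parameter(s) in '%s': %s", grp, paste(bad, collapse = ", ")))
    }
  }
  g <- utils::modifyList(ref, config)
  with(g$orientation, {
    assert_positive_scalar(sigma_spatial, "orientation$sigma_spatial")
    assert_positive_scalar(sigma_range, "orientation$sigma_range")
    assert_count(closing_radius, "orientation$closing_radius", min = 1L)
    if (length(frangi_scales) < 1L || any(frangi_scales <= 0)) {
      stop_validation("orientation$frangi_scales must be positive and non-empty")
    }
    assert_count(fiber_erosion_px, "orientation$fiber_erosion_px", min = 0L)
    assert_count(min_area_px, "orientation$min_area_px", min = 1L)
    if (eccentricity_min < 0 || eccentricity_min >= 1) {
      stop_validation("orientation$eccentricity_min must be in [0, 1)")
    }
  })
  with(g$deg, {
    if (fc_thresh < 1) stop_validation("deg$fc_thresh must be >= 1")
    if (p_thresh <= 0 || p_thresh > 1) stop_validation("deg$p_thresh must be in (0, 1]")
  })
  with(g$morphology3d, {
    assert_positive_scalar(smooth_sigma, "morphology3d$smooth_sigma")
    assert_count(min_voxels, "morphology3d$min_voxels", min = 1L)
  })
  invisible(config)
}

#' Load and validate a configuration from YAML
#'
#' @param path Path to a YAML file whose top level mirrors [default_config()].
#' @return Full configuration list (defaults overridden by the file).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  validate_config(user)
  utils::modifyList(default_config(), user)
}
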