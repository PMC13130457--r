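# Internal validation helpers. All user-facing errors carry a subclass of
# "fiberquant_error" so callers (and tests) can condition on the failure mode
# rather than on message wording.

stop_validation <- function(msg) {
  abort(msg, class = c("fiberquant_error_validation", "fiberquant_error"))
}

stop_io <- function(msg) {
  abort(msg, class = c("fiberquant_error_io", "fiberquant_error"))
}

stop_format <- function(msg) {
  abort(msg, class = c("fiberquant_error_format", "fiberquant_error"))
}

stop_lookup <- function(msg) {
  abort(msg, class = c("fiberquant_error_lookup", "fiberquant_error"))
}

stop_degenerate <- function(msg) {
  abort(msg, class = c("fiberquant_error_degenerate", "fiberquant_error"))
}

stop_capacity <- function(msg) {
  abort(msg, class = c("fiberquant_error_capacity", "fiberquant_error"))
}

stop_computation <- function(msg) {
  abort(msg, class = c("fiberquant_error_computation", "fiberquant_error"))
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_validation(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop_validation(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

#' Exact stratified counts by largest remainder
#'
#' Apportions `n` items over groups in proportion to `fractions` so that the
#' counts sum to `n` exactly: floor the raw quotas, then hand the remaining
#' units to the groups with the largest fractional parts (ties broken by
#' group order).
#'
#' @param n Total number of items (positive integer).
#' @param fractions Non-negative weights summing to 1 (within 1e-9).
#' @return Integer vector of counts, same length as `fractions`, summing to `n`.
#' @export
#' @examples
#' largest_remainder(1000, c(0.05, 0.065, 0.885))
largest_remainder <- function(n, fractions) {
  n <- assert_count(n, "n", min = 1L)
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop_validation("`fractions` must be non-negative and finite")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop_validation("`fractions` must sum to 1 (within 1e-9)")
  }
  quota <- n * fractions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Relabel a positive-integer label array so labels form 1..K with no gaps,
# preserving the order of first appearance by original label value.
relabel_sequential <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) {
    storage.mode(labels) <- "integer"
    return(labels)
  }
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  storage.mode(out) <- "integer"
  out
}

# Drop labelled components smaller than min_size voxels/pixels, relabel 1..K.
filter_labels <- function(labels, min_size) {
  if (min_size <= 1L) return(relabel_sequential(labels))
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_size)
  out <- labels
  out[!(labels %in% keep)] <- 0L
  relabel_sequential(out)
}
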