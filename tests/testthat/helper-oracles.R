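# Independent oracles and small mask builders shared across tests.

# Brute-force three-contrast classifier: plain nested conditionals per gene,
# with the DE rule written on the linear fold-change scale. Kept deliberately
# independent of the package's vectorized implementation.
oracle_classify <- function(records, fc = 1.5, pthr = 0.05) {
  de <- function(l2, p) {
    fcv <- 2^l2
    (fcv >= fc || fcv <= 1 / fc) && p < pthr
  }
  out <- character(nrow(records))
  for (r in seq_len(nrow(records))) {
    row <- records[r, ]
    D <- de(row$log2fc_den, row$p_den)
    I <- de(row$log2fc_sh_in, row$p_sh_in)
    E <- de(row$log2fc_sh_de, row$p_sh_de)
    out[r] <-
      if (!D && !I && !E) "none"
      else if (!D && I && E) "AIN_InDe"
      else if (!D && I) "AIN_In"
      else if (!D && E) "AIN_De"
      else if (D && !I && !E) "AD_untouched"
      else if (D && I && !E) {
        if ((row$log2fc_sh_in > 0) == (row$log2fc_den > 0)) "AD_In_pos" else "AD_In_neg"
      } else if (D && !I && E) {
        if ((row$log2fc_sh_de > 0) == (row$log2fc_den > 0)) "AD_De_pos" else "AD_De_neg"
      } else {
        if ((row$log2fc_sh_in > 0) != (row$log2fc_sh_de > 0)) "AD_InDe_inverse" else "AD_InDe"
      }
  }
  out
}

# Brute-force axial-angle fold: minimum over explicit 180-degree shifts.
oracle_fold <- function(a, b) {
  min(abs(a - b + c(-360, -180, 0, 180, 360)))
}

# Principal-axis angle of a pixel set via the eigenvector of the coordinate
# covariance matrix (a different route than the closed-form moment formula).
oracle_axis_angle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  ev <- eigen(stats::cov(xy))$vectors[, 1]
  (atan2(ev[2], ev[1]) * 180 / pi) %% 180
}

make_disk_mask <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

make_rect_mask <- function(nr, nc, h, w) {
  m <- matrix(FALSE, nr, nc)
  r0 <- (nr - h) %/% 2L
  c0 <- (nc - w) %/% 2L
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

# Random DE table with no relation to any class construction.
random_deg_records <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      gene = sprintf("g%04d", seq_len(n)),
      log2fc_den = runif(n, -2, 2), p_den = runif(n),
      log2fc_sh_in = runif(n, -2, 2), p_sh_in = runif(n),
      log2fc_sh_de = runif(n, -2, 2), p_sh_de = runif(n)
    )
  })
}

# A 3D blob (box) mask helper for fragment-count tests.
add_box <- function(arr, z, y, x, size) {
  arr[y:(y + size[2] - 1L), x:(x + size[3] - 1L), z:(z + size[1] - 1L)] <- TRUE
  arr
}
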