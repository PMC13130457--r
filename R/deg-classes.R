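# Classification of genes from three differential-expression contrasts into
# activity-dependent (AD) and activity-independent (AIN) classes. The three
# contrasts are:
#   den   - control innervated vs control denervated (the denervation effect)
#   sh_in - knockdown vs control in innervated muscle
#   sh_de - knockdown vs control in denervated muscle
# A gene is DE in a contrast when |log2FC| >= log2(fc_thresh) (boundary
# inclusive, i.e. linear |fold change| >= 1.5 by default) and p < p_thresh
# (strict). Classes partition the genes by which contrasts are DE, with
# signed subclasses from the agreement of log2FC signs ("correlation" of the
# knockdown effect with the denervation effect).

DEG_CLASSES <- c(
  "none", "AIN_In", "AIN_De", "AIN_InDe", "AD_untouched",
  "AD_In_pos", "AD_In_neg", "AD_De_pos", "AD_De_neg",
  "AD_InDe", "AD_InDe_inverse"
)

#' Differential-expression flag
#'
#' `TRUE` iff `|log2fc| >= log2(fc_thresh)` and `p < p_thresh`. Vectorized.
#'
#' @param log2fc Log2 fold change(s).
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param fc_thresh Linear fold-change threshold (boundary inclusive),
#'   default 1.5.
#' @param p_thresh P-value threshold (strict), default 0.05.
#' @return Logical vector.
#' @export
#' @examples
#' flag_de(log2(1.5), 0.049)  # TRUE: both boundaries as documented
#' flag_de(1.0, 0.05)         # FALSE: p not strictly below
flag_de <- function(log2fc, p, fc_thresh = 1.5, p_thresh = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  if (fc_thresh < 1) stop_validation("`fc_thresh` must be >= 1")
  if (p_thresh <= 0 || p_thresh > 1) stop_validation("`p_thresh` must be in (0, 1]")
  abs(log2fc) >= log2(fc_thresh) & p < p_thresh
}

# Vectorized class assignment from DE flags and log2FC signs.
assign_classes <- function(d, i, e, s_den, s_in, s_de) {
  dplyr::case_when(
    !d & !i & !e ~ "none",
    !d &  i &  e ~ "AIN_InDe",
    !d &  i      ~ "AIN_In",
    !d &       e ~ "AIN_De",
     d & !i & !e ~ "AD_untouched",
     d &  i & !e ~ dplyr::if_else(s_in == s_den, "AD_In_pos", "AD_In_neg"),
     d & !i &  e ~ dplyr::if_else(s_de == s_den, "AD_De_pos", "AD_De_neg"),
     d &  i &  e ~ dplyr::if_else(s_in != s_de, "AD_InDe_inverse", "AD_InDe")
  )
}

required_deg_cols <- c(
  "gene", "log2fc_den", "p_den", "log2fc_sh_in", "p_sh_in",
  "log2fc_sh_de", "p_sh_de"
)

validate_deg_table <- function(records) {
  if (!is.data.frame(records)) stop_validation("`records` must be a data frame")
  missing <- setdiff(required_deg_cols, names(records))
  if (length(missing)) {
    stop_validation(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(records$gene)) stop_validation("gene ids must be unique")
  invisible(records)
}

#' Classify a single gene
#'
#' @param record One-row data frame with columns `gene`, `log2fc_den`,
#'   `p_den`, `log2fc_sh_in`, `p_sh_in`, `log2fc_sh_de`, `p_sh_de`.
#' @param fc_thresh,p_thresh Thresholds as in [flag_de()].
#' @return One-row tibble with the DE flags and the assigned `class`.
#' @export
classify_gene <- function(record, fc_thresh = 1.5, p_thresh = 0.05) {
  validate_deg_table(record)
  if (nrow(record) != 1L) stop_validation("`record` must have exactly one row")
  classify_table(record, fc_thresh, p_thresh)$assignments
}

#' Classify a three-contrast DE table
#'
#' Assigns every gene exactly one class, and tallies class counts, the seven
#' Venn regions of the three DE sets, and the fraction of up-regulated genes
#' within each knockdown contrast's DE set.
#'
#' @param records Data frame with the columns listed under [classify_gene()];
#'   gene ids must be unique.
#' @param fc_thresh,p_thresh Thresholds as in [flag_de()].
#' @return A `deg_classification`: list with `assignments` (per-gene tibble
#'   with flags `de_den`, `de_sh_in`, `de_sh_de` and `class`),
#'   `class_counts`, `venn_counts` (regions `den_only`, `sh_in_only`,
#'   `sh_de_only`, `den_sh_in`, `den_sh_de`, `sh_in_sh_de`, `all_three`),
#'   `up_fractions`, and the thresholds used.
#' @export
classify_table <- function(records, fc_thresh = 1.5, p_thresh = 0.05) {
  validate_deg_table(records)
  records <- as_tibble(records)
  d <- flag_de(records$log2fc_den, records$p_den, fc_thresh, p_thresh)
  i <- flag_de(records$log2fc_sh_in, records$p_sh_in, fc_thresh, p_thresh)
  e <- flag_de(records$log2fc_sh_de, records$p_sh_de, fc_thresh, p_thresh)
  # sign() of a DE log2FC is never 0 (|log2fc| >= log2(fc_thresh) > 0 for
  # fc_thresh > 1); with fc_thresh == 1 a zero log2FC would leave the signed
  # subclass undefined.
  if (any((d & records$log2fc_den == 0) | (i & records$log2fc_sh_in == 0) |
          (e & records$log2fc_sh_de == 0))) {
    stop_computation("zero log2FC on a sign-determining DE contrast")
  }
  assignments <- records |>
    dplyr::mutate(
      de_den = d, de_sh_in = i, de_sh_de = e,
      class = assign_classes(
        d, i, e, sign(records$log2fc_den), sign(records$log2fc_sh_in),
        sign(records$log2fc_sh_de)
      )
    ) |>
    dplyr::select("gene", "de_den", "de_sh_in", "de_sh_de", "class")
  class_counts <- tibble(class = DEG_CLASSES) |>
    dplyr::left_join(dplyr::count(assignments, .data$class), by = "class") |>
    dplyr::mutate(n = as.integer(dplyr::coalesce(.data$n, 0L)))
  venn_counts <- tibble(
    region = c(
      "den_only", "sh_in_only", "sh_de_only", "den_sh_in", "den_sh_de",
      "sh_in_sh_de", "all_three"
    ),
    n = c(
      sum(d & !i & !e), sum(!d & i & !e), sum(!d & !i & e),
      sum(d & i & !e), sum(d & !i & e), sum(!d & i & e), sum(d & i & e)
    )
  )
  up_fractions <- tibble(
    contrast = c("sh_in", "sh_de"),
    n_de = c(sum(i), sum(e)),
    frac_up = c(
      if (sum(i)) mean(records$log2fc_sh_in[i] > 0) else NA_real_,
      if (sum(e)) mean(records$log2fc_sh_de[e] > 0) else NA_real_
    )
  )
  structure(list(
    assignments = assignments, class_counts = class_counts,
    venn_counts = venn_counts, up_fractions = up_fractions,
    fc_thresh = fc_thresh, p_thresh = p_thresh
  ), class = "deg_classification")
}

#' @export
print.deg_classification <- function(x, ...) {
  cat(sprintf(
    "<deg_classification> %d gene(s), |FC| >= %g, p < %g\n",
    nrow(x$assignments), x$fc_thresh, x$p_thresh
  ))
  nz <- dplyr::filter(x$class_counts, .data$n > 0L)
  if (nrow(nz)) print(as.data.frame(nz), row.names = FALSE)
  invisible(x)
}

#' @rdname classify_table
#' @param x A `deg_classification`.
#' @param ... Unused.
#' @export
tidy.deg_classification <- function(x, ...) x$assignments

#' @rdname classify_table
#' @export
glance.deg_classification <- function(x, ...) {
  tibble(
    n_genes = nrow(x$assignments),
    n_de_den = sum(x$assignments$de_den),
    n_de_sh_in = sum(x$assignments$de_sh_in),
    n_de_sh_de = sum(x$assignments$de_sh_de),
    frac_up_sh_in = x$up_fractions$frac_up[1],
    frac_up_sh_de = x$up_fractions$frac_up[2]
  )
}

#' @rdname classify_table
#' @param object A `deg_classification` (for `autoplot`).
#' @export
autoplot.deg_classification <- function(object, ...) {
  df <- dplyr::filter(object$class_counts, .data$class != "none")
  df$class <- factor(df$class, levels = DEG_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-gene z-scores of log2 fold changes across contrasts
#'
#' Each selected gene's `(den, sh_in, sh_de)` log2FC triple is centred and
#' scaled by its own population standard deviation (divisor n, documented
#' convention); rows with zero variance are set to zero and flagged.
#'
#' @param records DE table (see [classify_gene()]).
#' @param genes Character vector of gene ids to include (all must be present).
#' @return Numeric matrix (genes x contrasts) with attribute `constant`, a
#'   named logical vector marking zero-variance rows.
#' @export
zscore_matrix <- function(records, genes) {
  validate_deg_table(records)
  idx <- match(genes, records$gene)
  if (anyNA(idx)) {
    stop_lookup(paste("gene(s) not found:", paste(genes[is.na(idx)], collapse = ", ")))
  }
  m <- as.matrix(records[idx, c("log2fc_den", "log2fc_sh_in", "log2fc_sh_de")])
  rownames(m) <- genes
  colnames(m) <- c("den", "sh_in", "sh_de")
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  constant <- sdev == 0
  z <- (m - mu) / ifelse(constant, 1, sdev)
  z[constant, ] <- 0
  attr(z, "constant") <- stats::setNames(constant, genes)
  z
}
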