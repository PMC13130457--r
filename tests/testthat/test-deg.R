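test_that("flag_de applies the documented boundary conventions", {
  expect_true(flag_de(log2(1.5), 0.049))   # |FC| = 1.5 inclusive, p strict
  expect_true(flag_de(-log2(1.5), 0.049))
  expect_false(flag_de(0.50, 0.01))        # |FC| = 1.41 < 1.5
  expect_false(flag_de(1.0, 0.05))         # p not strictly below
  expect_true(flag_de(1.0, 0.0499999))
  expect_error(flag_de(1, 1.2), class = "fiberquant_error_validation")
  expect_error(flag_de(1, 0.01, fc_thresh = 0.5), class = "fiberquant_error_validation")
})

test_that("single-gene classification matches the published class logic", {
  rec <- tibble::tibble(
    gene = "g1",
    log2fc_den = 1, p_den = 0.001,
    log2fc_sh_in = 0.8, p_sh_in = 0.01,
    log2fc_sh_de = 0.1, p_sh_de = 0.8
  )
  expect_identical(classify_gene(rec)$class, "AD_In_pos")
  rec$log2fc_sh_in <- -0.8
  expect_identical(classify_gene(rec)$class, "AD_In_neg")
  rec2 <- tibble::tibble(
    gene = "g2", log2fc_den = 0.1, p_den = 0.9,
    log2fc_sh_in = 1, p_sh_in = 0.01, log2fc_sh_de = 0, p_sh_de = 1
  )
  expect_identical(classify_gene(rec2)$class, "AIN_In")
})

test_that("the full flag/sign truth table agrees with a brute-force oracle", {
  # every combination of DE flags x signs for the three contrasts
  lev <- list(c(-1, NA, 1))  # -1/+1: DE with that sign; NA: not DE
  combos <- expand.grid(den = lev[[1]], sh_in = lev[[1]], sh_de = lev[[1]])
  recs <- purrr::pmap_dfr(combos, function(den, sh_in, sh_de) {
    mk <- function(s) {
      if (is.na(s)) c(lfc = 0.1, p = 0.9) else c(lfc = s * 1.0, p = 0.001)
    }
    d <- mk(den); i <- mk(sh_in); e <- mk(sh_de)
    tibble::tibble(
      log2fc_den = d["lfc"], p_den = d["p"],
      log2fc_sh_in = i["lfc"], p_sh_in = i["p"],
      log2fc_sh_de = e["lfc"], p_sh_de = e["p"]
    )
  })
  recs$gene <- sprintf("g%02d", seq_len(nrow(recs)))
  cl <- classify_table(recs)
  expect_identical(cl$assignments$class, oracle_classify(recs))
  # classification is a partition
  expect_identical(sum(cl$class_counts$n), nrow(recs))
})

test_that("classification agrees with the oracle on many random tables", {
  for (s in 1:50) {
    recs <- random_deg_records(20, seed = 7000 + s)
    cl <- classify_table(recs)
    expect_identical(cl$assignments$class, oracle_classify(recs))
  }
})

test_that("raising the p threshold never shrinks a DE set", {
  recs <- random_deg_records(200, seed = 99)
  lo <- classify_table(recs, p_thresh = 0.01)
  hi <- classify_table(recs, p_thresh = 0.10)
  for (col in c("de_den", "de_sh_in", "de_sh_de")) {
    expect_true(all(hi$assignments[[col]] >= lo$assignments[[col]]))
  }
})

test_that("venn regions and up-fractions are consistent with the flags", {
  dt <- make_deg_table(
    c(AD_untouched = 4, AIN_In = 3, AD_InDe = 5, AD_De_neg = 2, none = 6),
    seed = 50
  )
  cl <- classify_table(dt$records)
  v <- cl$venn_counts
  expect_identical(v$n[v$region == "den_only"], 4L)
  expect_identical(v$n[v$region == "sh_in_only"], 3L)
  expect_identical(v$n[v$region == "all_three"], 5L)
  expect_identical(v$n[v$region == "den_sh_de"], 2L)
  expect_identical(sum(v$n), 14L)  # all DE-anywhere genes
  up <- cl$up_fractions
  a <- cl$assignments
  recs <- dt$records
  expect_equal(
    up$frac_up[up$contrast == "sh_in"],
    mean(recs$log2fc_sh_in[a$de_sh_in] > 0)
  )
  expect_error(
    classify_table(dplyr::bind_rows(dt$records, dt$records[1, ])),
    class = "fiberquant_error_validation"
  )
  expect_identical(sum(classify_table(dt$records[0, ])$class_counts$n), 0L)
})

test_that("z-score matrix uses the population-SD convention and flags constants", {
  recs <- tibble::tibble(
    gene = c("a", "b"),
    log2fc_den = c(1, 0.5), p_den = c(0.01, 0.2),
    log2fc_sh_in = c(2, 0.5), p_sh_in = c(0.01, 0.2),
    log2fc_sh_de = c(3, 0.5), p_sh_de = c(0.01, 0.2)
  )
  z <- zscore_matrix(recs, c("a", "b"))
  expect_equal(unname(z["a", ]), c(-1.2247, 0, 1.2247), tolerance = 1e-3)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_identical(unname(attr(z, "constant")), c(FALSE, TRUE))
  # non-constant rows have mean 0 and population SD 1
  expect_equal(mean(z["a", ]), 0)
  expect_equal(sqrt(mean((z["a", ] - mean(z["a", ]))^2)), 1)
  expect_error(zscore_matrix(recs, "missing"), class = "fiberquant_error_lookup")
})

test_that("tidy, glance and autoplot summarize a classification", {
  dt <- make_deg_table(c(AD_In_pos = 3, AIN_De = 2), seed = 51)
  cl <- classify_table(dt$records)
  expect_identical(nrow(tidy(cl)), 5L)
  g <- glance(cl)
  expect_identical(g$n_genes, 5L)
  expect_s3_class(autoplot(cl), "ggplot")
})
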