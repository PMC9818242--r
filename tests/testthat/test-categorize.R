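# Categorization of expression, copy number, single-cell counts, drug
# response, and dependency scores.

hk_tbl <- function(values, ids = sprintf("hk%d", seq_along(values))) {
  gene_tbl(do.call(rbind, values), ids,
           sprintf("s%d", seq_len(length(values[[1]]))))
}

fake_model <- function(sigma_bar, width_multiplier = 1,
                       center_statistic = "median") {
  structure(list(sigma_bar = sigma_bar, width_multiplier = width_multiplier,
                 center_statistic = center_statistic,
                 per_hk_cutoffs = tibble::tibble(), hk_gene_ids = character(),
                 target_outside = 0.3, achieved_outside = NA),
            class = "normal_range_model")
}

test_that("housekeeping cutoffs are interpolated quantiles and the normal-range SD uses n-1", {
  # 10 distinct values make the outside fraction move in steps of 0.2, so
  # the calibration warns about granularity; the cutoffs are what matter here
  m <- suppressWarnings(
    fit_normal_range_model(hk_tbl(list(1:10, 1:10)), c("hk1", "hk2"))
  )
  expect_equal(m$per_hk_cutoffs$lower, c(2.35, 2.35))
  expect_equal(m$per_hk_cutoffs$upper, c(8.65, 8.65))
  # normal set {3..8}, sample SD 1.8708...
  expect_equal(m$per_hk_cutoffs$normal_sd, rep(sd(3:8), 2))
  expect_equal(m$sigma_bar, sd(3:8))
})

test_that("a constant housekeeping gene contributes SD 0 with a warning", {
  tbl <- hk_tbl(list(1:10, rep(5, 10)))
  expect_warning(m <- fit_normal_range_model(tbl, c("hk1", "hk2")),
                 "zero normal-range SD")
  expect_equal(m$sigma_bar, sd(3:8) / 2)
})

test_that("missing housekeeping ids and all-constant panels are errors", {
  tbl <- hk_tbl(list(1:10))
  expect_error(fit_normal_range_model(tbl, c("hk1", "nope")),
               "nope", class = "plbin_id_error")
  const <- hk_tbl(list(rep(2, 10), rep(7, 10)))
  expect_error(suppressWarnings(fit_normal_range_model(const, c("hk1", "hk2"))),
               class = "plbin_degenerate_model")
})

test_that("expression states follow the center +/- width rule with inclusive-normal boundaries", {
  expr <- gene_tbl(rbind(c(0, 5, 10), c(3, 5, 7)), c("g1", "g2"),
                   c("s1", "s2", "s3"))
  cm <- categorize_expression(expr, fake_model(sigma_bar = 2))
  s <- gene_matrix(cm)
  expect_equal(unname(s["g1", ]), c(-1, 0, 1))
  # 3 and 7 sit exactly at center -/+ w: boundary maps to normal
  expect_equal(unname(s["g2", ]), c(0, 0, 0))
  expect_equal(state_arity(cm), 3L)
  expect_error(categorize_expression(expr, fake_model(sigma_bar = 0)),
               class = "plbin_degenerate_model")
})

test_that("categorization is invariant to shifting a gene when centered on the median", {
  sim <- sim_expression_with_housekeeping(30, 50, n_hk = 10, seed = 11)
  m <- fit_normal_range_model(sim$expr, sim$hk_ids)
  base <- gene_matrix(categorize_expression(sim$expr, m))
  shifted <- sim$expr
  shifted[5, -1] <- shifted[5, -1] + 100
  after <- gene_matrix(categorize_expression(shifted, m))
  expect_identical(after[5, ], base[5, ])
})

test_that("housekeeping calibration round-trips to the 30% outside target", {
  sim <- sim_expression_with_housekeeping(300, 120, n_hk = 20, seed = 5)
  m <- fit_normal_range_model(sim$expr, sim$hk_ids)
  cm <- categorize_expression(sim$expr, m)
  hk_states <- gene_matrix(cm)[sim$hk_ids, ]
  expect_lt(abs(mean(hk_states != 0) - 0.30), 0.02)
})

test_that("copy-number states map deletion / diploid / duplication", {
  cn <- gene_tbl(rbind(c(0, 1, 2), c(3, 4, 2)), c("g1", "g2"),
                 c("s1", "s2", "s3"))
  s <- gene_matrix(categorize_cnv(cn))
  expect_equal(unname(s["g1", ]), c(-1, -1, 0))
  expect_equal(unname(s["g2", ]), c(1, 1, 0))
})

test_that("copy-number categorization is total on non-negative integers and retracts CN states", {
  cn_vals <- matrix(0:11, 3, 4)
  s <- gene_matrix(categorize_cnv(gene_tbl(cn_vals)))
  expect_true(all(s %in% c(-1, 0, 1)))
  # states re-expressed as copy numbers around the diploid level are a
  # fixed point of the rule
  again <- gene_matrix(categorize_cnv(gene_tbl(s + 2)))
  expect_equal(unname(again), unname(s))
})

test_that("non-integer copy numbers need an explicit tolerance", {
  cn <- gene_tbl(matrix(c(1.7, 2.1, 2.4, 3.2), 1), "g1", paste0("s", 1:4))
  expect_error(categorize_cnv(cn), "tolerance", class = "plbin_input_error")
  s <- gene_matrix(categorize_cnv(cn, tolerance = 0.5))
  expect_equal(unname(s[1, ]), c(0, 0, 0, 1))
  s2 <- gene_matrix(categorize_cnv(cn, tolerance = 0.25))
  expect_equal(unname(s2[1, ]), c(-1, 0, 1, 1))
})

test_that("single-cell binarization preserves the zero pattern exactly", {
  counts <- sim_single_cell_counts(40, 60, dropout = 0.7, seed = 2)
  b <- binarize_single_cell(counts)
  expect_identical(gene_matrix(b) == 1, gene_matrix(counts) > 0)
  expect_equal(state_arity(b), 2L)
  neg <- gene_tbl(matrix(c(0, -1), 1), "g1", c("s1", "s2"))
  expect_error(binarize_single_cell(neg), class = "plbin_input_error")
})

test_that("drug response combines the dose rule with the mean +/- 0.5 SD band", {
  expect_equal(categorize_drug_response(15, 0.01, 10), "resistant")
  expect_equal(categorize_drug_response(0.001, 0.01, 10), "sensitive")
  # in-range values 1..5: m = 3, s = 1.5811, band [2.2094, 3.7906]
  expect_equal(categorize_drug_response(1:5, 0.01, 10),
               c("sensitive", "sensitive", "partial", "resistant", "resistant"))
  expect_error(categorize_drug_response(numeric(), 0, 1),
               class = "plbin_input_error")
})

test_that("dependency scores flag proliferation effects strictly below -0.5", {
  expect_equal(flag_proliferation_effect(c(-0.7, -0.5, 0.2)),
               c("significant", "not_significant", "not_significant"))
})
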