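# Baseline methods: correlation networks, entropy/MI, StepMiner thresholds
# and the quadrant sparsity test.

step_fit_at <- function(t, margin = 0.5) {
  structure(list(threshold = t, intermediate_margin = margin,
                 left_mean = t - 1, right_mean = t + 1, sse = 0, split = NA),
            class = "step_fit")
}

test_that("Pearson correlation matches hand values and rejects zero variance", {
  expect_equal(pearson_cc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cc(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_cc(c(1, 1, 1), c(1, 2, 3)),
               class = "plbin_undefined_stat")
})

test_that("correlation is invariant under positive affine transforms", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      x <- rnorm(30)
      y <- rnorm(30)
      expect_equal(pearson_cc(2.5 * x + 7, y), pearson_cc(x, y),
                   tolerance = 1e-12)
      expect_equal(pearson_cc(x, 0.1 * y - 3), pearson_cc(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("relevance networks threshold pairwise correlations", {
  vals <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 1, 3, 2))
  expr <- gene_tbl(vals, c("g1", "g2", "g3"), paste0("s", 1:4))
  e <- pcc_network(expr, threshold = 0.99)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$source, e$target), c("g1", "g2"))

  withr::with_seed(1, {
    base <- rnorm(50)
    planted <- 0.95 * scale(base)[, 1] + sqrt(1 - 0.95^2) * rnorm(50)
    noise <- matrix(rnorm(8 * 50), 8)
    expr2 <- gene_tbl(rbind(base, planted, noise),
                      c("gA", "gB", sprintf("n%d", 1:8)), sprintf("s%d", 1:50))
  })
  e2 <- pcc_network(expr2, threshold = 0.8)
  expect_true(any(e2$source == "gA" & e2$target == "gB"))
  # brute-force correlation matrix oracle: same edge set
  cm <- cor(t(gene_matrix(expr2)))
  expected_edges <- sum(abs(cm[upper.tri(cm)]) >= 0.8)
  expect_equal(nrow(e2), expected_edges)

  const <- gene_tbl(rbind(c(1, 1, 1), c(1, 2, 3)), c("c1", "g1"), paste0("s", 1:3))
  expect_warning(pcc_network(const, 0.5), "zero-variance")
})

test_that("entropy and mutual information match direct evaluation", {
  expect_equal(categorical_entropy(c(0, 0, 1, 1)), 1)
  expect_equal(categorical_entropy(rep(3, 10)), 0)
  expect_equal(categorical_entropy(c(1, 0, 0, 0)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-12)
  x <- rep(c(0, 1), 5)
  expect_equal(mutual_information(x, x), 1)
  # exact product joint counts: independence
  xi <- rep(c(0, 0, 1, 1), 5)
  yi <- rep(c(0, 1, 0, 1), 5)
  expect_equal(mutual_information(xi, yi), 0)
  # joint counts [[4,1],[1,4]]
  v <- counts_to_vectors(matrix(c(4, 1, 1, 4), 2, 2,
                                dimnames = list(c(0, 1), c(0, 1))))
  mi <- mutual_information(v$a, v$b)
  # H(X) + H(Y) - H(X,Y) with joint probabilities (.4, .1, .1, .4)
  expect_equal(mi, 2 - (-(2 * 0.4 * log2(0.4) + 2 * 0.1 * log2(0.1))),
               tolerance = 1e-12)
  expect_equal(round(mi, 4), 0.2781)
})

test_that("mutual information is symmetric, bounded and non-negative", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      x <- sample(0:2, 40, replace = TRUE)
      y <- sample(0:1, 40, replace = TRUE)
      mi <- mutual_information(x, y)
      expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
      expect_gte(mi, 0)
      expect_lte(mi, min(categorical_entropy(x), categorical_entropy(y)) + 1e-12)
    }
  })
})

test_that("one-step fits match the exhaustive split search", {
  f1 <- stepminer_threshold(c(1, 1, 1, 5, 5, 5))
  expect_equal(f1$threshold, 3)
  expect_equal(f1$sse, 0)
  f2 <- stepminer_threshold(c(1, 1, 1, 1, 9))
  expect_equal(f2$threshold, 5)
  expect_error(stepminer_threshold(rep(2, 6)), class = "plbin_no_step")
  withr::with_seed(19, {
    for (rep in 1:500) {
      n <- sample(4:50, 1)
      v <- round(rnorm(n), 2)
      if (diff(range(v)) == 0) next
      fit <- stepminer_threshold(v)
      oracle <- oracle_stepminer(v)
      expect_equal(fit$sse, oracle$sse, tolerance = 1e-9)
      expect_equal(fit$threshold, oracle$t, tolerance = 1e-9)
      expect_lte(fit$left_mean, fit$right_mean)
    }
  })
})

test_that("quadrant assignment excludes the intermediate zone", {
  q <- quadrant_counts(c(0, 0, 5, 5), c(0, 5, 0, 5),
                       step_fit_at(2.5), step_fit_at(2.5))
  expect_equal(unlist(q[, c("a_I", "a_II", "a_III", "a_IV")]),
               c(a_I = 1L, a_II = 1L, a_III = 1L, a_IV = 1L))
  # 2.6 with t = 2.5 sits inside t +/- 0.5 and is excluded
  q2 <- quadrant_counts(c(2.6, 0, 5), c(5, 0, 5),
                        step_fit_at(2.5), step_fit_at(2.5))
  expect_equal(q2$total, 2L)
  # mixed hand tally: A values 0,5,5,2.7,0; B values 5,5,0,0,0
  q3 <- quadrant_counts(c(0, 5, 5, 2.7, 0), c(5, 5, 0, 0, 0),
                        step_fit_at(2.5), step_fit_at(2.5))
  expect_equal(unlist(q3[, c("a_I", "a_II", "a_III", "a_IV")]),
               c(a_I = 1L, a_II = 1L, a_III = 1L, a_IV = 1L))
  expect_error(quadrant_counts(c(2.5, 2.6), c(0, 5),
                               step_fit_at(2.5), step_fit_at(2.5)),
               class = "plbin_empty_quadrants")
})

test_that("the sparsity statistic and error rate match the worked example", {
  q <- tibble::tibble(a_I = 40, a_II = 15, a_III = 40, a_IV = 1)
  st <- sahoo_test(q, "IV")
  expect_equal(st$expected, 41 * 41 / 96, tolerance = 1e-12)
  expect_equal(st$statistic, (41 * 41 / 96 - 1) / sqrt(41 * 41 / 96),
               tolerance = 1e-12)
  expect_equal(st$statistic, 3.95, tolerance = 0.01)
  expect_equal(st$error_rate, (1 / 41 + 1 / 41) / 2, tolerance = 1e-12)
  expect_true(st$significant)
})

test_that("observed equal to expected gives statistic 0 and the 3.0 cutoff is strict", {
  q0 <- tibble::tibble(a_I = 5, a_II = 5, a_III = 5, a_IV = 5)
  st0 <- sahoo_test(q0, "IV")
  expect_equal(st0$statistic, 0)
  expect_false(st0$significant)
  # constructed so expected = 16 and observed = 4: statistic exactly 3.0
  q3 <- tibble::tibble(a_I = 28, a_II = 0, a_III = 24, a_IV = 4)
  st3 <- sahoo_test(q3, "IV")
  expect_equal(st3$statistic, 3.0)
  expect_false(st3$significant)
})

test_that("the statistic is antisymmetric in observed around expected", {
  q <- tibble::tibble(a_I = 30, a_II = 10, a_III = 25, a_IV = 6)
  st <- sahoo_test(q, "IV")
  mirrored <- (st$expected - (2 * st$expected - st$observed)) / sqrt(st$expected)
  expect_equal(mirrored, -st$statistic, tolerance = 1e-12)
})

test_that("sparse quadrants map to implication relations", {
  fa <- step_fit_at(0.5)
  fb <- step_fit_at(0.5)
  mk <- function(nI, nII, nIII, nIV) {
    xa <- c(rep(2, nI), rep(-2, nII), rep(-2, nIII), rep(2, nIV))
    xb <- c(rep(2, nI), rep(2, nII), rep(-2, nIII), rep(-2, nIV))
    list(xa = xa, xb = xb)
  }
  v <- mk(40, 15, 40, 1)
  expect_equal(sahoo_rules(v$xa, v$xb, fa, fb), "A-high=>B-high")
  v2 <- mk(40, 1, 40, 1)
  expect_equal(sahoo_rules(v2$xa, v2$xb, fa, fb), "equivalent")
  v3 <- mk(1, 40, 1, 40)
  expect_equal(sahoo_rules(v3$xa, v3$xb, fa, fb), "opposite")
  v4 <- mk(20, 20, 20, 20)
  expect_equal(sahoo_rules(v4$xa, v4$xb, fa, fb), character(0))
})
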