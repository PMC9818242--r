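# Contingency tables, rule templates, scope/precision statistics, and rule
# selection.

# the worked binary table: LL=9, LH=2, HL=1, HH=8
worked_table <- function() {
  table_from_counts(matrix(c(9, 1, 2, 8), 2, 2, dimnames = list(c(0, 1), c(0, 1))))
}

test_that("contingency tables hold exact joint frequencies with pairwise deletion", {
  tab <- build_contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_true(all(tab$counts == 1))
  expect_equal(tab$n, 4)

  tab2 <- build_contingency(c(1, 1, NA), c(1, 1, 1))
  expect_equal(tab2$n, 2)
  expect_equal(tab2$counts["1", "1"], 2L)

  tab3 <- build_contingency(c(1, 0, -1), c(1, 0, -1))
  expect_equal(unname(diag(tab3$counts)), c(1L, 1L, 1L))

  expect_error(build_contingency(c(NA, NA), c(1, 1)),
               class = "plbin_empty_table")
})

test_that("margins are conserved on random tables", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      counts <- random_ternary_counts()
      tab <- table_from_counts(counts)
      expect_equal(tab$counts, counts)
      expect_equal(sum(tab$counts), tab$n)
      expect_equal(rowSums(tab$counts), rowSums(counts))
      expect_equal(colSums(tab$counts), colSums(counts))
    }
  })
})

test_that("error cells follow the strict and lenient semantics", {
  bin <- rule_templates(2, 2)
  expect_equal(which(bin$UP_UP$error_cells, arr.ind = TRUE)[1, ],
               c(row = 2L, col = 1L))  # (HIGH, LOW)
  tern <- rule_templates(3, 3)
  expect_equal(sort(colnames(tern$UP_UP$error_cells)[tern$UP_UP$error_cells["1", ]]),
               c("-1", "0"))           # (UP, NORMAL), (UP, DOWN)
  expect_equal(names(tern), c("UP_UP", "DOWN_DOWN", "UP_DOWN", "DOWN_UP",
                              "EQUIVALENT", "OPPOSITE"))
  # symmetric templates are unions with the transposed cells
  expect_equal(tern$EQUIVALENT$error_cells,
               tern$UP_UP$error_cells | t(tern$UP_UP$error_cells))
  expect_equal(tern$OPPOSITE$error_cells,
               tern$UP_DOWN$error_cells | t(tern$UP_DOWN$error_cells))
  len <- rule_templates(3, 3, "lenient")
  expect_equal(which(len$UP_UP$error_cells, arr.ind = TRUE)[1, ],
               c(row = 3L, col = 1L))  # only (UP, DOWN)
  # binary semantics coincide
  len2 <- rule_templates(2, 2, "lenient")
  for (nm in names(bin)) {
    expect_equal(len2[[nm]]$error_cells, bin[[nm]]$error_cells)
  }
  expect_error(rule_templates(4, 2), class = "plbin_input_error")
})

test_that("scope, error count, precision and z match the worked example", {
  st <- rule_stats(worked_table(), rule_templates(2, 2)$UP_UP)
  expect_equal(st$scope, 0.225)
  expect_equal(st$error_count, 1L)
  expect_equal(st$precision, 1 - (1 / 20) / 0.225, tolerance = 1e-12)
  expect_equal(st$z, (20 * 0.225 - 1) / sqrt(20 * 0.225 * 0.775),
               tolerance = 1e-12)
  expect_true(st$significant)
})

test_that("a rule with no observed errors has precision exactly 1", {
  tab <- table_from_counts(matrix(c(5, 0, 0, 5), 2, 2,
                                  dimnames = list(c(0, 1), c(0, 1))))
  st <- rule_stats(tab, rule_templates(2, 2)$UP_UP)
  expect_equal(st$precision, 1)
})

test_that("independence tables have zero precision for every template", {
  counts <- matrix(5L, 3, 3, dimnames = list(c(-1, 0, 1), c(-1, 0, 1)))
  tab <- table_from_counts(counts)
  for (tpl in rule_templates(3, 3)) {
    expect_equal(rule_stats(tab, tpl)$precision, 0, tolerance = 1e-12)
  }
})

test_that("the weighted-cell precision form agrees with the closed form", {
  tpls <- rule_templates(3, 3)
  withr::with_seed(7, {
    for (rep in 1:100) {
      counts <- random_ternary_counts()
      tab <- table_from_counts(counts)
      for (tpl in tpls) {
        st <- rule_stats(tab, tpl)
        w <- precision_weighted_form(counts, tpl$error_cells)
        if (is.na(st$precision)) {
          expect_true(is.na(w))
        } else {
          expect_equal(st$precision, w, tolerance = 1e-12)
        }
        expect_gte(st$scope, 0)
        expect_lte(st$scope, 1)
        if (!is.na(st$precision)) {
          expect_lte(st$precision, 1)
          expect_gte(st$precision, 1 - 1 / st$scope)
        }
      }
    }
  })
})

test_that("template stats are symmetric under joint transposition", {
  tpls <- rule_templates(3, 3)
  withr::with_seed(8, {
    for (rep in 1:20) {
      counts <- random_ternary_counts()
      tab <- table_from_counts(counts)
      ttab <- plbin:::t_contingency(tab)
      for (tpl in tpls) {
        ttpl <- structure(list(name = tpl$name, error_cells = t(tpl$error_cells),
                               semantics = tpl$semantics),
                          class = "rule_template")
        a <- rule_stats(tab, tpl)
        b <- rule_stats(ttab, ttpl)
        expect_equal(a$scope, b$scope, tolerance = 1e-12)
        expect_equal(a$precision, b$precision, tolerance = 1e-12)
        expect_equal(a$error_count, b$error_count)
      }
    }
  })
})

test_that("moving a sample out of an error cell never decreases precision", {
  tpls <- rule_templates(3, 3)
  withr::with_seed(9, {
    moved <- 0
    for (rep in 1:40) {
      counts <- random_ternary_counts()
      for (tpl in tpls) {
        err <- tpl$error_cells
        # pick an occupied error cell and a non-error cell in the same row
        cand <- which(err & counts > 0, arr.ind = TRUE)
        if (!nrow(cand)) next
        i <- cand[1, 1]
        dest <- which(!err[i, ])
        if (!length(dest)) next
        before <- rule_stats(table_from_counts(counts), tpl)$precision
        counts2 <- counts
        counts2[i, cand[1, 2]] <- counts2[i, cand[1, 2]] - 1L
        counts2[i, dest[1]] <- counts2[i, dest[1]] + 1L
        after <- rule_stats(table_from_counts(counts2), tpl)$precision
        if (is.na(before) || is.na(after)) next
        expect_gte(after, before - 1e-12)
        moved <- moved + 1
      }
    }
    expect_gt(moved, 50)
  })
})

test_that("degenerate margins give scope 0 and no significance", {
  tab <- table_from_counts(matrix(c(10, 0, 10, 0), 2, 2,
                                  dimnames = list(c(0, 1), c(0, 1))))
  st <- rule_stats(tab, rule_templates(2, 2)$UP_UP)
  expect_equal(st$scope, 0)
  expect_true(is.na(st$precision))
  expect_false(st$significant)
})

test_that("precision-first selection picks the worked example's UP_UP over EQUIVALENT and DOWN_DOWN", {
  tab <- worked_table()
  tpls <- rule_templates(2, 2)
  eq <- rule_stats(tab, tpls$EQUIVALENT)
  dd <- rule_stats(tab, tpls$DOWN_DOWN)
  expect_equal(eq$precision, 0.70, tolerance = 1e-12)
  expect_equal(eq$scope, 0.50)
  expect_equal(dd$precision, 1 - (2 / 20) / 0.275, tolerance = 1e-12)
  expect_equal(dd$scope, 0.275)
  sel <- select_rule(tab)
  expect_equal(sel$template, "UP_UP")
  # UP_UP has the top precision but EQUIVALENT the top scope: strict
  # dominance selects nothing
  expect_equal(nrow(select_rule(tab, policy = "strict_dominance")), 0L)
})

test_that("selection returns nothing when no template is significant", {
  counts <- matrix(5L, 3, 3, dimnames = list(c(-1, 0, 1), c(-1, 0, 1)))
  expect_equal(nrow(select_rule(table_from_counts(counts))), 0L)
})
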