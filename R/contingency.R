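# Prediction-logic scoring of pairwise implication rules.
#
# A rule is an if-then proposition on the joint states of two genes; it is
# scored on the pair's contingency table through its error cells (the cells
# whose occupancy contradicts the rule). Scope U_p is the independence-
# expected error mass, precision (del, written nabla below) is the
# proportional reduction of error:
#
#   U_p   = sum_{(i,j) in omega} N_i. * N_.j / N^2
#   del_p = 1 - (K / N) / U_p,   K = sum_{(i,j) in omega} N_ij
#
# del_p = 1 for a perfect rule, 0 under independence, negative when the rule
# is worse than chance.

ternary_states <- c(-1L, 0L, 1L)
binary_states <- c(0L, 1L)

template_order <- c("UP_UP", "DOWN_DOWN", "UP_DOWN", "DOWN_UP",
                    "EQUIVALENT", "OPPOSITE")

states_for_arity <- function(arity) {
  if (arity == 2L) binary_states else if (arity == 3L) ternary_states else
    abort("supported arities are 2 and 3", class = "plbin_input_error")
}

#' Cross-tabulate the states of two genes
#'
#' Builds the joint state-frequency table of two discrete state vectors,
#' dropping samples where either state is missing (pairwise deletion).
#'
#' @param a,b Integer state vectors of equal length over `{0,1}` (binary) or
#'   `{-1,0,1}` (ternary); `NA` marks missing.
#' @param arity_a,arity_b State-set sizes (2 or 3); inferred from the values
#'   when omitted (any negative value implies ternary).
#' @return An object of class `contingency_table`: counts matrix (rows = `a`
#'   states, columns = `b` states, ordered ascending), with retained sample
#'   count `n`.
#' @examples
#' build_contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
build_contingency <- function(a, b, arity_a = NULL, arity_b = NULL) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length", class = "plbin_input_error")
  }
  infer <- function(v, given) {
    if (!is.null(given)) return(as.integer(given))
    if (any(v < 0, na.rm = TRUE) || any(v == 0, na.rm = TRUE) && any(v == 1, na.rm = TRUE) &&
        any(v == -1, na.rm = TRUE)) return(3L)
    if (all(v %in% c(0L, 1L, NA))) 2L else 3L
  }
  arity_a <- infer(a, arity_a)
  arity_b <- infer(b, arity_b)
  sa <- states_for_arity(arity_a)
  sb <- states_for_arity(arity_b)
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) abort("zero retained samples", class = "plbin_empty_table")
  counts <- table(factor(a[keep], levels = sa), factor(b[keep], levels = sb))
  counts <- matrix(as.integer(counts), length(sa), length(sb),
                   dimnames = list(sa, sb))
  structure(list(counts = counts, row_states = sa, col_states = sb,
                 n = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (", x$n, " samples)\n", sep = "")
  print(x$counts)
  invisible(x)
}

# transpose a contingency table (swap the two variables)
t_contingency <- function(tab) {
  structure(list(counts = t(tab$counts), row_states = tab$col_states,
                 col_states = tab$row_states, n = tab$n),
            class = "contingency_table")
}

#' The six Boolean implication rule templates
#'
#' Four asymmetric rules (UP_UP: "A up implies B up"; UP_DOWN, DOWN_UP,
#' DOWN_DOWN analogous) and two symmetric rules (EQUIVALENT = UP_UP plus its
#' transpose, OPPOSITE = UP_DOWN plus its transpose). Under `"strict"`
#' semantics a cell is an error cell when the antecedent holds but the
#' consequent does not (for ternary data the NORMAL state fails an UP or
#' DOWN consequent); `"lenient"` semantics only counts outright
#' contradictions, removing NORMAL-containing cells from the error set. For
#' binary variables the two semantics coincide.
#'
#' @param arity_a,arity_b State-set sizes of the two variables (2 or 3).
#' @param semantics `"strict"` (default) or `"lenient"`.
#' @return Named list of six `rule_template` objects in the fixed order
#'   UP_UP, DOWN_DOWN, UP_DOWN, DOWN_UP, EQUIVALENT, OPPOSITE; each holds a
#'   logical error-cell matrix over the state grid.
#' @examples
#' rule_templates(3, 3)$UP_UP$error_cells
#' @export
rule_templates <- function(arity_a, arity_b, semantics = c("strict", "lenient")) {
  semantics <- match.arg(semantics)
  sa <- states_for_arity(as.integer(arity_a))
  sb <- states_for_arity(as.integer(arity_b))
  up_a <- max(sa); down_a <- min(sa)
  up_b <- max(sb); down_b <- min(sb)
  grid_names <- list(as.character(sa), as.character(sb))

  asym <- function(ante, cons) {
    m <- matrix(FALSE, length(sa), length(sb), dimnames = grid_names)
    m[as.character(ante), as.character(sb[sb != cons])] <- TRUE
    m
  }
  cells <- list(
    UP_UP = asym(up_a, up_b),
    DOWN_DOWN = asym(down_a, down_b),
    UP_DOWN = asym(up_a, down_b),
    DOWN_UP = asym(down_a, up_b)
  )
  if (length(sa) == length(sb)) {
    cells$EQUIVALENT <- cells$UP_UP | t(cells$UP_UP)
    cells$OPPOSITE <- cells$UP_DOWN | t(cells$UP_DOWN)
  } else {
    # mixed binary/ternary grids are not square; symmetric rules combine the
    # two directions' cells on the same grid
    tr <- function(m) {
      out <- matrix(FALSE, length(sa), length(sb), dimnames = grid_names)
      for (i in as.character(sa)) for (j in as.character(sb)) {
        if (i %in% colnames(m) && j %in% rownames(m) && m[j, i]) out[i, j] <- TRUE
      }
      out
    }
    cells$EQUIVALENT <- cells$UP_UP | tr(cells$UP_UP)
    cells$OPPOSITE <- cells$UP_DOWN | tr(cells$UP_DOWN)
  }
  if (semantics == "lenient") {
    # only outright contradictions count: drop NORMAL-containing cells
    for (nm in names(cells)) {
      m <- cells[[nm]]
      if (length(sa) == 3L) m["0", ] <- FALSE
      if (length(sb) == 3L) m[, "0"] <- FALSE
      cells[[nm]] <- m
    }
  }
  out <- purrr::imap(cells, function(m, nm) {
    structure(list(name = nm, error_cells = m, semantics = semantics),
              class = "rule_template")
  })
  out[template_order]
}

#' @export
print.rule_template <- function(x, ...) {
  cat("Rule template", x$name, "(", x$semantics, "semantics )\n")
  cat("error cells:\n")
  print(x$error_cells)
  invisible(x)
}

#' Scope, precision and z statistic of a rule on a table
#'
#' Computes the prediction-logic scope `U_p` (independence-expected error
#' mass), observed error count `K`, precision `del_p = 1 - (K/N)/U_p`, and a
#' one-tailed z statistic treating `K` as Binomial(N, U_p) under
#' independence: `z = (N U_p - K) / sqrt(N U_p (1 - U_p))`. A rule is
#' significant when `z >= z_preset`, the scope clears its feasibility bound
#' `U_p >= z_preset^2 / (N + z_preset^2)` (the smallest scope at which even
#' an error-free rule can reach `z_preset`), and `del_p > 0`.
#'
#' @param tab A `contingency_table`.
#' @param template A `rule_template` (error-cell grid matching `tab`).
#' @param z_preset One-tailed z threshold, default 1.645 (alpha = 0.05).
#' @param min_expected Additional normal-approximation guard: pairs with
#'   `N * U_p < min_expected` are marked infeasible. Default 0 here (the
#'   bare statistic); network induction uses 5.
#' @return One-row tibble: `template`, `scope`, `precision`, `error_count`,
#'   `z`, `scope_feasible`, `significant`.
#' @examples
#' tab <- build_contingency(rep(c(0, 1), c(11, 9)), c(rep(0, 9), rep(1, 2), 0, rep(1, 8)))
#' rule_stats(tab, rule_templates(2, 2)$UP_UP)
#' @export
rule_stats <- function(tab, template, z_preset = 1.645, min_expected = 0) {
  stopifnot(inherits(tab, "contingency_table"), inherits(template, "rule_template"))
  counts <- tab$counts
  omega <- template$error_cells
  if (!identical(dim(counts), dim(omega))) {
    abort("template grid does not match the table", class = "plbin_input_error")
  }
  n <- tab$n
  if (n < 1) abort("empty table", class = "plbin_empty_table")
  rm <- rowSums(counts)
  cm <- colSums(counts)
  scope <- sum(outer(rm, cm)[omega]) / n^2
  k <- sum(counts[omega])
  if (scope <= 0) {
    return(tibble(template = template$name, scope = 0, precision = NA_real_,
                  error_count = as.integer(k), z = NA_real_,
                  scope_feasible = FALSE, significant = FALSE))
  }
  precision <- 1 - (k / n) / scope
  z <- if (scope >= 1) {
    0  # error cells cover the whole grid: no discriminating power
  } else {
    (n * scope - k) / sqrt(n * scope * (1 - scope))
  }
  u_min <- z_preset^2 / (n + z_preset^2)
  feasible <- scope >= u_min && n * scope >= min_expected
  tibble(template = template$name,
         scope = scope,
         precision = precision,
         error_count = as.integer(k),
         z = z,
         scope_feasible = feasible,
         significant = feasible && !is.na(z) && z >= z_preset && precision > 0)
}

#' Select the implication rule for one gene pair
#'
#' Evaluates a set of rule templates on a contingency table and returns the
#' selected rule, if any. Under the default `"precision_first"` policy the
#' significant candidate with the highest precision wins, ties broken by
#' larger scope and then by the fixed template order; `"strict_dominance"`
#' returns a significant candidate only when it simultaneously maximizes
#' both precision and scope over every evaluated template.
#'
#' @param tab A `contingency_table`.
#' @param templates List of `rule_template`s; defaults to all six (strict
#'   semantics) for the table's state grid.
#' @param z_preset One-tailed z threshold, default 1.645.
#' @param policy `"precision_first"` (default) or `"strict_dominance"`.
#' @param min_expected Normal-approximation guard passed to [rule_stats()].
#' @return Tibble with 0 rows (no rule) or 1 row (the selected rule's
#'   statistics).
#' @examples
#' tab <- build_contingency(rep(c(0, 1), c(11, 9)), c(rep(0, 9), rep(1, 2), 0, rep(1, 8)))
#' select_rule(tab)
#' @export
select_rule <- function(tab, templates = NULL, z_preset = 1.645,
                        policy = c("precision_first", "strict_dominance"),
                        min_expected = 0) {
  policy <- match.arg(policy)
  if (is.null(templates)) {
    templates <- rule_templates(length(tab$row_states), length(tab$col_states))
  }
  if (!length(templates)) abort("`templates` must be non-empty", class = "plbin_input_error")
  all_stats <- purrr::map_dfr(templates, rule_stats, tab = tab,
                              z_preset = z_preset, min_expected = min_expected)
  all_stats$order <- match(all_stats$template, template_order)
  cand <- all_stats[all_stats$significant, , drop = FALSE]
  if (!nrow(cand)) return(all_stats[0, setdiff(names(all_stats), "order")])
  if (policy == "precision_first") {
    cand <- cand[order(-cand$precision, -cand$scope, cand$order), , drop = FALSE]
    sel <- cand[1, , drop = FALSE]
  } else {
    max_prec <- max(all_stats$precision, na.rm = TRUE)
    max_scope <- max(all_stats$scope, na.rm = TRUE)
    dom <- cand[cand$precision >= max_prec & cand$scope >= max_scope, , drop = FALSE]
    if (!nrow(dom)) return(all_stats[0, setdiff(names(all_stats), "order")])
    dom <- dom[order(dom$order), , drop = FALSE]
    sel <- dom[1, , drop = FALSE]
  }
  sel[, setdiff(names(sel), "order")]
}
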