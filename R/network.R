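# Genome-scale induction of prediction-logic Boolean implication networks.
#
# Every ordered gene pair is scored against the six rule templates on its
# pairwise-complete contingency table. The computation is O(n^2) in the
# number of genes and is carried out block-wise with dense matrix products:
# for each state s the indicator matrix M_s (genes x samples) gives, via
# M_s %*% t(M_t), the joint cell counts of every gene pair at once.

#' Induce a Boolean implication network from categorized data
#'
#' Evaluates all ordered gene pairs of a categorized gene table, scores the
#' six implication-rule templates by scope and precision, applies the
#' one-tailed z-test selection, and returns the network of selected rules.
#' Symmetric rules (EQUIVALENT, OPPOSITE) are emitted once per unordered
#' pair in the lexicographically canonical direction. Genes observed in a
#' single state carry no scope for any rule and are skipped (their count is
#' recorded). Output is deterministic given the input.
#'
#' @param m Categorized gene table (see [categorize_expression()],
#'   [binarize_single_cell()], [sim_null_states()], ...).
#' @param z_preset One-tailed z threshold; at least 1.645 (alpha = 0.05) is
#'   used for network construction. Default 1.645.
#' @param semantics Error-cell semantics for ternary data, `"strict"` or
#'   `"lenient"` (see [rule_templates()]).
#' @param policy Rule-selection policy (see [select_rule()]).
#' @param min_n Minimum retained (pairwise-complete) sample count for a pair
#'   to be evaluated. Default 10.
#' @param min_expected Normal-approximation guard: a rule on a pair with
#'   `N * U_p < min_expected` is infeasible. Default 5.
#' @param block_size Number of genes per row block in the blocked pairwise
#'   evaluation. Default 1024.
#' @return An object of class `plbin_network`: list with `edges` (tibble
#'   `source`, `target`, `rule`, `scope`, `precision`, `z`, `n`), `nodes`,
#'   `params`, and `n_skipped`. Use [tidy()] for the edge tibble and
#'   [glance()] for a one-row summary.
#' @examples
#' m <- sim_planted_implications(
#'   tibble::tibble(source = "g1", target = "g2", template = "UP_UP", epsilon = 0),
#'   n_genes = 10, n_samples = 100, seed = 1
#' )
#' net <- induce_network(m)
#' tidy(net)
#' @export
induce_network <- function(m, z_preset = 1.645,
                           semantics = c("strict", "lenient"),
                           policy = c("precision_first", "strict_dominance"),
                           min_n = 10, min_expected = 5, block_size = 1024) {
  semantics <- match.arg(semantics)
  policy <- match.arg(policy)
  m <- check_categorized(m, "m")
  arity <- state_arity(m)
  states <- states_for_arity(arity)
  S <- gene_matrix(m)
  ids <- rownames(S)
  G <- nrow(S)
  if (G < 2 || ncol(S) < 2) {
    abort("need at least 2 genes and 2 samples", class = "plbin_input_error")
  }

  # single-state genes carry zero scope for every template; they are skipped
  # (an all-constant input yields an empty network)
  single_state <- apply(S, 1, function(v) length(unique(v[!is.na(v)])) <= 1)

  templates <- rule_templates(arity, arity, semantics)
  tpl_names <- names(templates)
  symmetric <- tpl_names %in% c("EQUIVALENT", "OPPOSITE")

  O <- (!is.na(S)) * 1
  Ms <- lapply(states, function(s) (S == s & !is.na(S)) * 1)
  names(Ms) <- as.character(states)
  tO <- t(O)
  tMs <- lapply(Ms, t)

  u_min_of <- function(N) z_preset^2 / (N + z_preset^2)

  edge_chunks <- list()
  blocks <- split(seq_len(G), ceiling(seq_len(G) / block_size))
  for (rows in blocks) {
    Nb <- O[rows, , drop = FALSE] %*% tO                      # retained samples
    Rb <- lapply(Ms, function(Mx) Mx[rows, , drop = FALSE] %*% tO)
    Cb <- lapply(tMs, function(tMx) O[rows, , drop = FALSE] %*% tMx)
    cellb <- list()
    for (s in names(Ms)) {
      for (t in names(Ms)) {
        cellb[[paste(s, t)]] <- Ms[[s]][rows, , drop = FALSE] %*% tMs[[t]]
      }
    }

    best_prec <- matrix(-Inf, length(rows), G)
    best_scope <- matrix(-Inf, length(rows), G)
    best_z <- matrix(NA_real_, length(rows), G)
    best_tpl <- matrix(0L, length(rows), G)
    if (policy == "strict_dominance") {
      max_prec <- matrix(-Inf, length(rows), G)
      max_scope <- matrix(-Inf, length(rows), G)
      all_U <- list(); all_P <- list(); all_Z <- list(); all_sig <- list()
    }

    for (k in seq_along(templates)) {
      omega <- templates[[k]]$error_cells
      U <- matrix(0, length(rows), G)
      K <- matrix(0, length(rows), G)
      for (i in seq_along(states)) {
        for (j in seq_along(states)) {
          if (!omega[i, j]) next
          si <- as.character(states[i]); sj <- as.character(states[j])
          U <- U + Rb[[si]] * Cb[[sj]]
          K <- K + cellb[[paste(si, sj)]]
        }
      }
      U <- U / Nb^2
      prec <- 1 - (K / Nb) / U
      denom <- Nb * U * (1 - U)
      z <- (Nb * U - K) / sqrt(pmax(denom, .Machine$double.eps))
      z[U >= 1] <- 0
      ok_scope <- U > 0 & U < 1
      sig <- ok_scope & !is.na(z) & z >= z_preset &
        U >= u_min_of(Nb) & (Nb * U) >= min_expected &
        prec > 0 & Nb >= min_n
      sig[!ok_scope] <- FALSE
      if (policy == "strict_dominance") {
        safe_p <- prec; safe_p[!ok_scope] <- -Inf
        max_prec <- pmax(max_prec, safe_p, na.rm = TRUE)
        max_scope <- pmax(max_scope, U)
        all_U[[k]] <- U; all_P[[k]] <- prec; all_Z[[k]] <- z; all_sig[[k]] <- sig
      } else {
        better <- sig & (prec > best_prec | (prec == best_prec & U > best_scope))
        better[is.na(better)] <- FALSE
        best_prec[better] <- prec[better]
        best_scope[better] <- U[better]
        best_z[better] <- z[better]
        best_tpl[better] <- k
      }
    }

    if (policy == "strict_dominance") {
      for (k in seq_along(templates)) {
        dom <- all_sig[[k]] & all_P[[k]] >= max_prec & all_U[[k]] >= max_scope &
          best_tpl == 0L
        dom[is.na(dom)] <- FALSE
        best_prec[dom] <- all_P[[k]][dom]
        best_scope[dom] <- all_U[[k]][dom]
        best_z[dom] <- all_Z[[k]][dom]
        best_tpl[dom] <- k
      }
    }

    # self-pairs are not edges
    for (ii in seq_along(rows)) best_tpl[ii, rows[ii]] <- 0L

    hit <- which(best_tpl > 0L, arr.ind = TRUE)
    if (nrow(hit)) {
      src <- ids[rows[hit[, 1]]]
      tgt <- ids[hit[, 2]]
      rule <- tpl_names[best_tpl[hit]]
      sym <- rule %in% c("EQUIVALENT", "OPPOSITE")
      canon_src <- ifelse(sym, pmin(src, tgt), src)
      canon_tgt <- ifelse(sym, pmax(src, tgt), tgt)
      edge_chunks[[length(edge_chunks) + 1L]] <- tibble(
        source = canon_src, target = canon_tgt, rule = rule,
        scope = best_scope[hit], precision = best_prec[hit],
        z = best_z[hit], n = as.integer(Nb[hit])
      )
    }
  }

  edges <- if (length(edge_chunks)) dplyr::bind_rows(edge_chunks) else
    tibble(source = character(), target = character(), rule = character(),
           scope = double(), precision = double(), z = double(), n = integer())
  edges <- dplyr::distinct(edges) %>% arrange(.data$source, .data$target, .data$rule)

  structure(
    list(edges = edges,
         nodes = tibble(gene_id = ids, single_state = unname(single_state)),
         params = list(z_preset = z_preset, semantics = semantics,
                       policy = policy, min_n = min_n,
                       min_expected = min_expected, arity = arity),
         n_skipped = sum(single_state)),
    class = "plbin_network"
  )
}

#' @export
print.plbin_network <- function(x, ...) {
  cat("Boolean implication network:", nrow(x$edges), "edges over",
      nrow(x$nodes), "genes\n")
  cat(sprintf("  z preset %.3f, %s semantics, %s selection; %d single-state gene(s) skipped\n",
              x$params$z_preset, x$params$semantics, x$params$policy, x$n_skipped))
  if (nrow(x$edges)) print(utils::head(x$edges, 5))
  invisible(x)
}

#' Tidy an implication network into its edge tibble
#'
#' @param x A `plbin_network`.
#' @param ... Unused.
#' @return Tibble with one row per selected rule: `source`, `target`,
#'   `rule`, `scope`, `precision`, `z`, `n`.
#' @export
tidy.plbin_network <- function(x, ...) x$edges

#' One-row summary of an implication network
#'
#' @param x A `plbin_network`.
#' @param ... Unused.
#' @return One-row tibble: gene and edge counts, per-class edge counts,
#'   median precision, skipped genes.
#' @export
glance.plbin_network <- function(x, ...) {
  e <- x$edges
  tibble(
    n_genes = nrow(x$nodes),
    n_edges = nrow(e),
    n_asymmetric = sum(!e$rule %in% c("EQUIVALENT", "OPPOSITE")),
    n_symmetric = sum(e$rule %in% c("EQUIVALENT", "OPPOSITE")),
    median_precision = if (nrow(e)) median(e$precision) else NA_real_,
    median_scope = if (nrow(e)) median(e$scope) else NA_real_,
    n_skipped = x$n_skipped
  )
}

#' Plot an implication network
#'
#' Draws the network with a force-directed layout; edge color encodes the
#' rule class and node size the total degree.
#'
#' @param object A `plbin_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plbin_network <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2],
                  degree = igraph::degree(g))
  edf <- tidy(object) %>%
    left_join(nodes %>% select("name", xs = "x", ys = "y"),
              by = c(source = "name")) %>%
    left_join(nodes %>% select("name", xt = "x", yt = "y"),
              by = c(target = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edf,
      ggplot2::aes(x = .data$xs, y = .data$ys, xend = .data$xt, yend = .data$yt,
                   color = .data$rule),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      color = "grey20"
    ) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "rule", size = "degree")
}
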