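# Centrality metrics for hub-gene prioritization on inferred networks,
# top-percentile hub calling, and the random-subnetwork permutation test.
# Shortest-path machinery is delegated to igraph; the Wasserman-Faust
# closeness scaling and VoteRank are computed here.

#' Convert edges to an igraph graph
#'
#' Accepts a `plbin_network`, an edge tibble/data frame (first two columns
#' source and target), or an igraph object (returned as is).
#'
#' @param x Network, edge table, or igraph object.
#' @param directed Build a directed graph. Default `TRUE` for
#'   `plbin_network` input (implication rules are directed), `FALSE` for
#'   plain edge tables.
#' @param nodes Optional character vector of node ids to include (isolated
#'   nodes allowed).
#' @return An igraph object without self-loops.
#' @export
as_igraph <- function(x, directed = NULL, nodes = NULL) {
  if (inherits(x, "igraph")) return(x)
  if (inherits(x, "plbin_network")) {
    edges <- x$edges
    if (is.null(nodes)) {
      nodes <- sort(unique(c(edges$source, edges$target)))
    }
    directed <- directed %||% TRUE
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("edge table needs >= 2 columns", class = "plbin_input_error")
    edges <- tibble(source = as.character(x[[1]]), target = as.character(x[[2]]))
    directed <- directed %||% FALSE
  } else {
    abort("cannot interpret `x` as a graph", class = "plbin_input_error")
  }
  if (any(edges$source == edges$target)) {
    abort("self-loops are not allowed", class = "plbin_input_error")
  }
  nodes <- unique(c(nodes %||% character(), edges$source, edges$target))
  igraph::graph_from_data_frame(edges[, 1:2], directed = directed,
                                vertices = sort(nodes))
}

centrality_tbl <- function(g, metric, values, params = list()) {
  out <- tibble(node = igraph::V(g)$name, metric = metric,
                value = unname(values))
  attr(out, "params") <- params
  out
}

#' Degree centrality
#'
#' Number of neighbors of each node (in- or out-neighbors for directed
#' graphs), divided by `N - 1` when normalized.
#'
#' @param g Graph (anything [as_igraph()] accepts).
#' @param mode `"total"`, `"in"`, or `"out"` (the latter two require a
#'   directed graph).
#' @param normalized Divide by `N - 1`. Default `TRUE`.
#' @return Tibble `node`, `metric`, `value`.
#' @export
degree_centrality <- function(g, mode = c("total", "in", "out"),
                              normalized = TRUE) {
  g <- as_igraph(g)
  mode <- match.arg(mode)
  if (mode != "total" && !igraph::is_directed(g)) {
    abort("in/out degree requires a directed graph", class = "plbin_mode_error")
  }
  n <- igraph::vcount(g)
  if (normalized && n < 2) {
    abort("normalization needs >= 2 nodes", class = "plbin_input_error")
  }
  d <- igraph::degree(g, mode = switch(mode, total = "all", mode))
  if (normalized) d <- d / (n - 1)
  centrality_tbl(g, paste0(if (mode == "total") "" else paste0(mode, "_"), "degree"),
                 d, list(mode = mode, normalized = normalized))
}

#' Eigenvector centrality
#'
#' Principal-eigenvector centrality (each node's value proportional to the
#' sum of its neighbors' values), computed on the undirected projection by
#' default for stability on implication networks that are rarely strongly
#' connected. Values are non-negative and L2-normalized.
#'
#' @param g Graph.
#' @param directed Use the directed adjacency instead of the undirected
#'   projection. Default `FALSE`.
#' @param tol Power-iteration tolerance. Default 1e-6.
#' @param max_iter Iteration cap. Default 1000.
#' @return Tibble `node`, `metric`, `value`.
#' @export
eigenvector_centrality <- function(g, directed = FALSE, tol = 1e-6,
                                   max_iter = 1000) {
  g <- as_igraph(g)
  if (igraph::vcount(g) == 0) abort("empty graph", class = "plbin_input_error")
  gu <- if (directed) g else igraph::as_undirected(g, mode = "collapse")
  ev <- igraph::eigen_centrality(
    gu, directed = directed,
    options = list(maxiter = max_iter, tol = tol)
  )$vector
  ev <- abs(ev)
  nrm <- sqrt(sum(ev^2))
  if (nrm > 0) ev <- ev / nrm
  centrality_tbl(g, "eigenvector", ev,
                 list(directed = directed, tol = tol, max_iter = max_iter))
}

#' Closeness centrality (Wasserman-Faust)
#'
#' For each node with `r` reachable nodes (itself included) and `S` the sum
#' of shortest-path distances to them:
#' `((r - 1) / (N - 1)) * ((r - 1) / S)`. Handles disconnected graphs; an
#' isolated node scores 0.
#'
#' @param g Graph.
#' @return Tibble `node`, `metric`, `value`.
#' @export
closeness_centrality <- function(g) {
  g <- as_igraph(g)
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph", class = "plbin_input_error")
  d <- igraph::distances(g, mode = "out")
  vals <- vapply(seq_len(n), function(i) {
    di <- d[i, ]
    reach <- is.finite(di)
    r <- sum(reach)              # includes self (distance 0)
    s <- sum(di[reach])
    if (r <= 1 || s == 0 || n == 1) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / s)
  }, numeric(1))
  centrality_tbl(g, "closeness", vals, list(variant = "wasserman_faust"))
}

#' Betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node
#' (endpoints excluded), Brandes accumulation. Normalization divides by
#' `(N-1)(N-2)/2` for undirected and `(N-1)(N-2)` for directed graphs.
#'
#' @param g Graph.
#' @param normalized Default `TRUE`.
#' @return Tibble `node`, `metric`, `value`.
#' @export
betweenness_centrality <- function(g, normalized = TRUE) {
  g <- as_igraph(g)
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph", class = "plbin_input_error")
  b <- igraph::betweenness(g, directed = igraph::is_directed(g))
  if (normalized && n > 2) {
    denom <- (n - 1) * (n - 2)
    if (!igraph::is_directed(g)) denom <- denom / 2
    b <- b / denom
  } else if (normalized) {
    b[] <- 0
  }
  centrality_tbl(g, "betweenness", b, list(normalized = normalized))
}

#' VoteRank centrality
#'
#' Iterative influential-spreader ranking: every node starts with voting
#' ability 1; each round the node with the largest vote sum (the sum of its
#' neighbors' abilities) is elected and that vote sum recorded as its
#' score, its ability drops to 0, and each neighbor's ability is reduced by
#' `1 / <k>` (floored at 0), where `<k>` is the mean degree. Unelected
#' nodes score 0. Ties are broken lexicographically by node id.
#'
#' @param g Graph (undirected projection is used).
#' @param r Number of rounds; defaults to all nodes.
#' @return Tibble `node`, `metric`, `value` (the recorded vote sums).
#' @export
voterank_centrality <- function(g, r = NULL) {
  g <- as_igraph(g)
  gu <- igraph::as_undirected(g, mode = "collapse")
  n <- igraph::vcount(gu)
  if (n == 0) {
    out <- tibble(node = character(), metric = character(), value = double())
    attr(out, "params") <- list(r = 0)
    return(out)
  }
  ids <- igraph::V(gu)$name
  ord <- order(ids)
  adj <- igraph::as_adj_list(gu, mode = "all")
  adj <- lapply(adj, function(vs) as.integer(vs))
  mean_deg <- mean(igraph::degree(gu))
  r <- r %||% n
  ability <- rep(1, n)
  selected <- rep(FALSE, n)
  score <- rep(0, n)
  if (mean_deg > 0) {
    for (round in seq_len(min(r, n))) {
      votes <- vapply(seq_len(n), function(i) {
        if (selected[i]) return(-Inf)
        sum(ability[adj[[i]]])
      }, numeric(1))
      if (all(votes <= 0)) break
      cand <- which(votes == max(votes))
      win <- cand[order(ids[cand])][1]
      score[win] <- votes[win]
      selected[win] <- TRUE
      ability[win] <- 0
      nb <- adj[[win]]
      ability[nb] <- pmax(ability[nb] - 1 / mean_deg, 0)
    }
  }
  centrality_tbl(gu, "voterank", score, list(r = r, mean_degree = mean_deg))
}

#' Call hub nodes in the top percentile of a centrality metric
#'
#' The cutoff is the nearest-rank `(100 - pct)` percentile of the values;
#' all nodes at or above the cutoff are returned (ties included).
#'
#' @param centrality Tibble `node`, `value` (e.g. from
#'   [degree_centrality()]).
#' @param pct Percentile width in (0, 100). Default 10 (top 10th
#'   percentile).
#' @return Character vector of hub node ids.
#' @examples
#' ct <- tibble::tibble(node = letters[1:10], value = 1:10)
#' top_percentile_hubs(ct, 10)
#' @export
top_percentile_hubs <- function(centrality, pct = 10) {
  if (!is.data.frame(centrality) || !all(c("node", "value") %in% names(centrality))) {
    abort("`centrality` must have `node` and `value` columns", class = "plbin_input_error")
  }
  if (pct <= 0 || pct >= 100) abort("`pct` must lie in (0, 100)", class = "plbin_input_error")
  v <- sort(centrality$value)
  n <- length(v)
  idx <- min(floor((100 - pct) / 100 * n) + 1, n)
  cutoff <- v[idx]
  centrality$node[centrality$value >= cutoff]
}

#' Permutation test of a gene subset's average centrality
#'
#' Compares the mean centrality of a gene subset with the means of
#' `n_perm` random subsets of the same size drawn without replacement from
#' the network's nodes; the p value is the fraction of random subsets whose
#' mean is at least the observed mean (ties favor the null).
#'
#' @param centrality Tibble `node`, `value`.
#' @param subset Character vector of node ids (non-empty, all present).
#' @param n_perm Number of random draws. Default 1000.
#' @param seed Integer seed for reproducibility.
#' @return List of class `plbin_permtest`: `p_value`, `observed_mean`,
#'   `null_means`, `n_perm`, `seed`, `subset_size`.
#' @export
subnetwork_centrality_test <- function(centrality, subset, n_perm = 1000,
                                       seed = 1L) {
  if (!length(subset)) abort("`subset` must be non-empty", class = "plbin_input_error")
  if (!all(subset %in% centrality$node)) {
    abort("`subset` contains unknown node(s)", class = "plbin_input_error")
  }
  subset <- unique(subset)
  values <- setNames(centrality$value, centrality$node)
  observed <- mean(values[subset])
  null_means <- numeric(0)
  if (n_perm > 0) {
    null_means <- local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        mean(values[sample.int(length(values), length(subset))])
      }, numeric(1))
    })
  }
  p <- if (n_perm > 0) mean(null_means >= observed) else NA_real_
  structure(list(p_value = p, observed_mean = observed,
                 null_means = null_means, n_perm = n_perm, seed = seed,
                 subset_size = length(subset)),
            class = "plbin_permtest")
}

#' @export
print.plbin_permtest <- function(x, ...) {
  cat(sprintf("Subnetwork centrality permutation test (%d draws, seed %d)\n",
              x$n_perm, x$seed))
  cat(sprintf("  subset size %d, observed mean %.4g, p = %.4g\n",
              x$subset_size, x$observed_mean, x$p_value))
  invisible(x)
}

#' @export
glance.plbin_permtest <- function(x, ...) {
  tibble(observed_mean = x$observed_mean, p_value = x$p_value,
         n_perm = x$n_perm, seed = x$seed, subset_size = x$subset_size)
}

#' Plot the null distribution of a subnetwork centrality test
#'
#' @param object A `plbin_permtest`.
#' @param ... Unused.
#' @return A ggplot object: histogram of null means with the observed mean
#'   marked.
#' @export
autoplot.plbin_permtest <- function(object, ...) {
  df <- tibble(null_mean = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed_mean,
                        color = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "null mean centrality", y = "count",
                  title = sprintf("p = %.3g (%d permutations)",
                                  object$p_value, object$n_perm)) +
    ggplot2::theme_minimal()
}

# run code under a temporary RNG state
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
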