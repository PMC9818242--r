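# Seeded generators for every input class the toolkit consumes. All are
# pure functions of their parameters and seed; no hidden RNG state leaks.
# State probabilities default to 15% down / 70% normal / 15% up, mirroring
# the 30% outside-normal categorization target.

#' Simulate a null categorized gene table
#'
#' Independent, identically distributed discrete states per gene and
#' sample.
#'
#' @param n_genes,n_samples Dimensions.
#' @param state_probs Probabilities of states `(-1, 0, +1)` (ternary, length
#'   3) or `(0, 1)` (binary, length 2); must sum to 1. Default
#'   `c(0.15, 0.70, 0.15)`.
#' @param seed Integer seed.
#' @return A categorized gene table.
#' @examples
#' sim_null_states(10, 50, seed = 1)
#' @export
sim_null_states <- function(n_genes, n_samples,
                            state_probs = c(0.15, 0.70, 0.15), seed = 1L) {
  if (abs(sum(state_probs) - 1) > 1e-8 || any(state_probs < 0)) {
    abort("`state_probs` must be non-negative and sum to 1", class = "plbin_input_error")
  }
  if (!length(state_probs) %in% c(2, 3)) {
    abort("`state_probs` must have length 2 or 3", class = "plbin_input_error")
  }
  states <- if (length(state_probs) == 3) c(-1L, 0L, 1L) else c(0L, 1L)
  vals <- local_seed(seed, {
    matrix(sample(states, n_genes * n_samples, replace = TRUE, prob = state_probs),
           nrow = n_genes)
  })
  if (n_genes == 0) vals <- matrix(integer(), 0, n_samples)
  out <- gene_tbl(vals, sprintf("g%d", seq_len(n_genes)),
                  sprintf("s%d", seq_len(n_samples)))
  new_categorized_tbl(out, length(state_probs),
                      sprintf("iid null states, seed %d", seed))
}

consequent_of <- function(template, antecedent_state) {
  # target state implied by each template given the source's state; NA when
  # the template places no constraint
  switch(template,
         UP_UP = if (antecedent_state == 1L) 1L else NA_integer_,
         DOWN_DOWN = if (antecedent_state == -1L) -1L else NA_integer_,
         UP_DOWN = if (antecedent_state == 1L) -1L else NA_integer_,
         DOWN_UP = if (antecedent_state == -1L) 1L else NA_integer_,
         EQUIVALENT = antecedent_state,
         OPPOSITE = -antecedent_state,
         abort(sprintf("unknown template: %s", template), class = "plbin_spec_error"))
}

#' Simulate categorized data with planted implication rules
#'
#' Non-planted genes carry iid null states. For each planted
#' (source, target, template) spec the target gene satisfies the template's
#' consequent with probability `1 - epsilon` whenever the source state
#' constrains it, and is drawn from the null state distribution otherwise.
#' Symmetric templates constrain every source state (EQUIVALENT copies it,
#' OPPOSITE mirrors it).
#'
#' @param specs Tibble/data frame with columns `source`, `target`,
#'   `template` and optionally `epsilon` (default 0.05); ids must fall in
#'   `g1..g<n_genes>` and no target may be planted twice.
#' @param n_genes,n_samples Dimensions.
#' @param state_probs Null state distribution over `(-1, 0, +1)`.
#' @param seed Integer seed.
#' @return A ternary categorized gene table.
#' @examples
#' sim_planted_implications(
#'   tibble::tibble(source = "g1", target = "g2", template = "UP_UP"),
#'   n_genes = 20, n_samples = 100, seed = 1
#' )
#' @export
sim_planted_implications <- function(specs, n_genes, n_samples,
                                     state_probs = c(0.15, 0.70, 0.15),
                                     seed = 1L) {
  specs <- as_tibble(specs)
  if (!all(c("source", "target", "template") %in% names(specs))) {
    abort("`specs` needs columns source, target, template", class = "plbin_spec_error")
  }
  if (!"epsilon" %in% names(specs)) specs$epsilon <- 0.05
  if (any(specs$epsilon < 0 | specs$epsilon >= 0.5)) {
    abort("epsilon must lie in [0, 0.5)", class = "plbin_spec_error")
  }
  gene_ids <- sprintf("g%d", seq_len(n_genes))
  bad <- setdiff(c(specs$source, specs$target), gene_ids)
  if (length(bad)) {
    abort(sprintf("spec gene(s) out of range: %s", paste(bad, collapse = ", ")),
          class = "plbin_spec_error")
  }
  if (anyDuplicated(specs$target)) {
    abort("overlapping specs: a target gene may be planted only once",
          class = "plbin_spec_error")
  }
  if (any(specs$source == specs$target)) {
    abort("source and target must differ", class = "plbin_spec_error")
  }
  states <- c(-1L, 0L, 1L)
  vals <- local_seed(seed, {
    m <- matrix(sample(states, n_genes * n_samples, replace = TRUE,
                       prob = state_probs),
                nrow = n_genes, dimnames = list(gene_ids, NULL))
    for (i in seq_len(nrow(specs))) {
      src <- m[specs$source[i], ]
      cons <- vapply(src, consequent_of, integer(1),
                     template = specs$template[i])
      keep_null <- runif(n_samples) < specs$epsilon[i] | is.na(cons)
      tgt <- ifelse(keep_null, m[specs$target[i], ], cons)
      m[specs$target[i], ] <- tgt
    }
    m
  })
  out <- gene_tbl(vals, gene_ids, sprintf("s%d", seq_len(n_samples)))
  new_categorized_tbl(out, 3L,
                      sprintf("planted implications (%d spec(s)), seed %d",
                              nrow(specs), seed))
}

#' Simulate log-scale expression with a housekeeping panel
#'
#' Per-gene Gaussian values with gene-specific means and SDs; the first
#' `n_hk` genes form the housekeeping panel and share the (small) SD
#' `hk_sd`, emulating their stable expression.
#'
#' @param n_genes,n_samples Dimensions.
#' @param n_hk Number of housekeeping genes (`<= n_genes`).
#' @param hk_sd Housekeeping SD. Default 0.5 (log2 scale).
#' @param mean_range Range of per-gene mean expression. Default `c(4, 12)`.
#' @param sd_range Range of non-housekeeping per-gene SDs. Default
#'   `c(0.5, 2)`.
#' @param seed Integer seed.
#' @return List with `expr` (gene-by-sample tibble) and `hk_ids`.
#' @export
sim_expression_with_housekeeping <- function(n_genes, n_samples, n_hk,
                                             hk_sd = 0.5,
                                             mean_range = c(4, 12),
                                             sd_range = c(0.5, 2),
                                             seed = 1L) {
  if (n_hk > n_genes) abort("`n_hk` must be <= `n_genes`", class = "plbin_input_error")
  gene_ids <- c(sprintf("hk%d", seq_len(n_hk)),
                sprintf("g%d", seq_len(n_genes - n_hk)))
  vals <- local_seed(seed, {
    mu <- runif(n_genes, mean_range[1], mean_range[2])
    sds <- c(rep(hk_sd, n_hk),
             runif(n_genes - n_hk, sd_range[1], sd_range[2]))
    matrix(rnorm(n_genes * n_samples, mean = rep(mu, n_samples),
                 sd = rep(sds, n_samples)),
           nrow = n_genes)
  })
  list(expr = gene_tbl(vals, gene_ids, sprintf("s%d", seq_len(n_samples))),
       hk_ids = gene_ids[seq_len(n_hk)])
}

#' Simulate single-cell feature counts with dropout
#'
#' Each entry is zero with probability `dropout` and otherwise a Poisson
#' count conditioned to be at least 1, so the expected zero fraction equals
#' `dropout` exactly (the expressed component never contributes zeros).
#'
#' @param n_genes,n_cells Dimensions.
#' @param dropout Zero-inflation probability in `[0, 1)`. Default 0.8.
#' @param mean_count Poisson mean of the expressed component. Default 2.
#' @param seed Integer seed.
#' @return Gene-by-cell tibble of counts.
#' @export
sim_single_cell_counts <- function(n_genes, n_cells, dropout = 0.8,
                                   mean_count = 2, seed = 1L) {
  if (dropout < 0 || dropout >= 1) {
    abort("`dropout` must lie in [0, 1)", class = "plbin_input_error")
  }
  vals <- local_seed(seed, {
    expressed <- rbinom(n_genes * n_cells, 1, 1 - dropout)
    counts <- rpois(n_genes * n_cells, mean_count)
    # conditioned >= 1: resample zeros of the expressed component
    while (any(zero <- expressed == 1 & counts == 0)) {
      counts[zero] <- rpois(sum(zero), mean_count)
    }
    matrix(expressed * counts, nrow = n_genes)
  })
  gene_tbl(vals, sprintf("g%d", seq_len(n_genes)),
           sprintf("c%d", seq_len(n_cells)))
}

#' Toy graph topologies
#'
#' Named topologies for exercising the centrality metrics: a star (`K_1,n`),
#' a path, a complete graph, or a seeded Erdos-Renyi `G(n, p)` graph.
#'
#' @param kind `"star"`, `"path"`, `"complete"`, or `"erdos_renyi"`.
#' @param n Number of nodes.
#' @param p Edge probability (Erdos-Renyi only). Default 0.3.
#' @param seed Integer seed (Erdos-Renyi only).
#' @return An undirected igraph object with nodes `n1..n<n>` (`n1` is the
#'   star center).
#' @examples
#' toy_graph("star", 5)
#' @export
toy_graph <- function(kind = c("star", "path", "complete", "erdos_renyi"),
                      n, p = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  g <- switch(kind,
              star = igraph::make_star(n, mode = "undirected", center = 1),
              path = igraph::make_ring(n, circular = FALSE),
              complete = igraph::make_full_graph(n),
              erdos_renyi = local_seed(seed, {
                igraph::sample_gnp(n, p, directed = FALSE)
              }))
  igraph::V(g)$name <- sprintf("n%d", seq_len(n))
  g
}
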