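# Independent oracles and small fixture builders used across the suite.

# expand a counts matrix into paired state vectors
counts_to_vectors <- function(counts, row_states = NULL, col_states = NULL) {
  if (is.null(row_states)) row_states <- as.integer(rownames(counts))
  if (is.null(col_states)) col_states <- as.integer(colnames(counts))
  a <- integer(0)
  b <- integer(0)
  for (i in seq_along(row_states)) {
    for (j in seq_along(col_states)) {
      k <- counts[i, j]
      a <- c(a, rep(row_states[i], k))
      b <- c(b, rep(col_states[j], k))
    }
  }
  list(a = a, b = b)
}

table_from_counts <- function(counts, row_states = NULL, col_states = NULL) {
  v <- counts_to_vectors(counts, row_states, col_states)
  arity <- function(s) if (any(s < 0)) 3L else 2L
  rs <- if (is.null(row_states)) as.integer(rownames(counts)) else row_states
  cs <- if (is.null(col_states)) as.integer(colnames(counts)) else col_states
  build_contingency(v$a, v$b, arity_a = if (any(rs < 0) || length(rs) == 3) 3L else 2L,
                    arity_b = if (any(cs < 0) || length(cs) == 3) 3L else 2L)
}

# weighted-cell form of the precision: sum over error cells of
# (U_ij / U_p) * (1 - N_ij / (N * U_ij))
precision_weighted_form <- function(counts, error_cells) {
  n <- sum(counts)
  rm <- rowSums(counts)
  cm <- colSums(counts)
  uij <- outer(rm, cm) / n^2
  up <- sum(uij[error_cells])
  if (up == 0) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (!error_cells[i, j]) next
      if (uij[i, j] == 0) next
      total <- total + (uij[i, j] / up) * (1 - counts[i, j] / (n * uij[i, j]))
    }
  }
  total
}

random_ternary_counts <- function(n = 60) {
  p <- runif(9)
  matrix(as.integer(stats::rmultinom(1, n, p)), 3, 3,
         dimnames = list(c(-1, 0, 1), c(-1, 0, 1)))
}

# ---- graph oracles (independent of igraph) -------------------------------

# adjacency matrix of an undirected igraph (names preserved)
adj_of <- function(g) {
  n <- igraph::vcount(g)
  a <- matrix(0, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  for (k in seq_len(nrow(el))) {
    a[el[k, 1], el[k, 2]] <- 1
    a[el[k, 2], el[k, 1]] <- 1
  }
  a
}

# all-pairs shortest-path distances by breadth-first search on the
# adjacency matrix
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(a[v, ] > 0))))
      nxt <- nxt[!is.finite(d[s, nxt])]
      if (!length(nxt)) break
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# enumerate all simple paths between two nodes; return the shortest ones
oracle_shortest_paths <- function(a, from, to) {
  n <- nrow(a)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(a[v, ] > 0)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(from)
  if (!length(paths)) return(list())
  lens <- vapply(paths, length, integer(1))
  paths[lens == min(lens)]
}

# betweenness by exhaustive shortest-path enumeration (endpoints excluded)
oracle_betweenness <- function(a) {
  n <- nrow(a)
  b <- setNames(rep(0, n), rownames(a))
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      sp <- oracle_shortest_paths(a, s, t)
      if (!length(sp)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        onpath <- vapply(sp, function(p) v %in% p, logical(1))
        b[v] <- b[v] + sum(onpath) / length(sp)
      }
    }
  }
  b
}

oracle_closeness_wf <- function(a) {
  d <- oracle_distances(a)
  n <- nrow(a)
  setNames(vapply(seq_len(n), function(i) {
    reach <- is.finite(d[i, ])
    r <- sum(reach)
    s <- sum(d[i, reach])
    if (r <= 1 || s == 0) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / s)
  }, numeric(1)), rownames(a))
}

# exhaustive one-step SSE split search
oracle_stepminer <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- NULL
  for (k in seq_len(n - 1)) {
    lm <- mean(v[1:k])
    rm <- mean(v[(k + 1):n])
    sse <- sum((v[1:k] - lm)^2) + sum((v[(k + 1):n] - rm)^2)
    cand <- list(k = k, t = (lm + rm) / 2, sse = sse, bal = abs(k - n / 2))
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && cand$bal < best$bal)) {
      best <- cand
    }
  }
  best
}
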