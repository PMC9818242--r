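# Discrete Bayesian belief networks: chain-rule evaluation of the joint
# probability of a full assignment. Structure learning is out of scope; the
# model (DAG + conditional probability tables) is supplied by the user.

#' Construct a discrete Bayesian belief network
#'
#' A BBN is a directed acyclic graph over discrete variables with one
#' conditional probability table (CPT) per node. Each CPT is a data frame
#' with one column per parent, a `state` column, and a `prob` column; the
#' probabilities must sum to 1 (within 1e-9) for every parent configuration.
#'
#' @param nodes Named list; each element is a list with `parents` (character
#'   vector, possibly empty) and `cpt` (data frame as above).
#' @return An object of class `discrete_bbn` with nodes stored in
#'   topological order.
#' @examples
#' b <- discrete_bbn(list(
#'   B = list(parents = character(), cpt = data.frame(state = c(1, 0), prob = c(0.6, 0.4))),
#'   A = list(parents = "B", cpt = data.frame(
#'     B = c(1, 1, 0, 0), state = c(1, 0, 1, 0), prob = c(0.7, 0.3, 0.2, 0.8)
#'   ))
#' ))
#' bbn_joint_probability(b, c(A = 1, B = 1))
#' @export
discrete_bbn <- function(nodes) {
  if (!length(nodes) || is.null(names(nodes)) || any(names(nodes) == "")) {
    abort("`nodes` must be a non-empty named list", class = "plbin_model_error")
  }
  check_unique_ids(names(nodes), "node")
  nodes <- purrr::imap(nodes, function(nd, nm) {
    parents <- as.character(nd$parents %||% character())
    cpt <- as_tibble(nd$cpt)
    needed <- c(parents, "state", "prob")
    if (!all(needed %in% names(cpt))) {
      abort(sprintf("CPT of node %s must have columns: %s", nm,
                    paste(needed, collapse = ", ")),
            class = "plbin_model_error")
    }
    sums <- cpt %>%
      group_by(across(dplyr::all_of(parents))) %>%
      summarise(s = sum(.data$prob), .groups = "drop")
    if (any(abs(sums$s - 1) > 1e-9)) {
      abort(sprintf("CPT rows of node %s do not sum to 1", nm),
            class = "plbin_model_error")
    }
    list(name = nm, parents = parents, cpt = cpt)
  })
  unknown <- setdiff(unique(unlist(lapply(nodes, `[[`, "parents"))), names(nodes))
  if (length(unknown)) {
    abort(sprintf("unknown parent node(s): %s", paste(unknown, collapse = ", ")),
          class = "plbin_model_error")
  }
  # topological order (Kahn); failure means a cycle
  remaining <- names(nodes)
  ordered <- character()
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(nm) {
      all(nodes[[nm]]$parents %in% ordered)
    }, logical(1))]
    if (!length(free)) {
      abort("graph is not acyclic", class = "plbin_model_error")
    }
    ordered <- c(ordered, free)
    remaining <- setdiff(remaining, free)
  }
  structure(list(nodes = nodes[ordered]), class = "discrete_bbn")
}

#' @export
print.discrete_bbn <- function(x, ...) {
  cat("Discrete BBN with", length(x$nodes), "nodes:\n")
  for (nd in x$nodes) {
    cat(sprintf("  %s | parents: %s\n", nd$name,
                if (length(nd$parents)) paste(nd$parents, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Joint probability of a full assignment under a discrete BBN
#'
#' Chain-rule product of the per-node conditional probabilities:
#' `P(X_1, ..., X_n) = prod_i P(X_i | parents(X_i))`.
#'
#' @param b A `discrete_bbn`.
#' @param assignment Named vector or list giving one state per node.
#' @return Probability in `[0, 1]`.
#' @export
bbn_joint_probability <- function(b, assignment) {
  stopifnot(inherits(b, "discrete_bbn"))
  assignment <- unlist(assignment)
  missing_nodes <- setdiff(names(b$nodes), names(assignment))
  if (length(missing_nodes)) {
    abort(sprintf("assignment missing node(s): %s",
                  paste(missing_nodes, collapse = ", ")),
          class = "plbin_model_error")
  }
  prob <- 1
  for (nd in b$nodes) {
    cpt <- nd$cpt
    hit <- cpt$state == assignment[[nd$name]]
    for (p in nd$parents) hit <- hit & (cpt[[p]] == assignment[[p]])
    row <- which(hit)
    if (length(row) != 1) {
      abort(sprintf("no CPT entry for node %s under the given assignment", nd$name),
            class = "plbin_model_error")
    }
    prob <- prob * cpt$prob[row]
  }
  prob
}

#' Enumerate the state space of a discrete BBN
#'
#' @param b A `discrete_bbn`.
#' @return Tibble with one column per node, one row per joint assignment.
#' @export
bbn_state_space <- function(b) {
  stopifnot(inherits(b, "discrete_bbn"))
  states <- lapply(b$nodes, function(nd) sort(unique(nd$cpt$state)))
  names(states) <- names(b$nodes)
  as_tibble(expand.grid(states, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE))
}

#' Read a discrete BBN from a YAML config
#'
#' The config holds a `nodes` list; each entry has `name`, optional
#' `parents`, and `cpt` rows (each a mapping of parent states, `state`, and
#' `prob`).
#'
#' @param path Path to the YAML file.
#' @return A `discrete_bbn`.
#' @export
read_bbn <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nodes)) {
    abort("config must contain a `nodes` list", class = "plbin_model_error")
  }
  nodes <- list()
  for (nd in cfg$nodes) {
    if (is.null(nd$name)) abort("every node needs a `name`", class = "plbin_model_error")
    cpt <- dplyr::bind_rows(lapply(nd$cpt, as_tibble))
    nodes[[nd$name]] <- list(parents = nd$parents %||% character(), cpt = cpt)
  }
  discrete_bbn(nodes)
}
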