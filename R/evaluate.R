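# Gene-set-based validation of inferred networks: TP/FP/ND edge labeling,
# network precision, and permutation FDR / significance.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> gene ids);
#'   duplicates within a set are dropped, empty sets are invalid.
#' @param name Collection name.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, name = "collection") {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a non-empty named list", class = "plbin_input_error")
  }
  check_unique_ids(names(sets), "set")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) {
    abort("sets must be non-empty", class = "plbin_input_error")
  }
  structure(list(name = name, sets = sets,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets, %d annotated genes\n",
              x$name, length(x$sets), length(x$universe)))
  invisible(x)
}

as_collection_list <- function(collections) {
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  if (!length(collections) ||
      !all(vapply(collections, inherits, logical(1), "gene_set_collection"))) {
    abort("`collections` must be one or more gene_set_collection objects",
          class = "plbin_input_error")
  }
  collections
}

#' Label network edges against gene-set collections
#'
#' A gene pair is a true positive (TP) when both genes co-occur in at least
#' one set of any collection, non-discriminatory (ND) when either gene is
#' absent from the annotated universe (the union of all collections), and a
#' false positive (FP) otherwise (both annotated, never together).
#'
#' @param edges Edge table (tibble/data frame, first two columns source and
#'   target) or a `plbin_network`.
#' @param collections One or a list of [gene_set_collection()] objects.
#' @return The edge tibble with a `label` column in `c("TP", "FP", "ND")`.
#' @export
label_edges <- function(edges, collections) {
  if (inherits(edges, "plbin_network")) edges <- tidy(edges)
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("`edges` must have >= 2 columns", class = "plbin_input_error")
  }
  collections <- as_collection_list(collections)
  edges <- as_tibble(edges)
  src <- as.character(edges[[1]])
  tgt <- as.character(edges[[2]])
  universe <- unique(unlist(lapply(collections, `[[`, "universe")))
  # gene -> indices of sets containing it, over the pooled set list
  all_sets <- unlist(lapply(collections, `[[`, "sets"), recursive = FALSE)
  gene2set <- new.env(parent = emptyenv())
  for (i in seq_along(all_sets)) {
    for (gene in all_sets[[i]]) {
      assign(gene, c(gene2set[[gene]], i), envir = gene2set)
    }
  }
  share_set <- function(a, b) {
    sa <- gene2set[[a]]
    if (is.null(sa)) return(FALSE)
    sb <- gene2set[[b]]
    if (is.null(sb)) return(FALSE)
    length(intersect(sa, sb)) > 0
  }
  label <- vapply(seq_along(src), function(i) {
    if (!(src[i] %in% universe) || !(tgt[i] %in% universe)) return("ND")
    if (share_set(src[i], tgt[i])) "TP" else "FP"
  }, character(1))
  mutate(edges, label = label)
}

#' Network precision from edge labels
#'
#' Precision is `TP / (TP + FP)`; non-discriminatory edges are not
#' confirmatory and are excluded from the ratio.
#'
#' @param labels Character vector of edge labels (`"TP"`, `"FP"`, `"ND"`),
#'   or a labeled edge tibble from [label_edges()].
#' @return One-row tibble: `tp`, `fp`, `nd`, `precision` (`NA` when no
#'   confirmatory edges exist).
#' @examples
#' network_precision(c("TP", "FP", "ND", "ND"))
#' @export
network_precision <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  bad <- setdiff(unique(labels), c("TP", "FP", "ND"))
  if (length(bad)) {
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
          class = "plbin_input_error")
  }
  tp <- sum(labels == "TP")
  fp <- sum(labels == "FP")
  nd <- sum(labels == "ND")
  tibble(tp = tp, fp = fp, nd = nd,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Permutation FDR and significance of network precision
#'
#' Derives a network from the expression table and its class labels, then
#' re-derives it under `n_perm` seeded permutations of the class labels.
#' The FDR is the average of `FP / (TP + FP)` over permutations that yield
#' at least one confirmatory edge (the others are counted and excluded);
#' the p value is the fraction of permutations whose precision is at least
#' the observed precision.
#'
#' @param expr Gene-by-sample tibble.
#' @param class_labels Vector of per-sample class labels (>= 2 classes).
#' @param derive_fn Function `(expr, class_labels) -> edge table` (first
#'   two columns source/target); must be deterministic given its inputs.
#' @param collections One or a list of [gene_set_collection()] objects.
#' @param n_perm Number of label permutations. Default 1000.
#' @param seed Integer seed.
#' @return List of class `plbin_fdr_report`: `observed_precision`,
#'   `null_precisions`, `fdr`, `p_value`, `n_perm`,
#'   `n_undefined_permutations`, `seed`.
#' @export
permutation_fdr <- function(expr, class_labels, derive_fn, collections,
                            n_perm = 1000, seed = 1L) {
  expr <- check_gene_tbl(expr, "expr")
  if (length(class_labels) != ncol(expr) - 1) {
    abort("`class_labels` must have one label per sample", class = "plbin_input_error")
  }
  if (length(unique(class_labels)) < 2) {
    abort("need >= 2 classes", class = "plbin_input_error")
  }
  collections <- as_collection_list(collections)
  prec_of <- function(labels_vec) {
    edges <- derive_fn(expr, labels_vec)
    if (is.null(edges) || !nrow(edges)) {
      return(c(prec = NA_real_, fp_rate = NA_real_))
    }
    rep_ <- network_precision(label_edges(edges, collections))
    if (rep_$tp + rep_$fp == 0) return(c(prec = NA_real_, fp_rate = NA_real_))
    c(prec = rep_$precision, fp_rate = rep_$fp / (rep_$tp + rep_$fp))
  }
  obs <- prec_of(class_labels)
  null_prec <- numeric(0)
  null_fp <- numeric(0)
  if (n_perm > 0) {
    perms <- local_seed(seed, {
      lapply(seq_len(n_perm), function(i) sample(class_labels))
    })
    res <- purrr::imap(perms, function(p, i) {
      tryCatch(prec_of(p), error = function(e) {
        abort(sprintf("derivation failed in permutation %d: %s", i,
                      conditionMessage(e)),
              class = "plbin_permutation_error")
      })
    })
    null_prec <- vapply(res, `[[`, numeric(1), "prec")
    null_fp <- vapply(res, `[[`, numeric(1), "fp_rate")
  }
  defined <- !is.na(null_fp)
  fdr <- if (any(defined)) mean(null_fp[defined]) else NA_real_
  p_value <- if (n_perm > 0) {
    null_cmp <- ifelse(is.na(null_prec), -Inf, null_prec)
    obs_cmp <- if (is.na(obs[["prec"]])) -Inf else obs[["prec"]]
    mean(null_cmp >= obs_cmp)
  } else NA_real_
  structure(list(observed_precision = obs[["prec"]],
                 null_precisions = null_prec,
                 fdr = fdr, p_value = p_value, n_perm = n_perm,
                 n_undefined_permutations = sum(!defined),
                 seed = seed),
            class = "plbin_fdr_report")
}

#' @export
print.plbin_fdr_report <- function(x, ...) {
  cat(sprintf("Permutation FDR report (%d permutations, seed %d)\n",
              x$n_perm, x$seed))
  cat(sprintf("  observed precision %.4g, FDR %.4g, p = %.4g (%d undefined permutation(s))\n",
              x$observed_precision, x$fdr, x$p_value,
              x$n_undefined_permutations))
  invisible(x)
}

#' @export
glance.plbin_fdr_report <- function(x, ...) {
  tibble(observed_precision = x$observed_precision, fdr = x$fdr,
         p_value = x$p_value, n_perm = x$n_perm,
         n_undefined_permutations = x$n_undefined_permutations,
         seed = x$seed)
}
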