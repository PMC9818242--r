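# Gene-by-sample tables.
#
# Throughout the package a "gene table" is a wide tibble whose first column
# holds unique gene identifiers and whose remaining columns are samples
# (genes x samples, log-scale values for expression). Missing measurements
# are NA. These helpers convert between that tabular form and the numeric
# matrix used internally.

#' Build a gene-by-sample tibble
#'
#' Constructs the wide tabular form used by every function in the package:
#' one row per gene, first column `gene_id`, one numeric column per sample.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (row names of
#'   `values` when omitted).
#' @param sample_ids Character vector of unique sample identifiers (column
#'   names of `values` when omitted).
#' @return A tibble with `length(gene_ids)` rows and `1 + length(sample_ids)`
#'   columns.
#' @examples
#' gene_tbl(matrix(rnorm(6), 2, 3), c("g1", "g2"), c("s1", "s2", "s3"))
#' @export
gene_tbl <- function(values, gene_ids = rownames(values),
                     sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    abort("id lengths must match matrix dimensions", class = "plbin_input_error")
  }
  check_unique_ids(gene_ids, "gene")
  check_unique_ids(sample_ids, "sample")
  out <- as_tibble(values, .name_repair = "minimal")
  names(out) <- sample_ids
  dplyr::bind_cols(tibble(gene_id = as.character(gene_ids)), out)
}

#' Convert a gene table to a numeric matrix
#'
#' @param tbl A gene-by-sample tibble (first column gene ids).
#' @return Numeric matrix with gene ids as row names.
#' @export
gene_matrix <- function(tbl) {
  tbl <- check_gene_tbl(tbl)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tbl[[1]]
  m
}

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate %s ids: %s", what,
                  paste(head(dups, 5), collapse = ", ")),
          class = "plbin_id_error")
  }
  invisible(ids)
}

check_gene_tbl <- function(tbl, arg = "tbl") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort(sprintf("`%s` must be a data frame with a gene-id column and >= 1 sample column", arg),
          class = "plbin_input_error")
  }
  tbl <- as_tibble(tbl)
  tbl[[1]] <- as.character(tbl[[1]])
  check_unique_ids(tbl[[1]], "gene")
  check_unique_ids(names(tbl)[-1], "sample")
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  mode(vals) <- "numeric"
  if (any(!is.finite(vals) & !is.na(vals))) {
    abort("non-missing values must be finite", class = "plbin_input_error")
  }
  tbl
}

# Tag a categorized gene table with its state arity and a provenance string.
new_categorized_tbl <- function(tbl, arity, provenance) {
  stopifnot(arity %in% c(2L, 3L))
  attr(tbl, "arity") <- as.integer(arity)
  attr(tbl, "provenance") <- provenance
  class(tbl) <- unique(c("plbin_categorized", class(tbl)))
  tbl
}

#' State arity of a categorized gene table
#'
#' Returns 2 for binary (0/1) and 3 for ternary (-1/0/+1) tables. Falls back
#' to inspecting the values when the table does not carry an arity attribute
#' (e.g. after reading from disk).
#'
#' @param tbl A categorized gene table.
#' @return Integer, 2 or 3.
#' @export
state_arity <- function(tbl) {
  a <- attr(tbl, "arity")
  if (!is.null(a)) return(as.integer(a))
  vals <- gene_matrix(tbl)
  if (any(vals < 0, na.rm = TRUE)) 3L else if (all(vals %in% c(0, 1, NA))) 2L else 3L
}

check_categorized <- function(tbl, arg = "tbl") {
  tbl2 <- check_gene_tbl(tbl, arg)
  arity <- state_arity(tbl)
  states <- if (arity == 2L) c(0, 1) else c(-1, 0, 1)
  vals <- gene_matrix(tbl2)
  bad <- !is.na(vals) & !(vals %in% states)
  if (any(bad)) {
    abort(sprintf("`%s` contains states outside {%s}", arg,
                  paste(states, collapse = ", ")),
          class = "plbin_input_error")
  }
  new_categorized_tbl(tbl2, arity, attr(tbl, "provenance") %||% "unknown")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
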