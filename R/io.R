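# Readers and writers for the plain-text formats the toolkit touches:
# gene-by-sample TSV/CSV matrices, MatrixMarket triplets with feature and
# barcode files, GMT gene-set collections, and the edge-list TSV schema.

network_schema <- c("source", "target", "rule", "scope", "precision", "z", "n")
known_rules <- c(template_order,
                 "pcc", "mi", "sahoo", "A-high=>B-high", "A-high=>B-low",
                 "A-low=>B-high", "A-low=>B-low", "equivalent", "opposite")

#' Read a gene-by-sample table from TSV/CSV
#'
#' First column gene ids, header row of sample ids; empty cells or `"NA"`
#' are missing. Duplicate gene ids, ragged rows, and non-numeric cells are
#' errors.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A gene-by-sample tibble (see [gene_tbl()]).
#' @export
read_expression_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "plbin_io_error")
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  tbl <- tryCatch(
    suppressWarnings(
      reader(path, show_col_types = FALSE, na = c("", "NA"),
             col_types = readr::cols(.default = readr::col_character()))
    ),
    error = function(e) abort(sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e)),
                              class = "plbin_io_error")
  )
  prob <- readr::problems(tbl)
  if (nrow(prob)) {
    abort(sprintf("ragged or malformed rows in %s (first at line %d)",
                  path, prob$row[1] + 1L),
          class = "plbin_io_error")
  }
  if (ncol(tbl) < 2) abort("need a gene-id column plus >= 1 sample column",
                           class = "plbin_io_error")
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell at row %d, column %s",
                  idx[1], names(tbl)[idx[2] + 1]),
          class = "plbin_io_error")
  }
  gene_tbl(num, tbl[[1]], names(tbl)[-1])
}

#' Write a gene-by-sample table to TSV/CSV
#'
#' @param tbl Gene-by-sample tibble (categorized tables keep their integer
#'   states).
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tbl, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  tbl <- check_gene_tbl(tbl)
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(tbl, path, na = "NA")
  invisible(path)
}

#' Read single-cell counts from a MatrixMarket triplet
#'
#' Coordinate-format matrix with features (genes) as rows and cells as
#' columns, plus one-id-per-line feature and barcode files whose lengths
#' must match the declared dimensions.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to the feature (gene) id file.
#' @param barcodes_path Path to the cell barcode file.
#' @return A gene-by-cell tibble of counts.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) abort(sprintf("cannot read %s: %s",
                                                  matrix_path,
                                                  conditionMessage(e)),
                                          class = "plbin_io_error"))
  features <- readLines(features_path)
  barcodes <- readLines(barcodes_path)
  features <- features[nzchar(features)]
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(features) != nrow(m)) {
    abort(sprintf("feature count (%d) does not match matrix rows (%d)",
                  length(features), nrow(m)),
          class = "plbin_dimension_error")
  }
  if (length(barcodes) != ncol(m)) {
    abort(sprintf("barcode count (%d) does not match matrix columns (%d)",
                  length(barcodes), ncol(m)),
          class = "plbin_dimension_error")
  }
  dense <- as.matrix(m)
  if (any(dense < 0)) {
    abort("negative entries in count matrix", class = "plbin_io_error")
  }
  gene_tbl(dense, features, barcodes)
}

#' Read a gene-set collection from a GMT file
#'
#' Tab-separated lines: set name, description (ignored), then gene ids.
#' Duplicate genes within a set are deduplicated.
#'
#' @param path File path.
#' @param name Collection name; defaults to the file name.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
            class = "plbin_io_error")
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets, name = name %||% basename(path))
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a network edge list to TSV
#'
#' Schema `source target rule scope precision z n`, rows sorted by
#' (source, target, rule), floats printed with 6 significant digits.
#'
#' @param net A `plbin_network` or an edge tibble in the same schema.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  edges <- if (inherits(net, "plbin_network")) tidy(net) else as_tibble(net)
  if (!all(network_schema %in% names(edges))) {
    abort(sprintf("edge table must have columns: %s",
                  paste(network_schema, collapse = ", ")),
          class = "plbin_io_error")
  }
  edges <- edges[, network_schema] %>%
    arrange(.data$source, .data$target, .data$rule) %>%
    mutate(across(c("scope", "precision", "z"),
                  ~ formatC(.x, digits = 6, format = "g")))
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Read a network edge list from TSV
#'
#' @param path File path (schema as written by [write_network()]).
#' @return A `plbin_network` whose parameters are unknown (read from disk).
#' @export
read_network <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           source = readr::col_character(),
                           target = readr::col_character(),
                           rule = readr::col_character(),
                           scope = readr::col_character(),
                           precision = readr::col_character(),
                           z = readr::col_character(),
                           n = readr::col_integer()
                         ))
  if (!all(network_schema %in% names(tbl))) {
    abort(sprintf("network file must have columns: %s",
                  paste(network_schema, collapse = ", ")),
          class = "plbin_io_error")
  }
  bad_rule <- setdiff(unique(tbl$rule), known_rules)
  if (length(bad_rule)) {
    abort(sprintf("unknown rule name(s): %s", paste(bad_rule, collapse = ", ")),
          class = "plbin_schema_error")
  }
  num <- function(v, col) {
    suppressWarnings(x <- as.numeric(v))
    if (any(is.na(x) & !is.na(v))) {
      abort(sprintf("malformed float in column %s", col),
            class = "plbin_schema_error")
    }
    x
  }
  edges <- tibble(source = tbl$source, target = tbl$target, rule = tbl$rule,
                  scope = num(tbl$scope, "scope"),
                  precision = num(tbl$precision, "precision"),
                  z = num(tbl$z, "z"), n = tbl$n) %>%
    arrange(.data$source, .data$target, .data$rule)
  nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(edges = edges,
                 nodes = tibble(gene_id = nodes,
                                single_state = rep(FALSE, length(nodes))),
                 params = list(source = path), n_skipped = 0L),
            class = "plbin_network")
}
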