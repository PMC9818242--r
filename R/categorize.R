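# Categorization of raw multi-omics measurements into the discrete states the
# implication-network machinery consumes.

#' Fit a housekeeping-calibrated normal-range model
#'
#' Defines the up-regulation / normal / down-regulation ranges of log-scale
#' expression from a panel of housekeeping genes. The total mass outside the
#' normal range is fixed (default 30%, split symmetrically) for the
#' housekeeping panel: each housekeeping gene contributes quantile cutoffs at
#' `target_outside/2` and `1 - target_outside/2`, the sample standard
#' deviation of the values strictly inside those cutoffs is its normal-range
#' SD, and the average of these SDs (`sigma_bar`) is the width unit applied
#' to every other gene. A half-width multiplier is then calibrated by
#' bisection so that re-categorizing the housekeeping genes under the fitted
#' model reproduces the target outside fraction (within 0.5 percentage
#' points when the data's granularity allows).
#'
#' @param expr Gene-by-sample tibble of log-scale expression
#'   (see [gene_tbl()]).
#' @param hk_ids Character vector of housekeeping gene ids, all present in
#'   `expr`, each with at least 4 non-missing values.
#' @param target_outside Target total fraction of up- plus down-regulated
#'   samples for the housekeeping panel, in (0, 1). Default 0.30.
#' @param center_statistic Per-gene center of the normal range, `"median"`
#'   (default, translation-equivariant) or `"mean"`.
#' @param quantile_type Quantile algorithm: `"linear"` (interpolating,
#'   [stats::quantile()] type 7, default) or `"nearest"` (type 1).
#' @return An object of class `normal_range_model`: a list with
#'   `per_hk_cutoffs` (tibble: `gene_id`, `lower`, `upper`, `normal_sd`),
#'   `sigma_bar`, `width_multiplier`, `target_outside`, `center_statistic`,
#'   and the achieved housekeeping outside fraction.
#' @examples
#' sim <- sim_expression_with_housekeeping(100, 40, n_hk = 10, seed = 1)
#' fit_normal_range_model(sim$expr, sim$hk_ids)
#' @export
fit_normal_range_model <- function(expr, hk_ids, target_outside = 0.30,
                                   center_statistic = c("median", "mean"),
                                   quantile_type = c("linear", "nearest")) {
  expr <- check_gene_tbl(expr, "expr")
  center_statistic <- match.arg(center_statistic)
  quantile_type <- match.arg(quantile_type)
  if (!is.numeric(target_outside) || target_outside <= 0 || target_outside >= 1) {
    abort("`target_outside` must lie in (0, 1)", class = "plbin_input_error")
  }
  hk_ids <- as.character(hk_ids)
  missing_ids <- setdiff(hk_ids, expr[[1]])
  if (length(missing_ids)) {
    abort(sprintf("housekeeping id(s) absent from `expr`: %s",
                  paste(head(missing_ids, 5), collapse = ", ")),
          class = "plbin_id_error")
  }
  qtype <- if (quantile_type == "linear") 7L else 1L
  mat <- gene_matrix(expr)[hk_ids, , drop = FALSE]

  per_gene <- purrr::map(hk_ids, function(g) {
    v <- mat[g, ]
    v <- v[!is.na(v)]
    if (length(v) < 4) {
      abort(sprintf("housekeeping gene %s has fewer than 4 non-missing values", g),
            class = "plbin_input_error")
    }
    lo <- unname(quantile(v, target_outside / 2, type = qtype))
    hi <- unname(quantile(v, 1 - target_outside / 2, type = qtype))
    inside <- v[v > lo & v < hi]
    nsd <- if (length(inside) >= 2) sd(inside) else 0
    if (nsd == 0) {
      warn(sprintf("housekeeping gene %s has zero normal-range SD", g))
    }
    tibble(gene_id = g, lower = lo, upper = hi, normal_sd = nsd)
  })
  per_hk_cutoffs <- dplyr::bind_rows(per_gene)
  sigma_bar <- mean(per_hk_cutoffs$normal_sd)
  if (sigma_bar == 0) {
    abort("all housekeeping genes are (near-)constant: sigma_bar is 0",
          class = "plbin_degenerate_model")
  }

  center_fun <- if (center_statistic == "median") {
    function(v) median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  centers <- apply(mat, 1, center_fun)

  # mean outside fraction over the housekeeping panel for half-width m*sigma_bar
  outside_frac <- function(m) {
    w <- m * sigma_bar
    fr <- vapply(seq_len(nrow(mat)), function(i) {
      v <- mat[i, ]
      v <- v[!is.na(v)]
      mean(abs(v - centers[i]) > w)
    }, numeric(1))
    mean(fr)
  }

  # outside_frac is non-increasing in m; bisect to the target
  lo_m <- 0
  hi_m <- 1
  while (outside_frac(hi_m) > target_outside && hi_m < 1e6) hi_m <- hi_m * 2
  for (i in 1:60) {
    mid <- (lo_m + hi_m) / 2
    if (outside_frac(mid) > target_outside) lo_m <- mid else hi_m <- mid
  }
  cand <- c(lo_m, hi_m, (lo_m + hi_m) / 2)
  achieved <- vapply(cand, outside_frac, numeric(1))
  best <- which.min(abs(achieved - target_outside))
  width_multiplier <- cand[best]
  if (abs(achieved[best] - target_outside) > 0.005) {
    warn(sprintf(paste0("calibrated outside fraction %.4f misses the target %.2f by ",
                        "more than 0.005 (data granularity)"),
                 achieved[best], target_outside))
  }

  structure(
    list(per_hk_cutoffs = per_hk_cutoffs,
         sigma_bar = sigma_bar,
         width_multiplier = width_multiplier,
         target_outside = target_outside,
         achieved_outside = achieved[best],
         center_statistic = center_statistic,
         quantile_type = quantile_type,
         hk_gene_ids = hk_ids),
    class = "normal_range_model"
  )
}

#' @export
print.normal_range_model <- function(x, ...) {
  cat("Normal-range model calibrated on", length(x$hk_gene_ids),
      "housekeeping genes\n")
  cat(sprintf("  sigma_bar: %.4f   width multiplier: %.4f\n",
              x$sigma_bar, x$width_multiplier))
  cat(sprintf("  target outside fraction: %.2f   achieved: %.4f\n",
              x$target_outside, x$achieved_outside))
  cat("  center statistic:", x$center_statistic, "\n")
  invisible(x)
}

#' Categorize expression into down / normal / up states
#'
#' Applies a fitted [fit_normal_range_model()] to every gene: values more
#' than `width_multiplier * sigma_bar` above the gene's center are up (+1),
#' more than that below are down (-1), everything else (boundaries included)
#' is normal (0). Missing values stay missing.
#'
#' @param expr Gene-by-sample tibble of log-scale expression.
#' @param model A `normal_range_model`.
#' @return A categorized gene table (states -1/0/+1, arity 3).
#' @examples
#' sim <- sim_expression_with_housekeeping(50, 30, n_hk = 10, seed = 1)
#' m <- fit_normal_range_model(sim$expr, sim$hk_ids)
#' categorize_expression(sim$expr, m)
#' @export
categorize_expression <- function(expr, model) {
  expr <- check_gene_tbl(expr, "expr")
  if (!inherits(model, "normal_range_model")) {
    abort("`model` must be a normal_range_model", class = "plbin_input_error")
  }
  if (model$sigma_bar <= 0) {
    abort("degenerate model: sigma_bar is 0", class = "plbin_degenerate_model")
  }
  mat <- gene_matrix(expr)
  center_fun <- if (model$center_statistic == "median") {
    function(v) median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  centers <- apply(mat, 1, center_fun)
  w <- model$width_multiplier * model$sigma_bar
  states <- matrix(0L, nrow(mat), ncol(mat))
  states[mat > centers + w] <- 1L
  states[mat < centers - w] <- -1L
  states[is.na(mat)] <- NA_integer_
  out <- gene_tbl(states, expr[[1]], names(expr)[-1])
  new_categorized_tbl(out, 3L,
                      sprintf("normal-range model: center=%s, half-width=%.4f",
                              model$center_statistic, w))
}

#' Categorize integer copy numbers
#'
#' Maps copy-number states to deletion (-1) for CN < 2, normal (0) for
#' CN = 2, and duplication/amplification (+1) for CN > 2. Values must be
#' non-negative integers; real-valued CN estimates require an explicit
#' `tolerance`, under which a value is normal iff `|CN - 2| <= tolerance`.
#'
#' @param cn Gene-by-sample tibble of copy numbers.
#' @param tolerance Optional non-negative tolerance enabling non-integer
#'   input.
#' @return A categorized gene table (arity 3).
#' @examples
#' categorize_cnv(gene_tbl(matrix(c(1, 2, 3, 0), 2, 2)))
#' @export
categorize_cnv <- function(cn, tolerance = NULL) {
  cn <- check_gene_tbl(cn, "cn")
  mat <- gene_matrix(cn)
  if (any(mat < 0, na.rm = TRUE)) {
    abort("copy numbers must be non-negative", class = "plbin_input_error")
  }
  non_integer <- any(mat != round(mat), na.rm = TRUE)
  if (non_integer && is.null(tolerance)) {
    abort(paste0("non-integer copy numbers found: pass an explicit `tolerance` ",
                 "(normal iff |CN - 2| <= tolerance)"),
          class = "plbin_input_error")
  }
  tol <- if (is.null(tolerance)) 0 else tolerance
  if (tol < 0) abort("`tolerance` must be >= 0", class = "plbin_input_error")
  states <- matrix(0L, nrow(mat), ncol(mat))
  states[mat < 2 - tol] <- -1L
  states[mat > 2 + tol] <- 1L
  states[is.na(mat)] <- NA_integer_
  out <- gene_tbl(states, cn[[1]], names(cn)[-1])
  new_categorized_tbl(out, 3L,
                      sprintf("CNV rule: CN<2 deletion, CN>2 duplication (tolerance %.3g)", tol))
}

#' Binarize single-cell feature counts
#'
#' A gene is "expressed" (1) in a cell iff its feature count is greater than
#' 0, and "not expressed" (0) otherwise; the severe dropout in single-cell
#' data makes finer categorization unreliable.
#'
#' @param counts Gene-by-cell tibble of non-negative feature counts.
#' @return A categorized gene table (states 0/1, arity 2).
#' @examples
#' binarize_single_cell(gene_tbl(matrix(c(0, 5, 2, 0), 2, 2)))
#' @export
binarize_single_cell <- function(counts) {
  counts <- check_gene_tbl(counts, "counts")
  mat <- gene_matrix(counts)
  if (any(mat < 0, na.rm = TRUE)) {
    abort("feature counts must be >= 0", class = "plbin_input_error")
  }
  states <- matrix(0L, nrow(mat), ncol(mat))
  states[mat > 0] <- 1L
  states[is.na(mat)] <- NA_integer_
  out <- gene_tbl(states, counts[[1]], names(counts)[-1])
  new_categorized_tbl(out, 2L, "single-cell binarization: expressed iff count > 0")
}

#' Categorize drug-sensitivity measurements
#'
#' IC50/EC50 values above the maximum tested dose are resistant and values
#' below the minimum dose are sensitive. The remaining in-range values are
#' split at their mean plus/minus 0.5 sample standard deviations: below the
#' band is sensitive, above is resistant, inside (boundaries included) is a
#' partial response.
#'
#' @param values Numeric vector of IC50 or EC50 measurements.
#' @param min_dose,max_dose Dose range tested, `min_dose < max_dose`.
#' @param log10_scale Compute the mean/SD band on log10-transformed values
#'   (the dose rule is applied on the original scale). Default `FALSE`.
#' @return Character vector of labels in
#'   `c("sensitive", "partial", "resistant")`.
#' @examples
#' categorize_drug_response(c(0.001, 1, 3, 5, 15), min_dose = 0.01, max_dose = 10)
#' @export
categorize_drug_response <- function(values, min_dose, max_dose,
                                     log10_scale = FALSE) {
  if (!length(values)) abort("empty input", class = "plbin_input_error")
  if (!is.numeric(values)) abort("`values` must be numeric", class = "plbin_input_error")
  if (min_dose >= max_dose) {
    abort("`min_dose` must be < `max_dose`", class = "plbin_input_error")
  }
  labels <- rep(NA_character_, length(values))
  labels[values > max_dose] <- "resistant"
  labels[values < min_dose] <- "sensitive"
  in_range <- is.na(labels) & !is.na(values)
  v <- values[in_range]
  if (length(v) >= 2) {
    vv <- if (log10_scale) log10(v) else v
    m <- mean(vv)
    s <- sd(vv)
    lab <- rep("partial", length(vv))
    lab[vv < m - 0.5 * s] <- "sensitive"
    lab[vv > m + 0.5 * s] <- "resistant"
    labels[in_range] <- lab
  } else if (length(v)) {
    labels[in_range] <- "partial"
  }
  labels
}

#' Flag significant proliferation effects from dependency scores
#'
#' Normalized CRISPR/RNAi dependency scores are scaled so non-essential
#' genes have median 0 and essential genes median -1; a score strictly below
#' -0.5 marks a significant effect on proliferation.
#'
#' @param dependency_scores Numeric vector of normalized dependency scores.
#' @return Character vector in `c("significant", "not_significant")`.
#' @examples
#' flag_proliferation_effect(c(-0.7, -0.5, 0.2))
#' @export
flag_proliferation_effect <- function(dependency_scores) {
  if (!is.numeric(dependency_scores)) {
    abort("`dependency_scores` must be numeric", class = "plbin_input_error")
  }
  ifelse(dependency_scores < -0.5, "significant", "not_significant")
}
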