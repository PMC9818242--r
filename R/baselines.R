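# Printed baseline methods: correlation relevance networks, Shannon entropy
# and mutual information, and StepMiner-style Boolean implications with the
# quadrant sparsity test.

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return The correlation in `[-1, 1]`.
#' @examples
#' pearson_cc(c(1, 2, 3), c(2, 4, 6))
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2", class = "plbin_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: zero variance", class = "plbin_undefined_stat")
  }
  cor(x, y)
}

#' Threshold relevance network from pairwise correlations
#'
#' Connects two genes by an undirected edge when their (absolute, by
#' default) Pearson correlation reaches the threshold. Genes with zero
#' variance are skipped with a warning.
#'
#' @param expr Gene-by-sample tibble.
#' @param threshold Correlation threshold in (0, 1].
#' @param use_absolute Threshold `|r|` (default) rather than signed `r`.
#' @return Tibble of undirected edges: `source`, `target`, `r` (source <
#'   target lexicographically).
#' @examples
#' sim <- sim_expression_with_housekeeping(10, 30, n_hk = 2, seed = 1)
#' pcc_network(sim$expr, threshold = 0.8)
#' @export
pcc_network <- function(expr, threshold, use_absolute = TRUE) {
  expr <- check_gene_tbl(expr, "expr")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1]", class = "plbin_input_error")
  }
  mat <- gene_matrix(expr)
  sds <- apply(mat, 1, sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 0
  if (any(!keep)) {
    warn(sprintf("skipping %d zero-variance gene(s)", sum(!keep)))
  }
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2) {
    return(tibble(source = character(), target = character(), r = double()))
  }
  cm <- suppressWarnings(cor(t(mat), use = "pairwise.complete.obs"))
  score <- if (use_absolute) abs(cm) else cm
  idx <- which(upper.tri(cm) & score >= threshold, arr.ind = TRUE)
  ids <- rownames(mat)
  tibble(source = pmin(ids[idx[, 1]], ids[idx[, 2]]),
         target = pmax(ids[idx[, 1]], ids[idx[, 2]]),
         r = cm[idx]) %>%
    arrange(.data$source, .data$target)
}

#' Shannon entropy of a discrete vector (bits)
#'
#' Plug-in estimate over observed state frequencies, with `0 * log(0) = 0`.
#'
#' @param states Non-empty discrete vector (`NA`s dropped).
#' @return Entropy in bits.
#' @examples
#' categorical_entropy(c(0, 0, 1, 1))
#' @export
categorical_entropy <- function(states) {
  states <- states[!is.na(states)]
  if (!length(states)) abort("empty input", class = "plbin_input_error")
  p <- as.numeric(table(states)) / length(states)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of two discrete vectors (bits)
#'
#' `MI(X, Y) = H(X) + H(Y) - H(X, Y)` with plug-in joint frequencies
#' (pairwise-complete samples).
#'
#' @param x,y Discrete vectors of equal length.
#' @return Mutual information in bits (non-negative up to rounding).
#' @examples
#' x <- rep(c(0, 1), 5)
#' mutual_information(x, x)
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", class = "plbin_input_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) abort("empty input", class = "plbin_input_error")
  hx <- categorical_entropy(x)
  hy <- categorical_entropy(y)
  hxy <- categorical_entropy(paste(x, y, sep = "\r"))
  max(hx + hy - hxy, 0)
}

#' One-step StepMiner fit of an expression threshold
#'
#' Sorts the values and fits a one-step function: over every split position
#' the left and right means minimize the total squared error; the threshold
#' `t` is the midpoint of the two optimal means and the interval `t +/- 0.5`
#' (log2 scale) is the "intermediate" zone. SSE ties are broken by the most
#' balanced split.
#'
#' @param values Numeric vector, length >= 4, not all equal.
#' @param intermediate_margin Half-width of the intermediate zone. Default
#'   0.5.
#' @return An object of class `step_fit`: list with `threshold`,
#'   `intermediate_margin`, `left_mean`, `right_mean`, `sse`, `split`.
#' @examples
#' stepminer_threshold(c(1, 1, 1, 5, 5, 5))
#' @export
stepminer_threshold <- function(values, intermediate_margin = 0.5) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4) abort("need >= 4 values", class = "plbin_input_error")
  if (diff(range(values)) == 0) {
    abort("constant input: no step exists", class = "plbin_no_step")
  }
  v <- sort(values)
  cs <- cumsum(v)
  total <- cs[n]
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1)
  left_mean <- cs[k] / k
  right_mean <- (total - cs[k]) / (n - k)
  sse <- (cs2[k] - cs[k]^2 / k) +
    ((cs2[n] - cs2[k]) - (total - cs[k])^2 / (n - k))
  balance <- abs(k - n / 2)
  ord <- order(sse, balance, k)
  kb <- ord[1]
  structure(
    list(threshold = (left_mean[kb] + right_mean[kb]) / 2,
         intermediate_margin = intermediate_margin,
         left_mean = left_mean[kb],
         right_mean = right_mean[kb],
         sse = max(sse[kb], 0),
         split = kb),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: t = %.4f (means %.4f | %.4f, sse %.4g, split %d)\n",
              x$threshold, x$left_mean, x$right_mean, x$sse, x$split))
  cat(sprintf("intermediate zone: [%.4f, %.4f]\n",
              x$threshold - x$intermediate_margin,
              x$threshold + x$intermediate_margin))
  invisible(x)
}

#' Quadrant counts for a gene pair under StepMiner thresholds
#'
#' Samples with either value inside its gene's intermediate zone
#' (`t +/- margin`, boundaries included) are excluded; the rest are assigned
#' to quadrants by high/low relative to the thresholds. Quadrant I is
#' A-high/B-high, II A-low/B-high, III A-low/B-low, IV A-high/B-low.
#'
#' @param xa,xb Numeric value vectors of equal length for genes A and B.
#' @param fa,fb `step_fit` objects for A and B (see
#'   [stepminer_threshold()]).
#' @return One-row tibble: `a_I`, `a_II`, `a_III`, `a_IV`, `total`.
#' @examples
#' fit <- list(threshold = 2.5, intermediate_margin = 0.5)
#' class(fit) <- "step_fit"
#' quadrant_counts(c(0, 0, 5, 5), c(0, 5, 0, 5), fit, fit)
#' @export
quadrant_counts <- function(xa, xb, fa, fb) {
  if (length(xa) != length(xb)) {
    abort("`xa` and `xb` must have equal length", class = "plbin_input_error")
  }
  stopifnot(inherits(fa, "step_fit"), inherits(fb, "step_fit"))
  in_zone <- function(v, f) {
    !is.na(v) & abs(v - f$threshold) <= f$intermediate_margin
  }
  keep <- !is.na(xa) & !is.na(xb) & !in_zone(xa, fa) & !in_zone(xb, fb)
  if (!any(keep)) abort("all samples excluded", class = "plbin_empty_quadrants")
  a_high <- xa[keep] > fa$threshold
  b_high <- xb[keep] > fb$threshold
  tibble(a_I = sum(a_high & b_high),
         a_II = sum(!a_high & b_high),
         a_III = sum(!a_high & !b_high),
         a_IV = sum(a_high & !b_high),
         total = sum(keep))
}

# margins of each quadrant: the A-side and B-side halves it lies in
quadrant_margins <- function(q, quadrant) {
  switch(quadrant,
         I = c(row = q$a_I + q$a_IV, col = q$a_I + q$a_II),     # A-high, B-high
         II = c(row = q$a_II + q$a_III, col = q$a_I + q$a_II),  # A-low,  B-high
         III = c(row = q$a_II + q$a_III, col = q$a_III + q$a_IV), # A-low, B-low
         IV = c(row = q$a_I + q$a_IV, col = q$a_III + q$a_IV),  # A-high, B-low
         abort("`quadrant` must be one of I, II, III, IV", class = "plbin_input_error"))
}

#' Quadrant sparsity test for Boolean implications
#'
#' Tests whether one quadrant of the (intermediate-excluded) joint
#' distribution is significantly sparse. With `expected` the
#' margins-product expectation of the tested quadrant and `observed` its
#' count: `statistic = (expected - observed) / sqrt(expected)` and
#' `error rate = (observed/row margin + observed/column margin) / 2`. The
#' quadrant is significantly sparse when the statistic exceeds 3.0 and the
#' error rate is below 0.1 (both strict).
#'
#' @param q Quadrant counts (one-row tibble from [quadrant_counts()]).
#' @param quadrant One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return One-row tibble: `quadrant`, `expected`, `observed`, `statistic`,
#'   `error_rate`, `significant`.
#' @examples
#' sahoo_test(tibble::tibble(a_I = 40, a_II = 15, a_III = 40, a_IV = 1, total = 96), "IV")
#' @export
sahoo_test <- function(q, quadrant = c("IV", "I", "II", "III")) {
  quadrant <- match.arg(quadrant)
  counts <- c(I = q$a_I, II = q$a_II, III = q$a_III, IV = q$a_IV)
  total <- q$a_I + q$a_II + q$a_III + q$a_IV
  mg <- quadrant_margins(q, quadrant)
  if (mg["row"] <= 0 || mg["col"] <= 0) {
    abort("tested quadrant has a zero margin", class = "plbin_undefined_stat")
  }
  expected <- mg[["row"]] * mg[["col"]] / total
  if (expected <= 0) abort("expected count is 0", class = "plbin_undefined_stat")
  observed <- counts[[quadrant]]
  statistic <- (expected - observed) / sqrt(expected)
  error_rate <- (observed / mg[["row"]] + observed / mg[["col"]]) / 2
  tibble(quadrant = quadrant, expected = expected, observed = observed,
         statistic = statistic, error_rate = error_rate,
         significant = statistic > 3.0 && error_rate < 0.1)
}

#' Boolean implication relations between two genes (quadrant method)
#'
#' Runs the quadrant sparsity test on all four quadrants; each sparse
#' quadrant yields its asymmetric implication (sparse IV: A high implies B
#' high; sparse I: A high implies B low; sparse II: A low implies B low;
#' sparse III: A low implies B high). Sparse IV and II together give the
#' symmetric "equivalent" relation, sparse I and III give "opposite";
#' symmetric relations replace their constituent pair.
#'
#' @inheritParams quadrant_counts
#' @return Character vector of relations, possibly empty, from
#'   `c("A-high=>B-high", "A-high=>B-low", "A-low=>B-high", "A-low=>B-low",
#'   "equivalent", "opposite")`.
#' @export
sahoo_rules <- function(xa, xb, fa, fb) {
  q <- quadrant_counts(xa, xb, fa, fb)
  sparse <- vapply(c("I", "II", "III", "IV"), function(quad) {
    mg <- quadrant_margins(q, quad)
    if (mg["row"] <= 0 || mg["col"] <= 0) return(FALSE)
    sahoo_test(q, quad)$significant
  }, logical(1))
  rules <- character()
  if (sparse[["IV"]] && sparse[["II"]]) {
    rules <- c(rules, "equivalent")
  } else {
    if (sparse[["IV"]]) rules <- c(rules, "A-high=>B-high")
    if (sparse[["II"]]) rules <- c(rules, "A-low=>B-low")
  }
  if (sparse[["I"]] && sparse[["III"]]) {
    rules <- c(rules, "opposite")
  } else {
    if (sparse[["I"]]) rules <- c(rules, "A-high=>B-low")
    if (sparse[["III"]]) rules <- c(rules, "A-low=>B-high")
  }
  rules
}
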