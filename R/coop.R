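# Significance filters, logic matrices and the S1/S2/D cooperative-mode
# counting with positive/negative subtypes.
#
# For each row (one length fraction p) of a correlation table, a filter
# yields a threshold on the absolute correlations of that row; entries
# strictly above the threshold are "significant" (matrix L).  A second
# matrix Z records the sign of each correlation (c >= 0 counts as positive).
# Counting runs over all triples (p1-row, p2-row, mode): S1 = only pair 1
# significant, S2 = only pair 2, D = both; subtypes follow the signs.

#' Significance filter specification
#'
#' @param method `"median"`, `"tertile"`, `"quartile"` or `"mean"`.  The
#'   comparison is always strictly greater than the threshold.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(method = c("median", "tertile", "quartile", "mean")) {
  method <- match.arg(method)
  structure(list(method = method, strictness = "strict-greater"),
            class = "filter_spec")
}

#' Row threshold of a filter
#'
#' Thresholds act on absolute values.  `median` averages the two central
#' order statistics for an even count; `mean` is the arithmetic mean; the
#' quantile filters use the lower empirical quantile,
#' `inf{ v : F(v) >= p }` with `p = 1/3` (tertile) or `1/4` (quartile),
#' i.e. the smallest order statistic whose rank fraction reaches `p`.
#'
#' @param row Numeric vector of signed correlations (one table row).
#' @param filter A [filter_spec()] (or a method name).
#' @return The scalar threshold.
#' @export
row_threshold <- function(row, filter) {
  if (is.character(filter)) filter <- filter_spec(filter)
  stopifnot(inherits(filter, "filter_spec"))
  v <- abs(as.numeric(row))
  if (!length(v)) stop("empty row")
  switch(filter$method,
         median = median(v),
         mean = mean(v),
         tertile = sort(v)[ceiling(length(v) / 3)],
         quartile = sort(v)[ceiling(length(v) / 4)])
}

#' Significance and sign logic matrices of a correlation table
#'
#' `L[m, n] = |c_mn| > threshold_m` (strict), with `threshold_m` the filter
#' applied to row m; `Z[m, n] = c_mn >= 0`.
#'
#' @param table A `correlation_table`.
#' @param filter A [filter_spec()] or method name.
#' @return A `logic_pair`: logical matrices `L` and `Z`, the per-row
#'   `thresholds`, per-row significant-entry counts `n_sig_per_row`
#'   (a diagnostic for tie effects), and the filter used.
#' @export
logic_pair <- function(table, filter) {
  stopifnot(inherits(table, "correlation_table"))
  if (is.character(filter)) filter <- filter_spec(filter)
  thr <- apply(table$values, 1, row_threshold, filter = filter)
  L <- sweep(abs(table$values), 1, thr, ">")
  Z <- table$values >= 0
  structure(list(L = L, Z = Z, thresholds = thr,
                 n_sig_per_row = rowSums(L), filter = filter,
                 p_grid = table$p_grid, pair_id = table$pair_id),
            class = "logic_pair")
}

new_coop_counts <- function(s1, s1_pos, s1_neg, s2, s2_pos, s2_neg,
                            d, d_pos, d_neg, n_triples) {
  structure(list(s1 = s1, s1_pos = s1_pos, s1_neg = s1_neg,
                 s2 = s2, s2_pos = s2_pos, s2_neg = s2_neg,
                 d = d, d_pos = d_pos, d_neg = d_neg,
                 n_triples = n_triples),
            class = "coop_counts")
}

#' Cooperative-mode counts S1/S2/D with signed subtypes
#'
#' Runs over all triples `(m1, m2, n)` of a row of pair 1's logic matrices, a
#' row of pair 2's, and a mode: `s1` counts triples where only pair 1 is
#' significant, `s2` only pair 2, `d` both.  Subtypes: `s1_pos` requires a
#' positive sign in pair 1 (`Z1[m1, n]`), `s2_pos` a positive sign in pair 2;
#' `d_pos` requires the two significant correlations to share a sign.
#'
#' @param pair1,pair2 `logic_pair`s of the two protein pairs (same
#'   dimensions, same p grid).
#' @return A `coop_counts` with the nine counts and `n_triples`
#'   (6 x 6 x 10 = 360 for the default grids).
#' @export
coop_counts <- function(pair1, pair2) {
  stopifnot(inherits(pair1, "logic_pair"), inherits(pair2, "logic_pair"))
  if (!all(dim(pair1$L) == dim(pair2$L)))
    stop("logic matrices of the two pairs differ in dimension")
  if (!isTRUE(all.equal(pair1$p_grid, pair2$p_grid)))
    stop("the two pairs use different p grids")
  L1 <- pair1$L; Z1 <- pair1$Z; L2 <- pair2$L; Z2 <- pair2$Z
  M <- nrow(L1); N <- ncol(L1)
  s1 <- s1p <- s2 <- s2p <- d <- dp <- 0L
  for (m1 in seq_len(M)) for (m2 in seq_len(M)) for (n in seq_len(N)) {
    a <- L1[m1, n]; b <- L2[m2, n]
    if (a && !b) {
      s1 <- s1 + 1L
      if (Z1[m1, n]) s1p <- s1p + 1L
    } else if (!a && b) {
      s2 <- s2 + 1L
      if (Z2[m2, n]) s2p <- s2p + 1L
    } else if (a && b) {
      d <- d + 1L
      if (Z1[m1, n] == Z2[m2, n]) dp <- dp + 1L
    }
  }
  new_coop_counts(s1, s1p, s1 - s1p, s2, s2p, s2 - s2p, d, dp, d - dp,
                  M * M * N)
}

# Equivalent row-replication formulation: expand row m of pair 1's matrices
# into a full matrix of identical rows and combine with pair 2's matrices by
# elementwise logic.  Kept as an internal cross-check of coop_counts().
coop_counts_rowrep <- function(pair1, pair2) {
  L1 <- pair1$L; Z1 <- pair1$Z; L2 <- pair2$L; Z2 <- pair2$Z
  M <- nrow(L1); N <- ncol(L1)
  s1 <- s1p <- s2 <- s2p <- d <- dp <- 0L
  for (m in seq_len(M)) {
    L1m <- matrix(L1[m, ], nrow = M, ncol = N, byrow = TRUE)
    Z1m <- matrix(Z1[m, ], nrow = M, ncol = N, byrow = TRUE)
    s1 <- s1 + sum(L1m & !L2)
    s1p <- s1p + sum(L1m & !L2 & Z1m)
    s2 <- s2 + sum(!L1m & L2)
    s2p <- s2p + sum(!L1m & L2 & Z2)
    d <- d + sum(L1m & L2)
    dp <- dp + sum(L1m & L2 & (Z1m == Z2))
  }
  new_coop_counts(s1, s1p, s1 - s1p, s2, s2p, s2 - s2p, d, dp, d - dp,
                  M * M * N)
}

#' @export
print.coop_counts <- function(x, ...) {
  cat(sprintf("coop_counts over %d triples:\n", x$n_triples))
  cat(sprintf("  s1 = %3d (pos %3d / neg %3d)\n", x$s1, x$s1_pos, x$s1_neg))
  cat(sprintf("  s2 = %3d (pos %3d / neg %3d)\n", x$s2, x$s2_pos, x$s2_neg))
  cat(sprintf("  d  = %3d (pos %3d / neg %3d)\n", x$d, x$d_pos, x$d_neg))
  invisible(x)
}

#' Per-p median absolute correlations of the two pairs
#'
#' For each length fraction p, the median of the 10 absolute correlations of
#' that row, for each pair: the per-p summary used to compare the behaviour
#' of the two protein pairs.
#'
#' @param table1,table2 `correlation_table`s sharing one p grid.
#' @return Data frame with columns `p`, `pair1`, `pair2`.
#' @export
summarize_medians <- function(table1, table2) {
  stopifnot(inherits(table1, "correlation_table"),
            inherits(table2, "correlation_table"))
  if (!isTRUE(all.equal(table1$p_grid, table2$p_grid)))
    stop("tables use different p grids")
  data.frame(p = table1$p_grid,
             pair1 = apply(abs(table1$values), 1, median),
             pair2 = apply(abs(table2$values), 1, median))
}
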