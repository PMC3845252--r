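# The core statistic: Pearson correlation, the lambda-window maximal-|r|
# segment search between two unequal-length curves, assembly of the p-by-mode
# correlation tables, and the PCA / Fourier-magnitude curve condensations.

#' Pearson product-moment correlation
#'
#' `cov(x, y) / (sd(x) sd(y))`.  If either window has zero variance the
#' correlation is defined as 0 and the result carries a `degenerate`
#' attribute set to `TRUE` (a constant segment can never be significantly
#' correlated).
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return The correlation in \[-1, 1\], with attribute `degenerate`.
#' @export
pearson_cor <- function(x, y) {
  x <- curve_values(x); y <- curve_values(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 2L) stop("need at least 2 points")
  degen <- max(x) == min(x) || max(y) == min(y)
  r <- if (degen) 0 else {
    cx <- x - mean(x); cy <- y - mean(y)
    sum(cx * cy) / sqrt(sum(cx * cx) * sum(cy * cy))
  }
  structure(r, degenerate = degen)
}

#' Most correlated equal-length segment pair of two curves
#'
#' Exhaustively scores every placement of a `lambda`-length window in curve
#' `f1` against every placement in `f2` by the absolute Pearson correlation
#' and returns the maximising pair.  Ties are broken by the smallest start in
#' `f1`, then the smallest start in `f2`.  Zero-variance windows score 0 and
#' are flagged degenerate.
#'
#' The default `search = "all"` considers all start pairs (i, j)
#' independently; `search = "shift"` restricts the windows to a common
#' sliding offset (window at the start of the overlap for each relative
#' shift of one curve along the other).
#'
#' @param f1,f2 Numeric curves (or `motion_curve`s).
#' @param lambda Window length, `2 <= lambda <= min(length(f1), length(f2))`.
#' @param search `"all"` (default) or `"shift"`.
#' @return A `segment_match`: 0-based `start_a`, `start_b`, `length`, signed
#'   `correlation`, and a `degenerate` flag for the winning window.
#' @export
best_segment_pair <- function(f1, f2, lambda, search = c("all", "shift")) {
  search <- match.arg(search)
  a <- curve_values(f1); b <- curve_values(f2)
  na <- length(a); nb <- length(b)
  if (lambda < 2 || lambda > min(na, nb))
    stop("lambda must be in [2, min(length(f1), length(f2))]")
  lambda <- as.integer(lambda)
  # all lambda-windows as rows (embed reverses within rows, consistently for
  # both curves, which leaves every pairwise correlation unchanged)
  WA <- embed(a, lambda)
  WB <- embed(b, lambda)
  norm_rows <- function(W) {
    C <- W - rowMeans(W)
    den <- sqrt(rowSums(C * C))
    degen <- apply(W, 1, max) == apply(W, 1, min)
    C[degen, ] <- 0
    den[degen] <- 1
    list(C = C / den, degen = degen)
  }
  A <- norm_rows(WA); B <- norm_rows(WB)
  R <- tcrossprod(A$C, B$C)          # R[i, j] = pearson of windows i, j
  R <- clamp(R, -1, 1)
  if (search == "shift") {
    keep <- matrix(FALSE, nrow(R), ncol(R))
    for (s in seq.int(-(nrow(R) - 1L), ncol(R) - 1L)) {
      i <- max(1L, 1L - s)
      keep[i, i + s] <- TRUE
    }
    R[!keep] <- NA
  }
  absR <- abs(R)
  best <- max(absR, na.rm = TRUE)
  # windows within 1e-9 of the maximum are exact ties up to round-off
  # (e.g. every 2-point window has |r| = 1); ties break to the smallest
  # start in f1, then in f2
  hits <- which(absR >= best - 1e-9, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- unname(hits[1, 1]); j <- unname(hits[1, 2])
  structure(list(start_a = i - 1L, start_b = j - 1L, length = lambda,
                 correlation = R[i, j],
                 degenerate = A$degen[i] || B$degen[j]),
            class = "segment_match")
}

#' @export
print.segment_match <- function(x, ...) {
  cat(sprintf("segment_match: starts (%d, %d), length %d, r = %.4f%s\n",
              x$start_a, x$start_b, x$length, x$correlation,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Window length from a length fraction
#'
#' `lambda = round(p * x)` (half away from zero), clamped to `[2, x]`, with
#' `x` the shorter residue count of the observed pair.
#'
#' @param p Length fraction in (0, 1].
#' @param x Shorter curve length.
#' @return Integer window length.
#' @export
lambda_from_p <- function(p, x) {
  stopifnot(all(p > 0), all(p <= 1), x >= 2)
  as.integer(clamp(round_half_up(p * x), 2, x))
}

new_correlation_table <- function(values, p_grid, mode_numbers, pair_id = NA,
                                  matches = NULL, lambdas = NULL,
                                  degenerate = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(p_grid), ncol(values) == length(mode_numbers),
            all(abs(values) <= 1))
  dimnames(values) <- list(paste0("p", p_grid), paste0("mode", mode_numbers))
  structure(list(pair_id = pair_id, p_grid = p_grid,
                 mode_numbers = mode_numbers, values = values,
                 matches = matches, lambdas = lambdas, degenerate = degenerate),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat(sprintf("correlation_table: pair %s, %d p values x %d modes\n",
              x$pair_id, length(x$p_grid), length(x$mode_numbers)))
  print(round(x$values, 3))
  invisible(x)
}

#' Signed correlation table over a p grid and a mode list
#'
#' For every length fraction `p` (row) and mode (column), runs
#' [best_segment_pair()] between the two proteins' curves for that mode with
#' window length `lambda = round(p * x)`, `x` being the shorter curve length,
#' and stores the signed maximal correlation `c_mn`.
#'
#' @param curves_a,curves_b Lists of curves (one per mode, same mode order)
#'   for the two proteins of a pair; all curves of one protein must share one
#'   length.
#' @param p_grid Length fractions; default `1.0, 0.9, ..., 0.5`.
#' @param mode_numbers Mode labels for the columns; defaults to names of
#'   `curves_a` or `7..(6+k)`.
#' @param pair_id Stored pair label.
#' @param search Passed to [best_segment_pair()].
#' @return A `correlation_table` with `values` (p x mode signed matrix),
#'   per-cell `matches`, the per-row window lengths `lambdas` and a
#'   `degenerate` indicator matrix.
#' @export
correlation_table <- function(curves_a, curves_b, p_grid = seq(1, 0.5, by = -0.1),
                              mode_numbers = NULL, pair_id = NA,
                              search = "all") {
  stopifnot(length(curves_a) >= 1L, length(curves_a) == length(curves_b),
            all(p_grid > 0), all(p_grid <= 1))
  va <- lapply(curves_a, curve_values)
  vb <- lapply(curves_b, curve_values)
  la <- unique(lengths(va)); lb <- unique(lengths(vb))
  if (length(la) != 1L || length(lb) != 1L)
    stop("curves of one protein must all have the same length")
  if (is.null(mode_numbers)) {
    mode_numbers <- if (!is.null(names(curves_a))) as.integer(names(curves_a))
                    else seq.int(7L, 6L + length(curves_a))
  }
  x <- min(la, lb)
  lambdas <- lambda_from_p(p_grid, x)
  M <- length(p_grid); N <- length(curves_a)
  values <- matrix(NA_real_, M, N)
  degen <- matrix(FALSE, M, N)
  matches <- vector("list", M * N)
  dim(matches) <- c(M, N)
  for (n in seq_len(N)) {
    for (m in seq_len(M)) {
      sm <- best_segment_pair(va[[n]], vb[[n]], lambdas[m], search = search)
      values[m, n] <- sm$correlation
      degen[m, n] <- sm$degenerate
      matches[[m, n]] <- sm
    }
  }
  new_correlation_table(values, p_grid, mode_numbers, pair_id = pair_id,
                        matches = matches, lambdas = lambdas, degenerate = degen)
}

#' Write a correlation table (and its segment placements) as TSV
#'
#' The main file mirrors the published layout: rows are p values, columns are
#' modes, entries are signed correlations.  A companion
#' `<path>.segments.tsv` lists `(start_a, start_b, lambda)` per cell.
#'
#' @param table A `correlation_table`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_correlation_tsv <- function(table, path) {
  stopifnot(inherits(table, "correlation_table"))
  out <- data.frame(p = table$p_grid, table$values, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(table$matches)) {
    seg <- do.call(rbind, lapply(seq_along(table$p_grid), function(m) {
      do.call(rbind, lapply(seq_along(table$mode_numbers), function(n) {
        sm <- table$matches[[m, n]]
        data.frame(p = table$p_grid[m], mode = table$mode_numbers[n],
                   start_a = sm$start_a, start_b = sm$start_b,
                   lambda = sm$length, correlation = sm$correlation,
                   degenerate = sm$degenerate)
      }))
    }))
    write.table(seg, paste0(path, ".segments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Condense a family of curves to their first principal component
#'
#' Positions are observations (rows) and modes are variables (columns); after
#' column-centring, the condensed curve is the score series on the first
#' principal axis.  Its sign is chosen so that it correlates non-negatively
#' with the per-position mean of the input curves.  Used to reduce the 10
#' noisy rotation-angle curves of a protein to a single curve.
#'
#' @param curves List (>= 2) of equal-length curves.
#' @return A `condensed_curve` of kind `"pc1"`.
#' @export
pc1_condense <- function(curves) {
  stopifnot(length(curves) >= 2L)
  vals <- lapply(curves, curve_values)
  L <- unique(lengths(vals))
  if (length(L) != 1L || L < 2L) stop("curves must share one length >= 2")
  X <- do.call(cbind, vals)
  Xc <- sweep(X, 2, colMeans(X))
  if (all(Xc == 0)) stop("zero total variance: all curves are constant")
  sv <- svd(Xc)
  score <- sv$u[, 1] * sv$d[1]
  ref <- rowMeans(X)
  r <- pearson_cor(score, ref)
  if (!attr(r, "degenerate") && r < 0) score <- -score
  pid <- if (inherits(curves[[1]], "motion_curve")) curves[[1]]$protein_id else NA
  structure(list(protein_id = pid, kind = "pc1", values = score),
            class = "condensed_curve")
}

#' Fourier magnitude spectrum of a curve
#'
#' Unnormalised discrete Fourier transform of the full curve; the output is
#' the magnitude at every frequency bin `0..L-1`, DC included.  Used as a
#' noise-robust transform of rotation-angle curves before segment matching.
#'
#' @param curve Numeric curve (length >= 2).
#' @return A `condensed_curve` of kind `"fourier-magnitude"` with
#'   non-negative values.
#' @export
fourier_magnitude <- function(curve) {
  v <- curve_values(curve)
  if (length(v) < 2L) stop("need at least 2 points")
  structure(list(protein_id = if (inherits(curve, "motion_curve")) curve$protein_id else NA,
                 kind = "fourier-magnitude", values = Mod(fft(v))),
            class = "condensed_curve")
}

#' @export
print.condensed_curve <- function(x, ...) {
  cat(sprintf("condensed_curve (%s): protein %s, %d values\n",
              x$kind, x$protein_id, length(x$values)))
  invisible(x)
}
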