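#' Per-window read counts
#'
#' Tiles `[min(positions), max(positions)]` with half-open windows of
#' `window_size` base pairs and sums the per-site depth falling in each
#' window (empty windows count zero).
#'
#' @param depths per-site depth vector.
#' @param positions site positions (sorted, same length as `depths`).
#' @param window_size window length in bp (default 10,000).
#' @return numeric vector of per-window summed depth.
#' @export
window_counts <- function(depths, positions, window_size = 10000) {
  stopifnot(length(depths) == length(positions), length(depths) > 0,
            window_size > 0, !is.unsorted(positions))
  idx <- floor((positions - positions[1]) / window_size) + 1
  nwin <- floor((positions[length(positions)] - positions[1]) /
                  window_size) + 1
  out <- numeric(nwin)
  s <- rowsum(as.numeric(depths), idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fraction of sites covered by at least one read
#' @param depths per-site depth vector (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
covered_fraction <- function(depths) {
  stopifnot(length(depths) > 0)
  mean(depths >= 1)
}

#' Gini coefficient of coverage uniformity
#'
#' One minus twice the trapezoidal area under the Lorenz curve of cumulative
#' count share versus cumulative window share (windows sorted ascending).
#' Perfectly uniform counts give 0; all reads in one of `W` windows give
#' `(W - 1) / W`.
#'
#' @param counts per-window counts; nonnegative with at least one positive
#'   entry (all-zero input is undefined and rejected).
#' @return Gini coefficient in `[0, 1]`.
#' @export
gini <- function(counts) {
  stopifnot(length(counts) > 0, all(counts >= 0))
  if (sum(counts) == 0) stop("Gini is undefined for all-zero counts")
  y <- c(0, cumsum(sort(counts))) / sum(counts)
  x <- seq(0, 1, length.out = length(y))
  area <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  1 - 2 * area
}

#' Coverage breadth and uniformity profile
#'
#' Computes, from per-site depths (one individual) or a `site_reads` object
#' (averaging over individuals), the covered fraction, 10-kb window counts
#' and the Gini coefficient of the window Lorenz curve.
#'
#' @param x per-site depth vector or a `site_reads` object.
#' @param positions site positions (vector input only).
#' @param window_size Lorenz window in bp (default 10,000).
#' @param ... unused.
#' @return An object of class `coverage_profile` with `covered_fraction`,
#'   `gini`, `mean_depth`, `window_size` and `window_counts` (for
#'   `site_reads` input the scalar metrics are means over individuals and
#'   the window counts are summed).
#' @export
coverage_profile <- function(x, ...) UseMethod("coverage_profile")

#' @rdname coverage_profile
#' @export
coverage_profile.default <- function(x, positions, window_size = 10000, ...) {
  wc <- window_counts(x, positions, window_size)
  structure(list(covered_fraction = covered_fraction(x),
                 gini = if (sum(wc) > 0) gini(wc) else NA_real_,
                 mean_depth = mean(x), window_size = window_size,
                 window_counts = wc, n_individuals = 1L),
            class = "coverage_profile")
}

#' @rdname coverage_profile
#' @export
coverage_profile.site_reads <- function(x, window_size = 10000, ...) {
  dp <- x$n_ref + x$n_alt
  n <- nrow(dp)
  cov <- numeric(n); gin <- numeric(n)
  wc_tot <- numeric(0)
  for (i in seq_len(n)) {
    wc <- window_counts(dp[i, ], x$positions, window_size)
    cov[i] <- covered_fraction(dp[i, ])
    gin[i] <- if (sum(wc) > 0) gini(wc) else NA_real_
    wc_tot <- if (length(wc_tot)) wc_tot + wc else wc
  }
  structure(list(covered_fraction = mean(cov), gini = mean(gin, na.rm = TRUE),
                 mean_depth = mean(dp), window_size = window_size,
                 window_counts = wc_tot, n_individuals = n,
                 per_individual = data.frame(covered_fraction = cov,
                                             gini = gin)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "Coverage profile (%d individual%s): mean depth %.3fx, covered %.1f%%, Gini %.3f (%d x %g bp windows)\n",
    x$n_individuals, if (x$n_individuals > 1) "s" else "", x$mean_depth,
    100 * x$covered_fraction, x$gini, length(x$window_counts),
    x$window_size))
  invisible(x)
}

#' Lorenz curve plot of coverage uniformity
#' @param x a `coverage_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.coverage_profile <- function(x, ...) {
  y <- c(0, cumsum(sort(x$window_counts))) / sum(x$window_counts)
  xx <- seq(0, 1, length.out = length(y))
  graphics::plot(xx, y, type = "l", xlab = "cumulative window share",
                 ylab = "cumulative read share",
                 main = sprintf("Lorenz curve (Gini = %.3f)", x$gini), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Read a BED-like per-site depth table
#'
#' Three whitespace-separated columns (chromosome, position, depth), no
#' header; feeds [coverage_profile()] for externally computed depths.
#'
#' @param path file path.
#' @return list with `positions` (integer) and `depths` (numeric), sorted
#'   by position.
#' @export
read_depth_table <- function(path) {
  df <- read.table(path, header = FALSE)
  if (ncol(df) < 3) stop("depth table needs 3 columns: chrom, pos, depth")
  ord <- order(df[[2]])
  list(positions = as.integer(df[[2]])[ord],
       depths = as.numeric(df[[3]])[ord])
}
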