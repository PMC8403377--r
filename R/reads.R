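#' Simulate per-site sequencing reads from true genotypes
#'
#' Site-level read model: the number of reads covering a site is
#' `Poisson(mean_depth)` when `overdispersion = 0`, otherwise negative
#' binomial with the same mean and variance
#' `mean_depth + overdispersion * mean_depth^2` (nonuniform coverage for the
#' Lorenz/Gini analysis). Each read carries the alternate allele with
#' probability `(g/2) (1 - e) + (1 - g/2) e` for true genotype `g` and
#' per-base error `e`.
#'
#' @param genotypes a `diploid_geno`.
#' @param mean_depth mean reads per site (>= 0).
#' @param error_rate per-base miscall probability in `[0, 0.5)`.
#' @param overdispersion nonnegative extra-Poisson dispersion.
#' @param seed integer seed.
#' @return An object of class `site_reads` with integer matrices `n_ref`
#'   and `n_alt` (individuals x sites), `mean_depth`, `error_rate` and site
#'   metadata.
#' @export
simulate_reads <- function(genotypes, mean_depth, error_rate = 0.002,
                           overdispersion = 0, seed = 1) {
  stopifnot(inherits(genotypes, "diploid_geno"), mean_depth >= 0,
            error_rate >= 0, error_rate < 0.5, overdispersion >= 0)
  set.seed(seed)
  G <- genotypes$genotypes
  len <- length(G)
  depth <- if (mean_depth == 0) {
    integer(len)
  } else if (overdispersion == 0) {
    rpois(len, mean_depth)
  } else {
    rnbinom(len, size = 1 / overdispersion, mu = mean_depth)
  }
  p_alt <- (G / 2) * (1 - error_rate) + (1 - G / 2) * error_rate
  n_alt <- rbinom(len, depth, as.vector(p_alt))
  dim(n_alt) <- dim(G)
  n_ref <- matrix(depth, nrow(G), ncol(G)) - n_alt
  storage.mode(n_ref) <- "integer"
  storage.mode(n_alt) <- "integer"
  structure(list(n_ref = n_ref, n_alt = n_alt,
                 mean_depth = mean_depth, error_rate = error_rate,
                 site_ids = genotypes$site_ids,
                 positions = genotypes$positions,
                 ref = genotypes$ref, alt = genotypes$alt),
            class = "site_reads")
}

#' @export
print.site_reads <- function(x, ...) {
  dp <- x$n_ref + x$n_alt
  cat(sprintf(
    "Site reads: %d individuals x %d sites, nominal depth %.2fx (realised %.3fx), error %.3g\n",
    nrow(dp), ncol(dp), x$mean_depth, mean(dp), x$error_rate))
  invisible(x)
}

#' Binomial thinning of reads to a lower target depth
#'
#' Retains each read independently with probability
#' `target_depth / mean_depth`, mimicking proportional subsampling of
#' high-coverage sequencing to low-pass data. Thinning a Poisson depth
#' yields a Poisson depth at the target mean, and the ref/alt composition is
#' unbiased.
#'
#' @param reads a `site_reads` object.
#' @param target_depth target mean depth, at most `reads$mean_depth`.
#' @param seed integer seed.
#' @return a `site_reads` at the target depth.
#' @export
downsample_reads <- function(reads, target_depth, seed = 1) {
  stopifnot(inherits(reads, "site_reads"), target_depth >= 0)
  if (target_depth > reads$mean_depth)
    stop("target_depth exceeds the current mean depth (",
         reads$mean_depth, "x)")
  set.seed(seed)
  p <- if (reads$mean_depth > 0) target_depth / reads$mean_depth else 0
  thin <- function(m) {
    out <- rbinom(length(m), as.vector(m), p)
    dim(out) <- dim(m)
    storage.mode(out) <- "integer"
    out
  }
  out <- reads
  out$n_ref <- thin(reads$n_ref)
  out$n_alt <- thin(reads$n_alt)
  out$mean_depth <- target_depth
  out
}

#' Genotype likelihoods from read counts
#'
#' `L(g) = Binomial(n_alt; n_ref + n_alt, p_g)` with
#' `p_g = (g/2)(1 - e) + (1 - g/2) e`, stored in log space. At zero depth
#' the three likelihoods are equal (no data).
#'
#' @param reads a `site_reads` object.
#' @param error_rate per-base error in `(0, 0.5)`; defaults to the rate the
#'   reads were simulated with (floored at 1e-6 so likelihoods stay finite).
#' @return An object of class `geno_lik`: `loglik` (individuals x sites x 3
#'   array), `depth` matrix, `error_rate` and site metadata.
#' @export
compute_gl <- function(reads, error_rate = NULL) {
  stopifnot(inherits(reads, "site_reads"))
  e <- error_rate %||% max(reads$error_rate, 1e-6)
  if (e <= 0 || e >= 0.5) stop("error_rate must lie in (0, 0.5)")
  n_alt <- reads$n_alt
  depth <- reads$n_ref + n_alt
  ll <- array(NA_real_, c(nrow(depth), ncol(depth), 3L))
  p_g <- c(e, 0.5, 1 - e)
  for (g in 1:3)
    ll[, , g] <- dbinom(n_alt, depth, p_g[g], log = TRUE)
  structure(list(loglik = ll, depth = depth, error_rate = e,
                 site_ids = reads$site_ids, positions = reads$positions,
                 ref = reads$ref, alt = reads$alt),
            class = "geno_lik")
}

#' Hard genotype calls from genotype likelihoods
#'
#' The argmax genotype per individual and site, with ties broken toward the
#' smaller genotype (reference-majority convention), and a no-call (`NA`)
#' wherever the read depth falls below `min_depth`. This is the fixed-call
#' input that degrades traditional imputation at low coverage.
#'
#' @param gl a `geno_lik` object.
#' @param min_depth minimum depth for a call (default 1: zero-depth sites
#'   are missing).
#' @return An object of class `called_geno`: `calls` matrix over
#'   `{0, 1, 2, NA}`, `site_index` (columns' positions in the full site
#'   grid) and site metadata.
#' @export
hard_call <- function(gl, min_depth = 1) {
  stopifnot(inherits(gl, "geno_lik"))
  d <- dim(gl$loglik)
  flat <- matrix(gl$loglik, d[1] * d[2], 3L)
  call <- max.col(flat, ties.method = "first") - 1L
  dim(call) <- d[1:2]
  call[gl$depth < min_depth] <- NA_integer_
  structure(list(calls = call, site_index = seq_len(d[2]),
                 site_ids = gl$site_ids, positions = gl$positions,
                 ref = gl$ref, alt = gl$alt),
            class = "called_geno")
}

#' @export
print.called_geno <- function(x, ...) {
  cat("Called genotypes:", nrow(x$calls), "individuals x", ncol(x$calls),
      "typed sites;", sprintf("%.1f%%", 100 * mean(is.na(x$calls))),
      "missing\n")
  invisible(x)
}

#' Simulate a genotyping-array route
#'
#' Designates a seeded subset of sites as "array sites", sampled with
#' probability proportional to the cohort heterozygosity `p (1 - p)` to
#' mimic array design bias toward common variants, and types the true
#' genotype there with a symmetric error: with probability `array_error`
#' the call is replaced by one of the two other genotypes. All other sites
#' are untyped. The default `array_fraction` of 0.16 makes the array assay
#' roughly 0.4 times the number of sites covered by 0.5x sequencing
#' (`0.4 * (1 - exp(-0.5))`).
#'
#' @param genotypes a `diploid_geno`.
#' @param array_fraction fraction of sites on the array, in `(0, 1]`.
#' @param array_error per-genotype typing error probability.
#' @param seed integer seed.
#' @return a `called_geno` restricted to the array subset (`site_index`
#'   gives the typed columns in the full site grid).
#' @export
simulate_array <- function(genotypes, array_fraction = 0.16,
                           array_error = 0.002, seed = 1) {
  stopifnot(inherits(genotypes, "diploid_geno"),
            array_fraction > 0, array_fraction <= 1,
            array_error >= 0, array_error < 1)
  set.seed(seed)
  G <- genotypes$genotypes
  M <- ncol(G)
  p <- colMeans(G) / 2
  w <- p * (1 - p)
  n_array <- max(1L, round(array_fraction * M))
  if (array_fraction == 1) {
    sites <- seq_len(M)
  } else {
    pos_w <- which(w > 0)
    n_array <- min(n_array, length(pos_w))
    if (n_array == 0) stop("no polymorphic sites available for the array")
    sites <- sort(sample(pos_w, n_array, prob = w[pos_w]))
  }
  calls <- G[, sites, drop = FALSE]
  if (array_error > 0) {
    err <- which(runif(length(calls)) < array_error)
    if (length(err)) {
      old <- calls[err]
      calls[err] <- vapply(old, function(g) sample(setdiff(0:2, g), 1L),
                           integer(1))
    }
  }
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, site_index = sites,
                 site_ids = genotypes$site_ids[sites],
                 positions = genotypes$positions[sites],
                 ref = genotypes$ref[sites], alt = genotypes$alt[sites]),
            class = "called_geno")
}
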