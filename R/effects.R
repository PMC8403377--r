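#' Assign causal effects and published GWAS weights
#'
#' Draws a set of causal SNPs with true per-allele effects on the liability
#' scale and derives the "published" GWAS weight table the PRS engine
#' consumes. Raw causal effects are standard normal draws rescaled so that
#' the variance of the standardized genetic score equals `h2` (assuming
#' approximately independent sites); the published weight is the true effect
#' plus Gaussian estimation noise with standard deviation `weight_noise_sd`.
#' Non-causal SNPs receive noise-only weights and uniform P-values; causal
#' SNPs receive Wald-type P-values from a normal approximation at effective
#' GWAS sample size `n_gwas`, so P-value thresholding has realistic material
#' to act on.
#'
#' Weights are stored relative to the recorded effect allele: when the
#' effect allele is the reference allele, the published weight is the
#' negated alternate-allele effect (the `true_beta` column always refers to
#' the alternate allele).
#'
#' @param panel_afs per-site alternate allele frequencies (the standardizing
#'   frequencies for the liability model).
#' @param n_causal number of causal SNPs (`0` allowed: pure-null genetics).
#' @param h2 liability-scale SNP heritability in `[0, 1)`.
#' @param weight_noise_sd standard deviation of the weight estimation noise.
#' @param n_gwas effective sample size behind the Wald P-values.
#' @param site_ids optional SNP identifiers (defaults to `snp00001`, ...).
#' @param causal_maf_min minimum minor allele frequency of causal SNPs.
#'   GWAS-identified risk SNPs for complex disease are overwhelmingly
#'   common variants, so causal SNPs default to the common stratum
#'   (MAF >= 5%); set to 0 to draw them from the full spectrum. If fewer
#'   than `n_causal` sites qualify, the constraint is relaxed to the whole
#'   site set.
#' @param seed integer seed.
#' @return A `gwas_weights` data frame with columns `site_id`,
#'   `effect_allele` (`"ref"` or `"alt"`), `weight`, `p_value`, `is_causal`,
#'   `true_beta` and `af`, carrying `h2` as an attribute.
#' @export
assign_effects <- function(panel_afs, n_causal, h2, weight_noise_sd = 0.01,
                           n_gwas = 30000, site_ids = NULL,
                           causal_maf_min = 0.05, seed = 1) {
  M <- length(panel_afs)
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  stopifnot(n_causal >= 0, n_causal <= M, weight_noise_sd >= 0, n_gwas > 1)
  if (is.null(site_ids)) site_ids <- sprintf("snp%05d", seq_len(M))
  stopifnot(length(site_ids) == M, !anyDuplicated(site_ids))
  set.seed(seed)

  true_beta <- numeric(M)
  causal <- integer(0)
  if (n_causal > 0) {
    maf <- pmin(panel_afs, 1 - panel_afs)
    eligible <- which(maf >= causal_maf_min)
    if (length(eligible) < n_causal) eligible <- seq_len(M)
    causal <- sort(sample(eligible, n_causal))
    b <- rnorm(n_causal)
    if (h2 > 0) b <- b * sqrt(h2 / sum(b^2)) else b <- rep(0, n_causal)
    true_beta[causal] <- b
  }

  effect_allele <- sample(c("ref", "alt"), M, replace = TRUE)
  signed_beta <- ifelse(effect_allele == "ref", -true_beta, true_beta)
  weight <- signed_beta + rnorm(M, 0, weight_noise_sd)

  p_value <- runif(M)
  if (length(causal)) {
    z <- sqrt(n_gwas) * true_beta[causal] + rnorm(length(causal))
    p_value[causal] <- pmax(2 * pnorm(-abs(z)), 1e-300)
  }

  out <- data.frame(site_id = site_ids, effect_allele = effect_allele,
                    weight = weight, p_value = p_value,
                    is_causal = seq_len(M) %in% causal,
                    true_beta = true_beta, af = as.numeric(panel_afs),
                    stringsAsFactors = FALSE)
  attr(out, "h2") <- h2
  class(out) <- c("gwas_weights", "data.frame")
  out
}

#' Liability-threshold case/control phenotypes
#'
#' Standardized genotypes `(x - 2p) / sqrt(2 p (1 - p))` (with `p` the
#' panel frequency recorded in the weight table) are combined with the true
#' causal effects to form the genetic liability component; a Gaussian
#' residual with variance `1 - h2` completes the liability, and an
#' individual is a case when liability exceeds the threshold
#' `qnorm(1 - prevalence)`. The requested numbers of cases and controls are
#' then sampled from the pool; the defaults mirror a cohort of 87 cases and
#' 101 controls.
#'
#' @param genotypes a `diploid_geno` pool large enough to supply both groups.
#' @param weights a `gwas_weights` table from [assign_effects()].
#' @param prevalence disease prevalence in `(0, 1)`.
#' @param n_cases,n_controls group sizes to sample from the pool.
#' @param seed integer seed.
#' @return An object of class `phenotype_set`: `idx` (pool indices of the
#'   selected individuals, cases first), `label` (1 = case, 0 = control),
#'   `liability` for the selected individuals, `h2`, `prevalence`,
#'   `pool_n` and `pool_case_fraction`.
#' @export
simulate_phenotypes <- function(genotypes, weights, prevalence,
                                n_cases = 87, n_controls = 101, seed = 1) {
  stopifnot(inherits(genotypes, "diploid_geno"),
            inherits(weights, "gwas_weights"),
            prevalence > 0, prevalence < 1, n_cases >= 1, n_controls >= 1)
  if (!identical(genotypes$site_ids, weights$site_id))
    stop("weight table sites do not match the cohort's site set")
  set.seed(seed)
  h2 <- attr(weights, "h2")
  G <- genotypes$genotypes
  n <- nrow(G)

  g_val <- numeric(n)
  cidx <- which(weights$is_causal & weights$true_beta != 0)
  if (length(cidx)) {
    p <- weights$af[cidx]
    Z <- sweep(G[, cidx, drop = FALSE], 2, 2 * p, `-`)
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
    g_val <- as.vector(Z %*% weights$true_beta[cidx])
  }
  liability <- g_val + rnorm(n, 0, sqrt(1 - h2))
  case <- liability > qnorm(1 - prevalence)

  if (sum(case) < n_cases || sum(!case) < n_controls)
    stop("pool cannot supply ", n_cases, " cases and ", n_controls,
         " controls (pool has ", sum(case), " cases / ", sum(!case),
         " controls); increase the pool or revisit prevalence")
  idx <- c(sample(which(case), n_cases), sample(which(!case), n_controls))
  structure(list(idx = idx,
                 label = rep(c(1L, 0L), c(n_cases, n_controls)),
                 liability = liability[idx], h2 = h2,
                 prevalence = prevalence, pool_n = n,
                 pool_case_fraction = mean(case)),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat("Phenotype set:", sum(x$label == 1L), "cases /", sum(x$label == 0L),
      "controls sampled from a pool of", x$pool_n, "\n")
  cat(sprintf("  h2 = %.3f, prevalence = %.3f, pool case fraction = %.4f\n",
              x$h2, x$prevalence, x$pool_case_fraction))
  invisible(x)
}
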