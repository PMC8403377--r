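#' Simulate a phased biallelic reference haplotype panel
#'
#' Generates the haplotype panel that plays the role of a population-specific
#' imputation reference. Site frequencies are drawn from a neutral-like
#' spectrum with density proportional to 1/p, truncated to
#' `[maf_min, 0.5]`, so that rare, low-frequency and common variants are all
#' represented. Linkage disequilibrium is induced by generating the panel as
#' follows: `n_founders` founder haplotypes carry independent
#' `Bernoulli(p_m)` alleles, and the remaining haplotypes are mosaics of the
#' founders under a copying process with per-interval switch probability
#' `1 - exp(-mosaic_switch_rate * distance)`. When `maf_min > 0` the
#' realised panel minor allele frequency is enforced by construction: sites
#' below the bound have randomly chosen carriers injected (and symmetric
#' capping near fixation), which is also what populates the rare tail of the
#' frequency spectrum.
#'
#' @param n_haplotypes number of panel haplotypes (>= 4).
#' @param n_sites number of biallelic SNP sites (>= 2).
#' @param region_length length of the simulated region in base pairs;
#'   positions are drawn uniformly without replacement and sorted.
#' @param maf_min minimum panel minor allele frequency in `[0, 0.5)`. A
#'   positive value below `1/n_haplotypes` is unrepresentable and rejected.
#' @param n_founders number of founder haplotypes controlling LD strength.
#' @param mosaic_switch_rate per-bp switch intensity of the founder-copying
#'   process.
#' @param seed integer seed; the panel is a pure function of its arguments.
#' @return An object of class `hap_panel`: list with `positions` (strictly
#'   increasing integer bp), `alleles` (`n_haplotypes x n_sites` 0/1 integer
#'   matrix), `site_ids`, `ref`/`alt` nucleotide labels and `region_length`.
#' @examples
#' p <- simulate_panel(20, 50, seed = 1)
#' range(panel_af(p))
#' @export
simulate_panel <- function(n_haplotypes, n_sites, region_length = 1e6,
                           maf_min = 0, n_founders = min(20L, n_haplotypes),
                           mosaic_switch_rate = 5e-6, seed = 1) {
  stopifnot(n_haplotypes >= 4, n_sites >= 2, region_length >= n_sites,
            n_founders >= 2, n_founders <= n_haplotypes)
  if (maf_min < 0 || maf_min >= 0.5)
    stop("maf_min must lie in [0, 0.5)")
  if (maf_min > 0 && maf_min < 1 / n_haplotypes)
    stop("maf_min below 1/n_haplotypes cannot be represented by ",
         n_haplotypes, " haplotypes")
  set.seed(seed)
  K <- as.integer(n_haplotypes)
  M <- as.integer(n_sites)

  positions <- sort(sample.int(region_length, M))
  # inverse-CDF draw from f(p) ~ 1/p on [lo, 0.5]
  lo <- if (maf_min > 0) maf_min else 1 / (2 * K)
  p <- lo * (0.5 / lo)^runif(M)

  founders <- matrix(rbinom(n_founders * M, 1L, rep(p, each = n_founders)),
                     nrow = n_founders, ncol = M)
  if (K > n_founders) {
    rest <- cpp_mosaic_haplotypes(founders, as.numeric(positions),
                                  K - n_founders, mosaic_switch_rate, 0)
    alleles <- rbind(founders, rest)
  } else {
    alleles <- founders[seq_len(K), , drop = FALSE]
  }

  if (maf_min > 0) {
    cmin <- max(1L, as.integer(ceiling(maf_min * K)))
    cnt <- colSums(alleles)
    for (m in which(cnt < cmin)) {
      zero <- which(alleles[, m] == 0L)
      flip <- sample(zero, cmin - cnt[m])
      alleles[flip, m] <- 1L
    }
    for (m in which(cnt > K - cmin)) {
      one <- which(alleles[, m] == 1L)
      flip <- sample(one, cnt[m] - (K - cmin))
      alleles[flip, m] <- 0L
    }
  }
  storage.mode(alleles) <- "integer"

  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  structure(list(positions = as.integer(positions), alleles = alleles,
                 site_ids = sprintf("snp%05d", seq_len(M)),
                 ref = ref, alt = unname(alt),
                 region_length = as.numeric(region_length)),
            class = "hap_panel")
}

#' Panel alternate-allele frequency per site
#' @param panel a `hap_panel`.
#' @return numeric vector of per-site alternate allele frequencies.
#' @export
panel_af <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  unname(colMeans(panel$alleles))
}

#' @export
print.hap_panel <- function(x, ...) {
  af <- panel_af(x)
  cat("Phased haplotype panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites over", format(x$region_length, big.mark = ","),
      "bp\n")
  cat(sprintf("  alt allele frequency: min %.4f, median %.4f, max %.4f\n",
              min(af), stats::median(af), max(af)))
  invisible(x)
}

#' Simulate a diploid target cohort as panel mosaics
#'
#' Each individual receives two haplotypes generated by the Li-Stephens
#' copying process over the panel: the copied source switches between sites
#' with probability `1 - exp(-switch_rate * distance)` (uniform re-draw over
#' the panel) and the copied allele is flipped with probability
#' `mutation_rate`. Targets generated this way lie inside the model class of
#' the imputation HMM, so imputation accuracy must improve with depth.
#'
#' @param panel a `hap_panel`.
#' @param n_individuals cohort size.
#' @param switch_rate per-bp switch probability intensity in `[0, 1]`.
#' @param mutation_rate per-site allele flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @param keep_haplotypes keep the phased haplotype pair per individual.
#' @return An object of class `diploid_geno`: `genotypes`
#'   (`n_individuals x n_sites` matrix over 0/1/2), optionally `haplotypes`
#'   (`2 n x n_sites`, rows 2i-1 and 2i forming individual i), plus site
#'   metadata aligned with the panel.
#' @export
simulate_cohort <- function(panel, n_individuals, switch_rate = 1e-6,
                            mutation_rate = 2e-3, seed = 1,
                            keep_haplotypes = TRUE) {
  stopifnot(inherits(panel, "hap_panel"), n_individuals >= 1,
            switch_rate >= 0, switch_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  set.seed(seed)
  n <- as.integer(n_individuals)
  haps <- cpp_mosaic_haplotypes(panel$alleles, as.numeric(panel$positions),
                                2L * n, switch_rate, mutation_rate)
  geno <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  storage.mode(geno) <- "integer"
  colnames(geno) <- panel$site_ids
  structure(list(genotypes = geno,
                 haplotypes = if (keep_haplotypes) haps else NULL,
                 site_ids = panel$site_ids, positions = panel$positions,
                 ref = panel$ref, alt = panel$alt),
            class = "diploid_geno")
}

#' @export
print.diploid_geno <- function(x, ...) {
  cat("Diploid cohort:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "sites",
      if (is.null(x$haplotypes)) "(unphased)" else "(phased)", "\n")
  invisible(x)
}

#' Subset a cohort to selected individuals
#' @param cohort a `diploid_geno`.
#' @param idx integer indices of individuals to keep.
#' @return a `diploid_geno` restricted to `idx` (order preserved).
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "diploid_geno"),
            all(idx >= 1), all(idx <= nrow(cohort$genotypes)))
  hap <- NULL
  if (!is.null(cohort$haplotypes)) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- cohort$haplotypes[rows, , drop = FALSE]
  }
  structure(list(genotypes = cohort$genotypes[idx, , drop = FALSE],
                 haplotypes = hap, site_ids = cohort$site_ids,
                 positions = cohort$positions, ref = cohort$ref,
                 alt = cohort$alt),
            class = "diploid_geno")
}
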