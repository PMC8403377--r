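#' Squared Pearson correlation between truth and dosage
#'
#' @param truth genotype vector over `{0, 1, 2}`.
#' @param dosage numeric vector of the same length (>= 2).
#' @return squared Pearson correlation, or `NA_real_` when either vector is
#'   constant (undefined, deliberately distinct from 0).
#' @export
pearson_r2 <- function(truth, dosage) {
  if (length(truth) != length(dosage)) stop("length mismatch")
  if (length(truth) < 2) stop("need at least 2 pairs")
  if (sd(truth) == 0 || sd(dosage) == 0) return(NA_real_)
  cor(truth, dosage)^2
}

#' Non-reference discordance rate
#'
#' Among pairs where truth or the imputed best-guess carries at least one
#' alternate allele, the fraction that disagree. Insensitive to the
#' homozygous-reference majority.
#'
#' @param truth genotype vector over `{0, 1, 2}`.
#' @param imputed_bestguess best-guess genotype vector (argmax posterior).
#' @return discordance fraction, or `NA_real_` when no pair qualifies.
#' @export
ndr <- function(truth, imputed_bestguess) {
  if (length(truth) != length(imputed_bestguess)) stop("length mismatch")
  qual <- truth > 0 | imputed_bestguess > 0
  if (!any(qual)) return(NA_real_)
  mean(truth[qual] != imputed_bestguess[qual])
}

#' False positive and false negative rates of alternate-allele detection
#'
#' FPR: among truth homozygous-reference pairs, the fraction imputed with at
#' least one alternate allele. FNR: among truth alternate-carrying pairs,
#' the fraction imputed homozygous reference.
#'
#' @inheritParams ndr
#' @return named numeric vector `c(fpr =, fnr =)`; a component is
#'   `NA_real_` when its denominator is empty.
#' @export
fpr_fnr <- function(truth, imputed_bestguess) {
  if (length(truth) != length(imputed_bestguess)) stop("length mismatch")
  hom_ref <- truth == 0
  fpr <- if (any(hom_ref)) mean(imputed_bestguess[hom_ref] > 0) else NA_real_
  fnr <- if (any(!hom_ref)) mean(imputed_bestguess[!hom_ref] == 0) else
    NA_real_
  c(fpr = fpr, fnr = fnr)
}

#' Best-guess genotypes from posterior probabilities
#'
#' Argmax of the posterior genotype probabilities, ties broken toward the
#' smaller genotype (same convention as [hard_call()]).
#'
#' @param dosages an `imputed_dosages` object.
#' @return integer matrix of best-guess genotypes.
#' @export
best_guess <- function(dosages) {
  stopifnot(inherits(dosages, "imputed_dosages"))
  d <- dim(dosages$gp)
  flat <- matrix(dosages$gp, d[1] * d[2], 3L)
  bg <- max.col(flat, ties.method = "first") - 1L
  dim(bg) <- d[1:2]
  bg
}

#' Allele-frequency bins
#'
#' Default interior edges 0.5% and 5% define the conventional rare
#' (`AF < 0.5%`), low (`0.5% <= AF < 5%`) and common (`AF >= 5%`) strata of
#' non-reference allele frequency.
#'
#' @param edges strictly increasing interior edges in `(0, 1)`.
#' @param labels one label per bin (`length(edges) + 1`).
#' @return an object of class `af_bins`.
#' @export
af_bins <- function(edges = c(0.005, 0.05),
                    labels = c("rare", "low", "common")) {
  stopifnot(all(diff(edges) > 0), all(edges > 0), all(edges < 1),
            length(labels) == length(edges) + 1)
  structure(list(edges = edges, labels = labels), class = "af_bins")
}

#' Assign allele frequencies to bins
#' @param af numeric vector of non-reference allele frequencies.
#' @param bins an [af_bins()] object.
#' @return factor of bin labels (left-closed, right-open intervals).
#' @export
bin_af <- function(af, bins = af_bins()) {
  stopifnot(inherits(bins, "af_bins"))
  cut(af, breaks = c(-Inf, bins$edges, Inf), labels = bins$labels,
      right = FALSE)
}

#' Per-SNP squared correlations
#' @param truth genotype matrix (individuals x sites).
#' @param dosages dosage matrix of the same shape.
#' @return numeric vector of per-site `pearson_r2` values (`NA` where
#'   undefined).
#' @export
per_snp_r2 <- function(truth, dosages) {
  stopifnot(all(dim(truth) == dim(dosages)))
  vapply(seq_len(ncol(truth)),
         function(m) pearson_r2(truth[, m], dosages[, m]), numeric(1))
}

#' Aggregate imputation accuracy per allele-frequency bin
#'
#' For each bin reports both the pooled aggregate R-squared (all
#' individual-by-site pairs in the bin concatenated) and the mean and SD of
#' per-SNP R-squared over SNPs where it is defined, plus the SNP count.
#' Both flavours are emitted because "aggregate R2" conventionally means the
#' pooled value while a reported SD implies a per-SNP distribution.
#'
#' @param truth genotype matrix (individuals x sites).
#' @param dosages dosage matrix of the same shape.
#' @param afs per-site non-reference allele frequency from the designated
#'   AF reference (truth cohort or panel).
#' @param bins an [af_bins()] object.
#' @return data frame with one row per bin: `bin`, `n` (SNPs), `pooled_r2`,
#'   `mean_r2`, `sd_r2`, `n_defined` (SNPs with defined per-SNP R2). Empty
#'   bins keep `n = 0` and `NA` statistics.
#' @export
aggregate_r2_by_bin <- function(truth, dosages, afs, bins = af_bins()) {
  stopifnot(all(dim(truth) == dim(dosages)), length(afs) == ncol(truth))
  fac <- bin_af(afs, bins)
  res <- lapply(levels(fac), function(lv) {
    s <- which(fac == lv)
    if (!length(s))
      return(data.frame(bin = lv, n = 0L, pooled_r2 = NA_real_,
                        mean_r2 = NA_real_, sd_r2 = NA_real_,
                        n_defined = 0L))
    pooled <- pearson_r2(as.vector(truth[, s, drop = FALSE]),
                         as.vector(dosages[, s, drop = FALSE]))
    r2 <- per_snp_r2(truth[, s, drop = FALSE], dosages[, s, drop = FALSE])
    ok <- !is.na(r2)
    data.frame(bin = lv, n = length(s), pooled_r2 = pooled,
               mean_r2 = if (any(ok)) mean(r2[ok]) else NA_real_,
               sd_r2 = if (sum(ok) > 1) sd(r2[ok]) else NA_real_,
               n_defined = sum(ok))
  })
  out <- do.call(rbind, res)
  out$bin <- factor(out$bin, levels = bins$labels)
  out
}

#' Fraction of SNPs more accurately imputed on platform A
#'
#' Restricted to shared SNPs where the better of the two per-SNP R-squared
#' values exceeds `quality_threshold` (high-quality SNPs), the fraction
#' where platform A strictly beats platform B. Ties are never "more
#' accurate": they stay in the denominator but not the numerator. Pairs
#' with an undefined R2 on either platform are excluded.
#'
#' @param per_snp_r2_a,per_snp_r2_b aligned per-SNP R-squared vectors.
#' @param quality_threshold restriction threshold (default 0.8).
#' @return fraction in `[0, 1]`, or `NA_real_` when no SNP qualifies.
#' @export
fraction_more_accurate <- function(per_snp_r2_a, per_snp_r2_b,
                                   quality_threshold = 0.8) {
  if (length(per_snp_r2_a) != length(per_snp_r2_b)) stop("length mismatch")
  ok <- !is.na(per_snp_r2_a) & !is.na(per_snp_r2_b)
  a <- per_snp_r2_a[ok]; b <- per_snp_r2_b[ok]
  qual <- pmax(a, b) > quality_threshold
  if (!any(qual)) return(NA_real_)
  mean(a[qual] > b[qual])
}

#' Full genotype-concordance report for one imputation arm
#'
#' Pools all individual-by-site pairs for the overall Pearson R-squared and
#' computes NDR, FPR and FNR on the best-guess genotypes, plus the
#' AF-stratified aggregate-R2 table and the per-SNP R2 vector.
#'
#' @param truth a `diploid_geno` or genotype matrix covering the evaluated
#'   sites.
#' @param dosages an `imputed_dosages` object.
#' @param afs per-site allele frequency of the evaluated sites (AF
#'   reference).
#' @param sites integer indices of evaluated sites (default: all, typically
#'   the INFO-filtered set).
#' @param bins an [af_bins()] object.
#' @return An object of class `concordance_report` with fields
#'   `r2_overall`, `ndr`, `fpr`, `fnr`, `per_bin`, `per_snp_r2`, `sites`
#'   and `n_individuals`.
#' @export
concordance_report <- function(truth, dosages, afs, sites = NULL,
                               bins = af_bins()) {
  stopifnot(inherits(dosages, "imputed_dosages"))
  G <- if (inherits(truth, "diploid_geno")) truth$genotypes else
    as.matrix(truth)
  stopifnot(nrow(G) == nrow(dosages$ds))
  sites <- sites %||% seq_len(ncol(dosages$ds))
  stopifnot(length(afs) == ncol(G))
  Gt <- G[, sites, drop = FALSE]
  ds <- dosages$ds[, sites, drop = FALSE]
  bg <- best_guess(dosages)[, sites, drop = FALSE]
  rates <- fpr_fnr(as.vector(Gt), as.vector(bg))
  structure(list(
    r2_overall = pearson_r2(as.vector(Gt), as.vector(ds)),
    ndr = ndr(as.vector(Gt), as.vector(bg)),
    fpr = unname(rates["fpr"]), fnr = unname(rates["fnr"]),
    per_bin = aggregate_r2_by_bin(Gt, ds, afs[sites], bins),
    per_snp_r2 = stats::setNames(per_snp_r2(Gt, ds),
                                 dosages$site_ids[sites]),
    sites = sites, n_individuals = nrow(Gt)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "Concordance over %d sites x %d individuals:\n  R2 = %.4f, NDR = %.4f, FPR = %.4f, FNR = %.4f\n",
    length(x$sites), x$n_individuals, x$r2_overall, x$ndr, x$fpr, x$fnr))
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}
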