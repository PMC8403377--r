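#' Extract an effect-allele-countable dosage matrix
#'
#' Accepts an `imputed_dosages` (expected dosages), `diploid_geno` (true
#' genotypes), `called_geno` (fixed calls, `NA` at no-calls) or a plain
#' matrix with site-id column names, and returns a numeric matrix with site
#' ids as column names.
#' @param x genotype/dosage container.
#' @return numeric matrix (individuals x sites).
#' @export
as_dosage_matrix <- function(x) {
  if (inherits(x, "imputed_dosages")) {
    m <- x$ds; colnames(m) <- x$site_ids
  } else if (inherits(x, "diploid_geno")) {
    m <- x$genotypes; colnames(m) <- x$site_ids
  } else if (inherits(x, "called_geno")) {
    m <- x$calls; colnames(m) <- x$site_ids
  } else if (is.matrix(x)) {
    if (is.null(colnames(x))) stop("matrix input needs site-id colnames")
    m <- x
  } else stop("unsupported dosage container: ", class(x)[1])
  storage.mode(m) <- "double"
  m
}

#' Polygenic risk score: weighted effect-allele count
#'
#' `PRS_i = sum_k w_k X_ik` over the requested SNP subset, where `X` is the
#' effect-allele dosage: the alternate-allele dosage when the recorded
#' effect allele is the alternate, and `2 - dosage` when it is the
#' reference. SNPs in the subset but absent from the data are skipped with
#' a message (set `missing_action = "error"` to forbid this); entry-level
#' missing genotypes contribute the site mean when
#' `missing_entry = "mean"` (default) or zero when `"zero"`.
#'
#' @param x dosage/genotype container (see [as_dosage_matrix()]).
#' @param weights a `gwas_weights` table.
#' @param snp_subset site ids to score (default: every SNP in `weights`).
#' @param model label stored on the result.
#' @param missing_action `"skip"` (log and drop) or `"error"` for subset
#'   SNPs absent from the data.
#' @param missing_entry handling of `NA` genotype entries.
#' @param quiet suppress the skipped-site message.
#' @return An object of class `prs_result`: `score` (raw), `normalized`
#'   (`NULL` until [normalize_scores()]), `model`, `snps` used and
#'   `skipped`.
#' @export
compute_prs <- function(x, weights, snp_subset = NULL, model = "unadjusted",
                        missing_action = c("skip", "error"),
                        missing_entry = c("mean", "zero"), quiet = FALSE) {
  stopifnot(inherits(weights, "gwas_weights"))
  missing_action <- match.arg(missing_action)
  missing_entry <- match.arg(missing_entry)
  m <- as_dosage_matrix(x)
  snp_subset <- snp_subset %||% weights$site_id
  bad <- setdiff(snp_subset, weights$site_id)
  if (length(bad))
    stop("subset SNPs absent from the weight table: ",
         paste(utils::head(bad, 5), collapse = ", "))
  missing <- setdiff(snp_subset, colnames(m))
  if (length(missing)) {
    if (missing_action == "error")
      stop(length(missing), " subset SNPs absent from the data")
    if (!quiet)
      message("compute_prs: skipping ", length(missing),
              " SNP(s) absent from the data")
  }
  use <- intersect(snp_subset, colnames(m))
  if (!length(use))
    stop("no scoreable SNPs remain (upstream filtering removed all SNPs)")
  w <- weights[match(use, weights$site_id), ]
  X <- m[, use, drop = FALSE]
  if (anyNA(X)) {
    if (missing_entry == "mean") {
      mu <- colMeans(X, na.rm = TRUE)
      mu[is.nan(mu)] <- 0
      for (j in which(colSums(is.na(X)) > 0))
        X[is.na(X[, j]), j] <- mu[j]
    } else X[is.na(X)] <- 0
  }
  flip <- w$effect_allele == "ref"
  if (any(flip)) X[, flip] <- 2 - X[, flip]
  score <- as.vector(X %*% w$weight)
  structure(list(score = score, normalized = NULL, model = model,
                 snps = use, skipped = missing),
            class = "prs_result")
}

#' Mean-zero normalization of PRS
#' @param result a `prs_result` with at least one individual.
#' @return the same object with `normalized = score - mean(score)`.
#' @export
normalize_scores <- function(result) {
  stopifnot(inherits(result, "prs_result"), length(result$score) >= 1)
  result$normalized <- result$score - mean(result$score)
  result
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("PRS [%s]: %d individuals, %d SNPs", x$model,
              length(x$score), length(x$snps)))
  if (length(x$skipped)) cat(sprintf(" (%d skipped)", length(x$skipped)))
  cat(sprintf("\n  raw score: mean %.4f, sd %.4f%s\n", mean(x$score),
              sd(x$score),
              if (is.null(x$normalized)) "" else " (normalized to mean 0)"))
  invisible(x)
}

#' Greedy LD clumping of a weight table
#'
#' Visits SNPs by ascending P-value (ties broken by position) and keeps a
#' SNP unless its squared genotype correlation with an already-kept SNP is
#' at or above `r2_threshold` — i.e. the less significant member of a
#' correlated pair is excluded. Monomorphic reference columns count as
#' uncorrelated.
#'
#' @param reference_genotypes LD reference: any container accepted by
#'   [as_dosage_matrix()] covering the weighted SNPs.
#' @param weights a `gwas_weights` table.
#' @param r2_threshold squared-correlation exclusion threshold (default
#'   0.5).
#' @return character vector of retained site ids (in ascending-P order).
#' @export
ld_clump <- function(reference_genotypes, weights, r2_threshold = 0.5) {
  stopifnot(inherits(weights, "gwas_weights"),
            r2_threshold >= 0, r2_threshold <= 1)
  m <- as_dosage_matrix(reference_genotypes)
  if (!all(weights$site_id %in% colnames(m)))
    stop("LD reference does not cover all weighted SNPs")
  pos <- seq_len(nrow(weights))
  ord <- order(weights$p_value, pos)
  kept <- character(0)
  kept_cols <- NULL
  for (k in ord) {
    id <- weights$site_id[k]
    x <- m[, id]
    ok <- TRUE
    if (length(kept) && sd(x) > 0) {
      r <- suppressWarnings(cor(x, kept_cols))
      r[is.na(r)] <- 0
      if (any(r^2 >= r2_threshold)) ok <- FALSE
    }
    if (ok) {
      kept <- c(kept, id)
      kept_cols <- cbind(kept_cols, x)
    }
  }
  kept
}

#' Default P-value threshold grid for P+T
#'
#' Spans 5e-2 down to 1e-20.
#' @return numeric vector of thresholds.
#' @export
default_p_thresholds <- function() {
  c(5e-2, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6, 1e-8, 1e-10, 1e-12, 1e-15, 1e-20)
}

#' Clumping + thresholding (P+T) polygenic score
#'
#' Clumps once against the LD reference, then for each P-value threshold
#' restricts to clumped SNPs with `p < threshold`, scores, normalizes and
#' evaluates the AUC against the case/control labels. Returns the
#' best-threshold score together with the full per-threshold AUC table. A
#' threshold retaining zero SNPs is recorded with a `NA` AUC, not an
#' error. Ties on the best AUC resolve to the most inclusive (largest)
#' threshold.
#'
#' @param dosages dosage/genotype container to score.
#' @param weights a `gwas_weights` table.
#' @param labels binary case/control labels (or a `phenotype_set`).
#' @param thresholds non-empty P-value threshold vector.
#' @param ld_reference LD reference for clumping (default: the scored
#'   dosages themselves).
#' @param r2_threshold clumping threshold (default 0.5).
#' @return A list of class `p_plus_t`: `best_threshold`, `best_auc`,
#'   `best_result` (normalized `prs_result`), `auc_table`
#'   (threshold, n_snps, auc) and `clumped` site ids.
#' @export
p_plus_t <- function(dosages, weights, labels,
                     thresholds = default_p_thresholds(),
                     ld_reference = dosages, r2_threshold = 0.5) {
  stopifnot(length(thresholds) >= 1)
  if (inherits(labels, "phenotype_set")) labels <- labels$label
  thresholds <- sort(thresholds, decreasing = TRUE)
  clumped <- ld_clump(ld_reference, weights, r2_threshold)
  m <- as_dosage_matrix(dosages)
  rows <- lapply(thresholds, function(th) {
    set <- clumped[weights$p_value[match(clumped, weights$site_id)] < th]
    set <- intersect(set, colnames(m))
    if (!length(set))
      return(list(res = NULL,
                  row = data.frame(threshold = th, n_snps = 0L,
                                   auc = NA_real_)))
    res <- normalize_scores(compute_prs(dosages, weights, set,
                                        model = sprintf("P+T@%g", th),
                                        quiet = TRUE))
    a <- auc(res$normalized, labels, ci = FALSE)
    list(res = res, row = data.frame(threshold = th,
                                     n_snps = length(set), auc = a$auc))
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (all(is.na(tab$auc))) stop("no threshold retained any SNPs")
  best <- which.max(tab$auc)  # first max: most inclusive threshold
  structure(list(best_threshold = tab$threshold[best],
                 best_auc = tab$auc[best],
                 best_result = rows[[best]]$res,
                 auc_table = tab, clumped = clumped),
            class = "p_plus_t")
}

#' @export
print.p_plus_t <- function(x, ...) {
  cat(sprintf("P+T: best threshold %g (AUC %.3f, %d SNPs of %d clumped)\n",
              x$best_threshold, x$best_auc,
              x$auc_table$n_snps[x$auc_table$threshold == x$best_threshold],
              length(x$clumped)))
  print(x$auc_table, row.names = FALSE)
  invisible(x)
}
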