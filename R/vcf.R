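vcf_header <- function(format_lines, info_lines = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=lpsprs",
    "##contig=<ID=1>",
    info_lines,
    format_lines)
}

vcf_fix <- function(x, sites = seq_along(x$site_ids)) {
  data.frame(CHROM = "1", POS = x$positions[sites], ID = x$site_ids[sites],
             REF = x$ref[sites], ALT = x$alt[sites], QUAL = ".",
             FILTER = "PASS", stringsAsFactors = FALSE)
}

write_vcf_body <- function(path, header, fix, info, format, body,
                           sample_names) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_names), collapse = "\t"), con)
  lines <- paste(fix$CHROM, fix$POS, fix$ID, fix$REF, fix$ALT, fix$QUAL,
                 fix$FILTER, info, format,
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write package objects as VCF
#'
#' Plain-text VCFv4.2 emission for the pipeline's containers: a phased
#' panel writes `GT` with `|` separators over pseudo-individuals (pairs of
#' haplotypes; the panel must hold an even number), a cohort writes
#' unphased `GT`, genotype likelihoods write `GT:PL:DP` (PL in the scaled
#' integer convention `round(-10 log10 L / Lmax)`), fixed calls write `GT`
#' with `./.` at no-calls (array routes produce a sites-only VCF), and
#' imputed dosages write `GT:DS:GP` (DS and GP to 3 decimals) plus an
#' `R2=` INFO field carrying the imputation INFO score.
#'
#' @param x object to write.
#' @param path output file path.
#' @param ... unused.
#' @return the path, invisibly.
#' @export
write_vcf <- function(x, path, ...) UseMethod("write_vcf")

#' @rdname write_vcf
#' @export
write_vcf.hap_panel <- function(x, path, ...) {
  K <- nrow(x$alleles)
  if (K %% 2 != 0)
    stop("panel VCF needs an even number of haplotypes to form individuals")
  a <- t(x$alleles)  # sites x haplotypes
  gt <- matrix(paste(a[, seq(1, K, 2)], a[, seq(2, K, 2)], sep = "|"),
               nrow = ncol(x$alleles))
  write_vcf_body(path,
                 vcf_header('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
                 vcf_fix(x), ".", "GT", gt,
                 sprintf("PANEL%04d", seq_len(K / 2)))
}

gt_string <- function(g, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  out <- rep("./.", length(g))
  ok <- !is.na(g)
  out[ok & g == 0] <- paste0("0", sep, "0")
  out[ok & g == 1] <- paste0("0", sep, "1")
  out[ok & g == 2] <- paste0("1", sep, "1")
  out
}

#' @rdname write_vcf
#' @export
write_vcf.diploid_geno <- function(x, path, ...) {
  gt <- apply(x$genotypes, 1, gt_string)  # sites x individuals
  write_vcf_body(path,
                 vcf_header('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
                 vcf_fix(x), ".", "GT", gt,
                 sprintf("IND%04d", seq_len(nrow(x$genotypes))))
}

#' @rdname write_vcf
#' @export
write_vcf.called_geno <- function(x, path, ...) {
  gt <- apply(x$calls, 1, gt_string)
  write_vcf_body(path,
                 vcf_header('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
                 data.frame(CHROM = "1", POS = x$positions, ID = x$site_ids,
                            REF = x$ref, ALT = x$alt, QUAL = ".",
                            FILTER = "PASS", stringsAsFactors = FALSE),
                 ".", "GT", gt, sprintf("IND%04d", seq_len(nrow(x$calls))))
}

#' @rdname write_vcf
#' @export
write_vcf.geno_lik <- function(x, path, ...) {
  n <- dim(x$loglik)[1]; M <- dim(x$loglik)[2]
  mx <- pmax(x$loglik[, , 1], x$loglik[, , 2], x$loglik[, , 3])
  pl <- lapply(1:3, function(g)
    round(-10 / log(10) * (x$loglik[, , g] - mx)))
  calls <- hard_call(x, min_depth = 1)$calls
  body <- matrix("", M, n)
  for (i in seq_len(n)) {
    body[, i] <- sprintf("%s:%d,%d,%d:%d", gt_string(calls[i, ]),
                         pl[[1]][i, ], pl[[2]][i, ], pl[[3]][i, ],
                         x$depth[i, ])
  }
  hdr <- vcf_header(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=PL,Number=G,Type=Integer,Description="Phred-scaled genotype likelihoods">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'))
  write_vcf_body(path, hdr, vcf_fix(x), ".", "GT:PL:DP", body,
                 sprintf("IND%04d", seq_len(n)))
}

#' @rdname write_vcf
#' @export
write_vcf.imputed_dosages <- function(x, path, ...) {
  n <- nrow(x$ds); M <- ncol(x$ds)
  bg <- best_guess(x)
  body <- matrix("", M, n)
  for (i in seq_len(n)) {
    body[, i] <- sprintf("%s:%.3f:%.3f,%.3f,%.3f", gt_string(bg[i, ]),
                         x$ds[i, ], x$gp[i, , 1], x$gp[i, , 2],
                         x$gp[i, , 3])
  }
  hdr <- vcf_header(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Best-guess genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Expected alternate allele dosage">',
    '##FORMAT=<ID=GP,Number=G,Type=Float,Description="Posterior genotype probabilities">'),
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation INFO score (MaCH r-hat squared)">')
  info <- if (all(is.na(x$info))) rep(".", M) else sprintf("R2=%.4f", x$info)
  write_vcf_body(path, hdr, vcf_fix(x), info, "GT:DS:GP", body,
                 sprintf("IND%04d", seq_len(n)))
}

parse_gt_matrix <- function(gt) {
  # vcfR gives variants x samples character matrix
  g <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- sub(":.*", "", gt)
  g[clean %in% c("0/0", "0|0")] <- 0L
  g[clean %in% c("0/1", "0|1", "1/0", "1|0")] <- 1L
  g[clean %in% c("1/1", "1|1")] <- 2L
  g
}

#' Read a biallelic SNP VCF
#'
#' Parses a VCF through `vcfR` and returns the typed tables the pipeline
#' stages consume. Multiallelic or indel records are rejected with their
#' positions. Fields are extracted when present: `GT` (numeric genotypes,
#' `NA` at no-calls, plus phased haplotypes when every record uses `|`),
#' `PL` (converted back to natural-log genotype likelihoods), `DS`, `GP`
#' and `DP`.
#'
#' @param path VCF file path.
#' @return A list of class `lps_vcf`: `positions`, `site_ids`, `ref`,
#'   `alt`, `n_individuals`, `sample_names`, and matrices/arrays
#'   (individuals x sites) among `gt`, `haplotypes`, `loglik`, `dp`, `ds`,
#'   `gp`, `info_r2` depending on the file's FORMAT fields.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bad <- nchar(ref) != 1 | nchar(alt) != 1 | grepl(",", alt)
  if (any(bad))
    stop("multiallelic or indel records at position(s): ",
         paste(utils::head(fix[bad, "POS"], 5), collapse = ", "))
  out <- list(positions = as.integer(fix[, "POS"]),
              site_ids = fix[, "ID"], ref = ref, alt = alt)
  fields <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  samples <- colnames(v@gt)[-1]
  out$sample_names <- samples
  out$n_individuals <- length(samples)

  if ("GT" %in% fields) {
    raw <- vcfR::extract.gt(v, "GT")
    out$gt <- t(parse_gt_matrix(raw))
    if (all(grepl("\\|", raw))) {
      M <- nrow(raw); n <- ncol(raw)
      hap <- matrix(NA_integer_, 2 * n, M)
      a1 <- substr(raw, 1, 1); a2 <- substr(raw, 3, 3)
      hap[seq(1, 2 * n, 2), ] <- t(matrix(as.integer(a1), M, n))
      hap[seq(2, 2 * n, 2), ] <- t(matrix(as.integer(a2), M, n))
      out$haplotypes <- hap
    }
  }
  if ("PL" %in% fields) {
    pl <- vcfR::extract.gt(v, "PL")
    M <- nrow(pl); n <- ncol(pl)
    parts <- strsplit(as.vector(pl), ",")
    arr <- array(NA_real_, c(n, M, 3L))
    for (g in 1:3) {
      vals <- as.numeric(vapply(parts, `[`, character(1), g))
      arr[, , g] <- t(matrix(vals, M, n))
    }
    out$loglik <- -arr / 10 * log(10)
  }
  if ("DP" %in% fields)
    out$dp <- t(matrix(as.integer(vcfR::extract.gt(v, "DP")),
                       nrow(v@gt), length(samples)))
  if ("DS" %in% fields)
    out$ds <- t(matrix(as.numeric(vcfR::extract.gt(v, "DS")),
                       nrow(v@gt), length(samples)))
  if ("GP" %in% fields) {
    gp <- vcfR::extract.gt(v, "GP")
    M <- nrow(gp); n <- ncol(gp)
    parts <- strsplit(as.vector(gp), ",")
    arr <- array(NA_real_, c(n, M, 3L))
    for (g in 1:3)
      arr[, , g] <- t(matrix(as.numeric(vapply(parts, `[`, character(1),
                                               g)), M, n))
    out$gp <- arr
  }
  r2 <- vcfR::extract.info(v, "R2")
  if (!is.null(r2) && !all(is.na(r2))) out$info_r2 <- as.numeric(r2)
  class(out) <- "lps_vcf"
  out
}

#' Rebuild a haplotype panel from a phased VCF
#' @param vcf an `lps_vcf` with phased haplotypes.
#' @param region_length optional region length (defaults to the position
#'   span).
#' @return a `hap_panel`.
#' @export
as_hap_panel <- function(vcf, region_length = NULL) {
  stopifnot(inherits(vcf, "lps_vcf"))
  if (is.null(vcf$haplotypes)) stop("VCF is not fully phased")
  structure(list(positions = vcf$positions, alleles = vcf$haplotypes,
                 site_ids = vcf$site_ids, ref = vcf$ref, alt = vcf$alt,
                 region_length = region_length %||% max(vcf$positions)),
            class = "hap_panel")
}

#' Rebuild genotype likelihoods from a VCF with PL
#' @param vcf an `lps_vcf` carrying `PL` (and ideally `DP`).
#' @param error_rate the per-base error the likelihoods were built with.
#' @return a `geno_lik`.
#' @export
as_geno_lik <- function(vcf, error_rate = 0.01) {
  stopifnot(inherits(vcf, "lps_vcf"))
  if (is.null(vcf$loglik))
    stop("VCF lacks the PL field required for genotype-likelihood mode")
  depth <- vcf$dp %||%
    matrix(1L, dim(vcf$loglik)[1], dim(vcf$loglik)[2])
  structure(list(loglik = vcf$loglik, depth = depth,
                 error_rate = error_rate, site_ids = vcf$site_ids,
                 positions = vcf$positions, ref = vcf$ref, alt = vcf$alt),
            class = "geno_lik")
}

#' Rebuild fixed calls from a VCF with GT
#' @param vcf an `lps_vcf` carrying `GT`.
#' @return a `called_geno`.
#' @export
as_called_geno <- function(vcf) {
  stopifnot(inherits(vcf, "lps_vcf"))
  if (is.null(vcf$gt))
    stop("VCF lacks the GT field required for hard-call mode")
  structure(list(calls = vcf$gt, site_index = seq_along(vcf$site_ids),
                 site_ids = vcf$site_ids, positions = vcf$positions,
                 ref = vcf$ref, alt = vcf$alt),
            class = "called_geno")
}

#' Write a GWAS weight table as TSV
#'
#' Standard four-column interchange (`site_id`, `effect_allele`, `weight`,
#' `p_value`); simulation truth columns are not exported.
#' @param weights a `gwas_weights` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "gwas_weights"))
  write.table(weights[, c("site_id", "effect_allele", "weight", "p_value")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS weight table from TSV
#' @param path TSV with columns `site_id`, `effect_allele`, `weight`,
#'   `p_value`.
#' @return a `gwas_weights` table (truth columns `NA`, `h2` attribute
#'   `NA`).
#' @export
read_weights <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("site_id", "effect_allele", "weight", "p_value")
  if (!all(need %in% names(df)))
    stop("weight TSV must contain columns: ", paste(need, collapse = ", "))
  stopifnot(all(df$p_value > 0), all(df$p_value <= 1))
  out <- df[, need]
  out$is_causal <- NA
  out$true_beta <- NA_real_
  out$af <- NA_real_
  attr(out, "h2") <- NA_real_
  class(out) <- c("gwas_weights", "data.frame")
  out
}
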