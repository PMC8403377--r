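#' Copying-model parameters for the imputation HMM
#'
#' @param switch_rate per-bp copying switch intensity; the per-interval
#'   switch probability is `1 - exp(-switch_rate * distance)`. `NULL` means
#'   "one expected switch per region per haplotype", i.e. the reciprocal of
#'   the panel's position span, resolved when the HMM runs.
#' @param miscopy_rate per-allele copying error; `NULL` resolves to `1/K`
#'   for a panel of `K` haplotypes, following common Li-Stephens practice.
#' @param call_error genotype-observation error for hard-call emissions:
#'   a called genotype has likelihood `1 - call_error`, each other genotype
#'   `call_error / 2`.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(switch_rate = NULL, miscopy_rate = NULL,
                       call_error = 0.01) {
  if (!is.null(switch_rate)) stopifnot(switch_rate >= 0, switch_rate <= 1)
  if (!is.null(miscopy_rate)) stopifnot(miscopy_rate >= 0, miscopy_rate <= 1)
  stopifnot(call_error >= 0, call_error <= 1)
  structure(list(switch_rate = switch_rate, miscopy_rate = miscopy_rate,
                 call_error = call_error),
            class = "hmm_params")
}

resolve_params <- function(params, panel) {
  span <- diff(range(panel$positions))
  list(switch_rate = params$switch_rate %||% (1 / max(span, 1)),
       miscopy_rate = params$miscopy_rate %||% (1 / nrow(panel$alleles)),
       call_error = params$call_error)
}

# Shared engine: lik is an n x M_panel x 3 linear-scale emission array
# aligned with the panel's site grid.
run_diploid_hmm <- function(lik, panel, params, mode) {
  pp <- resolve_params(params, panel)
  if (nrow(panel$alleles) < 2)
    stop("panel must contain at least 2 haplotypes")
  gp <- cpp_diploid_fb(panel$alleles, as.numeric(panel$positions), lik,
                       pp$switch_rate, pp$miscopy_rate)
  ds <- gp[, , 2, drop = FALSE][, , 1] + 2 * gp[, , 3, drop = FALSE][, , 1]
  if (is.null(dim(ds))) ds <- matrix(ds, dim(gp)[1], dim(gp)[2])
  out <- structure(list(gp = gp, ds = ds, info = NULL,
                        site_ids = panel$site_ids,
                        positions = panel$positions,
                        ref = panel$ref, alt = panel$alt,
                        mode = mode, params = pp),
                   class = "imputed_dosages")
  out$info <- if (nrow(ds) >= 2) info_score(out) else
    rep(NA_real_, ncol(ds))
  out
}

# Map likelihoods observed at a subset of sites onto the panel grid;
# unobserved sites get flat (uninformative) emissions.
expand_lik <- function(lin, site_ids, panel) {
  idx <- match(site_ids, panel$site_ids)
  if (anyNA(idx))
    stop("sites absent from the panel: ",
         paste(utils::head(site_ids[is.na(idx)], 5), collapse = ", "))
  n <- dim(lin)[1]
  M <- length(panel$site_ids)
  full <- array(1, c(n, M, 3L))
  full[, idx, ] <- lin
  full
}

#' Impute from genotype likelihoods (GL-emission mode)
#'
#' Runs the exact diploid forward-backward over the panel with emissions
#' `sum_g' P(g' | copied genotype, miscopy) L(g')`, where `L` are the
#' observed genotype likelihoods. This is the genotype-likelihood-aware
#' route: read-level uncertainty is propagated instead of being collapsed
#' into a fixed call, which is what keeps accuracy high at ultra-low depth.
#' Sites on the panel grid without likelihoods receive flat emissions and
#' are imputed from the copying prior.
#'
#' @param gl a `geno_lik` object whose sites are a subset of the panel's.
#' @param panel a `hap_panel` with at least 2 haplotypes.
#' @param params an [hmm_params()] object.
#' @return An object of class `imputed_dosages`: `gp`
#'   (individuals x sites x 3 posterior genotype probabilities summing to
#'   1), `ds` (expected alternate-allele dosage in `[0, 2]`), per-site
#'   `info` score, site metadata, `mode` and the resolved `params`.
#' @export
impute_gl <- function(gl, panel, params = hmm_params()) {
  stopifnot(inherits(gl, "geno_lik"), inherits(panel, "hap_panel"),
            inherits(params, "hmm_params"))
  ll <- gl$loglik
  mx <- pmax(ll[, , 1], ll[, , 2], ll[, , 3])
  lin <- array(NA_real_, dim(ll))
  for (g in 1:3) lin[, , g] <- exp(ll[, , g] - mx)
  run_diploid_hmm(expand_lik(lin, gl$site_ids, panel), panel, params, "gl")
}

#' Impute from fixed genotype calls (hard-call emission mode)
#'
#' Identical HMM to [impute_gl()], but the emission is built from fixed
#' calls: the called genotype has likelihood `1 - call_error`, each other
#' genotype `call_error / 2`, and missing or untyped sites are
#' uninformative. The contrast with GL emissions isolates why fixed calls
#' from ultra-low-pass reads mislead traditional imputation.
#'
#' @param calls a `called_geno` object (possibly typed on a site subset,
#'   e.g. an array route).
#' @param panel a `hap_panel`.
#' @param params an [hmm_params()] object.
#' @return an `imputed_dosages` object (see [impute_gl()]).
#' @export
impute_hardcall <- function(calls, panel, params = hmm_params()) {
  stopifnot(inherits(calls, "called_geno"), inherits(panel, "hap_panel"),
            inherits(params, "hmm_params"))
  theta <- params$call_error
  cm <- calls$calls
  n <- nrow(cm); Msub <- ncol(cm)
  lin <- array(theta / 2, c(n, Msub, 3L))
  for (g in 0:2) {
    hit <- !is.na(cm) & cm == g
    lin[, , g + 1][hit] <- 1 - theta
  }
  miss <- is.na(cm)
  for (g in 1:3) lin[, , g][miss] <- 1
  run_diploid_hmm(expand_lik(lin, calls$site_ids, panel), panel, params,
                  "hardcall")
}

#' @export
print.imputed_dosages <- function(x, ...) {
  cat(sprintf(
    "Imputed dosages (%s emissions): %d individuals x %d sites\n",
    x$mode, nrow(x$ds), ncol(x$ds)))
  if (!all(is.na(x$info)))
    cat(sprintf("  INFO score: median %.3f, %.1f%% of sites >= 0.3\n",
                stats::median(x$info, na.rm = TRUE),
                100 * mean(x$info >= 0.3, na.rm = TRUE)))
  invisible(x)
}

#' MaCH-style imputation INFO score
#'
#' `r-hat^2 = Var(DS) / (2 p (1 - p))` with `p = mean(DS) / 2`, using the
#' population (divide-by-n) variance across individuals, defined as 0 when
#' `p` is 0 or 1 and clipped to `[0, 1]`.
#'
#' @param dosages an `imputed_dosages` object or a dosage matrix
#'   (individuals x sites) with at least 2 rows.
#' @param sites optional site indices (default: all sites).
#' @return numeric vector of INFO scores in `[0, 1]`.
#' @export
info_score <- function(dosages, sites = NULL) {
  ds <- if (inherits(dosages, "imputed_dosages")) dosages$ds else
    as.matrix(dosages)
  if (nrow(ds) < 2) stop("INFO score needs at least 2 individuals")
  if (!is.null(sites)) ds <- ds[, sites, drop = FALSE]
  mu <- colMeans(ds)
  p <- mu / 2
  v <- colMeans(ds^2) - mu^2
  out <- ifelse(p <= 0 | p >= 1, 0, v / (2 * p * (1 - p)))
  pmin(pmax(out, 0), 1)
}

#' Retain sites passing the INFO-score filter
#'
#' Sites with INFO strictly below the threshold are removed; a site at
#' exactly the threshold is retained (default threshold 0.3).
#'
#' @param dosages an `imputed_dosages` object.
#' @param threshold INFO threshold in `[0, 1]`.
#' @return named integer vector of retained site indices (names are site
#'   ids).
#' @export
filter_by_info <- function(dosages, threshold = 0.3) {
  stopifnot(inherits(dosages, "imputed_dosages"),
            threshold >= 0, threshold <= 1)
  keep <- which(!is.na(dosages$info) & dosages$info >= threshold)
  names(keep) <- dosages$site_ids[keep]
  keep
}
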