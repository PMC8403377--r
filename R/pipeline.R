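#' Experiment configuration
#'
#' One validated, serializable object describes a full synthetic
#' experiment: panel and cohort simulation, the depth grid with both
#' imputation modes and the array route, the concordance panel, and
#' (optionally) the case/control PRS study. `NA` for `hmm_switch_rate` or
#' `miscopy_rate` means "resolve at run time" (cohort switch rate and
#' `1/K` respectively). See [default_concordance_config()] and
#' [default_prs_config()] for the two study presets.
#'
#' @param seed global seed; per-stage seeds derive from it as
#'   `seed * 100 + stage offset`.
#' @param n_haplotypes,n_sites,region_length,maf_min,n_founders,mosaic_switch_rate
#'   panel simulation parameters (see [simulate_panel()]).
#' @param switch_rate,mutation_rate cohort copying parameters (see
#'   [simulate_cohort()]).
#' @param n_individuals concordance-cohort size; `0` disables the
#'   concordance study.
#' @param depths depth grid for the concordance study.
#' @param deep_depth the high-coverage depth that gets thinned to the grid.
#' @param error_rate,overdispersion read-model parameters.
#' @param hmm_switch_rate,miscopy_rate,call_error imputation HMM parameters
#'   (`NA` = resolve at run time).
#' @param info_threshold INFO-score retention threshold.
#' @param window_size Lorenz/Gini window in bp.
#' @param af_bin_edges interior allele-frequency bin edges.
#' @param quality_threshold per-SNP R2 restriction for the cross-platform
#'   comparison.
#' @param array_fraction,array_error array-route parameters.
#' @param do_prs enable the case/control PRS study.
#' @param n_cases,n_controls,pool_n,prevalence PRS cohort parameters.
#' @param h2,n_causal,weight_noise_sd,n_gwas genetic architecture of the
#'   simulated GWAS weights.
#' @param prs_depths sequencing depths for the PRS arms.
#' @param p_thresholds P+T threshold grid.
#' @param sig_threshold P-value cut defining the "published significant"
#'   SNP set scored by the unadjusted model.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1,
                              n_haplotypes = 100, n_sites = 400,
                              region_length = 1e6, maf_min = 0.01,
                              n_founders = 20, mosaic_switch_rate = 5e-6,
                              switch_rate = 1e-6, mutation_rate = 2e-3,
                              n_individuals = 8,
                              depths = c(0.5, 1, 2, 5), deep_depth = 27.2,
                              error_rate = 0.002, overdispersion = 0,
                              hmm_switch_rate = NA_real_,
                              miscopy_rate = NA_real_, call_error = 0.01,
                              info_threshold = 0.3, window_size = 1e4,
                              af_bin_edges = c(0.005, 0.05),
                              quality_threshold = 0.8,
                              array_fraction = 0.16, array_error = 0.002,
                              do_prs = FALSE, n_cases = 87,
                              n_controls = 101, pool_n = 20000,
                              prevalence = 0.01, h2 = 0.05, n_causal = 16,
                              weight_noise_sd = 0.01, n_gwas = 30000,
                              prs_depths = c(0.5, 1, 2),
                              p_thresholds = default_p_thresholds(),
                              sig_threshold = 5e-8) {
  num <- function(x) as.numeric(x)
  cfg <- list(seed = num(seed), n_haplotypes = num(n_haplotypes),
              n_sites = num(n_sites), region_length = num(region_length),
              maf_min = num(maf_min), n_founders = num(n_founders),
              mosaic_switch_rate = num(mosaic_switch_rate),
              switch_rate = num(switch_rate),
              mutation_rate = num(mutation_rate),
              n_individuals = num(n_individuals),
              depths = num(depths), deep_depth = num(deep_depth),
              error_rate = num(error_rate),
              overdispersion = num(overdispersion),
              hmm_switch_rate = num(hmm_switch_rate %||% NA_real_),
              miscopy_rate = num(miscopy_rate %||% NA_real_),
              call_error = num(call_error),
              info_threshold = num(info_threshold),
              window_size = num(window_size),
              af_bin_edges = num(af_bin_edges),
              quality_threshold = num(quality_threshold),
              array_fraction = num(array_fraction),
              array_error = num(array_error),
              do_prs = isTRUE(do_prs), n_cases = num(n_cases),
              n_controls = num(n_controls), pool_n = num(pool_n),
              prevalence = num(prevalence), h2 = num(h2),
              n_causal = num(n_causal),
              weight_noise_sd = num(weight_noise_sd),
              n_gwas = num(n_gwas), prs_depths = num(prs_depths),
              p_thresholds = num(p_thresholds),
              sig_threshold = num(sig_threshold))
  stopifnot(cfg$n_haplotypes >= 4, cfg$n_sites >= 2,
            cfg$deep_depth >= max(cfg$depths, 0),
            all(cfg$depths > 0), cfg$info_threshold >= 0,
            cfg$info_threshold <= 1)
  if (cfg$do_prs)
    stopifnot(cfg$deep_depth >= max(cfg$prs_depths),
              cfg$pool_n >= cfg$n_cases + cfg$n_controls)
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment config (seed", x$seed, "):\n")
  cat(sprintf("  panel %d haplotypes x %d sites over %g bp (maf_min %.4g)\n",
              x$n_haplotypes, x$n_sites, x$region_length, x$maf_min))
  if (x$n_individuals > 0)
    cat(sprintf("  concordance study: %d individuals, depths {%s}x + array\n",
                x$n_individuals, paste(x$depths, collapse = ", ")))
  if (x$do_prs)
    cat(sprintf("  PRS study: %d cases / %d controls (pool %d), h2 %.3g, depths {%s}x + array\n",
                x$n_cases, x$n_controls, x$pool_n, x$h2,
                paste(x$prs_depths, collapse = ", ")))
  invisible(x)
}

#' Preset: depth-grid concordance study
#'
#' Mirrors an evaluation on a handful of deeply sequenced genomes: 8
#' individuals, a 250-haplotype panel over 500 sites whose frequency
#' spectrum reaches below the 0.5% rare-bin edge, a 0.5-5x depth grid
#' thinned from 27.2x reads, both imputation emission modes, and the array
#' route.
#' @param seed global seed.
#' @param ... overrides passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
default_concordance_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_haplotypes = 250, n_sites = 500,
               maf_min = 1 / 250, n_individuals = 8,
               depths = c(0.5, 1, 2, 5), do_prs = FALSE)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

#' Preset: case/control PRS study
#'
#' Mirrors a cohort of 87 cases and 101 controls drawn from a
#' liability-threshold population (prevalence 1%, 16 causal SNPs explaining
#' 5% of liability variance), imputed at 0.5/1/2x and on the array route,
#' with unadjusted and P+T scores.
#' @param seed global seed.
#' @param ... overrides passed to [experiment_config()].
#' @return an `experiment_config`.
#' @export
default_prs_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_haplotypes = 100, n_sites = 400,
               maf_min = 0.01, n_individuals = 0, do_prs = TRUE)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

#' Serialize / restore an experiment configuration
#'
#' JSON with full numeric precision, so a written configuration restores
#' bit-exactly through [experiment_config()].
#' @param config an `experiment_config`.
#' @param path JSON file path.
#' @return `write_config` the path; `read_config` the restored config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), na = "null", null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw <- lapply(raw, function(x) if (is.null(x)) NA_real_ else x)
  do.call(experiment_config, raw)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

subset_weights <- function(weights, idx) {
  out <- weights[idx, , drop = FALSE]
  attr(out, "h2") <- attr(weights, "h2")
  class(out) <- c("gwas_weights", "data.frame")
  out
}

resolve_hmm_params <- function(cfg) {
  hmm_params(
    switch_rate = if (is.na(cfg$hmm_switch_rate)) cfg$switch_rate else
      cfg$hmm_switch_rate,
    miscopy_rate = if (is.na(cfg$miscopy_rate)) NULL else cfg$miscopy_rate,
    call_error = cfg$call_error)
}

# Cross-platform per-bin comparison of per-SNP accuracy, restricted to the
# overlap of the two arms' INFO-retained site sets.
compare_platforms <- function(arm_a, arm_b, afs, bins, quality_threshold) {
  shared <- intersect(arm_a$retained, arm_b$retained)
  fac <- bin_af(afs[shared], bins)
  ra <- arm_a$report$per_snp_r2[match(shared, arm_a$sites_all)]
  rb <- arm_b$report$per_snp_r2[match(shared, arm_b$sites_all)]
  out <- data.frame(bin = levels(fac),
                    n_shared = as.integer(table(fac)),
                    fraction_a_better = NA_real_)
  for (i in seq_along(levels(fac))) {
    s <- fac == levels(fac)[i]
    if (any(s))
      out$fraction_a_better[i] <-
        fraction_more_accurate(ra[s], rb[s], quality_threshold)
  }
  out$all_bins <- fraction_more_accurate(ra, rb, quality_threshold)
  out
}

concordance_arm <- function(name, depth, mode, imputed, truth, afs, cfg,
                            bins) {
  retained <- filter_by_info(imputed, cfg$info_threshold)
  rep <- concordance_report(truth, imputed, afs, retained, bins)
  list(name = name, depth = depth, mode = mode, imputed = imputed,
       retained = retained, sites_all = as.integer(retained),
       report = rep)
}

prs_arm <- function(name, depth, platform, dosage_obj, weights, sig_set,
                    labels, ld_ref, cfg, boot_seed) {
  unadj <- normalize_scores(compute_prs(dosage_obj, weights, sig_set,
                                        model = "unadjusted",
                                        quiet = TRUE))
  a <- auc(unadj$normalized, labels, ci = TRUE, seed = boot_seed)
  pt <- p_plus_t(dosage_obj, weights, labels,
                 thresholds = cfg$p_thresholds, ld_reference = ld_ref)
  list(name = name, depth = depth, platform = platform,
       unadjusted = unadj, auc = a, p_plus_t = pt,
       groups = group_summary(unadj$normalized, labels))
}

#' Run a full synthetic experiment
#'
#' Orchestrates, from one seeded configuration: panel and cohort
#' simulation; high-coverage reads thinned over the depth grid; coverage
#' profiling; imputation in both emission modes plus the array route;
#' INFO filtering; the genotype-concordance panel with AF-stratified
#' aggregate R2 and the cross-platform per-SNP comparison; and, when
#' enabled, the liability-threshold case/control cohort with unadjusted
#' and P+T polygenic scores, AUCs and cross-platform score correlations.
#' With `outdir` set, the report tables and a manifest (stage seeds,
#' package version, config hash) are written as TSV/JSON.
#'
#' @param config an [experiment_config()].
#' @param outdir optional output directory for TSV/JSON reports.
#' @param quiet suppress progress messages.
#' @return An object of class `lps_experiment` with elements `config`,
#'   `panel_af`, `concordance` (coverage profiles, arms, per-bin
#'   comparisons), `prs` (weights, phenotypes, arms, correlations) and
#'   `manifest`.
#' @export
run_experiment <- function(config, outdir = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  say <- function(...) if (!quiet) message(sprintf(...))
  seeds <- list(panel = stage_seed(cfg$seed, 1), cohort = stage_seed(cfg$seed, 2),
                deep = stage_seed(cfg$seed, 3), array = stage_seed(cfg$seed, 30),
                pool = stage_seed(cfg$seed, 40), effects = stage_seed(cfg$seed, 41),
                phenotypes = stage_seed(cfg$seed, 42),
                prs_deep = stage_seed(cfg$seed, 43),
                prs_array = stage_seed(cfg$seed, 60),
                bootstrap = stage_seed(cfg$seed, 70))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  say("simulating panel (%d haplotypes x %d sites)", cfg$n_haplotypes,
      cfg$n_sites)
  panel <- run_stage("panel", simulate_panel(
    cfg$n_haplotypes, cfg$n_sites, cfg$region_length, cfg$maf_min,
    n_founders = min(cfg$n_founders, cfg$n_haplotypes),
    mosaic_switch_rate = cfg$mosaic_switch_rate, seed = seeds$panel))
  afs <- panel_af(panel)
  bins <- af_bins(cfg$af_bin_edges)
  params <- resolve_hmm_params(cfg)

  concordance <- NULL
  if (cfg$n_individuals > 0) {
    cohort <- run_stage("cohort", simulate_cohort(
      panel, cfg$n_individuals, cfg$switch_rate, cfg$mutation_rate,
      seed = seeds$cohort))
    deep <- run_stage("reads", simulate_reads(
      cohort, cfg$deep_depth, cfg$error_rate, cfg$overdispersion,
      seed = seeds$deep))
    arms <- list()
    coverage <- list()
    for (i in seq_along(cfg$depths)) {
      d <- cfg$depths[i]
      say("concordance arm at %.1fx", d)
      reads_d <- run_stage("downsample", downsample_reads(
        deep, d, seed = stage_seed(cfg$seed, 10 + i)))
      coverage[[sprintf("%gx", d)]] <-
        coverage_profile(reads_d, cfg$window_size)
      gl <- run_stage("gl", compute_gl(reads_d))
      arm_gl <- run_stage("impute_gl", concordance_arm(
        sprintf("gl_%gx", d), d, "gl", impute_gl(gl, panel, params),
        cohort, afs, cfg, bins))
      calls <- hard_call(gl, min_depth = 1)
      arm_hc <- run_stage("impute_hardcall", concordance_arm(
        sprintf("hardcall_%gx", d), d, "hardcall",
        impute_hardcall(calls, panel, params), cohort, afs, cfg, bins))
      arms[[arm_gl$name]] <- arm_gl
      arms[[arm_hc$name]] <- arm_hc
    }
    say("array route")
    arr <- run_stage("array", simulate_array(
      cohort, cfg$array_fraction, cfg$array_error, seed = seeds$array))
    arms[["array"]] <- run_stage("impute_array", concordance_arm(
      "array", NA_real_, "array", impute_hardcall(arr, panel, params),
      cohort, afs, cfg, bins))
    comparisons <- list()
    for (i in seq_along(cfg$depths)) {
      nm <- sprintf("gl_%gx", cfg$depths[i])
      comparisons[[nm]] <- compare_platforms(
        arms[[nm]], arms[["array"]], afs, bins, cfg$quality_threshold)
    }
    concordance <- list(cohort = cohort, coverage = coverage, arms = arms,
                        lps_vs_array = comparisons)
  }

  prs <- NULL
  if (cfg$do_prs) {
    say("PRS study: pool of %d", cfg$pool_n)
    pool <- run_stage("pool", simulate_cohort(
      panel, cfg$pool_n, cfg$switch_rate, cfg$mutation_rate,
      seed = seeds$pool, keep_haplotypes = FALSE))
    weights <- run_stage("effects", assign_effects(
      afs, cfg$n_causal, cfg$h2, cfg$weight_noise_sd, cfg$n_gwas,
      site_ids = panel$site_ids, seed = seeds$effects))
    phen <- run_stage("phenotypes", simulate_phenotypes(
      pool, weights, cfg$prevalence, cfg$n_cases, cfg$n_controls,
      seed = seeds$phenotypes))
    target <- subset_cohort(pool, phen$idx)
    labels <- phen$label
    # the "published significant" SNP set: genome-wide significant hits,
    # LD-clumped against the target cohort
    sig <- weights$site_id[weights$p_value < cfg$sig_threshold]
    sig_set <- if (length(sig))
      ld_clump(target, subset_weights(weights,
                                      match(sig, weights$site_id))) else
      character(0)
    if (!length(sig_set)) sig_set <- NULL  # fall back to all SNPs
    arms <- list()
    arms[["truth"]] <- run_stage("prs_truth", prs_arm(
      "truth", NA_real_, "truth", target, weights, sig_set, labels,
      target, cfg, seeds$bootstrap))
    arr <- run_stage("prs_array", simulate_array(
      target, cfg$array_fraction, cfg$array_error, seed = seeds$prs_array))
    arms[["array"]] <- run_stage("prs_array_impute", prs_arm(
      "array", NA_real_, "array",
      impute_hardcall(arr, panel, params), weights, sig_set, labels,
      target, cfg, seeds$bootstrap))
    deep <- run_stage("prs_reads", simulate_reads(
      target, cfg$deep_depth, cfg$error_rate, cfg$overdispersion,
      seed = seeds$prs_deep))
    for (i in seq_along(cfg$prs_depths)) {
      d <- cfg$prs_depths[i]
      say("PRS arm at %.1fx", d)
      reads_d <- run_stage("prs_downsample", downsample_reads(
        deep, d, seed = stage_seed(cfg$seed, 50 + i)))
      nm <- sprintf("lps_%gx", d)
      arms[[nm]] <- run_stage("prs_impute", prs_arm(
        nm, d, "lps", impute_gl(compute_gl(reads_d), panel, params),
        weights, sig_set, labels, target, cfg, seeds$bootstrap))
    }
    correlations <- do.call(rbind, lapply(
      setdiff(names(arms), "array"), function(nm) {
        sc <- score_correlation(arms[[nm]]$unadjusted$normalized,
                                arms[["array"]]$unadjusted$normalized)
        data.frame(platform_a = nm, platform_b = "array",
                   r = unname(sc["r"]), r2 = unname(sc["r2"]))
      }))
    prs <- list(weights = weights, phenotypes = phen, arms = arms,
                correlations = correlations, sig_set = arms[[1]]$unadjusted$snps)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("lpsprs")),
                   seed = cfg$seed, stage_seeds = seeds,
                   config_hash = config_hash(cfg))
  out <- structure(list(config = cfg, panel = panel, panel_af = afs,
                        concordance = concordance, prs = prs,
                        manifest = manifest),
                   class = "lps_experiment")
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' Tabulate an experiment's concordance metrics
#' @param x an `lps_experiment` with a concordance study.
#' @return data frame, one row per (arm, bin), with overall and per-bin
#'   metrics.
#' @export
concordance_table <- function(x) {
  stopifnot(inherits(x, "lps_experiment"), !is.null(x$concordance))
  do.call(rbind, lapply(x$concordance$arms, function(a) {
    pb <- a$report$per_bin
    data.frame(arm = a$name, depth = a$depth, mode = a$mode,
               n_retained = length(a$retained),
               r2_overall = a$report$r2_overall, ndr = a$report$ndr,
               fpr = a$report$fpr, fnr = a$report$fnr, bin = pb$bin,
               n = pb$n, pooled_r2 = pb$pooled_r2, mean_r2 = pb$mean_r2,
               sd_r2 = pb$sd_r2, row.names = NULL)
  }))
}

#' Tabulate an experiment's PRS metrics
#' @param x an `lps_experiment` with a PRS study.
#' @return data frame, one row per arm, with unadjusted and P+T AUCs.
#' @export
prs_table <- function(x) {
  stopifnot(inherits(x, "lps_experiment"), !is.null(x$prs))
  do.call(rbind, lapply(x$prs$arms, function(a) {
    data.frame(arm = a$name, platform = a$platform, depth = a$depth,
               auc_unadjusted = a$auc$auc, ci_low = a$auc$ci_low,
               ci_high = a$auc$ci_high,
               auc_pt = a$p_plus_t$best_auc,
               pt_threshold = a$p_plus_t$best_threshold,
               mean_case = a$groups$mean_case,
               mean_control = a$groups$mean_control, row.names = NULL)
  }))
}

write_experiment <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(x$concordance)) {
    wt(concordance_table(x), "concordance.tsv")
    cov <- do.call(rbind, lapply(names(x$concordance$coverage), function(d) {
      cp <- x$concordance$coverage[[d]]
      data.frame(depth = d, covered_fraction = cp$covered_fraction,
                 gini = cp$gini, mean_depth = cp$mean_depth)
    }))
    wt(cov, "coverage.tsv")
    cmp <- do.call(rbind, lapply(names(x$concordance$lps_vs_array),
                                 function(nm) {
      df <- x$concordance$lps_vs_array[[nm]]
      cbind(arm = nm, df)
    }))
    wt(cmp, "lps_vs_array.tsv")
  }
  if (!is.null(x$prs)) {
    wt(prs_table(x), "prs_auc.tsv")
    wt(x$prs$correlations, "prs_correlations.tsv")
    scores <- do.call(rbind, lapply(x$prs$arms, function(a)
      data.frame(arm = a$name, individual = seq_along(a$unadjusted$score),
                 label = x$prs$phenotypes$label,
                 raw = a$unadjusted$score,
                 normalized = a$unadjusted$normalized, row.names = NULL)))
    wt(scores, "prs_scores.tsv")
    write_weights(x$prs$weights, file.path(outdir, "weights.tsv"))
  }
  jsonlite::write_json(x$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(x$config, file.path(outdir, "config.json"))
  invisible(outdir)
}

#' @export
print.lps_experiment <- function(x, ...) {
  cat("Synthetic LPS/array experiment (seed", x$config$seed, ")\n")
  if (!is.null(x$concordance)) {
    cat("\nCoverage and concordance:\n")
    tab <- unique(concordance_table(x)[, c("arm", "depth", "mode",
                                           "n_retained", "r2_overall",
                                           "ndr", "fpr", "fnr")])
    print(tab, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$prs)) {
    cat("\nPRS discrimination:\n")
    print(prs_table(x)[, c("arm", "auc_unadjusted", "ci_low", "ci_high",
                           "auc_pt")], row.names = FALSE, digits = 4)
    cat("\nScore correlation vs array (unadjusted model):\n")
    print(x$prs$correlations, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
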