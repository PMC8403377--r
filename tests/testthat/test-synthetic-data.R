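test_that("simulate_panel honours shape, domain and MAF constraints", {
  p <- simulate_panel(4, 10, region_length = 1e4, seed = 7)
  expect_equal(dim(p$alleles), c(4L, 10L))
  expect_true(all(p$alleles %in% c(0L, 1L)))
  expect_true(all(diff(p$positions) > 0))
  expect_false(anyDuplicated(p$site_ids) > 0)

  p2 <- simulate_panel(40, 200, maf_min = 0.05, seed = 2)
  af <- panel_af(p2)
  expect_true(all(af >= 0.05 & af <= 0.95))

  expect_identical(simulate_panel(10, 20, seed = 3),
                   simulate_panel(10, 20, seed = 3))
  expect_error(simulate_panel(10, 20, maf_min = 0.05),
               "cannot be represented")
  expect_error(simulate_panel(10, 20, maf_min = 0.6))
})

test_that("panel frequency spectrum is rare-heavy under the 1/p law", {
  p <- simulate_panel(400, 2000, maf_min = 1 / 400, n_founders = 400,
                      seed = 5)
  af <- pmin(panel_af(p), 1 - panel_af(p))
  # under f(p) ~ 1/p on [1/400, 0.5], more mass below 0.05 than above
  expect_gt(mean(af < 0.05), mean(af > 0.25))
})

test_that("simulate_cohort forced limits reproduce the copying process", {
  pan <- tiny_panel(matrix(0L, 4, 6))
  g <- simulate_cohort(pan, 5, mutation_rate = 0, seed = 1)
  expect_true(all(g$genotypes == 0L))

  pan2 <- simulate_panel(8, 30, seed = 4)
  g2 <- simulate_cohort(pan2, 6, switch_rate = 0, mutation_rate = 0,
                        seed = 2)
  for (h in seq_len(nrow(g2$haplotypes))) {
    match_row <- apply(pan2$alleles, 1, function(r)
      all(r == g2$haplotypes[h, ]))
    expect_true(any(match_row))
  }
})

test_that("cohort allele frequencies track the panel", {
  pan <- simulate_panel(100, 300, maf_min = 0.01, seed = 11)
  g <- simulate_cohort(pan, 200, seed = 12)
  caf <- colMeans(g$genotypes) / 2
  expect_gt(cor(caf, panel_af(pan), method = "spearman"), 0.9)
})

test_that("assign_effects scales, nulls and noise behave as specified", {
  af <- rep(0.3, 50)
  w0 <- assign_effects(af, n_causal = 10, h2 = 0.4, weight_noise_sd = 0,
                       seed = 3)
  alt_scale <- ifelse(w0$effect_allele == "ref", -w0$weight, w0$weight)
  expect_equal(alt_scale[w0$is_causal], w0$true_beta[w0$is_causal])
  expect_equal(sum(w0$true_beta^2), 0.4, tolerance = 1e-12)

  wn <- assign_effects(af, n_causal = 0, h2 = 0.4, seed = 3)
  expect_true(all(wn$true_beta == 0))
  expect_error(assign_effects(af, 5, h2 = 1.2), "h2")

  # causal SNPs enriched at small P
  w <- assign_effects(rep(0.3, 400), n_causal = 20, h2 = 0.3, seed = 9)
  expect_lt(median(w$p_value[w$is_causal]), 1e-6)
  expect_gt(median(w$p_value[!w$is_causal]), 0.2)
})

test_that("genetic score variance matches h2 on a low-LD cohort", {
  pan <- simulate_panel(400, 400, maf_min = 0.05, n_founders = 400,
                        seed = 21)
  w <- assign_effects(panel_af(pan), n_causal = 20, h2 = 0.25,
                      weight_noise_sd = 0, site_ids = pan$site_ids,
                      seed = 22)
  g <- simulate_cohort(pan, 2000, mutation_rate = 0, seed = 23)
  cidx <- which(w$is_causal)
  p <- w$af[cidx]
  Z <- sweep(g$genotypes[, cidx], 2, 2 * p, `-`)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), `/`)
  v <- var(as.vector(Z %*% w$true_beta[cidx]))
  expect_equal(v, 0.25, tolerance = 0.1)  # +-10 % relative
})

test_that("liability-threshold phenotypes calibrate to prevalence", {
  pan <- simulate_panel(60, 100, maf_min = 0.05, seed = 31)
  w <- assign_effects(panel_af(pan), 10, h2 = 0.3,
                      site_ids = pan$site_ids, seed = 32)
  pool <- simulate_cohort(pan, 10000, seed = 33)
  ph <- simulate_phenotypes(pool, w, prevalence = 0.1, n_cases = 87,
                            n_controls = 101, seed = 34)
  expect_equal(ph$pool_case_fraction, 0.1, tolerance = 0.1)  # binomial noise
  expect_identical(sum(ph$label == 1L), 87L)
  expect_identical(sum(ph$label == 0L), 101L)

  expect_error(simulate_phenotypes(pool, w, prevalence = 0.0005,
                                   n_cases = 87, n_controls = 101,
                                   seed = 35),
               "pool cannot supply")
})
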