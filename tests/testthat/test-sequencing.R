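make_geno <- function(G, positions = NULL) {
  storage.mode(G) <- "integer"
  M <- ncol(G)
  colnames(G) <- sprintf("snp%05d", seq_len(M))
  structure(list(genotypes = G, haplotypes = NULL,
                 site_ids = colnames(G),
                 positions = as.integer(positions %||%
                                          seq(100, by = 100,
                                              length.out = M)),
                 ref = rep("A", M), alt = rep("C", M)),
            class = "diploid_geno")
}

test_that("read simulation respects depth, error and forced limits", {
  g <- make_geno(matrix(rep(0:2, length.out = 60), 6, 10))
  r0 <- simulate_reads(g, mean_depth = 0, seed = 1)
  expect_true(all(r0$n_ref == 0L) && all(r0$n_alt == 0L))

  g2 <- make_geno(matrix(2L, 10, 10))
  r2 <- simulate_reads(g2, mean_depth = 5, error_rate = 0, seed = 2)
  expect_true(all(r2$n_ref == 0L))

  big <- make_geno(matrix(1L, 100, 1000))
  rb <- simulate_reads(big, mean_depth = 0.5, seed = 3)
  expect_equal(mean(rb$n_ref + rb$n_alt), 0.5, tolerance = 0.02)

  ro <- simulate_reads(big, mean_depth = 2, overdispersion = 0.5, seed = 4)
  dp <- ro$n_ref + ro$n_alt
  expect_gt(var(as.vector(dp)), 2 * 1.5)  # var = mu + od * mu^2 = 4
})

test_that("binomial thinning preserves the Poisson law and edge cases", {
  g <- make_geno(matrix(1L, 100, 1000))
  deep <- simulate_reads(g, mean_depth = 5, seed = 5)
  same <- downsample_reads(deep, 5, seed = 6)
  expect_identical(same$n_ref, deep$n_ref)
  expect_identical(same$n_alt, deep$n_alt)

  zero <- downsample_reads(deep, 0, seed = 7)
  expect_true(all(zero$n_ref == 0L) && all(zero$n_alt == 0L))
  expect_error(downsample_reads(deep, 6), "exceeds")

  thin <- downsample_reads(deep, 0.5, seed = 8)
  dp <- as.vector(thin$n_ref + thin$n_alt)
  expect_equal(mean(dp), 0.5, tolerance = 0.02)
  # Poisson(0.5) zero class and variance
  expect_equal(mean(dp == 0), exp(-0.5), tolerance = 0.01)
  expect_equal(var(dp), 0.5, tolerance = 0.05)
})

test_that("genotype likelihoods match the binomial formula and oracle", {
  # hand example: 2 ref reads, error 0.01 -> L propto (0.9801, 0.25, 1e-4)
  g <- make_geno(matrix(0L, 1, 1))
  r <- simulate_reads(g, 0, seed = 1)
  r$n_ref[1, 1] <- 2L
  gl <- compute_gl(r, error_rate = 0.01)
  lin <- exp(gl$loglik[1, 1, ])
  expect_equal(lin, c(0.9801, 0.25, 1e-4), tolerance = 1e-10)

  # zero depth: all equal
  r$n_ref[1, 1] <- 0L
  gl0 <- compute_gl(r, error_rate = 0.01)
  expect_equal(exp(gl0$loglik[1, 1, ]), rep(1, 3))

  # brute-force per-read product oracle for all depth <= 3 configurations
  for (e in c(0.01, 0.05, 0.2)) {
    for (nr in 0:3) for (na in 0:(3 - nr)) {
      rr <- r
      rr$n_ref[1, 1] <- nr; rr$n_alt[1, 1] <- as.integer(na)
      got <- exp(compute_gl(rr, error_rate = e)$loglik[1, 1, ])
      expect_equal(got / sum(got), oracle_gl(nr, na, e), tolerance = 1e-12)
    }
  }
})

test_that("hard calls take the argmax, break ties low, and mislead at low depth", {
  g <- make_geno(matrix(0L, 1, 3))
  r <- simulate_reads(g, 0, seed = 1)
  r$n_ref[1, ] <- c(2L, 0L, 0L)
  r$n_alt[1, ] <- c(0L, 0L, 1L)
  gl <- compute_gl(r, error_rate = 0.01)
  hc <- hard_call(gl, min_depth = 1)
  expect_identical(hc$calls[1, 1], 0L)       # argmax of (0.98, 0.25, 1e-4)
  expect_true(is.na(hc$calls[1, 2]))         # zero depth -> missing
  expect_identical(hc$calls[1, 3], 2L)       # single alt read -> hom alt

  # ties toward the smaller genotype
  gl$loglik[1, 2, ] <- log(c(0.4, 0.4, 0.2))
  hc2 <- hard_call(gl, min_depth = 0)
  expect_identical(hc2$calls[1, 2], 0L)

  # deep reads + tiny error recover the truth
  truth <- matrix(rep(0:2, length.out = 200), 10, 20)
  gd <- make_geno(truth)
  rd <- simulate_reads(gd, 50, error_rate = 0.001, seed = 9)
  cd <- hard_call(compute_gl(rd), min_depth = 1)
  expect_true(all(cd$calls == truth, na.rm = TRUE))
  expect_lt(mean(is.na(cd$calls)), 1e-6)
})

test_that("array simulation types a biased subset with controlled error", {
  set.seed(42)
  G <- matrix(rbinom(200 * 50, 2, 0.3), 200, 50)
  g <- make_geno(G)
  arr0 <- simulate_array(g, array_fraction = 0.4, array_error = 0,
                         seed = 10)
  expect_identical(unname(arr0$calls), G[, arr0$site_index])

  arr_all <- simulate_array(g, array_fraction = 1, array_error = 0,
                            seed = 11)
  expect_identical(ncol(arr_all$calls), 50L)

  arr <- simulate_array(g, array_fraction = 0.4, array_error = 0.1,
                        seed = 12)
  err <- mean(arr$calls != G[, arr$site_index])
  expect_equal(err, 0.1, tolerance = 0.25)
  expect_identical(simulate_array(g, 0.4, 0.01, seed = 13),
                   simulate_array(g, 0.4, 0.01, seed = 13))
})

test_that("array sites favour common variants", {
  pan <- simulate_panel(200, 500, maf_min = 1 / 200, n_founders = 200,
                        seed = 14)
  g <- simulate_cohort(pan, 100, seed = 15)
  arr <- simulate_array(g, array_fraction = 0.2, seed = 16)
  af <- colMeans(g$genotypes) / 2
  maf <- pmin(af, 1 - af)
  expect_gt(mean(maf[arr$site_index]), mean(maf))
})

test_that("sequential thinning composes in distribution", {
  g <- make_geno(matrix(1L, 50, 400))
  deep <- simulate_reads(g, 5, seed = 20)
  two_step <- downsample_reads(downsample_reads(deep, 2, seed = 21), 0.5,
                               seed = 22)
  one_step <- downsample_reads(deep, 0.5, seed = 23)
  d2 <- as.vector(two_step$n_ref + two_step$n_alt)
  d1 <- as.vector(one_step$n_ref + one_step$n_alt)
  expect_equal(mean(d2), mean(d1), tolerance = 0.05)
  expect_equal(var(d2), var(d1), tolerance = 0.1)
  expect_equal(mean(d2 == 0), mean(d1 == 0), tolerance = 0.02)
})
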