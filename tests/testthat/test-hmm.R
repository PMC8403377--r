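test_that("forward-backward equals exhaustive path enumeration on small instances", {
  set.seed(1)
  for (rep in 1:12) {
    K <- sample(2:3, 1)
    M <- sample(1:3, 1)
    H <- matrix(rbinom(K * M, 1, 0.5), K, M)
    pan <- tiny_panel(H, positions = sort(sample(1000, M)))
    lik <- matrix(runif(M * 3, 0.05, 1), M, 3)
    mu <- runif(1, 0.005, 0.3)
    sr <- runif(1, 1e-4, 5e-3)
    imp <- impute_gl(make_gl(array(lik, c(1, M, 3)), pan),
                     pan, hmm_params(switch_rate = sr, miscopy_rate = mu))
    want <- oracle_diploid_posterior(H, pan$positions, lik, sr, mu)
    got <- matrix(imp$gp[1, , ], M, 3)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("hard-call emissions match the path-sum oracle too", {
  set.seed(2)
  for (rep in 1:6) {
    K <- sample(2:3, 1); M <- sample(2:3, 1)
    H <- matrix(rbinom(K * M, 1, 0.5), K, M)
    pan <- tiny_panel(H)
    calls <- matrix(sample(c(0:2, NA), M, replace = TRUE), 1, M)
    theta <- 0.05; mu <- 0.02; sr <- 1e-3
    lik <- matrix(theta / 2, M, 3)
    for (m in seq_len(M)) {
      if (is.na(calls[1, m])) lik[m, ] <- 1
      else lik[m, calls[1, m] + 1] <- 1 - theta
    }
    cg <- structure(list(calls = calls, site_index = seq_len(M),
                         site_ids = pan$site_ids,
                         positions = pan$positions, ref = pan$ref,
                         alt = pan$alt), class = "called_geno")
    imp <- impute_hardcall(cg, pan,
                           hmm_params(switch_rate = sr, miscopy_rate = mu,
                                      call_error = theta))
    want <- oracle_diploid_posterior(H, pan$positions, lik, sr, mu)
    expect_equal(matrix(imp$gp[1, , ], M, 3), want, tolerance = 1e-10)
  }
})

test_that("uninformative data falls back to the panel prior", {
  # monomorphic-ref site, tiny miscopy: dosage driven to 0
  H <- cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  pan <- tiny_panel(H)
  lik <- array(1, c(1, 2, 3))  # zero-depth GLs everywhere
  imp <- impute_gl(make_gl(lik, pan), pan,
                   hmm_params(miscopy_rate = 1e-6))
  expect_lt(imp$ds[1, 1], 1e-4)
  # and the polymorphic site reflects the panel frequency (af = 0.5 -> ds = 1)
  expect_equal(imp$ds[1, 2], 1, tolerance = 1e-6)

  # all-missing hard calls are equivalent to zero-depth GL mode
  cg <- structure(list(calls = matrix(NA_integer_, 1, 2),
                       site_index = 1:2, site_ids = pan$site_ids,
                       positions = pan$positions, ref = pan$ref,
                       alt = pan$alt), class = "called_geno")
  imp2 <- impute_hardcall(cg, pan, hmm_params(miscopy_rate = 1e-6))
  expect_equal(imp2$gp, imp$gp, tolerance = 1e-12)
})

test_that("degenerate emissions: certainty makes both modes agree and forces calls", {
  set.seed(3)
  pan <- tiny_panel(matrix(rbinom(4 * 5, 1, 0.5), 4, 5))
  calls <- matrix(sample(0:2, 5, replace = TRUE), 1, 5)
  lin <- array(0, c(1, 5, 3))
  for (m in 1:5) lin[1, m, calls[1, m] + 1] <- 1
  cg <- structure(list(calls = calls, site_index = 1:5,
                       site_ids = pan$site_ids, positions = pan$positions,
                       ref = pan$ref, alt = pan$alt),
                  class = "called_geno")
  par0 <- hmm_params(miscopy_rate = 0.05, call_error = 0)
  imp_hc <- impute_hardcall(cg, pan, par0)
  imp_gl <- impute_gl(make_gl(pmax(lin, 1e-300), pan), pan, par0)
  expect_equal(imp_hc$gp, imp_gl$gp, tolerance = 1e-9)
  # error-free calls with theta = 0 are reproduced exactly
  expect_equal(imp_hc$ds[1, ], as.numeric(calls[1, ]), tolerance = 1e-9)
})

test_that("posteriors are normalized and dosages bounded", {
  pan <- simulate_panel(30, 40, seed = 4)
  g <- simulate_cohort(pan, 5, seed = 5)
  gl <- compute_gl(simulate_reads(g, 1, seed = 6))
  imp <- impute_gl(gl, pan)
  expect_equal(apply(imp$gp, c(1, 2), sum),
               matrix(1, 5, 40), tolerance = 1e-9)
  expect_true(all(imp$ds >= 0 & imp$ds <= 2))
  expect_true(all(imp$info >= 0 & imp$info <= 1))
})

test_that("deep reads recover true genotypes through the HMM", {
  pan <- simulate_panel(50, 100, maf_min = 0.02, seed = 7)
  g <- simulate_cohort(pan, 10, seed = 8)
  gl <- compute_gl(simulate_reads(g, 30, error_rate = 0.001, seed = 9))
  imp <- impute_gl(gl, pan)
  close <- abs(imp$ds - g$genotypes) < 0.05
  expect_gte(mean(close), 0.99)
})

test_that("info score matches its defining formula and degenerate cases", {
  mk <- function(ds) {
    structure(list(gp = NULL, ds = ds, info = NULL,
                   site_ids = sprintf("s%d", seq_len(ncol(ds))),
                   positions = seq_len(ncol(ds)), mode = "gl"),
              class = "imputed_dosages")
  }
  # hand arithmetic: var_pop = 0.1875, 2pq = 0.46875 -> 0.4
  expect_equal(info_score(mk(matrix(c(0.5, 0.5, 0.5, 1.5), 4, 1))), 0.4)
  # Hardy-Weinberg hard genotypes -> exactly 1
  expect_equal(info_score(mk(matrix(c(0, 1, 1, 2), 4, 1))), 1)
  # no alternate alleles -> defined as 0
  expect_equal(info_score(mk(matrix(0, 4, 1))), 0)
  expect_error(info_score(mk(matrix(1, 1, 2))), "at least 2")
})

test_that("info filtering keeps the boundary and respects thresholds", {
  ds <- matrix(c(0, 1, 1, 2), 4, 5)         # info 1 at every site
  x <- structure(list(gp = NULL, ds = ds,
                      info = c(0.29, 0.3, 0.31, 0, 1),
                      site_ids = sprintf("s%d", 1:5),
                      positions = 1:5, mode = "gl"),
                 class = "imputed_dosages")
  expect_identical(unname(filter_by_info(x, 0.3)), c(2L, 3L, 5L))
  expect_identical(unname(filter_by_info(x, 0)), 1:5)
  expect_identical(names(filter_by_info(x, 0.3)), c("s2", "s3", "s5"))
})
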