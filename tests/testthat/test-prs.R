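mk_weights <- function(site_id, effect_allele, weight, p_value,
                       is_causal = NULL, true_beta = NULL, af = NULL,
                       h2 = 0.1) {
  out <- data.frame(site_id = site_id, effect_allele = effect_allele,
                    weight = weight, p_value = p_value,
                    is_causal = is_causal %||% rep(FALSE, length(site_id)),
                    true_beta = true_beta %||% rep(0, length(site_id)),
                    af = af %||% rep(0.3, length(site_id)),
                    stringsAsFactors = FALSE)
  attr(out, "h2") <- h2
  class(out) <- c("gwas_weights", "data.frame")
  out
}

mk_mat <- function(...) {
  m <- rbind(...)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

test_that("compute_prs does weighted effect-allele arithmetic with flips", {
  w <- mk_weights(c("s1", "s2"), c("alt", "alt"), c(0.2, -0.1),
                  c(0.01, 0.02))
  m <- mk_mat(c(2, 1))
  expect_equal(compute_prs(m, w)$score, 0.2 * 2 - 0.1 * 1)

  # all-zero weights -> all-zero scores
  w0 <- mk_weights(c("s1", "s2"), c("alt", "ref"), c(0, 0), c(0.5, 0.5))
  expect_equal(compute_prs(mk_mat(c(1, 2), c(0, 1)), w0)$score, c(0, 0))

  # reference effect allele flips the dosage: DS 0.5 -> X = 1.5
  wr <- mk_weights("s1", "ref", 0.4, 0.01)
  expect_equal(compute_prs(mk_mat(0.5), wr)$score, 0.4 * 1.5)

  # missing sites are skipped with a message; empty set errors
  w2 <- mk_weights(c("s1", "zz"), c("alt", "alt"), c(1, 1), c(0.1, 0.1))
  expect_message(res <- compute_prs(mk_mat(c(1, 0)), w2), "skipping")
  expect_identical(res$skipped, "zz")
  expect_error(compute_prs(mk_mat(c(1, 0)), w2, snp_subset = "nope"),
               "absent from the weight table")
})

test_that("PRS is linear over disjoint SNP sets and allele-flip invariant", {
  set.seed(6)
  m <- matrix(runif(60, 0, 2), 6, 10)
  colnames(m) <- sprintf("s%d", 1:10)
  w <- mk_weights(colnames(m), sample(c("ref", "alt"), 10, TRUE),
                  rnorm(10), runif(10))
  s_all <- compute_prs(m, w)$score
  s_a <- compute_prs(m, w, snp_subset = colnames(m)[1:4])$score
  s_b <- compute_prs(m, w, snp_subset = colnames(m)[5:10])$score
  expect_equal(s_a + s_b, s_all, tolerance = 1e-12)

  # flip every recorded effect allele and complement the dosage scale:
  # w' = -w, X' = 2 - X shifts each SNP by a constant, so normalized
  # scores are unchanged
  w_f <- w
  w_f$effect_allele <- ifelse(w$effect_allele == "ref", "alt", "ref")
  n1 <- normalize_scores(compute_prs(m, w))$normalized
  n2 <- normalize_scores(compute_prs(m, w_f))$normalized
  expect_equal(n2, -n1, tolerance = 1e-12)
  w_f$weight <- -w$weight
  n3 <- normalize_scores(compute_prs(m, w_f))$normalized
  expect_equal(n3, n1, tolerance = 1e-12)
})

test_that("normalize_scores centres scores exactly", {
  w <- mk_weights("s1", "alt", 1, 0.5)
  r <- compute_prs(mk_mat(1, 2, 3) , w)
  n <- normalize_scores(r)
  expect_equal(n$normalized, c(-1, 0, 1))
  expect_lt(abs(sum(n$normalized)), 1e-9)
  one <- normalize_scores(compute_prs(mk_mat(2), w))
  expect_equal(one$normalized, 0)
})

test_that("ld_clump keeps the most significant SNP of a correlated pair", {
  set.seed(7)
  x <- rbinom(50, 2, 0.4)
  m <- cbind(x, x, rbinom(50, 2, 0.4))
  colnames(m) <- c("s1", "s2", "s3")
  w <- mk_weights(c("s1", "s2", "s3"), rep("alt", 3), c(1, 1, 1),
                  c(1e-4, 1e-10, 0.5))
  kept <- ld_clump(m, w, 0.5)
  expect_true("s2" %in% kept)    # the 1e-10 member survives
  expect_false("s1" %in% kept)   # its perfectly correlated 1e-4 partner dies
  expect_true("s3" %in% kept)

  # pairwise-uncorrelated SNPs are all retained; single SNP is retained
  m2 <- matrix(rbinom(300, 2, 0.5), 100, 3)
  colnames(m2) <- c("s1", "s2", "s3")
  w2 <- mk_weights(colnames(m2), rep("alt", 3), rep(1, 3),
                   c(0.1, 0.2, 0.3))
  expect_setequal(ld_clump(m2, w2, 0.5), colnames(m2))
  expect_identical(ld_clump(mk_mat(c(1), c(0), c(2)),
                            mk_weights("s1", "alt", 1, 0.5)), "s1")
})

test_that("p_plus_t scans thresholds, tolerates empty ones, finds the causal SNP", {
  set.seed(8)
  n <- 200
  causal <- rbinom(n, 2, 0.5)
  noise1 <- rbinom(n, 2, 0.5)
  noise2 <- rbinom(n, 2, 0.5)
  m <- cbind(causal, noise1, noise2)
  colnames(m) <- c("s1", "s2", "s3")
  labels <- as.integer(causal + rnorm(n, 0, 0.8) > 1)
  if (all(labels == labels[1])) labels[1] <- 1L - labels[1]
  w <- mk_weights(colnames(m), rep("alt", 3), c(1, 0.5, -0.5),
                  c(1e-12, 0.04, 0.045))
  pt <- p_plus_t(m, w, labels, thresholds = c(5e-2, 1e-8, 1e-20))
  expect_identical(pt$best_result$snps, "s1")
  expect_identical(pt$auc_table$n_snps, c(3L, 1L, 0L))
  expect_true(is.na(pt$auc_table$auc[pt$auc_table$threshold == 1e-20]))
  expect_gte(pt$best_auc, pt$auc_table$auc[1])

  # a single threshold keeping everything equals the unadjusted model on
  # the clumped set
  pt2 <- p_plus_t(m, w, labels, thresholds = 1)
  unadj <- normalize_scores(compute_prs(m, w, pt2$clumped))
  expect_equal(pt2$best_result$normalized, unadj$normalized)
})
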