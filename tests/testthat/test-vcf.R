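test_that("a phased panel round-trips through VCF", {
  pan <- simulate_panel(10, 12, region_length = 5e4, seed = 21)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pan, tf)
  back <- as_hap_panel(read_vcf(tf), region_length = pan$region_length)
  expect_identical(back$positions, pan$positions)
  expect_identical(back$site_ids, pan$site_ids)
  expect_identical(unname(back$alleles), unname(pan$alleles))
  expect_identical(back$ref, unname(pan$ref))
})

test_that("cohort genotypes and fixed calls round-trip, with missing and subsets", {
  pan <- simulate_panel(12, 10, seed = 22)
  g <- simulate_cohort(pan, 4, seed = 23)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, tf)
  v <- read_vcf(tf)
  expect_identical(unname(v$gt), unname(g$genotypes))

  gl <- compute_gl(simulate_reads(g, 1, seed = 24))
  calls <- hard_call(gl)
  write_vcf(calls, tf)
  v2 <- read_vcf(tf)
  expect_identical(unname(v2$gt), unname(calls$calls))

  arr <- simulate_array(g, array_fraction = 0.5, seed = 25)
  write_vcf(arr, tf)
  v3 <- read_vcf(tf)
  expect_identical(v3$site_ids, arr$site_ids)
  expect_identical(unname(v3$gt), unname(arr$calls))
})

test_that("PL fields carry likelihoods losslessly up to phred rounding", {
  pan <- simulate_panel(12, 8, seed = 26)
  g <- simulate_cohort(pan, 3, seed = 27)
  gl <- compute_gl(simulate_reads(g, 2, seed = 28))
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gl, tf)
  v <- read_vcf(tf)
  back <- as_geno_lik(v, error_rate = gl$error_rate)
  expect_identical(unname(back$depth), unname(gl$depth))
  # normalized log-likelihoods agree to within phred integer rounding
  norm <- function(a) a - array(rep(apply(a, c(1, 2), max), 3), dim(a))
  expect_equal(norm(back$loglik), norm(gl$loglik),
               tolerance = 0.06)  # 0.5 phred in natural log
})

test_that("dosage VCFs keep DS = GP1 + 2 GP2 and the R2 INFO field", {
  pan <- simulate_panel(12, 8, seed = 29)
  g <- simulate_cohort(pan, 5, seed = 30)
  imp <- impute_gl(compute_gl(simulate_reads(g, 1, seed = 31)), pan)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(imp, tf)
  v <- read_vcf(tf)
  expect_equal(unname(v$ds), unname(imp$ds), tolerance = 6e-4)
  ds_from_gp <- v$gp[, , 2] + 2 * v$gp[, , 3]
  expect_equal(unname(v$ds), unname(ds_from_gp), tolerance = 3e-3)
  expect_lt(max(abs(v$info_r2 - imp$info)), 5.01e-5)  # 4-decimal rounding
})

test_that("the reader rejects records it cannot honour", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\ts1\tAT\tA\t.\tPASS\t.\tGT\t0/1"), tf)
  expect_error(read_vcf(tf), "multiallelic or indel")

  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\ts1\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), tf)
  expect_error(read_vcf(tf), "multiallelic or indel")

  # a GT-only VCF cannot feed genotype-likelihood mode
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="G">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/1"), tf)
  expect_error(as_geno_lik(read_vcf(tf)), "PL")
})

test_that("weight tables round-trip through TSV", {
  w <- assign_effects(runif(20, 0.05, 0.5), 5, 0.2, seed = 32)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_weights(w, tf)
  back <- read_weights(tf)
  expect_identical(back$site_id, w$site_id)
  expect_identical(back$effect_allele, w$effect_allele)
  expect_equal(back$weight, w$weight, tolerance = 1e-12)
  expect_equal(back$p_value, w$p_value, tolerance = 1e-12)
})
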