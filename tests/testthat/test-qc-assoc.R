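test_that("HWE exact test: perfect proportions, symmetry, enumeration oracle", {
  # expected counts equal observed at maf 0.5 -> p close to 1
  expect_gt(hwe_exact_test(25, 50, 25), 0.9)
  # allele-label symmetry
  expect_identical(hwe_exact_test(3, 10, 80), hwe_exact_test(80, 10, 3))
  expect_error(hwe_exact_test(0, 0, 0), "zero")

  # worked triple against the enumeration oracle
  expect_equal(hwe_exact_test(57, 14, 50), enum_hwe(57, 14, 50),
               tolerance = 1e-10)

  # 100 random triples
  set.seed(7)
  for (i in 1:100) {
    tr <- as.integer(rmultinom(1, sample(10:200, 1), runif(3, 0.05, 1)))
    expect_equal(hwe_exact_test(tr[1], tr[2], tr[3]),
                 enum_hwe(tr[1], tr[2], tr[3]),
                 tolerance = 1e-9)
  }

  # chi-square approximation agrees at large balanced counts
  expect_equal(hwe_chisq_test(400, 800, 400), 1, tolerance = 1e-6)
})

test_that("QC removes exactly the planted violations, in order", {
  co <- toy_cohort(n = 400, m = 120, seed = 13)
  co <- inject_missingness(co, snp_rate = 0.1, n_snps = 10, seed = 4)
  bad_cr <- attr(co, "missing_snps")
  # plant 5 monomorphic SNPs (MAF 0) among the clean ones
  mono <- setdiff(seq_len(120), bad_cr)[1:5]
  co$dosages[, mono] <- 0
  res <- apply_qc(co, "T1")
  expect_identical(res$report$subjects_removed, 0L)
  expect_equal(res$report$snp_call_rate_removed, 10)
  expect_equal(res$report$snp_maf_removed, 5)
  expect_equal(res$report$snp_hwe_removed, 0)
  expect_identical(ncol(res$cohort$dosages), 120L - 15L)
})

test_that("QC catches injected HWE violations in controls", {
  co <- toy_cohort(n = 500, m = 80, seed = 17)
  co <- inject_hwe_violations(co, n_snps = 6, f = 0.95, seed = 5)
  res <- apply_qc(co, "T1")
  expect_identical(res$report$snp_hwe_removed, length(attr(co, "hwe_snps")))
})

test_that("subject filter precedes SNP filter: a SNP missing only in dropped subjects survives", {
  # 6 subjects x 4 SNPs; subject 1 misses 3 of 4 SNPs (call rate 0.25);
  # SNP 1 is missing only in subject 1, so once subject 1 is dropped its
  # call rate is 1 and it survives.
  dos <- matrix(1L, 6, 4)
  dos[1, c(1, 2, 3)] <- NA
  co <- smotescan:::new_cohort(
    dos,
    data.frame(chrom = 1L, pos = 1:4 * 10L, id = paste0("s", 1:4),
               ref = "A", alt = "C", stringsAsFactors = FALSE),
    data.frame(subject_id = paste0("S", 1:6), sex = rep(c("F", "M"), 3),
               age = rep(50, 6), stringsAsFactors = FALSE),
    matrix(c(0L, 1L, 0L, 1L, 0L, 1L), 6, 1, dimnames = list(NULL, "D")),
    list(D = integer(0)))
  co$dosages[, 4] <- c(NA, 0L, 2L, 0L, 2L, 1L)  # polymorphic, complete after drop
  co$dosages[, 2] <- c(NA, 0L, 2L, 1L, 1L, 2L)
  co$dosages[, 3] <- c(NA, 2L, 0L, 1L, 2L, 1L)
  co$dosages[, 1] <- c(NA, 1L, 1L, 2L, 0L, 1L)
  res <- apply_qc(co, "D", qc_thresholds(min_call_rate = 0.5))
  expect_identical(res$report$subjects_removed, 1L)
  expect_identical(res$report$snp_call_rate_removed, 0L)
  expect_true("s1" %in% res$cohort$snp_meta$id)
})

test_that("QC is idempotent", {
  co <- toy_cohort(n = 300, m = 60, seed = 19)
  co <- inject_missingness(co, snp_rate = 0.1, n_snps = 5, seed = 1)
  once <- apply_qc(co, "T1")
  twice <- apply_qc(once$cohort, "T1")
  expect_identical(twice$cohort$dosages, once$cohort$dosages)
  expect_identical(twice$report$snp_call_rate_removed, 0L)
})

test_that("allelic chi-square matches the textbook formula and its edge cases", {
  # identical allele frequencies -> statistic 0, p 1
  r0 <- smotescan:::allelic_chi2(10, 90, 100, 900)
  expect_equal(r0[1], 0)
  expect_equal(r0[2], 1)
  # hand-computed table: cases (30, 70), controls (10, 90)
  a <- 30; b <- 70; cc <- 10; d <- 90
  n <- a + b + cc + d
  stat <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  r1 <- smotescan:::allelic_chi2(a, b, cc, d)
  expect_equal(r1[1], stat, tolerance = 1e-12)
  expect_equal(r1[2], pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
  # against R's own chi-square test (no continuity correction)
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  expect_equal(r1[1], unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-10)
})

test_that("null p-values are uniform and lambda is calibrated", {
  co <- simulate_cohort(cohort_spec(2000, 2000, trait_spec("D", 0.1, n_causal = 0),
                                    maf_low = 0.05, maf_high = 0.5, seed = 55))
  at <- assoc_scan(co, "D")
  expect_true(all(at$p > 0 & at$p <= 1))
  ks <- suppressWarnings(ks.test(at$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  lam <- genomic_lambda(at)
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})

test_that("logistic scan is invariant to adding a constant to a SNP's dosages", {
  co <- toy_cohort(n = 300, m = 10, seed = 29)
  p1 <- assoc_scan(co, "T1", method = "logistic_dosage")$p
  co$dosages <- co$dosages + 0.5   # affine shift, also forces fractional path
  p2 <- assoc_scan(co, "T1")$p
  expect_identical(attr(assoc_scan(co, "T1"), "method"), "logistic_dosage")
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("logistic scan agrees with stats::glm on a fractional-dosage cohort", {
  co <- toy_cohort(n = 250, m = 5, seed = 31)
  co$dosages <- co$dosages + matrix(runif(250 * 5, 0, 0.4), 250, 5)
  at <- assoc_scan(co, "T1", method = "logistic_dosage")
  j <- 3
  fit <- glm(co$traits[, "T1"] ~ co$dosages[, j] +
               I(co$subjects$sex == "M") + co$subjects$age,
             family = binomial())
  p_ref <- summary(fit)$coefficients[2, 4]
  # two independently converged optimizers (Newton here, IRLS in glm)
  expect_equal(at$p[order(match(at$id, co$snp_meta$id))][j], p_ref,
               tolerance = 3e-6)
})

test_that("separation is flagged as p = 1, not dropped", {
  dos <- matrix(c(rep(2L, 10), rep(0L, 10)), ncol = 1)
  co <- smotescan:::new_cohort(
    dos,
    data.frame(chrom = 1L, pos = 100L, id = "s1", ref = "A", alt = "C",
               stringsAsFactors = FALSE),
    data.frame(subject_id = paste0("S", 1:20), sex = rep(c("F", "M"), 10),
               age = runif(20, 30, 70), stringsAsFactors = FALSE),
    matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1, dimnames = list(NULL, "D")),
    list(D = integer(0)))
  at <- assoc_scan(co, "D", method = "logistic_dosage")
  expect_identical(nrow(at), 1L)
  expect_identical(at$p, 1)
  expect_identical(at$flag, "nonconverged")
})
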