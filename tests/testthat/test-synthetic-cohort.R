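test_that("null-model trait prevalence matches the target", {
  n <- 4000
  spec <- cohort_spec(n, 50, trait_spec("D", 0.1, n_causal = 0),
                      seed = 11)
  co <- simulate_cohort(spec)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(co$traits[, "D"]) - 0.1), 3 * se)
})

test_that("same-block traits are more phi-correlated than cross-block, over seeds", {
  diffs <- vapply(1:20, function(s) {
    spec <- cohort_spec(600, 20,
                        list(trait_spec("A", 0.15, n_causal = 0),
                             trait_spec("B", 0.15, n_causal = 0),
                             trait_spec("C", 0.15, n_causal = 0)),
                        comorbidity_groups = list(c(1, 2), 3), seed = s)
    co <- simulate_cohort(spec)
    within <- phi_correlation(co$traits[, 1], co$traits[, 2])
    cross <- mean(c(phi_correlation(co$traits[, 1], co$traits[, 3]),
                    phi_correlation(co$traits[, 2], co$traits[, 3])))
    within - cross
  }, 0)
  expect_gt(mean(diffs), 0)
  # and phi here agrees with generic Pearson correlation to near machine precision
  spec <- cohort_spec(600, 10, list(trait_spec("A", 0.2), trait_spec("B", 0.2)),
                      seed = 3)
  co <- simulate_cohort(spec)
  expect_lt(abs(phi_correlation(co$traits[, 1], co$traits[, 2]) -
                  cor(co$traits[, 1], co$traits[, 2])), 1e-12)
})

test_that("simulation is bit-identical under the same spec and seed", {
  spec <- cohort_spec(300, 80, trait_spec("D", 0.1), seed = 5)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
  spec2 <- cohort_spec(300, 80, trait_spec("D", 0.1), seed = 6)
  expect_false(identical(simulate_cohort(spec), simulate_cohort(spec2)))
})

test_that("empirical MAF tracks the drawn MAF within 3 binomial SE", {
  co <- simulate_cohort(cohort_spec(1500, 300, trait_spec("D", 0.1),
                                    maf_low = 0.05, maf_high = 0.5, seed = 9))
  emp <- colMeans(co$dosages) / 2
  se <- sqrt(co$maf * (1 - co$maf) / (2 * 1500))
  expect_true(all(abs(emp - co$maf) < 3.5 * se))  # 300 SNPs; allow tail room
  expect_gt(mean(abs(emp - co$maf) < 3 * se), 0.98)
})

test_that("impossible prevalence fails with the trait named", {
  spec <- cohort_spec(200, 10,
                      trait_spec("sat", 0.999, n_causal = 2, effect_size = -60),
                      maf_low = 0.4, maf_high = 0.5)
  expect_error(simulate_cohort(spec), "sat")
})

test_that("injected missingness hits exactly the designated SNPs and subjects", {
  co <- toy_cohort(n = 200, m = 60)
  expect_identical(inject_missingness(co, 0, 0)$dosages, co$dosages)

  hit <- inject_missingness(co, snp_rate = 0.1, n_snps = 10, seed = 2)
  cr <- colMeans(!is.na(hit$dosages))
  expect_identical(which(cr <= 0.95), structure(attr(hit, "missing_snps"),
                                                names = NULL))
  expect_length(attr(hit, "missing_snps"), 10)

  hit2 <- inject_missingness(co, subject_rate = 0.1, n_subjects = 5, seed = 2)
  scr <- rowMeans(!is.na(hit2$dosages))
  expect_identical(which(scr <= 0.95), structure(attr(hit2, "missing_subjects"),
                                                 names = NULL))
  # original untouched
  expect_false(anyNA(co$dosages))
})

test_that("cohort round-trips through VCF + TSV", {
  co <- toy_cohort(n = 10, m = 20, seed = 1)
  co$dosages[3, 7] <- NA
  td <- withr::local_tempdir()
  write_cohort(co, file.path(td, "c.vcf"), file.path(td, "p.tsv"))
  back <- read_cohort(file.path(td, "c.vcf"), file.path(td, "p.tsv"))
  expect_equal(back$dosages, unname(co$dosages), tolerance = 1e-6)
  expect_identical(back$snp_meta, co$snp_meta)
  expect_identical(back$traits, co$traits)
  expect_identical(back$causal_truth, co$causal_truth)
  expect_equal(back$maf, co$maf, tolerance = 1e-6)

  # fractional dosages survive via DS
  aug <- co
  aug$dosages[1, 1] <- 0.731234
  write_cohort(aug, file.path(td, "c2.vcf"), file.path(td, "p2.tsv"))
  back2 <- read_cohort(file.path(td, "c2.vcf"), file.path(td, "p2.tsv"))
  expect_equal(back2$dosages[1, 1], 0.731234, tolerance = 1e-6)
})

test_that("malformed inputs are rejected with location", {
  co <- toy_cohort(n = 6, m = 8, seed = 2)
  td <- withr::local_tempdir()
  write_cohort(co, file.path(td, "c.vcf"), file.path(td, "p.tsv"))

  # phenotype missing the sex column
  ph <- read.delim(file.path(td, "p.tsv"))
  ph$sex <- NULL
  write.table(ph, file.path(td, "nosex.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_cohort(file.path(td, "c.vcf"), file.path(td, "nosex.tsv")),
               "sex")

  # unsorted VCF positions
  lines <- readLines(file.path(td, "c.vcf"))
  body_start <- grep("^#CHROM", lines) + 1L
  lines[c(body_start, body_start + 1L)] <- lines[c(body_start + 1L, body_start)]
  writeLines(lines, file.path(td, "unsorted.vcf"))
  expect_error(read_cohort(file.path(td, "unsorted.vcf"), file.path(td, "p.tsv")),
               "out of order|increasing")

  # truncated row
  lines2 <- readLines(file.path(td, "c.vcf"))
  lines2[body_start] <- sub("\t[^\t]*$", "", lines2[body_start])
  writeLines(lines2, file.path(td, "short.vcf"))
  expect_error(read_cohort(file.path(td, "short.vcf"), file.path(td, "p.tsv")),
               "line")
})

test_that("written VCF is readable by an independent parser", {
  skip_if_not_installed("vcfR")
  co <- toy_cohort(n = 8, m = 12, seed = 3)
  td <- withr::local_tempdir()
  write_cohort(co, file.path(td, "c.vcf"), file.path(td, "p.tsv"))
  v <- vcfR::read.vcfR(file.path(td, "c.vcf"), verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  expect_equal(unname(t(gt)), unname(co$dosages), tolerance = 1e-6)
})

test_that("causal SNPs show stronger association signal than null SNPs", {
  spec <- cohort_spec(2000, 400, trait_spec("D", 0.2, n_causal = 8,
                                            effect_size = 0.6),
                      maf_low = 0.1, maf_high = 0.5, seed = 21)
  co <- simulate_cohort(spec)
  at <- assoc_scan(co, "D")
  causal <- co$causal_truth$D
  expect_lt(median(at$p[causal]), median(at$p[-causal]))
})
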