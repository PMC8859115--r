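test_that("k-NN neighbor lists: collinear, duplicates, k = n-1", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  nn <- knn_minority(X, 1)
  expect_identical(nn, list(2L, 1L, 2L))
  # duplicate point is its own nearest neighbor (distance 0)
  Xd <- matrix(c(0, 0, 5, 9), ncol = 1)
  nnd <- knn_minority(Xd, 1)
  expect_identical(nnd[[1]], 2L)
  expect_identical(nnd[[2]], 1L)
  # k = n - 1 lists every other sample
  nall <- knn_minority(Xd, 3)
  for (i in 1:4) expect_setequal(nall[[i]], setdiff(1:4, i))
  expect_error(knn_minority(Xd, 4), "k\\+1")
})

test_that("SMOTE formula: gamma endpoints and provenance recomputation", {
  set.seed(2)
  X <- matrix(runif(40, 0, 2), 10, 4)
  g0 <- smote_generate(X, 3, 25, seed = 1, gamma_fixed = 0)
  expect_equal(g0$X, X[g0$provenance$base, ], ignore_attr = TRUE)
  g1 <- smote_generate(X, 3, 25, seed = 1, gamma_fixed = 1)
  expect_equal(g1$X, X[g1$provenance$neighbor, ], ignore_attr = TRUE)

  gen <- smote_generate(X, 3, 50, seed = 9)
  pr <- gen$provenance
  recon <- X[pr$base, ] + (X[pr$neighbor, ] - X[pr$base, ]) * pr$gamma
  expect_equal(gen$X, recon, ignore_attr = TRUE)
  # interpolation stays inside the attribute-wise envelope
  lo <- pmin(X[pr$base, ], X[pr$neighbor, ])
  hi <- pmax(X[pr$base, ], X[pr$neighbor, ])
  expect_true(all(gen$X >= lo - 1e-12 & gen$X <= hi + 1e-12))
  expect_error(smote_generate(X, 3, -1), "n_new")
})

test_that("determinism under seed; distinct seeds give distinct gamma streams", {
  X <- matrix(runif(30), 10, 3)
  a <- smote_generate(X, 2, 20, seed = 5)
  b <- smote_generate(X, 2, 20, seed = 5)
  expect_identical(a, b)
  c3 <- smote_generate(X, 2, 20, seed = 6)
  expect_false(identical(a$provenance$gamma, c3$provenance$gamma))
})

test_that("stratified counts equal round(ratio x majority) per stratum", {
  # construct a cohort with designed per-stratum majority counts
  maj <- c(100, 200, 50, 50, 100, 100, 200, 200)
  n_cases_per <- 8
  ages <- c(40, 50, 57, 65)   # one per band given breaks 47/55/60
  subj <- NULL; traits <- NULL
  for (s in 1:8) {
    sex <- if (s <= 4) "F" else "M"
    age <- ages[(s - 1) %% 4 + 1]
    n_s <- maj[s] + n_cases_per
    subj <- rbind(subj, data.frame(
      subject_id = sprintf("S%d_%03d", s, seq_len(n_s)), sex = sex,
      age = age, stringsAsFactors = FALSE))
    traits <- c(traits, rep(1L, n_cases_per), rep(0L, maj[s]))
  }
  n <- nrow(subj)
  set.seed(31)
  co <- smotescan:::new_cohort(
    matrix(rbinom(n * 6, 2, 0.3), n, 6),
    data.frame(chrom = 1L, pos = 1:6 * 100L, id = paste0("s", 1:6),
               ref = "A", alt = "C", stringsAsFactors = FALSE),
    subj, matrix(traits, ncol = 1, dimnames = list(NULL, "D")),
    list(D = integer(0)))
  aug <- stratified_smote(co, "D", smote_config(0.1, seed = 7))
  expect_equal(sum(aug$synthetic), sum(round(0.1 * maj)))
  pr <- attr(aug, "smote_provenance")
  per_stratum <- table(pr$stratum)
  expect_identical(as.integer(per_stratum), as.integer(round(0.1 * maj)))
  # synthetic rows are cases with sex/age inherited from their base sample
  syn <- which(aug$synthetic)
  expect_true(all(aug$traits[syn, "D"] == 1L))
  expect_identical(aug$subjects$age[syn], aug$subjects$age[pr$base])
  expect_identical(aug$subjects$sex[syn], aug$subjects$sex[pr$base])
  # controls untouched
  expect_equal(aug$dosages[seq_len(n), ], co$dosages)

  # ratio small enough that every stratum rounds to zero -> unchanged
  none <- stratified_smote(co, "D", smote_config(0.001, seed = 7))
  expect_identical(nrow(none$dosages), n)
})

test_that("synthetic dosages respect the stratum convex envelope", {
  co <- toy_cohort(n = 600, m = 40, seed = 37, prevalence = 0.15)
  aug <- stratified_smote(co, "T1", smote_config(0.1, seed = 3))
  pr <- attr(aug, "smote_provenance")
  syn_rows <- which(aug$synthetic)
  stratum <- assign_strata(co$subjects)
  y <- co$traits[, "T1"]
  for (s in unique(pr$stratum)) {
    cases <- which(stratum == s & y == 1)
    lo <- apply(co$dosages[cases, , drop = FALSE], 2, min)
    hi <- apply(co$dosages[cases, , drop = FALSE], 2, max)
    rows <- syn_rows[pr$stratum == s]
    X <- aug$dosages[rows, , drop = FALSE]
    expect_true(all(t(X) >= lo - 1e-12 & t(X) <= hi + 1e-12))
  }
  # post-SMOTE MAF drift of the case group stays small at ratio <= 0.1
  case_mean_before <- colMeans(co$dosages[y == 1, , drop = FALSE])
  aug_y <- aug$traits[, "T1"]
  case_mean_after <- colMeans(aug$dosages[aug_y == 1, , drop = FALSE])
  expect_lt(mean(abs(case_mean_after - case_mean_before)), 0.05)
})

test_that("sparse strata fall back by reducing k or merging age bands", {
  # 7 cases total, all female and nearly all in one band
  subj <- data.frame(subject_id = sprintf("S%03d", 1:200),
                     sex = rep(c("F", "M"), 100),
                     age = runif(200, 30, 70), stringsAsFactors = FALSE)
  set.seed(41)
  y <- integer(200)
  y[which(subj$sex == "F")[1:7]] <- 1L
  co <- smotescan:::new_cohort(
    matrix(rbinom(200 * 5, 2, 0.4), 200, 5),
    data.frame(chrom = 1L, pos = 1:5 * 50L, id = paste0("s", 1:5),
               ref = "A", alt = "C", stringsAsFactors = FALSE),
    subj, matrix(y, ncol = 1, dimnames = list(NULL, "D")),
    list(D = integer(0)))
  aug <- stratified_smote(co, "D", smote_config(0.1, k_neighbors = 5, seed = 2))
  expect_gt(sum(aug$synthetic), 0)
  pr <- attr(aug, "smote_provenance")
  recon <- co$dosages[pr$base, ] + (co$dosages[pr$neighbor, ] -
                                      co$dosages[pr$base, ]) * pr$gamma
  expect_equal(unname(aug$dosages[aug$synthetic, ]), unname(recon))
})

test_that("mixed ratio plan echoes ratios and validates names", {
  plan <- mixed_ratio_plan(c(A = 0.001, B = 0.005, C = 0.03),
                           trait_names = c("A", "B", "C"))
  expect_identical(names(plan), c("A", "B", "C"))
  expect_identical(vapply(plan, `[[`, 0, "ratio"),
                   c(A = 0.001, B = 0.005, C = 0.03))
  expect_length(mixed_ratio_plan(list()), 0)
  expect_error(mixed_ratio_plan(c(A = 0.1, A = 0.2)), "duplicate")
  expect_error(mixed_ratio_plan(c(A = 0.1, Z = 0.2), trait_names = c("A", "B")),
               "unknown trait")
})
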