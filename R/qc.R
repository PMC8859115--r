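#' Quality-control thresholds
#'
#' Subjects and SNPs are retained only when strictly above each threshold:
#' call rate > `min_call_rate`, MAF > `min_maf`, exact HWE p > `hwe_alpha`.
#'
#' @param min_call_rate Minimum call rate (default 0.95).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level (default 0.001).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          hwe_alpha = 0.001) {
  for (v in c(min_call_rate, min_maf, hwe_alpha))
    if (!(v > 0 && v < 1)) stop("thresholds must lie in (0, 1)")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha), class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test (Levene-Haldane distribution): given the genotype
#' counts, all heterozygote counts compatible with the observed allele totals
#' are enumerated, and the p-value is the summed probability of outcomes no
#' more probable than the observed one (no mid-p correction). Symmetric in
#' allele labelling: `hwe_exact_test(a, b, c) == hwe_exact_test(c, b, a)`.
#'
#' Probabilities follow the standard recurrence
#' P(nAB+2)/P(nAB) relation on the hypergeometric-like kernel, normalized at
#' the end, which is stable for large counts.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, not all zero).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_aa + n_Aa           # minor or major, symmetric below
  rare <- min(n_a, 2 * n - n_a)    # rarer allele count
  # heterozygote counts share the parity of the rare allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  logp <- numeric(length(het_vals))
  # log unnormalized probability: P(nAB) proportional to
  # 1 / (nAA! nAB! nBB!) * 2^nAB with nAA=(rare-nAB)/2 rare-homs etc.
  for (i in seq_along(het_vals)) {
    nab <- het_vals[i]
    naa <- (rare - nab) / 2
    nbb <- n - naa - nab
    logp[i] <- nab * log(2) - lfactorial(naa) - lfactorial(nab) - lfactorial(nbb)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(het_vals == n_Aa)
  if (!length(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit approximation, provided as a
#' cross-check for [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return Approximate p-value.
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- n * c(p^2, 2 * p * q, q^2)
  if (any(e == 0)) return(1)
  stat <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Apply quality-control filters to a cohort
#'
#' Filters in PLINK-conventional order: (1) subjects with call rate <=
#' `min_call_rate`; then on the retained subjects (2) SNPs with call rate <=
#' `min_call_rate`; (3) SNPs with MAF <= `min_maf`; (4) SNPs whose exact HWE
#' p-value, computed in the controls of `trait`, is <= `hwe_alpha`. All
#' inequalities are strict, so records failing exactly at a threshold are
#' removed.
#'
#' @param cohort A `cohort`.
#' @param trait Trait name whose controls define the HWE test set.
#' @param thresholds A [qc_thresholds()].
#' @return A list with the filtered `cohort` and a `report` listing counts
#'   removed per criterion in application order.
#' @export
apply_qc <- function(cohort, trait, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "cohort"))
  if (!trait %in% colnames(cohort$traits))
    stop("unknown trait '", trait, "'")
  dos <- cohort$dosages

  subj_cr <- rowMeans(!is.na(dos))
  keep_subj <- subj_cr > thresholds$min_call_rate
  n_subj_removed <- sum(!keep_subj)
  if (!any(keep_subj)) stop("no subjects survive the call-rate filter")
  cohort <- subset_cohort(cohort, subjects = keep_subj)
  dos <- cohort$dosages

  snp_cr <- colMeans(!is.na(dos))
  fail_cr <- snp_cr <= thresholds$min_call_rate

  p_alt <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  fail_maf <- !fail_cr & (is.na(maf) | maf <= thresholds$min_maf)

  controls <- cohort$traits[, trait] == 0L
  g <- round(dos[controls, , drop = FALSE])
  fail_hwe <- rep(FALSE, ncol(dos))
  for (j in which(!fail_cr & !fail_maf)) {
    gj <- g[, j]
    n_aa <- sum(gj == 0, na.rm = TRUE)
    n_ab <- sum(gj == 1, na.rm = TRUE)
    n_bb <- sum(gj == 2, na.rm = TRUE)
    if (n_aa + n_ab + n_bb == 0) next
    fail_hwe[j] <- hwe_exact_test(n_aa, n_ab, n_bb) <= thresholds$hwe_alpha
  }

  keep_snp <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep_snp)) stop("no SNPs survive QC")
  out <- subset_cohort(cohort, snps = keep_snp)
  report <- structure(list(subjects_removed = n_subj_removed,
                           snp_call_rate_removed = sum(fail_cr),
                           snp_maf_removed = sum(fail_maf),
                           snp_hwe_removed = sum(fail_hwe),
                           thresholds = thresholds),
                      class = "qc_report")
  list(cohort = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> removed:", x$subjects_removed, "subjects (call rate);",
      x$snp_call_rate_removed, "SNPs (call rate);",
      x$snp_maf_removed, "SNPs (MAF);",
      x$snp_hwe_removed, "SNPs (HWE)\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report[c("subjects_removed",
                                        "snp_call_rate_removed",
                                        "snp_maf_removed",
                                        "snp_hwe_removed")]),
                       path, auto_unbox = TRUE)
  invisible(path)
}
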