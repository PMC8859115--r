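new_assoc_table <- function(chrom, pos, id, stat, p, flag) {
  df <- data.frame(chrom = chrom, pos = pos, id = id, stat = stat, p = p,
                   flag = flag, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("assoc_table", "data.frame")
  df
}

#' Per-SNP association scan
#'
#' Computes one association p-value per SNP for a binary trait — the
#' y-values of the Manhattan plot.
#'
#' * `allelic_chi2`: 2x2 allele-count chi-square (1 df, no continuity
#'   correction) on rounded dosages; the classic GWAS allelic test.
#' * `logistic_dosage`: per-SNP logistic regression of the trait on dosage +
#'   sex + age with a Wald p-value on the dosage coefficient. Required for
#'   SMOTE-augmented cohorts, whose interpolated dosages are fractional and
#'   have no allele counts.
#'
#' `method = "auto"` picks `allelic_chi2` when every dosage is an integer and
#' `logistic_dosage` otherwise. Non-convergence or separation is recorded as
#' p = 1 with flag `"nonconverged"`, never dropped.
#'
#' @param cohort A `cohort`.
#' @param trait Binary trait name with at least one case and one control.
#' @param method `"auto"`, `"allelic_chi2"` or `"logistic_dosage"`.
#' @return An `assoc_table` data frame: `chrom`, `pos`, `id`, `stat`, `p` in
#'   (0, 1], `flag`; sorted by (chrom, pos), with attributes `n_cases`,
#'   `n_controls` and `method`.
#' @export
assoc_scan <- function(cohort, trait,
                       method = c("auto", "allelic_chi2", "logistic_dosage")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort"))
  if (!trait %in% colnames(cohort$traits))
    stop("unknown trait '", trait, "'")
  y <- cohort$traits[, trait]
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    stop("trait '", trait, "' needs at least one case and one control")
  dos <- cohort$dosages
  if (method == "auto") {
    frac <- any(abs(dos - round(dos)) > 1e-9, na.rm = TRUE)
    method <- if (frac) "logistic_dosage" else "allelic_chi2"
  }
  m <- ncol(dos)
  stat <- rep(NA_real_, m); p <- rep(1, m); flag <- rep("", m)

  if (method == "allelic_chi2") {
    g <- round(dos)
    case <- y == 1
    for (j in seq_len(m)) {
      gj <- g[, j]
      ok <- !is.na(gj)
      a1 <- sum(gj[ok & case]); n1 <- 2 * sum(ok & case)   # alt, total case alleles
      a0 <- sum(gj[ok & !case]); n0 <- 2 * sum(ok & !case)
      res <- allelic_chi2(a1, n1 - a1, a0, n0 - a0)
      stat[j] <- res[1]; p[j] <- res[2]
      if (is.na(res[1])) flag[j] <- "degenerate"
    }
  } else {
    covar <- cbind(1, as.numeric(cohort$subjects$sex == "M"),
                   cohort$subjects$age)
    null_fit <- suppressWarnings(glm.fit(covar, y, family = binomial()))
    eta0 <- covar %*% null_fit$coefficients
    res <- logistic_scan_cpp(dos, as.numeric(y), covar, as.numeric(eta0))
    conv <- res$converged == 1L
    stat[conv] <- res$stat[conv]
    p[conv] <- pchisq(res$stat[conv], df = 1, lower.tail = FALSE)
    p[!conv] <- 1
    flag[!conv] <- "nonconverged"
  }
  p[p <= 0] <- .Machine$double.xmin
  out <- new_assoc_table(cohort$snp_meta$chrom, cohort$snp_meta$pos,
                         cohort$snp_meta$id, stat, p, flag)
  attr(out, "n_cases") <- sum(y == 1)
  attr(out, "n_controls") <- sum(y == 0)
  attr(out, "method") <- method
  out
}

# 2x2 allele-count chi-square: (alt, ref) x (case, control).
allelic_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(c(NA_real_, 1))
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  c(stat, pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Genomic-control lambda
#'
#' Median chi-square statistic divided by the null median (0.456), a
#' standard check that an association scan is calibrated: values near 1
#' indicate neither inflation nor deflation.
#'
#' @param assoc An `assoc_table`.
#' @return Lambda (numeric).
#' @export
genomic_lambda <- function(assoc) {
  stat <- assoc$stat
  if (all(is.na(stat))) stat <- qchisq(assoc$p, df = 1, lower.tail = FALSE)
  median(stat, na.rm = TRUE) / qchisq(0.5, df = 1, lower.tail = FALSE)
}
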