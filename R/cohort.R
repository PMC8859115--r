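#' Describe one binary trait for cohort simulation
#'
#' @param name Trait name (unique within a cohort).
#' @param prevalence Target population prevalence in (0, 1). Heavily
#'   imbalanced designs use 0.01-0.2 (case:control roughly 1:100 to 1:4).
#' @param n_causal Number of causal SNPs for the trait.
#' @param effect_size Per-allele log-odds at each causal SNP.
#' @param sex_effect Log-odds added for male subjects.
#' @param age_effect Log-odds per year of age (centered at 50).
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, prevalence, n_causal = 5, effect_size = 0.5,
                       sex_effect = 0, age_effect = 0) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must lie in (0, 1)")
  stopifnot(n_causal >= 0)
  structure(list(name = name, prevalence = prevalence, n_causal = n_causal,
                 effect_size = effect_size, sex_effect = sex_effect,
                 age_effect = age_effect),
            class = "trait_spec")
}

#' Specify a synthetic case-control cohort
#'
#' Defines the generative model for an imbalanced biobank-like cohort:
#' biallelic autosomal SNPs in Hardy-Weinberg proportions with uniform minor
#' allele frequencies, binary traits assigned by a logistic model on causal
#' dosages plus sex and age, and a designed comorbidity structure in which
#' traits of the same block share a latent Gaussian risk factor.
#'
#' @param n_subjects,n_snps Cohort dimensions.
#' @param traits List of [trait_spec()] objects.
#' @param n_chromosomes Autosomes to spread SNPs across (default 22).
#' @param maf_low,maf_high Bounds of the uniform minor-allele-frequency
#'   distribution; must satisfy `0 < maf_low <= maf_high <= 0.5`.
#' @param comorbidity_groups Partition of trait indices into blocks, as a
#'   list of integer vectors. Defaults to every trait in its own block.
#' @param comorbidity_strength Loading of the shared per-block latent factor
#'   on each member trait's linear predictor.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects, n_snps, traits, n_chromosomes = 22,
                        maf_low = 0.01, maf_high = 0.5,
                        comorbidity_groups = NULL,
                        comorbidity_strength = 1.5, seed = 1L) {
  stopifnot(n_subjects >= 2, n_snps >= 1, n_chromosomes >= 1)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1, all(vapply(traits, inherits, TRUE, "trait_spec")))
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate trait names")
  for (tr in traits)
    if (tr$n_causal > n_snps) stop("n_causal exceeds n_snps for trait ", tr$name)
  nt <- length(traits)
  if (is.null(comorbidity_groups))
    comorbidity_groups <- as.list(seq_len(nt))
  comorbidity_groups <- lapply(comorbidity_groups, as.integer)
  idx <- sort(unlist(comorbidity_groups))
  if (!identical(idx, seq_len(nt)))
    stop("comorbidity_groups must partition trait indices 1..", nt)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 maf_low = maf_low, maf_high = maf_high, traits = traits,
                 comorbidity_groups = comorbidity_groups,
                 comorbidity_strength = comorbidity_strength,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

new_cohort <- function(dosages, snp_meta, subjects, traits, causal_truth,
                       maf = NULL, synthetic = NULL) {
  if (is.null(synthetic)) synthetic <- rep(FALSE, nrow(dosages))
  structure(list(dosages = dosages, snp_meta = snp_meta, subjects = subjects,
                 traits = traits, causal_truth = causal_truth, maf = maf,
                 synthetic = synthetic),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d synthetic) x %d SNPs, %d trait(s): %s\n",
              nrow(x$dosages), sum(x$synthetic), ncol(x$dosages),
              ncol(x$traits), paste(colnames(x$traits), collapse = ", ")))
  invisible(x)
}

# Bisection for the trait intercept: mean(plogis(b + eta)) == prevalence.
find_intercept <- function(eta, prevalence, trait_name) {
  f <- function(b) mean(plogis(b + eta)) - prevalence
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop("cannot reach prevalence ", prevalence, " for trait '", trait_name,
         "': intercept search fails to bracket")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate an imbalanced case-control cohort
#'
#' Draws genotypes per SNP as binomial(2, maf) with maf ~ Uniform(maf_low,
#' maf_high) (Hardy-Weinberg proportions, no linkage disequilibrium), ages
#' Uniform(30, 70), sex Bernoulli(1/2), and assigns each binary trait from a
#' logistic model on its causal dosages, sex, age, and a latent factor shared
#' within its comorbidity block. The trait intercept is found by bisection so
#' the expected prevalence matches the target. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` object: integer dosage matrix in 0/1/2 (NA for
#'   missing), SNP metadata (chromosome, 1-based position, id, ref/alt),
#'   subject table (id, sex, age), binary trait matrix, the per-trait causal
#'   SNP indices in `causal_truth`, and the drawn per-SNP `maf`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects; m <- spec$n_snps
  maf <- runif(m, spec$maf_low, spec$maf_high)
  dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)

  chrom <- sort(rep_len(seq_len(spec$n_chromosomes), m))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    j <- which(chrom == cc)
    pos[j] <- sort(sample.int(2.5e8, length(j)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  snp_meta <- data.frame(chrom = chrom, pos = pos,
                         id = sprintf("snp%06d", seq_len(m)),
                         ref = ref, alt = unname(alt),
                         stringsAsFactors = FALSE)
  rownames(snp_meta) <- NULL

  subjects <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(runif(n, 30, 70), 1),
    stringsAsFactors = FALSE)

  nt <- length(spec$traits)
  nblock <- length(spec$comorbidity_groups)
  z <- matrix(rnorm(n * nblock), n, nblock)
  block_of <- integer(nt)
  for (b in seq_len(nblock)) block_of[spec$comorbidity_groups[[b]]] <- b

  traits <- matrix(0L, n, nt,
                   dimnames = list(NULL, vapply(spec$traits, `[[`, "", "name")))
  causal_truth <- vector("list", nt)
  names(causal_truth) <- colnames(traits)
  sexM <- as.numeric(subjects$sex == "M")
  agec <- subjects$age - 50
  for (t in seq_len(nt)) {
    tr <- spec$traits[[t]]
    causal <- if (tr$n_causal > 0) sort(sample.int(m, tr$n_causal)) else integer(0)
    causal_truth[[t]] <- causal
    eta <- tr$sex_effect * sexM + tr$age_effect * agec +
      spec$comorbidity_strength * z[, block_of[t]]
    if (length(causal))
      eta <- eta + as.numeric(dos[, causal, drop = FALSE] %*%
                                rep(tr$effect_size, length(causal)))
    b0 <- find_intercept(eta, tr$prevalence, tr$name)
    traits[, t] <- rbinom(n, 1L, plogis(b0 + eta))
  }
  new_cohort(dos, snp_meta, subjects, traits, causal_truth, maf = maf)
}

#' Inject genotype missingness into a cohort
#'
#' Places NA sentinels so that designated SNPs and/or subjects fall to a
#' chosen call rate, for exercising call-rate quality-control filters. The
#' input cohort is not modified.
#'
#' @param cohort A `cohort`.
#' @param subject_rate,snp_rate Fraction of entries set missing within each
#'   designated subject / SNP, in `[0, 1)`. A designated SNP's call rate
#'   becomes `1 - snp_rate` (up to rounding).
#' @param n_subjects,n_snps How many subjects / SNPs to designate (drawn at
#'   random).
#' @param seed RNG seed.
#' @return A new `cohort` with attributes `missing_snps` and
#'   `missing_subjects` recording the designated indices.
#' @export
inject_missingness <- function(cohort, subject_rate = 0, snp_rate = 0,
                               n_subjects = 0, n_snps = 0, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"),
            subject_rate >= 0, subject_rate < 1,
            snp_rate >= 0, snp_rate < 1)
  out <- cohort
  set.seed(seed)
  n <- nrow(out$dosages); m <- ncol(out$dosages)
  snps <- subj <- integer(0)
  if (snp_rate > 0 && n_snps > 0) {
    snps <- sort(sample.int(m, n_snps))
    k <- round(snp_rate * n)
    for (j in snps) out$dosages[sample.int(n, k), j] <- NA
  }
  if (subject_rate > 0 && n_subjects > 0) {
    subj <- sort(sample.int(n, n_subjects))
    k <- round(subject_rate * m)
    for (i in subj) out$dosages[i, sample.int(m, k)] <- NA
  }
  attr(out, "missing_snps") <- snps
  attr(out, "missing_subjects") <- subj
  out
}

#' Inject Hardy-Weinberg-violating SNPs
#'
#' Resamples the genotypes of `n_snps` randomly chosen SNPs under an
#' inbreeding-coefficient distortion of their empirical allele frequency:
#' P(AA) = p^2 + f*p*q, P(Aa) = 2pq(1-f), P(aa) = q^2 + f*p*q. With large `f`
#' these SNPs show a strong heterozygote deficit and fail an exact HWE test.
#'
#' @param cohort A `cohort`.
#' @param n_snps Number of SNPs to distort.
#' @param f Inbreeding coefficient in (0, 1].
#' @param seed RNG seed.
#' @return A new cohort with attribute `hwe_snps` (the distorted indices).
#' @export
inject_hwe_violations <- function(cohort, n_snps, f = 0.9, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), f > 0, f <= 1)
  set.seed(seed)
  out <- cohort
  n <- nrow(out$dosages)
  snps <- sort(sample.int(ncol(out$dosages), n_snps))
  for (j in snps) {
    p <- mean(out$dosages[, j], na.rm = TRUE) / 2
    q <- 1 - p
    probs <- c(q^2 + f * p * q, 2 * p * q * (1 - f), p^2 + f * p * q)
    out$dosages[, j] <- sample(0:2, n, replace = TRUE, prob = probs)
  }
  attr(out, "hwe_snps") <- snps
  out
}

# Subset a cohort by subject and/or SNP index, keeping metadata aligned.
subset_cohort <- function(cohort, subjects = NULL, snps = NULL) {
  out <- cohort
  if (!is.null(subjects)) {
    out$dosages <- out$dosages[subjects, , drop = FALSE]
    out$subjects <- out$subjects[subjects, , drop = FALSE]
    rownames(out$subjects) <- NULL
    out$traits <- out$traits[subjects, , drop = FALSE]
    out$synthetic <- out$synthetic[subjects]
  }
  if (!is.null(snps)) {
    out$dosages <- out$dosages[, snps, drop = FALSE]
    out$snp_meta <- out$snp_meta[snps, , drop = FALSE]
    rownames(out$snp_meta) <- NULL
    if (!is.null(out$maf)) out$maf <- out$maf[snps]
    keep <- if (is.logical(snps)) which(snps) else snps
    out$causal_truth <- lapply(out$causal_truth, function(ix)
      match(intersect(ix, keep), keep))
  }
  out
}
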