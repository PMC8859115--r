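#' Covariate stratification rules for SMOTE
#'
#' Eight strata: 2 sexes x 4 age bands, with the age bands cut at the three
#' break ages (defaults 47, 55, 60 — the cohort's 25/50/75 age percentiles
#' in the motivating design).
#'
#' @param age_breaks Three strictly increasing break ages.
#' @return A `strata_spec`.
#' @export
strata_spec <- function(age_breaks = c(47, 55, 60)) {
  stopifnot(length(age_breaks) == 3)
  if (any(diff(age_breaks) <= 0)) stop("age_breaks must be strictly increasing")
  structure(list(age_breaks = age_breaks), class = "strata_spec")
}

#' Assign subjects to sex x age-quartile strata
#'
#' @param subjects Data frame with `sex` ("F"/"M") and `age` columns.
#' @param strata A [strata_spec()].
#' @return Integer stratum id in 1..8 (F bands 1-4, then M bands 5-8).
#' @export
assign_strata <- function(subjects, strata = strata_spec()) {
  band <- findInterval(subjects$age, strata$age_breaks) + 1L   # 1..4
  band + ifelse(subjects$sex == "M", 4L, 0L)
}

#' SMOTE configuration
#'
#' @param ratio Generation scale in (0, 1]; per stratum, `round(ratio *
#'   n_majority)` synthetic minority samples are created (grid values used
#'   in the motivating design: 0.1, 0.03, 0.005, 0.001).
#' @param k_neighbors Number of nearest minority neighbors (default 5).
#' @param seed RNG seed.
#' @param round_dosages Round synthetic dosages to the nearest of 0/1/2.
#' @param ratio_mode `"majority"` (the default above) or
#'   `"target_minority_fraction"`: generate until the minority count reaches
#'   `round(ratio * n_majority)` per stratum.
#' @param per_attr_gamma Draw an independent gamma per attribute instead of
#'   one per sample (sensitivity variant; default off).
#' @return A `smote_config`.
#' @export
smote_config <- function(ratio, k_neighbors = 5L, seed = 1L,
                         round_dosages = FALSE,
                         ratio_mode = c("majority", "target_minority_fraction"),
                         per_attr_gamma = FALSE) {
  stopifnot(ratio > 0, ratio <= 1, k_neighbors >= 1)
  structure(list(ratio = ratio, k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed), round_dosages = round_dosages,
                 ratio_mode = match.arg(ratio_mode),
                 per_attr_gamma = per_attr_gamma),
            class = "smote_config")
}

#' k nearest minority neighbors
#'
#' Euclidean distances among minority samples, self excluded, ties broken by
#' lowest index.
#'
#' @param X Minority sample x attribute matrix with at least `k + 1` rows.
#' @param k Neighbors per sample.
#' @return List of integer vectors, one per row of `X`.
#' @export
knn_minority <- function(X, k) {
  n <- nrow(X)
  if (n < k + 1)
    stop("need at least k+1 = ", k + 1, " minority samples (have ", n,
         "); reduce k or merge this stratum with an adjacent one")
  dm <- as.matrix(dist(X))
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(dm[i, others], others)[seq_len(k)]]
  })
}

#' Generate synthetic minority samples (SMOTE)
#'
#' Each synthetic sample interpolates a base minority sample x_i toward one
#' of its k nearest minority neighbors x_ij:
#' `x_new = x_i + (x_ij - x_i) * gamma`, with the base drawn uniformly, the
#' neighbor uniformly from the k-NN list, and gamma ~ Uniform(0, 1) drawn
#' once per sample and shared across attributes.
#'
#' @param X Minority sample x attribute matrix.
#' @param k Neighbors (see [knn_minority()]).
#' @param n_new Number of synthetic samples (>= 0).
#' @param seed RNG seed.
#' @param gamma_fixed Optional fixed gamma in `[0, 1]` replacing the random
#'   draw (test hook: 0 reproduces the base, 1 the neighbor).
#' @param per_attr_gamma Independent gamma per attribute (variant).
#' @return List with `X` (n_new x attributes matrix) and `provenance`
#'   (data frame: `base`, `neighbor`, `gamma`; with per-attribute gammas the
#'   column holds the first attribute's draw and the full matrix is attached
#'   as attribute `gamma_matrix`).
#' @export
smote_generate <- function(X, k, n_new, seed = 1L, gamma_fixed = NULL,
                           per_attr_gamma = FALSE) {
  if (n_new < 0) stop("n_new must be >= 0")
  X <- as.matrix(X)
  nn <- knn_minority(X, k)
  d <- ncol(X)
  set.seed(seed)
  if (n_new == 0)
    return(list(X = X[0, , drop = FALSE],
                provenance = data.frame(base = integer(0), neighbor = integer(0),
                                        gamma = numeric(0))))
  base <- sample.int(nrow(X), n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  neighbor <- vapply(seq_len(n_new), function(s) nn[[base[s]]][pick[s]], 0L)
  gm <- if (per_attr_gamma) {
    matrix(runif(n_new * d), n_new, d)
  } else if (is.null(gamma_fixed)) {
    matrix(runif(n_new), n_new, d)
  } else {
    matrix(gamma_fixed, n_new, d)
  }
  Xn <- X[base, , drop = FALSE] + (X[neighbor, , drop = FALSE] -
                                     X[base, , drop = FALSE]) * gm
  prov <- data.frame(base = base, neighbor = neighbor, gamma = gm[, 1])
  if (per_attr_gamma) attr(prov, "gamma_matrix") <- gm
  list(X = Xn, provenance = prov)
}

# Merge strata with < 2 cases into the age-adjacent stratum of the same sex.
merge_sparse_strata <- function(stratum, cases, min_cases = 2L) {
  repeat {
    tab <- vapply(1:8, function(s) sum(cases & stratum == s), 0L)
    present <- vapply(1:8, function(s) any(stratum == s), TRUE)
    sparse <- which(present & tab < min_cases)
    if (!length(sparse)) return(stratum)
    s <- sparse[1]
    sex_block <- if (s <= 4) 1:4 else 5:8
    cands <- setdiff(sex_block[present[sex_block]], s)
    if (!length(cands)) return(stratum)  # nothing to merge into
    tgt <- cands[which.min(abs(cands - s))]
    stratum[stratum == s] <- tgt
  }
}

#' Covariate-stratified SMOTE oversampling of cases
#'
#' Within each sex x age-band stratum, generates `round(ratio *
#' n_majority_in_stratum)` synthetic cases by [smote_generate()] from that
#' stratum's real cases and appends them to the cohort with the trait set to
#' 1, the `synthetic` flag on, and sex/age inherited from the base sample.
#' Controls are untouched. Strata with fewer than `k + 1` cases fall back to
#' `k = n_cases - 1`; strata with fewer than 2 cases are merged into the
#' age-adjacent stratum of the same sex (recorded in the provenance).
#'
#' @param cohort A `cohort`.
#' @param trait Trait to balance; its cases must be the minority.
#' @param cfg A [smote_config()].
#' @param strata A [strata_spec()].
#' @return The augmented `cohort`, with attribute `smote_provenance` (data
#'   frame: stratum, base and neighbor as cohort row indices, gamma).
#' @export
stratified_smote <- function(cohort, trait, cfg, strata = strata_spec()) {
  stopifnot(inherits(cohort, "cohort"), inherits(cfg, "smote_config"))
  if (!trait %in% colnames(cohort$traits))
    stop("unknown trait '", trait, "'")
  y <- cohort$traits[, trait]
  if (sum(y == 1) > sum(y == 0))
    stop("cases are not the minority for trait '", trait, "'")
  stratum <- assign_strata(cohort$subjects, strata)
  stratum <- merge_sparse_strata(stratum, y == 1)

  new_dos <- list(); new_rows <- list(); prov <- list()
  for (s in sort(unique(stratum))) {
    in_s <- stratum == s
    case_idx <- which(in_s & y == 1)
    n_maj <- sum(in_s & y == 0)
    n_new <- if (cfg$ratio_mode == "majority") {
      round(cfg$ratio * n_maj)
    } else {
      max(0L, round(cfg$ratio * n_maj) - length(case_idx))
    }
    if (n_new == 0) next
    k_use <- min(cfg$k_neighbors, length(case_idx) - 1L)
    if (k_use < 1) next   # unmergeable stratum with a single case
    gen <- smote_generate(cohort$dosages[case_idx, , drop = FALSE], k_use,
                          n_new, seed = cfg$seed + s,
                          per_attr_gamma = cfg$per_attr_gamma)
    new_dos[[length(new_dos) + 1L]] <- gen$X
    base_glob <- case_idx[gen$provenance$base]
    sub <- cohort$subjects[base_glob, , drop = FALSE]
    tra <- cohort$traits[base_glob, , drop = FALSE]
    tra[, trait] <- 1L
    new_rows[[length(new_rows) + 1L]] <- list(sub = sub, tra = tra)
    prov[[length(prov) + 1L]] <-
      data.frame(stratum = s, base = base_glob,
                 neighbor = case_idx[gen$provenance$neighbor],
                 gamma = gen$provenance$gamma)
  }
  if (!length(new_dos)) {
    attr(cohort, "smote_provenance") <-
      data.frame(stratum = integer(0), base = integer(0),
                 neighbor = integer(0), gamma = numeric(0))
    return(cohort)
  }
  Xn <- do.call(rbind, new_dos)
  if (cfg$round_dosages) Xn <- pmin(pmax(round(Xn), 0), 2)
  sub <- do.call(rbind, lapply(new_rows, `[[`, "sub"))
  sub$subject_id <- sprintf("SYN%06d", seq_len(nrow(sub)))
  tra <- do.call(rbind, lapply(new_rows, `[[`, "tra"))
  out <- cohort
  out$dosages <- rbind(cohort$dosages, Xn)
  out$subjects <- rbind(cohort$subjects, sub)
  rownames(out$subjects) <- NULL
  out$traits <- rbind(cohort$traits, tra)
  out$synthetic <- c(cohort$synthetic, rep(TRUE, nrow(Xn)))
  attr(out, "smote_provenance") <- do.call(rbind, prov)
  out
}

#' Per-trait SMOTE configurations with distinct ratios
#'
#' Builds the per-trait configuration set for a multi-trait image corpus in
#' which each trait gets its own generation ratio (a "mixed ratio" plan).
#'
#' @param traits_to_ratio Named numeric vector or list mapping trait name to
#'   ratio; duplicate names are an error.
#' @param trait_names Optional vector of known traits to validate against.
#' @param ... Passed to [smote_config()] (e.g. `k_neighbors`, `seed`).
#' @return Named list of `smote_config`, one per trait.
#' @export
mixed_ratio_plan <- function(traits_to_ratio, trait_names = NULL, ...) {
  ratios <- unlist(traits_to_ratio)
  if (!length(ratios)) return(structure(list(), names = character(0)))
  nms <- names(ratios)
  if (is.null(nms) || any(!nzchar(nms))) stop("ratios must be named by trait")
  if (anyDuplicated(nms)) stop("duplicate trait name in ratio map")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (!is.null(trait_names)) {
    unknown <- setdiff(nms, trait_names)
    if (length(unknown)) stop("unknown trait name(s): ",
                              paste(unknown, collapse = ", "))
  }
  setNames(lapply(ratios, function(r) smote_config(ratio = r, ...)), nms)
}
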