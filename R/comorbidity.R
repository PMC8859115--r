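#' Phi correlation of two binary vectors
#'
#' phi = (n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0) from the 2x2
#' contingency table; identical to the Pearson correlation of the two 0/1
#' vectors.
#'
#' @param x,y Binary (0/1 or logical) vectors of equal length >= 2, neither
#'   constant.
#' @return phi in `[-1, 1]`.
#' @export
phi_correlation <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (!all(x %in% 0:1) || !all(y %in% 0:1))
    stop("inputs must be binary 0/1")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("phi is undefined for a constant vector")
  n11 <- as.numeric(sum(x == 1 & y == 1)); n10 <- as.numeric(sum(x == 1 & y == 0))
  n01 <- as.numeric(sum(x == 0 & y == 1)); n00 <- as.numeric(sum(x == 0 & y == 0))
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

#' Trait distance matrix from binary phenotypes
#'
#' Default distance is `1 - phi` (phi = 1 maps to 0, phi = -1 to 2). A
#' cosine alternative (`1 -` cosine similarity of the 0/1 vectors) is
#' provided; see the methods vignette for why both exist.
#'
#' @param traits Subjects x traits binary matrix with column names.
#' @param method `"phi"` (default) or `"cosine"`.
#' @return Square symmetric distance matrix with trait-name dimnames, zero
#'   diagonal.
#' @export
trait_distance <- function(traits, method = c("phi", "cosine")) {
  method <- match.arg(method)
  nt <- ncol(traits)
  d <- matrix(0, nt, nt, dimnames = list(colnames(traits), colnames(traits)))
  for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
    d[i, j] <- d[j, i] <- if (method == "phi") {
      1 - phi_correlation(traits[, i], traits[, j])
    } else {
      xi <- traits[, i]; xj <- traits[, j]
      1 - sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  d
}

# total distance of each point to its nearest medoid; ties to lowest medoid
pam_assign <- function(d, medoids) {
  sub <- d[, medoids, drop = FALSE]
  nearest <- max.col(-sub, ties.method = "first")
  list(assignment = nearest,
       cost = sum(sub[cbind(seq_len(nrow(d)), nearest)]))
}

#' Partitioning around medoids (PAM)
#'
#' k-medoids on a precomputed distance matrix. Small instances (at most 500
#' candidate medoid subsets) are solved exactly by enumeration; larger ones
#' use the classical greedy BUILD initialization followed by SWAP steps that
#' apply the best improving (medoid, non-medoid) exchange until no single
#' swap lowers the total distance of points to their medoids. Deterministic;
#' distance ties are broken by lowest index.
#'
#' @param d Square symmetric distance matrix.
#' @param k Number of clusters, `1 <= k <= nrow(d)`.
#' @param seed Ignored (the algorithm is deterministic); kept so callers can
#'   treat all clustering entry points uniformly.
#' @return A `pam_clustering`: `k`, `medoids` (indices), `assignment`
#'   (cluster id per point, numbered by medoid order), `cost`, and mean
#'   `silhouette` (NA when k < 2).
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  n <- nrow(d)
  stopifnot(is.matrix(d), n == ncol(d))
  if (k < 1 || k > n) stop("k must lie in 1..", n)

  # Exact enumeration when the medoid search space is tiny: single-swap
  # local search (ours and the classical one alike) can stall one swap
  # short of the optimum, and at this size the optimum is cheap to certify.
  # Ties go to the lexicographically smallest subset.
  if (choose(n, k) <= 500) {
    combs <- utils::combn(n, k)
    costs <- apply(combs, 2, function(m) pam_assign(d, m)$cost)
    medoids <- combs[, which.min(costs)]
    return(finish_pam(d, k, medoids))
  }

  # BUILD: first medoid minimizes total distance; then greedy additions
  medoids <- unname(which.min(colSums(d)))
  while (length(medoids) < k) {
    best_gain <- -Inf; best_j <- NA_integer_
    cur <- apply(d[, medoids, drop = FALSE], 1, min)
    for (j in setdiff(seq_len(n), medoids)) {
      gain <- sum(pmax(cur - d[, j], 0))
      if (gain > best_gain + 1e-12) { best_gain <- gain; best_j <- j }
    }
    medoids <- c(medoids, best_j)
  }

  # SWAP to local optimum
  cur <- pam_assign(d, medoids)
  repeat {
    best <- list(delta = -1e-12)
    for (mi in seq_along(medoids)) {
      for (j in setdiff(seq_len(n), medoids)) {
        cand <- medoids; cand[mi] <- j
        cost <- pam_assign(d, cand)$cost
        delta <- cur$cost - cost
        if (delta > best$delta + 1e-12) best <- list(delta = delta, cand = cand)
      }
    }
    if (is.null(best$cand)) break
    medoids <- best$cand
    nxt <- pam_assign(d, medoids)
    stopifnot(nxt$cost <= cur$cost + 1e-9)  # SWAP never increases cost
    cur <- nxt
  }
  finish_pam(d, k, medoids)
}

finish_pam <- function(d, k, medoids) {
  medoids <- sort(medoids)
  asg <- pam_assign(d, medoids)
  sil <- if (k >= 2 && length(unique(asg$assignment)) >= 2)
    silhouette_score(d, asg$assignment) else NA_real_
  structure(list(k = as.integer(k), medoids = as.integer(medoids),
                 assignment = asg$assignment,
                 cost = asg$cost, silhouette = sil, labels = rownames(d)),
            class = "pam_clustering")
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat(sprintf("<pam_clustering> k = %d, cost = %.4g, mean silhouette = %.3f\n",
              x$k, x$cost, x$silhouette))
  invisible(x)
}

#' Mean silhouette score of a clustering
#'
#' For each point, a = mean distance to its own cluster's other members, b =
#' smallest mean distance to another cluster; the point's silhouette is
#' (b - a) / max(a, b), and a singleton cluster's point contributes 0.
#'
#' @param d Distance matrix.
#' @param assignment Integer cluster id per point; at least 2 nonempty
#'   clusters.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(d, assignment) {
  cl <- unique(assignment)
  if (length(cl) < 2) stop("silhouette requires at least 2 clusters")
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, assignment[i]), function(cc)
      mean(d[i, assignment == cc]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Runs [pam_cluster()] for each k in `k_range` and returns the clustering
#' with the largest mean silhouette; ties go to the smallest k.
#'
#' @param d Distance matrix.
#' @param k_range Candidate cluster counts, a subset of `2..(n-1)`.
#' @param seed Passed through to [pam_cluster()].
#' @return The winning `pam_clustering`.
#' @export
select_k <- function(d, k_range, seed = NULL) {
  if (!length(k_range)) stop("k_range is empty")
  n <- nrow(d)
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within 2..", n - 1)
  k_range <- sort(k_range)
  best <- NULL
  for (k in k_range) {
    cl <- pam_cluster(d, k, seed)
    if (is.null(best) || cl$silhouette > best$silhouette + 1e-12) best <- cl
  }
  best
}

#' Remove comorbid controls for a trait
#'
#' Controls of `trait` that carry any other disease assigned to the same
#' cluster are dropped; cases are never touched. This homogenizes the
#' control group before association testing.
#'
#' @param cohort A `cohort`.
#' @param trait Target trait name.
#' @param clustering A `pam_clustering` over the cohort's traits (labels
#'   must match trait columns).
#' @return The pruned `cohort`, with attribute `n_pruned` (removed count)
#'   and `pruned_traits` (the same-cluster diseases used).
#' @export
prune_comorbid_controls <- function(cohort, trait, clustering) {
  stopifnot(inherits(cohort, "cohort"), inherits(clustering, "pam_clustering"))
  labels <- clustering$labels
  if (is.null(labels)) labels <- colnames(cohort$traits)
  ti <- match(trait, labels)
  if (is.na(ti)) stop("trait '", trait, "' not assigned in clustering")
  same <- labels[clustering$assignment == clustering$assignment[ti]]
  others <- setdiff(same, trait)
  if (!length(others)) {
    attr(cohort, "n_pruned") <- 0L
    attr(cohort, "pruned_traits") <- character(0)
    return(cohort)
  }
  is_control <- cohort$traits[, trait] == 0L
  comorbid <- rowSums(cohort$traits[, others, drop = FALSE]) > 0
  drop <- is_control & comorbid
  out <- subset_cohort(cohort, subjects = !drop)
  attr(out, "n_pruned") <- sum(drop)
  attr(out, "pruned_traits") <- others
  out
}
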