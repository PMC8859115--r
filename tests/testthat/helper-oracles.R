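# Independent brute-force oracles used across the suite. These deliberately
# use the most naive formulation available so they share no code with the
# implementation they check.

# neighborhood max/min with edge replication, plain double loop
naive_morph <- function(img, se, dilate = TRUE) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(se); kw <- ncol(se)
  ah <- kh %/% 2; aw <- kw %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in seq_len(kh)) for (dj in seq_len(kw)) {
      if (!se[di, dj]) next
      ii <- min(max(i + di - 1 - ah, 1), H)
      jj <- min(max(j + dj - 1 - aw, 1), W)
      vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- if (dilate) max(vals) else min(vals)
  }
  out
}

naive_median <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  a <- k %/% 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- pmin(pmax((i - a):(i + a), 1), H)
    jj <- pmin(pmax((j - a):(j + a), 1), W)
    out[i, j] <- median(img[ii, jj])
  }
  out
}

# direct (non-separable) 2-D Gaussian convolution with edge replication
naive_gaussian <- function(img, sigma, ksize) {
  a <- ksize %/% 2
  k1 <- dnorm(-a:a, sd = sigma); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- pmin(pmax((i - a):(i + a), 1), H)
    jj <- pmin(pmax((j - a):(j + a), 1), W)
    out[i, j] <- sum(k2 * img[ii, jj])
  }
  out
}

# Levene-Haldane HWE p-value by direct enumeration of factorial formula
enum_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- 2 * nAA + nAa   # count of A alleles
  prob <- function(nab) {
    naa_ <- (na - nab) / 2
    nbb_ <- n - naa_ - nab
    exp(lfactorial(n) - lfactorial(naa_) - lfactorial(nab) - lfactorial(nbb_) +
          nab * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  ps <- vapply(hets, prob, 0)
  p_obs <- ps[hets == nAa]
  sum(ps[ps <= p_obs * (1 + 1e-12)])
}

# exhaustive PAM optimum: search all medoid subsets
brute_pam_cost <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  best <- Inf
  for (ci in seq_len(ncol(combs))) {
    cost <- sum(apply(d[, combs[, ci], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# per-point silhouette computed longhand
naive_silhouette <- function(d, assignment) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mine <- assignment == assignment[i]
    if (sum(mine) == 1) { s[i] <- 0; next }
    a <- mean(d[i, mine & seq_len(n) != i])
    b <- Inf
    for (cl in setdiff(unique(assignment), assignment[i]))
      b <- min(b, mean(d[i, assignment == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# small deterministic cohort used by several files
toy_cohort <- function(n = 400, m = 100, seed = 42, prevalence = 0.2,
                       n_traits = 1) {
  traits <- lapply(seq_len(n_traits), function(i)
    trait_spec(paste0("T", i), prevalence, n_causal = 0))
  simulate_cohort(cohort_spec(n, m, traits, maf_low = 0.1, maf_high = 0.5,
                              seed = seed))
}

# synthetic separable image fixture: one horizontal band per class
band_image <- function(cls, side = 64, noise_sd = 4, bands = 3) {
  img <- matrix(255, side, side)
  h <- side %/% (bands + 1)
  r0 <- cls * h - h %/% 2
  img[r0:(r0 + h %/% 2), round(side * 0.15):round(side * 0.85)] <- 0
  pmin(pmax(img + matrix(rnorm(side * side, 0, noise_sd), side, side), 0), 255)
}
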