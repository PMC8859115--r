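small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_classes = 3, input_size = 32, conv_filters = c(16L, 16L, 32L),
         dense_units = 32, epochs = 4, batch_size = 8,
         steps_per_epoch = 3, seed = 2),
    list(...))
  do.call(cnn_config, args)
}

test_that("softmax output is normalized and sized by n_classes", {
  cfg <- small_cfg()
  m <- build_cnn(cfg)
  imgs <- replicate(4, matrix(runif(64 * 64, 0, 255), 64), simplify = FALSE)
  rep1 <- predict_similarity(m, imgs)
  expect_identical(ncol(rep1$probs), 3L)
  expect_true(all(abs(rowSums(rep1$probs) - 1) < 1e-6))
  expect_true(all(rep1$probs >= 0 & rep1$probs <= 1))
})

test_that("weight initialization is reproducible from the seed", {
  cfg <- small_cfg()
  expect_identical(build_cnn(cfg)$weights, build_cnn(cfg)$weights)
  cfg2 <- small_cfg(seed = 99)
  expect_false(identical(build_cnn(cfg)$weights, build_cnn(cfg2)$weights))
  expect_error(cnn_config(n_classes = 2, input_size = 12), "too small")
})

test_that("analytic gradients match numerical differentiation", {
  # tiny network so central differences are cheap and well-conditioned
  cfg <- cnn_config(n_classes = 2, input_size = 22,
                    conv_filters = c(2L, 2L, 3L), dense_units = 5,
                    seed = 4)
  m <- build_cnn(cfg)
  set.seed(5)
  xb <- array(runif(22 * 22 * 2), c(22, 22, 2))
  y <- c(0L, 1L)
  res <- smotescan:::cnn_grad_cpp(m$weights, xb, y)
  loss_at <- function(w) smotescan:::cnn_grad_cpp(w, xb, y)$loss
  eps <- 1e-5
  for (nm in names(m$weights)) {
    g <- res$grads[[nm]]
    idx <- sample(length(g), min(4, length(g)))
    for (i in idx) {
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("stratified split arithmetic: 40 images over 3 classes gives 6 validation", {
  imgs <- replicate(40, matrix(255, 16, 16), simplify = FALSE)
  labs <- rep(c("a", "b", "c"), length.out = 40)   # 14, 13, 13
  cfg <- small_cfg()
  corp <- make_corpus(imgs, labs, cfg, seed = 3)
  expect_identical(length(corp$val_x), 6L)
  expect_identical(length(corp$train_x), 34L)
  # every class present on both sides
  expect_setequal(unique(corp$val_y), 0:2)
  expect_setequal(unique(corp$train_y), 0:2)
  expect_error(make_corpus(imgs[1:3], c("a", "a", "b"), cfg), "classes")
})

test_that("zero-range augmentation yields exact originals; same seed, same batches", {
  imgs <- replicate(9, matrix(runif(32 * 32, 0, 255), 32), simplify = FALSE)
  labs <- rep(c("a", "b", "c"), each = 3)
  cfg <- small_cfg(train_fraction = 0.7)
  corp <- make_corpus(imgs, labs, cfg,
                      augment = augment_spec(0, 0, 0), seed = 4)
  set.seed(10)
  b <- corpus_batch(corp, 5)
  for (i in seq_len(5)) {
    match_any <- any(vapply(corp$train_x, function(tx)
      isTRUE(all.equal(tx, b$x[, , i])), TRUE))
    expect_true(match_any)
  }
  set.seed(77); b1 <- corpus_batch(corp, 6)
  set.seed(77); b2 <- corpus_batch(corp, 6)
  expect_identical(b1, b2)
  # augmentation invariants: shifts capped at 0.2, no flip field exists
  expect_error(augment_spec(width_shift = 0.3), "width_shift")
  expect_false(any(grepl("flip", names(augment_spec()))))
})

test_that("training separates a 3-class banded corpus and predicts it back", {
  set.seed(6)
  imgs <- list(); labs <- character(0)
  for (cls in 1:3) for (r in 1:8) {
    imgs <- c(imgs, list(band_image(cls)))
    labs <- c(labs, paste0("T", cls))
  }
  cfg <- small_cfg(epochs = 10)
  corp <- make_corpus(imgs, labs, cfg, seed = 6)
  m <- train_cnn(build_cnn(cfg), corp)
  expect_identical(nrow(m$history), 10L)
  expect_gte(m$history$accuracy[10], 0.95)
  # overfit-then-recall: training-set images classify to their labels
  sr <- predict_similarity(m, imgs, labs)
  expect_gte(sr$accuracy, 0.95)
  # report accuracy equals its definition recomputed from the raw table
  expect_equal(sr$accuracy,
               mean(apply(sr$probs, 1, which.max) ==
                      as.integer(factor(labs))))
  # loss on a perfectly predicted set is small
  expect_lt(sr$loss, 0.1)
})

test_that("random labels train to chance-level validation accuracy", {
  set.seed(7)
  imgs <- list(); labs <- character(0)
  for (cls in 1:3) for (r in 1:10) {
    imgs <- c(imgs, list(band_image(cls)))
    labs <- c(labs, paste0("T", cls))
  }
  labs_perm <- sample(labs)   # break the image-label link
  cfg <- small_cfg(epochs = 5, train_fraction = 0.7)
  corp <- make_corpus(imgs, labs_perm, cfg, seed = 7)
  m <- train_cnn(build_cnn(cfg), corp)
  sr <- predict_similarity(m, imgs, labs)   # true labels
  # binomial noise around 1/3 on 30 images: stay well below real learning
  expect_lt(sr$accuracy, 0.67)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(8)
  imgs <- list(); labs <- character(0)
  for (cls in 1:3) for (r in 1:4) {
    imgs <- c(imgs, list(band_image(cls)))
    labs <- c(labs, paste0("T", cls))
  }
  cfg <- small_cfg(epochs = 2)
  corp <- make_corpus(imgs, labs, cfg, seed = 9)
  m1 <- train_cnn(build_cnn(cfg), corp)
  m2 <- train_cnn(build_cnn(cfg), corp)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
})

test_that("cross-arm evaluation tabulates per-trait similarity and validates labels", {
  set.seed(9)
  imgs <- list(); labs <- character(0)
  for (cls in 1:3) for (r in 1:6) {
    imgs <- c(imgs, list(band_image(cls)))
    labs <- c(labs, paste0("T", cls))
  }
  cfg <- small_cfg(epochs = 8)
  corp <- make_corpus(imgs, labs, cfg, seed = 10)
  m <- train_cnn(build_cnn(cfg), corp)
  # arm B: fresh draws from the same generative pattern
  imgs_b <- list(); labs_b <- character(0)
  for (cls in 1:3) for (r in 1:2) {
    imgs_b <- c(imgs_b, list(band_image(cls)))
    labs_b <- c(labs_b, paste0("T", cls))
  }
  cx <- cross_arm_evaluate(m, imgs_b, labs_b)
  expect_identical(dim(cx$mean_similarity), c(3L, 3L))
  expect_identical(cx$per_trait$trait, paste0("T", 1:3))
  expect_identical(sum(cx$per_trait$n), 6L)
  expect_true(all(abs(rowSums(cx$probs) - 1) < 1e-6))
  # same training images back in: accuracy equals in-sample accuracy
  in_sample <- predict_similarity(m, imgs, labs)$accuracy
  again <- cross_arm_evaluate(m, imgs, labs)
  expect_identical(again$accuracy, in_sample)
  expect_error(cross_arm_evaluate(m, imgs_b, rep("T9", 6)), "unknown")
})
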