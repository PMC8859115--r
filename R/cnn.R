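#' Configuration of the compact Manhattan-plot CNN
#'
#' Architecture: three blocks of 3x3 valid convolution + ReLU + 2x2 max
#' pooling extracting `conv_filters` (default 32, 32, 64) feature maps,
#' followed by a flatten, a ReLU dense layer of `dense_units`, and a softmax
#' output over `n_classes`. Input is a square single-channel (grayscale)
#' image of side `input_size`.
#'
#' @param n_classes Number of trait classes (>= 2).
#' @param input_size Input side in pixels (default 128); must leave at least
#'   one pixel after the three conv/pool stages.
#' @param conv_filters Filters per conv layer (length 3).
#' @param dense_units Dense layer width (default 64).
#' @param epochs,batch_size Training schedule (defaults 20 and 32).
#' @param steps_per_epoch Gradient steps per epoch (default 3).
#' @param validation_steps Validation batches evaluated per epoch (default 4).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param train_fraction Training share of the stratified split (default 0.85).
#' @param seed RNG seed used for weight init, splitting, augmentation and
#'   batch order.
#' @return A `cnn_config`.
#' @export
cnn_config <- function(n_classes, input_size = 128L,
                       conv_filters = c(32L, 32L, 64L), dense_units = 64L,
                       epochs = 20L, batch_size = 32L, steps_per_epoch = 3L,
                       validation_steps = 4L, learning_rate = 1e-3,
                       train_fraction = 0.85, seed = 1L) {
  stopifnot(n_classes >= 2, length(conv_filters) == 3,
            train_fraction > 0, train_fraction < 1,
            epochs >= 1, batch_size >= 1, steps_per_epoch >= 1,
            validation_steps >= 1)
  s <- as.integer(input_size)
  for (l in 1:3) {
    s <- s - 2L
    if (s < 2L) stop("input_size ", input_size,
                     " is too small for three conv/pool stages")
    s <- s %/% 2L
  }
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 validation_steps = as.integer(validation_steps),
                 learning_rate = learning_rate,
                 train_fraction = train_fraction,
                 seed = as.integer(seed),
                 final_side = s),
            class = "cnn_config")
}

glorot <- function(nr, nc, fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

#' Build (initialize) the CNN
#'
#' Weights are drawn from a Glorot-uniform distribution seeded by
#' `cfg$seed`, so two builds with the same configuration are identical.
#'
#' @param cfg A [cnn_config()].
#' @return A `cnn_model`: weight list, config, parameter count.
#' @export
build_cnn <- function(cfg) {
  stopifnot(inherits(cfg, "cnn_config"))
  set.seed(cfg$seed)
  f <- cfg$conv_filters
  flat <- cfg$final_side^2 * f[3]
  w <- list(
    W1 = glorot(f[1], 9L, 9, f[1]), b1 = numeric(f[1]),
    W2 = glorot(f[2], 9L * f[1], 9 * f[1], f[2]), b2 = numeric(f[2]),
    W3 = glorot(f[3], 9L * f[2], 9 * f[2], f[3]), b3 = numeric(f[3]),
    Wd = glorot(cfg$dense_units, flat, flat, cfg$dense_units),
    bd = numeric(cfg$dense_units),
    Wo = glorot(cfg$n_classes, cfg$dense_units, cfg$dense_units, cfg$n_classes),
    bo = numeric(cfg$n_classes))
  structure(list(weights = w, cfg = cfg, classes = NULL,
                 n_params = sum(vapply(w, length, 0L))),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %dx%d, filters %s, dense %d, %d classes, %d parameters%s\n",
              x$cfg$input_size, x$cfg$input_size,
              paste(x$cfg$conv_filters, collapse = "/"),
              x$cfg$dense_units, x$cfg$n_classes, x$n_params,
              if (is.null(x$classes)) " (untrained)" else ""))
  invisible(x)
}

#' Data augmentation specification
#'
#' Random translations and zooms with constant fill. Flips are deliberately
#' unavailable: the Manhattan x axis is genomic position and the y axis is
#' significance, so mirroring would destroy the image semantics.
#'
#' @param width_shift,height_shift Maximum shift as a fraction of the image
#'   side, in `[0, 0.2]`.
#' @param zoom Maximum zoom deviation (scale drawn from `1 +/- zoom`).
#' @param fill Constant fill value for exposed borders (default 0 =
#'   background in the network's inverted intensity convention).
#' @return An `augment_spec`.
#' @export
augment_spec <- function(width_shift = 0.1, height_shift = 0.1, zoom = 0.1,
                         fill = 0) {
  stopifnot(width_shift >= 0, width_shift <= 0.2,
            height_shift >= 0, height_shift <= 0.2, zoom >= 0, zoom < 1)
  structure(list(width_shift = width_shift, height_shift = height_shift,
                 zoom = zoom, fill = fill), class = "augment_spec")
}

# nearest-neighbor resize to h x w
resize_nearest <- function(img, h, w) {
  img <- unclass(img)
  ri <- ceiling(seq_len(h) * nrow(img) / h)
  ci <- ceiling(seq_len(w) * ncol(img) / w)
  img[ri, ci, drop = FALSE]
}

# random shift + zoom with nearest-neighbor lookup and constant fill;
# consumes R RNG (three draws), so it is reproducible under set.seed
augment_image <- function(x, spec) {
  h <- nrow(x); w <- ncol(x)
  dy <- round(runif(1, -spec$height_shift, spec$height_shift) * h)
  dx <- round(runif(1, -spec$width_shift, spec$width_shift) * w)
  z <- 1 + runif(1, -spec$zoom, spec$zoom)
  if (dy == 0 && dx == 0 && z == 1) return(x)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  si <- round((seq_len(h) - cy) / z + cy - dy)
  sj <- round((seq_len(w) - cx) / z + cx - dx)
  out <- matrix(spec$fill, h, w)
  ok_i <- si >= 1 & si <= h
  ok_j <- sj >= 1 & sj <= w
  out[ok_i, ok_j] <- x[si[ok_i], sj[ok_j], drop = FALSE]
  out
}

# to network intensity convention: feature-bright in [0, 1]
as_input <- function(img, input_size) {
  x <- resize_nearest(unclass(img), input_size, input_size)
  (255 - x) / 255
}

#' Build a training/validation image corpus
#'
#' Images are resized (nearest neighbor) to the network input size,
#' inverted to feature-bright intensities in `[0, 1]`, and split
#' stratified by class: each class contributes
#' `max(1, round((1 - train_fraction) * n_class))` images to validation and
#' the rest to training. The training side is served as a stream of
#' randomly augmented variants (see [augment_spec()]); validation images
#' are never augmented.
#'
#' @param images List of image matrices (0..255, dark features).
#' @param labels Class label per image (coerced to factor); at least two
#'   images per class.
#' @param cfg A [cnn_config()]; `n_classes` must equal the number of label
#'   levels.
#' @param augment An [augment_spec()].
#' @param seed Split seed.
#' @return A `cnn_corpus`: `train_x`/`val_x` (lists of normalized
#'   matrices), `train_y`/`val_y` (0-based integer labels), `classes`,
#'   `augment`.
#' @export
make_corpus <- function(images, labels, cfg, augment = augment_spec(),
                        seed = 1L) {
  labels <- factor(labels)
  stopifnot(length(images) == length(labels))
  if (nlevels(labels) != cfg$n_classes)
    stop("corpus has ", nlevels(labels), " classes but cfg expects ",
         cfg$n_classes)
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 images")
  xs <- lapply(images, as_input, input_size = cfg$input_size)
  set.seed(seed)
  val <- logical(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round((1 - cfg$train_fraction) * length(idx)))
    if (n_val >= length(idx))
      stop("class '", cl, "' would have no training images")
    val[sample(idx, n_val)] <- TRUE
  }
  structure(list(train_x = xs[!val], train_y = as.integer(labels[!val]) - 1L,
                 val_x = xs[val], val_y = as.integer(labels[val]) - 1L,
                 classes = levels(labels), augment = augment),
            class = "cnn_corpus")
}

#' Draw one augmented training batch from a corpus
#'
#' Samples `batch_size` training images with replacement and applies the
#' corpus's random augmentation to each. Consumes the R RNG stream, so a
#' fixed seed reproduces identical batches.
#'
#' @param corpus A `cnn_corpus`.
#' @param batch_size Batch size.
#' @return List with `x` (H x W x batch array) and `y` (0-based labels).
#' @export
corpus_batch <- function(corpus, batch_size) {
  idx <- sample.int(length(corpus$train_x), batch_size, replace = TRUE)
  h <- nrow(corpus$train_x[[1]])
  xb <- array(0, c(h, h, batch_size))
  for (b in seq_along(idx))
    xb[, , b] <- augment_image(corpus$train_x[[idx[b]]], corpus$augment)
  list(x = xb, y = corpus$train_y[idx])
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0),
       t = 0L)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(w)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

eval_batch <- function(weights, xs, y) {
  h <- nrow(xs[[1]])
  xb <- array(unlist(xs), c(h, h, length(xs)))
  p <- cnn_forward_cpp(weights, xb)
  list(loss = -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12))),
       accuracy = mean(max.col(p, ties.method = "first") == y + 1L),
       probs = p)
}

#' Train the CNN on an image corpus
#'
#' Minimizes categorical cross-entropy with Adam for `epochs x
#' steps_per_epoch` gradient steps of `batch_size` augmented images.
#' Validation loss/accuracy are measured each epoch on up to
#' `validation_steps * batch_size` unaugmented validation images. Training
#' is deterministic given `cfg$seed` (single-threaded).
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param corpus A `cnn_corpus` from [make_corpus()].
#' @param verbose Print per-epoch metrics.
#' @return The trained `cnn_model` with a `history` data frame (per-epoch
#'   `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_cnn <- function(model, corpus, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), inherits(corpus, "cnn_corpus"))
  cfg <- model$cfg
  if (length(corpus$classes) != cfg$n_classes)
    stop("corpus classes do not match model n_classes")
  w <- model$weights
  st <- adam_init(w)
  set.seed(cfg$seed + 1L)
  n_val_eval <- min(length(corpus$val_x),
                    cfg$validation_steps * cfg$batch_size)
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                     accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    losses <- accs <- numeric(cfg$steps_per_epoch)
    for (s in seq_len(cfg$steps_per_epoch)) {
      b <- corpus_batch(corpus, cfg$batch_size)
      res <- cnn_grad_cpp(w, b$x, b$y)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", ep, " step ", s)
      up <- adam_step(w, res$grads, st, cfg$learning_rate)
      w <- up$w; st <- up$st
      losses[s] <- res$loss; accs[s] <- res$accuracy
    }
    vi <- if (n_val_eval < length(corpus$val_x))
      sample.int(length(corpus$val_x), n_val_eval) else seq_along(corpus$val_x)
    ev <- eval_batch(w, corpus$val_x[vi], corpus$val_y[vi])
    hist[ep, 2:5] <- c(mean(losses), mean(accs), ev$loss, ev$accuracy)
    if (verbose)
      message(sprintf("epoch %2d: loss %.4f acc %.3f | val_loss %.4f val_acc %.3f",
                      ep, mean(losses), mean(accs), ev$loss, ev$accuracy))
  }
  model$weights <- w
  model$classes <- corpus$classes
  model$history <- hist
  model
}

#' Softmax similarity of images to the trained classes
#'
#' Runs the network on each image and reports the per-class softmax vector
#' — the "similarity" of the image to each trait class. The predicted class
#' is the argmax (ties broken by lowest class index).
#'
#' @param model Trained `cnn_model`.
#' @param images List of image matrices (resized as needed).
#' @param labels Optional true labels (character or factor over the model's
#'   classes) enabling accuracy/loss.
#' @return A `similarity_report`: `probs` (rows sum to 1), `predicted`,
#'   `truth`, `accuracy` (n_correct / n_total) and mean cross-entropy
#'   `loss` when labels are given.
#' @export
predict_similarity <- function(model, images, labels = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  classes <- model$classes
  if (is.null(classes)) classes <- paste0("class", seq_len(model$cfg$n_classes))
  xs <- lapply(images, as_input, input_size = model$cfg$input_size)
  h <- model$cfg$input_size
  xb <- array(unlist(xs), c(h, h, length(xs)))
  p <- cnn_forward_cpp(model$weights, xb)
  colnames(p) <- classes
  pred <- factor(classes[max.col(p, ties.method = "first")], levels = classes)
  truth <- accuracy <- loss <- NULL
  if (!is.null(labels)) {
    truth <- factor(as.character(labels), levels = classes)
    if (anyNA(truth)) stop("labels contain classes unknown to the model")
    accuracy <- mean(pred == truth)
    loss <- -mean(log(pmax(p[cbind(seq_along(truth), as.integer(truth))],
                           1e-12)))
  }
  structure(list(probs = p, predicted = pred, truth = truth,
                 accuracy = accuracy, loss = loss, classes = classes),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report> %d image(s), %d classes%s\n",
              nrow(x$probs), length(x$classes),
              if (!is.null(x$accuracy))
                sprintf(", accuracy %.3f", x$accuracy) else ""))
  invisible(x)
}

#' Cross-arm evaluation: classify one arm's images with a model trained on
#' another
#'
#' The headline comparison of the package: a network trained on one
#' balancing arm's preprocessed Manhattan plots (e.g. the SMOTE arm)
#' predicts the other arm's plots of the same traits. Reported per trait:
#' how many of its images were classified correctly and the mean softmax
#' similarity assigned to each class.
#'
#' @param model Trained `cnn_model`.
#' @param images List of images from the other arm.
#' @param labels True trait per image; every label must be one of the
#'   model's classes.
#' @return A `similarity_report` with an extra `per_trait` data frame
#'   (`trait`, `n`, `n_correct`, `mean_true_similarity`) and
#'   `mean_similarity` matrix (true trait x class).
#' @export
cross_arm_evaluate <- function(model, images, labels) {
  sr <- predict_similarity(model, images, labels = labels)
  truth <- sr$truth
  classes <- sr$classes
  ms <- t(vapply(classes, function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(rep(NA_real_, length(classes)))
    colMeans(sr$probs[sel, , drop = FALSE])
  }, numeric(length(classes))))
  dimnames(ms) <- list(truth = classes, class = classes)
  per <- data.frame(
    trait = classes,
    n = as.integer(table(truth)[classes]),
    n_correct = vapply(classes, function(cl)
      sum(truth == cl & sr$predicted == cl), 0L),
    mean_true_similarity = diag(ms))
  rownames(per) <- NULL
  sr$per_trait <- per
  sr$mean_similarity <- ms
  sr
}

#' Save / load CNN weights as JSON
#'
#' Text checkpoint of the weight matrices, configuration and class labels.
#'
#' @param model A `cnn_model`.
#' @param path JSON path.
#' @export
save_cnn <- function(model, path) {
  obj <- list(cfg = unclass(model$cfg), classes = model$classes,
              weights = model$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  cfg <- do.call(cnn_config, obj$cfg[setdiff(names(obj$cfg), "final_side")])
  w <- obj$weights
  for (nm in c("b1", "b2", "b3", "bd", "bo")) w[[nm]] <- as.numeric(w[[nm]])
  for (nm in c("W1", "W2", "W3", "Wd", "Wo")) w[[nm]] <- as.matrix(w[[nm]])
  structure(list(weights = w, cfg = cfg, classes = obj$classes,
                 n_params = sum(vapply(w, length, 0L))),
            class = "cnn_model")
}
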