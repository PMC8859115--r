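#' Structuring element for grayscale morphology
#'
#' @param size Odd side length of an all-ones square mask (default 3), or
#'   pass `mask` directly.
#' @param mask Logical matrix with odd dimensions and at least one TRUE
#'   cell; the anchor is the center.
#' @return A `structuring_element` (logical matrix).
#' @export
structuring_element <- function(size = 3L, mask = NULL) {
  if (is.null(mask)) {
    stopifnot(size >= 1, size %% 2 == 1)
    mask <- matrix(TRUE, size, size)
  }
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (nrow(mask) %% 2 == 0 || ncol(mask) %% 2 == 0)
    stop("structuring element dimensions must be odd")
  if (!any(mask)) stop("structuring element has no TRUE cell")
  structure(mask, class = c("structuring_element", "matrix", "array"))
}

# Manhattan rasters are dark marks on a white background; the morphological
# definitions act on bright features. With features = "dark" the operators
# run on the inverted image and invert back, so "dilation" enlarges the
# marks as intended. features = "bright" applies the raw neighborhood
# max/min (the form checked against brute-force oracles).
prep_polarity <- function(img, features) {
  if (features == "dark") 255 - unclass(img) else unclass(img)
}
unprep_polarity <- function(img, features) {
  if (features == "dark") 255 - img else img
}

#' Grayscale dilation
#'
#' Neighborhood maximum over the structuring element (edge replication at
#' borders): expands the image's features.
#'
#' @param img Numeric matrix in 0..255 (a `manhattan_image` keeps its
#'   provenance, with the operation appended to its chain).
#' @param se A [structuring_element()].
#' @param features `"dark"` (default; features are dark marks on white) or
#'   `"bright"`.
#' @return Filtered image of the same class.
#' @export
dilate <- function(img, se = structuring_element(), features = c("dark", "bright")) {
  features <- match.arg(features)
  out <- unprep_polarity(cpp_morph(prep_polarity(img, features), se, TRUE),
                         features)
  rewrap_image(out, img, "dilate")
}

#' Grayscale erosion
#'
#' Neighborhood minimum; the dual of [dilate()]:
#' `erode(img) == invert(dilate(invert(img)))` for a symmetric element.
#'
#' @inheritParams dilate
#' @export
erode <- function(img, se = structuring_element(), features = c("dark", "bright")) {
  features <- match.arg(features)
  out <- unprep_polarity(cpp_morph(prep_polarity(img, features), se, FALSE),
                         features)
  rewrap_image(out, img, "erode")
}

#' Morphological gradient
#'
#' Pixelwise dilation minus erosion, clipped to 0..255: outlines feature
#' boundaries. The gradient magnitude is polarity-invariant; with
#' `features = "dark"` the result is re-inverted so edges come out as dark
#' marks on white, matching the raster convention.
#'
#' @inheritParams dilate
#' @export
morph_gradient <- function(img, se = structuring_element(),
                           features = c("dark", "bright")) {
  features <- match.arg(features)
  x <- prep_polarity(img, features)
  grad <- pmin(pmax(cpp_morph(x, se, TRUE) - cpp_morph(x, se, FALSE), 0), 255)
  rewrap_image(unprep_polarity(grad, features), img, "gradient")
}

#' Gaussian smoothing filter
#'
#' Separable convolution with a truncated, normalized Gaussian kernel
#' (weights sum to 1 within 1e-9); edge replication at borders.
#'
#' @param img Numeric matrix in 0..255.
#' @param sigma Standard deviation in pixels (> 0).
#' @param kernel_size Odd kernel side length (default 5).
#' @return Filtered image.
#' @export
gaussian_filter <- function(img, sigma = 1, kernel_size = 5L) {
  stopifnot(sigma > 0)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  a <- kernel_size %/% 2
  kern <- dnorm(-a:a, sd = sigma)
  kern <- kern / sum(kern)
  rewrap_image(cpp_sepconv(unclass(img), kern), img, "gaussian")
}

#' Median filter
#'
#' Neighborhood median over a square window, edge replication.
#'
#' @param img Numeric matrix in 0..255.
#' @param kernel_size Odd window side length (default 3, matched to the
#'   renderer's default marker radius so that data marks survive the filter
#'   while isolated single-pixel noise is removed).
#' @return Filtered image.
#' @export
median_filter <- function(img, kernel_size = 3L) {
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  rewrap_image(cpp_median_filter(unclass(img), kernel_size), img, "median")
}

rewrap_image <- function(pixels, original, opname) {
  if (inherits(original, "manhattan_image")) {
    pv <- attr(original, "provenance")
    pv$chain <- c(pv$chain, opname)
    out <- structure(pixels, class = class(original))
    attr(out, "provenance") <- pv
    out
  } else pixels
}

#' Preprocessing chain specification
#'
#' One smoothing filter followed by one morphological operation, addressed
#' by the canonical two-letter codes: `GD` (Gaussian + dilation), `GG`
#' (Gaussian + gradient), `MD` (median + dilation), `MG` (median +
#' gradient).
#'
#' @param code One of "GD", "GG", "MD", "MG".
#' @param gauss_sigma,gauss_kernel Gaussian parameters (defaults 1, 5).
#' @param median_kernel Median window (default 3; see [median_filter()]).
#' @param se Structuring element for the morphology step.
#' @return A `preprocess_chain`.
#' @export
preprocess_chain <- function(code, gauss_sigma = 1, gauss_kernel = 5L,
                             median_kernel = 3L, se = structuring_element()) {
  if (!code %in% c("GD", "GG", "MD", "MG"))
    stop("unknown chain code '", code, "' (expected GD, GG, MD or MG)")
  structure(list(code = code,
                 filter = if (substr(code, 1, 1) == "G") "gaussian" else "median",
                 morph = if (substr(code, 2, 2) == "D") "dilation" else "gradient",
                 gauss_sigma = gauss_sigma, gauss_kernel = gauss_kernel,
                 median_kernel = median_kernel, se = se),
            class = "preprocess_chain")
}

#' Apply a preprocessing chain to an image
#'
#' @param img Image matrix (0..255).
#' @param chain A [preprocess_chain()] or a chain code string.
#' @return Preprocessed image; for a `manhattan_image`, the provenance chain
#'   records both steps.
#' @export
apply_chain <- function(img, chain) {
  if (is.character(chain)) chain <- preprocess_chain(chain)
  stopifnot(inherits(chain, "preprocess_chain"))
  x <- if (chain$filter == "gaussian") {
    gaussian_filter(img, chain$gauss_sigma, chain$gauss_kernel)
  } else {
    median_filter(img, chain$median_kernel)
  }
  if (chain$morph == "dilation") dilate(x, chain$se)
  else morph_gradient(x, chain$se)
}
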