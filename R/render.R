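#' Manhattan raster configuration
#'
#' The raster is a pure data image: black marks on a white background, no
#' axes, ticks or text, so that a downstream classifier sees only the
#' association signal.
#'
#' @param width,height Pixel dimensions (>= 32; defaults 512 x 256).
#' @param y_max Cap on the -log10(p) axis (default 30); stronger signals are
#'   clipped to the top row. `NA` auto-scales each image to its own maximum
#'   observed -log10(p), the way interactive Manhattan plots fit their axis.
#' @param point_radius Marker disc radius in pixels (default 1).
#' @param gap_bp Inter-chromosome spacing in bp units (default 5e6).
#' @return A `render_config`.
#' @export
render_config <- function(width = 512L, height = 256L, y_max = 30,
                          point_radius = 1L, gap_bp = 5e6) {
  stopifnot(width >= 32, height >= 32, is.na(y_max) || y_max > 0,
            point_radius >= 0, gap_bp >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 y_max = y_max, point_radius = as.integer(point_radius),
                 gap_bp = gap_bp), class = "render_config")
}

#' Map SNPs to genome-wide x pixel coordinates
#'
#' Positions are laid out on a cumulative base-pair axis: chromosome lengths
#' (max observed position per chromosome) concatenated with `gap_bp` spacing,
#' then mapped linearly so the first base of the first chromosome hits pixel
#' 0 and the last base of the last chromosome hits pixel `width - 1`. The
#' mapping is monotone in (chromosome, position).
#'
#' @param snp_meta Data frame with `chrom` and 1-based `pos`, sorted by
#'   position within chromosome.
#' @param gap_bp Spacing between chromosomes in bp.
#' @param width Image width in pixels.
#' @return Integer x coordinate per SNP in `0..(width - 1)`.
#' @export
genome_x <- function(snp_meta, gap_bp, width) {
  chroms <- unique(snp_meta$chrom)
  offset <- 0
  g <- numeric(nrow(snp_meta))
  for (cc in chroms) {
    sel <- snp_meta$chrom == cc
    p <- snp_meta$pos[sel]
    if (any(diff(p) <= 0))
      stop("positions not sorted within chromosome ", cc)
    g[sel] <- offset + p
    offset <- offset + max(p) + gap_bp
  }
  total <- offset - gap_bp          # genome span including inter-chrom gaps
  if (total <= 1) return(rep(0L, nrow(snp_meta)))
  as.integer(round((g - 1) / (total - 1) * (width - 1)))
}

#' Rasterize an association table into a Manhattan image
#'
#' Each SNP becomes a filled black disc of `point_radius` at
#' (`genome_x`, y) with y = `height - 1 - round(min(-log10 p, y_max) /
#' y_max * (height - 1))`; p = 1 sits on the bottom row and p <= 10^-y_max
#' reaches the top row. Rendering is deterministic (no anti-aliasing) and
#' overplotting is idempotent, so the image is invariant to input row order.
#'
#' @param assoc Nonempty `assoc_table` (or data frame with `chrom`, `pos`,
#'   `p`); all p must be > 0.
#' @param cfg A [render_config()].
#' @param trait,arm,ratio,chain Provenance fields stored with the image.
#' @return A `manhattan_image`: height x width numeric matrix in 0..255 with
#'   a `provenance` attribute.
#' @export
render_manhattan <- function(assoc, cfg = render_config(), trait = NA,
                             arm = NA, ratio = NA, chain = character(0)) {
  if (!nrow(assoc)) stop("association table is empty")
  if (any(assoc$p <= 0)) stop("p-values must be > 0")
  o <- order(assoc$chrom, assoc$pos)
  assoc <- assoc[o, , drop = FALSE]
  x <- genome_x(assoc, cfg$gap_bp, cfg$width)
  y_max <- if (is.na(cfg$y_max)) max(-log10(assoc$p), 1e-6) else cfg$y_max
  yv <- pmin(-log10(assoc$p), y_max)
  y <- cfg$height - 1L - as.integer(round(yv / y_max * (cfg$height - 1L)))
  img <- matrix(255, cfg$height, cfg$width)
  r <- cfg$point_radius
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, , drop = FALSE]
  for (s in seq_along(x)) {
    py <- y[s] + offs$dy; px <- x[s] + offs$dx
    ok <- py >= 0 & py < cfg$height & px >= 0 & px < cfg$width
    img[cbind(py[ok] + 1L, px[ok] + 1L)] <- 0
  }
  new_manhattan_image(img, trait = trait, arm = arm, ratio = ratio,
                      chain = chain, config = cfg)
}

new_manhattan_image <- function(pixels, trait = NA, arm = NA, ratio = NA,
                                chain = character(0), config = NULL) {
  structure(pixels,
            provenance = list(trait = trait, arm = arm, ratio = ratio,
                              chain = chain,
                              config_hash = config_hash(config)),
            class = c("manhattan_image", "matrix", "array"))
}

# stable short signature of a render config (or any list of scalars)
config_hash <- function(cfg) {
  if (is.null(cfg)) return(NA_character_)
  paste(vapply(unclass(cfg), function(v) paste(format(v), collapse = ","), ""),
        collapse = "|")
}

#' @export
print.manhattan_image <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<manhattan_image> %d x %d, trait=%s arm=%s chain=[%s]\n",
              nrow(x), ncol(x), pv$trait, pv$arm,
              paste(pv$chain, collapse = ",")))
  invisible(x)
}

#' Save / load a Manhattan image as 8-bit grayscale PNG
#'
#' The pixel round trip is bit-exact; provenance is serialized as JSON into
#' a PNG text chunk and restored on load. Loading a non-grayscale PNG is an
#' error.
#'
#' @param img A `manhattan_image` (values 0..255).
#' @param path PNG path.
#' @return `save_manhattan_png` the path invisibly; `load_manhattan_png` a
#'   `manhattan_image`.
#' @export
save_manhattan_png <- function(img, path) {
  pv <- attr(img, "provenance")
  meta <- jsonlite::toJSON(pv, auto_unbox = TRUE, null = "null")
  # quantize to the 8-bit grid so the PNG round trip is bit-exact
  px <- pmin(pmax(round(unclass(img)), 0), 255)
  png::writePNG(px / 255, target = path,
                text = c(provenance = as.character(meta)))
  invisible(path)
}

#' @rdname save_manhattan_png
#' @export
load_manhattan_png <- function(path) {
  raw <- png::readPNG(path, info = TRUE)
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] > 2) stop("not a grayscale PNG: ", path)
    raw <- raw[, , 1]
  }
  img <- round(raw * 255)
  info <- attr(raw, "info")
  pv <- NULL
  if (!is.null(info$text) && "provenance" %in% names(info$text))
    pv <- jsonlite::fromJSON(info$text[["provenance"]])
  attr(img, "info") <- NULL
  out <- structure(img, class = c("manhattan_image", "matrix", "array"))
  attr(out, "provenance") <- pv
  out
}
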