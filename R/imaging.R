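#' Convert a linear RGB image to true luminance
#'
#' Collapses the three linear colour channels to a single luminance plane
#' using the ITU-R BT.709 primaries: `0.2126 R + 0.7152 G + 0.0722 B`. The
#' coefficients sum to one, so an input in `[0, 1]` maps to `[0, 1]` and the
#' operation is linear in the channel intensities.
#'
#' @param rgb Either an `h x w x 3` numeric array or a list with elements
#'   `r`, `g`, `b`, each an `h x w` matrix. All values must lie in `[0, 1]`.
#' @return An `h x w` numeric matrix of luminance values in `[0, 1]`.
#' @export
#' @examples
#' to_luminance(array(c(1, 0, 0), dim = c(1, 1, 3)))  # pure red -> 0.2126
to_luminance <- function(rgb) {
  if (is.list(rgb) && !is.null(rgb$r)) {
    ch <- list(rgb$r, rgb$g, rgb$b)
  } else if (is.array(rgb) && length(dim(rgb)) == 3 && dim(rgb)[3] >= 3) {
    ch <- lapply(1:3, function(i) {
      matrix(rgb[, , i], dim(rgb)[1], dim(rgb)[2])
    })
  } else {
    stop("`rgb` must be an h x w x 3 array or a list with r, g, b matrices",
         call. = FALSE)
  }
  dims <- lapply(ch, dim)
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("RGB channels must share dimensions", call. = FALSE)
  }
  vals <- unlist(ch, use.names = FALSE)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
    stop("channel intensities must be finite and within [0, 1]", call. = FALSE)
  }
  lum <- 0.2126 * ch[[1]] + 0.7152 * ch[[2]] + 0.0722 * ch[[3]]
  dim(lum) <- dims[[1]]
  lum
}

validate_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("an image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(image) < 3 || ncol(image) < 3) {
    stop("images must be at least 3 x 3 pixels", call. = FALSE)
  }
  if (anyNA(image) || any(image < 0) || any(image > 1)) {
    stop("image intensities must be finite and within [0, 1]", call. = FALSE)
  }
  invisible(image)
}

validate_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("a mask must be a logical matrix (TRUE = foreground)", call. = FALSE)
  }
  if (!is.null(image) && !identical(dim(mask), dim(image))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  invisible(mask)
}

mask_touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

#' Generate a synthetic grayscale image with ground truth of graded complexity
#'
#' Emulates the structure of a two-region segmentation task with unambiguous
#' ground truth: a single foreground object, entirely inside the image, whose
#' boundary roughness is controlled by a single knob. The object is a radial
#' star-domain around the image centre whose radius is perturbed by random
#' cosine harmonics; the harmonic amplitudes scale with `shape_complexity`,
#' so the boundary's box-counting (fractal) dimension grows monotonically
#' with the knob, and `shape_complexity = 0` yields a smooth disk. Foreground
#' and background intensities are separated by `contrast` and corrupted by
#' i.i.d. Gaussian noise.
#'
#' The generator is a pure function of its parameters and `seed`: the global
#' RNG state is left untouched.
#'
#' @param shape_complexity Boundary roughness in `[0, 1]`.
#' @param noise_sd Standard deviation of additive intensity noise (intensity
#'   units; the image is clipped back to `[0, 1]`).
#' @param size Integer vector `c(w, h)`, both at least 16.
#' @param seed Integer RNG seed; required so runs are reproducible.
#' @param contrast Mean intensity separation between object and background.
#' @return A list with elements `image` (`h x w` matrix in `[0, 1]`) and
#'   `mask` (logical `h x w` matrix, `TRUE` = foreground) — the mask never
#'   touches the image border.
#' @export
make_synthetic_image <- function(shape_complexity = 0.5, noise_sd = 0.05,
                                 size = c(64, 64), seed, contrast = 0.5) {
  stopifnot(length(size) == 2, size[1] >= 16, size[2] >= 16,
            noise_sd >= 0, shape_complexity >= 0, shape_complexity <= 1,
            contrast > 0, contrast <= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  w <- as.integer(size[1])
  h <- as.integer(size[2])
  withr::with_seed(as.integer(seed), {
    cx <- (w - 1) / 2
    cy <- (h - 1) / 2
    r0 <- 0.3 * min(w, h)
    ks <- 2:20
    amp <- shape_complexity * 0.9 * runif(length(ks), -1, 1) / sqrt(ks)
    phase <- runif(length(ks), 0, 2 * pi)

    xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
    ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    theta <- atan2(ys - cy, xs - cx)
    perturb <- matrix(0, h, w)
    for (i in seq_along(ks)) {
      perturb <- perturb + amp[i] * cos(ks[i] * theta + phase[i])
    }
    # keep the radius positive and strictly inside the border
    perturb <- pmax(pmin(perturb, 0.45), -0.65)
    radius <- r0 * (1 + perturb)
    mask <- r < radius
    if (mask_touches_border(mask)) {
      stop("synthetic foreground touched the image border; reduce complexity",
           call. = FALSE)
    }
    bg <- 0.5 - contrast / 2
    fg <- 0.5 + contrast / 2
    image <- matrix(bg, h, w)
    image[mask] <- fg
    if (noise_sd > 0) {
      image <- image + matrix(rnorm(h * w, sd = noise_sd), h, w)
    }
    image <- pmin(pmax(image, 0), 1)
    list(image = image, mask = mask)
  })
}

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unknown image format: '", ext, "' (use png or tiff)", call. = FALSE)
}

#' Read and write grayscale images and binary masks
#'
#' Images are exchanged as PNG or TIFF files and represented in memory as
#' numeric matrices normalised to `[0, 1]` regardless of the file bit depth.
#' RGB files are collapsed with [to_luminance()]. Masks are stored as
#' single-channel PNG/TIFF with 0 = background and 255 = foreground.
#'
#' @param path File path; the format is chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param image,mask Matrix to write (`[0, 1]` intensities / logical).
#' @param bits Bit depth for writing (8 or 16).
#' @return `read_image()` a numeric matrix; `read_mask()` a logical matrix;
#'   the writers return `path` invisibly.
#' @name image_io
NULL

#' @rdname image_io
#' @export
read_image <- function(path) {
  fmt <- img_format(path)
  x <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(x)) == 3) {
    x <- if (dim(x)[3] >= 3) to_luminance(x) else x[, , 1]
  }
  x
}

#' @rdname image_io
#' @export
write_image <- function(image, path, bits = 8) {
  validate_gray_image(image)
  fmt <- img_format(path)
  if (fmt == "png") {
    png::writePNG(image, target = path)
  } else {
    tiff::writeTIFF(image, where = path, bits.per.sample = bits)
  }
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask <- function(path) {
  fmt <- img_format(path)
  x <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x >= 0.5
}

#' @rdname image_io
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  fmt <- img_format(path)
  vals <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (fmt == "png") {
    png::writePNG(vals, target = path)
  } else {
    tiff::writeTIFF(vals, where = path, bits.per.sample = 8)
  }
  invisible(path)
}
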