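#' Grayscale image with physical pixel spacing
#'
#' A minimal container for a 2D B-mode-like grayscale image: a numeric matrix
#' of non-negative intensities plus the physical pixel spacing in millimetres
#' (row spacing, column spacing). All radiomic computations in this package
#' operate on this container.
#'
#' @param values numeric matrix of finite, non-negative intensities.
#' @param spacing positive numeric of length 1 (isotropic) or 2
#'   `(row_mm, col_mm)`.
#' @param bit_depth integer, 8 or 16; the native intensity scale
#'   (`0 .. 2^bit_depth - 1`).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(values, spacing = c(1, 1), bit_depth = 8L) {
  stopifnot(is.matrix(values), all(is.finite(values)))
  if (any(values < 0)) stop("gray_image values must be non-negative")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  stopifnot(length(spacing) == 2L, all(spacing > 0))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(list(values = values, spacing = as.numeric(spacing),
                 bit_depth = as.integer(bit_depth)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, spacing %.4g x %.4g mm, %d-bit\n",
              nrow(x$values), ncol(x$values), x$spacing[1], x$spacing[2],
              x$bit_depth))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param values logical (or 0/1) matrix, same shape as its image, with at
#'   least one foreground pixel.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values) {
  if (!is.logical(values)) {
    stopifnot(all(values %in% c(0, 1)))
    values <- matrix(values != 0, nrow(values), ncol(values))
  }
  stopifnot(is.matrix(values))
  if (!any(values)) stop("roi_mask must contain at least one foreground pixel")
  structure(list(values = values), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d px, %d foreground\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

# internal: check that a mask matches its image
check_pair <- function(image, mask) {
  stopifnot(inherits(image, "gray_image"), inherits(mask, "roi_mask"))
  if (!identical(dim(image$values), dim(mask$values)))
    stop("mask shape does not match image shape")
  invisible(TRUE)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a grayscale image (with sidecar manifest) to PNG or TIFF
#'
#' 8-bit images are written as grayscale PNG, 16-bit as grayscale TIFF
#' (format is inferred from the file extension). A JSON sidecar
#' `<path>.json` records pixel spacing and bit depth so the round-trip is
#' lossless including physical metadata.
#'
#' @param image a [gray_image].
#' @param path output path ending in `.png` or `.tif(f)`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  maxv <- 2^image$bit_depth - 1
  v <- clamp(round(image$values), 0, maxv) / maxv
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, where = path, bits.per.sample = image$bit_depth)
  } else {
    stop("unsupported image extension: ", ext)
  }
  jsonlite::write_json(
    list(pixel_spacing_mm = image$spacing, bit_depth = image$bit_depth),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a grayscale image written by [write_image()]
#'
#' Accepts 8/16-bit single-channel PNG or TIFF. Color images are rejected.
#' Pixel spacing is read from the JSON sidecar manifest; if the sidecar is
#' missing, spacing defaults to 1.0 mm isotropic with a warning.
#'
#' @param path path to a `.png` or `.tif(f)` file.
#' @return A [gray_image] on the native integer intensity scale.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    info <- attr(raw, "info")
    depth <- if (!is.null(info$bits.per.sample))
      as.integer(info$bits.per.sample) else 8L
  } else {
    stop("unsupported image extension: ", ext)
  }
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] > 1L && !all(raw[, , 1] == raw[, , 2]))
      stop("grayscale required: image has color channels")
    raw <- raw[, , 1]
  }
  sp <- c(1, 1)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    man <- jsonlite::read_json(sc, simplifyVector = TRUE)
    sp <- as.numeric(man$pixel_spacing_mm)
    if (!is.null(man$bit_depth)) depth <- as.integer(man$bit_depth)
  } else {
    warning("no sidecar manifest for ", path,
            "; assuming 1.0 mm isotropic spacing")
  }
  v <- round(raw * (2^depth - 1))
  attributes(v) <- list(dim = dim(v))
  gray_image(v, spacing = sp, bit_depth = depth)
}

#' Write / read a binary ROI mask as a 0/255 PNG
#'
#' @param mask a [roi_mask].
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  png::writePNG(mask$values * 1.0, target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  roi_mask(raw > 0.5)
}
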