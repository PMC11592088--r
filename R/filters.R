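#' Specify an intensity/spatial filter for the radiomic filter bank
#'
#' The bank contains the identity plus four transforms whose outputs feed the
#' same feature families as the raw image: per-pixel gradient magnitude
#' (central differences, mm-aware through the pixel spacing),
#' Laplacian-of-Gaussian convolution (scale in mm, kernel truncated at 4
#' sigma, reflect padding), and the pointwise square and square-root maps
#' normalized by the bit-depth maximum so that outputs stay on the native
#' intensity scale.
#'
#' @param kind one of `"identity"`, `"gradient"`, `"log"`, `"square"`,
#'   `"squareroot"`.
#' @param log_sigma_mm positive LoG scale in millimetres (used only when
#'   `kind = "log"`; default 1.0 mm).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("identity", "gradient", "log", "square",
                                 "squareroot"),
                        log_sigma_mm = 1.0) {
  kind <- match.arg(kind)
  stopifnot(log_sigma_mm > 0)
  structure(list(kind = kind, log_sigma_mm = log_sigma_mm),
            class = "filter_spec")
}

#' The default five-filter bank
#'
#' @param log_sigma_mm LoG scale passed to [filter_spec()].
#' @return A named list of [filter_spec] objects
#'   (identity, gradient, log, square, squareroot).
#' @export
default_filter_bank <- function(log_sigma_mm = 1.0) {
  kinds <- c("identity", "gradient", "log", "square", "squareroot")
  stats::setNames(lapply(kinds, filter_spec, log_sigma_mm = log_sigma_mm),
                  kinds)
}

# internal: reflect-pad a matrix by (pr, pc) pixels on each side
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(rev(seq_len(min(pr, nr))), seq_len(nr),
            nr + 1 - rev(seq_len(min(pr, nr))))
  if (pr > nr) stop("reflect pad larger than image")
  cidx <- c(rev(seq_len(min(pc, nc))), seq_len(nc),
            nc + 1 - rev(seq_len(min(pc, nc))))
  m[ridx, cidx, drop = FALSE]
}

# internal: 2D convolution with reflect padding (EBImage FFT backend)
conv_reflect <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  p <- pad_reflect(m, kr, kc)
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  out[(kr + 1):(kr + nrow(m)), (kc + 1):(kc + ncol(m)), drop = FALSE]
}

# internal: normalized 2D Gaussian kernel (isotropic, sigma in pixels,
# truncated at 3 sigma)
gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  x <- seq(-h, h)
  g1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# internal: Laplacian-of-Gaussian kernel, scale sigma in pixels per axis,
# truncated at 4 sigma. Zero-mean by construction (numerically re-centred).
log_kernel <- function(sigma_r, sigma_c, truncate = 4) {
  hr <- max(1L, ceiling(truncate * sigma_r))
  hc <- max(1L, ceiling(truncate * sigma_c))
  r <- seq(-hr, hr); cc <- seq(-hc, hc)
  R <- matrix(r, length(r), length(cc))
  C <- matrix(cc, length(r), length(cc), byrow = TRUE)
  g <- exp(-(R^2 / (2 * sigma_r^2) + C^2 / (2 * sigma_c^2)))
  g <- g / sum(g)
  k <- g * ((R^2 / sigma_r^4 - 1 / sigma_r^2) +
            (C^2 / sigma_c^4 - 1 / sigma_c^2))
  k - mean(k)  # enforce zero response to constant input
}

#' Apply a bank filter to a grayscale image
#'
#' `identity` returns the image unchanged. `gradient` computes the per-pixel
#' magnitude of the central-difference spatial gradient in intensity per mm
#' (replicated edges). `log` convolves with a Laplacian-of-Gaussian kernel of
#' scale `log_sigma_mm` (truncated at 4 sigma, reflect padding) and shifts
#' the output so its minimum is zero, keeping intensities non-negative ahead
#' of ROI discretization. `square` maps `x` to `(x/x_max)^2 * x_max` and
#' `squareroot` maps `x` to `sqrt(x/x_max) * x_max`, with `x_max` the
#' bit-depth maximum; both are monotone bijections of `[0, x_max]`.
#'
#' @param image a [gray_image].
#' @param spec a [filter_spec].
#' @return A [gray_image] with the same shape, spacing and bit depth.
#' @export
apply_filter <- function(image, spec) {
  stopifnot(inherits(image, "gray_image"), inherits(spec, "filter_spec"))
  v <- image$values
  xmax <- 2^image$bit_depth - 1
  out <- switch(spec$kind,
    identity = v,
    gradient = {
      nr <- nrow(v); nc <- ncol(v)
      up    <- v[c(1L, seq_len(nr - 1L)), , drop = FALSE]
      down  <- v[c(seq_len(nr)[-1L], nr), , drop = FALSE]
      left  <- v[, c(1L, seq_len(nc - 1L)), drop = FALSE]
      right <- v[, c(seq_len(nc)[-1L], nc), drop = FALSE]
      gr <- (down - up) / (2 * image$spacing[1])
      gc <- (right - left) / (2 * image$spacing[2])
      sqrt(gr^2 + gc^2)
    },
    log = {
      k <- log_kernel(spec$log_sigma_mm / image$spacing[1],
                      spec$log_sigma_mm / image$spacing[2])
      r <- conv_reflect(v, k)
      r - min(r)
    },
    square = (v / xmax)^2 * xmax,
    squareroot = sqrt(pmax(v, 0) / xmax) * xmax,
    stop("unknown filter kind: ", spec$kind)
  )
  gray_image(out, spacing = image$spacing, bit_depth = image$bit_depth)
}
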