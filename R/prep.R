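#' ROI preprocessing configuration
#'
#' Controls intensity discretization and the resampling pixel caps applied
#' before feature extraction. The defaults follow the workflow this package
#' implements: a fixed number of 64 grey-level bins for all discretized
#' (histogram and texture) features, and mask-size caps of 1e7 pixels for
#' texture features and 1e6 pixels for other features, enforced by uniformly
#' coarsening the target isotropic spacing.
#'
#' @param n_bins integer number of grey levels (default 64).
#' @param texture_pixel_cap maximum resampled mask size for texture features.
#' @param other_pixel_cap maximum resampled mask size for non-texture features.
#' @return A `prep_config` list.
#' @export
prep_config <- function(n_bins = 64L, texture_pixel_cap = 1e7,
                        other_pixel_cap = 1e6) {
  stopifnot(n_bins >= 2, texture_pixel_cap > 0, other_pixel_cap > 0)
  structure(list(n_bins = as.integer(n_bins),
                 texture_pixel_cap = texture_pixel_cap,
                 other_pixel_cap = other_pixel_cap),
            class = "prep_config")
}

# internal: vectorized bilinear resampling of a matrix to new dimensions,
# mapping output pixel centres onto the input grid (edge-clamped)
resample_bilinear <- function(m, out_nr, out_nc) {
  nr <- nrow(m); nc <- ncol(m)
  # centre-aligned coordinate of each output pixel in input pixel units
  ri <- (seq_len(out_nr) - 0.5) * nr / out_nr + 0.5
  ci <- (seq_len(out_nc) - 0.5) * nc / out_nc + 0.5
  r0 <- clamp(floor(ri), 1, nr); r1 <- clamp(r0 + 1, 1, nr)
  c0 <- clamp(floor(ci), 1, nc); c1 <- clamp(c0 + 1, 1, nc)
  fr <- matrix(clamp(ri - floor(ri), 0, 1), out_nr, out_nc)
  fc <- matrix(clamp(ci - floor(ci), 0, 1), out_nr, out_nc, byrow = TRUE)
  top <- m[r0, c0, drop = FALSE] * (1 - fc) + m[r0, c1, drop = FALSE] * fc
  bot <- m[r1, c0, drop = FALSE] * (1 - fc) + m[r1, c1, drop = FALSE] * fc
  top * (1 - fr) + bot * fr
}

# internal: nearest-neighbour resampling (for masks)
resample_nearest <- function(m, out_nr, out_nc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(ceiling((seq_len(out_nr) - 0.5) * nr / out_nr), 1, nr)
  ci <- clamp(ceiling((seq_len(out_nc) - 0.5) * nc / out_nc), 1, nc)
  m[ri, ci, drop = FALSE]
}

#' Resample an image/mask pair to isotropic pixel spacing with pixel caps
#'
#' The target isotropic spacing is the coarser of the two input spacings, so
#' resampling only ever down-samples. If the resampled mask would exceed the
#' pixel cap for the stated purpose (1e7 pixels for texture features, 1e6 for
#' other features), the target spacing is coarsened uniformly by the smallest
#' factor that brings the mask under the cap. The image is interpolated
#' bilinearly; the mask uses nearest-neighbour interpolation and stays
#' strictly binary. An already-isotropic pair under the cap is returned
#' unchanged.
#'
#' @param image a [gray_image].
#' @param mask a [roi_mask] of the same shape.
#' @param cfg a [prep_config].
#' @param purpose `"texture"` or `"other"`; selects the pixel cap.
#' @return A list with elements `image` and `mask`.
#' @export
resample_isotropic <- function(image, mask, cfg = prep_config(),
                               purpose = c("texture", "other")) {
  check_pair(image, mask)
  purpose <- match.arg(purpose)
  cap <- if (purpose == "texture") cfg$texture_pixel_cap else cfg$other_pixel_cap
  sp <- image$spacing
  target <- max(sp)
  # predicted mask foreground count at a candidate spacing
  n_fg_at <- function(s) {
    scale_r <- sp[1] / s; scale_c <- sp[2] / s
    sum(mask$values) * scale_r * scale_c
  }
  if (n_fg_at(target) > cap) {
    target <- target * sqrt(n_fg_at(target) / cap)
  }
  if (isTRUE(all.equal(sp[1], sp[2])) && isTRUE(all.equal(target, sp[1]))) {
    return(list(image = image, mask = mask))
  }
  repeat {
    out_nr <- max(1L, as.integer(round(nrow(image$values) * sp[1] / target)))
    out_nc <- max(1L, as.integer(round(ncol(image$values) * sp[2] / target)))
    newm <- resample_nearest(mask$values, out_nr, out_nc)
    # dimension rounding can leave the realized count a sliver over the cap
    if (sum(newm) <= cap) break
    target <- target * 1.01
  }
  newv <- resample_bilinear(image$values, out_nr, out_nc)
  if (!any(newm)) stop("mask is empty after resampling")
  list(image = gray_image(pmax(newv, 0), spacing = c(target, target),
                          bit_depth = image$bit_depth),
       mask = roi_mask(newm))
}

#' Fixed-bin-number discretization of ROI intensities
#'
#' Maps ROI intensities onto integer grey levels `1..n_bins` using the
#' fixed-bin-number rule over the ROI's own intensity range:
#' `level(x) = floor(n_bins * (x - roi_min) / (roi_max - roi_min)) + 1`,
#' with `x = roi_max` mapped to `n_bins`. A constant ROI maps every pixel to
#' level 1. Levels are invariant under any positive affine rescaling of the
#' ROI intensities.
#'
#' @param image a [gray_image] (possibly filtered).
#' @param mask a [roi_mask] of the same shape.
#' @param cfg a [prep_config]; `cfg$n_bins` grey levels are used.
#' @return A `disc_roi` object: `levels` (integer matrix, `NA` outside the
#'   ROI), `n_bins`, and the pre-discretization ROI extrema `roi_min`,
#'   `roi_max`.
#' @export
discretize_fbn <- function(image, mask, cfg = prep_config()) {
  check_pair(image, mask)
  nb <- cfg$n_bins
  x <- image$values
  fg <- mask$values
  rmin <- min(x[fg]); rmax <- max(x[fg])
  lv <- matrix(NA_integer_, nrow(x), ncol(x))
  if (rmax > rmin) {
    l <- floor(nb * (x[fg] - rmin) / (rmax - rmin)) + 1
    lv[fg] <- as.integer(pmin(l, nb))
  } else {
    lv[fg] <- 1L
  }
  structure(list(levels = lv, n_bins = nb, roi_min = rmin, roi_max = rmax),
            class = "disc_roi")
}

#' @export
print.disc_roi <- function(x, ...) {
  cat(sprintf("<disc_roi> %d ROI px, %d bins, range [%.4g, %.4g]\n",
              sum(!is.na(x$levels)), x$n_bins, x$roi_min, x$roi_max))
  invisible(x)
}
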