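#' Configuration of the synthetic ultrasound-nodule cohort generator
#'
#' The generator emulates single-nodule B-mode thyroid images at desk scale:
#' an axis-aligned elliptical nodule (the ROI) on a darker tissue background,
#' both textured with spatially correlated multiplicative gamma speckle over
#' a smooth radial echogenic base. Benign nodules carry a pronounced smooth
#' macro-scale echotexture modulation (the mixed/spongiform pattern of
#' benign nodules); malignant nodules have a more homogeneous echogenic
#' background but add a Poisson-distributed number of small dark
#' (hypoechoic) circular foci inside the ROI and inflate the speckle
#' dispersion, giving the higher intensity variability concentrated in many
#' small darker areas that characterizes malignancy in this setting.
#'
#' Defaults reproduce the study conditions: a training/internal cohort of
#' 102 benign + 40 malignant cases (28.2% malignant); use
#' `n_benign = 15, n_malignant = 6` for the 21-case external cohort.
#'
#' @param n_benign,n_malignant class counts (default 102 / 40).
#' @param image_height,image_width image size in pixels (default 256).
#' @param pixel_spacing_mm isotropic spacing (scalar) or `(row, col)` pair.
#' @param bit_depth 8 or 16.
#' @param speckle_shape gamma shape of the multiplicative speckle
#'   (coefficient of variation `1/sqrt(shape)` before spatial correlation).
#' @param speckle_correlation_px standard deviation, in pixels, of the
#'   Gaussian point-spread blur applied to the speckle field (B-mode speckle
#'   is correlated at the resolution-cell scale; 0 disables the blur).
#' @param macro_heterogeneity amplitude (standard deviation) of the smooth
#'   multiplicative echotexture modulation inside benign nodules, emulating
#'   the mixed/spongiform macro-structure of benign echotexture.
#' @param macro_correlation_px correlation length (Gaussian blur sigma, in
#'   pixels) of the macro-modulation field.
#' @param malignant_macro_factor multiplier in `[0, 1]` on
#'   `macro_heterogeneity` for malignant nodules, whose echogenic background
#'   is more homogeneous (their variability comes from the dark foci).
#' @param roi_axes_range pixel range for the nodule ellipse semi-axes.
#' @param malignant_focus_rate expected number of hypoechoic foci per
#'   malignant nodule (Poisson mean).
#' @param focus_radius_range pixel range for focus radii.
#' @param focus_intensity_factor multiplicative darkening of foci, in (0, 1).
#' @param malignant_speckle_contrast multiplier > 1 on the speckle standard
#'   deviation in malignant nodules.
#' @param split cohort split tag stored on every case.
#' @param seed integer seed; the cohort is deterministic given the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_benign = 102L, n_malignant = 40L,
                          image_height = 256L, image_width = 256L,
                          pixel_spacing_mm = 0.1, bit_depth = 8L,
                          speckle_shape = 30, speckle_correlation_px = 1.0,
                          macro_heterogeneity = 0.5,
                          macro_correlation_px = 6,
                          malignant_macro_factor = 0.0,
                          roi_axes_range = c(25, 60),
                          malignant_focus_rate = 6,
                          focus_radius_range = c(4, 6),
                          focus_intensity_factor = 0.55,
                          malignant_speckle_contrast = 1.4,
                          split = c("train_internal", "external"),
                          seed = 1L) {
  split <- match.arg(split)
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  stopifnot(n_benign >= 0, n_malignant >= 0,
            image_height > 0, image_width > 0,
            all(pixel_spacing_mm > 0), speckle_shape > 0,
            speckle_correlation_px >= 0, macro_heterogeneity >= 0,
            macro_correlation_px > 0, malignant_macro_factor >= 0,
            malignant_macro_factor <= 1,
            length(roi_axes_range) == 2L, all(roi_axes_range > 0),
            malignant_focus_rate >= 0,
            length(focus_radius_range) == 2L, all(focus_radius_range > 0),
            focus_intensity_factor > 0, focus_intensity_factor <= 1,
            malignant_speckle_contrast >= 1)
  if (2 * max(roi_axes_range) >= min(image_height, image_width))
    stop("roi_axes_range exceeds image bounds")
  structure(list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_spacing_mm = as.numeric(pixel_spacing_mm),
    bit_depth = as.integer(bit_depth), speckle_shape = speckle_shape,
    speckle_correlation_px = speckle_correlation_px,
    macro_heterogeneity = macro_heterogeneity,
    macro_correlation_px = macro_correlation_px,
    malignant_macro_factor = malignant_macro_factor,
    roi_axes_range = roi_axes_range,
    malignant_focus_rate = malignant_focus_rate,
    focus_radius_range = focus_radius_range,
    focus_intensity_factor = focus_intensity_factor,
    malignant_speckle_contrast = malignant_speckle_contrast,
    split = split, seed = as.integer(seed)), class = "cohort_config")
}

#' A cohort config for the 21-case external cohort
#'
#' 15 benign + 6 malignant (about 71% / 29%), otherwise identical defaults.
#'
#' @param ... overrides passed on to [cohort_config()].
#' @export
external_cohort_config <- function(...) {
  args <- list(...)
  defaults <- list(n_benign = 15L, n_malignant = 6L, split = "external",
                   seed = 2L)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

#' Render one synthetic nodule case
#'
#' Benign: elliptical ROI with homogeneous multiplicative gamma speckle over
#' a smooth radial echogenic base. Malignant: the same base plus
#' `Poisson(malignant_focus_rate)` dark circular foci (radius uniform on
#' `focus_radius_range`, base intensity multiplied by
#' `focus_intensity_factor`, placed fully inside the ROI, overlaps allowed)
#' and speckle standard deviation inflated by `malignant_speckle_contrast`.
#' Intensities are clipped to the image bit depth. Uses (and advances) the
#' current RNG state.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param config a [cohort_config].
#' @param case_id case identifier string.
#' @return A `synthetic_case`: `case_id`, `label`, `split`, `image`, `mask`.
#' @export
render_case <- function(label = c("benign", "malignant"), config,
                        case_id = "case") {
  label <- match.arg(label)
  h <- config$image_height; w <- config$image_width
  xmax <- 2^config$bit_depth - 1

  ax <- stats::runif(1, config$roi_axes_range[1], config$roi_axes_range[2])
  # mild random eccentricity around the first semi-axis
  bx <- clamp(ax * stats::runif(1, 0.6, 1.0),
              config$roi_axes_range[1], config$roi_axes_range[2])
  if (ax <= 0 || bx <= 0) stop("degenerate ROI ellipse")
  cy <- h / 2 + stats::runif(1, -0.1, 0.1) * h
  cx <- w / 2 + stats::runif(1, -0.1, 0.1) * w
  # keep ellipse fully inside the image
  cy <- clamp(cy, ax + 2, h - ax - 2)
  cx <- clamp(cx, bx + 2, w - bx - 2)

  R <- matrix(seq_len(h), h, w)
  C <- matrix(seq_len(w), h, w, byrow = TRUE)
  rad2 <- ((R - cy) / ax)^2 + ((C - cx) / bx)^2
  fg <- rad2 <= 1

  # smooth echogenic base: bright nodule with gentle radial falloff on a
  # darker tissue background
  base_bg <- 0.28 * xmax
  base_fg <- 0.62 * xmax * (1 - 0.20 * rad2)
  base <- ifelse(fg, base_fg, base_bg)

  # smooth macro-scale echotexture modulation: pronounced in benign nodules
  # (mixed/spongiform pattern), strongly damped in malignant ones, whose
  # echogenic background is more homogeneous
  amp <- config$macro_heterogeneity *
    if (label == "malignant") config$malignant_macro_factor else 1
  if (amp > 0) {
    macro <- conv_reflect(matrix(stats::rnorm(h * w), h, w),
                          gauss_kernel(config$macro_correlation_px))
    macro <- macro / stats::sd(macro)
    # darkening-only modulation: spongiform texture is hypoechoic (cystic)
    # patches in an echogenic matrix, so the bright side stays at the base
    # level and no saturation is introduced
    base[fg] <- base[fg] * pmax(1 - amp * pmax(macro[fg], 0), 0.1)
  }

  if (label == "malignant") {
    n_foci <- stats::rpois(1, config$malignant_focus_rate)
    if (n_foci > 0) {
      for (i in seq_len(n_foci)) {
        rf <- stats::runif(1, config$focus_radius_range[1],
                           config$focus_radius_range[2])
        # place centre so the focus stays fully inside the ROI: sample in the
        # ellipse shrunk by the focus radius (rejection sampling)
        sa <- max(ax - rf, 1); sb <- max(bx - rf, 1)
        repeat {
          u <- stats::runif(1, -1, 1); v2 <- stats::runif(1, -1, 1)
          if (u^2 + v2^2 <= 1) break
        }
        fy <- cy + u * sa; fx <- cx + v2 * sb
        inside <- (R - fy)^2 + (C - fx)^2 <= rf^2
        base[inside] <- base[inside] * config$focus_intensity_factor
      }
    }
    shape_fg <- config$speckle_shape / config$malignant_speckle_contrast^2
  } else {
    shape_fg <- config$speckle_shape
  }

  shape <- matrix(config$speckle_shape, h, w)
  shape[fg] <- shape_fg
  speckle <- matrix(stats::rgamma(h * w, shape = shape, rate = shape), h, w)
  if (config$speckle_correlation_px > 0) {
    # B-mode speckle is correlated at the resolution-cell scale: blur the
    # noise field (not the base, so hypoechoic focus edges stay sharp)
    speckle <- conv_reflect(speckle,
                            gauss_kernel(config$speckle_correlation_px))
  }
  img <- clamp(round(base * speckle), 0, xmax)

  structure(list(case_id = case_id, label = label, split = config$split,
                 image = gray_image(img, spacing = config$pixel_spacing_mm,
                                    bit_depth = config$bit_depth),
                 mask = roi_mask(fg)),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s [%s, %s], %d ROI px\n", x$case_id,
              x$label, x$split, sum(x$mask$values)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Produces exactly `n_benign + n_malignant` cases with exact class counts,
#' deterministic given `config$seed` (byte-identical images across calls).
#' Case order interleaves the two classes in a seeded random permutation.
#'
#' @param config a [cohort_config].
#' @return A list of `synthetic_case` objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_benign + config$n_malignant
  if (n == 0L) return(list())
  labels <- c(rep("benign", config$n_benign),
              rep("malignant", config$n_malignant))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(config$seed, paste0("cohort_", config$split)))
  labels <- sample(labels)
  prefix <- if (config$split == "external") "ext" else "case"
  lapply(seq_len(n), function(i) {
    render_case(labels[i], config,
                case_id = sprintf("%s_%03d", prefix, i))
  })
}

#' Extract the label table of a cohort
#'
#' @param cases list of `synthetic_case`.
#' @return A data.frame with columns `case_id`, `label`, `split`.
#' @export
cohort_labels <- function(cases) {
  data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
             label = vapply(cases, `[[`, "", "label"),
             split = vapply(cases, `[[`, "", "split"),
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk (images, masks, labels, manifest)
#'
#' Images are written as 8-bit grayscale PNG (16-bit TIFF when the config's
#' bit depth is 16), masks as 0/255 PNG, labels as a CSV
#' (`case_id,label,split`), and a JSON manifest records the full config.
#'
#' @param cases list of `synthetic_case`.
#' @param dir output directory (created if needed).
#' @param config the [cohort_config] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cases, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (config$bit_depth == 16L) "tiff" else "png"
  for (cs in cases) {
    write_image(cs$image, file.path(dir, paste0(cs$case_id, ".", ext)))
    write_mask(cs$mask, file.path(dir, paste0(cs$case_id, "_mask.png")))
  }
  utils::write.csv(cohort_labels(cases), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A list of `synthetic_case` objects.
#' @export
read_cohort <- function(dir) {
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  lapply(seq_len(nrow(lab)), function(i) {
    id <- lab$case_id[i]
    img_path <- Filter(file.exists,
                       file.path(dir, paste0(id, c(".png", ".tiff", ".tif"))))
    if (length(img_path) == 0L) stop("missing image for case ", id)
    structure(list(case_id = id, label = lab$label[i], split = lab$split[i],
                   image = read_image(img_path[1]),
                   mask = read_mask(file.path(dir, paste0(id, "_mask.png")))),
              class = "synthetic_case")
  })
}
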