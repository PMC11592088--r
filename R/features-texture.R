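#' Texture-matrix configuration
#'
#' Conventions shared by all grey-level matrix families: 2D computation over
#' the four unique direction offsets (0, 45, 90, 135 degrees) at the given
#' pixel distance, matrices merged by averaging after normalization, and a
#' Chebyshev-radius-1 neighbourhood with coarseness tolerance `alpha` for
#' the dependence matrix (the dependence count includes the centre pixel, so
#' counts start at 1).
#'
#' @param glcm_distance pixel offset distance for GLCM (default 1).
#' @param ngldm_alpha non-negative integer grey-level tolerance (default 0).
#' @return A `texture_config` list.
#' @export
texture_config <- function(glcm_distance = 1L, ngldm_alpha = 0L) {
  stopifnot(glcm_distance >= 1, ngldm_alpha >= 0)
  structure(list(glcm_distance = as.integer(glcm_distance),
                 ngldm_alpha = as.integer(ngldm_alpha),
                 directions = list(c(0L, 1L), c(-1L, 1L),
                                   c(-1L, 0L), c(-1L, -1L))),
            class = "texture_config")
}

# internal: crop a levels matrix to the ROI bounding box
crop_levels <- function(lv) {
  fg <- !is.na(lv)
  rr <- range(which(rowSums(fg) > 0))
  cr <- range(which(colSums(fg) > 0))
  lv[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
}

# internal: levels matrix padded by one NA ring, plus the 8 Chebyshev-1
# neighbour matrices aligned with the unpadded grid
neighbor_shifts <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  p <- matrix(NA_integer_, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- lv
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
               c(1L, -1L), c(1L, 0L), c(1L, 1L))
  lapply(offs, function(o) {
    p[(2L + o[1]):(nr + 1L + o[1]), (2L + o[2]):(nc + 1L + o[2]),
      drop = FALSE]
  })
}

# internal: entropy in bits of a probability vector/matrix
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Grey-level co-occurrence matrix features
#'
#' Builds a symmetric co-occurrence matrix per direction at the configured
#' distance over in-ROI pixel pairs only (pairs with either pixel outside
#' the ROI are skipped), normalizes each matrix, averages the normalized
#' matrices over the directions that contain at least one pair, and computes
#' the features on the averaged matrix. `correlation` of a degenerate
#' (zero-variance) matrix is 1 by convention.
#'
#' @param d a `disc_roi`.
#' @param cfg a [texture_config].
#' @return Named numeric vector of 16 GLCM features.
#' @export
glcm_features <- function(d, cfg = texture_config()) {
  stopifnot(inherits(d, "disc_roi"))
  lv <- crop_levels(d$levels)
  nb <- d$n_bins
  nr <- nrow(lv); nc <- ncol(lv)
  acc <- matrix(0, nb, nb)
  used <- 0L
  for (o in cfg$directions) {
    dr <- o[1] * cfg$glcm_distance; dc <- o[2] * cfg$glcm_distance
    if (min(nr, nr - dr) < max(1L, 1L - dr) ||
        min(nc, nc - dc) < max(1L, 1L - dc)) next
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- lv[r0, c0, drop = FALSE]
    b <- lv[r0 + dr, c0 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    cnt <- tabulate((a[ok] - 1L) * nb + b[ok], nbins = nb * nb)
    M <- matrix(cnt, nb, nb, byrow = TRUE)
    M <- M + t(M)  # symmetric
    acc <- acc + M / sum(M)
    used <- used + 1L
  }
  if (used == 0L) stop("GLCM undefined: no valid in-ROI pixel pairs")
  P <- acc / used
  I <- row(P); J <- col(P)
  mu <- sum(I * P)                       # joint average (symmetric)
  pi_ <- rowSums(P)
  sd2 <- sum((seq_len(nb) - mu)^2 * pi_)
  autoc <- sum(I * J * P)
  corr <- if (sd2 <= 0) 1 else (autoc - mu^2) / sd2
  diffk <- abs(I - J)
  p_sum <- tapply(P, I + J, sum)
  p_diff <- tapply(P, diffk, sum)
  c(joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sum((I - mu)^2 * P),
    joint_entropy = entropy_bits(P),
    contrast = sum((I - J)^2 * P),
    dissimilarity = sum(diffk * P),
    inverse_difference = sum(P / (1 + diffk)),
    inverse_difference_moment = sum(P / (1 + (I - J)^2)),
    correlation = corr,
    autocorrelation = autoc,
    cluster_shade = sum((I + J - 2 * mu)^3 * P),
    cluster_prominence = sum((I + J - 2 * mu)^4 * P),
    sum_average = sum((I + J) * P),
    sum_entropy = entropy_bits(p_sum),
    difference_average = sum(as.numeric(names(p_diff)) * p_diff),
    difference_entropy = entropy_bits(p_diff))
}

# internal: run-length counts for one set of scan lines (levels with NA -> 0)
runs_from_lines <- function(lines, nb, maxlen) {
  cnt <- matrix(0, nb, maxlen)
  for (ln in lines) {
    ln[is.na(ln)] <- 0L
    r <- rle(ln)
    keep <- r$values > 0L
    if (any(keep)) {
      for (k in which(keep)) {
        cnt[r$values[k], r$lengths[k]] <- cnt[r$values[k], r$lengths[k]] + 1
      }
    }
  }
  cnt
}

#' Grey-level run-length matrix features
#'
#' Run-length matrices over the four directions (runs broken by the ROI
#' boundary). Emphasis/distribution features are computed on the average of
#' the per-direction normalized matrices; the count-based features
#' (grey-level / run-length non-uniformity, run percentage) are computed per
#' direction and averaged, since they are not functions of the normalized
#' matrix alone.
#'
#' @param d a `disc_roi`.
#' @param cfg a [texture_config].
#' @return Named numeric vector of 10 GLRLM features.
#' @export
glrlm_features <- function(d, cfg = texture_config()) {
  stopifnot(inherits(d, "disc_roi"))
  lv <- crop_levels(d$levels)
  nb <- d$n_bins
  nr <- nrow(lv); nc <- ncol(lv)
  npix <- sum(!is.na(lv))
  maxlen <- max(nr, nc)
  dir_lines <- list(
    split(lv, row(lv)),                # 0 deg
    split(lv, col(lv)),                # 90 deg
    split(lv, row(lv) - col(lv)),      # 45 deg (anti-diagonal scan)
    split(lv, row(lv) + col(lv))       # 135 deg
  )
  pacc <- matrix(0, nb, maxlen)
  gln <- rln <- rpc <- 0
  for (lines in dir_lines) {
    cnt <- runs_from_lines(lines, nb, maxlen)
    nruns <- sum(cnt)
    pacc <- pacc + cnt / nruns
    gln <- gln + sum(rowSums(cnt)^2) / nruns
    rln <- rln + sum(colSums(cnt)^2) / nruns
    rpc <- rpc + nruns / npix
  }
  nd <- length(dir_lines)
  P <- pacc / nd
  I <- row(P); J <- col(P)
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  c(short_run_emphasis = sum(P / J^2),
    long_run_emphasis = sum(P * J^2),
    low_grey_level_run_emphasis = sum(P / I^2),
    high_grey_level_run_emphasis = sum(P * I^2),
    grey_level_non_uniformity = gln / nd,
    run_length_non_uniformity = rln / nd,
    run_percentage = rpc / nd,
    run_entropy = entropy_bits(P),
    run_length_variance = sum(P * (J - mu_j)^2),
    grey_level_variance = sum(P * (I - mu_i)^2))
}

#' Grey-level size-zone matrix features
#'
#' Zones are 8-connected components of equal grey level within the ROI
#' (computed exactly via connected components of the pixel-adjacency graph).
#'
#' @param d a `disc_roi`.
#' @return Named numeric vector of 9 GLSZM features.
#' @export
glszm_features <- function(d) {
  stopifnot(inherits(d, "disc_roi"))
  lv <- crop_levels(d$levels)
  nr <- nrow(lv); nc <- ncol(lv)
  fg <- !is.na(lv)
  npix <- sum(fg)
  idx <- matrix(NA_integer_, nr, nc)
  idx[fg] <- seq_len(npix)
  edges <- NULL
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    if (min(nr, nr - o[1]) < max(1L, 1L - o[1]) ||
        min(nc, nc - o[2]) < max(1L, 1L - o[2])) next
    r0 <- max(1L, 1L - o[1]):min(nr, nr - o[1])
    c0 <- max(1L, 1L - o[2]):min(nc, nc - o[2])
    a <- lv[r0, c0, drop = FALSE]
    b <- lv[r0 + o[1], c0 + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (any(ok)) {
      ia <- idx[r0, c0, drop = FALSE][ok]
      ib <- idx[r0 + o[1], c0 + o[2], drop = FALSE][ok]
      edges <- c(edges, rbind(ia, ib))
    }
  }
  g <- igraph::make_empty_graph(n = npix, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  zsize <- comp$csize
  zlevel <- tapply(lv[fg], comp$membership, function(v) v[1])
  nz <- length(zsize)
  p <- rep(1 / nz, nz)
  i <- as.numeric(zlevel); z <- as.numeric(zsize)
  mu_z <- sum(p * z)
  # count aggregates for non-uniformities
  s_i <- tapply(rep(1, nz), i, sum)
  s_z <- tapply(rep(1, nz), z, sum)
  c(small_zone_emphasis = sum(p / z^2),
    large_zone_emphasis = sum(p * z^2),
    low_grey_level_zone_emphasis = sum(p / i^2),
    high_grey_level_zone_emphasis = sum(p * i^2),
    grey_level_non_uniformity = sum(s_i^2) / nz,
    zone_size_non_uniformity = sum(s_z^2) / nz,
    zone_percentage = nz / npix,
    zone_entropy = entropy_bits(as.numeric(table(paste(i, z))) / nz),
    zone_size_variance = sum(p * (z - mu_z)^2))
}

#' Neighbourhood grey-tone difference matrix features
#'
#' For each grey level `i` present among valid pixels (those with at least
#' one in-ROI Chebyshev-1 neighbour): `n_i` is the pixel count,
#' `p_i = n_i / N`, and `s_i` sums `|i - Abar_k|` over pixels `k` of level
#' `i`, where `Abar_k` is the mean level of pixel `k`'s in-ROI neighbours.
#' Coarseness (`1 / sum(p_i s_i)`) is capped at 1e6 when the denominator is
#' zero (perfectly homogeneous ROI).
#'
#' @param d a `disc_roi`.
#' @param cfg a [texture_config] (neighbourhood convention holder).
#' @return Named numeric vector: coarseness, contrast, busyness, complexity,
#'   strength.
#' @export
ngtdm_features <- function(d, cfg = texture_config()) {
  stopifnot(inherits(d, "disc_roi"))
  lv <- crop_levels(d$levels)
  sh <- neighbor_shifts(lv)
  nsum <- Reduce(`+`, lapply(sh, function(m) ifelse(is.na(m), 0, m)))
  ncnt <- Reduce(`+`, lapply(sh, function(m) (!is.na(m)) + 0L))
  valid <- !is.na(lv) & ncnt >= 1L
  if (!any(valid)) stop("NGTDM undefined: no ROI pixel has in-ROI neighbors")
  abar <- nsum[valid] / ncnt[valid]
  li <- lv[valid]
  N <- length(li)
  nb <- d$n_bins
  n_i <- tabulate(li, nbins = nb)
  s_i <- rep(0, nb)
  agg <- tapply(abs(li - abar), li, sum)
  s_i[as.integer(names(agg))] <- agg
  p_i <- n_i / N
  present <- which(p_i > 0)
  ngp <- length(present)
  denom_ps <- sum(p_i * s_i)
  coarseness <- if (denom_ps > 0) min(1 / denom_ps, 1e6) else 1e6
  if (ngp > 1) {
    pi_p <- p_i[present]; lev <- present
    dif <- outer(lev, lev, `-`)
    pp <- outer(pi_p, pi_p)
    contrast <- (sum(pp * dif^2) / (ngp * (ngp - 1))) * (sum(s_i) / N)
    bus_den <- sum(abs(outer(lev * pi_p, lev * pi_p, `-`)))
    busyness <- if (bus_den > 0) denom_ps / bus_den else 0
    psi <- pi_p * s_i[present]
    complexity <- sum(abs(dif) * (outer(psi, psi, `+`)) /
                        (outer(pi_p, pi_p, `+`))) / N
    s_sum <- sum(s_i)
    strength <- if (s_sum > 0) sum(outer(pi_p, pi_p, `+`) * dif^2) / s_sum
                else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

#' Neighbouring grey-level dependence matrix features
#'
#' For each ROI pixel of level `i`, the dependence count is `j = 1 +` the
#' number of in-ROI Chebyshev-1 neighbours whose level differs from `i` by
#' at most `alpha`; `s(i, j)` counts pixels and `p = s / N`. Dependence
#' count energy lies in `(0, 1]` and equals 1 iff the ROI maps to a single
#' `(level, dependence)` cell.
#'
#' @param d a `disc_roi`.
#' @param cfg a [texture_config]; `cfg$ngldm_alpha` is the tolerance.
#' @return Named numeric vector of 8 NGLDM features.
#' @export
ngldm_features <- function(d, cfg = texture_config()) {
  stopifnot(inherits(d, "disc_roi"))
  lv <- crop_levels(d$levels)
  sh <- neighbor_shifts(lv)
  a <- cfg$ngldm_alpha
  dep <- Reduce(`+`, lapply(sh, function(m) {
    (!is.na(m) & !is.na(lv) & abs(m - lv) <= a) + 0L
  }))
  fg <- !is.na(lv)
  li <- lv[fg]
  ji <- dep[fg] + 1L
  N <- length(li)
  nb <- d$n_bins
  maxj <- 9L  # Chebyshev-1 neighbourhood: at most 8 neighbours + centre
  s <- matrix(tabulate((li - 1L) * maxj + ji, nbins = nb * maxj),
              nb, maxj, byrow = TRUE)
  P <- s / N
  I <- row(P); J <- col(P)
  mu_j <- sum(J * P); mu_i <- sum(I * P)
  c(low_dependence_emphasis = sum(P / J^2),
    high_dependence_emphasis = sum(P * J^2),
    low_grey_level_count_emphasis = sum(P / I^2),
    high_grey_level_count_emphasis = sum(P * I^2),
    dependence_count_energy = sum(P^2),
    dependence_count_variance = sum(P * (J - mu_j)^2),
    dependence_count_entropy = entropy_bits(P),
    grey_level_variance = sum(P * (I - mu_i)^2))
}
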