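# Independent brute-force oracles for the texture-matrix families.
# These deliberately use naive per-pixel loops and separate code paths from
# the package implementations; they encode the same documented conventions
# (4-direction averaged-normalized merge, Chebyshev-1 neighbourhoods,
# dependence count including the centre pixel).

o_entropy2 <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

o_glcm <- function(lv, nb, dist = 1,
                   dirs = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))) {
  nr <- nrow(lv); nc <- ncol(lv)
  acc <- matrix(0, nb, nb); used <- 0
  for (d in dirs) {
    P <- matrix(0, nb, nb)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(lv[r, c])) next
      for (sgn in c(1, -1)) {
        rr <- r + sgn * d[1] * dist; cc <- c + sgn * d[2] * dist
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !is.na(lv[rr, cc])) {
          P[lv[r, c], lv[rr, cc]] <- P[lv[r, c], lv[rr, cc]] + 1
        }
      }
    }
    if (sum(P) > 0) { acc <- acc + P / sum(P); used <- used + 1 }
  }
  stopifnot(used > 0)
  P <- acc / used
  ja <- 0; autoc <- 0; contrast <- 0; dissim <- 0; idn <- 0; idm <- 0
  cs <- 0; cp <- 0; sa <- 0
  psum <- rep(0, 2 * nb); pdiff <- rep(0, nb)
  for (i in 1:nb) for (j in 1:nb) {
    p <- P[i, j]
    ja <- ja + i * p
    autoc <- autoc + i * j * p
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    idn <- idn + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    sa <- sa + (i + j) * p
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  jv <- 0
  for (i in 1:nb) for (j in 1:nb) jv <- jv + (i - ja)^2 * P[i, j]
  for (i in 1:nb) for (j in 1:nb) {
    cs <- cs + (i + j - 2 * ja)^3 * P[i, j]
    cp <- cp + (i + j - 2 * ja)^4 * P[i, j]
  }
  pi_ <- rowSums(P)
  sd2 <- 0
  for (i in 1:nb) sd2 <- sd2 + (i - ja)^2 * pi_[i]
  corr <- if (sd2 <= 0) 1 else (autoc - ja^2) / sd2
  da <- 0
  for (k in seq_along(pdiff)) da <- da + (k - 1) * pdiff[k]
  c(joint_maximum = max(P), joint_average = ja, joint_variance = jv,
    joint_entropy = o_entropy2(P), contrast = contrast,
    dissimilarity = dissim, inverse_difference = idn,
    inverse_difference_moment = idm, correlation = corr,
    autocorrelation = autoc, cluster_shade = cs, cluster_prominence = cp,
    sum_average = sa, sum_entropy = o_entropy2(psum),
    difference_average = da, difference_entropy = o_entropy2(pdiff))
}

o_glrlm <- function(lv, nb) {
  nr <- nrow(lv); nc <- ncol(lv)
  npix <- sum(!is.na(lv))
  maxlen <- max(nr, nc)
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  pacc <- matrix(0, nb, maxlen)
  gln <- rln <- rpc <- 0
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  for (d in dirs) {
    cnt <- matrix(0, nb, maxlen)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(lv[r, c])) next
      pr <- r - d[1]; pc <- c - d[2]
      is_start <- !inb(pr, pc) || is.na(lv[pr, pc]) ||
        lv[pr, pc] != lv[r, c]
      if (!is_start) next
      len <- 1
      rr <- r + d[1]; cc <- c + d[2]
      while (inb(rr, cc) && !is.na(lv[rr, cc]) &&
             lv[rr, cc] == lv[r, c]) {
        len <- len + 1; rr <- rr + d[1]; cc <- cc + d[2]
      }
      cnt[lv[r, c], len] <- cnt[lv[r, c], len] + 1
    }
    nruns <- sum(cnt)
    pacc <- pacc + cnt / nruns
    gln <- gln + sum(rowSums(cnt)^2) / nruns
    rln <- rln + sum(colSums(cnt)^2) / nruns
    rpc <- rpc + nruns / npix
  }
  P <- pacc / length(dirs)
  sre <- lre <- lglre <- hglre <- rlv <- glv <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:nb) for (j in seq_len(maxlen)) {
    mu_i <- mu_i + i * P[i, j]; mu_j <- mu_j + j * P[i, j]
  }
  for (i in 1:nb) for (j in seq_len(maxlen)) {
    p <- P[i, j]
    sre <- sre + p / j^2; lre <- lre + p * j^2
    lglre <- lglre + p / i^2; hglre <- hglre + p * i^2
    rlv <- rlv + p * (j - mu_j)^2; glv <- glv + p * (i - mu_i)^2
  }
  c(short_run_emphasis = sre, long_run_emphasis = lre,
    low_grey_level_run_emphasis = lglre,
    high_grey_level_run_emphasis = hglre,
    grey_level_non_uniformity = gln / 4,
    run_length_non_uniformity = rln / 4,
    run_percentage = rpc / 4, run_entropy = o_entropy2(P),
    run_length_variance = rlv, grey_level_variance = glv)
}

o_glszm <- function(lv, nb) {
  nr <- nrow(lv); nc <- ncol(lv)
  npix <- sum(!is.na(lv))
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (is.na(lv[r0, c0]) || seen[r0, c0]) next
    # BFS flood fill, 8-connected, equal level
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            !seen[rr, cc] && !is.na(lv[rr, cc]) &&
            lv[rr, cc] == lv[r0, c0]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lv[r0, c0], size)
  }
  zl <- vapply(zones, `[`, 0, 1)
  zs <- vapply(zones, `[`, 0, 2)
  nz <- length(zl)
  sze <- lze <- lgl <- hgl <- zsv <- 0
  mu_z <- mean(zs)
  for (k in seq_len(nz)) {
    sze <- sze + (1 / nz) / zs[k]^2
    lze <- lze + (1 / nz) * zs[k]^2
    lgl <- lgl + (1 / nz) / zl[k]^2
    hgl <- hgl + (1 / nz) * zl[k]^2
    zsv <- zsv + (1 / nz) * (zs[k] - mu_z)^2
  }
  gln_ <- 0
  for (i in unique(zl)) gln_ <- gln_ + sum(zl == i)^2
  zsn <- 0
  for (s in unique(zs)) zsn <- zsn + sum(zs == s)^2
  cellp <- table(paste(zl, zs)) / nz
  c(small_zone_emphasis = sze, large_zone_emphasis = lze,
    low_grey_level_zone_emphasis = lgl, high_grey_level_zone_emphasis = hgl,
    grey_level_non_uniformity = gln_ / nz, zone_size_non_uniformity = zsn / nz,
    zone_percentage = nz / npix, zone_entropy = o_entropy2(as.numeric(cellp)),
    zone_size_variance = zsv)
}

o_neighbors <- function(lv, r, c) {
  out <- c()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(lv) && cc >= 1 && cc <= ncol(lv) &&
        !is.na(lv[rr, cc])) out <- c(out, lv[rr, cc])
  }
  out
}

o_ngtdm <- function(lv, nb) {
  n_i <- rep(0, nb); s_i <- rep(0, nb); N <- 0
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    if (is.na(lv[r, c])) next
    nbrs <- o_neighbors(lv, r, c)
    if (length(nbrs) == 0) next
    N <- N + 1
    i <- lv[r, c]
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nbrs))
  }
  stopifnot(N > 0)
  p_i <- n_i / N
  pres <- which(p_i > 0)
  den <- sum(p_i * s_i)
  coarseness <- if (den > 0) min(1 / den, 1e6) else 1e6
  ngp <- length(pres)
  contrast <- busyness <- complexity <- strength <- 0
  if (ngp > 1) {
    csum <- 0; bden <- 0; ssum <- sum(s_i)
    for (i in pres) for (j in pres) {
      csum <- csum + p_i[i] * p_i[j] * (i - j)^2
      bden <- bden + abs(i * p_i[i] - j * p_i[j])
      complexity <- complexity +
        abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
        (p_i[i] + p_i[j])
      strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
    }
    contrast <- csum / (ngp * (ngp - 1)) * ssum / N
    busyness <- if (bden > 0) den / bden else 0
    complexity <- complexity / N
    strength <- if (ssum > 0) strength / ssum else 0
  }
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

o_ngldm <- function(lv, nb, alpha = 0) {
  maxj <- 9
  s <- matrix(0, nb, maxj)
  N <- 0
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    if (is.na(lv[r, c])) next
    N <- N + 1
    nbrs <- o_neighbors(lv, r, c)
    j <- 1 + sum(abs(nbrs - lv[r, c]) <= alpha)
    s[lv[r, c], j] <- s[lv[r, c], j] + 1
  }
  P <- s / N
  mu_j <- 0; mu_i <- 0
  for (i in 1:nb) for (j in 1:maxj) {
    mu_j <- mu_j + j * P[i, j]; mu_i <- mu_i + i * P[i, j]
  }
  lde <- hde <- lgl <- hgl <- dce <- dcv <- glv <- 0
  for (i in 1:nb) for (j in 1:maxj) {
    p <- P[i, j]
    lde <- lde + p / j^2; hde <- hde + p * j^2
    lgl <- lgl + p / i^2; hgl <- hgl + p * i^2
    dce <- dce + p^2
    dcv <- dcv + p * (j - mu_j)^2
    glv <- glv + p * (i - mu_i)^2
  }
  c(low_dependence_emphasis = lde, high_dependence_emphasis = hde,
    low_grey_level_count_emphasis = lgl,
    high_grey_level_count_emphasis = hgl, dependence_count_energy = dce,
    dependence_count_variance = dcv,
    dependence_count_entropy = o_entropy2(P), grey_level_variance = glv)
}

# random small discretized ROI for oracle-equivalence sweeps
random_disc <- function(nr, nc, nlev, roi_prob = 0.85) {
  repeat {
    lv <- matrix(sample.int(nlev, nr * nc, replace = TRUE), nr, nc)
    lv[matrix(stats::runif(nr * nc) > roi_prob, nr, nc)] <- NA_integer_
    fg <- !is.na(lv)
    if (sum(fg) < 2) next
    # need at least one in-ROI adjacent pair for GLCM/NGTDM
    ok <- FALSE
    for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      r0 <- max(1, 1 - o[1]):(nr - max(0, o[1]))
      c0 <- max(1, 1 - o[2]):(nc - max(0, o[2]))
      a <- fg[r0, c0, drop = FALSE]
      b <- fg[r0 + o[1], c0 + o[2], drop = FALSE]
      if (any(a & b)) { ok <- TRUE; break }
    }
    if (ok) break
  }
  lv
}

as_disc <- function(lv, nb = max(lv, na.rm = TRUE)) {
  structure(list(levels = lv, n_bins = nb,
                 roi_min = min(lv, na.rm = TRUE),
                 roi_max = max(lv, na.rm = TRUE)),
            class = "disc_roi")
}

expect_feature_match <- function(impl, oracle, tol = 1e-9, label = "") {
  expect_identical(sort(names(impl)), sort(names(oracle)))
  for (nm in names(oracle)) {
    denom <- max(abs(oracle[[nm]]), 1e-12)
    expect_lt(abs(impl[[nm]] - oracle[[nm]]) / denom, tol,
              label = paste0(label, nm, " impl=", impl[[nm]],
                             " oracle=", oracle[[nm]]))
  }
}
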