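#' ADASYN configuration
#'
#' @param beta target balance fraction in (0, 1]; the number of synthetic
#'   minority samples targeted is `G = (m_majority - m_minority) * beta`.
#' @param k_neighbors neighbourhood size for the density ratio and for
#'   interpolation partners (default 5).
#' @param seed integer seed for the synthetic draws.
#' @return An `adasyn_config` list.
#' @export
adasyn_config <- function(beta = 1, k_neighbors = 5L, seed = 1L) {
  stopifnot(beta > 0, beta <= 1, k_neighbors >= 1)
  structure(list(beta = beta, k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)), class = "adasyn_config")
}

# internal: indices of the k nearest rows of `ref` to each row of `q`
# (Euclidean), excluding exact self-matches by index when self = TRUE
knn_index <- function(q, ref, k, self = FALSE) {
  d2 <- outer(rowSums(q^2), rep(1, nrow(ref))) +
        outer(rep(1, nrow(q)), rowSums(ref^2)) - 2 * q %*% t(ref)
  ord <- t(apply(d2, 1, order))
  if (self) ord <- t(vapply(seq_len(nrow(q)),
                            function(i) ord[i, ord[i, ] != i],
                            numeric(ncol(ord) - 1L)))
  ord[, seq_len(k), drop = FALSE]
}

#' Adaptive synthetic (ADASYN) oversampling of the minority class
#'
#' Implements the adaptive synthetic sampling scheme: with minority size
#' `m_s` and majority size `m_l`, the synthetic target is
#' `G = (m_l - m_s) * beta`. Each minority point `x_i` receives weight
#' `r_i = Delta_i / k` (the fraction of its `k` nearest neighbours among all
#' samples that belong to the majority class); weights are normalized to
#' `rhat_i` and `g_i = round(rhat_i * G)` synthetic points are generated
#' from `x_i` as `x_i + lambda * (x_z - x_i)` with `lambda ~ U(0, 1)` and
#' `x_z` one of the `k` nearest minority neighbours of `x_i`. When no
#' minority point has majority neighbours the weights fall back to uniform.
#' Original samples are returned unchanged; the majority class is untouched.
#' Deterministic given the seed.
#'
#' @param X numeric feature matrix.
#' @param y class labels (two classes).
#' @param cfg an [adasyn_config].
#' @param minority_class label of the minority class; defaults to the rarer
#'   label.
#' @return list: `X` (original rows then synthetic rows), `y`, `synthetic`
#'   (logical row flag), `g` (per-minority-point synthetic counts).
#' @export
adasyn_oversample <- function(X, y, cfg = adasyn_config(),
                              minority_class = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  tab <- table(y)
  if (length(tab) != 2) stop("ADASYN requires exactly two classes")
  if (is.null(minority_class)) minority_class <- names(tab)[which.min(tab)]
  m_s <- sum(y == minority_class)
  m_l <- sum(y != minority_class)
  if (m_s >= m_l) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X)),
                g = integer(0)))
  }
  k <- cfg$k_neighbors
  if (m_s < k + 1) {
    warning("minority class smaller than k + 1; reducing k to ", m_s - 1)
    k <- m_s - 1L
    if (k < 1) stop("minority class too small for ADASYN")
  }
  G <- (m_l - m_s) * cfg$beta
  min_idx <- which(y == minority_class)
  Xmin <- X[min_idx, , drop = FALSE]
  # density ratio: k nearest neighbours among ALL samples
  nn_all <- knn_index(Xmin, X, k + 1L)  # self is nearest; drop it
  r <- vapply(seq_len(m_s), function(i) {
    nb <- setdiff(nn_all[i, ], min_idx[i])[seq_len(k)]
    mean(y[nb] != minority_class)
  }, numeric(1))
  rhat <- if (sum(r) > 0) r / sum(r) else rep(1 / m_s, m_s)
  g <- as.integer(round(rhat * G))
  nn_min <- knn_index(Xmin, Xmin, min(k, m_s - 1L), self = TRUE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  synth <- vector("list", m_s)
  for (i in seq_len(m_s)) {
    if (g[i] == 0L) next
    z <- nn_min[i, sample.int(ncol(nn_min), g[i], replace = TRUE)]
    lam <- stats::runif(g[i])
    synth[[i]] <- Xmin[rep(i, g[i]), , drop = FALSE] +
      lam * (Xmin[z, , drop = FALSE] - Xmin[rep(i, g[i]), , drop = FALSE])
  }
  S <- do.call(rbind, synth)
  n_new <- if (is.null(S)) 0L else nrow(S)
  list(X = rbind(X, S),
       y = c(y, rep(minority_class, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)),
       g = g)
}
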