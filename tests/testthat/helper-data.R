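# Two Gaussian blobs in 2D: a quick stand-in for a selected feature matrix
two_blob_data <- function(n_maj = 102, n_min = 40, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_maj * 2), ncol = 2),
             matrix(stats::rnorm(n_min * 2, mean = sep), ncol = 2))
  colnames(X) <- c("f1", "f2")
  y <- c(rep("benign", n_maj), rep("malignant", n_min))
  list(X = X, y = y)
}
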