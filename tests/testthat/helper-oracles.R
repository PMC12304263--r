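# Independent oracles and tiny fixture builders shared across the suite.
# Each oracle is a deliberately naive implementation (dense solves,
# O(n^2) scans) kept separate from the production code paths it checks.

# Dense direct-solve implementation of the asymmetric-least-squares
# iteration, built on base solve() over explicit matrices.
asls_dense_oracle <- function(y, lambda = 1000, p = 0.05, max_iter = 10L) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- as.numeric(solve(diag(w) + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) break
    w <- w_new
  }
  list(baseline = z, corrected = y - z)
}

# O(n^2) gift-wrapping lower convex hull: from each hull vertex walk to
# the point of minimal slope (farthest on ties, skipping collinear
# interior points).
lower_hull_oracle <- function(x, y) {
  n <- length(x)
  hull <- 1L
  i <- 1L
  while (i < n) {
    slopes <- (y[(i + 1):n] - y[i]) / (x[(i + 1):n] - x[i])
    cand <- which(slopes <= min(slopes) + 0) # exact min
    j <- i + max(cand)
    hull <- c(hull, j)
    i <- j
  }
  hull
}

# Pairwise Mann-Whitney AUC: average over all positive-negative pairs of
# 1[pos > neg] + 0.5 * 1[pos == neg].
auc_pairwise_oracle <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# A 3-sample x 5-wavenumber toy dataset used by the I/O tests.
toy_dataset <- function() {
  spectral_dataset(
    grid = c(1000, 1010, 1020, 1030, 1040),
    intensities = matrix(c(1, 2, 3, 2, 1,
                           0.5, 1.5, 2.5, 1.5, 0.5,
                           2, 2, 2, 2, 2), nrow = 3, byrow = TRUE),
    samples = data.frame(
      patient_id = c("P1", "P2", "P3"),
      group = c("cancer", "healthy", "pcos"),
      modality = "ftir", hydration = "wet", replicate = 1L))
}

# Two well-separated 2-D Gaussian blobs (10 + 10 points) for classifier
# smoke tests.
separable_blobs <- function(seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(20, -3, 0.3), 10),
             matrix(rnorm(20, 3, 0.3), 10))
  list(X = X, y = rep(c("control", "cancer"), each = 10))
}
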