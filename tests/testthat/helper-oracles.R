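# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# flood-fill component labeling (8-connectivity), pure R
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# lattice disk mask: pixels within euclidean distance r of (ci, cj)
oracle_disk_mask <- function(H, W, ci, cj, r) {
  d2 <- outer((seq_len(H) - ci)^2, (seq_len(W) - cj)^2, "+")
  (d2 <= r^2) * 1
}

# brute-force InfoNCE: normalised rows, scaled cosine logits, softmax CE
oracle_patchnce <- function(q, k, tau) {
  qn <- q / sqrt(rowSums(q^2)); kn <- k / sqrt(rowSums(k^2))
  n <- nrow(q)
  losses <- vapply(seq_len(n), function(i) {
    s <- as.numeric(qn[i, ] %*% t(kn)) / tau
    -log(exp(s[i]) / sum(exp(s)))
  }, numeric(1))
  mean(losses)
}

# brute-force unbiased MMD^2 with the degree-3 polynomial kernel
oracle_mmd2 <- function(x, y) {
  d <- ncol(x)
  kf <- function(a, b) (sum(a * b) / d + 1)^3
  m <- nrow(x); n <- nrow(y)
  sxx <- 0; for (i in 1:m) for (j in 1:m) if (i != j) sxx <- sxx + kf(x[i, ], x[j, ])
  syy <- 0; for (i in 1:n) for (j in 1:n) if (i != j) syy <- syy + kf(y[i, ], y[j, ])
  sxy <- 0; for (i in 1:m) for (j in 1:n) sxy <- sxy + kf(x[i, ], y[j, ])
  sxx / (m * (m - 1)) + syy / (n * (n - 1)) - 2 * sxy / (m * n)
}

# kappa from a 2x2 contingency table (a, b / c, d), counting raters directly
oracle_kappa_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  (po - pe) / (1 - pe)
}

# intersection-over-union of two binary masks
iou <- function(a, b) {
  u <- sum((a + b) > 0)
  if (u == 0) return(1)
  sum(a * b > 0) / u
}

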