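#' Distribution-level metrics for generated images
#'
#' The Frechet distance compares Gaussian fits (mean + covariance) of two
#' embedding sets; the kernel distance is an unbiased MMD^2 estimate with
#' the polynomial kernel `(x . y / d + 1)^3`. Both operate on any embedding
#' matrix, with the feature extractor injected: the bundled lightweight
#' extractor is a fixed-seed random convolutional projection that needs no
#' pretrained weights, adequate for relative comparisons on synthetic data;
#' values comparable to published Inception-based scores require the
#' standard pretrained Inception extractor, which this package does not
#' ship.
#'
#' @name genmetrics
NULL

#' Frechet distance between two embedding sets
#'
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^(1/2))`, with unbiased
#' covariance estimates and the matrix square root computed by symmetric
#' eigendecomposition with negative eigenvalues clipped to 0.
#'
#' @param features_a,features_b n x d matrices (n >= 2 each, equal d).
#' @return scalar >= 0 (up to numerical error).
#' @export
fid <- function(features_a, features_b) {
  if (ncol(features_a) != ncol(features_b)) stop("feature dimension mismatch")
  if (nrow(features_a) < 2 || nrow(features_b) < 2)
    stop("need at least 2 samples per set")
  mua <- colMeans(features_a); mub <- colMeans(features_b)
  sa <- stats::cov(features_a); sb <- stats::cov(features_b)
  # tr((Sa Sb)^{1/2}) via the symmetric product Sa^{1/2} Sb Sa^{1/2}
  ea <- eigen(sa, symmetric = TRUE)
  ra <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  m <- ra %*% sb %*% ra
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  sum((mua - mub)^2) + sum(diag(sa)) + sum(diag(sb)) - 2 * tr_sqrt
}

poly_kernel <- function(x, y) (tcrossprod(x, y) / ncol(x) + 1)^3

#' Kernel distance (unbiased MMD^2) between two embedding sets
#'
#' Unbiased block estimator with the degree-3 polynomial kernel
#' `(x . y / d + 1)^3`. With `blocks = 1` the full double sum is used.
#'
#' @param features_a,features_b n x d matrices of embeddings.
#' @param blocks number of equal blocks to average over (default 1).
#' @return scalar MMD^2 estimate (can be slightly negative by design).
#' @export
kid <- function(features_a, features_b, blocks = 1L) {
  if (ncol(features_a) != ncol(features_b)) stop("feature dimension mismatch")
  na <- nrow(features_a); nb <- nrow(features_b)
  bs_a <- na %/% blocks; bs_b <- nb %/% blocks
  if (bs_a < 2 || bs_b < 2) stop("block size must be at least 2")
  mmd2 <- function(x, y) {
    m <- nrow(x); n <- nrow(y)
    kxx <- poly_kernel(x, x); kyy <- poly_kernel(y, y); kxy <- poly_kernel(x, y)
    (sum(kxx) - sum(diag(kxx))) / (m * (m - 1)) +
      (sum(kyy) - sum(diag(kyy))) / (n * (n - 1)) -
      2 * mean(kxy)
  }
  est <- vapply(seq_len(blocks), function(b) {
    ia <- (b - 1) * bs_a + seq_len(bs_a)
    ib <- (b - 1) * bs_b + seq_len(bs_b)
    mmd2(features_a[ia, , drop = FALSE], features_b[ib, , drop = FALSE])
  }, numeric(1))
  mean(est)
}

#' Embed images for FID / KID
#'
#' The `lightweight-test` extractor applies a fixed-seed random 2-layer
#' convolutional projection (ReLU between layers) followed by global mean
#' and standard-deviation pooling; it is deterministic for a given seed and
#' requires no downloads. A `pahisto_resnet` or any `function(image) ->
#' vector` can be injected instead.
#'
#' @param images list of tiles / arrays on the 0-255 scale (one modality).
#' @param extractor `"lightweight-test"`, a `pahisto_resnet`, or a function.
#' @param seed seed for the random projection (default 7).
#' @param dim number of random channels (embedding is `2 * dim`).
#' @return n x d matrix of class `feature_set` with attribute `extractor`.
#' @export
extract_embeddings <- function(images, extractor = "lightweight-test",
                               seed = 7L, dim = 32L) {
  if (length(images) < 2) stop("need at least 2 images")
  fn <- if (is.function(extractor)) {
    extractor
  } else if (inherits(extractor, "pahisto_resnet")) {
    function(px) as.numeric(resnet_embed(extractor,
      ag_const(as_chan(px, attr(extractor, "cin"))))$v)
  } else if (identical(extractor, "lightweight-test")) {
    c1 <- with_seed(seed, array(stats::rnorm(3 * 3 * 3 * dim, 0, 0.3),
                                c(3, 3, 3, dim)))
    c2 <- with_seed(seed + 1L, array(stats::rnorm(3 * 3 * dim * dim, 0, 0.3),
                                     c(3, 3, dim, dim)))
    b0 <- numeric(dim)
    function(px) {
      if (n_channels(px) == 1L) px <- stack_to_3ch(px)
      x <- px / 127.5 - 1
      h <- cpp_conv2d(x, c1, b0, 2L, 1L)
      h <- pmax(h, 0)
      h <- cpp_conv2d(h, c2, b0, 2L, 1L)
      c(apply(h, 3, mean), apply(h, 3, stats::sd))
    }
  } else stop("unknown extractor")
  emb <- t(vapply(images, function(im) fn(tile_pixels(im)),
                  numeric(length(fn(tile_pixels(images[[1]]))))))
  structure(emb, extractor = if (is.character(extractor)) extractor else "custom",
            class = c("feature_set", class(emb)))
}

#' FID/KID report for two image directories or lists
#'
#' @param real,fake lists of tiles or directories of PNG files.
#' @param extractor passed to [extract_embeddings()].
#' @param kid_blocks block count for [kid()].
#' @return list: fid, kid, n_real, n_fake, extractor.
#' @export
generation_metrics <- function(real, fake, extractor = "lightweight-test",
                               kid_blocks = 1L) {
  load_dir <- function(x) {
    if (is.character(x) && length(x) == 1 && dir.exists(x)) {
      fs <- sort(list.files(x, "\\.(png|tiff?)$", full.names = TRUE,
                            ignore.case = TRUE))
      lapply(fs, function(f) read_tile_png(f, "HE"))
    } else x
  }
  real <- load_dir(real); fake <- load_dir(fake)
  fa <- extract_embeddings(real, extractor)
  fb <- extract_embeddings(fake, extractor)
  list(fid = fid(unclass(fa), unclass(fb)),
       kid = kid(unclass(fa), unclass(fb), blocks = kid_blocks),
       n_real = nrow(fa), n_fake = nrow(fb),
       extractor = attr(fa, "extractor"))
}
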