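#' Nucleus segmentation with a U-Net
#'
#' A 4-down / 4-up U-Net with skip connections maps an input tile to a
#' per-pixel nucleus probability. Training minimises binary cross-entropy
#' plus Dice loss; inference optionally averages probabilities over the four
#' flip orientations (test-time augmentation) before thresholding.
#'
#' @name segmentation
NULL

#' Binary cross-entropy + Dice loss
#'
#' `BCE(p, t) + (1 - Dice(p, t))`, equally weighted, with the Dice
#' coefficient smoothed by `eps`:
#' `Dice = (2 * sum(p t) + eps) / (sum(p) + sum(t) + eps)`.
#'
#' @param pred_probs predicted probabilities in [0, 1].
#' @param target_mask binary mask of the same shape.
#' @param eps Dice smoothing constant (default 1).
#' @return scalar loss.
#' @export
bce_dice_loss <- function(pred_probs, target_mask, eps = 1) {
  if (!identical(dim(pred_probs), dim(target_mask)) &&
      !identical(length(pred_probs), length(target_mask)))
    stop("prediction and mask differ in shape")
  p <- pmin(pmax(pred_probs, 1e-12), 1 - 1e-12)
  t <- target_mask
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dice <- (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  bce + (1 - dice)
}

# graph version from logits (numerically stable BCE + smoothed Dice)
ag_bce_dice <- function(logits, target, eps = 1) {
  z <- logits$v
  t <- array(as.vector(target), dim = dim(z))
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  bce_v <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  sp <- sum(p); st <- sum(t); spt <- sum(p * t)
  den <- sp + st + eps
  dice_v <- (2 * spt + eps) / den
  new_node(bce_v + (1 - dice_v), list(logits), function(nd) {
    g <- as.numeric(nd$g)
    dbce_dz <- (p - t) / n
    ddice_dp <- (2 * t * den - (2 * spt + eps)) / den^2
    dz <- dbce_dz - ddice_dp * p * (1 - p)
    acc_grad(logits, keep_dim(g * dz, z))
  })
}

#' Dice score between two binary masks
#'
#' @param a,b binary masks.
#' @return `2|A and B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_score <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' U-Net training configuration
#'
#' Full-scale defaults: Adam beta1 = 0.9, beta2 = 0.999, learning rate 1e-4,
#' mini-batch 64, up to 300 epochs with early stopping on validation loss,
#' horizontal and vertical flip augmentation. `nf` scales channel widths for
#' the CPU test profile.
#'
#' @param lr learning rate.
#' @param beta1,beta2 Adam moments.
#' @param batch mini-batch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience in epochs (0 disables early stop).
#' @param val_frac fraction of the data held out for validation (0 disables).
#' @param nf base channel width.
#' @param flip_augment apply random horizontal/vertical flips.
#' @param seed RNG seed.
#' @return list of class `unet_train_config`.
#' @export
unet_train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                              batch = 64L, epochs = 300L, patience = 20L,
                              val_frac = 0.2, nf = 16L, flip_augment = TRUE,
                              seed = 1L) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 patience = as.integer(patience), val_frac = val_frac,
                 nf = as.integer(nf), flip_augment = flip_augment,
                 seed = as.integer(seed)),
            class = "unet_train_config")
}

unet_prep_input <- function(px) {
  if (n_channels(px) == 1L) px <- stack_to_3ch(px)
  tile_pixels(px) / 127.5 - 1
}

#' Train the segmentation U-Net
#'
#' @param dataset list of `list(image, mask)` pairs; images are 1- or
#'   3-channel 8-bit tiles (1-channel input is stacked to 3), masks are
#'   binary matrices of the same height/width.
#' @param cfg a [unet_train_config()].
#' @return object of class `unet_model` with the best-validation weights
#'   (last-epoch weights when no validation split), `history` (per-epoch
#'   train/validation loss) and the config.
#' @export
train_unet <- function(dataset, cfg = unet_train_config()) {
  if (length(dataset) == 0) stop("empty training set")
  set.seed(cfg$seed)
  xs <- lapply(dataset, function(d) unet_prep_input(tile_pixels(d$image)))
  ms <- lapply(dataset, function(d) {
    m <- tile_pixels(d$mask)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  n <- length(xs)
  n_val <- if (cfg$val_frac > 0 && n >= 5) max(1L, round(cfg$val_frac * n)) else 0L
  idx <- sample.int(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  net <- make_unet(cfg$nf, cin = 3L)
  ps <- params_of(net)
  opt <- adam_new(ps)
  flip <- function(a, h, v) {
    if (h) a <- if (length(dim(a)) == 3) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
           else a[, rev(seq_len(ncol(a)))]
    if (v) a <- if (length(dim(a)) == 3) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
           else a[rev(seq_len(nrow(a))), ]
    a
  }
  val_loss <- function() {
    mean(vapply(val_idx, function(i) {
      z <- unet_forward(net, ag_const(xs[[i]]))
      p <- 1 / (1 + exp(-z$v[, , 1]))
      bce_dice_loss(p, ms[[i]])
    }, numeric(1)))
  }
  best <- list(loss = Inf, state = NULL, epoch = 0L)
  history <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  wait <- 0L
  for (e in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    tot <- 0
    bsz <- min(cfg$batch, length(ord))
    nb <- 0L
    for (start in seq(1, length(ord), by = bsz)) {
      bidx <- ord[start:min(start + bsz - 1, length(ord))]
      ag_begin()
      bl <- NULL
      for (i in bidx) {
        h <- cfg$flip_augment && stats::runif(1) < 0.5
        v <- cfg$flip_augment && stats::runif(1) < 0.5
        z <- unet_forward(net, ag_const(flip(xs[[i]], h, v)))
        li <- ag_bce_dice(z, flip(ms[[i]], h, v))
        bl <- if (is.null(bl)) li else ag_add(bl, li)
      }
      bl <- ag_affine(bl, 1 / length(bidx))
      if (!is.finite(bl$v)) stop("non-finite segmentation loss at epoch ", e)
      backward(bl)
      ag_end()
      adam_step(ps, opt, cfg$lr, cfg$beta1, cfg$beta2)
      tot <- tot + bl$v; nb <- nb + 1L
    }
    vl <- if (n_val > 0) val_loss() else NA_real_
    history <- rbind(history, data.frame(epoch = e, train = tot / nb, val = vl))
    if (n_val > 0 && cfg$patience > 0) {
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, state = net_state(net), epoch = e)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (!is.null(best$state)) net_load_state(net, best$state)
  structure(list(net = net, cfg = cfg, history = history,
                 best_epoch = if (is.null(best$state)) nrow(history) else best$epoch,
                 version = 1L),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model: nf=%d, trained %d epochs (best at %d)\n",
              x$cfg$nf, nrow(x$history), x$best_epoch))
  invisible(x)
}

unet_probs <- function(model, px) {
  z <- unet_forward(model$net, ag_const(unet_prep_input(px)))
  1 / (1 + exp(-z$v[, , 1]))
}

#' Predict a binary nucleus mask
#'
#' With `tta = TRUE` the probability maps of the identity, horizontal flip,
#' vertical flip and double flip (each mapped back to the original frame) are
#' averaged before thresholding, making the prediction invariant to input
#' flips.
#'
#' @param model a trained `unet_model`.
#' @param tile 1- or 3-channel 8-bit tile / array.
#' @param tta use test-time flip augmentation (default TRUE).
#' @param threshold probability cut for binarisation (default 0.5).
#' @return binary H x W matrix.
#' @export
predict_mask <- function(model, tile, tta = TRUE, threshold = 0.5) {
  px <- tile_pixels(tile)
  if (!tta) return((unet_probs(model, px) > threshold) * 1)
  hf <- function(a) if (length(dim(a)) == 3) a[, rev(seq_len(dim(a)[2])), , drop = FALSE] else a[, rev(seq_len(ncol(a)))]
  vf <- function(a) if (length(dim(a)) == 3) a[rev(seq_len(dim(a)[1])), , , drop = FALSE] else a[rev(seq_len(nrow(a))), ]
  p <- unet_probs(model, px)
  ph <- unet_probs(model, hf(px)); ph <- ph[, rev(seq_len(ncol(ph)))]
  pv <- unet_probs(model, vf(px)); pv <- pv[rev(seq_len(nrow(pv))), ]
  phv <- unet_probs(model, vf(hf(px)))
  phv <- phv[rev(seq_len(nrow(phv))), rev(seq_len(ncol(phv)))]
  ((p + ph + pv + phv) / 4 > threshold) * 1
}

#' @export
predict.unet_model <- function(object, newdata, tta = TRUE, threshold = 0.5, ...)
  predict_mask(object, newdata, tta = tta, threshold = threshold)

#' Save / load a U-Net checkpoint
#' @param model a `unet_model`.
#' @param path checkpoint file path.
#' @return `unet_load`: the restored model.
#' @export
unet_save <- function(model, path) {
  saveRDS(list(version = 1L, cfg = model$cfg, history = model$history,
               best_epoch = model$best_epoch, net = net_state(model$net)), path)
  invisible(path)
}

#' @rdname unet_save
#' @export
unet_load <- function(path) {
  s <- readRDS(path)
  if (is.null(s$version) || s$version != 1L) stop("unknown checkpoint version")
  net <- make_unet(s$cfg$nf, cin = 3L)
  net_load_state(net, s$net)
  structure(list(net = net, cfg = s$cfg, history = s$history,
                 best_epoch = s$best_epoch, version = 1L),
            class = "unet_model")
}
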