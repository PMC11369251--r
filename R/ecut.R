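#' E-CUT: saliency-constrained contrastive unpaired translation
#'
#' Virtual staining is learned from *unpaired* source (inverted grayscale
#' PAH) and target (H&E-style RGB) tiles by a single generator/discriminator
#' pair. The objective combines three terms:
#'
#'   total = l_adv + (l_NCE(X) + l_NCE(Y)) / 2 + l_saliency
#'
#' where `l_adv` is a least-squares GAN loss on a 70x70 patch discriminator,
#' the PatchNCE terms are InfoNCE losses over matched encoder-feature patches
#' of input and output (the Y term is computed on the identity pass G(y) and
#' discourages unnecessary changes), and `l_saliency` is the L1 distance
#' between the soft-threshold saliency masks of the input and the generated
#' output. All three weights default to 1 (an equal combination).
#'
#' @name ecut
NULL

#' E-CUT loss configuration
#'
#' @param w_adv,w_nce,w_saliency non-negative term weights (default 1 each).
#' @param temperature InfoNCE temperature (default 0.07).
#' @param n_patches feature locations sampled per encoder depth.
#' @param proj_dim dimension of the 2-layer projection head.
#' @param x_threshold,y_threshold,slope saliency parameters, see
#'   [saliency_mask()].
#' @return list of class `ecut_loss_config`.
#' @export
ecut_loss_config <- function(w_adv = 1, w_nce = 1, w_saliency = 1,
                             temperature = 0.07, n_patches = 256L,
                             proj_dim = 256L,
                             x_threshold = 90, y_threshold = 170, slope = 100) {
  stopifnot(w_adv >= 0, w_nce >= 0, w_saliency >= 0, temperature > 0)
  structure(list(w_adv = w_adv, w_nce = w_nce, w_saliency = w_saliency,
                 temperature = temperature, n_patches = as.integer(n_patches),
                 proj_dim = as.integer(proj_dim), x_threshold = x_threshold,
                 y_threshold = y_threshold, slope = slope),
            class = "ecut_loss_config")
}

#' E-CUT training configuration
#'
#' Defaults follow the full-scale recipe: Adam with beta1 = 0.5,
#' beta2 = 0.999, 400 epochs at learning rate 2e-4 held constant for the
#' first half and decayed linearly to exactly zero at the final epoch,
#' batch size 1, horizontal-flip augmentation applied independently per
#' domain. Reduced `epochs`/`ngf`/`ndf` give the CPU test profile.
#'
#' @param epochs total training epochs.
#' @param lr initial learning rate.
#' @param beta1,beta2 Adam moment coefficients.
#' @param flip_augment sample a horizontal flip per tile per step.
#' @param ngf,ndf generator / discriminator base widths.
#' @param n_res number of residual blocks (9 in the full-scale model).
#' @param seed integer RNG seed; fixes init, sampling and augmentation.
#' @return list of class `ecut_train_config`.
#' @export
ecut_train_config <- function(epochs = 400L, lr = 2e-4, beta1 = 0.5,
                              beta2 = 0.999, flip_augment = TRUE,
                              ngf = 64L, ndf = 64L, n_res = 9L, seed = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, flip_augment = flip_augment,
                 ngf = as.integer(ngf), ndf = as.integer(ndf),
                 n_res = as.integer(n_res), seed = as.integer(seed)),
            class = "ecut_train_config")
}

#' Learning-rate schedule: constant, then linear decay to zero
#'
#' @param epoch 1-based epoch index.
#' @param total total epochs.
#' @param lr0 initial rate.
#' @return the rate for `epoch`; exactly 0 at `epoch == total`.
#' @export
lr_schedule <- function(epoch, total, lr0) {
  half <- ceiling(total / 2)
  if (epoch <= half || total == half) return(lr0)
  lr0 * (total - epoch) / (total - half)
}

#' Least-squares adversarial loss
#'
#' Discriminator side: `mean((real - 1)^2 + fake^2) / 2`; generator side:
#' `mean((fake - 1)^2)`. Operates on patch score maps of any shape.
#'
#' @param real_scores,fake_scores numeric arrays of discriminator patch
#'   scores (`real_scores` ignored on the generator side).
#' @param side `"generator"` or `"discriminator"`.
#' @return scalar loss.
#' @export
adversarial_loss <- function(real_scores = NULL, fake_scores,
                             side = c("discriminator", "generator")) {
  side <- match.arg(side)
  if (side == "generator") return(mean((fake_scores - 1)^2))
  (mean((real_scores - 1)^2) + mean(fake_scores^2)) / 2
}

#' PatchNCE (InfoNCE) loss over matched feature locations
#'
#' Row i of `query_feats` and row i of `positive_feats` come from the same
#' spatial location of the output and input feature maps; the other N - 1
#' rows of `positive_feats` act as negatives. Rows are L2-normalised, so the
#' logits are cosine similarities scaled by 1 / temperature, and the loss is
#' the mean softmax cross-entropy with the matched row as the correct class.
#'
#' @param query_feats,positive_feats N x d matrices.
#' @param temperature softmax temperature (default 0.07).
#' @return scalar loss; equals `log(N)` when all similarities are equal.
#' @export
patchnce_loss <- function(query_feats, positive_feats, temperature = 0.07) {
  if (!identical(dim(query_feats), dim(positive_feats)))
    stop("query and key feature matrices differ in shape")
  q <- query_feats / pmax(sqrt(rowSums(query_feats^2)), 1e-12)
  k <- positive_feats / pmax(sqrt(rowSums(positive_feats^2)), 1e-12)
  logits <- (q %*% t(k)) / temperature
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - diag(logits))
}

# ---- internal: loss graph builders -----------------------------------------

to_net <- function(px8) ag_const(px8 / 127.5 - 1)  # 8-bit -> [-1, 1]
from_net <- function(v) pmin(pmax(round((v + 1) * 127.5), 0), 255)

# InfoNCE over ag feature maps at the depths returned by gen_encode().
# Same random locations for query and key per depth (matched patches).
nce_graph <- function(feats_q, feats_k, heads, cfg) {
  total <- NULL
  for (l in seq_along(feats_q)) {
    term <- local({
      d <- dim(feats_q[[l]]$v)
      npat <- min(cfg$n_patches, d[1] * d[2])
      idx <- sample.int(d[1] * d[2], npat)
      q <- nce_project(heads[[l]], ag_gather_rows(feats_q[[l]], idx))
      k <- nce_project(heads[[l]], ag_gather_rows(feats_k[[l]], idx))
      kt <- new_node(t(k$v), list(k), function(nd) acc_grad(k, t(nd$g)))
      logits <- ag_affine(ag_matmul(q, kt), 1 / cfg$temperature)
      ag_cross_entropy_rows(logits, seq_len(npat))
    })
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  ag_affine(total, 1 / length(feats_q))
}

#' Full E-CUT objective on one unpaired tile pair
#'
#' Builds the generator-side loss graph for a source tile `x` and target tile
#' `y` and returns the total and the per-term breakdown; the reported total
#' always equals the weighted sum of the reported terms.
#'
#' @param x 3-channel source tile (8-bit array or [image_tile()]), already
#'   inverted and channel-stacked.
#' @param y 3-channel target tile.
#' @param generator,discriminator,heads networks as built by [train_ecut()].
#' @param cfg an [ecut_loss_config()].
#' @return list with `total` (ag node), `terms` (named numeric values of
#'   adv, nce_x, nce_y, saliency), and `fake` (ag node of G(x)).
#' @keywords internal
ecut_loss_graph <- function(x, y, generator, discriminator, heads, cfg) {
  xn <- to_net(tile_pixels(x)); yn <- to_net(tile_pixels(y))
  encx <- gen_encode(generator, xn)
  fake <- gen_decode(generator, encx$h, encx$mid)
  adv <- ag_sqmean(disc_forward(discriminator, fake), 1)
  encf <- gen_encode(generator, fake)
  nce_x <- nce_graph(encf$feats, encx$feats, heads, cfg)
  ency <- gen_encode(generator, yn)
  idt <- gen_decode(generator, ency$h, ency$mid)
  enci <- gen_encode(generator, idt)
  nce_y <- nce_graph(enci$feats, ency$feats, heads, cfg)
  # saliency: source mask on the raw x, output mask on gray(G(x)) in 8-bit units
  mx <- saliency_mask(rgb_to_gray(tile_pixels(x)), cfg$x_threshold, cfg$slope)
  fake8 <- ag_affine(ag_chanmean(fake), 127.5, 127.5)
  my <- ag_saliency(fake8, cfg$y_threshold, cfg$slope)
  sal <- ag_l1(my, array(unclass(mx), dim = dim(my$v)))
  total <- ag_affine(adv, cfg$w_adv)
  total <- ag_add(total, ag_affine(ag_add(nce_x, nce_y), cfg$w_nce / 2))
  total <- ag_add(total, ag_affine(sal, cfg$w_saliency))
  list(total = total, fake = fake,
       terms = c(adv = adv$v, nce_x = nce_x$v, nce_y = nce_y$v,
                 saliency = sal$v))
}

#' Combine E-CUT loss terms
#'
#' The bookkeeping identity used throughout training:
#' `w_adv * adv + w_nce * (nce_x + nce_y) / 2 + w_saliency * saliency`.
#' With `w_saliency = 0` this is exactly the plain CUT objective.
#'
#' @param adv,nce_x,nce_y,saliency numeric term values.
#' @param cfg an [ecut_loss_config()].
#' @return scalar total.
#' @export
ecut_total_loss <- function(adv, nce_x, nce_y, saliency,
                            cfg = ecut_loss_config()) {
  cfg$w_adv * adv + cfg$w_nce * (nce_x + nce_y) / 2 + cfg$w_saliency * saliency
}

#' Train an E-CUT virtual-staining model
#'
#' Alternates generator updates (adversarial + PatchNCE + saliency terms)
#' and discriminator updates (least-squares real/fake loss) with batch
#' size 1 over unpaired source and target tile lists. The loss history
#' records every term per epoch; runs with the same seed and configuration
#' reproduce the history exactly.
#'
#' @param x_tiles list of 3-channel source tiles (8-bit arrays or
#'   [image_tile()]s; inverted, channel-stacked PAH).
#' @param y_tiles list of 3-channel target tiles (H&E-style).
#' @param loss_cfg an [ecut_loss_config()].
#' @param train_cfg an [ecut_train_config()].
#' @param snapshot_dir if non-NULL, per-epoch PNG dumps of the input/output
#'   saliency masks and the discriminator's integrated-gradients attribution
#'   for the first tile are written here.
#' @return object of class `ecut_model` with the trained generator,
#'   discriminator, projection heads, configs and per-epoch `history`.
#' @export
train_ecut <- function(x_tiles, y_tiles, loss_cfg = ecut_loss_config(),
                       train_cfg = ecut_train_config(),
                       snapshot_dir = NULL) {
  if (length(x_tiles) == 0 || length(y_tiles) == 0)
    stop("empty training set")
  xs <- lapply(x_tiles, tile_pixels)
  ys <- lapply(y_tiles, tile_pixels)
  if (n_channels(xs[[1]]) != 3L)
    stop("source tiles must be 3-channel (use stack_to_3ch)")
  set.seed(train_cfg$seed)
  gen <- make_generator(train_cfg$ngf, train_cfg$n_res)
  disc <- make_discriminator(train_cfg$ndf)
  feat_ch <- c(3L, train_cfg$ngf, 2L * train_cfg$ngf,
               4L * train_cfg$ngf, 4L * train_cfg$ngf)
  heads <- make_nce_heads(feat_ch, loss_cfg$proj_dim)
  gp <- c(params_of(gen), params_of(heads))
  dp <- params_of(disc)
  opt_g <- adam_new(gp); opt_d <- adam_new(dp)
  hflip <- function(a) a[, rev(seq_len(ncol(a))), , drop = FALSE]
  E <- train_cfg$epochs
  history <- data.frame(epoch = seq_len(E), adv = NA_real_, nce_x = NA_real_,
                        nce_y = NA_real_, saliency = NA_real_,
                        total = NA_real_, d_loss = NA_real_)
  for (e in seq_len(E)) {
    lr <- lr_schedule(e, E, train_cfg$lr)
    ord <- sample.int(length(xs))
    sums <- c(adv = 0, nce_x = 0, nce_y = 0, saliency = 0, total = 0, d = 0)
    for (i in ord) {
      x <- xs[[i]]
      y <- ys[[sample.int(length(ys), 1)]]
      if (train_cfg$flip_augment) {
        if (stats::runif(1) < 0.5) x <- hflip(x)
        if (stats::runif(1) < 0.5) y <- hflip(y)
      }
      ag_begin()
      gl <- ecut_loss_graph(x, y, gen, disc, heads, loss_cfg)
      if (!is.finite(gl$total$v))
        stop("non-finite generator loss at epoch ", e, " (adv=", gl$terms["adv"],
             ", nce_x=", gl$terms["nce_x"], ", nce_y=", gl$terms["nce_y"],
             ", saliency=", gl$terms["saliency"], ")")
      backward(gl$total)
      fake_v <- gl$fake$v
      ag_end()
      adam_step(gp, opt_g, lr, train_cfg$beta1, train_cfg$beta2)
      zero_grads(dp)   # generator loss also reached D; discard those grads
      ag_begin()
      dr <- ag_sqmean(disc_forward(disc, to_net(y)), 1)
      df <- ag_sqmean(disc_forward(disc, ag_const(fake_v)), 0)
      dl <- ag_affine(ag_add(dr, df), 0.5)
      if (!is.finite(dl$v)) stop("non-finite discriminator loss at epoch ", e)
      backward(dl)
      ag_end()
      adam_step(dp, opt_d, lr, train_cfg$beta1, train_cfg$beta2)
      sums <- sums + c(gl$terms, total = gl$total$v, d = dl$v)
    }
    n <- length(ord)
    history[e, 2:7] <- sums / n
    if (!is.null(snapshot_dir)) ecut_snapshot(snapshot_dir, e, xs[[1]],
                                              gen, disc, loss_cfg)
  }
  structure(list(generator = gen, discriminator = disc, heads = heads,
                 loss_cfg = loss_cfg, train_cfg = train_cfg,
                 history = history, version = 1L),
            class = "ecut_model")
}

ecut_snapshot <- function(dir, epoch, x, gen, disc, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fake <- from_net(gen_forward(gen, to_net(x))$v)
  mx <- saliency_mask(rgb_to_gray(x), cfg$x_threshold, cfg$slope)
  my <- saliency_mask(rgb_to_gray(fake), cfg$y_threshold, cfg$slope)
  att <- integrated_gradients(disc, fake, steps = 8)
  rng <- max(abs(att)); if (rng == 0) rng <- 1
  png::writePNG(unclass(mx), file.path(dir, sprintf("mask_x_e%04d.png", epoch)))
  png::writePNG(unclass(my), file.path(dir, sprintf("mask_y_e%04d.png", epoch)))
  png::writePNG((att / rng + 1) / 2, file.path(dir, sprintf("ig_e%04d.png", epoch)))
  invisible(NULL)
}

#' @export
print.ecut_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("ecut_model: ngf=%d, ndf=%d, %d residual blocks, %d epochs\n",
              x$train_cfg$ngf, x$train_cfg$ndf, x$train_cfg$n_res,
              nrow(h)))
  cat(sprintf("  final losses: total=%.4f adv=%.4f nce_x=%.4f nce_y=%.4f saliency=%.4f\n",
              h$total[nrow(h)], h$adv[nrow(h)], h$nce_x[nrow(h)],
              h$nce_y[nrow(h)], h$saliency[nrow(h)]))
  invisible(x)
}

#' Apply a trained generator to source tiles
#'
#' @param model an `ecut_model` (or a bare generator from
#'   [make_generator()]).
#' @param tiles a `tile_grid`, a list of tiles, or a single 3-channel tile /
#'   array on the 0-255 scale.
#' @return the same shape of container with virtually stained (`VHE`) tiles;
#'   origins are preserved, so [stitch_tiles()] yields the stained slide.
#' @export
virtual_stain <- function(model, tiles) {
  gen <- if (inherits(model, "ecut_model")) model$generator else model
  stain1 <- function(t) {
    px <- tile_pixels(t)
    if (n_channels(px) != 3L)
      stop("virtual staining needs 3-channel input (use stack_to_3ch)")
    out <- from_net(gen_forward(gen, to_net(px))$v)
    if (inherits(t, "image_tile"))
      image_tile(out, origin = t$origin, modality = "VHE")
    else out
  }
  if (inherits(tiles, "tile_grid")) {
    tiles$tiles <- lapply(tiles$tiles, stain1)
    tiles$modality <- "VHE"
    tiles
  } else if (is.list(tiles) && !inherits(tiles, "image_tile")) {
    lapply(tiles, stain1)
  } else stain1(tiles)
}

#' @export
predict.ecut_model <- function(object, newdata, ...) virtual_stain(object, newdata)

#' Integrated-gradients attribution of a discriminator score
#'
#' Approximates the path integral of the score gradient along the straight
#' line from a baseline image (default: zero/black) to the input with
#' `steps` midpoint evaluations:
#' `IG_i = (x_i - b_i) * mean_k dF/dx_i at b + ((k - 1/2)/steps)(x - b)`,
#' where F is the mean patch score. The per-channel attributions are summed
#' to one H x W map. The map carries `f_input` and `f_baseline` attributes
#' so the completeness identity `sum(IG) ~ F(x) - F(b)` can be checked.
#'
#' @param discriminator a `pahisto_discriminator`, or any function taking an
#'   `ag` tensor and returning a scalar `ag` node.
#' @param image input image; for a `pahisto_discriminator`, an 8-bit
#'   3-channel array or tile (normalised internally).
#' @param steps number of path points (default 50).
#' @param baseline baseline image on the same scale as `image`; default zero.
#' @return H x W attribution matrix.
#' @export
integrated_gradients <- function(discriminator, image, steps = 50L,
                                 baseline = NULL) {
  stopifnot(steps >= 1)
  px <- tile_pixels(image)
  if (inherits(discriminator, "pahisto_discriminator")) {
    fn <- function(z) disc_score(discriminator, z)
    x <- px / 127.5 - 1
    b <- if (is.null(baseline)) array(-1, dim(x)) else tile_pixels(baseline) / 127.5 - 1
  } else {
    fn <- discriminator
    x <- px
    b <- if (is.null(baseline)) array(0, dim(x)) else tile_pixels(baseline)
  }
  gsum <- array(0, dim(x))
  f_in <- f_base <- NA_real_
  for (k in seq_len(steps)) {
    ag_begin()
    # midpoint rule: lower discretisation error than the endpoint sum
    xk <- ag_var(b + ((k - 0.5) / steps) * (x - b))
    s <- fn(xk)
    backward(s)
    gsum <- gsum + xk$g
    ag_end()
  }
  att <- (x - b) * gsum / steps
  if (length(dim(att)) == 3) att <- apply(att, c(1, 2), sum)
  ag_begin(); f_in <- fn(ag_const(x))$v; ag_end()
  ag_begin(); f_base <- fn(ag_const(b))$v; ag_end()
  attr(att, "f_input") <- f_in
  attr(att, "f_baseline") <- f_base
  att
}

#' Save / load an E-CUT checkpoint
#'
#' Checkpoints are self-describing (architecture hyperparameters and a
#' format version travel with the weights); a save/load round trip gives
#' bitwise-identical inference.
#'
#' @param model an `ecut_model`.
#' @param path checkpoint file path.
#' @return `ecut_load`: the restored `ecut_model`.
#' @export
ecut_save <- function(model, path) {
  saveRDS(list(version = 1L,
               train_cfg = model$train_cfg, loss_cfg = model$loss_cfg,
               history = model$history,
               gen = net_state(model$generator),
               disc = net_state(model$discriminator),
               heads = net_state(model$heads)), path)
  invisible(path)
}

#' @rdname ecut_save
#' @export
ecut_load <- function(path) {
  s <- readRDS(path)
  if (is.null(s$version) || s$version != 1L) stop("unknown checkpoint version")
  gen <- make_generator(s$train_cfg$ngf, s$train_cfg$n_res)
  disc <- make_discriminator(s$train_cfg$ndf)
  feat_ch <- c(3L, s$train_cfg$ngf, 2L * s$train_cfg$ngf,
               4L * s$train_cfg$ngf, 4L * s$train_cfg$ngf)
  heads <- make_nce_heads(feat_ch, s$loss_cfg$proj_dim)
  net_load_state(gen, s$gen)
  net_load_state(disc, s$disc)
  net_load_state(heads, s$heads)
  structure(list(generator = gen, discriminator = disc, heads = heads,
                 loss_cfg = s$loss_cfg, train_cfg = s$train_cfg,
                 history = s$history, version = 1L),
            class = "ecut_model")
}
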