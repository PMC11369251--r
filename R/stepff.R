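#' StepFF: stepwise deep-feature-fusion classification
#'
#' Binary cancer classification from up to three information sources: the
#' 1-channel PAH tile and the 3-channel VHE tile are each embedded by a
#' ResNet-18-style backbone and mapped by a fully connected layer to a
#' 16-dimensional deep feature vector (DFV); the six per-tile segmentation
#' features (area, count, distance from PAH and from VHE), z-normalised with
#' training-fold statistics, are mapped by a fully connected layer to a
#' third 16-dim DFV. The DFVs are concatenated (48-dim for the full model)
#' and a final fully connected layer with softmax yields the cancer
#' probability. Training uses focal loss and stratified five-fold
#' cross-validation; single- and dual-modality ablations use the same head
#' over fewer DFVs.
#'
#' @name stepff
NULL

#' Focal loss
#'
#' `mean(-alpha * (1 - p_t)^gamma * log(p_t))` where `p_t` is the predicted
#' probability of the true class. With `gamma = 0, alpha = 1` this is exactly
#' the cross-entropy.
#'
#' @param probs predicted probability of the positive (cancerous) class,
#'   in (0, 1).
#' @param labels binary labels (1 = cancerous).
#' @param gamma focusing parameter (default 2).
#' @param alpha class weight (default 0.5; neutral for balanced data).
#' @return scalar loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2, alpha = 0.5) {
  stopifnot(length(probs) == length(labels), all(probs > 0 & probs < 1))
  pt <- ifelse(labels == 1, probs, 1 - probs)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

# focal loss from 2-class logits as an autodiff node; labels are 1/2 indices
ag_focal <- function(logits, labels, gamma = 2, alpha = 0.5) {
  lm <- logits$v
  if (is.null(dim(lm))) lm <- matrix(lm, 1)
  n <- nrow(lm)
  mx <- apply(lm, 1, max)
  ex <- exp(lm - mx)
  sm <- ex / rowSums(ex)
  pt <- pmin(pmax(sm[cbind(seq_len(n), labels)], 1e-12), 1 - 1e-12)
  loss <- mean(-alpha * (1 - pt)^gamma * log(pt))
  new_node(loss, list(logits), function(nd) {
    # dL/dp_t, then chain through softmax: dp_t/dz_j = p_t (1[j==t] - p_j)
    dldpt <- -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
    oh <- matrix(0, n, ncol(lm)); oh[cbind(seq_len(n), labels)] <- 1
    dz <- (dldpt * pt / n) * (oh - sm)
    acc_grad(logits, keep_dim(as.numeric(nd$g) * dz, logits$v))
  })
}

#' Segmentation-feature normaliser
#'
#' Per-feature mean/sd estimated on training rows only; transformed training
#' features have mean 0, sd 1. Near-constant features get sd 1 (guard), and
#' missing values (e.g. undefined distance at count < 2) map to 0, the
#' training mean.
#'
#' @param x n x 6 matrix of training-fold segmentation features.
#' @return object of class `seg_normalizer`.
#' @export
fit_seg_normalizer <- function(x) {
  mu <- apply(x, 2, function(v) mean(v, na.rm = TRUE))
  mu[is.na(mu)] <- 0
  sd_ <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE))
  sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
  structure(list(mean = mu, sd = sd_), class = "seg_normalizer")
}

#' @rdname fit_seg_normalizer
#' @param nrm a fitted `seg_normalizer`.
#' @export
apply_seg_normalizer <- function(nrm, x) {
  one <- is.null(dim(x))
  if (one) x <- matrix(x, 1)
  z <- sweep(sweep(x, 2, nrm$mean, "-"), 2, nrm$sd, "/")
  z[is.na(z)] <- 0
  if (one) as.numeric(z) else z
}

#' StepFF configuration
#'
#' Full-scale defaults: Adam beta1 = 0.9, beta2 = 0.999, learning rate 1e-4,
#' mini-batch 32, up to 1000 epochs with early stopping, h/v-flip
#' augmentation, five folds, backbone width 64 (512-dim embeddings).
#' `modalities` selects the DFVs used (ablations mirror the PAH / VHE /
#' PAH+VHE variants).
#'
#' @param modalities subset of `c("pah", "vhe", "seg")`.
#' @param width backbone base width; the embedding is `8 * width`-dim.
#' @param lr,beta1,beta2,batch,epochs,patience,folds training parameters.
#' @param gamma,alpha focal-loss parameters.
#' @param flip_augment random h/v flips of image inputs during training.
#' @param seed RNG seed.
#' @return list of class `stepff_config`.
#' @export
stepff_config <- function(modalities = c("pah", "vhe", "seg"), width = 64L,
                          lr = 1e-4, beta1 = 0.9, beta2 = 0.999, batch = 32L,
                          epochs = 1000L, patience = 10L, folds = 5L,
                          gamma = 2, alpha = 0.5, flip_augment = TRUE,
                          seed = 1L) {
  modalities <- match.arg(modalities, c("pah", "vhe", "seg"), several.ok = TRUE)
  structure(list(modalities = modalities, width = as.integer(width), lr = lr,
                 beta1 = beta1, beta2 = beta2, batch = as.integer(batch),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 folds = as.integer(folds), gamma = gamma, alpha = alpha,
                 flip_augment = flip_augment, seed = as.integer(seed)),
            class = "stepff_config")
}

make_stepff_net <- function(cfg) {
  ed <- 8L * cfg$width
  net <- list()
  if ("pah" %in% cfg$modalities) {
    net$pah <- make_resnet(cfg$width, cin = 1L)
    net$head_pah <- nn_linear(ed, 16L)
  }
  if ("vhe" %in% cfg$modalities) {
    net$vhe <- make_resnet(cfg$width, cin = 3L)
    net$head_vhe <- nn_linear(ed, 16L)
  }
  if ("seg" %in% cfg$modalities) net$head_seg <- nn_linear(6L, 16L)
  net$fusion <- nn_linear(16L * length(cfg$modalities), 2L)
  net
}

as_chan <- function(px, c) array(as.vector(px) / 127.5 - 1, c(dim(px)[1], dim(px)[2], c))

# concatenated DFVs -> 2 logits; item fields pah / vhe / seg as needed
stepff_logits <- function(net, cfg, item, nrm, flip_h = FALSE, flip_v = FALSE) {
  fl <- function(a) {
    if (flip_h) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
    if (flip_v) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    a
  }
  dfvs <- list()
  if ("pah" %in% cfg$modalities) {
    if (is.null(item$pah)) stop("model expects a PAH tile")
    x <- fl(as_chan(tile_pixels(item$pah), 1L))
    dfvs$pah <- ag_linear(resnet_embed(net$pah, ag_const(x)),
                          net$head_pah$w, net$head_pah$b)
  }
  if ("vhe" %in% cfg$modalities) {
    if (is.null(item$vhe)) stop("model expects a VHE tile")
    px <- tile_pixels(item$vhe)
    x <- fl(as_chan(px, 3L))
    dfvs$vhe <- ag_linear(resnet_embed(net$vhe, ag_const(x)),
                          net$head_vhe$w, net$head_vhe$b)
  }
  if ("seg" %in% cfg$modalities) {
    if (is.null(item$seg)) stop("model expects segmentation features")
    z <- apply_seg_normalizer(nrm, as.numeric(item$seg))
    dfvs$seg <- ag_linear(ag_const(z), net$head_seg$w, net$head_seg$b)
  }
  fused <- dfvs[[1]]
  if (length(dfvs) > 1) for (k in 2:length(dfvs)) {
    fused <- local({
      a <- fused; b <- dfvs[[k]]; na <- length(a$v); nb <- length(b$v)
      new_node(c(a$v, b$v), list(a, b), function(nd) {
        acc_grad(a, nd$g[seq_len(na)])
        acc_grad(b, nd$g[na + seq_len(nb)])
      })
    })
  }
  ag_linear(fused, net$fusion$w, net$fusion$b)
}

#' Extract a 16-dim deep feature vector from one branch
#'
#' @param model a trained `stepff_model`.
#' @param branch `"pah"`, `"vhe"` or `"seg"`.
#' @param input image tile (pah/vhe) or raw 6-vector of segmentation
#'   features (seg).
#' @param fold which fold's network to use (default 1).
#' @return numeric vector of length 16.
#' @export
extract_dfv <- function(model, branch = c("pah", "vhe", "seg"), input,
                        fold = 1L) {
  branch <- match.arg(branch)
  fl <- model$folds[[fold]]
  net <- fl$net; cfg <- model$cfg
  if (!branch %in% cfg$modalities) stop("model was built without the ",
                                        branch, " branch")
  v <- if (branch == "seg") {
    z <- apply_seg_normalizer(fl$normalizer, as.numeric(input))
    ag_linear(ag_const(z), net$head_seg$w, net$head_seg$b)
  } else {
    c_in <- if (branch == "pah") 1L else 3L
    x <- as_chan(tile_pixels(input), c_in)
    h <- resnet_embed(net[[branch]], ag_const(x))
    hd <- net[[paste0("head_", branch)]]
    ag_linear(h, hd$w, hd$b)
  }
  as.numeric(v$v)
}

#' Predict a cancer probability for one tile
#'
#' Softmax over the two fusion-head logits; the probability of the cancerous
#' class is returned. Fold models are averaged by default.
#'
#' @param model a trained `stepff_model`.
#' @param pah_tile,vhe_tile,seg_features the modality inputs the model was
#'   built with (others may be NULL).
#' @param fold a fold index, or NULL (default) to average all folds.
#' @return probability in [0, 1].
#' @export
fuse_predict <- function(model, pah_tile = NULL, vhe_tile = NULL,
                         seg_features = NULL, fold = NULL) {
  item <- list(pah = pah_tile, vhe = vhe_tile, seg = seg_features)
  folds <- if (is.null(fold)) seq_along(model$folds) else fold
  ps <- vapply(folds, function(k) {
    fl <- model$folds[[k]]
    z <- stepff_logits(fl$net, model$cfg, item, fl$normalizer)$v
    e <- exp(z - max(z))
    (e / sum(e))[2]
  }, numeric(1))
  mean(ps)
}

#' Classification metrics (cancerous = positive class)
#'
#' @param y_true,y_pred equal-length binary vectors (1 = cancerous).
#' @return named list: accuracy, f1, precision, recall. Undefined ratios
#'   (no predicted / no true positives) are reported as 0 with a warning.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  acc <- mean(y_true == y_pred)
  if (tp + fp == 0) { warning("no predicted positives; precision set to 0");
    prec <- 0 } else prec <- tp / (tp + fp)
  if (tp + fn == 0) { warning("no true positives; recall set to 0");
    rec <- 0 } else rec <- tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, f1 = f1, precision = prec, recall = rec)
}

label_to_int <- function(lb) {
  if (is.numeric(lb)) as.integer(lb > 0)
  else as.integer(lb == "cancerous")
}

#' Train the StepFF classifier with stratified k-fold cross-validation
#'
#' The segmentation-feature normaliser is refitted on each training fold
#' (no leakage into the held-out fold); early stopping monitors the
#' held-out fold's focal loss. Items sharing a `group` id are co-assigned
#' to one fold, so tiles cut with spatial overlap never straddle a split.
#'
#' @param dataset list of items `list(pah, vhe, seg, label)`; `label` is
#'   0/1 or "noncancerous"/"cancerous". Fields not named in
#'   `cfg$modalities` may be absent.
#' @param cfg a [stepff_config()].
#' @param groups optional vector of group ids, one per item.
#' @return object of class `stepff_model`: per-fold networks + normalisers,
#'   per-fold and mean metrics, out-of-fold probabilities, the config.
#' @export
train_stepff <- function(dataset, cfg = stepff_config(), groups = NULL) {
  n <- length(dataset)
  labels <- vapply(dataset, function(d) label_to_int(d$label), integer(1))
  if (min(table(labels)) < cfg$folds)
    stop("need at least ", cfg$folds, " items per class for ", cfg$folds,
         "-fold cross-validation")
  set.seed(cfg$seed)
  if (is.null(groups)) groups <- seq_len(n)
  # stratified fold assignment at group level (group label = majority label)
  gid <- unique(groups)
  glab <- vapply(gid, function(g) round(mean(labels[groups == g])), numeric(1))
  fold_of_group <- integer(length(gid))
  for (lb in unique(glab)) {
    gi <- which(glab == lb)
    fold_of_group[gi[sample.int(length(gi))]] <-
      rep_len(seq_len(cfg$folds), length(gi))
  }
  fold_id <- fold_of_group[match(groups, gid)]
  if (any(vapply(seq_len(cfg$folds), function(k)
    length(unique(labels[fold_id == k])) < 2, logical(1))))
    stop("a class is absent from one fold; supply more data")
  folds <- list()
  metrics <- NULL
  oof <- rep(NA_real_, n)
  for (k in seq_len(cfg$folds)) {
    tr <- which(fold_id != k); va <- which(fold_id == k)
    segm <- NULL
    if ("seg" %in% cfg$modalities)
      segm <- do.call(rbind, lapply(dataset, function(d) as.numeric(d$seg)))
    nrm <- if (is.null(segm)) NULL else fit_seg_normalizer(segm[tr, , drop = FALSE])
    net <- make_stepff_net(cfg)
    ps <- params_of(net)
    opt <- adam_new(ps)
    best <- list(loss = Inf, state = NULL); wait <- 0L
    val_probs <- function() vapply(va, function(i) {
      z <- stepff_logits(net, cfg, dataset[[i]], nrm)$v
      e <- exp(z - max(z)); (e / sum(e))[2]
    }, numeric(1))
    for (e in seq_len(cfg$epochs)) {
      ord <- sample(tr)
      for (start in seq(1, length(ord), by = cfg$batch)) {
        bidx <- ord[start:min(start + cfg$batch - 1, length(ord))]
        ag_begin()
        bl <- NULL
        for (i in bidx) {
          fh <- cfg$flip_augment && stats::runif(1) < 0.5
          fv <- cfg$flip_augment && stats::runif(1) < 0.5
          li <- local({
            z <- stepff_logits(net, cfg, dataset[[i]], nrm, fh, fv)
            zi <- new_node(matrix(z$v, 1), list(z),
                           function(nd) acc_grad(z, as.numeric(nd$g)))
            ag_focal(zi, labels[i] + 1L, cfg$gamma, cfg$alpha)
          })
          bl <- if (is.null(bl)) li else ag_add(bl, li)
        }
        bl <- ag_affine(bl, 1 / length(bidx))
        if (!is.finite(bl$v)) stop("non-finite classification loss")
        backward(bl)
        ag_end()
        adam_step(ps, opt, cfg$lr, cfg$beta1, cfg$beta2)
      }
      vp <- val_probs()
      vl <- focal_loss(pmin(pmax(vp, 1e-12), 1 - 1e-12), labels[va],
                       cfg$gamma, cfg$alpha)
      if (cfg$patience > 0) {
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, state = net_state(net)); wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    if (!is.null(best$state)) net_load_state(net, best$state)
    vp <- val_probs()
    oof[va] <- vp
    m <- classification_metrics(labels[va], as.integer(vp >= 0.5))
    metrics <- rbind(metrics, data.frame(fold = k, accuracy = m$accuracy,
                                         f1 = m$f1, precision = m$precision,
                                         recall = m$recall))
    folds[[k]] <- list(net = net, normalizer = nrm)
  }
  structure(list(folds = folds, cfg = cfg, metrics = metrics,
                 mean_metrics = colMeans(metrics[, -1]),
                 oof_probs = oof, labels = labels, fold_id = fold_id,
                 version = 1L),
            class = "stepff_model")
}

#' @export
print.stepff_model <- function(x, ...) {
  mm <- x$mean_metrics
  cat(sprintf("stepff_model: modalities {%s}, width %d, %d folds\n",
              paste(x$cfg$modalities, collapse = ", "), x$cfg$width,
              x$cfg$folds))
  cat(sprintf("  mean CV: accuracy %.3f, F1 %.3f, precision %.3f, recall %.3f\n",
              mm["accuracy"], mm["f1"], mm["precision"], mm["recall"]))
  invisible(x)
}

#' @export
predict.stepff_model <- function(object, newdata, ...) {
  vapply(newdata, function(it)
    fuse_predict(object, it$pah, it$vhe, it$seg), numeric(1))
}

#' Whole-slide cancer-probability map
#'
#' Each tile is painted with the linear interpolation between blue
#' (probability 0, RGB 0/0/255) and purple (probability 1, RGB 128/0/128)
#' and the painted tiles are merged with the overlap-averaging stitcher,
#' giving a slide-sized colour map of the classifier output.
#'
#' @param tile_probs one probability per tile of `grid`.
#' @param grid the `tile_grid` the probabilities belong to.
#' @return H x W x 3 8-bit RGB array on the grid's source canvas.
#' @export
probability_map <- function(tile_probs, grid) {
  stopifnot(inherits(grid, "tile_grid"),
            length(tile_probs) == length(grid$tiles))
  if (any(tile_probs < 0 | tile_probs > 1))
    stop("probabilities must lie in [0, 1]")
  blue <- c(0, 0, 255); purple <- c(128, 0, 128)
  ts <- grid$tile_size
  g2 <- grid
  g2$modality <- "VHE"
  g2$tiles <- lapply(seq_along(grid$tiles), function(i) {
    col <- blue + tile_probs[i] * (purple - blue)
    image_tile(array(rep(col, each = ts * ts), c(ts, ts, 3)),
               origin = grid$tiles[[i]]$origin, modality = "VHE")
  })
  stitch_tiles(g2)
}

#' Cohen's kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' marginal expected agreement `p_e`; -1 indicates complete disagreement and
#' 1 complete agreement. When both raters are constant and identical
#' (`p_e = 1`), kappa is defined as 1 by convention.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return kappa in [-1, 1].
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) > 0)
  lev <- sort(unique(c(ratings_a, ratings_b)))
  a <- factor(ratings_a, lev); b <- factor(ratings_b, lev)
  po <- mean(a == b)
  pe <- sum(prop.table(table(a)) * prop.table(table(b)))
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for three or more raters
#'
#' @param ratings_matrix n_subjects x n_raters matrix of categorical
#'   ratings.
#' @return Fleiss' kappa; 1 when all raters always agree.
#' @export
fleiss_kappa <- function(ratings_matrix) {
  stopifnot(is.matrix(ratings_matrix), ncol(ratings_matrix) >= 2)
  lev <- sort(unique(as.vector(ratings_matrix)))
  n <- nrow(ratings_matrix); r <- ncol(ratings_matrix)
  cnt <- t(apply(ratings_matrix, 1, function(row)
    vapply(lev, function(l) sum(row == l), numeric(1))))
  pj <- colSums(cnt) / (n * r)
  pi_ <- (rowSums(cnt^2) - r) / (r * (r - 1))
  pbar <- mean(pi_)
  pe <- sum(pj^2)
  if (abs(1 - pe) < 1e-12) return(if (pbar == 1) 1 else 0)
  (pbar - pe) / (1 - pe)
}

#' Save / load a StepFF checkpoint
#' @param model a `stepff_model`.
#' @param path checkpoint file path.
#' @return `stepff_load`: the restored model.
#' @export
stepff_save <- function(model, path) {
  saveRDS(list(version = 1L, cfg = model$cfg, metrics = model$metrics,
               oof_probs = model$oof_probs, labels = model$labels,
               fold_id = model$fold_id,
               folds = lapply(model$folds, function(f)
                 list(net = net_state(f$net), normalizer = f$normalizer))),
          path)
  invisible(path)
}

#' @rdname stepff_save
#' @export
stepff_load <- function(path) {
  s <- readRDS(path)
  if (is.null(s$version) || s$version != 1L) stop("unknown checkpoint version")
  folds <- lapply(s$folds, function(f) {
    net <- make_stepff_net(s$cfg)
    net_load_state(net, f$net)
    list(net = net, normalizer = f$normalizer)
  })
  structure(list(folds = folds, cfg = s$cfg, metrics = s$metrics,
                 mean_metrics = colMeans(s$metrics[, -1]),
                 oof_probs = s$oof_probs, labels = s$labels,
                 fold_id = s$fold_id, version = 1L),
            class = "stepff_model")
}
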