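test_that("focal loss reduces to cross-entropy and matches its formula", {
  set.seed(1)
  p <- runif(20, 0.05, 0.95); y <- rbinom(20, 1, 0.5)
  pt <- ifelse(y == 1, p, 1 - p)
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 1), mean(-log(pt)))
  expect_lt(focal_loss(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-15)
  expect_equal(focal_loss(p, y, gamma = 2, alpha = 0.5),
               mean(-0.5 * (1 - pt)^2 * log(pt)))
})

test_that("classification metrics follow confusion-matrix arithmetic", {
  m <- classification_metrics(rep(1, 4), rep(1, 4))
  expect_equal(unlist(m), c(accuracy = 1, f1 = 1, precision = 1, recall = 1))
  # TP=5 FP=1 FN=2 TN=2
  yt <- c(rep(1, 7), rep(0, 3))
  yp <- c(rep(1, 5), 0, 0, 1, 0, 0)
  m2 <- classification_metrics(yt, yp)
  expect_equal(m2$precision, 5 / 6)
  expect_equal(m2$recall, 5 / 7)
  expect_equal(m2$f1, 10 / 13)
  expect_equal(m2$accuracy, 7 / 10)
  expect_warning(m3 <- classification_metrics(c(1, 0), c(0, 0)), "precision")
  expect_equal(m3$precision, 0)
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("segmentation-feature normaliser standardises and guards degeneracy", {
  set.seed(2)
  x <- cbind(matrix(rnorm(60, 50, 9), 20), matrix(rnorm(60, 5, 2), 20))
  nrm <- fit_seg_normalizer(x)
  z <- apply_seg_normalizer(nrm, x)
  expect_equal(unname(colMeans(z)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # constant feature and NA inputs
  x2 <- x; x2[, 3] <- 7; x2[4, 5] <- NA
  nrm2 <- fit_seg_normalizer(x2)
  z2 <- apply_seg_normalizer(nrm2, x2)
  expect_true(all(is.finite(z2)))
  expect_equal(z2[4, 5], 0)  # missing -> training mean
})

test_that("Cohen's kappa matches the contingency oracle, exhaustively on small tables", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1)), 1)
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  tab <- function(a, b, c, d) {
    ra <- c(rep(0, a + b), rep(1, c + d))
    rb <- c(rep(0, a), rep(1, b), rep(0, c), rep(1, d))
    cohens_kappa(ra, rb)
  }
  expect_equal(tab(40, 5, 5, 50), oracle_kappa_2x2(40, 5, 5, 50))
  for (a in 0:5) for (b in 0:5) for (c in 0:5) for (d in 0:5) {
    n <- a + b + c + d
    if (n == 0) next
    pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
    if (abs(1 - pe) < 1e-12) next   # convention cases tested separately
    expect_equal(tab(a, b, c, d), oracle_kappa_2x2(a, b, c, d))
  }
  # constant identical raters: convention kappa = 1
  expect_equal(cohens_kappa(c(1, 1, 1), c(1, 1, 1)), 1)
})

test_that("Fleiss' kappa agrees with Cohen's direction and is 1 on unanimity", {
  m <- matrix(c(1, 1, 1, 0, 0, 0, 1, 1, 1), 3, byrow = TRUE)
  expect_equal(fleiss_kappa(m), 1)
  set.seed(3)
  r <- matrix(rbinom(60, 1, 0.5), 20, 3)
  k <- fleiss_kappa(r)
  expect_true(k >= -1 && k <= 1)
})

test_that("probability map interpolates exactly between blue and purple", {
  mk_grid <- function(probs) {
    n <- length(probs); ts <- 8L
    tiles <- lapply(seq_len(n), function(i)
      image_tile(matrix(0, ts, ts), origin = c(0L, (i - 1L) * ts),
                 modality = "HE"))
    structure(list(tiles = tiles, canvas_size = c(ts, n * ts),
                   padded_size = c(ts, n * ts), tile_size = ts, stride = ts,
                   pad_value = 255, modality = "HE"), class = "tile_grid")
  }
  pm <- probability_map(c(0, 1, 0.5), mk_grid(c(0, 1, 0.5)))
  expect_equal(pm[1, 1, ], c(0, 0, 255))      # p = 0: pure blue
  expect_equal(pm[1, 9, ], c(128, 0, 128))    # p = 1: pure purple
  expect_equal(pm[1, 17, ], c(64, 0, 192))    # p = 0.5: channel midpoint
  expect_error(probability_map(c(0, 2, 0), mk_grid(c(0, 1, 0))), "0, 1")
})

test_that("a tiny fused model trains, predicts coherently and serialises", {
  set.seed(4)
  n <- 8
  mk_item <- function(lbl) {
    base <- if (lbl == 1) 60 else 200
    list(pah = matrix(pmin(pmax(rnorm(256, base, 10), 0), 255), 16, 16),
         vhe = array(pmin(pmax(rnorm(768, 255 - base, 10), 0), 255), c(16, 16, 3)),
         seg = c(rnorm(3, if (lbl == 1) 10 else 2), rnorm(3, if (lbl == 1) 10 else 2)),
         label = lbl)
  }
  items <- c(lapply(rep(1, n), mk_item), lapply(rep(0, n), mk_item))
  cfg <- stepff_config(width = 2L, lr = 3e-3, batch = 8, epochs = 2,
                       patience = 0, folds = 2, seed = 5)
  suppressWarnings(m <- train_stepff(items, cfg))
  expect_equal(nrow(m$metrics), 2)
  p <- fuse_predict(m, items[[1]]$pah, items[[1]]$vhe, items[[1]]$seg)
  expect_true(p >= 0 && p <= 1)
  # two-logit head: complements sum to one by construction of softmax
  dfv <- extract_dfv(m, "seg", items[[1]]$seg)
  expect_length(dfv, 16)
  dfp <- extract_dfv(m, "pah", items[[1]]$pah)
  expect_length(dfp, 16)
  # missing modality is an explicit error
  expect_error(fuse_predict(m, items[[1]]$pah, NULL, items[[1]]$seg),
               "VHE")
  # determinism of the whole CV under a fixed seed
  suppressWarnings(m2 <- train_stepff(items, cfg))
  expect_identical(m$metrics, m2$metrics)
  expect_identical(m$fold_id, m2$fold_id)
  # serialisation round trip preserves predictions bitwise
  fn <- withr::local_tempfile(fileext = ".rds")
  stepff_save(m, fn)
  m3 <- stepff_load(fn)
  expect_identical(fuse_predict(m3, items[[1]]$pah, items[[1]]$vhe,
                                items[[1]]$seg), p)
})

test_that("fold normalisers depend only on their training rows (no leakage)", {
  set.seed(6)
  n <- 12
  items <- lapply(seq_len(n), function(i) list(
    pah = matrix(runif(64, 0, 255), 8, 8),
    seg = rnorm(6, i), label = as.integer(i %% 2 == 0)))
  cfg <- stepff_config(modalities = c("pah", "seg"), width = 2L, lr = 1e-3,
                       batch = 6, epochs = 1, patience = 0, folds = 3,
                       seed = 7)
  suppressWarnings(m <- train_stepff(items, cfg))
  segm <- do.call(rbind, lapply(items, `[[`, "seg"))
  for (k in seq_len(3)) {
    tr <- which(m$fold_id != k)
    redo <- fit_seg_normalizer(segm[tr, , drop = FALSE])
    expect_equal(m$folds[[k]]$normalizer$mean, redo$mean)
    expect_equal(m$folds[[k]]$normalizer$sd, redo$sd)
  }
  # grouped items are co-assigned
  grp <- rep(1:6, each = 2)
  suppressWarnings(mg <- train_stepff(items, cfg, groups = grp))
  expect_true(all(tapply(mg$fold_id, grp, function(v) length(unique(v))) == 1))
})
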