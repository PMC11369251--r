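test_that("BCE + Dice loss matches its closed forms", {
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  near <- abs(m - 1e-9)
  expect_lt(bce_dice_loss(near, m), 1e-3)      # perfect prediction
  # uniform 0.5 prediction: BCE term is exactly ln 2
  p5 <- matrix(0.5, 8, 8)
  dice <- (2 * sum(p5 * m) + 1) / (sum(p5) + sum(m) + 1)
  expect_equal(bce_dice_loss(p5, m), log(2) + (1 - dice))
  # random inputs against a term-by-term oracle
  set.seed(1)
  for (i in 1:5) {
    p <- matrix(runif(64, 0.01, 0.99), 8, 8)
    t <- matrix(rbinom(64, 1, 0.5), 8, 8)
    bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
    d <- (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1)
    expect_equal(bce_dice_loss(p, t), bce + (1 - d))
  }
  expect_error(bce_dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("dice_score handles agreement, disagreement and empty masks", {
  a <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, 1 - a), 0)
  expect_equal(dice_score(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
})

test_that("training with the same seed reproduces the history exactly", {
  ds <- generate_dataset(2, canvas_size = c(64, 64), seed = 5)
  pairs <- lapply(ds, function(it) list(image = it$he, mask = it$mask))
  cfg <- unet_train_config(lr = 1e-3, batch = 4, epochs = 2, patience = 0,
                           val_frac = 0, nf = 4, seed = 11)
  h1 <- train_unet(pairs, cfg)$history
  h2 <- train_unet(pairs, cfg)$history
  expect_identical(h1, h2)
  expect_error(train_unet(list()), "empty")
})

test_that("flip TTA makes predictions invariant to input flips", {
  ds <- generate_dataset(1, canvas_size = c(64, 64), seed = 6)
  pairs <- lapply(ds, function(it) list(image = it$he, mask = it$mask))
  m <- train_unet(pairs, unet_train_config(lr = 1e-3, batch = 2, epochs = 2,
                                           patience = 0, val_frac = 0, nf = 4,
                                           seed = 1))
  px <- tile_pixels(ds[[1]]$he)
  hf <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  p1 <- predict_mask(m, px, tta = TRUE)
  p2 <- predict_mask(m, hf, tta = TRUE)
  expect_equal(p1, p2[, rev(seq_len(ncol(p2)))])
  # a model thresholded above its probabilities yields an empty mask
  expect_true(all(predict_mask(m, px, tta = FALSE, threshold = 1) == 0))
  # checkpoint round trip gives identical predictions
  fn <- withr::local_tempfile(fileext = ".rds")
  unet_save(m, fn)
  m2 <- unet_load(fn)
  expect_identical(predict_mask(m2, px), p1)
})

test_that("morphometry matches lattice-disk geometry exactly", {
  f0 <- extract_features(matrix(0, 32, 32))
  expect_identical(f0$cell_count, 0L)
  expect_true(is.na(f0$cell_area) && is.na(f0$mean_distance))
  # 3 disjoint disks of radius 5 at the stated centres
  m <- oracle_disk_mask(80, 80, 20, 20, 5) + oracle_disk_mask(80, 80, 20, 60, 5) +
    oracle_disk_mask(80, 80, 60, 20, 5)
  f <- extract_features(m)
  expect_equal(f$cell_count, 3L)
  expect_equal(f$cell_area, 81)
  expect_equal(f$mean_distance, 40)        # nearest neighbour is 40 px for all
  fa <- extract_features(m, distance = "allpairs")
  expect_equal(fa$mean_distance, (40 + 40 + 40 * sqrt(2)) / 3)
  # single disk: count 1, distance undefined
  f1 <- extract_features(oracle_disk_mask(32, 32, 16, 16, 5))
  expect_equal(f1$cell_count, 1L)
  expect_true(is.na(f1$mean_distance))
  expect_equal(f1$cell_area, 81)
})

test_that("component labeling equals the exhaustive flood-fill oracle", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rbinom(64 * 64, 1, runif(1, 0.2, 0.6)), 64, 64)
    got <- pahisto:::cpp_label8(matrix(as.integer(m), 64, 64))
    want <- oracle_label8(m)
    # same partition: counts per component match after canonical relabeling
    expect_equal(max(got), max(want))
    expect_true(all(tapply(want[m == 1], got[m == 1],
                           function(v) length(unique(v))) == 1))
    expect_equal(sort(tabulate(got[got > 0])), sort(tabulate(want[want > 0])))
  }
})

test_that("features are invariant to translation and flips, monotone in min_area", {
  m <- matrix(0, 64, 64)
  m[10:14, 10:14] <- 1; m[40:46, 30:36] <- 1; m[20:22, 50:53] <- 1
  f <- extract_features(m, min_area = 5)
  sh <- matrix(0, 64, 64); sh[4:58, 6:60] <- m[1:55, 1:55]
  fs <- extract_features(sh, min_area = 5)
  expect_equal(fs$cell_count, f$cell_count)
  expect_equal(fs$cell_area, f$cell_area)
  expect_equal(fs$mean_distance, f$mean_distance)
  ff <- extract_features(m[64:1, ], min_area = 5)
  expect_equal(ff$cell_count, f$cell_count)
  expect_equal(ff$cell_area, f$cell_area)
  expect_equal(ff$mean_distance, f$mean_distance)
  cnt <- vapply(c(1, 9, 12, 26, 50),
                function(a) extract_features(m, min_area = a)$cell_count, 0L)
  expect_true(all(diff(cnt) <= 0))
})

test_that("IQR fencing keeps inliers, order, and subset structure", {
  expect_equal(iqr_filter(rep(4, 10)), rep(4, 10))
  v <- c(1:9, 1000)
  expect_equal(iqr_filter(v), 1:9)
  set.seed(8)
  x <- rnorm(50)
  out <- iqr_filter(x)
  expect_true(all(out %in% x))
  expect_identical(out, x[x %in% out])
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
  expect_identical(out, x[x >= lo & x <= hi])
})

test_that("minimum enclosing circle is correct on known point sets", {
  mec <- pahisto:::min_enclosing_circle
  c1 <- mec(matrix(c(0, 0, 0, 4), 2, byrow = TRUE))
  expect_equal(c1$center, c(0, 2)); expect_equal(c1$radius, 2)
  # equilateral-ish: circle through three corners of a square has r = sqrt(2)/2 * side
  c2 <- mec(matrix(c(0, 0, 0, 2, 2, 0, 2, 2), 4, byrow = TRUE))
  expect_equal(c2$center, c(1, 1))
  expect_equal(c2$radius, sqrt(2))
  # all points inside the returned circle (random sets)
  set.seed(9)
  for (i in 1:10) {
    p <- matrix(runif(40), 20, 2)
    cc <- mec(p)
    expect_true(all(sqrt(rowSums(sweep(p, 2, cc$center)^2)) <= cc$radius + 1e-7))
  }
})

test_that("feature_table bypasses the model with ground-truth masks", {
  ds <- generate_dataset(4, canvas_size = c(64, 64), seed = 10)
  tab <- feature_table(lapply(ds, `[[`, "he"),
                       masks = lapply(ds, `[[`, "mask"),
                       labels = vapply(ds, `[[`, "", "label"))
  expect_equal(nrow(tab), 8)
  for (i in seq_along(ds)) {
    f <- extract_features(ds[[i]]$mask)
    expect_equal(tab$cell_count[i], f$cell_count)
    expect_equal(tab$cell_area[i], f$cell_area)
  }
  expect_gt(mean(tab$cell_count[tab$label == "cancerous"]),
            mean(tab$cell_count[tab$label == "noncancerous"]))
  s <- feature_summary(tab)
  expect_true(all(c("mean_raw", "mean_iqr") %in% names(s)))
})

test_that("count recovery: extracted counts track scene counts for sparse scenes", {
  p <- scene_params(density = c(noncancerous = 8, cancerous = 8),
                    min_sep_factor = 1.4)
  true_n <- integer(0); est_n <- integer(0)
  for (i in 1:30) {
    s <- generate_scene(p, "cancerous", c(64, 64), seed = 400 + i)
    true_n <- c(true_n, nrow(s$centers))
    est_n <- c(est_n, extract_features(render_mask(s))$cell_count)
  }
  keep <- true_n > 0
  fit <- coef(lm(est_n[keep] ~ true_n[keep]))
  expect_gte(fit[2], 0.8)
  expect_lte(fit[2], 1.1)
})
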