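test_that("scene generation is deterministic and respects degenerate density", {
  p <- scene_params()
  s1 <- generate_scene(p, "cancerous", c(64, 64), seed = 3)
  s2 <- generate_scene(p, "cancerous", c(64, 64), seed = 3)
  expect_identical(s1$centers, s2$centers)
  expect_identical(s1$radii, s2$radii)
  s3 <- generate_scene(p, "cancerous", c(64, 64), seed = 4)
  expect_false(identical(s1$centers, s3$centers))
  # all centres inside the canvas, radii positive
  expect_true(all(s1$centers[, 1] >= 1 & s1$centers[, 1] <= 64))
  expect_true(all(s1$centers[, 2] >= 1 & s1$centers[, 2] <= 64))
  expect_true(all(s1$radii > 0))
  # density so low that the expected count rounds to zero nuclei
  p0 <- scene_params(density = c(noncancerous = 1e-9, cancerous = 1e-9))
  s0 <- generate_scene(p0, "noncancerous", c(64, 64), seed = 1)
  expect_identical(nrow(s0$centers), 0L)
  expect_error(generate_scene(p, "cancerous", c(32, 32), seed = 1), "64")
})

test_that("over-dense scenes fail with a placement error", {
  p <- scene_params(density = c(noncancerous = 5, cancerous = 2000),
                    min_sep_factor = 2)
  expect_error(generate_scene(p, "cancerous", c(64, 64), seed = 1),
               "separation")
})

test_that("class contrast: cancerous scenes are denser and more crowded", {
  p <- scene_params()
  stats_for <- function(lbl) {
    t(vapply(1:500, function(i) {
      s <- generate_scene(p, lbl, c(64, 64), seed = 10000 + i)
      n <- nrow(s$centers)
      nn <- if (n >= 2) {
        dm <- as.matrix(dist(s$centers)); diag(dm) <- Inf
        mean(apply(dm, 1, min))
      } else NA_real_
      c(n = n, nn = nn)
    }, numeric(2)))
  }
  nc <- stats_for("noncancerous"); ca <- stats_for("cancerous")
  expect_gt(mean(ca[, "n"]), mean(nc[, "n"]))
  expect_lt(t.test(nc[, "n"], ca[, "n"])$p.value, 0.01)
  expect_lt(mean(ca[, "nn"], na.rm = TRUE), mean(nc[, "nn"], na.rm = TRUE))
  expect_lt(t.test(nc[, "nn"], ca[, "nn"])$p.value, 0.01)
})

test_that("PAH render: geometry, noise-free degenerate cases", {
  p <- scene_params(noise_sd = 0)
  s0 <- generate_scene(scene_params(density = c(noncancerous = 1e-9,
                                                cancerous = 1e-9),
                                    noise_sd = 0),
                       "noncancerous", c(64, 64), seed = 1)
  t0 <- render_pah(s0)
  expect_true(all(t0$pixels == 20))   # constant background
  # one disk: far pixels at background, centre bright
  s1 <- generate_scene(p, "noncancerous", c(64, 64), seed = 2)
  while (nrow(s1$centers) != 1)
    s1 <- generate_scene(p, "noncancerous", c(64, 64),
                         seed = s1$seed + 1L)
  t1 <- render_pah(s1)
  d <- sqrt(outer((1:64 - s1$centers[1, 1])^2, (1:64 - s1$centers[1, 2])^2, "+"))
  expect_true(all(t1$pixels[d > s1$radii[1] + 1] == 20))
  expect_equal(t1$pixels[s1$centers[1, 1], s1$centers[1, 2]], 200)
})

test_that("midpoint threshold on the PAH render recovers the mask", {
  p <- scene_params(radius_min = 4)
  for (seed in 1:3) {
    s <- generate_scene(p, "cancerous", c(64, 64), seed = seed)
    pah <- render_pah(s)
    m <- render_mask(s)
    rec <- (tile_pixels(pah) > (20 + 200) / 2) * 1
    expect_gte(iou(rec, tile_pixels(m)), 0.95)
  }
})

test_that("H&E render shares geometry with PAH and uses the stated palette", {
  p <- scene_params(noise_sd = 0)
  s0 <- generate_scene(scene_params(density = c(noncancerous = 1e-9,
                                                cancerous = 1e-9),
                                    noise_sd = 0),
                       "noncancerous", c(64, 64), seed = 1)
  h0 <- render_he(s0)
  expect_true(all(h0$pixels == 250))  # near-white constant tile
  s <- generate_scene(p, "cancerous", c(64, 64), seed = 5)
  he <- render_he(s); msk <- tile_pixels(render_mask(s))
  px <- he$pixels
  # nucleus pixels: purple (blue channel > green)
  expect_true(all(px[, , 3][msk == 1] >= px[, , 2][msk == 1]))
  # colour-threshold mask matches the analytic mask
  rec <- (px[, , 2] < 120) * 1
  expect_gte(iou(rec, msk), 0.9)
})

test_that("mask render counts lattice pixels exactly", {
  # empty scene -> all-zero mask
  s0 <- generate_scene(scene_params(density = c(noncancerous = 1e-9,
                                                cancerous = 1e-9)),
                       "noncancerous", c(64, 64), seed = 1)
  expect_true(all(tile_pixels(render_mask(s0)) == 0))
  # single disk of radius 5 has 81 lattice pixels
  s <- s0
  s$centers <- matrix(c(32, 32), 1); s$radii <- 5
  expect_equal(sum(tile_pixels(render_mask(s))), 81)
  expect_equal(sum(oracle_disk_mask(64, 64, 32, 32, 5)), 81)
  # union of overlapping disks equals the brute-force pixel union
  s$centers <- matrix(c(30, 30, 34, 36, 10, 50), 3, byrow = TRUE)
  s$radii <- c(5, 4, 6)
  got <- tile_pixels(render_mask(s))
  want <- pmin(oracle_disk_mask(64, 64, 30, 30, 5) +
                 oracle_disk_mask(64, 64, 34, 36, 4) +
                 oracle_disk_mask(64, 64, 10, 50, 6), 1)
  expect_identical(got, want)
})

test_that("datasets are balanced, deterministic, and class-separable", {
  ds <- generate_dataset(3, canvas_size = c(64, 64), seed = 9)
  expect_length(ds, 6)
  expect_equal(sum(vapply(ds, `[[`, "", "label") == "cancerous"), 3)
  ds2 <- generate_dataset(3, canvas_size = c(64, 64), seed = 9)
  expect_identical(lapply(ds, function(i) i$pah$pixels),
                   lapply(ds2, function(i) i$pah$pixels))
  expect_identical(lapply(ds, function(i) i$he$pixels),
                   lapply(ds2, function(i) i$he$pixels))
  # ground-truth-mask features separate the classes by a count threshold
  big <- generate_dataset(100, canvas_size = c(64, 64), seed = 21)
  cnt <- vapply(big, function(it) extract_features(it$mask)$cell_count, 0L)
  lab <- vapply(big, `[[`, "", "label") == "cancerous"
  best <- max(vapply(0:15, function(t) mean((cnt >= t) == lab), 0))
  expect_gte(best, 0.9)
})

test_that("write_dataset produces PNG tiles and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, canvas_size = c(64, 64), seed = 4)
  man <- write_dataset(ds, dir)
  expect_equal(nrow(man), 12)  # 4 items x 3 modalities
  expect_true(all(file.exists(file.path(dir, man$path))))
  back <- read_tile_png(file.path(dir, man$path[man$modality == "PAH"][1]), "PAH")
  expect_equal(back$pixels, ds[[1]]$pah$pixels)
  prm <- file.path(dir, "params.yml")
  yaml::write_yaml(list(density = c(noncancerous = 3, cancerous = 12)), prm)
  p2 <- read_scene_params(prm)
  expect_equal(unname(p2$density), c(3, 12))
  expect_equal(p2$bg_level, 20)   # defaults retained
  expect_error(read_scene_params({
    yaml::write_yaml(list(bogus = 1), prm); prm
  }), "unknown")
})
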