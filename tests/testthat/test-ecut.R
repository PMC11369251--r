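test_that("least-squares adversarial loss follows the closed form", {
  expect_equal(adversarial_loss(matrix(1, 3, 3), matrix(0, 3, 3),
                                side = "discriminator"), 0)
  expect_equal(adversarial_loss(fake_scores = matrix(1, 3, 3),
                                side = "generator"), 0)
  set.seed(1)
  r <- matrix(rnorm(16), 4); f <- matrix(rnorm(16), 4)
  expect_equal(adversarial_loss(r, f, "discriminator"),
               (mean((r - 1)^2) + mean(f^2)) / 2)
  expect_equal(adversarial_loss(fake_scores = f, side = "generator"),
               mean((f - 1)^2))
})

test_that("PatchNCE equals log N under uniform similarity and the brute-force oracle", {
  n <- 16; d <- 8
  # orthonormal rows: positives at similarity 1, all negatives at 0
  q <- diag(n)[, seq_len(n)]
  expect_equal(patchnce_loss(q, q, temperature = 1),
               -log(exp(1) / (exp(1) + (n - 1) * exp(0))), tolerance = 1e-12)
  # all-equal similarities -> exactly log N
  ones <- matrix(1, n, d)
  expect_equal(patchnce_loss(ones, ones, temperature = 0.07), log(n))
  # orthonormal case at tau = 0.07 with N = 256 is within 1e-3 of zero
  q256 <- diag(256)
  expect_lt(patchnce_loss(q256, q256, temperature = 0.07), 1e-3)
  # random features match the independent oracle
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(rnorm(16 * 6), 16); b <- matrix(rnorm(16 * 6), 16)
    expect_equal(patchnce_loss(a, b, 0.07), oracle_patchnce(a, b, 0.07),
                 tolerance = 1e-6)
  }
  expect_error(patchnce_loss(matrix(0, 2, 2), matrix(0, 3, 2)), "shape")
})

test_that("total objective is the stated combination of terms", {
  expect_equal(ecut_total_loss(1, 2, 4, 3), 7)   # 1 + (2+4)/2 + 3
  cfg0 <- ecut_loss_config(w_saliency = 0)
  expect_equal(ecut_total_loss(1, 2, 4, 3, cfg0), 4)  # CUT objective
  set.seed(3)
  for (i in 1:10) {
    tv <- runif(4, 0, 5)
    w <- ecut_loss_config(w_adv = runif(1), w_nce = runif(1),
                          w_saliency = runif(1))
    expect_equal(ecut_total_loss(tv[1], tv[2], tv[3], tv[4], w),
                 w$w_adv * tv[1] + w$w_nce * (tv[2] + tv[3]) / 2 +
                   w$w_saliency * tv[4])
  }
})

test_that("loss graph accounting holds and saliency weight 0 reproduces CUT", {
  set.seed(4)
  gen <- pahisto:::make_generator(4L, 2L)
  disc <- pahisto:::make_discriminator(4L)
  heads <- pahisto:::make_nce_heads(c(3L, 4L, 8L, 16L, 16L), 16L)
  x <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  y <- array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3))
  cfg <- ecut_loss_config(n_patches = 16, proj_dim = 16)
  set.seed(5)
  gl <- pahisto:::ecut_loss_graph(x, y, gen, disc, heads, cfg)
  expect_equal(gl$total$v,
               ecut_total_loss(gl$terms["adv"], gl$terms["nce_x"],
                               gl$terms["nce_y"], gl$terms["saliency"], cfg),
               ignore_attr = TRUE)
  # ablation: with w_saliency = 0 and the same patch sampling, the total is
  # the CUT objective and all shared terms are identical
  cfg0 <- ecut_loss_config(n_patches = 16, proj_dim = 16, w_saliency = 0)
  set.seed(5)
  gl0 <- pahisto:::ecut_loss_graph(x, y, gen, disc, heads, cfg0)
  expect_equal(gl0$terms[c("adv", "nce_x", "nce_y")],
               gl$terms[c("adv", "nce_x", "nce_y")])
  expect_equal(gl0$total$v,
               gl$terms[["adv"]] + (gl$terms[["nce_x"]] + gl$terms[["nce_y"]]) / 2)
})

test_that("learning-rate schedule is flat then decays linearly to zero", {
  expect_equal(lr_schedule(1, 400, 2e-4), 2e-4)
  expect_equal(lr_schedule(200, 400, 2e-4), 2e-4)
  expect_equal(lr_schedule(300, 400, 2e-4), 1e-4)
  expect_equal(lr_schedule(400, 400, 2e-4), 0)
  d <- diff(vapply(201:400, lr_schedule, 0, total = 400, lr0 = 2e-4))
  expect_true(all(abs(d - d[1]) < 1e-18))
})

test_that("integrated gradients recover linear attributions and vanish on constants", {
  set.seed(6)
  w <- matrix(rnorm(64), 8, 8)
  lin <- function(z) pahisto:::ag_mean(pahisto:::ag_affine(
    pahisto:::ag_add(pahisto:::as_ag(z), 0), 1))
  # linear scorer F(x) = sum(w * x) via an ag graph
  scorer <- function(z) {
    prod_ <- pahisto:::new_node(z$v * w, list(z),
                                function(nd) pahisto:::acc_grad(z, nd$g * w))
    s <- pahisto:::ag_mean(prod_)
    pahisto:::ag_affine(s, length(w))
  }
  x <- matrix(runif(64), 8, 8)
  for (steps in c(1, 7, 50)) {
    att <- integrated_gradients(scorer, x, steps = steps)
    expect_equal(unclass(att), w * x, tolerance = 1e-10, ignore_attr = TRUE)
  }
  const <- function(z) pahisto:::ag_affine(pahisto:::ag_mean(z), 0, add = 3)
  attc <- integrated_gradients(const, x, steps = 5)
  expect_true(all(attc == 0))
})

test_that("virtual staining preserves shape and rejects 1-channel input", {
  set.seed(7)
  gen <- pahisto:::make_generator(4L, 2L)
  tile <- image_tile(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)),
                     origin = c(64, 128), modality = "PAH")
  out <- virtual_stain(gen, tile)
  expect_equal(dim(out$pixels), c(32, 32, 3))
  expect_equal(out$origin, c(64L, 128L))
  expect_equal(out$modality, "VHE")
  expect_error(virtual_stain(gen, matrix(0, 32, 32)), "3-channel")
  # fully convolutional: multiple tile sizes through the same weights
  for (sz in c(16, 32, 64)) {
    o <- virtual_stain(gen, array(0, c(sz, sz, 3)))
    expect_equal(dim(o), c(sz, sz, 3))
  }
  d <- pahisto:::make_discriminator(4L)
  for (sz in c(16, 64)) {
    sc <- pahisto:::disc_forward(d, pahisto:::ag_const(array(0, c(sz, sz, 3))))
    expect_equal(length(dim(sc$v)), 3L)
  }
})

test_that("stained tile grids stitch to the source canvas", {
  set.seed(8)
  gen <- pahisto:::make_generator(2L, 1L)
  img <- matrix(sample(0:255, 96 * 96, TRUE), 96, 96)
  grid <- crop_tiles(stack_to_3ch(img), 64, 0.5, modality = "PAH")
  vhe <- virtual_stain(gen, grid)
  out <- stitch_tiles(vhe)
  expect_equal(dim(out), c(96, 96, 3))
})
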