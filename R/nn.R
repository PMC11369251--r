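# Layer constructors and the four network architectures used by the
# framework. All forwards take and return `ag` tensors; images inside the
# networks live on the [-1, 1] scale as (H, W, C) arrays.

nn_conv <- function(kh, kw, cin, cout, sd = 0.02) {
  list(w = ag_var(array(stats::rnorm(kh * kw * cin * cout, 0, sd),
                        dim = c(kh, kw, cin, cout))),
       b = ag_var(numeric(cout)))
}

nn_conv_he <- function(kh, kw, cin, cout) {
  nn_conv(kh, kw, cin, cout, sd = sqrt(2 / (kh * kw * cin)))
}

nn_norm <- function(c) list(gamma = ag_var(rep(1, c)), beta = ag_var(rep(0, c)))

nn_linear <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / cin)
  list(w = ag_var(matrix(stats::rnorm(cin * cout, 0, sd), cin, cout)),
       b = ag_var(numeric(cout)))
}

conv_in_relu <- function(x, cv, nm, stride = 1L, pad = 1L) {
  ag_relu(ag_instnorm(ag_conv2d(x, cv$w, cv$b, stride, pad), nm$gamma, nm$beta))
}

# ---- translation generator -------------------------------------------------
# Encoder (stem + 2 stride-2 downsamplings) -> 9 padding-preserving residual
# blocks -> decoder (2 nearest-upsample + conv stages) -> 7x7 conv + tanh.

make_generator <- function(ngf = 64L, n_res = 9L, cin = 3L, cout = 3L) {
  g <- list(
    stem  = list(cv = nn_conv(7, 7, cin, ngf), nm = nn_norm(ngf)),
    down1 = list(cv = nn_conv(3, 3, ngf, 2 * ngf), nm = nn_norm(2 * ngf)),
    down2 = list(cv = nn_conv(3, 3, 2 * ngf, 4 * ngf), nm = nn_norm(4 * ngf)),
    res = lapply(seq_len(n_res), function(i) list(
      cv1 = nn_conv(3, 3, 4 * ngf, 4 * ngf), nm1 = nn_norm(4 * ngf),
      cv2 = nn_conv(3, 3, 4 * ngf, 4 * ngf), nm2 = nn_norm(4 * ngf))),
    up1 = list(cv = nn_conv(3, 3, 4 * ngf, 2 * ngf), nm = nn_norm(2 * ngf)),
    up2 = list(cv = nn_conv(3, 3, 2 * ngf, ngf), nm = nn_norm(ngf)),
    out = nn_conv(7, 7, ngf, cout)
  )
  structure(g, ngf = ngf, n_res = n_res, cin = cin, cout = cout,
            class = "pahisto_generator")
}

# encoder pass; returns features at the depths sampled by the PatchNCE loss
gen_encode <- function(g, x) {
  f0 <- x
  h <- conv_in_relu(x, g$stem$cv, g$stem$nm, 1L, 3L)
  f1 <- h
  h <- conv_in_relu(h, g$down1$cv, g$down1$nm, 2L, 1L)
  f2 <- h
  h <- conv_in_relu(h, g$down2$cv, g$down2$nm, 2L, 1L)
  f3 <- h
  nres <- length(g$res)
  mid <- max(1L, nres %/% 2L)
  for (i in seq_len(mid)) {
    b <- g$res[[i]]
    r <- conv_in_relu(h, b$cv1, b$nm1, 1L, 1L)
    r <- ag_instnorm(ag_conv2d(r, b$cv2$w, b$cv2$b, 1L, 1L), b$nm2$gamma, b$nm2$beta)
    h <- ag_add(h, r)
  }
  f4 <- h
  list(h = h, mid = mid, feats = list(f0, f1, f2, f3, f4))
}

gen_decode <- function(g, h, mid) {
  nres <- length(g$res)
  if (mid < nres) for (i in seq.int(mid + 1L, nres)) {
    b <- g$res[[i]]
    r <- conv_in_relu(h, b$cv1, b$nm1, 1L, 1L)
    r <- ag_instnorm(ag_conv2d(r, b$cv2$w, b$cv2$b, 1L, 1L), b$nm2$gamma, b$nm2$beta)
    h <- ag_add(h, r)
  }
  h <- conv_in_relu(ag_upsample2(h), g$up1$cv, g$up1$nm, 1L, 1L)
  h <- conv_in_relu(ag_upsample2(h), g$up2$cv, g$up2$nm, 1L, 1L)
  ag_tanh(ag_conv2d(h, g$out$w, g$out$b, 1L, 3L))
}

gen_forward <- function(g, x, with_feats = FALSE) {
  enc <- gen_encode(g, x)
  y <- gen_decode(g, enc$h, enc$mid)
  if (with_feats) list(y = y, feats = enc$feats) else y
}

# ---- 70x70 patch discriminator ---------------------------------------------

make_discriminator <- function(ndf = 64L, cin = 3L) {
  d <- list(
    c1 = nn_conv(4, 4, cin, ndf),
    c2 = list(cv = nn_conv(4, 4, ndf, 2 * ndf), nm = nn_norm(2 * ndf)),
    c3 = list(cv = nn_conv(4, 4, 2 * ndf, 4 * ndf), nm = nn_norm(4 * ndf)),
    c4 = list(cv = nn_conv(4, 4, 4 * ndf, 8 * ndf), nm = nn_norm(8 * ndf)),
    out = nn_conv(4, 4, 8 * ndf, 1L)
  )
  structure(d, ndf = ndf, cin = cin, class = "pahisto_discriminator")
}

disc_forward <- function(d, x) {
  h <- ag_lrelu(ag_conv2d(x, d$c1$w, d$c1$b, 2L, 1L))
  h <- ag_lrelu(ag_instnorm(ag_conv2d(h, d$c2$cv$w, d$c2$cv$b, 2L, 1L),
                            d$c2$nm$gamma, d$c2$nm$beta))
  h <- ag_lrelu(ag_instnorm(ag_conv2d(h, d$c3$cv$w, d$c3$cv$b, 2L, 1L),
                            d$c3$nm$gamma, d$c3$nm$beta))
  h <- ag_lrelu(ag_instnorm(ag_conv2d(h, d$c4$cv$w, d$c4$cv$b, 1L, 1L),
                            d$c4$nm$gamma, d$c4$nm$beta))
  ag_conv2d(h, d$out$w, d$out$b, 1L, 1L)
}

# scalar discriminator output: mean over the patch score map
disc_score <- function(d, x) ag_mean(disc_forward(d, x))

# ---- PatchNCE projection heads ---------------------------------------------

make_nce_heads <- function(feat_channels, proj_dim = 256L) {
  lapply(feat_channels, function(c) list(
    l1 = nn_linear(c, proj_dim), l2 = nn_linear(proj_dim, proj_dim)))
}

nce_project <- function(head, rows) {
  h <- ag_relu(ag_linear(rows, head$l1$w, head$l1$b))
  ag_l2norm_rows(ag_linear(h, head$l2$w, head$l2$b))
}

# ---- U-Net ------------------------------------------------------------------
# 4 downscaling and 4 upscaling levels with skip connections; 1-logit output.

unet_dconv <- function(cin, cout) list(
  c1 = nn_conv_he(3, 3, cin, cout), n1 = nn_norm(cout),
  c2 = nn_conv_he(3, 3, cout, cout), n2 = nn_norm(cout))

unet_dconv_fw <- function(x, blk) {
  h <- conv_in_relu(x, blk$c1, blk$n1, 1L, 1L)
  conv_in_relu(h, blk$c2, blk$n2, 1L, 1L)
}

make_unet <- function(nf = 16L, cin = 3L, depth = 4L) {
  widths <- nf * 2^(0:depth)
  u <- list(
    downs = lapply(seq_len(depth), function(i)
      unet_dconv(if (i == 1) cin else widths[i - 1], widths[i])),
    mid = unet_dconv(widths[depth], widths[depth + 1]),
    upc = lapply(seq_len(depth), function(i)
      nn_conv_he(3, 3, widths[depth + 2 - i], widths[depth + 1 - i])),
    ups = lapply(seq_len(depth), function(i)
      unet_dconv(2 * widths[depth + 1 - i], widths[depth + 1 - i])),
    out = nn_conv_he(1, 1, widths[1], 1L)
  )
  structure(u, nf = nf, cin = cin, depth = depth, class = "pahisto_unet")
}

unet_forward <- function(u, x) {
  depth <- attr(u, "depth")
  skips <- vector("list", depth)
  h <- x
  for (i in seq_len(depth)) {
    h <- unet_dconv_fw(h, u$downs[[i]])
    skips[[i]] <- h
    h <- ag_maxpool2(h)
  }
  h <- unet_dconv_fw(h, u$mid)
  for (i in seq_len(depth)) {
    h <- ag_conv2d(ag_upsample2(h), u$upc[[i]]$w, u$upc[[i]]$b, 1L, 1L)
    h <- ag_concat_c(skips[[depth + 1 - i]], h)
    h <- unet_dconv_fw(h, u$ups[[i]])
  }
  ag_conv2d(h, u$out$w, u$out$b, 1L, 0L)   # logits
}

# ---- ResNet-18-style backbone ----------------------------------------------
# Stem + 4 stages of 2 basic blocks; widths double per stage; global average
# pool to a (8*width)-dim embedding. width = 64 gives the canonical 512-dim
# deep feature vector; tests use reduced widths.

res_block <- function(cin, cout, stride) {
  b <- list(
    c1 = nn_conv_he(3, 3, cin, cout), n1 = nn_norm(cout),
    c2 = nn_conv_he(3, 3, cout, cout), n2 = nn_norm(cout))
  if (stride != 1L || cin != cout)
    b$proj <- nn_conv_he(1, 1, cin, cout)
  attr(b, "stride") <- stride
  b
}

res_block_fw <- function(x, b) {
  s <- attr(b, "stride")
  h <- conv_in_relu(x, b$c1, b$n1, s, 1L)
  h <- ag_instnorm(ag_conv2d(h, b$c2$w, b$c2$b, 1L, 1L), b$n2$gamma, b$n2$beta)
  sk <- if (!is.null(b$proj)) ag_conv2d(x, b$proj$w, b$proj$b, s, 0L) else x
  ag_relu(ag_add(h, sk))
}

make_resnet <- function(width = 64L, cin = 3L) {
  w <- width
  net <- list(
    stem = list(cv = nn_conv_he(3, 3, cin, w), nm = nn_norm(w)),
    s1 = list(res_block(w, w, 1L), res_block(w, w, 1L)),
    s2 = list(res_block(w, 2 * w, 2L), res_block(2 * w, 2 * w, 1L)),
    s3 = list(res_block(2 * w, 4 * w, 2L), res_block(4 * w, 4 * w, 1L)),
    s4 = list(res_block(4 * w, 8 * w, 2L), res_block(8 * w, 8 * w, 1L))
  )
  structure(net, width = w, cin = cin, embed_dim = 8L * w,
            class = "pahisto_resnet")
}

resnet_embed <- function(net, x) {
  h <- conv_in_relu(x, net$stem$cv, net$stem$nm, 1L, 1L)
  for (st in list(net$s1, net$s2, net$s3, net$s4))
    for (b in st) h <- res_block_fw(h, b)
  ag_gap(h)
}
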