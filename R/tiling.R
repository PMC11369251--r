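#' Image tiles
#'
#' The unit image container: an 8-bit pixel grid (values on the 0-255 scale,
#' stored numeric) or a float probability map in [0, 1], together with its
#' 0-based (row, col) origin in a parent slide and a modality tag.
#'
#' @param pixels matrix (H x W) or array (H x W x 3).
#' @param origin integer (row, col), 0-based top-left position in the parent.
#' @param modality one of `"PAH"`, `"VHE"`, `"HE"`, `"MASK"`, `"PROB"`.
#' @return object of class `image_tile`.
#' @export
image_tile <- function(pixels, origin = c(0L, 0L),
                       modality = c("PAH", "VHE", "HE", "MASK", "PROB")) {
  modality <- match.arg(modality)
  if (is.null(dim(pixels))) stop("pixels must be a matrix or 3-d array")
  if (any(origin < 0)) stop("origin must be non-negative")
  if (modality %in% c("PAH", "VHE", "HE") &&
      (min(pixels) < 0 || max(pixels) > 255))
    stop("8-bit tile values must lie in [0, 255]")
  structure(list(pixels = pixels, origin = as.integer(origin),
                 modality = modality), class = "image_tile")
}

#' @export
print.image_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_tile [%s]: %d x %d x %d at origin (%d, %d)\n",
              x$modality, d[1], d[2], if (length(d) > 2) d[3] else 1L,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Pixel array of a tile (pass-through for plain arrays)
#' @param x an [image_tile()] or array.
#' @return the pixel matrix / array.
#' @export
tile_pixels <- function(x) if (inherits(x, "image_tile")) x$pixels else x

n_channels <- function(px) if (length(dim(px)) == 3) dim(px)[3] else 1L

#' Read / write tiles as PNG or TIFF
#'
#' 8-bit modalities are scaled to/from the [0,1] file range; `MASK` tiles are
#' stored as 0/1, `PROB` tiles as raw floats.
#'
#' @param tile an [image_tile()].
#' @param path file path ending in .png, .tif or .tiff.
#' @return `write_tile_png`: the path, invisibly. `read_tile_png`: an
#'   [image_tile()].
#' @export
write_tile_png <- function(tile, path) {
  px <- tile_pixels(tile)
  mod <- if (inherits(tile, "image_tile")) tile$modality else "PAH"
  v <- if (mod %in% c("MASK", "PROB")) px else px / 255
  v <- pmin(pmax(v, 0), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::writeTIFF(v, path) else png::writePNG(v, path)
  invisible(path)
}

#' @rdname write_tile_png
#' @param modality modality tag to attach on read.
#' @param origin origin to attach on read.
#' @export
read_tile_png <- function(path, modality = "PAH", origin = c(0L, 0L)) {
  v <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(v)) == 3 && dim(v)[3] == 4) v <- v[, , 1:3]  # drop alpha
  if (length(dim(v)) == 3 && dim(v)[3] == 1) v <- v[, , 1]
  px <- switch(modality,
               MASK = round(v),
               PROB = v,
               round(v * 255))
  image_tile(px, origin = origin, modality = modality)
}

#' Crop an image into overlapping tiles
#'
#' Cuts `tile_size` x `tile_size` windows at stride
#' `tile_size * (1 - overlap)` using 0-based, row-major, half-open windows.
#' The image is padded with `pad_value` up to the next full stride multiple;
#' the padding extent is recorded on the grid and removed again by
#' [stitch_tiles()].
#'
#' @param image matrix / array or [image_tile()].
#' @param tile_size window side in px (default 512).
#' @param overlap fraction in [0, 1); default 0.5.
#' @param pad_value constant used to pad ragged edges; default 255 (white),
#'   matching the inverted-PAH / H&E background.
#' @param modality modality tag for the produced tiles.
#' @return object of class `tile_grid`: list of tiles plus canvas bookkeeping.
#' @export
crop_tiles <- function(image, tile_size = 512L, overlap = 0.5,
                       pad_value = 255, modality = "PAH") {
  if (tile_size < 1) stop("tile_size must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  px <- tile_pixels(image)
  if (inherits(image, "image_tile")) modality <- image$modality
  stride <- as.integer(round(tile_size * (1 - overlap)))
  if (stride < 1) stop("overlap too large for this tile_size")
  d <- dim(px); H <- d[1]; W <- d[2]; C <- n_channels(px)
  pad_to <- function(n) {
    if (n <= tile_size) return(as.integer(tile_size))
    as.integer(tile_size + stride * ceiling((n - tile_size) / stride))
  }
  Hp <- pad_to(H); Wp <- pad_to(W)
  canvas <- array(pad_value, c(Hp, Wp, C))
  canvas[seq_len(H), seq_len(W), ] <- as.vector(px)
  rows <- seq(0L, Hp - tile_size, by = stride)
  cols <- seq(0L, Wp - tile_size, by = stride)
  tiles <- list()
  for (r in rows) for (cl in cols) {
    win <- canvas[r + seq_len(tile_size), cl + seq_len(tile_size), , drop = FALSE]
    if (C == 1L) win <- win[, , 1]
    tiles[[length(tiles) + 1L]] <- image_tile(win, origin = c(r, cl),
                                              modality = modality)
  }
  structure(list(tiles = tiles, canvas_size = c(H, W),
                 padded_size = c(Hp, Wp), tile_size = as.integer(tile_size),
                 stride = stride, pad_value = pad_value, modality = modality),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d tiles of %d px (stride %d) covering %d x %d (padded %d x %d)\n",
              length(x$tiles), x$tile_size, x$stride, x$canvas_size[1],
              x$canvas_size[2], x$padded_size[1], x$padded_size[2]))
  invisible(x)
}

#' Stitch tiles back into the parent image
#'
#' Overlap-averaged merge: tile values are summed per pixel in float64 and
#' divided by the number of covering tiles; the recorded padding is cropped
#' away. 8-bit modalities are rounded half-away-from-zero so that a
#' crop -> stitch round trip reproduces integer inputs exactly.
#'
#' @param grid a `tile_grid` (tile pixel values may have been replaced, e.g.
#'   by a virtual-staining generator, as long as origins are intact).
#' @return matrix or H x W x 3 array of the stitched canvas.
#' @export
stitch_tiles <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  Hp <- grid$padded_size[1]; Wp <- grid$padded_size[2]
  C <- n_channels(tile_pixels(grid$tiles[[1]]))
  acc <- array(0, c(Hp, Wp, C))
  cnt <- matrix(0, Hp, Wp)
  ts <- grid$tile_size
  for (t in grid$tiles) {
    ri <- t$origin[1] + seq_len(ts); ci <- t$origin[2] + seq_len(ts)
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] +
      array(as.vector(tile_pixels(t)), c(ts, ts, C))
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt[seq_len(grid$canvas_size[1]), seq_len(grid$canvas_size[2])] == 0))
    stop("some canvas pixels are covered by no tile")
  cnt[cnt == 0] <- 1
  for (ch in seq_len(C)) acc[, , ch] <- acc[, , ch] / cnt
  out <- acc[seq_len(grid$canvas_size[1]), seq_len(grid$canvas_size[2]), ,
             drop = FALSE]
  if (!grid$modality %in% c("PROB"))
    out <- sign(out) * floor(abs(out) + 0.5)   # half away from zero
  if (C == 1L) out <- out[, , 1]
  out
}

#' Invert 8-bit intensities (v -> 255 - v)
#'
#' Used to flip pre-inversion PAH tiles (bright nuclei, dark background) into
#' the white-background convention of H&E slides. An involution.
#'
#' @param tile [image_tile()] or plain array on the 0-255 scale.
#' @return same type as the input.
#' @export
invert_intensity <- function(tile) {
  if (inherits(tile, "image_tile")) {
    tile$pixels <- 255 - tile$pixels
    tile
  } else 255 - tile
}

#' Downsample an image by 2 with area averaging
#'
#' Each output pixel is the mean of its 2 x 2 source block (edge rows/cols of
#' odd-sized images average the available pixels); output dims are
#' `ceiling(dims / 2)`; result rounded half-up to the 8-bit grid.
#'
#' @param image matrix or H x W x C array.
#' @return downsampled image of the same kind.
#' @export
downsample_2x <- function(image) {
  px <- tile_pixels(image)
  d <- dim(px); C <- n_channels(px)
  if (d[1] < 2 || d[2] < 2) stop("image must be at least 2 x 2")
  gi <- ceiling(seq_len(d[1]) / 2); gj <- ceiling(seq_len(d[2]) / 2)
  out <- array(0, c(max(gi), max(gj), C))
  for (ch in seq_len(C)) {
    m <- if (C == 1L && length(d) == 2) px else px[, , ch]
    s <- rowsum(m, gi)                 # sum over row pairs
    s <- t(rowsum(t(s), gj))           # then col pairs
    n <- outer(tabulate(gi), tabulate(gj))
    out[, , ch] <- s / n
  }
  out <- floor(out + 0.5)
  if (C == 1L) out[, , 1] else out
}

#' Stack a 1-channel tile to 3 identical channels
#'
#' Grayscale PAH tiles are replicated to 3 channels so source and target of
#' the translation network have matching shape.
#'
#' @param tile 1-channel [image_tile()] or matrix.
#' @return 3-channel tile of the same kind.
#' @export
stack_to_3ch <- function(tile) {
  px <- tile_pixels(tile)
  if (n_channels(px) != 1L) stop("input must be 1-channel")
  m <- if (length(dim(px)) == 3) px[, , 1] else px
  out <- array(rep(m, 3), c(dim(m), 3L))
  if (inherits(tile, "image_tile")) {
    tile$pixels <- out
    tile
  } else out
}

#' Fraction of a tile covered by tissue
#'
#' A pixel counts as tissue when its intensity deviates from the background
#' level by more than `tolerance` in any channel. Tiles below a coverage
#' threshold (the study excluded tiles under 20%) can then be filtered out.
#'
#' @param tile [image_tile()] or array on the 0-255 scale.
#' @param background_level background intensity (default 255, white).
#' @param tolerance allowed deviation still counting as background.
#' @return fraction in [0, 1].
#' @export
tissue_coverage <- function(tile, background_level = 255, tolerance = 10) {
  px <- tile_pixels(tile)
  dev <- abs(px - background_level) > tolerance
  if (length(dim(px)) == 3) dev <- apply(dev, c(1, 2), any)
  mean(dev)
}

#' Save / load a tile grid as PNG files plus a CSV manifest
#'
#' @param grid a `tile_grid`.
#' @param dir output directory.
#' @return `save_tile_grid`: manifest path, invisibly; `load_tile_grid`: the
#'   reconstructed `tile_grid`.
#' @export
save_tile_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(grid$tiles), function(i) {
    t <- grid$tiles[[i]]
    fn <- file.path(dir, sprintf("tile_r%05d_c%05d.png", t$origin[1], t$origin[2]))
    write_tile_png(t, fn)
    data.frame(path = basename(fn), row = t$origin[1], col = t$origin[2])
  })
  man <- do.call(rbind, rows)
  man$canvas_h <- grid$canvas_size[1]; man$canvas_w <- grid$canvas_size[2]
  man$padded_h <- grid$padded_size[1]; man$padded_w <- grid$padded_size[2]
  man$tile_size <- grid$tile_size; man$stride <- grid$stride
  man$pad_value <- grid$pad_value; man$modality <- grid$modality
  fn <- file.path(dir, "grid.csv")
  utils::write.csv(man, fn, row.names = FALSE)
  invisible(fn)
}

#' @rdname save_tile_grid
#' @export
load_tile_grid <- function(dir) {
  man <- utils::read.csv(file.path(dir, "grid.csv"))
  tiles <- lapply(seq_len(nrow(man)), function(i)
    read_tile_png(file.path(dir, man$path[i]), modality = man$modality[1],
                  origin = c(man$row[i], man$col[i])))
  structure(list(tiles = tiles, canvas_size = c(man$canvas_h[1], man$canvas_w[1]),
                 padded_size = c(man$padded_h[1], man$padded_w[1]),
                 tile_size = man$tile_size[1], stride = man$stride[1],
                 pad_value = man$pad_value[1], modality = man$modality[1]),
            class = "tile_grid")
}
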