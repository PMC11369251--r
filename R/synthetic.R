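#' Synthetic tissue scenes and paired renderings
#'
#' The clinical PAH / H&E data this framework was designed around are not
#' publicly distributable, so the package ships a seeded generator of
#' histology-like scenes: random non-overlapping(ish) nucleus disks whose
#' density and size differ between a "noncancerous" and a "cancerous" class,
#' rendered as a grayscale PAH-like tile (bright nuclei on dark background),
#' an H&E-like RGB tile (purple nuclei, pink cytoplasm, white background)
#' and a binary ground-truth nucleus mask. The same scene drives all three
#' renderings, so tests can use pairings the real (unpaired) data never had.
#'
#' @name synthetic_data
NULL

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 16807) %% 2147483647L) + 1L
}

#' Scene generation parameters
#'
#' Densities are nuclei per 10^4 px^2; the cancerous class is denser and has
#' slightly larger nuclei (nuclear crowding and enlargement), so ground-truth
#' nucleus count is higher and nearest-neighbour distance lower for cancerous
#' scenes. Intensities are 8-bit levels chosen so that the soft-threshold
#' saliency sigmoid saturates exactly as it does on real 8-bit data.
#'
#' @param density named numeric, nuclei per 10^4 px^2 per class.
#' @param radius_mean,radius_sd,radius_min named numeric, nucleus radius
#'   distribution (px) per class, truncated below at `radius_min`.
#' @param bg_level,fg_level PAH background / nucleus intensity (pre-inversion).
#' @param noise_sd additive Gaussian noise level (8-bit units).
#' @param he_nucleus,he_cytoplasm,he_background RGB triples of the H&E palette.
#' @param min_sep_factor centres i, j must be at least
#'   `min_sep_factor * (r_i + r_j)` apart; < 1 allows mild overlap.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(density = c(noncancerous = 6, cancerous = 30),
                         radius_mean = c(noncancerous = 4.5, cancerous = 5.5),
                         radius_sd = c(noncancerous = 0.8, cancerous = 0.8),
                         radius_min = 3,
                         bg_level = 20, fg_level = 200, noise_sd = 8,
                         he_nucleus = c(120, 60, 160),
                         he_cytoplasm = c(230, 180, 200),
                         he_background = c(250, 250, 250),
                         min_sep_factor = 0.8) {
  stopifnot(all(density > 0), radius_min >= 1, all(radius_mean > 0))
  p <- list(density = density, radius_mean = radius_mean, radius_sd = radius_sd,
            radius_min = radius_min, bg_level = bg_level, fg_level = fg_level,
            noise_sd = noise_sd, he_nucleus = he_nucleus,
            he_cytoplasm = he_cytoplasm, he_background = he_background,
            min_sep_factor = min_sep_factor)
  class(p) <- "scene_params"
  p
}

#' Read scene parameters from a YAML or JSON file
#' @param path file with any subset of [scene_params()] fields.
#' @return `scene_params` object with defaults filled in.
#' @export
read_scene_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else yaml::read_yaml(path)
  dflt <- scene_params()
  known <- names(dflt)
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown scene parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(raw)) {
    v <- unlist(raw[[nm]])
    if (!is.null(names(dflt[[nm]])) && is.null(names(v)) &&
        length(v) == length(dflt[[nm]])) names(v) <- names(dflt[[nm]])
    dflt[[nm]] <- v
  }
  do.call(scene_params, unclass(dflt))
}

#' Generate a random tissue scene
#'
#' Nucleus count is Poisson with mean `density * area / 1e4`; centres are
#' placed by rejection sampling on the integer pixel lattice honouring the
#' minimum separation; radii are truncated-normal.
#'
#' @param params a [scene_params()] object.
#' @param class_label `"noncancerous"` or `"cancerous"`.
#' @param canvas_size integer (height, width), both >= 64.
#' @param seed integer seed; identical (params, class, canvas, seed) give an
#'   identical scene.
#' @return object of class `tissue_scene` with fields `centers` (n x 2 matrix,
#'   row/col, 1-based), `radii`, `class_label`, `canvas_size`, `seed`.
#' @export
generate_scene <- function(params, class_label = c("noncancerous", "cancerous"),
                           canvas_size = c(64L, 64L), seed = 1L) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(params, "scene_params"), length(canvas_size) == 2)
  if (any(canvas_size < 64)) stop("canvas_size must be at least 64 x 64")
  H <- as.integer(canvas_size[1]); W <- as.integer(canvas_size[2])
  with_seed(seed, {
    lambda <- params$density[[class_label]] * H * W / 1e4
    n <- stats::rpois(1, lambda)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    attempts <- 0L
    max_attempts <- 200L * max(n, 1L)
    while (nrow(centers) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " nuclei with the requested separation; ",
             "density too high for the canvas")
      r <- max(params$radius_min,
               stats::rnorm(1, params$radius_mean[[class_label]],
                            params$radius_sd[[class_label]]))
      ci <- sample.int(H, 1); cj <- sample.int(W, 1)
      ok <- TRUE
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - ci)^2 + (centers[, 2] - cj)^2)
        if (any(dd < params$min_sep_factor * (radii + r))) ok <- FALSE
      }
      if (ok) {
        centers <- rbind(centers, c(ci, cj))
        radii <- c(radii, r)
      }
    }
    structure(list(centers = centers, radii = radii, class_label = class_label,
                   canvas_size = c(H, W), seed = as.integer(seed),
                   params = params),
              class = "tissue_scene")
  })
}

#' @export
print.tissue_scene <- function(x, ...) {
  cat("tissue_scene:", nrow(x$centers), "nuclei,", x$class_label, "class,",
      paste(x$canvas_size, collapse = " x "), "px, seed", x$seed, "\n")
  invisible(x)
}

# distance of every pixel to a disk centre; coverage-based anti-aliasing
disk_coverage <- function(H, W, ci, cj, r) {
  d <- sqrt(outer((seq_len(H) - ci)^2, (seq_len(W) - cj)^2, "+"))
  pmin(pmax(r + 0.5 - d, 0), 1)
}

# max coverage over all disks (scenes may mildly overlap)
scene_coverage <- function(scene) {
  H <- scene$canvas_size[1]; W <- scene$canvas_size[2]
  cov <- matrix(0, H, W)
  for (k in seq_along(scene$radii))
    cov <- pmax(cov, disk_coverage(H, W, scene$centers[k, 1],
                                   scene$centers[k, 2], scene$radii[k]))
  cov
}

#' Render the PAH-like grayscale tile of a scene
#'
#' Bright anti-aliased nucleus disks on a dark background (DNA/RNA absorbs UV
#' strongly, so label-free photoacoustic imaging shows nuclei bright before
#' intensity inversion), plus additive Gaussian noise, clipped to 0-255.
#'
#' @param scene a [generate_scene()] result.
#' @return an [image_tile()] with modality `"PAH"`.
#' @export
render_pah <- function(scene) {
  p <- scene$params
  cov <- scene_coverage(scene)
  img <- p$bg_level + (p$fg_level - p$bg_level) * cov
  if (p$noise_sd > 0)
    img <- img + with_seed(derive_seed(scene$seed, 101L),
                           matrix(stats::rnorm(length(img), 0, p$noise_sd),
                                  nrow(img), ncol(img)))
  image_tile(round(pmin(pmax(img, 0), 255)), modality = "PAH")
}

#' Render the H&E-like RGB tile of a scene
#'
#' White background, pink cytoplasm halo around each nucleus, purple nucleus
#' disks co-located with the PAH rendering of the same scene.
#'
#' @inheritParams render_pah
#' @return an [image_tile()] with modality `"HE"`.
#' @export
render_he <- function(scene) {
  p <- scene$params
  H <- scene$canvas_size[1]; W <- scene$canvas_size[2]
  nuc <- scene_coverage(scene)
  cyto <- matrix(0, H, W)
  for (k in seq_along(scene$radii))
    cyto <- pmax(cyto, disk_coverage(H, W, scene$centers[k, 1],
                                     scene$centers[k, 2], 2.2 * scene$radii[k]))
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    base <- p$he_background[ch] + (p$he_cytoplasm[ch] - p$he_background[ch]) * cyto
    img[, , ch] <- base + (p$he_nucleus[ch] - base) * nuc
  }
  if (p$noise_sd > 0)
    img <- img + with_seed(derive_seed(scene$seed, 202L),
                           array(stats::rnorm(length(img), 0, p$noise_sd), dim(img)))
  image_tile(round(pmin(pmax(img, 0), 255)), modality = "HE")
}

#' Render the binary ground-truth nucleus mask of a scene
#'
#' A pixel is foreground iff its lattice coordinate lies within distance
#' `r` of some nucleus centre.
#'
#' @inheritParams render_pah
#' @return an [image_tile()] with modality `"MASK"`, pixel values 0/1.
#' @export
render_mask <- function(scene) {
  H <- scene$canvas_size[1]; W <- scene$canvas_size[2]
  m <- matrix(0, H, W)
  for (k in seq_along(scene$radii)) {
    d2 <- outer((seq_len(H) - scene$centers[k, 1])^2,
                (seq_len(W) - scene$centers[k, 2])^2, "+")
    m[d2 <= scene$radii[k]^2] <- 1
  }
  image_tile(m, modality = "MASK")
}

#' Generate a balanced synthetic dataset
#'
#' @param n_per_class items per class (>= 1).
#' @param params a [scene_params()] object.
#' @param canvas_size tile size in px.
#' @param seed master seed; per-item seeds are derived deterministically.
#' @return list of items, each `list(pah, he, mask, label, scene)`; exactly
#'   `n_per_class` per class, noncancerous first.
#' @export
generate_dataset <- function(n_per_class, params = scene_params(),
                             canvas_size = c(64L, 64L), seed = 1L) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("noncancerous", "cancerous"), each = n_per_class)
  lapply(seq_along(labels), function(i) {
    sc <- generate_scene(params, labels[i], canvas_size,
                         seed = derive_seed(seed, i))
    list(pah = render_pah(sc), he = render_he(sc), mask = render_mask(sc),
         label = labels[i], scene = sc)
  })
}

#' Write a dataset to PNG tiles plus a CSV manifest
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame (path relative to `dir`,
#'   modality, label, seed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(dataset)) {
    it <- dataset[[i]]
    for (mod in c("pah", "he", "mask")) {
      fn <- file.path(dir, sprintf("tile%04d_%s.png", i, mod))
      write_tile_png(it[[mod]], fn)
      rows[[length(rows) + 1L]] <- data.frame(
        path = basename(fn), modality = toupper(mod), item = i,
        label = it$label, seed = it$scene$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
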