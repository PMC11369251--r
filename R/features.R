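#' Nucleus morphometry from binary masks
#'
#' Connected components (8-connectivity) of a binary nucleus mask with pixel
#' area at least `min_area` are treated as nuclei. Three per-tile features
#' summarise them: mean nucleus area (px^2), nucleus count, and the mean
#' distance between nucleus centres, where each centre is the centre of the
#' component's minimum enclosing circle. "Distance" defaults to the mean
#' nearest-neighbour distance; the all-pairs mean is available as an option.
#'
#' @name morphometry
NULL

# minimum enclosing circle (Welzl, move-to-front) of an n x 2 point matrix
min_enclosing_circle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  circ2 <- function(a, b) list(center = (a + b) / 2,
                               radius = sqrt(sum((a - b)^2)) / 2)
  circ3 <- function(a, b, c) {
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      # collinear: widest pair
      cand <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      return(cand[[which.max(vapply(cand, `[[`, 0, "radius"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
    list(center = c(ux, uy), radius = sqrt(sum((a - c(ux, uy))^2)))
  }
  inside <- function(circ, p) sqrt(sum((p - circ$center)^2)) <= circ$radius + 1e-9
  circ <- circ2(pts[1, ], pts[2, ])
  if (n >= 3) for (i in 3:n) {
    p <- pts[i, ]
    if (inside(circ, p)) next
    circ <- circ2(pts[1, ], p)
    for (j in seq_len(i - 1)) {
      q <- pts[j, ]
      if (inside(circ, q)) next
      circ <- circ2(p, q)
      for (k in seq_len(j - 1)) {
        r <- pts[k, ]
        if (!inside(circ, r)) circ <- circ3(p, q, r)
      }
    }
  }
  circ
}

#' Extract per-tile segmentation features from a binary mask
#'
#' @param mask binary H x W matrix (or `MASK` [image_tile()]).
#' @param min_area components smaller than this many pixels are treated as
#'   speckle and dropped (default 10).
#' @param distance `"nn"` (mean nearest-neighbour distance between centres,
#'   default) or `"allpairs"` (mean over all centre pairs).
#' @return object of class `segmentation_features`: list with `cell_count`
#'   (integer >= 0), `cell_area` (mean component area in px^2, `NA` when the
#'   count is 0), `mean_distance` (px, `NA` when the count is < 2) and
#'   `centers` (n x 2 matrix of circle centres, row/col).
#' @export
extract_features <- function(mask, min_area = 10, distance = c("nn", "allpairs")) {
  distance <- match.arg(distance)
  m <- tile_pixels(mask)
  if (length(dim(m)) == 3) m <- m[, , 1]
  lab <- cpp_label8(matrix(as.integer(m != 0), nrow(m), ncol(m)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  count <- length(keep)
  if (count == 0)
    return(structure(list(cell_count = 0L, cell_area = NA_real_,
                          mean_distance = NA_real_,
                          centers = matrix(numeric(0), 0, 2)),
                     class = "segmentation_features"))
  centers <- t(vapply(keep, function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    min_enclosing_circle(pix)$center
  }, numeric(2)))
  md <- NA_real_
  if (count >= 2) {
    dm <- as.matrix(stats::dist(centers))
    md <- if (distance == "nn") {
      diag(dm) <- Inf
      mean(apply(dm, 1, min))
    } else mean(dm[upper.tri(dm)])
  }
  structure(list(cell_count = count, cell_area = mean(sizes[keep]),
                 mean_distance = md, centers = centers),
            class = "segmentation_features")
}

#' @export
print.segmentation_features <- function(x, ...) {
  cat(sprintf("segmentation_features: count=%d, area=%s px^2, distance=%s px\n",
              x$cell_count,
              ifelse(is.na(x$cell_area), "NA", sprintf("%.1f", x$cell_area)),
              ifelse(is.na(x$mean_distance), "NA", sprintf("%.1f", x$mean_distance))))
  invisible(x)
}

#' Interquartile-range outlier fence
#'
#' Retains values in `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with linear-interpolation
#' quartiles; order is preserved and the output is a subset of the input.
#'
#' @param values numeric vector (NA values are dropped first).
#' @return the retained values.
#' @export
iqr_filter <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(values)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

#' Per-tile feature table
#'
#' Runs segmentation (or uses supplied ground-truth masks) over a set of
#' tiles and tabulates the three morphometric features per tile. Undefined
#' features are `NA` (written as empty cells by `write.csv`).
#'
#' @param tiles list of 1- or 3-channel tiles.
#' @param model a trained `unet_model`, or NULL to use `masks`.
#' @param masks optional list of binary masks (the ground-truth bypass).
#' @param labels optional per-tile class labels.
#' @param modality modality tag recorded in the table.
#' @param min_area,distance passed to [extract_features()].
#' @param tta passed to [predict_mask()].
#' @return data.frame with columns tile, modality, label, cell_area,
#'   cell_count, mean_distance.
#' @export
feature_table <- function(tiles, model = NULL, masks = NULL, labels = NULL,
                          modality = "VHE", min_area = 10,
                          distance = c("nn", "allpairs"), tta = TRUE) {
  distance <- match.arg(distance)
  if (is.null(model) && is.null(masks))
    stop("supply a segmentation model or ground-truth masks")
  n <- if (is.null(masks)) length(tiles) else length(masks)
  rows <- lapply(seq_len(n), function(i) {
    m <- if (!is.null(masks)) tile_pixels(masks[[i]])
         else predict_mask(model, tiles[[i]], tta = tta)
    f <- extract_features(m, min_area = min_area, distance = distance)
    data.frame(tile = i, modality = modality,
               label = if (is.null(labels)) NA_character_ else labels[i],
               cell_area = f$cell_area, cell_count = f$cell_count,
               mean_distance = f$mean_distance)
  })
  do.call(rbind, rows)
}

#' Per-class feature summary, with and without IQR fencing
#'
#' @param table a [feature_table()] result with labels.
#' @return data.frame of per-class means of each feature, computed on the
#'   raw values and on the IQR-fenced values.
#' @export
feature_summary <- function(table) {
  stopifnot(all(c("label", "cell_area", "cell_count", "mean_distance") %in%
                  names(table)))
  out <- list()
  for (lb in unique(table$label)) {
    sub <- table[table$label == lb, ]
    for (f in c("cell_area", "cell_count", "mean_distance")) {
      v <- sub[[f]]
      out[[length(out) + 1L]] <- data.frame(
        label = lb, feature = f,
        mean_raw = mean(v, na.rm = TRUE),
        mean_iqr = mean(iqr_filter(v)),
        n_raw = sum(!is.na(v)), n_iqr = length(iqr_filter(v)))
    }
  }
  do.call(rbind, out)
}

#' Read (image, mask) pair directories
#'
#' Generic loader for external segmentation datasets laid out as parallel
#' image and mask directories with matching file names.
#'
#' @param image_dir,mask_dir directories of PNG/TIFF files.
#' @return list of `list(image, mask)` pairs usable by [train_unet()].
#' @export
read_pair_dir <- function(image_dir, mask_dir) {
  imgs <- sort(list.files(image_dir, "\\.(png|tiff?)$", full.names = TRUE,
                          ignore.case = TRUE))
  if (length(imgs) == 0) stop("no images found in ", image_dir)
  lapply(imgs, function(f) {
    mf <- file.path(mask_dir, basename(f))
    if (!file.exists(mf)) stop("no mask for ", basename(f))
    list(image = read_tile_png(f, "HE"), mask = read_tile_png(mf, "MASK"))
  })
}
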