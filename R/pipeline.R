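#' Run configuration and the end-to-end pipeline
#'
#' A run configuration bundles the per-stage sub-configurations (scene
#' generation, tiling, virtual-staining, segmentation, classification,
#' metrics) with a single global seed that fans out to fixed per-stage
#' seeds, so each stage is independently reproducible. Defaults are the
#' full-scale recipe (512-px tiles with 50% overlap, staining at lr 2e-4
#' for 400 epochs, U-Net at lr 1e-4 batch 64, classifier at lr 1e-4 batch
#' 32, saliency thresholds 90/170); tests and the examples use the reduced
#' desk profile by overriding sizes and epochs.
#'
#' @name cli_config
NULL

pipeline_defaults <- function() list(
  seed = 1L,
  out_dir = "pahisto_run",
  verbose = TRUE,
  stages = c("synth", "stain", "segment", "classify", "probmap", "metrics"),
  data = list(n_per_class = 10L, canvas = 64L),
  scene = lapply(unclass(scene_params()), function(x) x),
  tiling = list(tile_size = 512L, overlap = 0.5, pad_value = 255),
  ecut = list(epochs = 400L, lr = 2e-4, ngf = 64L, ndf = 64L, n_res = 9L,
              w_adv = 1, w_nce = 1, w_saliency = 1, temperature = 0.07,
              n_patches = 256L, proj_dim = 256L,
              x_threshold = 90, y_threshold = 170, slope = 100),
  unet = list(epochs = 300L, lr = 1e-4, batch = 64L, nf = 16L,
              patience = 20L, val_frac = 0.2),
  stepff = list(epochs = 1000L, lr = 1e-4, batch = 32L, width = 64L,
                folds = 5L, patience = 10L, gamma = 2, alpha = 0.5),
  metrics = list(extractor = "lightweight-test", kid_blocks = 1L)
)

merge_config <- function(dflt, raw, path = "") {
  for (nm in names(raw)) {
    if (!nm %in% names(dflt))
      stop("unknown configuration key: ", paste0(path, nm))
    if (is.list(dflt[[nm]]) && !is.null(names(dflt[[nm]]))) {
      if (!is.list(raw[[nm]]))
        stop("configuration key ", paste0(path, nm), " must be a mapping")
      dflt[[nm]] <- merge_config(dflt[[nm]], raw[[nm]], paste0(path, nm, "."))
    } else {
      v <- raw[[nm]]
      if (!is.null(names(dflt[[nm]])) && is.null(names(v)) &&
          length(v) == length(dflt[[nm]])) names(v) <- names(dflt[[nm]])
      dflt[[nm]] <- v
    }
  }
  dflt
}

#' Validate a raw configuration against the schema and fill defaults
#'
#' @param raw a named list, a YAML/JSON file path, or NULL for all-defaults.
#' @return object of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (grepl("\\.json$", raw, ignore.case = TRUE))
      jsonlite::read_json(raw, simplifyVector = TRUE) else yaml::read_yaml(raw)
  }
  if (is.null(raw)) raw <- list()
  cfg <- merge_config(pipeline_defaults(), raw)
  if (cfg$tiling$overlap < 0 || cfg$tiling$overlap >= 1)
    stop("tiling.overlap must lie in [0, 1)")
  if (cfg$tiling$tile_size < 1) stop("tiling.tile_size must be positive")
  if (cfg$data$n_per_class < 1) stop("data.n_per_class must be >= 1")
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#' @param cfg a `run_config`.
#' @param path output file; `validate_config(path)` restores it losslessly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  sem <- unclass(cfg)
  sem$out_dir <- NULL   # where results land is not a semantic field
  sem$verbose <- NULL
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(sem, tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline: synth -> stain -> segment -> classify -> probmap
#'
#' Executes the configured stages in dependency order on synthetic data:
#' scene generation and rendering, virtual staining of the inverted PAH
#' tiles, U-Net segmentation feeding per-tile morphometric features, StepFF
#' cross-validated classification, a stitched cancer-probability map of a
#' montage slide, and FID/KID between real-style and virtually stained
#' tiles. When the `stain` stage is disabled the classifier runs as the
#' PAH(+segmentation) ablation and generation metrics are skipped.
#'
#' @param config a `run_config` from [validate_config()].
#' @return list with the artifact `manifest` (file, stage, md5), the
#'   `config_hash`, and in-memory stage results (`stepff`, `features`,
#'   `metrics`, ...).
#' @export
run_pipeline <- function(config = validate_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), stage = character(0))
  emit <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(file = path, stage = stage))
    path
  }
  say <- function(...) if (isTRUE(config$verbose)) message("[pahisto] ", ...)
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("stage %-9s done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }
  sp <- do.call(scene_params, config$scene)
  canvas <- rep(as.integer(config$data$canvas), 2)

  ## synth
  ds <- run_stage("synth", generate_dataset(
    config$data$n_per_class, sp, canvas, seed = derive_seed(config$seed, 1L)))
  labels <- vapply(ds, `[[`, "", "label")
  pah_inv <- lapply(ds, function(it) stack_to_3ch(invert_intensity(it$pah)))
  he <- lapply(ds, function(it) it$he)
  masks <- lapply(ds, function(it) tile_pixels(it$mask))
  write_dataset(ds[seq_len(min(4, length(ds)))],
                file.path(config$out_dir, "tiles"))
  for (f in list.files(file.path(config$out_dir, "tiles"), full.names = TRUE))
    emit(f, "synth")

  ## stain
  vhe <- NULL; ecut <- NULL
  if ("stain" %in% config$stages) {
    ec <- config$ecut
    ecut <- run_stage("stain", train_ecut(
      pah_inv, he,
      loss_cfg = ecut_loss_config(ec$w_adv, ec$w_nce, ec$w_saliency,
                                  ec$temperature, ec$n_patches, ec$proj_dim,
                                  ec$x_threshold, ec$y_threshold, ec$slope),
      train_cfg = ecut_train_config(ec$epochs, ec$lr, ngf = ec$ngf,
                                    ndf = ec$ndf, n_res = ec$n_res,
                                    seed = derive_seed(config$seed, 2L))))
    vhe <- lapply(pah_inv, function(t) virtual_stain(ecut, t))
    hist_fn <- file.path(config$out_dir, "ecut_history.json")
    jsonlite::write_json(ecut$history, hist_fn, digits = NA)
    emit(hist_fn, "stain")
  }

  ## segment
  seg_feats <- NULL; unet <- NULL; ftab <- NULL
  if ("segment" %in% config$stages) {
    uc <- config$unet
    seg_train <- lapply(seq_along(ds), function(i)
      list(image = he[[i]], mask = masks[[i]]))
    unet <- run_stage("segment", train_unet(seg_train, unet_train_config(
      lr = uc$lr, batch = uc$batch, epochs = uc$epochs, patience = uc$patience,
      val_frac = uc$val_frac, nf = uc$nf,
      seed = derive_seed(config$seed, 3L))))
    vhe_like <- if (is.null(vhe)) he else vhe
    tab_p <- feature_table(pah_inv, model = unet, labels = labels,
                           modality = "PAH")
    tab_v <- feature_table(vhe_like, model = unet, labels = labels,
                           modality = if (is.null(vhe)) "HE" else "VHE")
    ftab <- rbind(tab_p, tab_v)
    fn <- file.path(config$out_dir, "features.csv")
    utils::write.csv(ftab, fn, row.names = FALSE)
    emit(fn, "segment")
    seg_feats <- lapply(seq_along(ds), function(i)
      c(tab_p$cell_area[i], tab_p$cell_count[i], tab_p$mean_distance[i],
        tab_v$cell_area[i], tab_v$cell_count[i], tab_v$mean_distance[i]))
  }

  ## classify
  stepff <- NULL
  if ("classify" %in% config$stages) {
    mods <- c("pah", if (!is.null(vhe)) "vhe", if (!is.null(seg_feats)) "seg")
    sc <- config$stepff
    items <- lapply(seq_along(ds), function(i) list(
      pah = tile_pixels(invert_intensity(ds[[i]]$pah)),
      vhe = if (is.null(vhe)) NULL else tile_pixels(vhe[[i]]),
      seg = if (is.null(seg_feats)) NULL else seg_feats[[i]],
      label = labels[i]))
    stepff <- run_stage("classify", train_stepff(items, stepff_config(
      modalities = mods, width = sc$width, lr = sc$lr, batch = sc$batch,
      epochs = sc$epochs, patience = sc$patience, folds = sc$folds,
      gamma = sc$gamma, alpha = sc$alpha,
      seed = derive_seed(config$seed, 4L))))
    fn <- file.path(config$out_dir, "cv_metrics.csv")
    utils::write.csv(stepff$metrics, fn, row.names = FALSE)
    emit(fn, "classify")
  }

  ## probability map over a montage slide of the dataset tiles
  probmap <- NULL
  if ("probmap" %in% config$stages && !is.null(stepff)) {
    probmap <- run_stage("probmap", {
      n <- length(ds); side <- ceiling(sqrt(n)); ts <- canvas[1]
      rows <- ceiling(n / side)
      # fill the trailing cells of the montage with background so every
      # canvas pixel is covered; fillers render at probability 0
      ncell <- rows * side
      tiles <- lapply(seq_len(ncell), function(i) image_tile(
        if (i <= n) tile_pixels(ds[[i]]$he) else matrix(255, ts, ts),
        origin = c(((i - 1) %/% side) * ts, ((i - 1) %% side) * ts),
        modality = "HE"))
      grid <- structure(list(
        tiles = tiles, canvas_size = c(rows * ts, side * ts),
        padded_size = c(rows * ts, side * ts), tile_size = ts, stride = ts,
        pad_value = 255, modality = "HE"), class = "tile_grid")
      pm <- probability_map(c(stepff$oof_probs, rep(0, ncell - n)), grid)
      fn <- file.path(config$out_dir, "probability_map.png")
      png::writePNG(pm / 255, fn)
      emit(fn, "probmap")
      pm
    })
  }

  ## generation metrics
  gm <- NULL
  if ("metrics" %in% config$stages && !is.null(vhe)) {
    gm <- run_stage("metrics", generation_metrics(
      he, vhe, extractor = config$metrics$extractor,
      kid_blocks = config$metrics$kid_blocks))
    fn <- file.path(config$out_dir, "generation_metrics.json")
    jsonlite::write_json(gm, fn, auto_unbox = TRUE, digits = NA)
    emit(fn, "metrics")
  }

  manifest$md5 <- unname(tools::md5sum(manifest$file))
  mf <- file.path(config$out_dir, "manifest.csv")
  utils::write.csv(cbind(manifest, config_hash = config_hash(config)), mf,
                   row.names = FALSE)
  list(manifest = manifest, config_hash = config_hash(config),
       dataset = ds, ecut = ecut, unet = unet, features = ftab,
       stepff = stepff, probmap = probmap, metrics = gm)
}
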