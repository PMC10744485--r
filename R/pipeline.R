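#' @include phantom.R volume-roi.R drr.R xray-prep.R train.R evaluation.R
NULL

pipelineStages <- c("phantoms", "crop", "drr", "preprocess", "package",
                    "split", "train", "evaluate", "angle_sweep")

#' Validate a pipeline configuration
#'
#' Checks that every stage's required fields are present and well formed
#' before any work starts. The transfer function control points must be
#' given explicitly (six strictly increasing (intensity, opacity) pairs).
#'
#' @param config a nested list (see `inst/extdata/pipeline_small.yaml` for
#'   the layout) or a YAML file path.
#' @return The normalized configuration list, invisibly usable downstream.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  req <- function(ok, what) if (!ok) stop("invalid pipeline config: ", what)
  req(!is.null(config$out_dir), "out_dir is required")
  req(!is.null(config$seed), "seed is required")
  req(!is.null(config$phantom$n_cases), "phantom.n_cases is required")
  req(!is.null(config$drr$tf_points), "drr.tf_points (transfer function) is required")
  tfp <- do.call(rbind, lapply(config$drr$tf_points, as.numeric))
  req(is.matrix(tfp) && nrow(tfp) == 6L && ncol(tfp) == 2L,
      "drr.tf_points must be six (intensity, opacity) pairs")
  config$drr$tf_points <- tfp
  req(!is.null(config$gan$volume_size), "gan.volume_size is required")
  req(!is.null(config$gan$n_epochs), "gan.n_epochs is required")
  config$drr$intensity_scale <- config$drr$intensity_scale %||% 2500
  config$drr$step_mm <- config$drr$step_mm %||% 1
  config$drr$image_size <- config$drr$image_size %||% 128L
  config$preprocess$out_size <- config$preprocess$out_size %||% 128L
  config$split$train_frac <- config$split$train_frac %||% 0.8
  config$metrics$angles <- config$metrics$angles %||% c(90, 85, 80, 75)
  config$metrics$ssim_win <- config$metrics$ssim_win %||% 11L
  config
}

pipelineSpec <- function(config) {
  ph <- config$phantom
  phantomSpec(
    nVertebrae = ph[["n_vertebrae"]] %||% 3L,
    bodyRadiusMm = as.numeric(ph[["body_radius_mm"]] %||% c(9, 13)),
    bodyHeightMm = as.numeric(ph[["body_height_mm"]] %||% c(8, 12)),
    discGapMm = ph[["disc_gap_mm"]] %||% 4,
    archEnabled = ph[["arch_enabled"]] %||% TRUE,
    noiseSd = ph[["noise_sd"]] %||% 20,
    volumeShape = as.integer(ph[["volume_shape"]] %||% 64L),
    voxelSizeMm = as.numeric(ph[["voxel_size_mm"]] %||% 1))
}

pipelineGanConfig <- function(config) {
  g <- config$gan
  lw <- g$loss_weights
  ganConfig(
    learningRate = g[["learning_rate"]] %||% 2e-4,
    beta1 = g[["beta1"]] %||% 0.5, beta2 = g[["beta2"]] %||% 0.99,
    batchSize = g[["batch_size"]] %||% 1L,
    nEpochs = g[["n_epochs"]], baseChannels = g[["base_channels"]] %||% 16L,
    volumeSize = g[["volume_size"]],
    lossWeights = lossWeights(wGan = lw[["gan"]] %||% 0.1,
                              wRecon = lw[["recon"]] %||% 10,
                              wProj = lw[["proj"]] %||% 10,
                              wFm = lw[["fm"]] %||% 10,
                              wIdt = lw[["idt"]] %||% 5),
    seed = as.integer(config$seed),
    checkpointEvery = g[["checkpoint_every"]] %||% 0L)
}

caseIdsOf <- function(config)
  sprintf("case_%03d", seq_len(config$phantom$n_cases))

#' Run the full reconstruction pipeline
#'
#' Executes, in order, the requested stages of
#' phantom generation, mask cropping, DRR synthesis, X-ray preprocessing,
#' paired-sample packaging, train/test splitting, GAN training, evaluation
#' and the angle sweep, under a single seeded configuration. Any subset of
#' stages can be run (resuming from prior artifacts on disk); the first
#' failing stage aborts with a stage-named error, retaining partial
#' artifacts. A manifest CSV listing every artifact with its stage and seed
#' is (re)written after each run.
#'
#' @param config configuration list or YAML path; see
#'   [validatePipelineConfig()].
#' @param stages character vector of stages to run (default: all, in
#'   canonical order).
#' @param verbose print stage progress.
#' @return Invisibly, the output directory. Side effects: artifacts under
#'   `out_dir` (`cases/`, `cropped/`, `drr/`, `prep/`, `packaged/`,
#'   `split.csv`, `train/`, `eval/`, `manifest.csv`).
#' @export
runPipeline <- function(config, stages = pipelineStages, verbose = FALSE) {
  config <- validatePipelineConfig(config)
  stages <- match.arg(stages, pipelineStages, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  ids <- caseIdsOf(config)
  manifest <- list()
  note <- function(stage, paths) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, path = as.character(paths), seed = seed)
  }
  runStage <- function(stage, fn) {
    if (!(stage %in% stages)) return(invisible(NULL))
    if (verbose) message("[", stage, "] ...")
    t0 <- Sys.time()
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (verbose)
      message("[", stage, "] done in ",
              format(Sys.time() - t0, digits = 3))
  }
  tf <- opacityTransferFunction(config$drr$tf_points)
  geom <- projectionGeometry(
    imageSize = as.integer(config$drr$image_size),
    intensityScale = config$drr$intensity_scale,
    stepMm = config$drr$step_mm)

  runStage("phantoms", function() {
    dirs <- generateCohort(config$phantom$n_cases, seed = seed,
                           outDir = file.path(out, "cases"),
                           specRanges = pipelineSpec(config),
                           nVertebraeRange =
                             as.integer(config$phantom$n_vertebrae_range %||%
                                          c(2L, 4L)))
    note("phantoms", c(file.path(dirs, "ct.nii.gz"),
                       file.path(dirs, "mask.nii.gz")))
  })

  runStage("crop", function() {
    for (id in ids) {
      vol <- readVolume(file.path(out, "cases", id, "ct.nii.gz"))
      mask <- readMask(file.path(out, "cases", id, "mask.nii.gz"))
      cr <- cropToMask(vol, mask)
      d <- file.path(out, "cropped", id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      writeVolume(cr$ct, file.path(d, "ct.nii.gz"))
      writeMask(cr$mask, file.path(d, "mask.nii.gz"))
      note("crop", file.path(d, c("ct.nii.gz", "mask.nii.gz")))
    }
  })

  runStage("drr", function() {
    for (id in ids) {
      vol <- readVolume(file.path(out, "cropped", id, "ct.nii.gz"))
      bp <- makeBiplanar(vol, tf, lateralAngleDeg = 90, geom = geom)
      d <- file.path(out, "drr", id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      fa <- file.path(d, paste0(id, "_anterior.png"))
      fl <- file.path(d, paste0(id, "_lateral.png"))
      writeXRay(bp$anterior, fa)
      writeXRay(bp$lateral, fl)
      note("drr", c(fa, fl))
    }
  })

  runStage("preprocess", function() {
    for (id in ids) {
      d <- file.path(out, "prep", id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (view in c("anterior", "lateral")) {
        src <- file.path(out, "drr", id, paste0(id, "_", view, ".png"))
        img <- preprocessXray(src,
                              outSize = as.integer(config$preprocess$out_size))
        fp <- file.path(d, paste0(view, ".png"))
        writeXRay(img, fp)
        note("preprocess", fp)
      }
    }
  })

  runStage("package", function() {
    d <- file.path(out, "packaged")
    dir.create(d, showWarnings = FALSE)
    for (id in ids) {
      ct <- readVolume(file.path(out, "cropped", id, "ct.nii.gz"))
      x1 <- readXRay(file.path(out, "prep", id, "anterior.png"))
      x2 <- readXRay(file.path(out, "prep", id, "lateral.png"))
      fp <- file.path(d, paste0(id, ".rds"))
      packageCase(ct, x1, x2, fp,
                  intensityScale = config$drr$intensity_scale)
      note("package", fp)
    }
  })

  runStage("split", function() {
    sp <- splitCases(ids, trainFrac = config$split$train_frac, seed = seed)
    writeSplit(sp, file.path(out, "split.csv"))
    note("split", file.path(out, "split.csv"))
  })

  runStage("train", function() {
    sp <- readSplit(file.path(out, "split.csv"))
    dataset <- lapply(sp@trainIds, function(id) {
      cs <- readCase(file.path(out, "packaged", paste0(id, ".rds")))
      pairedSample(cs$ct, xrayImage(cs$xray1), xrayImage(cs$xray2), id)
    })
    res <- trainGan(dataset, pipelineGanConfig(config),
                    logDir = file.path(out, "train"),
                    augment = config$gan$augment %||% TRUE,
                    verbose = verbose)
    note("train", c(file.path(out, "train", "loss_log.csv"),
                    res$checkpoints))
  })

  loadTrainedGenerator <- function() {
    cks <- sort(list.files(file.path(out, "train"),
                           pattern = "^checkpoint_epoch.*\\.rds$",
                           full.names = TRUE))
    if (!length(cks)) stop("no checkpoint found; run the train stage first")
    ck <- readRDS(cks[length(cks)])
    restoreNet(buildGenerator(pipelineGanConfig(config)),
               ck$generator)
  }

  runStage("evaluate", function() {
    sp <- readSplit(file.path(out, "split.csv"))
    gen <- loadTrainedGenerator()
    N <- gen$cfg@volumeSize
    pairs <- lapply(sp@testIds, function(id) {
      cs <- readCase(file.path(out, "packaged", paste0(id, ".rds")))
      pred <- predictVolume(gen, cs$xray1, cs$xray2)
      list(gt = resizeVolume(cs$ct, rep(N, 3L)), pred = pred)
    })
    repObj <- evaluatePairs(pairs,
                         maxIntensity = config$metrics$max_intensity %||%
                           config$drr$intensity_scale,
                         ssimWinSize = as.integer(config$metrics$ssim_win))
    d <- file.path(out, "eval")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(metricTable(repObj), file.path(d, "metrics.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(metricTable(repObj),
                                           row.names = FALSE)),
               file.path(d, "metrics.txt"))
    note("evaluate", file.path(d, c("metrics.csv", "metrics.txt")))
  })

  runStage("angle_sweep", function() {
    sp <- readSplit(file.path(out, "split.csv"))
    gen <- loadTrainedGenerator()
    vols <- lapply(sp@testIds, function(id)
      readVolume(file.path(out, "cropped", id, "ct.nii.gz")))
    sw <- angleSweep(gen, vols,
                     angles = as.numeric(config$metrics$angles), tf = tf,
                     geom = geom,
                     outSize = as.integer(config$preprocess$out_size),
                     maxIntensity = config$metrics$max_intensity %||%
                       config$drr$intensity_scale,
                     ssimWinSize = as.integer(config$metrics$ssim_win))
    d <- file.path(out, "eval")
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(sweepTable(sw), file.path(d, "angle_sweep.csv"),
                     row.names = FALSE)
    writeLines(utils::capture.output(print(sweepTable(sw),
                                           row.names = FALSE)),
               file.path(d, "angle_sweep.txt"))
    note("angle_sweep", file.path(d, c("angle_sweep.csv", "angle_sweep.txt")))
  })

  if (length(manifest)) {
    mf <- do.call(rbind, manifest)
    mfPath <- file.path(out, "manifest.csv")
    if (file.exists(mfPath)) {
      old <- utils::read.csv(mfPath, stringsAsFactors = FALSE)
      old <- old[!(old$stage %in% mf$stage), , drop = FALSE]
      mf <- rbind(old, mf)
    }
    utils::write.csv(mf, mfPath, row.names = FALSE)
  }
  invisible(out)
}
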