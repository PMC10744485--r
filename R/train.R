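#' @include generator.R discriminator.R losses.R xray-prep.R
NULL

#' Learning rate at a given epoch
#'
#' Constant for the first half of the epochs, then decays linearly towards
#' zero (reached one epoch past the end), so the final epoch always trains
#' with a small but nonzero rate.
#'
#' @param lr base learning rate.
#' @param epoch current epoch (1-based).
#' @param nEpochs total epochs.
#' @return The scheduled learning rate.
#' @export
lrAtEpoch <- function(lr, epoch, nEpochs) {
  half <- ceiling(nEpochs / 2)
  if (epoch <= half) return(lr)
  lr * (nEpochs - epoch + 1) / (nEpochs - half + 1)
}

#' Desk-scale training configuration
#'
#' A small configuration for CPU-scale sanity runs: 32^3 output, base width
#' 4, 38 epochs (152 generator updates over four samples), learning rate
#' 2e-3, and reconstruction-dominant loss weights
#' (`wGan = 0.1, wRecon = 10, wProj = 10, wFm = 1, wIdt = 0.5`). At this
#' step count the discriminator's features are still nearly random, so the
#' desk run down-weights feature matching and the identity term relative to
#' the full-scale defaults; the larger learning rate compensates for the
#' short schedule. Pair it with `augment = FALSE` in [trainGan()] when the
#' goal is optimization sanity rather than generalization.
#'
#' @param seed integer seed.
#' @param nEpochs number of epochs (default 38).
#' @return A [GanConfig-class].
#' @export
deskGanConfig <- function(seed = 11L, nEpochs = 38L) {
  ganConfig(volumeSize = 32L, baseChannels = 4L, nEpochs = nEpochs,
            learningRate = 2e-3, seed = as.integer(seed),
            lossWeights = lossWeights(wGan = 0.1, wRecon = 10, wProj = 10,
                                      wFm = 1, wIdt = 0.5))
}

finiteOrAbort <- function(x, term) {
  if (!is.finite(x))
    stop("non-finite ", term, " loss encountered; aborting training")
  x
}

#' Train the two-view fusion GAN
#'
#' Alternating discriminator/generator updates with Adam
#' (`learningRate`, `beta1`, `beta2` from `cfg`), batch size 1 semantics
#' (samples are visited one at a time in a seeded shuffled order per epoch).
#' The generator objective is
#' `wGan * L_adv + wRecon * L_mse + wProj * L_proj + wFm * L_fm +
#' wIdt * L_idt`, where the identity term ties the axis-mean projections of
#' the generated volume to the two input X-rays. With
#' `wGan = wFm = 0` the discriminator is never built into the graph and the
#' loop reduces to supervised regression. The learning rate follows
#' [lrAtEpoch()]. Losses are logged per epoch; checkpoints are written at
#' `cfg@checkpointEvery` intervals (and always at the end) when `logDir` is
#' given. Fully seeded: parameter initialization, data order and
#' augmentation all derive from `cfg@seed`.
#'
#' @param dataset nonempty list of [PairedSample-class] objects. X-rays and
#'   CT grids are resampled to `cfg@volumeSize` as needed.
#' @param cfg a [GanConfig-class].
#' @param logDir optional directory for `loss_log.csv` and checkpoints.
#' @param augment apply training-time augmentation ([augmentSample()]).
#' @param verbose print per-epoch summaries.
#' @return A list with `generator`, `discriminator`, `log` (per-epoch
#'   data.frame with learning rate and epoch-mean losses) and
#'   `checkpoints` (paths written).
#' @export
trainGan <- function(dataset, cfg, logDir = NULL, augment = TRUE,
                     verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty training dataset")
  stopifnot(all(vapply(dataset, is, logical(1), class2 = "PairedSample")))
  validObject(cfg)
  N <- cfg@volumeSize
  w <- cfg@lossWeights
  useD <- (w@wGan > 0 || w@wFm > 0)

  gen <- buildGenerator(cfg)
  disc <- if (useD) buildDiscriminator(cfg) else NULL
  gParams <- flattenParams(gen$params)
  gState <- adamInit(gParams)
  if (useD) {
    dParams <- flattenParams(disc$params)
    dState <- adamInit(dParams)
  }

  # pre-resample ground truth volumes once
  gts <- lapply(dataset, function(s) {
    v <- resizeVolume(s@ct, rep(N, 3L))
    v <- pmin(pmax(v, 0), 1)
    dim(v) <- c(N, N, N, 1L)
    v
  })

  if (!is.null(logDir) && !dir.exists(logDir))
    dir.create(logDir, recursive = TRUE)
  log <- data.frame()
  checkpoints <- character()
  set.seed(cfg@seed)
  tG <- 0L; tD <- 0L
  n <- length(dataset)

  for (epoch in seq_len(cfg@nEpochs)) {
    lr <- lrAtEpoch(cfg@learningRate, epoch, cfg@nEpochs)
    order <- sample(n)
    eD <- eG <- eR <- 0
    for (si in order) {
      s <- dataset[[si]]
      aug <- augmentSample(s, seed = caseSeed(cfg@seed, epoch * n + si))
      x1 <- pmin(pmax(resizeBilinear(if (augment) aug$xray1 else
        s@xray1@pixels, N, N), 0), 1)
      x2 <- pmin(pmax(resizeBilinear(if (augment) aug$xray2 else
        s@xray2@pixels, N, N), 0), 1)
      gt <- agConst(gts[[si]])

      fake <- genForward(gen, x1, x2)

      lossDVal <- NA_real_
      realFeats <- NULL
      if (useD) {
        # discriminator step (generator output detached)
        agZeroGrad(dParams); agZeroGrad(gParams)
        dReal <- discForward(disc, gt, x1, x2)
        dFake <- discForward(disc, agTensor(fake$val), x1, x2)
        ones <- array(1, dim(dReal$scores$val))
        zeros <- array(0, dim(dReal$scores$val))
        lossD <- agScale(agAdd(agMSE(dReal$scores, ones),
                               agMSE(dFake$scores, zeros)), 0.5)
        finiteOrAbort(lossD$val, "discriminator")
        agBackward(lossD)
        tD <- tD + 1L
        dState <- adamStep(dParams, dState, lr, cfg@beta1, cfg@beta2, tD)
        lossDVal <- lossD$val
        realFeats <- lapply(dReal$features, function(f) agTensor(f$val))
      }

      # generator step
      agZeroGrad(gParams)
      if (useD) agZeroGrad(dParams)
      terms <- list()
      lossRecon <- agMSE(fake, gt)
      finiteOrAbort(lossRecon$val, "reconstruction")
      if (w@wRecon > 0) terms <- c(terms, list(agScale(lossRecon, w@wRecon)))
      if (useD) {
        dFakeG <- discForward(disc, fake, x1, x2)
        if (w@wGan > 0) {
          ones <- array(1, dim(dFakeG$scores$val))
          adv <- agMSE(dFakeG$scores, ones)
          finiteOrAbort(adv$val, "adversarial")
          terms <- c(terms, list(agScale(adv, w@wGan)))
        }
        if (w@wFm > 0) {
          fms <- mapply(function(r, f) agMAE(f, r), realFeats,
                        dFakeG$features, SIMPLIFY = FALSE)
          fm <- agScale(agSum(fms), 1 / length(fms))
          finiteOrAbort(fm$val, "feature-matching")
          terms <- c(terms, list(agScale(fm, w@wFm)))
        }
      }
      if (w@wProj > 0) {
        projs <- lapply(1:3, function(ax)
          agMSE(agMeanAxis(fake, ax), meanProjection(gts[[si]][, , , 1], ax)))
        proj <- agScale(agSum(projs), 1 / 3)
        finiteOrAbort(proj$val, "projection")
        terms <- c(terms, list(agScale(proj, w@wProj)))
      }
      if (w@wIdt > 0) {
        idt <- agScale(agAdd(agMSE(agMeanAxis(fake, 2L), x1),
                             agMSE(agMeanAxis(fake, 3L), x2)), 0.5)
        finiteOrAbort(idt$val, "identity")
        terms <- c(terms, list(agScale(idt, w@wIdt)))
      }
      lossG <- if (length(terms) == 1L) terms[[1]] else agSum(terms)
      finiteOrAbort(lossG$val, "generator total")
      agBackward(lossG)
      tG <- tG + 1L
      gState <- adamStep(gParams, gState, lr, cfg@beta1, cfg@beta2, tG)

      eD <- eD + (if (is.na(lossDVal)) 0 else lossDVal)
      eG <- eG + lossG$val
      eR <- eR + lossRecon$val
    }
    row <- data.frame(epoch = epoch, lr = lr,
                      lossD = if (useD) eD / n else NA_real_,
                      lossG = eG / n, lossRecon = eR / n)
    log <- rbind(log, row)
    if (verbose)
      message(sprintf("epoch %d: lr %.2g, G %.4g, recon %.4g", epoch, lr,
                      row$lossG, row$lossRecon))
    if (!is.null(logDir)) {
      utils::write.csv(log, file.path(logDir, "loss_log.csv"),
                       row.names = FALSE)
      if ((cfg@checkpointEvery > 0L && epoch %% cfg@checkpointEvery == 0L) ||
          epoch == cfg@nEpochs) {
        ck <- file.path(logDir, sprintf("checkpoint_epoch%03d.rds", epoch))
        saveRDS(list(generator = serializeNet(gen),
                     discriminator = if (useD) serializeNet(disc)), ck)
        checkpoints <- c(checkpoints, ck)
      }
    }
  }
  list(generator = gen, discriminator = disc, log = log,
       checkpoints = checkpoints)
}
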