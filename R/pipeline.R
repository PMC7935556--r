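# Dataset construction, SVM classification and evaluation statistics, plus
# config-driven orchestration of the full preprocessing chain.

#' Cohen's kappa from a confusion matrix
#'
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with \eqn{p_o} the observed
#' agreement and \eqn{p_e} the chance agreement from the marginals.
#'
#' @param confusion square count matrix (rows: truth, columns: prediction).
#' @return kappa in \eqn{[-1, 1]}; perfect agreement gives 1.
#' @export
cohenKappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Class-label map of a phantom scene
#'
#' @param truth a [SceneTruth-class]
#' @return character \code{(nx, ny)} matrix: \code{"healthy"} /
#'   \code{"infected"} on blob pixels, \code{NA} elsewhere.
#' @export
truthClassMap <- function(truth) {
  stopifnot(is(truth, "SceneTruth"))
  cm <- matrix(NA_character_, nrow(truth@labelMap), ncol(truth@labelMap))
  on <- truth@labelMap > 0L
  cm[on] <- truth@labels$class[truth@labelMap[on]]
  cm
}

#' Mask of the stage region outside all plate footprints
#'
#' @param spec a [SceneSpec-class]
#' @param margin plate footprints are inflated by this many pixels.
#' @return a [BinaryMask-class], \code{TRUE} off-plate.
#' @export
plateFreeMask <- function(spec, margin = 2L) {
  stopifnot(is(spec, "SceneSpec"))
  g <- matrix(TRUE, spec@nx, spec@ny)
  for (p in spec@plates) {
    xr <- max(1L, p@xInterval[1L] - margin):min(spec@nx,
                                                p@xInterval[2L] + margin)
    yr <- max(1L, p@yInterval[1L] - margin):min(spec@ny,
                                                p@yInterval[2L] + margin)
    g[xr, yr] <- FALSE
  }
  BinaryMask(g)
}

#' Build a labelled pixel dataset from cubes, masks and class maps
#'
#' Draws, per cube and per class, \code{nTrain + nTest} foreground pixels
#' without replacement and assigns them at random to the train/test splits
#' (so the configured ratio holds exactly per cube and class). Features are
#' the raw pixel spectra, or their projections onto the first \code{pcaK}
#' principal components fitted on the training samples only.
#'
#' @param cubes a [HyperCube-class] or list of them.
#' @param masks a [BinaryMask-class] or list, aligned with \code{cubes};
#'   sampling is restricted to mask foreground.
#' @param classMaps character label matrix or list of them (NA = unlabeled).
#' @param nTrain,nTest samples per cube and class in each split.
#' @param featureMode \code{"raw"} or \code{"pca"}.
#' @param pcaK number of components for \code{featureMode = "pca"}.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return a [PixelDataset-class]
#' @export
buildPixelDataset <- function(cubes, masks, classMaps, nTrain, nTest,
                              featureMode = c("raw", "pca"), pcaK = 6L,
                              seed = 1L) {
  featureMode <- match.arg(featureMode)
  if (is(cubes, "HyperCube")) cubes <- list(cubes)
  if (is(masks, "BinaryMask")) masks <- list(masks)
  if (!is.list(classMaps)) classMaps <- list(classMaps)
  stopifnot(length(cubes) == length(masks),
            length(cubes) == length(classMaps))
  nTrain <- as.integer(nTrain); nTest <- as.integer(nTest)
  .withSeed(seed, {
    feat <- list(); lab <- character(0); spl <- character(0)
    prov <- list()
    for (ci in seq_along(cubes)) {
      cube <- cubes[[ci]]; d <- dim(cube@data)
      X <- matrix(cube@data, d[1L] * d[2L], d[3L])
      fg <- masks[[ci]]@grid
      if (!all(dim(fg) == d[1:2]))
        stop("mask does not align with cube ", ci, call. = FALSE)
      cm <- classMaps[[ci]]
      classes <- sort(unique(cm[!is.na(cm)]))
      for (cls in classes) {
        cand <- which(fg & !is.na(cm) & cm == cls)
        need <- nTrain + nTest
        if (length(cand) < need)
          stop(sprintf(
            "cube %d class '%s': %d labelled foreground pixels, need %d",
            ci, cls, length(cand), need), call. = FALSE)
        pick <- sample(cand, need)
        split <- sample(rep(c("train", "test"), c(nTrain, nTest)))
        feat[[length(feat) + 1L]] <- X[pick, , drop = FALSE]
        lab <- c(lab, rep(cls, need))
        spl <- c(spl, split)
        prov[[length(prov) + 1L]] <- data.frame(
          cube = ci,
          x = ((pick - 1L) %% d[1L]) + 1L,
          y = ((pick - 1L) %/% d[1L]) + 1L)
      }
    }
    features <- do.call(rbind, feat)
    if (featureMode == "pca") {
      tr <- spl == "train"
      pc <- stats::prcomp(features[tr, , drop = FALSE], center = TRUE,
                          scale. = FALSE, rank. = as.integer(pcaK))
      features <- sweep(features, 2L, pc$center) %*% pc$rotation
    }
    new("PixelDataset", features = features, labels = factor(lab),
        split = factor(spl, levels = c("train", "test")),
        provenance = do.call(rbind, prov), featureMode = featureMode,
        seed = as.integer(seed))
  })
}

#' Train an SVM pixel classifier
#'
#' Radial-basis-function SVM (\code{e1071::svm}) on the dataset's training
#' split; features are scaled internally, so the default gamma is relative
#' to the feature variances. Training is deterministic given the dataset.
#'
#' @param dataset a [PixelDataset-class]
#' @param cost soft-margin cost parameter.
#' @param gamma optional RBF width (default \code{1 / nfeatures} on scaled
#'   features).
#' @return a classifier handle (list with the fitted model and the feature
#'   mode), usable by [evaluateClassifier()]; serializes with
#'   \code{saveRDS}.
#' @export
trainClassifier <- function(dataset, cost = 1, gamma = NULL) {
  stopifnot(is(dataset, "PixelDataset"))
  tr <- dataset@split == "train"
  y <- droplevels(dataset@labels[tr])
  if (nlevels(y) < 2L)
    stop("training split contains a single class", call. = FALSE)
  x <- dataset@features[tr, , drop = FALSE]
  args <- list(x = x, y = y, kernel = "radial", cost = cost,
               type = "C-classification")
  if (!is.null(gamma)) args$gamma <- gamma
  model <- do.call(e1071::svm, args)
  structure(list(model = model, featureMode = dataset@featureMode,
                 levels = levels(y)),
            class = "cubeprepClassifier")
}

#' Evaluate a classifier on a pixel dataset
#'
#' Confusion matrix and accuracy on the test split; "total" accuracy over
#' the pooled train + test predictions; Cohen's kappa from the test
#' confusion matrix.
#'
#' @param classifier handle from [trainClassifier()].
#' @param dataset the [PixelDataset-class] it was trained on (or one with
#'   the same feature mode and dimensionality).
#' @return an [EvalResult-class]
#' @export
evaluateClassifier <- function(classifier, dataset) {
  stopifnot(inherits(classifier, "cubeprepClassifier"),
            is(dataset, "PixelDataset"))
  if (!identical(classifier$featureMode, dataset@featureMode))
    stop("feature mode mismatch between classifier and dataset",
         call. = FALSE)
  pred <- stats::predict(classifier$model, dataset@features)
  truth <- dataset@labels
  lev <- union(levels(truth), levels(pred))
  te <- dataset@split == "test"
  confusion <- table(factor(truth[te], lev), factor(pred[te], lev))
  confusion <- unclass(as.matrix(confusion))
  new("EvalResult",
      confusion = confusion,
      testAccuracy = mean(pred[te] == truth[te]),
      totalAccuracy = mean(pred == truth),
      kappa = cohenKappa(confusion))
}

#' Default pipeline configuration
#'
#' @param seed master seed for the scene and all sampling.
#' @return nested list understood by [runPipeline()].
#' @export
pipelineConfig <- function(seed = 20260101L) {
  list(
    seed = as.integer(seed),
    scene = list(),                       # extra args to sceneSpec()
    segmentation = list(k = 20L, pcIndex = "auto"),
    filters = list(sg = c(m = 7L, n = 3L), tsg = c(m = 3L, n = 4L)),
    dataset = list(nTrain = 180L, nTest = 20L, featureMode = "pca",
                   pcaK = 6L),
    classifier = list(cost = 1),
    comparative = TRUE)
}

#' Run the full preprocessing + classification pipeline on a phantom scene
#'
#' Orchestrates simulate -> double-plate correct -> segment -> filter ->
#' dataset -> SVM -> evaluate. In comparative mode the classification is run
#' on three byte-identical upstream inputs differing only in the filtering
#' stage: no filtering, spectral SG, and spatial-spectral TSG; a three-row
#' summary of test/total accuracy and kappa is produced, together with a
#' quality report of the TSG cube against its unfiltered input. Every
#' artifact and parameter is logged in a JSON manifest with file hashes.
#'
#' @param config list as from [pipelineConfig()].
#' @param outDir artifact directory (created if missing); \code{NULL} skips
#'   writing files.
#' @return list with \code{summary} (data.frame), \code{evals},
#'   \code{mask}, \code{corrected}, \code{quality} and \code{manifest}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  cfg <- utils::modifyList(pipelineConfig(), config)
  spec <- do.call(sceneSpec, c(list(seed = cfg$seed), cfg$scene))
  scene <- renderScene(spec)

  refl <- vapply(spec@plates, function(p) p@reflectance[1L], numeric(1))
  pLow <- spec@plates[[which.min(refl)]]
  pHigh <- spec@plates[[which.max(refl)]]
  corr <- doublePlateCorrect(scene$cube, pLow, pHigh)

  seg <- segmentPipeline(corr$reflectance, k = cfg$segmentation$k,
                         pcIndex = cfg$segmentation$pcIndex,
                         region = plateFreeMask(spec))
  mask <- seg$mask

  variants <- list(none = corr$reflectance)
  if (isTRUE(cfg$comparative)) {
    sgp <- cfg$filters$sg
    tsgp <- cfg$filters$tsg
    variants$sg <- sgFilterSpectra(corr$reflectance, sgp[["m"]], sgp[["n"]])
    variants$tsg <- tsgFilter(corr$reflectance, tsgp[["m"]], tsgp[["n"]])
  }

  cm <- truthClassMap(scene$truth)
  evals <- list()
  for (v in names(variants)) {
    ds <- buildPixelDataset(variants[[v]], mask, cm,
                            nTrain = cfg$dataset$nTrain,
                            nTest = cfg$dataset$nTest,
                            featureMode = cfg$dataset$featureMode,
                            pcaK = cfg$dataset$pcaK,
                            seed = cfg$seed + 1L)
    model <- trainClassifier(ds, cost = cfg$classifier$cost)
    evals[[v]] <- evaluateClassifier(model, ds)
  }
  summary <- data.frame(
    filtering = names(evals),
    test_accuracy = vapply(evals, function(e) e@testAccuracy, numeric(1)),
    total_accuracy = vapply(evals, function(e) e@totalAccuracy, numeric(1)),
    kappa = vapply(evals, function(e) e@kappa, numeric(1)),
    row.names = NULL)

  qual <- if (isTRUE(cfg$comparative))
    qualityReport(corr$reflectance, variants$tsg) else NULL

  manifest <- list(config = cfg,
                   scene = list(extents = c(spec@nx, spec@ny, spec@nbands),
                                seed = spec@seed),
                   segmentation = seg$diagnostics,
                   summary = summary)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMask(mask, file.path(outDir, "mask.png"))
    writeCube(corr$reflectance, file.path(outDir, "corrected.hcube"),
              format = "array")
    utils::write.table(summary, file.path(outDir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(qual))
      writeQualityReport(qual, file.path(outDir, "quality.tsv"))
    files <- list.files(outDir, full.names = TRUE)
    files <- setdiff(files, file.path(outDir, "manifest.json"))
    manifest$artifacts <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(summary = summary, evals = evals, mask = mask,
       corrected = corr$reflectance, quality = qual, manifest = manifest)
}
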