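#' Default pipeline configuration
#'
#' Nested sections for every stage, all with documented defaults. The
#' single global `seed` fans out to stage-level seeds as `seed + stage
#' index` (stages numbered: 1 simulate, 2 segment, 3 split, 4 train).
#'
#' @param seed global seed.
#' @return Nested list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    preprocessing = list(sigma = 1.5, hairRemoval = FALSE,
                         order = "hair_first"),
    segmentation = unclass(segmentationConfig()),
    lbp = unclass(lbpConfig()),
    glcm = unclass(glcmConfig()),
    classifier = unclass(trainConfig()),
    split = list(fraction = 0.8, stratified = TRUE)
  ), class = "PipelineConfig")
}

knownConfigKeys <- function() {
  template <- pipelineConfig()
  lapply(template, function(x) if (is.list(x)) names(x) else NULL)
}

#' Load a pipeline configuration file (YAML or JSON)
#'
#' Values present in the file override the defaults of [pipelineConfig()];
#' unknown sections or keys are rejected.
#'
#' @param path config file.
#' @return A `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  known <- knownConfigKeys()
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop("unknown config section: ", sec, call. = FALSE)
    if (is.list(user[[sec]])) {
      bad <- setdiff(names(user[[sec]]), known[[sec]])
      if (length(bad))
        stop("unknown key(s) in section '", sec, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

restoreClass <- function(x, cls) structure(x, class = cls)

pipelineLog <- function(level, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full diagnosis pipeline
#'
#' Executes preprocess, segment, feature extraction, stratified split, MLP
#' training and evaluation on a labeled dataset, optionally writing masks,
#' the features CSV, the model file and a JSON report to `outDir`. Fully
#' deterministic given the config's global seed.
#'
#' @param dataset list of [LesionImage-class] objects (e.g. from
#'   [simulateDataset()] or [readDataset()]).
#' @param cfg a [pipelineConfig()].
#' @param outDir optional output directory for artifacts.
#' @param verbose log stage progress.
#' @return List with `manifest` (per-sample data.frame: label, split,
#'   predicted label, class probabilities, Dice vs ground truth where
#'   available), `report` (an [evaluationReport()]), `model`
#'   ([MLPModel-class]), `features` (matrix) and `masks` (list).
#' @export
runPipeline <- function(dataset, cfg = pipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
  say <- function(...) if (verbose) pipelineLog("info", ...)
  seed <- cfg$seed
  segCfg <- restoreClass(cfg$segmentation, "SegmentationConfig")
  lbpCfg <- restoreClass(cfg$lbp, "LBPConfig")
  glcmCfg <- restoreClass(cfg$glcm, "GLCMConfig")
  gspec <- gaussianSpec(sigma = cfg$preprocessing$sigma)

  say("preprocessing and segmenting ", length(dataset), " images")
  masks <- vector("list", length(dataset))
  pre <- vector("list", length(dataset))
  dice <- rep(NA_real_, length(dataset))
  for (i in seq_along(dataset)) {
    img <- preprocessImage(imgData(dataset[[i]]), gspec,
                           hairRemoval = isTRUE(cfg$preprocessing$hairRemoval),
                           order = cfg$preprocessing$order)
    pre[[i]] <- pmin(pmax(img, 0), 255)
    res <- tryCatch(segmentLesion(img, segCfg), error = function(e)
      stop("segmentation failed for sample ", i, ": ", conditionMessage(e),
           call. = FALSE))
    masks[[i]] <- roiMask(res)
    if (!is.null(maskData(dataset[[i]])))
      dice[i] <- diceCoefficient(masks[[i]], maskData(dataset[[i]]))
  }

  say("extracting 216-dimensional features")
  # features are computed on the preprocessed image (the denoising stage
  # precedes both segmentation and description in the workflow)
  X <- tryCatch(
    do.call(rbind, lapply(seq_along(dataset), function(i)
      extractFeatures(pre[[i]], masks[[i]], lbpCfg, glcmCfg))),
    error = function(e)
      stop("feature extraction failed: ", conditionMessage(e),
           call. = FALSE))
  labels <- vapply(dataset, imgLabel, character(1))
  attr(X, "labels") <- labels

  say("splitting ", nrow(X), " samples ", cfg$split$fraction * 100, "/",
      (1 - cfg$split$fraction) * 100)
  sp <- splitDataset(labels, fraction = cfg$split$fraction,
                     stratified = isTRUE(cfg$split$stratified),
                     seed = deriveSeed(seed, 3L))
  tcfg <- restoreClass(cfg$classifier, "TrainConfig")
  tcfg$seed <- deriveSeed(seed, 4L)

  say("training MLP on ", length(sp$train), " samples")
  model <- mlpFit(X[sp$train, , drop = FALSE], labels[sp$train], tcfg)

  say("evaluating on ", length(sp$test), " held-out samples")
  proba <- mlpPredictProba(model, X[sp$test, , drop = FALSE])
  pred <- mlpPredict(model, X[sp$test, , drop = FALSE])
  report <- evaluationReport(labels[sp$test], pred, proba = proba,
                             classes = model@classes)

  split <- rep("train", length(labels)); split[sp$test] <- "test"
  predAll <- mlpPredict(model, X)
  probAll <- mlpPredictProba(model, X)
  manifest <- data.frame(sample = seq_along(labels), label = labels,
                         split = split, predicted = predAll,
                         dice = dice, stringsAsFactors = FALSE)
  manifest <- cbind(manifest,
                    stats::setNames(as.data.frame(probAll),
                                    paste0("p_", colnames(probAll))))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(masks))
      writeGrayPNG(masks[[i]] * 255,
                   file.path(outDir, sprintf("roi_%04d.png", i)))
    utils::write.csv(cbind(data.frame(label = labels), as.data.frame(X)),
                     file.path(outDir, "features.csv"), row.names = FALSE)
    saveModel(model, file.path(outDir, "model.json"))
    utils::write.csv(manifest, file.path(outDir, "run_manifest.csv"),
                     row.names = FALSE)
    writeReportJSON(report, file.path(outDir, "report.json"))
    say("artifacts written to ", outDir)
  }
  list(manifest = manifest, report = report, model = model, features = X,
       masks = masks)
}

#' Serialize an evaluation report as JSON
#'
#' @param report an [evaluationReport()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  obj <- list(confusion = list(classes = colnames(report$confusion),
                               counts = unname(apply(report$confusion, 1,
                                                     as.numeric,
                                                     simplify = FALSE))),
              perClass = report$perClass,
              macro = report$macro,
              overallAccuracy = report$overallAccuracy,
              auc = if (!is.null(report$roc))
                lapply(report$roc, function(r) r$auc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
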