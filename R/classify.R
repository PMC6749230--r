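#' One-nearest-neighbour prediction under Euclidean distance
#'
#' Assigns each query the label of the closest training row. Distance ties
#' break toward the lowest training-row index, deterministically.
#'
#' @param trainFeatures `M x d` matrix of training feature vectors.
#' @param trainLabels length-`M` labels.
#' @param query a length-`d` vector or a `Q x d` matrix of queries.
#' @return A single label, or a length-`Q` vector for matrix input.
#' @export
knnPredict <- function(trainFeatures, trainLabels, query) {
  trainFeatures <- as.matrix(trainFeatures)
  M <- nrow(trainFeatures)
  if (M < 1L) stop("empty training set")
  if (length(trainLabels) != M) {
    stop("'trainLabels' must have one entry per training row")
  }
  single <- !is.matrix(query)
  Q <- if (single) matrix(query, nrow = 1L) else as.matrix(query)
  if (ncol(Q) != ncol(trainFeatures)) {
    stop("query dimension ", ncol(Q), " does not match training dimension ",
         ncol(trainFeatures))
  }
  # squared Euclidean distances; the query's own norm is constant per row
  cross <- Q %*% t(trainFeatures)
  d2 <- sweep(-2 * cross, 2L, rowSums(trainFeatures^2), "+")
  nn <- max.col(-d2, ties.method = "first")
  pred <- trainLabels[nn]
  if (single) pred[1L] else pred
}

#' Configuration of the repeated random-split identification experiment
#'
#' The evaluation protocol: per repeat, draw a pool of `nTotal` gait
#' samples (or all samples if fewer exist), pick `nTrainPerSubject`
#' training samples per subject, fit the whole pipeline on the training
#' samples only, and classify the remaining pool samples. The defaults
#' mirror the standard protocol for a 14-subject cohort: a 700-sample
#' pool, 3 training samples per subject (42 in total) and 25 repeats.
#'
#' @param nTotal pool size drawn per repeat (default 700).
#' @param nTrainPerSubject training samples per subject (default 3).
#' @param nRepeats number of random-split repeats (default 25).
#' @param k consecutive steps per gait sample (default 1).
#' @param featureDims multi-modal feature dimensions `d` to sweep;
#'   `NULL` means the single default operating point `min(20, 2(C-1))`,
#'   where identification rates saturate.
#' @param seed master seed; per-repeat seeds are derived from it.
#' @param cycleLength,referenceFoot,minCycleFrames,noiseHigh preprocessing
#'   settings (see [preprocessCohort()], [groupSteps()]).
#' @param m,direction fusion settings (see [buildGraph()],
#'   [selectFeatures()]).
#' @param tol NLDA eigenvalue threshold (see [nldaFit()]).
#' @param shuffleLabels if `TRUE`, randomly permute the subject labels of
#'   the pooled samples each repeat — a chance-level control that should
#'   score about `1/C`.
#' @return A list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(nTotal = 700L, nTrainPerSubject = 3L,
                             nRepeats = 25L, k = 1L, featureDims = NULL,
                             seed = 1L, cycleLength = 63L,
                             referenceFoot = "left", minCycleFrames = 10L,
                             noiseHigh = 0.1, m = 2, direction = "larger",
                             tol = 1e-10, shuffleLabels = FALSE) {
  stopifnot(nTotal >= 1L, nTrainPerSubject >= 1L, nRepeats >= 1L, k >= 1L)
  structure(list(nTotal = as.integer(nTotal),
                 nTrainPerSubject = as.integer(nTrainPerSubject),
                 nRepeats = as.integer(nRepeats), k = as.integer(k),
                 featureDims = featureDims, seed = as.integer(seed),
                 cycleLength = as.integer(cycleLength),
                 referenceFoot = referenceFoot,
                 minCycleFrames = as.integer(minCycleFrames),
                 noiseHigh = noiseHigh, m = m, direction = direction,
                 tol = tol, shuffleLabels = isTRUE(shuffleLabels)),
            class = "ExperimentConfig")
}

sampleMatrix <- function(samples, what = c("pressure", "acceleration")) {
  what <- match.arg(what)
  get_ <- if (what == "pressure") pressureVector else accelVector
  do.call(rbind, lapply(samples, get_))
}

#' Run the repeated random-split identification experiment
#'
#' Per repeat: (1) regularize and group the normalized steps into
#' `k`-step gait samples; (2) draw the sample pool; (3) pick the per-subject
#' training samples; (4) fit NLDA per modality on the training samples;
#' (5) build the candidate features, similarity graph, Laplacian scores
#' and feature selection on the training samples only; (6) classify every
#' held-out pool sample with the 1-NN rule, for each modality and each
#' feature dimension. Single-modal classification uses the per-modality
#' NLDA features directly, ordered by their between-class eigenvalues
#' (capped at `C - 1` dimensions); multi-modal classification uses the
#' Laplacian-score selection. No information flows from held-out samples
#' into any fitted artifact.
#'
#' @param sessions list of [RecordingSession] (the cohort).
#' @param config an [experimentConfig()].
#' @param steps optional precomputed output of [preprocessCohort()] on
#'   `sessions` (lets [sweepK()] share the deterministic preprocessing).
#' @return An [ExperimentResult].
#' @export
runExperiment <- function(sessions, config = experimentConfig(),
                          steps = NULL) {
  stopifnot(inherits(config, "ExperimentConfig"))
  if (is.null(steps)) {
    steps <- preprocessCohort(sessions, cycleLength = config$cycleLength,
                              referenceFoot = config$referenceFoot,
                              minCycleFrames = config$minCycleFrames)
  }
  if (length(steps) < 2L) stop("the cohort must contain at least 2 subjects")
  subjects <- names(steps)
  C <- length(subjects)

  repeatSeeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max, config$nRepeats))

  rows <- list()
  confusion <- NULL
  for (r in seq_len(config$nRepeats)) {
    rep_ <- withr::with_seed(repeatSeeds[r],
      runOneRepeat(steps, subjects, config))
    rep_$results$repeat_ <- r
    rows[[r]] <- rep_$results
    confusion <- if (is.null(confusion)) rep_$confusion else
      confusion + rep_$confusion
  }
  res <- do.call(rbind, rows)
  res <- res[, c("repeat_", "k", "d", "modality", "accuracy",
                 "n_train", "n_test")]
  new("ExperimentResult", results = res, confusion = as.table(confusion),
      config = unclass(config))
}

# One random split, executed inside a seeded RNG context.
runOneRepeat <- function(steps, subjects, config) {
  C <- length(subjects)
  samples <- list()
  for (s in subjects) {
    samples <- c(samples, groupSteps(steps[[s]], k = config$k,
                                     noiseHigh = config$noiseHigh))
  }
  labels <- vapply(samples, subjectID, character(1))
  if (config$shuffleLabels) labels <- sample(labels)

  total <- length(samples)
  poolIdx <- if (total > config$nTotal) {
    sort(sample.int(total, config$nTotal))
  } else {
    seq_len(total)
  }
  poolLabels <- labels[poolIdx]
  counts <- table(factor(poolLabels, levels = subjects))
  short <- names(counts)[counts < config$nTrainPerSubject + 1L]
  if (length(short)) {
    stop("subject(s) with too few samples in the pool for ",
         config$nTrainPerSubject, " training + 1 test: ",
         paste(short, collapse = ", "))
  }

  trainMask <- logical(length(poolIdx))
  for (s in subjects) {
    own <- which(poolLabels == s)
    trainMask[sample(own, config$nTrainPerSubject)] <- TRUE
  }
  testMask <- !trainMask

  Xp <- sampleMatrix(samples[poolIdx], "pressure")
  Xa <- sampleMatrix(samples[poolIdx], "acceleration")
  trLab <- poolLabels[trainMask]

  fitP <- nldaFit(Xp[trainMask, , drop = FALSE], trLab,
                  modality = "pressure", tol = config$tol)
  fitA <- nldaFit(Xa[trainMask, , drop = FALSE], trLab,
                  modality = "acceleration", tol = config$tol)
  Yp <- nldaTransform(fitP, Xp)
  Ya <- nldaTransform(fitA, Xa)
  cand <- cbind(Yp, Ya)
  p <- ncol(cand)

  cfs <- candidateFeatures(Yp[trainMask, , drop = FALSE],
                           Ya[trainMask, , drop = FALSE], trLab,
                           m = config$m, direction = config$direction)
  sel <- selectionOrder(cfs)

  dims <- config$featureDims
  if (is.null(dims)) dims <- min(20L, p)
  dims <- sort(unique(pmin(as.integer(dims), p)))
  dDefault <- min(20L, p)

  teLab <- poolLabels[testMask]
  nTr <- sum(trainMask)
  nTe <- sum(testMask)
  out <- list()
  confusion <- NULL
  for (d in dims) {
    for (mod in c("pressure", "acceleration", "multimodal")) {
      Ft <- switch(mod,
        pressure = Yp[, seq_len(min(d, ncol(Yp))), drop = FALSE],
        acceleration = Ya[, seq_len(min(d, ncol(Ya))), drop = FALSE],
        multimodal = cand[, sel[seq_len(d)], drop = FALSE])
      pred <- knnPredict(Ft[trainMask, , drop = FALSE], trLab,
                         Ft[testMask, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        k = config$k, d = d, modality = mod,
        accuracy = mean(pred == teLab), n_train = nTr, n_test = nTe,
        stringsAsFactors = FALSE)
      if (mod == "multimodal" && d == dDefault) {
        confusion <- table(factor(teLab, levels = subjects),
                           factor(pred, levels = subjects))
      }
    }
  }
  if (is.null(confusion)) {
    confusion <- table(factor(character(), levels = subjects),
                       factor(character(), levels = subjects))
  }
  list(results = do.call(rbind, out), confusion = confusion)
}

#' Sweep the number of consecutive steps per sample
#'
#' Runs [runExperiment()] for each `k` in `ks`, sharing the deterministic
#' preprocessing (segmentation + normalization) of the raw sessions.
#'
#' @param sessions list of [RecordingSession].
#' @param config an [experimentConfig()]; its `k` is overridden per run.
#' @param ks integer vector of steps-per-sample values (e.g. `1:3`).
#' @return An [ExperimentResult] whose table stacks all `k` values.
#' @export
sweepK <- function(sessions, config = experimentConfig(), ks = 1:3) {
  stopifnot(length(ks) >= 1L)
  steps <- preprocessCohort(sessions, cycleLength = config$cycleLength,
                            referenceFoot = config$referenceFoot,
                            minCycleFrames = config$minCycleFrames)
  parts <- lapply(as.integer(ks), function(k) {
    cfg <- config
    cfg$k <- k
    runExperiment(sessions, cfg, steps = steps)
  })
  res <- do.call(rbind, lapply(parts, resultsTable))
  conf <- Reduce(`+`, lapply(parts, confusionCounts))
  new("ExperimentResult", results = res, confusion = as.table(conf),
      config = unclass(config))
}

#' Fit a deployable identification pipeline on a training cohort
#'
#' Preprocesses the sessions, groups steps into `k`-step samples
#' (regularization seeded by `config$seed`), fits the per-modality NLDA
#' models on all samples, scores and selects candidate features, and
#' stores the multi-modal training features for 1-NN identification of
#' new sessions.
#'
#' @param sessions list of [RecordingSession] (training cohort).
#' @param config an [experimentConfig()]; `featureDims[1]` (or the
#'   default `min(20, 2(C-1))`) sets the deployed feature dimension.
#' @return A [GaitIdentifier].
#' @seealso [identifySubject()]
#' @export
fitIdentifier <- function(sessions, config = experimentConfig()) {
  steps <- preprocessCohort(sessions, cycleLength = config$cycleLength,
                            referenceFoot = config$referenceFoot,
                            minCycleFrames = config$minCycleFrames)
  if (length(steps) < 2L) stop("the cohort must contain at least 2 subjects")
  samples <- list()
  for (s in names(steps)) {
    samples <- c(samples, groupSteps(steps[[s]], k = config$k,
                                     noiseHigh = config$noiseHigh,
                                     seed = config$seed))
  }
  labels <- vapply(samples, subjectID, character(1))
  Xp <- sampleMatrix(samples, "pressure")
  Xa <- sampleMatrix(samples, "acceleration")
  fitP <- nldaFit(Xp, labels, modality = "pressure", tol = config$tol)
  fitA <- nldaFit(Xa, labels, modality = "acceleration", tol = config$tol)
  Yp <- nldaTransform(fitP, Xp)
  Ya <- nldaTransform(fitA, Xa)
  cfs <- candidateFeatures(Yp, Ya, labels, m = config$m,
                           direction = config$direction)
  p <- ncol(candidateMatrix(cfs))
  d <- if (is.null(config$featureDims)) min(20L, p) else
    min(as.integer(config$featureDims[1L]), p)
  sel <- selectionOrder(cfs)[seq_len(d)]
  trainF <- buildMultimodal(cbind(Yp, Ya), sel)
  new("GaitIdentifier", nldaPressure = fitP, nldaAccel = fitA,
      selection = as.integer(sel), trainFeatures = as.matrix(trainF),
      trainLabels = labels, config = unclass(config))
}

#' @rdname identifySubject
#' @export
setMethod("identifySubject", "GaitIdentifier",
          function(identifier, session, seed = NULL) {
  cfg <- identifier@config
  segs <- segmentSteps(session, referenceFoot = cfg$referenceFoot,
                       minCycleFrames = cfg$minCycleFrames)
  if (length(segs) < cfg$k) {
    stop("no steps detected: the session contains no complete gait cycle ",
         "(need at least k = ", cfg$k, ")")
  }
  norm <- lapply(segs, normalizeStep, l = cfg$cycleLength)
  samples <- groupSteps(norm, k = cfg$k, noiseHigh = cfg$noiseHigh,
                        seed = seed)
  Xp <- sampleMatrix(samples, "pressure")
  Xa <- sampleMatrix(samples, "acceleration")
  Yp <- nldaTransform(identifier@nldaPressure, Xp)
  Ya <- nldaTransform(identifier@nldaAccel, Xa)
  F <- buildMultimodal(cbind(Yp, Ya), identifier@selection)
  pred <- knnPredict(identifier@trainFeatures, identifier@trainLabels, F)
  votes <- sort(table(pred), decreasing = TRUE)
  list(label = names(votes)[1L], perSample = pred, votes = votes)
})
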