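#' @rdname soleID-accessors
#' @export
setMethod("subjectID", "RecordingSession", function(x) x@subjectID)
#' @rdname soleID-accessors
#' @export
setMethod("subjectID", "StepSegment", function(x) x@subjectID)
#' @rdname soleID-accessors
#' @export
setMethod("subjectID", "NormalizedStep", function(x) x@subjectID)
#' @rdname soleID-accessors
#' @export
setMethod("subjectID", "GaitSample", function(x) x@subjectID)

#' @rdname soleID-accessors
#' @export
setMethod("sampleRate", "RecordingSession", function(x) x@sampleRate)

#' @rdname soleID-accessors
#' @export
setMethod("nFrames", "RecordingSession", function(x) nrow(x@pressure))
#' @rdname soleID-accessors
#' @export
setMethod("nFrames", "StepSegment", function(x) nrow(x@pressure))

#' @rdname soleID-accessors
#' @export
setMethod("pressureMatrix", "RecordingSession", function(x) x@pressure)
#' @rdname soleID-accessors
#' @export
setMethod("pressureMatrix", "StepSegment", function(x) x@pressure)
#' @rdname soleID-accessors
#' @export
setMethod("pressureMatrix", "NormalizedStep", function(x) x@pressureMatrix)

#' @rdname soleID-accessors
#' @export
setMethod("accelMatrix", "RecordingSession", function(x) x@acceleration)
#' @rdname soleID-accessors
#' @export
setMethod("accelMatrix", "StepSegment", function(x) x@acceleration)
#' @rdname soleID-accessors
#' @export
setMethod("accelMatrix", "NormalizedStep", function(x) x@accelMatrix)

#' @rdname soleID-accessors
#' @export
setMethod("pressureVector", "NormalizedStep", function(x)
  vectorizeMatrix(x@pressureMatrix))
#' @rdname soleID-accessors
#' @export
setMethod("pressureVector", "GaitSample", function(x) x@pressureInput)

#' @rdname soleID-accessors
#' @export
setMethod("accelVector", "NormalizedStep", function(x)
  vectorizeMatrix(x@accelMatrix))
#' @rdname soleID-accessors
#' @export
setMethod("accelVector", "GaitSample", function(x) x@accelInput)

#' @rdname soleID-accessors
#' @export
setMethod("cycleLength", "NormalizedStep", function(x) x@cycleLength)

#' @rdname soleID-accessors
#' @export
setMethod("frameRange", "StepSegment", function(x)
  c(start = x@startFrame, end = x@endFrame))

#' @rdname soleID-accessors
#' @export
setMethod("projectionMatrix", "NLDAModel", function(x) x@W)

#' @rdname soleID-accessors
#' @export
setMethod("classCentroids", "NLDAModel", function(x) x@centroids)

#' @rdname soleID-accessors
#' @export
setMethod("featureScores", "CandidateFeatureSet", function(x) x@scores)

#' @rdname soleID-accessors
#' @export
setMethod("selectionOrder", "CandidateFeatureSet", function(x)
  x@selectionOrder)

#' @rdname soleID-accessors
#' @export
setMethod("candidateMatrix", "CandidateFeatureSet", function(x) x@F)

#' @rdname soleID-accessors
#' @export
setMethod("resultsTable", "ExperimentResult", function(x) x@results)

#' @rdname soleID-accessors
#' @export
setMethod("confusionCounts", "ExperimentResult", function(x) x@confusion)

setMethod("show", "RecordingSession", function(object) {
  cat("RecordingSession for subject '", object@subjectID, "'\n", sep = "")
  cat("  ", nrow(object@pressure), " frames at ", object@sampleRate,
      " Hz (", sprintf("%.1f", nrow(object@pressure) / object@sampleRate),
      " s)\n", sep = "")
  cat("  16 pressure channels (levels 0/1/2), 6 acceleration channels\n")
})

setMethod("show", "StepSegment", function(object) {
  cat("StepSegment [", object@startFrame, ", ", object@endFrame,
      ") of subject '", object@subjectID, "': ",
      nrow(object@pressure), " frames\n", sep = "")
})

setMethod("show", "NormalizedStep", function(object) {
  cat("NormalizedStep of subject '", object@subjectID, "': l = ",
      object@cycleLength, " (pressure ", object@cycleLength, "x16, accel ",
      object@cycleLength, "x6)\n", sep = "")
})

setMethod("show", "NLDAModel", function(object) {
  cat("NLDAModel (", object@modality, "): ", nrow(object@W), " -> ",
      ncol(object@W), " features over ", length(object@classLevels),
      " classes\n", sep = "")
})

setMethod("show", "CandidateFeatureSet", function(object) {
  cat("CandidateFeatureSet: ", nrow(object@F), " samples x ",
      ncol(object@F), " candidate features\n", sep = "")
  cat("  Laplacian scores in [",
      sprintf("%.4g", min(object@scores)), ", ",
      sprintf("%.4g", max(object@scores)), "]\n", sep = "")
})

setMethod("show", "GaitIdentifier", function(object) {
  cat("GaitIdentifier over ", length(unique(object@trainLabels)),
      " subjects (", nrow(object@trainFeatures), " training samples, ",
      ncol(object@trainFeatures), " multi-modal features)\n", sep = "")
})

setMethod("show", "ExperimentResult", function(object) {
  res <- object@results
  cat("ExperimentResult: ", length(unique(res$repeat_)), " repeats, k in {",
      paste(sort(unique(res$k)), collapse = ", "), "}\n", sep = "")
  agg <- stats::aggregate(accuracy ~ modality + k, data = res,
                          FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-13s k=%d: %.3f +/- %.3f\n", agg$modality[i], agg$k[i],
                agg$accuracy[i, "mean"],
                ifelse(is.na(agg$accuracy[i, "sd"]), 0, agg$accuracy[i, "sd"])))
  }
})
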