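#' @name soleID-accessors
#' @title Accessors for soleID data classes
#'
#' @description Slot accessors for the core classes. Use these instead of
#' `@` access.
#'
#' @param x an object of one of the soleID classes.
#' @param object an object of one of the soleID classes.
#' @return The corresponding slot contents (see each method).
NULL

#' @rdname soleID-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname soleID-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname soleID-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname soleID-accessors
#' @export
setGeneric("pressureMatrix", function(x) standardGeneric("pressureMatrix"))

#' @rdname soleID-accessors
#' @export
setGeneric("accelMatrix", function(x) standardGeneric("accelMatrix"))

#' @rdname soleID-accessors
#' @export
setGeneric("pressureVector", function(x) standardGeneric("pressureVector"))

#' @rdname soleID-accessors
#' @export
setGeneric("accelVector", function(x) standardGeneric("accelVector"))

#' @rdname soleID-accessors
#' @export
setGeneric("cycleLength", function(x) standardGeneric("cycleLength"))

#' @rdname soleID-accessors
#' @export
setGeneric("frameRange", function(x) standardGeneric("frameRange"))

#' @rdname soleID-accessors
#' @export
setGeneric("projectionMatrix", function(x) standardGeneric("projectionMatrix"))

#' @rdname soleID-accessors
#' @export
setGeneric("classCentroids", function(x) standardGeneric("classCentroids"))

#' @rdname soleID-accessors
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' @rdname soleID-accessors
#' @export
setGeneric("selectionOrder", function(x) standardGeneric("selectionOrder"))

#' @rdname soleID-accessors
#' @export
setGeneric("candidateMatrix", function(x) standardGeneric("candidateMatrix"))

#' @rdname soleID-accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname soleID-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' Project a sample into the fitted discriminant feature space
#'
#' Applies the fitted NLDA projection: `y = W' x` (no centering; pairwise
#' feature distances, which are all the 1-NN classifier uses, are
#' unaffected by centering).
#'
#' @param model a fitted [NLDAModel].
#' @param x a numeric vector of length `n` (the model's input dimension),
#'   or an `N x n` matrix of row vectors.
#' @return A length-`n'` feature vector, or an `N x n'` matrix when `x` is
#'   a matrix.
#' @export
setGeneric("nldaTransform", function(model, x) standardGeneric("nldaTransform"))

#' Identify the subject of a recording with a fitted pipeline
#'
#' Segments the session into gait cycles, normalizes, projects through the
#' per-modality NLDA models, gathers the training-derived multi-modal
#' feature selection, and classifies each gait sample with the 1-NN rule.
#'
#' @param identifier a fitted [GaitIdentifier].
#' @param session a [RecordingSession].
#' @param seed optional integer seeding the per-step regularization noise.
#' @return A list with `label` (majority-vote subject label), `perSample`
#'   (character vector of per-sample predictions) and `votes` (a table of
#'   prediction counts).
#' @export
setGeneric("identifySubject", function(identifier, session, seed = NULL)
  standardGeneric("identifySubject"))
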