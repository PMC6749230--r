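#' @import methods
NULL

# Channel-layout constants for the dual-foot insole: 8 pressure sensors per
# foot (left 1-8, then right 1-8) and a triaxial accelerometer per foot
# (left x,y,z, then right x,y,z), sampled synchronously at 100 Hz.
N_PRESSURE_CHANNELS <- 16L
N_ACCEL_CHANNELS <- 6L
PRESSURE_LEVELS <- c(0, 1, 2)
DEFAULT_SAMPLE_RATE <- 100

pressureChannelNames <- function() {
  c(paste0("Lp", 1:8), paste0("Rp", 1:8))
}

accelChannelNames <- function() {
  c("Lax", "Lay", "Laz", "Rax", "Ray", "Raz")
}

#' RecordingSession: a labeled dual-foot insole recording
#'
#' Holds one continuous walking recording from a smart insole: a
#' `time x 16` plantar-pressure matrix (each value quantized to 0, 1 or 2)
#' and a `time x 6` triaxial acceleration matrix (arbitrary sensor units),
#' sampled synchronously, together with the subject label.
#'
#' Pressure channels are ordered left-foot sensors 1--8 then right-foot
#' sensors 1--8; acceleration channels are left (x, y, z) then right
#' (x, y, z).
#'
#' @slot subjectID character(1); subject label.
#' @slot sampleRate numeric(1); frames per second (100 for the insole).
#' @slot pressure numeric matrix, `n x 16`, values in \{0, 1, 2\}.
#' @slot acceleration numeric matrix, `n x 6`.
#'
#' @seealso [readSession()], [synthSession()], [segmentSteps()]
#' @export
setClass("RecordingSession",
  representation(
    subjectID = "character",
    sampleRate = "numeric",
    pressure = "matrix",
    acceleration = "matrix"
  )
)

setValidity("RecordingSession", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L || is.na(object@subjectID) ||
      !nzchar(object@subjectID)) {
    msg <- c(msg, "'subjectID' must be a single non-empty string")
  }
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0) {
    msg <- c(msg, "'sampleRate' must be a single positive number")
  }
  if (ncol(object@pressure) != N_PRESSURE_CHANNELS) {
    msg <- c(msg, sprintf("'pressure' must have %d columns",
                          N_PRESSURE_CHANNELS))
  }
  if (ncol(object@acceleration) != N_ACCEL_CHANNELS) {
    msg <- c(msg, sprintf("'acceleration' must have %d columns",
                          N_ACCEL_CHANNELS))
  }
  if (nrow(object@pressure) < 1L) {
    msg <- c(msg, "a session must contain at least one frame")
  }
  if (nrow(object@pressure) != nrow(object@acceleration)) {
    msg <- c(msg, "pressure and acceleration must have the same frame count")
  }
  bad <- !(object@pressure %in% PRESSURE_LEVELS)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(object@pressure)), arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "pressure values must be 0, 1 or 2 (first violation: frame %d, channel %s)",
      idx[1L], pressureChannelNames()[idx[2L]]))
  }
  if (any(!is.finite(object@acceleration))) {
    msg <- c(msg, "acceleration values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' StepSegment: one gait cycle cut from a recording
#'
#' A contiguous slice of a [RecordingSession] spanning one complete gait
#' cycle of the reference foot, from one swing-phase onset to the next
#' (half-open frame interval `[start, end)`, 0-based). Carries all 16
#' pressure and all 6 acceleration channels over that span.
#'
#' @slot subjectID character(1).
#' @slot pressure numeric matrix, `T x 16`.
#' @slot acceleration numeric matrix, `T x 6`.
#' @slot startFrame integer(1); 0-based first frame in the source session.
#' @slot endFrame integer(1); 0-based one-past-last frame.
#'
#' @seealso [segmentSteps()], [normalizeStep()]
#' @export
setClass("StepSegment",
  representation(
    subjectID = "character",
    pressure = "matrix",
    acceleration = "matrix",
    startFrame = "integer",
    endFrame = "integer"
  )
)

setValidity("StepSegment", function(object) {
  msg <- character()
  T_ <- nrow(object@pressure)
  if (T_ < 2L) msg <- c(msg, "a step must span at least 2 frames")
  if (nrow(object@acceleration) != T_) {
    msg <- c(msg, "pressure and acceleration must have the same frame count")
  }
  if (object@endFrame - object@startFrame != T_) {
    msg <- c(msg, "duration must equal endFrame - startFrame")
  }
  if (length(msg)) msg else TRUE
})

#' NormalizedStep: a gait cycle resampled to fixed length
#'
#' One gait cycle with every channel linearly resampled onto a common grid
#' of `cycleLength` frames (63 by default), removing walking-speed
#' variability. The per-modality vector forms (row-major, i.e. time-major
#' lexicographic flattening) are available through [pressureVector()] and
#' [accelVector()].
#'
#' @slot subjectID character(1).
#' @slot pressureMatrix numeric matrix, `l x 16` (real-valued after
#'   interpolation; no re-quantization).
#' @slot accelMatrix numeric matrix, `l x 6`.
#' @slot cycleLength integer(1); the normalized length `l`.
#'
#' @seealso [normalizeStep()], [vectorizeMatrix()]
#' @export
setClass("NormalizedStep",
  representation(
    subjectID = "character",
    pressureMatrix = "matrix",
    accelMatrix = "matrix",
    cycleLength = "integer"
  )
)

setValidity("NormalizedStep", function(object) {
  msg <- character()
  l <- object@cycleLength
  if (nrow(object@pressureMatrix) != l || nrow(object@accelMatrix) != l) {
    msg <- c(msg, "matrices must have exactly 'cycleLength' rows")
  }
  if (ncol(object@pressureMatrix) != N_PRESSURE_CHANNELS ||
      ncol(object@accelMatrix) != N_ACCEL_CHANNELS) {
    msg <- c(msg, "matrices must have 16 (pressure) and 6 (acceleration) columns")
  }
  if (length(msg)) msg else TRUE
})

#' GaitSample: the classifier input built from k consecutive steps
#'
#' The concatenation, in time order, of `k` consecutive normalized steps of
#' one subject, after per-step regularization (small additive uniform
#' noise). `pressureInput` has length `k * l * 16` and `accelInput`
#' `k * l * 6`.
#'
#' @slot subjectID character(1).
#' @slot k integer(1); number of consecutive steps per sample.
#' @slot pressureInput numeric vector of length `k * l * 16`.
#' @slot accelInput numeric vector of length `k * l * 6`.
#'
#' @seealso [groupSteps()]
#' @export
setClass("GaitSample",
  representation(
    subjectID = "character",
    k = "integer",
    pressureInput = "numeric",
    accelInput = "numeric"
  )
)

setValidity("GaitSample", function(object) {
  msg <- character()
  if (object@k < 1L) msg <- c(msg, "'k' must be >= 1")
  rat <- length(object@pressureInput) / length(object@accelInput)
  if (!isTRUE(all.equal(rat, N_PRESSURE_CHANNELS / N_ACCEL_CHANNELS))) {
    msg <- c(msg, "pressure/acceleration input lengths are inconsistent")
  }
  if (length(msg)) msg else TRUE
})

#' NLDAModel: a fitted null-space discriminant projection
#'
#' The projection matrix `W` of null-space linear discriminant analysis for
#' one sensing modality: `W` spans directions inside the null space of the
#' within-class scatter that maximize between-class scatter, so all
#' training samples of a class project onto a single point (their class
#' centroid image). Features (columns) are ordered by descending
#' between-class eigenvalue.
#'
#' @slot W numeric matrix, `n x n'`; orthonormal columns.
#' @slot modality character(1); `"pressure"` or `"acceleration"`.
#' @slot centroids numeric matrix, `C x n'`; projected training class means.
#' @slot classLevels character; class labels, aligned with `centroids` rows.
#' @slot sbEigenvalues numeric; between-class eigenvalue per feature.
#'
#' @seealso [nldaFit()], [nldaTransform()]
#' @export
setClass("NLDAModel",
  representation(
    W = "matrix",
    modality = "character",
    centroids = "matrix",
    classLevels = "character",
    sbEigenvalues = "numeric"
  )
)

setValidity("NLDAModel", function(object) {
  msg <- character()
  if (ncol(object@W) != ncol(object@centroids) &&
      nrow(object@centroids) > 0L) {
    msg <- c(msg, "'centroids' must have one column per projection vector")
  }
  if (nrow(object@centroids) != length(object@classLevels)) {
    msg <- c(msg, "'centroids' must have one row per class level")
  }
  if (length(object@sbEigenvalues) != ncol(object@W)) {
    msg <- c(msg, "'sbEigenvalues' must have one entry per feature")
  }
  if (length(msg)) msg else TRUE
})

#' CandidateFeatureSet: merged single-modal features with Laplacian scores
#'
#' The candidate feature matrix over training samples (pressure features
#' first, then acceleration; `p = 2(C-1)` columns), each column's
#' supervised Laplacian score, and the resulting selection order.
#'
#' @slot F numeric matrix, `N x p`.
#' @slot labels factor of length `N`.
#' @slot scores numeric of length `p`.
#' @slot selectionOrder integer permutation of `1:p`, best feature first.
#'
#' @seealso [candidateFeatures()], [laplacianScores()], [selectFeatures()]
#' @export
setClass("CandidateFeatureSet",
  representation(
    F = "matrix",
    labels = "factor",
    scores = "numeric",
    selectionOrder = "integer"
  )
)

setValidity("CandidateFeatureSet", function(object) {
  msg <- character()
  p <- ncol(object@F)
  if (length(object@scores) != p) {
    msg <- c(msg, "'scores' must have one entry per candidate feature")
  }
  if (!identical(sort(object@selectionOrder), seq_len(p))) {
    msg <- c(msg, "'selectionOrder' must be a permutation of 1:p")
  }
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (nrow(object@F) != length(object@labels)) {
    msg <- c(msg, "'labels' must have one entry per row of 'F'")
  }
  if (length(msg)) msg else TRUE
})

#' GaitIdentifier: a complete fitted identification pipeline
#'
#' Everything needed to identify the subject of a new recording: the two
#' per-modality NLDA models, the training-derived Laplacian-score feature
#' selection, the multi-modal training features and their labels, and the
#' preprocessing configuration. Identification of new sessions is a pure
#' function of these training-fit artifacts.
#'
#' @slot nldaPressure fitted [NLDAModel] for the pressure modality.
#' @slot nldaAccel fitted [NLDAModel] for the acceleration modality.
#' @slot selection integer; candidate-feature indices in selection order.
#' @slot trainFeatures numeric matrix, `M x d`; multi-modal training vectors.
#' @slot trainLabels character of length `M`.
#' @slot config list; preprocessing/fusion configuration used at fit time.
#'
#' @seealso [fitIdentifier()], [identifySubject()]
#' @export
setClass("GaitIdentifier",
  representation(
    nldaPressure = "NLDAModel",
    nldaAccel = "NLDAModel",
    selection = "integer",
    trainFeatures = "matrix",
    trainLabels = "character",
    config = "list"
  )
)

#' ExperimentResult: identification rates over repeated random splits
#'
#' Per-repeat identification accuracies from the repeated random-split
#' protocol, broken down by modality, feature dimension and steps-per-sample
#' `k`, plus a confusion-count matrix accumulated across repeats (at the
#' default operating point) for diagnostics.
#'
#' @slot results data.frame with columns `repeat_`, `k`, `d`, `modality`,
#'   `accuracy`, `n_train`, `n_test`.
#' @slot confusion table of true x predicted counts (multi-modal features at
#'   the default dimension), summed over repeats.
#' @slot config list; the [experimentConfig()] used.
#'
#' @seealso [runExperiment()], [sweepK()], [resultsTable()]
#' @export
setClass("ExperimentResult",
  representation(
    results = "data.frame",
    confusion = "table",
    config = "list"
  )
)

setValidity("ExperimentResult", function(object) {
  msg <- character()
  need <- c("repeat_", "k", "d", "modality", "accuracy", "n_train", "n_test")
  if (!all(need %in% names(object@results))) {
    msg <- c(msg, paste("'results' must have columns",
                        paste(need, collapse = ", ")))
  } else if (nrow(object@results) &&
             (any(object@results$accuracy < 0) ||
              any(object@results$accuracy > 1))) {
    msg <- c(msg, "accuracies must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
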