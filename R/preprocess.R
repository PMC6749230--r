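#' Detect swing-phase onsets for one foot
#'
#' The swing phase of a foot is the interval during which every pressure
#' sensor of that foot reads zero. Each maximal all-zero run marks one
#' swing phase; its first frame is the swing-phase onset, the anchor event
#' used to delimit gait cycles.
#'
#' @param footPressure `time x 8` matrix of one foot's pressure channels.
#' @return Integer vector of 0-based onset frame indices, increasing;
#'   empty when the foot never fully leaves the ground.
#' @examples
#' p <- matrix(1, 10, 8); p[4:6, ] <- 0
#' detectSwingOnsets(p)  # 3 (0-based)
#' @export
detectSwingOnsets <- function(footPressure) {
  footPressure <- as.matrix(footPressure)
  stopifnot(ncol(footPressure) == 8L)
  zero <- rowSums(footPressure != 0) == 0L
  if (!any(zero)) return(integer(0))
  starts <- which(zero & !c(FALSE, zero[-length(zero)]))
  as.integer(starts - 1L)  # 0-based
}

#' Segment a recording into gait cycles
#'
#' A gait cycle spans from one swing-phase onset of the reference foot to
#' the next (half-open `[start, end)`, 0-based frames). Every segment
#' carries all 16 pressure and all 6 acceleration channels over its span;
#' partial leading/trailing cycles are discarded, as are implausibly short
#' segments (sensor glitches).
#'
#' @param session a [RecordingSession].
#' @param referenceFoot `"left"` or `"right"`; which foot's swing onsets
#'   delimit cycles.
#' @param minCycleFrames segments shorter than this many frames are
#'   dropped (default 10 frames = 0.1 s at 100 Hz).
#' @return A list of [StepSegment] objects (possibly empty).
#' @seealso [detectSwingOnsets()], [normalizeStep()]
#' @export
segmentSteps <- function(session, referenceFoot = c("left", "right"),
                         minCycleFrames = 10L) {
  stopifnot(is(session, "RecordingSession"))
  referenceFoot <- match.arg(referenceFoot)
  cols <- if (referenceFoot == "left") 1:8 else 9:16
  onsets <- detectSwingOnsets(session@pressure[, cols, drop = FALSE])
  if (length(onsets) < 2L) return(list())
  segs <- vector("list", length(onsets) - 1L)
  keep <- logical(length(segs))
  for (i in seq_along(segs)) {
    s <- onsets[i]
    e <- onsets[i + 1L]
    if (e - s < max(2L, minCycleFrames)) next
    rows <- (s + 1L):e  # 1-based rows for 0-based [s, e)
    segs[[i]] <- new("StepSegment",
      subjectID = session@subjectID,
      pressure = session@pressure[rows, , drop = FALSE],
      acceleration = session@acceleration[rows, , drop = FALSE],
      startFrame = as.integer(s), endFrame = as.integer(e))
    keep[i] <- TRUE
  }
  segs[keep]
}

resampleChannel <- function(v, l) {
  T_ <- length(v)
  if (T_ == l) return(v)
  stats::approx(x = seq_len(T_) - 1L, y = v,
                xout = seq(0, T_ - 1L, length.out = l))$y
}

#' Normalize a gait cycle to a fixed length
#'
#' Resamples every channel independently from its `T` frames onto a
#' uniform grid of `l` frames by linear interpolation (the grid maps
#' `[0, T-1]` onto `[0, l-1]`), removing walking-speed variability.
#' Pressure values become real-valued; they are not re-quantized.
#'
#' @param step a [StepSegment] with at least 2 frames.
#' @param l target cycle length (default 63, giving per-step vectors of
#'   length 1008 for pressure and 378 for acceleration).
#' @return A [NormalizedStep].
#' @export
normalizeStep <- function(step, l = 63L) {
  stopifnot(is(step, "StepSegment"))
  l <- as.integer(l)
  if (l < 2L) stop("'l' must be at least 2")
  if (nrow(step@pressure) < 2L) {
    stop("degenerate step: fewer than 2 frames cannot be resampled")
  }
  pm <- apply(step@pressure, 2L, resampleChannel, l = l)
  am <- apply(step@acceleration, 2L, resampleChannel, l = l)
  new("NormalizedStep", subjectID = step@subjectID,
      pressureMatrix = pm, accelMatrix = am, cycleLength = l)
}

#' Flatten a time-by-channel matrix in lexicographic (row-major) order
#'
#' Element `(t, ch)` of the matrix maps to vector index `t * c + ch`
#' (0-based): time varies slowest. A normalized 63 x 16 pressure matrix
#' yields a length-1008 vector, a 63 x 6 acceleration matrix a length-378
#' vector.
#'
#' @param m an `l x c` numeric matrix.
#' @return A numeric vector of length `l * c`.
#' @seealso [unvectorizeMatrix()]
#' @export
vectorizeMatrix <- function(m) {
  m <- as.matrix(m)
  as.vector(t(m))
}

#' Invert [vectorizeMatrix()]
#'
#' @param v a numeric vector of length `l * nChannels`.
#' @param nChannels number of channels `c`.
#' @return The `l x c` matrix whose row-major flattening is `v`.
#' @export
unvectorizeMatrix <- function(v, nChannels) {
  if (length(v) %% nChannels != 0L) {
    stop("vector length is not a multiple of the channel count")
  }
  matrix(v, ncol = nChannels, byrow = TRUE)
}

#' Regularize a vector by small additive uniform noise
#'
#' Adds independent draws from Uniform[0, `noiseHigh`) to every element.
#' The swing phase forces entire stretches of the pressure vectors to zero
#' in all samples, which would make scatter matrices rank-deficient; this
#' jitter restores numerical rank before eigendecomposition.
#'
#' @param v numeric vector.
#' @param noiseHigh upper bound of the uniform noise (default 0.1).
#' @param seed optional integer; when given, seeds the draw locally
#'   (the caller's RNG state is untouched). When `NULL`, the current RNG
#'   stream is used.
#' @return The perturbed vector, same length.
#' @export
regularize <- function(v, noiseHigh = 0.1, seed = NULL) {
  draw <- function() v + stats::runif(length(v), min = 0, max = noiseHigh)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Group consecutive normalized steps into classifier samples
#'
#' Forms non-overlapping windows of `k` consecutive steps of one subject,
#' regularizes each step's pressure and acceleration vectors once, and
#' concatenates them in time order. The trailing `n mod k` leftover steps
#' are discarded, so `n` steps yield `floor(n / k)` samples.
#'
#' @param steps list of [NormalizedStep] for one subject, in time order.
#' @param k steps per sample (>= 1).
#' @param noiseHigh regularization noise bound (default 0.1).
#' @param seed optional integer seeding the regularization noise locally.
#' @return A list of [GaitSample] objects.
#' @seealso [regularize()], [preprocessCohort()]
#' @export
groupSteps <- function(steps, k = 1L, noiseHigh = 0.1, seed = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  if (length(steps) > 0L) {
    ids <- unique(vapply(steps, subjectID, character(1)))
    if (length(ids) > 1L) stop("all steps must belong to one subject")
  }
  build <- function() {
    nSamples <- length(steps) %/% k
    out <- vector("list", nSamples)
    for (i in seq_len(nSamples)) {
      chunk <- steps[((i - 1L) * k + 1L):(i * k)]
      pv <- unlist(lapply(chunk, function(s)
        regularize(pressureVector(s), noiseHigh)))
      av <- unlist(lapply(chunk, function(s)
        regularize(accelVector(s), noiseHigh)))
      out[[i]] <- new("GaitSample", subjectID = subjectID(chunk[[1L]]),
                      k = k, pressureInput = pv, accelInput = av)
    }
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Segment and normalize every session of a cohort
#'
#' Runs the deterministic part of preprocessing (segmentation into gait
#' cycles and length normalization) over a list of sessions, returning
#' normalized steps grouped by subject in time order. Regularization and
#' `k`-step grouping, which consume randomness, are applied later by
#' [groupSteps()].
#'
#' @param sessions list of [RecordingSession] objects.
#' @param cycleLength normalized cycle length `l` (default 63).
#' @param referenceFoot foot whose swing onsets delimit cycles.
#' @param minCycleFrames glitch filter passed to [segmentSteps()].
#' @return A named list (one element per subject) of lists of
#'   [NormalizedStep].
#' @export
preprocessCohort <- function(sessions, cycleLength = 63L,
                             referenceFoot = "left", minCycleFrames = 10L) {
  bySubject <- list()
  for (s in sessions) {
    segs <- segmentSteps(s, referenceFoot = referenceFoot,
                         minCycleFrames = minCycleFrames)
    if (length(segs) == 0L) next
    norm <- lapply(segs, normalizeStep, l = cycleLength)
    id <- subjectID(s)
    bySubject[[id]] <- c(bySubject[[id]], norm)
  }
  bySubject
}
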