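# Population prototype of the per-foot stance activation windows
# (fractions of the stance phase) and peak levels. Layout per foot:
# sensors 1-3 front-left, 4-6 front-right, 7-8 heel. Heel sensors load
# from stance onset; forefoot sensors load towards push-off. Sensor 8
# (heel) keeps onset 0 and sensor 1 (forefoot) keeps offset 1 so the
# union of active windows always covers the whole stance: no stance frame
# is ever all-zero and swing runs stay maximal.
protoOnset <- c(0.35, 0.40, 0.45, 0.35, 0.40, 0.30, 0.00, 0.00)
protoOffset <- c(1.00, 0.95, 0.90, 0.95, 0.90, 0.85, 0.60, 0.55)
protoPeak <- c(2, 1, 1, 2, 1, 1, 2, 2)

#' Specification of a synthetic walking cohort
#'
#' Bundles the knobs of the cohort simulator. The defaults are the
#' standard operating point used throughout the package's evaluation: 14
#' subjects (the typical small-cohort identification setting), moderate
#' between-subject separation, step-timing and cadence variability within
#' subject, and additive accelerometer noise.
#'
#' @param C number of subjects (>= 2).
#' @param separation scale of between-subject template differences; 0
#'   makes all subjects identical, 1 is the moderate default.
#' @param stepsPerSubject gait cycles recorded per subject.
#' @param seed master seed for template and session generation.
#' @param meanCycleBase population mean gait-cycle length in frames at
#'   100 Hz (default 115, i.e. 1.15 s; subjects deviate by up to ~15
#'   frames at separation 1, spanning roughly 1.0--1.3 s).
#' @param cycleCv within-subject coefficient of variation of cycle length.
#' @param accelNoiseSd standard deviation of the additive Gaussian noise
#'   on acceleration channels (waveform amplitudes are order 1).
#' @param stepJitterSd per-step standard deviation of sensor
#'   activation-window timing (fractions of stance).
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(C = 14L, separation = 1, stepsPerSubject = 40L,
                       seed = 1L, meanCycleBase = 115, cycleCv = 0.05,
                       accelNoiseSd = 0.3, stepJitterSd = 0.02) {
  stopifnot(C >= 2L, separation >= 0, stepsPerSubject >= 1L,
            meanCycleBase >= 20, cycleCv >= 0, accelNoiseSd >= 0,
            stepJitterSd >= 0)
  structure(list(C = as.integer(C), separation = separation,
                 stepsPerSubject = as.integer(stepsPerSubject),
                 seed = as.integer(seed), meanCycleBase = meanCycleBase,
                 cycleCv = cycleCv, accelNoiseSd = accelNoiseSd,
                 stepJitterSd = stepJitterSd),
            class = "CohortSpec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Draw the subject templates of a synthetic cohort
#'
#' Each subject's gait template is the shared population prototype
#' perturbed by subject-specific deviations scaled by `separation`:
#' per-sensor activation onset/offset shifts and occasional peak-level
#' flips for the 16 pressure sensors, amplitude and phase perturbations of
#' a 3-harmonic acceleration waveform per channel, and a subject-specific
#' mean cadence. With `separation = 0` every template equals the
#' prototype; template differences grow monotonically with `separation`
#' for a fixed seed (the underlying deviates do not depend on it).
#'
#' @param spec a [cohortSpec()].
#' @return A list of `SubjectTemplate` lists with fields `subjectID`,
#'   `onset`, `offset`, `peak` (length 16), `accelAmp`, `accelPhase`
#'   (6 x 3), `meanCycleFrames`, `cycleCv`, `accelNoiseSd`.
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  sep <- spec$separation
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$C), function(i) {
      onJit <- sep * stats::runif(16, -0.08, 0.08)
      offJit <- sep * stats::runif(16, -0.08, 0.08)
      onset <- clamp(rep(protoOnset, 2) + onJit, 0, 0.85)
      offset <- clamp(rep(protoOffset, 2) + offJit, 0.05, 1)
      # coverage guarantees (see prototype comment): per foot, sensor 8
      # loads at stance onset, sensor 1 through push-off
      for (foot in c(0L, 8L)) {
        onset[foot + 8L] <- 0
        offset[foot + 8L] <- clamp(offset[foot + 8L], 0.5, 0.9)
        offset[foot + 1L] <- 1
        onset[foot + 1L] <- clamp(onset[foot + 1L], 0.1, 0.5)
      }
      offset <- pmax(offset, onset + 0.05)

      flip <- stats::runif(16) < 0.25 * sep
      peak <- rep(protoPeak, 2)
      peak[flip] <- 3 - peak[flip]  # 1 <-> 2

      baseAmp <- matrix(rep(c(1.0, 0.5, 0.25), each = 6), 6, 3)
      chScale <- c(1, 0.8, 1.2, 1, 0.8, 1.2)
      ampJit <- matrix(stats::runif(18, -0.3, 0.3), 6, 3)
      accelAmp <- baseAmp * chScale * (1 + sep * ampJit)
      basePhase <- matrix(rep(c(0, 0, 0, pi, pi, pi), 3), 6, 3)
      accelPhase <- basePhase + sep * matrix(stats::runif(18, -0.6, 0.6), 6, 3)

      mcf <- max(20, round(spec$meanCycleBase + sep * stats::runif(1, -15, 15)))

      structure(list(
        subjectID = sprintf("S%02d", i),
        onset = onset, offset = offset, peak = peak,
        accelAmp = accelAmp, accelPhase = accelPhase,
        meanCycleFrames = mcf, cycleCv = spec$cycleCv,
        accelNoiseSd = spec$accelNoiseSd
      ), class = "SubjectTemplate")
    })
  })
}

renderStanceRow <- function(psi, onset, offset, peak) {
  ifelse(psi >= onset & psi <= offset, peak, 0)
}

# Render one foot's 8 pressure channels for one cycle of length L whose
# swing phase occupies cycle fraction [swingStart, swingStart + swingFrac)
# (mod 1). The reference (left) foot has swingStart = 0 so the cycle
# begins exactly at its swing onset; the contralateral foot is offset by
# half a cycle.
renderFootCycle <- function(L, swingFrac, swingStart, onset, offset, peak,
                            jitterSd) {
  out <- matrix(0, L, 8)
  phi <- ((seq_len(L) - 1L) / L - swingStart) %% 1
  stanceMask <- phi >= swingFrac
  sf <- which(stanceMask)
  if (length(sf) == 0L) return(out)
  psi <- (phi[sf] - swingFrac) / (1 - swingFrac)
  psi <- (psi - min(psi)) / max(max(psi) - min(psi), .Machine$double.eps)
  on <- clamp(onset + stats::rnorm(8, 0, jitterSd), 0, 1)
  off <- clamp(offset + stats::rnorm(8, 0, jitterSd), 0, 1)
  # keep the stance-coverage guarantee under jitter
  on[8L] <- 0
  off[8L] <- max(off[8L], 0.5)
  off[1L] <- 1
  on[1L] <- min(on[1L], 0.5)
  off <- pmax(off, on + 0.02)
  for (s in 1:8) {
    out[sf, s] <- renderStanceRow(psi, on[s], off[s], peak[s])
  }
  out
}

renderAccel <- function(L, template, phiOffset = 0) {
  phi <- ((seq_len(L) - 1L) / L + phiOffset) %% 1
  out <- matrix(0, L, 6)
  for (ch in 1:6) {
    v <- 0
    for (h in 1:3) {
      v <- v + template$accelAmp[ch, h] *
        sin(2 * pi * h * phi + template$accelPhase[ch, h])
    }
    out[, ch] <- v + stats::rnorm(L, 0, template$accelNoiseSd)
  }
  out
}

#' Synthesize one walking session from a subject template
#'
#' Renders `nSteps` consecutive gait cycles: per cycle a length is drawn
#' around the subject's mean cadence, the reference (left) foot swings for
#' the first 40% of the cycle (all-zero pressure) and then loads its
#' sensors through their subject-specific activation windows; the right
#' foot follows the same pattern offset by half a cycle; acceleration is
#' the subject's 3-harmonic waveform warped to the cycle plus Gaussian
#' noise. A final partial swing is appended so the last complete cycle is
#' bounded by a detectable swing onset. The exact ground-truth cycle
#' boundaries (0-based, half-open, matching the swing-onset convention of
#' [segmentSteps()]) are returned alongside the session.
#'
#' @param template a `SubjectTemplate` from [makeCohort()].
#' @param nSteps number of complete gait cycles to render.
#' @param seed integer seed; the draw is deterministic given
#'   (template, nSteps, seed).
#' @param stanceFraction fraction of the cycle spent in stance
#'   (default 0.6).
#' @param stepJitterSd per-step timing jitter of the activation windows.
#' @return A list with `session` (a [RecordingSession]) and `boundaries`
#'   (an `nSteps x 2` matrix of `[start, end)` frame indices).
#' @export
synthSession <- function(template, nSteps, seed = 1L, stanceFraction = 0.6,
                         stepJitterSd = 0.02) {
  stopifnot(inherits(template, "SubjectTemplate"), nSteps >= 1L)
  swingFrac <- 1 - stanceFraction
  withr::with_seed(seed, {
    lens <- pmax(20L, as.integer(round(stats::rnorm(
      nSteps, template$meanCycleFrames,
      template$cycleCv * template$meanCycleFrames))))
    pr <- vector("list", nSteps + 1L)
    ac <- vector("list", nSteps + 1L)
    for (i in seq_len(nSteps)) {
      L <- lens[i]
      left <- renderFootCycle(L, swingFrac, 0, template$onset[1:8],
                              template$offset[1:8], template$peak[1:8],
                              stepJitterSd)
      right <- renderFootCycle(L, swingFrac, 0.5, template$onset[9:16],
                               template$offset[9:16], template$peak[9:16],
                               stepJitterSd)
      pr[[i]] <- cbind(left, right)
      ac[[i]] <- cbind(renderAccel(L, template, 0)[, 1:3],
                       renderAccel(L, template, 0.5)[, 4:6])
    }
    # trailing partial cycle: just the left-foot swing, so the final
    # complete cycle ends at a detectable swing onset
    Lx <- template$meanCycleFrames
    tail_ <- max(2L, as.integer(floor(swingFrac * Lx)) - 1L)
    right <- renderFootCycle(Lx, swingFrac, 0.5, template$onset[9:16],
                             template$offset[9:16], template$peak[9:16],
                             stepJitterSd)[seq_len(tail_), , drop = FALSE]
    pr[[nSteps + 1L]] <- cbind(matrix(0, tail_, 8), right)
    ac[[nSteps + 1L]] <- cbind(renderAccel(Lx, template, 0)[seq_len(tail_), 1:3,
                                                            drop = FALSE],
                               renderAccel(Lx, template, 0.5)[seq_len(tail_),
                                                              4:6, drop = FALSE])
    session <- RecordingSession(template$subjectID, do.call(rbind, pr),
                                do.call(rbind, ac))
    starts <- cumsum(c(0L, lens[-nSteps]))
    boundaries <- cbind(start = starts, end = starts + lens)
    list(session = session, boundaries = boundaries)
  })
}

#' Simulate a full cohort of walking sessions
#'
#' Draws the subject templates and renders one session per subject, with
#' per-session seeds derived deterministically from the cohort seed.
#'
#' @param spec a [cohortSpec()].
#' @return A list with `sessions` (list of [RecordingSession]),
#'   `boundaries` (list of ground-truth boundary matrices, same order) and
#'   `templates`.
#' @export
simulateCohort <- function(spec) {
  templates <- makeCohort(spec)
  sessionSeeds <- withr::with_seed(spec$seed + 1L,
    sample.int(.Machine$integer.max, spec$C))
  out <- lapply(seq_along(templates), function(i)
    synthSession(templates[[i]], spec$stepsPerSubject,
                 seed = sessionSeeds[i], stepJitterSd = spec$stepJitterSd))
  list(sessions = lapply(out, `[[`, "session"),
       boundaries = lapply(out, `[[`, "boundaries"),
       templates = templates)
}
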