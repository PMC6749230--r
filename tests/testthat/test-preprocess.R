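# Brute-force reference: first index of every maximal all-zero run.
naiveZeroRunStarts <- function(zeroFlags) {
  starts <- integer(0)
  for (i in seq_along(zeroFlags)) {
    if (zeroFlags[i] && (i == 1L || !zeroFlags[i - 1L])) {
      starts <- c(starts, i - 1L)
    }
  }
  starts
}

test_that("swing onsets are the starts of maximal all-zero runs", {
  p <- matrix(1, 91, 8)
  p[42:51, ] <- 0   # 0-based frames 41-50
  p[82:91, ] <- 0   # 0-based frames 81-90
  expect_identical(detectSwingOnsets(p), c(41L, 81L))

  expect_identical(detectSwingOnsets(matrix(1, 10, 8)), integer(0))
  expect_identical(detectSwingOnsets(matrix(0, 10, 8)), 0L)
  # a single nonzero sensor keeps the frame out of the swing phase
  p2 <- matrix(0, 5, 8); p2[3, 7] <- 2
  expect_identical(detectSwingOnsets(p2), c(0L, 3L))

  for (seed in 1:20) {
    z <- withr::with_seed(seed, runif(60) < 0.4)
    p3 <- matrix(withr::with_seed(seed + 100,
                                  sample(0:2, 60 * 8, replace = TRUE)), 60, 8)
    p3[z, ] <- 0
    p3[!z, 1] <- pmax(p3[!z, 1], 1)  # ensure non-swing frames stay nonzero
    zero <- rowSums(p3 != 0) == 0
    expect_identical(detectSwingOnsets(p3), naiveZeroRunStarts(zero))
  }
})

makeTinySessionFullContact <- function() {
  RecordingSession("S01", matrix(1, 50, 16), matrix(0, 50, 6))
}

test_that("segmentation spans onset-to-onset and drops partial cycles", {
  # 3 onsets -> 2 complete cycles
  p <- matrix(1, 100, 16)
  p[11:25, 1:8] <- 0; p[41:55, 1:8] <- 0; p[76:90, 1:8] <- 0
  s <- RecordingSession("S01", p, matrix(0, 100, 6))
  segs <- segmentSteps(s)
  expect_length(segs, 2L)
  expect_identical(unname(frameRange(segs[[1]])), c(10L, 40L))
  expect_identical(unname(frameRange(segs[[2]])), c(40L, 75L))
  expect_identical(nFrames(segs[[1]]), 30L)

  # constant full contact: no swing phase, no cycles
  expect_length(segmentSteps(makeTinySessionFullContact()), 0L)

  # right-foot reference uses the other channel block
  segsR <- segmentSteps(s, referenceFoot = "right")
  expect_length(segsR, 0L)
})

test_that("segmentation recovers simulator ground truth exactly", {
  for (seed in c(3, 17)) {
    sim <- simulateCohort(cohortSpec(C = 3, stepsPerSubject = 12,
                                     seed = seed))
    for (i in seq_along(sim$sessions)) {
      segs <- segmentSteps(sim$sessions[[i]])
      got <- t(vapply(segs, frameRange, numeric(2)))
      expect_equal(unname(got), unname(sim$boundaries[[i]]))
    }
  }
})

test_that("length normalization interpolates each channel linearly", {
  mkStep <- function(p, a) new("StepSegment", subjectID = "S01",
                               pressure = p, acceleration = a,
                               startFrame = 0L, endFrame = nrow(p))
  # constants are preserved at any length
  st <- mkStep(matrix(2, 17, 16), matrix(7, 17, 6))
  ns <- normalizeStep(st, l = 63)
  expect_identical(dim(pressureMatrix(ns)), c(63L, 16L))
  expect_true(all(pressureMatrix(ns) == 2))
  expect_true(all(accelMatrix(ns) == 7))

  # T == l is the identity
  a <- matrix(rnorm(63 * 6), 63, 6)
  p <- matrix(sample(0:2, 63 * 16, replace = TRUE), 63, 16)
  ns <- normalizeStep(mkStep(p, a), l = 63)
  expect_equal(unname(accelMatrix(ns)), a)
  expect_equal(unname(pressureMatrix(ns)), p)

  # closed form: a linear ramp over T=127 frames resampled to l=63
  # evaluates to j/62 at output row j (linear interpolation is exact on
  # linear signals)
  ramp <- seq(0, 1, length.out = 127)
  st <- mkStep(matrix(0, 127, 16), matrix(ramp, 127, 6))
  ns <- normalizeStep(st, l = 63)
  expect_equal(accelMatrix(ns)[, 1], (0:62) / 62, tolerance = 1e-12)

  expect_error(normalizeStep(mkStep(matrix(0, 2, 16), matrix(0, 2, 6)),
                             l = 1), "at least 2")
})

test_that("vectorization is row-major and invertible", {
  expect_identical(vectorizeMatrix(rbind(c(1, 2), c(3, 4))), c(1, 2, 3, 4))
  m <- matrix(rnorm(63 * 16), 63, 16)
  expect_length(vectorizeMatrix(m), 1008L)
  expect_length(vectorizeMatrix(matrix(0, 63, 6)), 378L)
  # element (t, ch) lands at index t*c + ch (0-based)
  v <- vectorizeMatrix(m)
  expect_identical(v[(10 - 1) * 16 + 3], m[10, 3])
  expect_equal(unvectorizeMatrix(v, 16), m)
  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(rnorm(7 * 4), 7, 4))
    expect_equal(unvectorizeMatrix(vectorizeMatrix(m), 4), m)
  }
})

test_that("regularization adds bounded uniform noise reproducibly", {
  v <- rnorm(1e5)
  out <- regularize(v, seed = 5)
  expect_length(out, length(v))
  expect_true(all(out - v >= 0 & out - v < 0.1))
  # law of large numbers: mean noise ~ 0.05
  expect_lt(abs(mean(out - v) - 0.05), 0.002)
  expect_identical(regularize(v, seed = 5), out)
  expect_false(identical(regularize(v, seed = 6), out))
})

test_that("k-step grouping windows, discards leftovers and concatenates", {
  sim <- simulateCohort(cohortSpec(C = 2, stepsPerSubject = 5, seed = 9))
  steps <- preprocessCohort(sim$sessions)[["S01"]]
  expect_length(steps, 5L)

  g2 <- groupSteps(steps, k = 2, seed = 1)
  expect_length(g2, 2L)  # floor(5/2), one step discarded
  g1 <- groupSteps(steps, k = 1, seed = 1)
  expect_length(g1, 5L)
  expect_length(pressureVector(g1[[1]]), 1008L)
  expect_length(pressureVector(g2[[1]]), 2 * 1008L)
  expect_length(accelVector(g2[[1]]), 2 * 378L)
  expect_length(groupSteps(steps, k = 6, seed = 1), 0L)

  # concatenation preserves time order; noise is bounded by 0.1
  raw <- c(pressureVector(steps[[1]]), pressureVector(steps[[2]]))
  diff_ <- pressureVector(g2[[1]]) - raw
  expect_true(all(diff_ >= 0 & diff_ < 0.1))

  # per-subject counts across a cohort sum to sum_s floor(n_s / k)
  sim <- simulateCohort(cohortSpec(C = 4, stepsPerSubject = 11, seed = 2))
  steps <- preprocessCohort(sim$sessions)
  for (k in 1:3) {
    tot <- sum(vapply(steps, function(st)
      length(groupSteps(st, k = k, seed = 1)), integer(1)))
    expect_identical(tot, sum(vapply(steps, length, integer(1)) %/% k))
  }
})

test_that("the preprocess chain is deterministic given its seed", {
  sim <- simulateCohort(cohortSpec(C = 2, stepsPerSubject = 6, seed = 4))
  steps1 <- preprocessCohort(sim$sessions)
  steps2 <- preprocessCohort(sim$sessions)
  expect_equal(steps1, steps2)
  g1 <- groupSteps(steps1[["S01"]], k = 2, seed = 77)
  g2 <- groupSteps(steps2[["S01"]], k = 2, seed = 77)
  expect_equal(g1, g2)
})
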