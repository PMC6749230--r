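# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal valid session with arbitrary (but valid) values.
makeTinySession <- function(n = 3L, subject = "S01") {
  RecordingSession(subject,
                   pressure = matrix(0, n, 16),
                   acceleration = matrix(0, n, 6))
}

# A random valid session for round-trip properties.
randomSession <- function(seed, n = NULL) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(1:40, 1)
    RecordingSession(
      sprintf("S%02d", sample(1:20, 1)),
      pressure = matrix(sample(0:2, n * 16, replace = TRUE), n, 16),
      acceleration = matrix(rnorm(n * 6), n, 6))
  })
}

# Small labeled data in the small-sample regime (n > N - C), with
# class-specific offsets plus within-class jitter.
smallSampleData <- function(seed, C = 3L, perClass = 3L, n = 50L,
                            jitterDim = 2L, sepScale = 5) {
  withr::with_seed(seed, {
    N <- C * perClass
    centers <- matrix(rnorm(C * n, sd = sepScale), C, n)
    J <- matrix(rnorm(n * jitterDim), n, jitterDim)  # jitter subspace
    X <- centers[rep(seq_len(C), each = perClass), ] +
      matrix(rnorm(N * jitterDim), N, jitterDim) %*% t(J)
    list(X = X, labels = rep(sprintf("c%d", seq_len(C)), each = perClass))
  })
}

# Brute-force scatter matrices straight from their defining double sums.
naiveScatters <- function(X, labels) {
  labels <- factor(labels)
  n <- ncol(X)
  SW <- matrix(0, n, n)
  SB <- matrix(0, n, n)
  mu <- colMeans(X)
  for (lv in levels(labels)) {
    Xi <- X[labels == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    for (j in seq_len(nrow(Xi))) {
      d <- Xi[j, ] - mi
      SW <- SW + outer(d, d)
    }
    db <- mi - mu
    SB <- SB + nrow(Xi) * outer(db, db)
  }
  list(SW = SW, SB = SB)
}

# Brute-force Laplacian scores from the pairwise-sum identity:
# f~' L f~ = sum_ij (f~_i - f~_j)^2 W_ij / 2.
naiveLaplacianScores <- function(F, labels, m = 2) {
  N <- nrow(F)
  W <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j && labels[i] == labels[j]) {
      W[i, j] <- exp(-sum((F[i, ] - F[j, ])^2) / m)
    }
  }
  deg <- rowSums(W)
  vapply(seq_len(ncol(F)), function(r) {
    f <- F[, r]
    if (max(f) == min(f)) return(0)
    ft <- f - sum(f * deg) / sum(deg)
    num <- 0
    for (i in seq_len(N)) for (j in seq_len(N)) {
      num <- num + (ft[i] - ft[j])^2 * W[i, j]
    }
    num <- num / 2
    den <- sum(ft^2 * deg)
    if (den == 0) 0 else num / den
  }, numeric(1))
}

# The moderate-difficulty synthetic cohort used by the efficacy checks.
standardCohort <- function(seed = 101L, C = 14L, stepsPerSubject = 40L) {
  simulateCohort(cohortSpec(C = C, stepsPerSubject = stepsPerSubject,
                            seed = seed))
}
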