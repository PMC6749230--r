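#' Merge single-modal feature vectors into a candidate vector
#'
#' Concatenates the pressure-modality and acceleration-modality NLDA
#' feature vectors (pressure first) into the length `2(C-1)` candidate
#' vector from which the multi-modal features are selected.
#'
#' @param yP pressure feature vector, length `C - 1`.
#' @param yA acceleration feature vector, same length.
#' @return Numeric vector of length `2(C-1)`.
#' @export
buildCandidate <- function(yP, yA) {
  if (length(yP) != length(yA)) {
    stop("modal feature vectors must have equal length (got ",
         length(yP), " and ", length(yA), ")")
  }
  c(yP, yA)
}

#' Build the supervised similarity graph for Laplacian scoring
#'
#' Nodes are training samples; an edge joins two samples iff they share a
#' class label, weighted by the Gaussian kernel
#' `exp(-||y_i - y_j||^2 / m)` with bandwidth `m` (default 2). The graph
#' has no self-loops. Returns the weight matrix, the degree vector and the
#' graph Laplacian `L = D - W`.
#'
#' @param F `N x p` matrix of candidate vectors, one sample per row.
#' @param labels length-`N` class labels.
#' @param m kernel bandwidth (default 2).
#' @return A list with `weights` (`N x N`), `degree` (length `N`),
#'   `laplacian` (`N x N`) and `m`.
#' @seealso [laplacianScores()]
#' @export
buildGraph <- function(F, labels, m = 2) {
  F <- as.matrix(F)
  labels <- as.character(labels)
  N <- nrow(F)
  if (N < 2L) stop("at least 2 samples are required")
  if (length(labels) != N) stop("'labels' must have one entry per row")
  d2 <- as.matrix(stats::dist(F))^2
  same <- outer(labels, labels, "==")
  W <- exp(-d2 / m) * same
  diag(W) <- 0
  deg <- rowSums(W)
  L <- diag(deg) - W
  list(weights = W, degree = deg, laplacian = L, m = m)
}

#' Supervised Laplacian score of each candidate feature
#'
#' For feature column `f_r`, with `D = diag(degree)`, `L` the graph
#' Laplacian and `1` the all-ones vector, the score is
#' \deqn{LS_r = \frac{\tilde f_r^T L \tilde f_r}{\tilde f_r^T D \tilde f_r},
#' \quad \tilde f_r = f_r - \frac{f_r^T D 1}{1^T D 1} 1.}
#' A constant column (degenerate denominator) scores 0 by convention.
#' Scores are invariant to shifting a feature by a constant.
#'
#' @param graph result of [buildGraph()] on the same `N` samples.
#' @param F `N x p` feature matrix.
#' @return Numeric vector of `p` scores.
#' @export
laplacianScores <- function(graph, F) {
  F <- as.matrix(F)
  deg <- graph$degree
  if (nrow(F) != length(deg)) {
    stop("'F' must have one row per graph node")
  }
  degSum <- sum(deg)
  if (degSum <= 0) {
    stop("degenerate graph: no within-class pairs (all degrees zero)")
  }
  vapply(seq_len(ncol(F)), function(r) {
    f <- F[, r]
    if (max(f) == min(f)) return(0)  # constant feature convention
    ft <- f - sum(f * deg) / degSum
    den <- sum(ft^2 * deg)
    if (den == 0) return(0)
    num <- drop(crossprod(ft, graph$laplacian %*% ft))
    num / den
  }, numeric(1))
}

#' Rank candidate features by Laplacian score
#'
#' Orders features by score and returns the first `d`. The default keeps
#' the larger scores, the direction used throughout this pipeline; note
#' this inverts the usual unsupervised Laplacian-score convention
#' (smaller = more locality-preserving), so `direction = "smaller"` is
#' also exposed. Ties break toward the lower candidate index,
#' deterministically.
#'
#' @param scores numeric vector of `p` scores.
#' @param d number of features to select (`1 <= d <= p`).
#' @param direction `"larger"` (default) or `"smaller"`.
#' @return Integer vector of `d` candidate indices, best first.
#' @export
selectFeatures <- function(scores, d, direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  p <- length(scores)
  if (d < 1L || d > p) stop("'d' must be between 1 and ", p)
  key <- if (direction == "larger") -scores else scores
  ord <- order(key, seq_len(p))  # stable: ties toward lower index
  ord[seq_len(d)]
}

#' Gather the selected features into the multi-modal vector
#'
#' Applies a training-derived selection to one candidate vector, in
#' selection order. The same selection is applied unchanged to training
#' and test candidates.
#'
#' @param candidate length-`p` candidate vector (or `N x p` matrix).
#' @param selection integer indices from [selectFeatures()].
#' @return The selected values in selection order (vector, or `N x d`
#'   matrix for matrix input).
#' @export
buildMultimodal <- function(candidate, selection) {
  selection <- as.integer(selection)
  p <- if (is.matrix(candidate)) ncol(candidate) else length(candidate)
  if (any(selection < 1L) || any(selection > p)) {
    stop("selection index out of bounds (p = ", p, ")")
  }
  if (anyDuplicated(selection)) stop("selection indices must be distinct")
  if (is.matrix(candidate)) candidate[, selection, drop = FALSE]
  else candidate[selection]
}

#' Score and rank merged single-modal features on a training set
#'
#' Builds the candidate matrix (pressure NLDA features first, then
#' acceleration), the supervised similarity graph, the Laplacian score of
#' every candidate feature, and the resulting selection order.
#'
#' @param yP `N x (C-1)` pressure feature matrix (training samples).
#' @param yA `N x (C-1)` acceleration feature matrix.
#' @param labels length-`N` class labels.
#' @param m graph kernel bandwidth (default 2).
#' @param direction score ordering passed to [selectFeatures()].
#' @return A [CandidateFeatureSet].
#' @export
candidateFeatures <- function(yP, yA, labels, m = 2,
                              direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  yP <- as.matrix(yP)
  yA <- as.matrix(yA)
  if (nrow(yP) != nrow(yA) || ncol(yP) != ncol(yA)) {
    stop("modal feature matrices must have identical dimensions")
  }
  F <- cbind(yP, yA)
  colnames(F) <- c(paste0("P", seq_len(ncol(yP))),
                   paste0("A", seq_len(ncol(yA))))
  graph <- buildGraph(F, labels, m = m)
  scores <- laplacianScores(graph, F)
  ord <- selectFeatures(scores, d = ncol(F), direction = direction)
  new("CandidateFeatureSet", F = F, labels = factor(labels),
      scores = scores, selectionOrder = as.integer(ord))
}
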