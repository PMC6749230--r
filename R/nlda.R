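checkLabeledMatrix <- function(X, labels) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nrow(X) != length(labels)) {
    stop("'labels' must have one entry per row of the data matrix")
  }
  counts <- table(labels)
  if (any(counts == 0L)) {
    stop("every class must have at least one sample (empty: ",
         paste(names(counts)[counts == 0L], collapse = ", "), ")")
  }
  if (nlevels(labels) < 2L) stop("at least 2 classes are required")
  list(X = X, labels = labels, counts = as.vector(counts),
       levels = levels(labels))
}

#' Within- and between-class scatter matrices
#'
#' Computes the unnormalized scatter sums of discriminant analysis:
#' \deqn{S_W = \sum_i \sum_{x_j \in c_i} (x_j - \mu_i)(x_j - \mu_i)^T}
#' \deqn{S_B = \sum_i N_i (\mu_i - \mu)(\mu_i - \mu)^T}
#' where \eqn{\mu_i} is the mean of class \eqn{c_i} (with \eqn{N_i}
#' samples) and \eqn{\mu} the global mean.
#'
#' Intended for analysis and moderate dimensions; [nldaFit()] works in the
#' span of the data and never forms these `n x n` matrices.
#'
#' @param X `N x n` matrix, one sample per row.
#' @param labels length-`N` class labels (>= 2 classes, none empty).
#' @return A list with elements `SW`, `SB` (`n x n` matrices),
#'   `classMeans` (`C x n`), `globalMean` (length `n`) and `counts`.
#' @export
computeScatters <- function(X, labels) {
  lm <- checkLabeledMatrix(X, labels)
  X <- lm$X
  n <- ncol(X)
  mu <- colMeans(X)
  classMeans <- t(vapply(lm$levels, function(lv)
    colMeans(X[lm$labels == lv, , drop = FALSE]), numeric(n)))
  Hw <- X - classMeans[as.integer(lm$labels), , drop = FALSE]
  SW <- crossprod(Hw)
  Hb <- sweep(classMeans, 2L, mu) * sqrt(lm$counts)
  SB <- crossprod(Hb)
  rownames(classMeans) <- lm$levels
  list(SW = SW, SB = SB, classMeans = classMeans, globalMean = mu,
       counts = stats::setNames(lm$counts, lm$levels))
}

#' Fit a null-space linear discriminant model
#'
#' Null-space LDA for the small-sample regime (`n > N - C`, data dimension
#' exceeding the within-class degrees of freedom): the projection `W`
#' satisfies `W' S_W W = 0`, collapsing every training class onto one
#' point, and within that null space maximizes the between-class scatter
#' `W' S_B W`. Up to `C - 1` discriminative features exist.
#'
#' The fit proceeds in three stages, entirely inside the span of the data
#' so the `n x n` scatters are never formed: (1) an orthonormal basis `U`
#' of the significant total-scatter eigenvectors (rank <= N-1) via SVD of
#' the globally centered data; (2) within `span(U)`, the null-space basis
#' `Q` of the within-class scatter (eigenvalues below `tol` times the
#' leading total-scatter eigenvalue); (3) the top `nComponents`
#' between-class eigenvectors `V` there. `W = U Q V` has orthonormal
#' columns, ordered by descending between-class eigenvalue. Symmetric
#' eigen-solvers on symmetrized matrices make the fit deterministic.
#'
#' @param X `N x n` training matrix, one sample per row.
#' @param labels length-`N` class labels over `C >= 2` classes.
#' @param nComponents number of features `n'` (default `C - 1`).
#' @param modality tag stored in the model (`"pressure"`,
#'   `"acceleration"`, ...).
#' @param tol relative eigenvalue threshold separating null from non-null
#'   directions (default `1e-10` times the leading eigenvalue).
#' @return A fitted [NLDAModel].
#' @seealso [nldaTransform()], [computeScatters()]
#' @export
nldaFit <- function(X, labels, nComponents = NULL, modality = "unspecified",
                    tol = 1e-10) {
  lm <- checkLabeledMatrix(X, labels)
  X <- lm$X
  N <- nrow(X)
  C <- length(lm$levels)
  if (is.null(nComponents)) nComponents <- C - 1L
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > C - 1L) {
    stop("'nComponents' must be between 1 and C - 1 = ", C - 1L)
  }

  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  evT <- sv$d^2
  if (max(evT) <= 0) stop("degenerate fit: all samples are identical")
  thr <- tol * max(evT)
  keep <- evT > thr
  U <- sv$v[, keep, drop = FALSE]  # n x r basis of significant S_T span

  classMeans <- t(vapply(lm$levels, function(lv)
    colMeans(X[lm$labels == lv, , drop = FALSE]), numeric(ncol(X))))
  Hw <- X - classMeans[as.integer(lm$labels), , drop = FALSE]
  A <- Hw %*% U                       # N x r
  ew <- eigen((crossprod(A) + t(crossprod(A))) / 2, symmetric = TRUE)
  nullIdx <- which(ew$values < thr)   # thresholded on the S_T scale
  if (length(nullIdx) == 0L) {
    stop("degenerate fit: the within-class scatter has no null space ",
         "within the data span (data are not in the small-sample regime)")
  }
  Q <- ew$vectors[, nullIdx, drop = FALSE]

  Hb <- sweep(classMeans, 2L, mu) * sqrt(lm$counts)
  UQ <- U %*% Q
  B <- Hb %*% UQ                      # C x q
  eb <- eigen((crossprod(B) + t(crossprod(B))) / 2, symmetric = TRUE)
  rankB <- sum(eb$values > thr)
  if (rankB < nComponents) {
    stop("requested ", nComponents, " components but the between-class ",
         "scatter restricted to the null space has rank ", rankB)
  }
  V <- eb$vectors[, seq_len(nComponents), drop = FALSE]
  W <- UQ %*% V                       # orthonormal: U, Q, V all orthonormal

  centroids <- classMeans %*% W
  rownames(centroids) <- lm$levels
  new("NLDAModel", W = W, modality = as.character(modality),
      centroids = centroids, classLevels = lm$levels,
      sbEigenvalues = eb$values[seq_len(nComponents)])
}

#' @rdname nldaTransform
#' @export
setMethod("nldaTransform", "NLDAModel", function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != nrow(model@W)) {
      stop("dimension mismatch: samples have ", ncol(x),
           " columns, model expects ", nrow(model@W))
    }
    return(x %*% model@W)
  }
  if (length(x) != nrow(model@W)) {
    stop("dimension mismatch: input has length ", length(x),
         ", model expects ", nrow(model@W))
  }
  drop(crossprod(model@W, x))
})
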