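#' Chord transformation
#'
#' Scales each sample's (relative) abundance row to unit Euclidean norm, so
#' that Euclidean distances between rows become chord distances. Applied
#' before PCA it reduces the tendency for ordination patterns to be driven by
#' shared absences.
#'
#' @param m samples x OTUs non-negative matrix.
#' @return matrix of the same shape with unit-norm rows.
#' @export
chordTransform <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop("all-zero sample row(s): ",
         paste((rownames(m) %||% seq_len(nrow(m)))[nrm == 0], collapse = ", "))
  m / nrm
}

#' Principal component analysis of a community matrix
#'
#' PCA on the column-centered (but not variance-scaled) matrix, via
#' eigendecomposition of the covariance matrix. Scores are projections onto
#' the top eigenvectors; `explained` is eigenvalue / total variance. Each
#' axis is sign-fixed so its largest-magnitude loading is positive, making
#' runs comparable across platforms.
#'
#' @param m samples x variables real matrix (typically chord-transformed
#'   relative abundances).
#' @param nAxes number of axes to retain.
#' @return an [OrdinationResult-class] with scores, explained fractions,
#'   eigenvalues and OTU loadings.
#' @export
pcaOrdination <- function(m, nAxes = 2) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("PCA needs at least 2 samples")
  if (nAxes > min(nrow(m) - 1, ncol(m)))
    stop("nAxes exceeds min(samples - 1, variables) = ",
         min(nrow(m) - 1, ncol(m)))
  xc <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  load <- eg$vectors[, seq_len(nAxes), drop = FALSE]
  # sign convention: largest-|loading| entry positive per axis
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- xc %*% load
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(nAxes)))
  dimnames(load) <- list(colnames(m), colnames(scores))
  new("OrdinationResult", scores = scores,
      explained = lambda[seq_len(nAxes)] / sum(lambda),
      eigenvalues = eg$values, method = "pca_chord", loadings = load)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 * sum_i min(x_i, y_i) / (sum x + sum y), computed with
#' [vegan::vegdist()]. A pair of all-zero samples is assigned distance 0 with
#' a warning (convention; Bray-Curtis is undefined there).
#'
#' @param m samples x OTUs non-negative matrix (counts or relative
#'   abundances).
#' @return a [stats::dist] object with sample labels.
#' @export
brayCurtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  zero <- rowSums(m) == 0
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (any(zero)) {
    warning("all-zero sample row(s); distances between them set to 0: ",
            paste(rownames(m)[zero], collapse = ", "))
    dm <- as.matrix(d)
    dm[zero, ] <- 1; dm[, zero] <- 1
    dm[zero, zero] <- 0
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes it; scores are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Negative
#' eigenvalues, which arise for non-Euclidean dissimilarities such as
#' Bray-Curtis, are reported in `eigenvalues` but their axes are dropped and
#' they are excluded from the explained fractions. No Cailliez/Lingoes
#' correction is applied.
#'
#' @param d a [stats::dist] or symmetric matrix of dissimilarities.
#' @param nAxes number of axes requested; if it exceeds the number of
#'   positive eigenvalues, all available axes are returned with a warning.
#' @return an [OrdinationResult-class].
#' @export
pcoaOrdination <- function(d, nAxes = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  cs <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- cs$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (nAxes > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning ", npos,
            " axes")
    nAxes <- npos
  }
  scores <- cs$points[, seq_len(nAxes), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PCO", seq_len(nAxes))
  new("OrdinationResult", scores = scores,
      explained = eig[seq_len(nAxes)] / sum(eig[eig > 0]),
      eigenvalues = eig, method = "pcoa_bray", loadings = NULL)
}

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("%s ordination: %d samples, %d axes\n", object@method,
              nrow(object@scores), ncol(object@scores)))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * object@explained),
                            collapse = ", "), "\n")
})

#' UPGMA clustering of a dissimilarity matrix
#'
#' Size-weighted average-linkage agglomeration (`stats::hclust(method =
#' "average")`, exactly classic UPGMA). The resulting tree is ultrametric;
#' each internal node sits at half the average inter-cluster dissimilarity,
#' so two leaves merging at dissimilarity 2 are each one unit from their
#' common ancestor. Tied merge candidates are resolved deterministically by
#' hclust's input-order rule.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @return list with elements `hclust` (the merge table and heights on the
#'   dissimilarity scale), `phylo` (an ultrametric [ape] tree with node
#'   heights = dissimilarity / 2) and `newick` (its newick string).
#' @export
upgmaTree <- function(d) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 2) stop("UPGMA needs at least 2 samples")
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc) # edge lengths from height/2: ultrametric
  list(hclust = hc, phylo = phy,
       newick = ape::write.tree(phy))
}
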