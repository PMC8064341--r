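# Simple-matching distance, principal coordinates analysis, and the
# eigenvector phenotypes consumed by the association scan.

#' Simple matching distance between samples
#'
#' `d(i, j) = 1 - matches / jointly non-missing markers` over the 0/1
#' calls.  Note the simple matching distance of 0/1 vectors equals the
#' squared Euclidean distance divided by the marker count, so it is a
#' squared-type dissimilarity: principal coordinates on it are not the
#' same axes as a covariance PCA.
#'
#' @param panel a [GenotypePanel-class] (or a bare 0/1/NA matrix, markers x
#'   samples)
#' @return symmetric distance matrix with zero diagonal, entries in
#'   \[0, 1\], sample ids as dimnames.
#' @export
simpleMatchingDistance <- function(panel) {
  calls <- if (is(panel, "GenotypePanel")) callMatrix(panel) else as.matrix(panel)
  if (ncol(calls) < 2) stop("need at least two samples")
  X <- t(calls)
  O <- !is.na(X)
  M1 <- X; M1[!O] <- 0L
  storage.mode(M1) <- "double"
  Od <- O; storage.mode(Od) <- "double"
  M0 <- Od - M1
  joint <- tcrossprod(Od)
  if (any(joint[upper.tri(joint)] == 0)) {
    idx <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)[1, ]
    stop(sprintf("samples '%s' and '%s' share no non-missing marker",
                 rownames(X)[idx[1]], rownames(X)[idx[2]]))
  }
  matches <- tcrossprod(M1) + tcrossprod(M0)
  d <- 1 - matches / joint
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by an
#' eigendecomposition.  Axis coordinates are eigenvectors scaled by the
#' square root of their (positive) eigenvalues.  Negative eigenvalues
#' (non-Euclidean input) are reported but excluded from the
#' variance-explained denominator.  When `orient` is supplied (a logical
#' or factor marking a reference group, typically the landrace era), every
#' axis is flipped so that the reference-group mean coordinate is
#' non-negative, making axis signs reproducible.
#'
#' @param d symmetric distance matrix (e.g. [simpleMatchingDistance()])
#' @param k_axes number of axes to return
#' @param orient optional logical vector (or something coercible) over
#'   samples marking the reference group for axis orientation
#' @return object of class `PCoAResult`: list with `eigenvalues` (all, in
#'   decreasing order), `coordinates` (samples x axes), `pct_variance`
#'   (per returned axis, over the positive-eigenvalue sum), `n_positive`,
#'   `n_negative`, `sample_ids`.
#' @export
pcoaOrdination <- function(d, k_axes = 10, orient = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k_axes < 1) stop("k_axes must be >= 1")
  B <- -0.5 * d^2
  J <- diag(n) - 1 / n
  B <- J %*% B %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  if (k_axes > length(pos)) {
    warning("only ", length(pos), " positive axes available; truncating")
    k_axes <- length(pos)
  }
  lam <- e$values[seq_len(k_axes)]
  coords <- e$vectors[, seq_len(k_axes), drop = FALSE] %*%
    diag(sqrt(lam), k_axes)
  if (!is.null(orient)) {
    ref <- as.logical(orient)
    for (a in seq_len(k_axes)) {
      mu <- mean(coords[ref, a], na.rm = TRUE)
      if (!is.na(mu) && mu < 0) coords[, a] <- -coords[, a]
    }
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(k_axes))
  structure(list(eigenvalues = e$values,
                 coordinates = coords,
                 pct_variance = 100 * lam / sum(e$values[pos]),
                 n_positive = length(pos),
                 n_negative = sum(e$values < -max(abs(e$values)) * 1e-12),
                 sample_ids = rownames(d)),
            class = "PCoAResult")
}

#' @export
print.PCoAResult <- function(x, ...) {
  cat("PCoAResult:", length(x$sample_ids), "samples,",
      ncol(x$coordinates), "axes returned\n")
  cat("  top eigenvalues:",
      paste(signif(head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  cat("  pct variance (returned axes):",
      paste(sprintf("%.1f", head(x$pct_variance, 5)), collapse = ", "), "\n")
  invisible(x)
}

#' Eigenvector phenotypes for the association scan
#'
#' The top `top_k` principal-coordinate axes, standardised to zero mean and
#' unit variance, ready to serve as the phenotypes of the eigenvector
#' association scan.  Per-axis variance percentages ride along as the
#' `"pct_variance"` attribute.
#'
#' @param pcoa a `PCoAResult`
#' @param top_k number of axes (default 10)
#' @return samples x `top_k` numeric matrix (columns `EV1`...)
#' @export
eigenPhenotypes <- function(pcoa, top_k = 10) {
  if (pcoa$n_positive < top_k)
    stop("only ", pcoa$n_positive, " positive axes; cannot take ", top_k)
  if (ncol(pcoa$coordinates) < top_k)
    stop("PCoA was computed with fewer than ", top_k, " axes")
  Y <- scale(pcoa$coordinates[, seq_len(top_k), drop = FALSE])
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  colnames(Y) <- paste0("EV", seq_len(top_k))
  rownames(Y) <- pcoa$sample_ids
  attr(Y, "pct_variance") <- pcoa$pct_variance[seq_len(top_k)]
  Y
}
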