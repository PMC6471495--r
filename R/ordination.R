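#' Principal coordinate analysis (classical metric scaling)
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' The `n_axes` largest nonnegative eigenvalues are retained; coordinates are
#' eigenvectors scaled by the square root of their eigenvalue, so for
#' Euclidean-embeddable input the pairwise distances among the full-rank
#' coordinates reproduce the input matrix. Percent variance per axis is
#' computed over the sum of positive eigenvalues; negative eigenvalues
#' (non-Euclidean input) are excluded from the denominator and reported via
#' a message, with no Cailliez/Lingoes correction.
#'
#' @param dm symmetric distance matrix with dimnames, or `dist` object.
#' @param n_axes number of axes requested (>= 1); if fewer positive
#'   eigenvalues exist, fewer axes are returned with a warning.
#' @return list of class `pcoa_result`: `sample_ids`, `coordinates`
#'   (samples x axes), `eigenvalues` (all, nonincreasing), `pct_variance`
#'   (retained axes, percent of positive-eigenvalue sum).
#' @export
pcoa <- function(dm, n_axes = 3) {
  if (n_axes < 1) stop("n_axes must be >= 1")
  D <- as.matrix(dm)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  neg <- ev < -1e-8 * max(abs(ev), 1)
  if (any(neg))
    message(sum(neg), " negative eigenvalue(s) excluded (largest magnitude ",
            format(min(ev), digits = 3), "); distances are non-Euclidean")
  pos <- which(ev > 1e-12 * max(abs(ev), 1))
  k <- min(n_axes, length(pos))
  if (k < n_axes)
    warning("only ", length(pos), " positive eigenvalue(s); returning ", k,
            " axes")
  if (k == 0) stop("no positive eigenvalues; degenerate distance matrix")
  axes <- pos[seq_len(k)]
  coords <- e$vectors[, axes, drop = FALSE] %*% diag(sqrt(ev[axes]), k)
  dimnames(coords) <- list(rownames(D), paste0("Axis", seq_len(k)))
  structure(list(sample_ids = rownames(D), coordinates = coords,
                 eigenvalues = ev,
                 pct_variance = 100 * ev[axes] / sum(ev[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d axes (%s%% of variance)\n",
              length(x$sample_ids), ncol(x$coordinates),
              paste(sprintf("%.2f", x$pct_variance), collapse = ", ")))
  invisible(x)
}

#' Genotype-covariance PCA (comparison mode)
#'
#' Direct PCA of the centred dosage matrix (missing dosages mean-imputed
#' per locus), provided as an alternative view to distance-based [pcoa()].
#'
#' @param gm a [genotype_matrix()].
#' @param n_axes number of axes.
#' @return as [pcoa()] (eigenvalues of the sample covariance).
#' @export
genotype_pca <- function(gm, n_axes = 3) {
  d <- gm$dosage
  mu <- colMeans(d, na.rm = TRUE)
  x <- sweep(d, 2, mu)
  x[is.na(x)] <- 0
  s <- svd(x)
  ev <- s$d^2 / max(1, nrow(d) - 1)
  k <- min(n_axes, sum(ev > 1e-12))
  coords <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k)
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_len(k)))
  structure(list(sample_ids = rownames(d), coordinates = coords,
                 eigenvalues = ev,
                 pct_variance = 100 * ev[seq_len(k)] / sum(ev)),
            class = "pcoa_result")
}
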