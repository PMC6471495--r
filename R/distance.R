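#' Identity-by-state genetic distance
#'
#' For two samples, per-locus similarity is the number of shared alleles in
#' the unordered genotype comparison divided by 2: identical genotypes 1,
#' het versus hom (one shared allele) 0.5, opposite homozygotes 0. The
#' distance is 1 minus the mean similarity over loci typed in both samples
#' (equivalently, mean absolute dosage difference / 2). Pairs with zero
#' co-typed loci are an error.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @return symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames, entries in `[0, 1]`.
#' @export
ibs_distance <- function(gm) {
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  d <- gm$dosage
  # dist(manhattan) rescales the sum over non-missing coordinates to the
  # full length, so dividing by L gives the mean |dosage diff| over co-typed
  # loci; NaN marks pairs with zero co-typed loci
  dm <- as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
  diag(dm) <- 0
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm), arr.ind = TRUE)[1, ]
    stop("no co-typed loci for sample pair ",
         rownames(dm)[bad[1]], " / ", colnames(dm)[bad[2]])
  }
  dm
}

# label of a cluster = lexicographically smallest member leaf label
#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Classical UPGMA: iteratively merge the closest pair of clusters; distances
#' from a merged cluster are size-weighted arithmetic means of the member
#' distances; each merge's height is half the merging distance, so the tree
#' is rooted and ultrametric. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf label).
#'
#' @param dm symmetric distance matrix with dimnames (e.g. from
#'   [ibs_distance()]), or a `dist` object.
#' @return list of class `upgma_tree`: `phylo` (an [ape] tree with branch
#'   lengths), `hclust` (the merge structure; `$height` holds merging
#'   distances), `merge_heights` (node heights = merging distance / 2) and
#'   `labels`.
#' @export
upgma <- function(dm) {
  dm <- as.matrix(dm)
  if (any(is.na(dm))) stop("NaN/NA in distance matrix")
  labels <- rownames(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- dm
  size <- rep(1L, n)
  minlab <- labels
  id <- -seq_len(n)          # hclust convention: negative = singleton
  active <- seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (k in seq_len(n - 1)) {
    best <- NULL
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      i <- active[ai]; j <- active[bi]
      dij <- D[i, j]
      lab <- sort(c(minlab[i], minlab[j]))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(i = i, j = j, d = dij, lab = lab)
      }
    }
    i <- best$i; j <- best$j
    height[k] <- best$d
    merge[k, ] <- sort(c(id[i], id[j]))
    # Lance-Williams average linkage update, stored in slot i
    for (m in setdiff(active, c(i, j)))
      D[i, m] <- D[m, i] <- (size[i] * D[i, m] + size[j] * D[j, m]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    id[i] <- k
    active <- setdiff(active, j)
  }

  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "ibs"),
                  class = "hclust")
  phy <- ape::as.phylo(hc)
  structure(list(phylo = phy, hclust = hc, merge_heights = height / 2,
                 labels = labels),
            class = "upgma_tree")
}

# leaf ordering for an hclust merge matrix (left-to-right DFS)
hclust_order <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4g\n",
              length(x$labels), max(x$merge_heights)))
  invisible(x)
}

#' Write / read a UPGMA tree in Newick format
#'
#' Standard Newick with branch lengths; labels with metacharacters are quoted
#' by [ape::write.tree()]. Re-parsing gives identical topology and heights to
#' within 1e-9.
#'
#' @param tree an `upgma_tree` or an `ape` `phylo` object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "upgma_tree")) tree$phylo else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
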