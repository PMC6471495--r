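#' Keep only loci with complete genotype calls
#'
#' Retains exactly the loci with zero missing calls across all samples of the
#' matrix (the first step of the race-diagnostic locus filter). Sample set
#' and locus order are unchanged; idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @return a [genotype_matrix()] with the incomplete loci dropped.
#' @export
filter_complete <- function(gm) {
  keep <- colSums(is.na(gm$dosage)) == 0L
  subset_gm(gm, loci = locus_ids(gm)[keep])
}

#' Optional minor-allele-frequency screen
#'
#' Not applied implicitly anywhere in the package; provided for users who
#' want a MAF floor before pruning or ordination.
#'
#' @param gm a [genotype_matrix()].
#' @param min_maf retain loci with MAF >= `min_maf` (computed over typed
#'   samples; loci with no typed samples are dropped).
#' @return a [genotype_matrix()].
#' @export
filter_maf <- function(gm, min_maf) {
  ft <- freq_table(gm)
  keep <- !is.na(ft$maf) & ft$maf >= min_maf
  subset_gm(gm, loci = locus_ids(gm)[keep])
}

#' Sliding-window LD pruning parameters
#'
#' The defaults are the standard indep-pairwise parameters used for this kind
#' of panel: windows of 50 loci shifted by 5, squared-correlation threshold
#' 0.2.
#'
#' @param window_size loci per window (>= 2).
#' @param step loci shifted per step (1 <= step <= window_size).
#' @param r2_threshold remove one of any within-window pair with pairwise
#'   dosage r^2 strictly above this value.
#' @return a list of class `prune_params`.
#' @export
prune_params <- function(window_size = 50, step = 5, r2_threshold = 0.2) {
  if (window_size < 2) stop("window_size must be >= 2")
  if (step < 1 || step > window_size) stop("step must satisfy 1 <= step <= window_size")
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold must be in [0, 1]")
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 r2_threshold = r2_threshold), class = "prune_params")
}

#' LD-based locus pruning (sliding window, greedy)
#'
#' Treats the input locus order as genomic order and slides a window of
#' `window_size` surviving loci by `step`. Within a window, pairs are scanned
#' in order; whenever a pair's squared Pearson correlation between alt-dosage
#' vectors (over samples non-missing at both loci) exceeds `r2_threshold`,
#' one locus of the pair is removed: the one with the higher missing rate,
#' ties broken by removing the later locus in input order. Full sweeps over
#' the surviving list are repeated until a sweep removes nothing, so the
#' operation is idempotent and no retained pair within any window of the
#' output exceeds the threshold.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [prune_params()].
#' @return a [genotype_matrix()] containing the surviving loci in input order.
#' @export
ld_prune <- function(gm, params = prune_params()) {
  stopifnot(inherits(params, "prune_params"))
  d <- gm$dosage
  miss <- locus_missing_rate(gm)
  surv <- seq_len(ncol(d))
  W <- params$window_size; S <- params$step; thr <- params$r2_threshold
  repeat {
    removed_any <- FALSE
    start <- 1L
    while (start <= length(surv)) {
      repeat {
        win <- surv[seq(start, min(start + W - 1L, length(surv)))]
        if (length(win) < 2L) break
        # pairwise-complete r^2 for the whole window at once; undefined
        # correlations (zero variance or < 2 complete pairs) count as 0
        R2 <- suppressWarnings(
          stats::cor(d[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        R2[!is.finite(R2)] <- 0
        removed_here <- FALSE
        for (a in seq_len(length(win) - 1L)) {
          i <- win[a]
          if (!(i %in% surv)) next
          for (b in seq(a + 1L, length(win))) {
            j <- win[b]
            if (!(j %in% surv)) next
            if (R2[a, b] > thr) {
              drop <- if (miss[i] > miss[j]) i else j
              surv <- setdiff(surv, drop)
              removed_here <- TRUE
              removed_any <- TRUE
              if (drop == i) break  # row locus gone; stop comparing against it
            }
          }
        }
        if (!removed_here) break  # window clean; refill-and-rescan done
      }
      if (start + W - 1L >= length(surv)) break
      start <- start + S
    }
    if (!removed_any) break
  }
  subset_gm(gm, loci = locus_ids(gm)[surv])
}
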