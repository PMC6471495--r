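#' Two-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style decomposition from squared pairwise distances. With N
#' samples in G populations of sizes n_g:
#' * `SS_total = (1/N) * sum_{i<j} d_ij^2`
#' * `SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2`
#' * `SS_among = SS_total - SS_within`
#'
#' with `df_among = G - 1`, `df_within = N - G` (samples, not haplotypes, are
#' the experimental unit; `df_total = N - 1`). Mean squares follow;
#' `sigma2_b = MS_within`, `sigma2_a = (MS_among - MS_within) / n0` with the
#' standard unequal-size coefficient `n0 = (N - sum n_g^2 / N) / (G - 1)`,
#' and `phi_st = sigma2_a / (sigma2_a + sigma2_b)`. The permutation p-value
#' randomly relabels samples to populations with group sizes fixed and uses
#' the add-one estimator `(1 + #{phi_perm >= phi_obs}) / (1 + n_perm)`.
#'
#' The molecular-distance convention follows the classical AMOVA for marker
#' data: the pairwise allele-mismatch count between two genotypes *is* the
#' squared molecular distance `d^2`. The IBS distance of [ibs_distance()] is
#' proportional to the mismatch count, so by default (`squared = TRUE`) the
#' supplied matrix enters the sums-of-squares directly as `d^2`. Set
#' `squared = FALSE` for a Euclidean-type distance matrix that should be
#' squared entrywise first. `phi_st` is invariant to uniform scaling either
#' way.
#'
#' @param dm symmetric distance matrix with sample ids as dimnames (e.g.
#'   [ibs_distance()]).
#' @param grouping named character vector mapping sample_id to population;
#'   at least 2 populations, each with at least 2 samples.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param squared whether `dm` already holds squared (mismatch-proportional)
#'   molecular distances; default TRUE, the right setting for IBS input.
#' @return list of class `amova_result` with the fields described above plus
#'   `p_value` and `n_permutations`.
#' @export
amova_two_level <- function(dm, grouping, n_perm = 999, seed = 1,
                            squared = TRUE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  D <- as.matrix(dm)
  if (!squared) D <- D^2
  ids <- rownames(D)
  grouping <- grouping[names(grouping) %in% ids]
  keep <- ids[ids %in% names(grouping)]
  D <- D[keep, keep, drop = FALSE]
  fac <- factor(unname(grouping[keep]))
  sizes <- table(fac)
  if (length(sizes) < 2) stop("need at least 2 populations")
  if (any(sizes < 2))
    stop("population(s) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  d2 <- D
  obs <- amova_components(d2, fac)
  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    phi_p <- amova_components(d2, sample(fac))$phi_st
    if (phi_p >= obs$phi_st) n_ge <- n_ge + 1L
  }
  out <- c(obs, list(pct_among = 100 * obs$phi_st,
                     p_value = (1 + n_ge) / (1 + n_perm),
                     n_permutations = n_perm))
  class(out) <- "amova_result"
  out
}

# variance components from a squared-distance matrix and a grouping factor
amova_components <- function(d2, fac) {
  N <- nrow(d2)
  G <- nlevels(fac)
  sizes <- tabulate(fac, nbins = G)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in seq_len(G)) {
    idx <- which(as.integer(fac) == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / sizes[g]
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  sigma2_b <- ms_within
  sigma2_a <- (ms_among - ms_within) / n0
  list(df_among = df_among, df_within = df_within,
       ss_among = ss_among, ss_within = ss_within,
       sigma2_a = sigma2_a, sigma2_b = sigma2_b,
       phi_st = sigma2_a / (sigma2_a + sigma2_b))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Two-level AMOVA (distance-based; samples as experimental unit)\n")
  tab <- data.frame(
    source = c("Among populations", "Within populations"),
    df = c(x$df_among, x$df_within),
    SS = c(x$ss_among, x$ss_within),
    sigma2 = c(x$sigma2_a, x$sigma2_b))
  print(tab, row.names = FALSE, digits = 5)
  cat(sprintf("Phi_ST = %.4f (%.2f%% among); p = %.4g (%d permutations)\n",
              x$phi_st, x$pct_among, x$p_value, x$n_permutations))
  invisible(x)
}
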