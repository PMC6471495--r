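# Fixtures and independent reference implementations used across the suite.
# Oracles deliberately use direct enumeration / naive algorithms so that the
# package's optimised code paths are checked against a second derivation.

# random genotype matrix with per-locus frequencies drawn uniformly
rand_gm <- function(n, L, seed = 1, missing_rate = 0, freq_range = c(0.05, 0.95)) {
  set.seed(seed)
  p <- runif(L, freq_range[1], freq_range[2])
  d <- vapply(seq_len(L), function(l) rbinom(n, 2L, p[l]), integer(n))
  d <- matrix(d, nrow = n,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("L%03d", seq_len(L))))
  if (missing_rate > 0) d[runif(n * L) < missing_rate] <- NA_integer_
  genotype_matrix(d, "A", "G")
}

# random symmetric distance matrix with zero diagonal
rand_dist <- function(n, seed = 1, labels = LETTERS[seq_len(n)]) {
  set.seed(seed)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.05, 1)
  D + t(D)
}

# --- diversity oracle: direct per-locus tallies ----------------------------
div_oracle <- function(gm, samples = NULL) {
  d <- dosage(gm)
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  out <- lapply(seq_len(ncol(d)), function(j) {
    g <- d[, j][!is.na(d[, j])]
    n <- length(g)
    if (n == 0) return(rep(NA_real_, 8))
    n_alt <- sum(g == 1L) + 2L * sum(g == 2L)
    p <- n_alt / (2 * n)
    q <- 1 - p
    sh <- 0
    for (x in c(p, q)) if (x > 0) sh <- sh - x * log(x)
    c(n_typed = n, p_alt = p, maf = min(p, q),
      ho = sum(g == 1L) / n, he = 2 * p * q,
      nei = if (n >= 1) 2 * n / (2 * n - 1) * 2 * p * q else NA_real_,
      shannon_i = sh,
      pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2)
  })
  do.call(rbind, out)
}

# --- UPGMA oracle: cluster distances recomputed from the original matrix ---
# (average linkage distance between clusters equals the arithmetic mean of
# all original inter-member distances; ties broken by the lexicographically
# smallest pair of cluster labels, a cluster labelled by its smallest leaf)
upgma_ref_heights <- function(D) {
  labels <- rownames(D)
  clusters <- lapply(seq_len(nrow(D)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      dd <- mean(D[clusters[[a]], clusters[[b]]])
      la <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
      if (is.null(best) || dd < best$d - 1e-15 ||
          (abs(dd - best$d) <= 1e-15 &&
           (la[1] < best$lab[1] ||
            (la[1] == best$lab[1] && la[2] < best$lab[2])))) {
        best <- list(a = a, b = b, d = dd, lab = la)
      }
    }
    heights <- c(heights, best$d)
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  heights
}

# --- LD-pruning oracle: naive quadratic sweeps to fixpoint -----------------
prune_ref <- function(gm, params) {
  d <- dosage(gm)
  L <- ncol(d)
  # full pairwise-complete r^2 matrix computed up front (the package prunes
  # window by window instead); undefined correlations count as 0
  r2 <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))^2
  r2[!is.finite(r2)] <- 0
  miss <- colMeans(is.na(d))
  surv <- seq_len(L)
  W <- params$window_size; S <- params$step; thr <- params$r2_threshold
  repeat {
    removed_any <- FALSE
    start <- 1L
    while (start <= length(surv)) {
      repeat {
        win <- surv[seq(start, min(start + W - 1L, length(surv)))]
        if (length(win) < 2L) break
        removed_here <- FALSE
        for (a in seq_len(length(win) - 1L)) for (b in seq(a + 1L, length(win))) {
          i <- win[a]; j <- win[b]
          if (!(i %in% surv) || !(j %in% surv)) next
          if (r2[i, j] > thr) {
            surv <- setdiff(surv, if (miss[i] > miss[j]) i else j)
            removed_here <- TRUE; removed_any <- TRUE
          }
        }
        if (!removed_here) break
      }
      if (start + W - 1L >= length(surv)) break
      start <- start + S
    }
    if (!removed_any) break
  }
  locus_ids(gm)[surv]
}

# --- AMOVA oracle: direct enumeration of all pairwise terms ----------------
amova_ref <- function(D2, grouping) {
  ids <- rownames(D2)
  fac <- grouping[ids]
  N <- length(ids)
  pops <- unique(fac)
  G <- length(pops)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N))
    ss_total <- ss_total + D2[i, j] / N
  ss_within <- 0
  for (p in pops) {
    idx <- which(fac == p)
    for (i in idx) for (j in idx) if (j > i)
      ss_within <- ss_within + D2[i, j] / length(idx)
  }
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (N - G)
  n_g <- as.numeric(table(fac)[pops])
  n0 <- (N - sum(n_g^2) / N) / (G - 1)
  sigma2_a <- (ms_among - ms_within) / n0
  sigma2_b <- ms_within
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       sigma2_a = sigma2_a, sigma2_b = sigma2_b,
       phi_st = sigma2_a / (sigma2_a + sigma2_b))
}

# brute-force re-check of the three marker-filter predicates for one locus
check_marker_predicates <- function(gm, panel, locus, race, allele,
                                    hybrid_min_frac = 11 / 14) {
  pan <- panel[panel$race_label != "UNKNOWN", ]
  g <- dosage(gm)[pan$sample_id, locus]
  if (anyNA(g)) return(FALSE)                      # step 1
  diag_dose <- if (allele == "alt") g else 2L - g
  own <- diag_dose[pan$race_label == race]
  oth <- diag_dose[pan$race_label %in% setdiff(c("M", "G", "WI"), race)]
  if (!(all(own == 2L) && all(oth == 0L))) return(FALSE)  # step 2
  hyb <- switch(race,
                M = pan$sample_id[pan$race_label == "GxM"],
                WI = pan$sample_id[pan$race_label == "GxWI"],
                G = pan$sample_id[pan$race_label %in% c("GxM", "GxWI")])
  if (length(hyb) == 0) return(TRUE)
  carriers <- sum(diag_dose[hyb] >= 1L)
  need <- if (race == "G") ceiling(hybrid_min_frac * length(hyb)) else length(hyb)
  carriers >= need                                  # step 3
}
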