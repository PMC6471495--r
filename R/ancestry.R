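#' Per-race reference allele frequencies
#'
#' Alt-allele frequency per locus within each race's pure accessions,
#' clamped to `[eps, 1 - eps]` so genotype log-likelihoods stay finite at
#' fixed loci. Loci with no typed pure accession in a race get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [sample_panel()] with at least one pure accession per race.
#' @param eps clamping constant.
#' @return numeric matrix, loci x 3 (columns `M`, `G`, `WI`).
#' @export
reference_freqs <- function(gm, panel, eps = 1e-3) {
  pan <- panel_for(panel, gm)
  out <- matrix(NA_real_, n_loci(gm), 3, dimnames = list(locus_ids(gm), RACES))
  for (r in RACES) {
    ps <- pure_samples(pan, r)
    if (length(ps) == 0) stop("no pure accessions for race ", r)
    ft <- freq_table(gm, ps)
    out[, r] <- ifelse(ft$n_typed > 0, pmin(pmax(ft$p_alt, eps), 1 - eps), NA_real_)
  }
  out
}

#' Supervised ancestry-proportion estimation
#'
#' Maximises the binomial genotype log-likelihood over admixture proportions
#' q on the simplex: with per-source alt frequencies `p_r(l)` and
#' `p_mix(l) = sum_r q_r p_r(l)`, a dosage g at locus l contributes
#' `log dbinom(g, 2, p_mix(l))`. Each allele copy's source population is the
#' latent variable of a standard EM whose fixed points are the maximisers;
#' the log-likelihood is non-decreasing across iterations (asserted).
#' Missing loci and loci with missing reference frequencies are skipped.
#' When the references are identical across sources the likelihood is flat
#' in q and the uniform initialisation is returned unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @param freqs loci x K matrix of reference alt frequencies (from
#'   [reference_freqs()], or any K sources), with column names.
#' @param sample a sample id.
#' @param min_loci minimum usable loci (default 50).
#' @param max_iter,tol EM iteration cap and convergence tolerance on
#'   `max |q_new - q|`.
#' @return list of class `ancestry_estimate`: `sample_id`, `q` (named, sums
#'   to 1), `loglik`, `n_loci_used`, `n_iter`, `monotone` (TRUE if the
#'   log-likelihood never decreased).
#' @export
estimate_q <- function(gm, freqs, sample, min_loci = 50,
                       max_iter = 10000, tol = 1e-9) {
  lid <- intersect(locus_ids(gm), rownames(freqs))
  g <- gm$dosage[sample, lid]
  P <- freqs[lid, , drop = FALSE]
  use <- !is.na(g) & rowSums(is.na(P)) == 0
  g <- as.numeric(g[use])
  P <- P[use, , drop = FALSE]
  if (length(g) < min_loci)
    stop("only ", length(g), " usable loci for sample ", sample,
         " (need >= ", min_loci, ")")
  K <- ncol(P)
  q <- rep(1 / K, K)
  Lc <- length(g)
  const <- sum(lchoose(2, g))
  gr <- 2 - g
  Pc <- 1 - P
  pm <- drop(P %*% q)
  ll_old <- const + sum(g * log(pm) + gr * log1p(-pm))
  monotone <- TRUE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step posteriors folded into the M-step: q_new_r is q_r times the
    # average per-copy responsibility ratio over the 2L allele copies
    s <- drop(crossprod(P, g / pm)) + drop(crossprod(Pc, gr / (1 - pm)))
    q_new <- q * s / (2 * Lc)
    q_new <- q_new / sum(q_new)
    pm <- drop(P %*% q_new)
    ll_new <- const + sum(g * log(pm) + gr * log1p(-pm))
    if (ll_new < ll_old - 1e-8) monotone <- FALSE
    delta <- max(abs(q_new - q))
    q <- q_new
    ll_old <- ll_new
    if (delta < tol || iter >= max_iter) break
  }
  structure(list(sample_id = sample,
                 q = stats::setNames(q, colnames(P)),
                 loglik = ll_old, n_loci_used = length(g),
                 n_iter = iter, monotone = monotone),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf("<ancestry_estimate> %s: %s (loglik %.2f, %d loci)\n",
              x$sample_id,
              paste(sprintf("%s=%.3f", names(x$q), x$q), collapse = " "),
              x$loglik, x$n_loci_used))
  invisible(x)
}

#' Ancestry proportions for many samples
#'
#' @inheritParams estimate_q
#' @param samples sample ids (default all).
#' @return data.frame: `sample_id`, one `q_*` column per source, `loglik`,
#'   `n_loci_used`, `monotone`.
#' @export
estimate_q_all <- function(gm, freqs, samples = sample_ids(gm), ...) {
  rows <- lapply(samples, function(s) {
    e <- estimate_q(gm, freqs, s, ...)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(e$q, paste0("q_", names(e$q))))),
          data.frame(loglik = e$loglik, n_loci_used = e$n_loci_used,
                     monotone = e$monotone))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evanno delta-K statistic
#'
#' From replicate clustering log-likelihoods L(K) over consecutive K:
#' `L'(K) = mean L(K) - mean L(K-1)`,
#' `|L''(K)| = |mean L(K+1) - 2 mean L(K) + mean L(K-1)|`, and
#' `deltaK(K) = |L''(K)| / sd(L(K))`, defined for interior K with >= 2
#' replicates and positive sd (otherwise excluded from the argmax, with a
#' message).
#'
#' @param table named list mapping K (coercible to integer, consecutive,
#'   >= 3 values) to numeric vectors of replicate log-likelihoods (>= 2
#'   replicates each).
#' @return list of class `delta_k_table`: `table` (data.frame with K,
#'   mean_L, sd_L, d1, d2_abs, delta_k) and `best_k` (argmax over interior
#'   K, NA if none defined).
#' @export
delta_k <- function(table) {
  Ks <- sort(as.integer(names(table)))
  if (length(Ks) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1)) stop("K values must be consecutive")
  if (any(vapply(table, length, 0L) < 2)) stop("need >= 2 replicates per K")
  mean_L <- vapply(as.character(Ks), function(k) mean(table[[k]]), 0)
  sd_L <- vapply(as.character(Ks), function(k) stats::sd(table[[k]]), 0)
  n <- length(Ks)
  d1 <- c(NA, diff(mean_L))
  d2 <- rep(NA_real_, n)
  d2[2:(n - 1)] <- abs(mean_L[3:n] - 2 * mean_L[2:(n - 1)] + mean_L[1:(n - 2)])
  dk <- d2 / sd_L
  undef <- !is.na(d2) & sd_L == 0
  if (any(undef)) {
    message("deltaK undefined at K = ", paste(Ks[undef], collapse = ", "),
            " (zero replicate sd)")
    dk[undef] <- NA_real_
  }
  best <- if (all(is.na(dk))) NA_integer_ else Ks[which.max(dk)]
  structure(list(table = data.frame(K = Ks, mean_L = mean_L, sd_L = sd_L,
                                    d1 = d1, d2_abs = d2, delta_k = dk),
                 best_k = best),
            class = "delta_k_table")
}

#' @export
print.delta_k_table <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 4)
  cat("best K:", x$best_k, "\n")
  invisible(x)
}

#' STRUCTURE-like likelihood table over K
#'
#' A fast supervised stand-in for unsupervised clustering likelihoods, used
#' to feed [delta_k()]: samples are cut into K groups by UPGMA on the IBS
#' distance matrix, group allele frequencies become the K reference sources,
#' and each replicate scores the panel's total [estimate_q()] log-likelihood
#' on a random locus subset (the same subsets across K, so values are
#' comparable within a replicate).
#'
#' @param gm a [genotype_matrix()].
#' @param k_range consecutive K values (default 1:5).
#' @param n_rep replicates per K.
#' @param prop_loci fraction of loci scored per replicate.
#' @param seed RNG seed.
#' @param eps frequency clamping constant.
#' @return named list mapping K to replicate log-likelihood vectors, ready
#'   for [delta_k()].
#' @export
structure_like_likelihoods <- function(gm, k_range = 1:5, n_rep = 3,
                                       prop_loci = 0.8, seed = 1, eps = 1e-3) {
  hc <- upgma(ibs_distance(gm))$hclust
  set.seed(seed)
  L <- n_loci(gm)
  subsets <- lapply(seq_len(n_rep), function(i)
    sort(sample.int(L, max(2, round(prop_loci * L)))))
  out <- list()
  for (K in k_range) {
    grp <- if (K == 1) rep(1L, n_samples(gm)) else stats::cutree(hc, k = K)
    names(grp) <- sample_ids(gm)
    lls <- vapply(subsets, function(loci) {
      sub <- subset_gm(gm, loci = locus_ids(gm)[loci])
      P <- vapply(seq_len(K), function(g) {
        ft <- freq_table(sub, names(grp)[grp == g])
        ifelse(ft$n_typed > 0, pmin(pmax(ft$p_alt, eps), 1 - eps), NA_real_)
      }, numeric(length(loci)))
      P <- matrix(P, ncol = K,
                  dimnames = list(locus_ids(sub), paste0("src", seq_len(K))))
      sum(vapply(sample_ids(sub), function(s)
        estimate_q(sub, P, s, min_loci = 1, max_iter = 500, tol = 1e-7)$loglik,
        0))
    }, 0)
    out[[as.character(K)]] <- lls
  }
  out
}
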