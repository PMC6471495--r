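# internal vectorised allele-frequency table over a sample subset
freq_table <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  n_typed <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  p_alt <- ifelse(n_typed > 0, alt / (2 * n_typed), NA_real_)
  ho <- ifelse(n_typed > 0, colSums(d == 1L, na.rm = TRUE) / n_typed, NA_real_)
  data.frame(locus_id = colnames(gm$dosage), n_typed = n_typed, p_alt = p_alt,
             maf = pmin(p_alt, 1 - p_alt), ho = ho,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Alt-allele frequency at a locus
#'
#' Counted over typed (non-missing) samples only: `p_alt` is the alt-allele
#' count divided by twice the number of typed samples. With zero typed
#' samples `p_alt` is `NA` and downstream statistics are undefined for the
#' locus.
#'
#' @param gm a [genotype_matrix()].
#' @param locus a locus id.
#' @param samples optional sample-id subset.
#' @return list with `p_alt` and `n_typed`.
#' @export
allele_freq <- function(gm, locus, samples = NULL) {
  g <- gm$dosage[if (is.null(samples)) TRUE else samples, locus]
  n_typed <- sum(!is.na(g))
  list(p_alt = if (n_typed > 0) sum(g, na.rm = TRUE) / (2 * n_typed) else NA_real_,
       n_typed = n_typed)
}

# closed-form per-locus statistics from p (alt freq), ho and n (typed samples)
locus_stats <- function(p, ho, n) {
  q <- 1 - p
  he <- 2 * p * q
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  data.frame(
    maf = pmin(p, q),
    ho = ho,
    he = he,
    nei = (2 * n / (2 * n - 1)) * he,
    shannon_i = -(plogp(p) + plogp(q)),
    pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2)
}

#' Per-locus diversity statistics
#'
#' For a biallelic locus with alt frequency `p`, `q = 1 - p` and `n` typed
#' samples:
#' * `maf = min(p, q)`
#' * `ho` — observed heterozygote fraction among typed samples
#' * `he = 2pq` — expected heterozygosity
#' * `nei = (2n / (2n - 1)) * 2pq` — unbiased gene diversity
#' * `shannon_i = -(p ln p + q ln q)` with `0 ln 0 := 0`
#' * `pic = 1 - (p^2 + q^2) - 2 p^2 q^2`
#'
#' All statistics are missing-aware (typed samples only). Requires `n >= 2`.
#'
#' @inheritParams allele_freq
#' @return one-row data.frame with `locus_id`, `n_typed`, `p_alt` and the six
#'   statistics.
#' @export
locus_diversity <- function(gm, locus, samples = NULL) {
  af <- allele_freq(gm, locus, samples)
  if (af$n_typed < 2)
    stop("locus ", locus, " has fewer than 2 typed samples")
  g <- gm$dosage[if (is.null(samples)) TRUE else samples, locus]
  ho <- sum(g == 1L, na.rm = TRUE) / af$n_typed
  cbind(data.frame(locus_id = locus, n_typed = af$n_typed, p_alt = af$p_alt,
                   stringsAsFactors = FALSE),
        locus_stats(af$p_alt, ho, af$n_typed))
}

#' Diversity table for all loci
#'
#' Vectorised [locus_diversity()] over every locus with at least two typed
#' samples in the subset; loci below that are returned with `NA` statistics
#' and reported via a message.
#'
#' @inheritParams allele_freq
#' @return data.frame, one row per locus.
#' @export
diversity_table <- function(gm, samples = NULL) {
  ft <- freq_table(gm, samples)
  st <- locus_stats(ft$p_alt, ft$ho, ft$n_typed)
  skip <- ft$n_typed < 2
  if (any(skip)) {
    message(sum(skip), " locus/loci with fewer than 2 typed samples skipped")
    st[skip, ] <- NA_real_
  }
  cbind(ft[c("locus_id", "n_typed", "p_alt")], st)
}

#' Per-population mean diversity
#'
#' For each population, per-locus statistics are computed over that
#' population's samples and averaged (unweighted) across the loci typed in at
#' least two of its samples.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping named character vector mapping sample_id to population
#'   (see [race_grouping()]); samples absent from the mapping are ignored.
#' @return data.frame with one row per population: `population`, `n_samples`,
#'   `n_loci_used` and the mean `maf`, `ho`, `he`, `nei`, `shannon_i`, `pic`.
#' @export
population_diversity <- function(gm, grouping) {
  grouping <- grouping[names(grouping) %in% sample_ids(gm)]
  pops <- unique(grouping)
  sizes <- table(factor(grouping, levels = pops))
  if (any(sizes < 2))
    stop("population(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  rows <- lapply(pops, function(pp) {
    tab <- diversity_table(gm, samples = names(grouping)[grouping == pp])
    use <- tab$n_typed >= 2
    data.frame(population = pp, n_samples = unname(sizes[pp]),
               n_loci_used = sum(use),
               maf = mean(tab$maf[use]), ho = mean(tab$ho[use]),
               he = mean(tab$he[use]), nei = mean(tab$nei[use]),
               shannon_i = mean(tab$shannon_i[use]), pic = mean(tab$pic[use]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weir-Cockerham F_ST estimator
#'
#' Multi-population theta-hat as the ratio of summed variance components
#' (a over a+b+c) across loci, from genotype data. Used mainly to check that
#' simulated panels realise their nominal divergence.
#'
#' @param gm a [genotype_matrix()].
#' @param grouping named character vector mapping sample_id to population.
#' @return scalar estimate.
#' @export
wc_fst <- function(gm, grouping) {
  grouping <- grouping[names(grouping) %in% sample_ids(gm)]
  pops <- unique(grouping)
  r <- length(pops)
  if (r < 2) stop("need at least 2 populations")
  ft <- lapply(pops, function(pp) freq_table(gm, names(grouping)[grouping == pp]))
  A <- B <- C <- 0
  for (l in seq_len(n_loci(gm))) {
    n_i <- vapply(ft, function(x) x$n_typed[l], 0)
    if (any(n_i < 1) || sum(n_i) < 2) next
    p_i <- vapply(ft, function(x) x$p_alt[l], 0)
    h_i <- vapply(ft, function(x) x$ho[l], 0)
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}
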