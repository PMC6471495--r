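#' Configuration for the multi-race panel simulator
#'
#' The simulator emulates a reduced-representation SNP genotype panel over
#' three diverged ancestral races (M, G, WI) plus interracial hybrid classes.
#' Non-diagnostic loci follow the Balding-Nichols model: an ancestral
#' alt-allele frequency `p` is drawn uniformly from `ancestral_freq_range`,
#' and each race's frequency is Beta-distributed with mean `p` and variance
#' `divergence_F * p * (1 - p)` (with `divergence_F = 0` the race frequencies
#' equal `p` exactly). Race-diagnostic loci are planted by overwriting the
#' race frequencies with fixed differences.
#'
#' @param n_per_group named integer vector of accession counts per class;
#'   names from `M, G, WI, GxM, GxWI`.
#' @param n_loci total biallelic loci (must be >= 3 * `n_diagnostic_per_race`).
#' @param divergence_F race divergence parameter in `[0, 1)`.
#' @param n_diagnostic_per_race planted fixed-difference loci per race.
#' @param missing_rate i.i.d. per-call missing probability in `[0, 1)`.
#' @param hybrid_q per hybrid class, the admixture fraction of the dominant
#'   (non-Guatemalan) parent: the M fraction for `GxM`, the WI fraction for
#'   `GxWI`. A scalar fixes it; a length-2 vector gives a range sampled
#'   uniformly per individual.
#' @param ancestral_freq_range interval within (0, 1) for ancestral
#'   frequencies. The default (0.1, 0.9) reflects a discovery panel filtered
#'   to reasonably common variants.
#' @param hybrid_mode `"admixed"` draws each allele copy's source race
#'   independently from the individual's q (admixed-gamete model); `"f1"`
#'   draws one allele copy from each parent race, so hybrids are guaranteed
#'   heterozygous carriers of both parental diagnostic alleles.
#' @param guard_diagnostic when all three races have pure accessions,
#'   deterministically re-draw any non-planted locus whose realised pure-race
#'   genotypes happen to form a perfect diagnostic pattern, so that the
#'   planted loci are exactly the race-diagnostic answer set.
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(M = 30, G = 30, WI = 30),
                       n_loci = 5000,
                       divergence_F = 0.2,
                       n_diagnostic_per_race = 0,
                       missing_rate = 0,
                       hybrid_q = list(GxM = 0.5, GxWI = 0.5),
                       ancestral_freq_range = c(0.1, 0.9),
                       hybrid_mode = c("admixed", "f1"),
                       guard_diagnostic = TRUE,
                       seed = 1) {
  hybrid_mode <- match.arg(hybrid_mode)
  cls <- names(n_per_group)
  if (is.null(cls) || !all(cls %in% c("M", "G", "WI", "GxM", "GxWI")))
    stop("n_per_group must be named with classes among M, G, WI, GxM, GxWI")
  if (any(n_per_group < 0)) stop("negative group size")
  if (3 * n_diagnostic_per_race > n_loci)
    stop("3 * n_diagnostic_per_race exceeds n_loci")
  if (divergence_F < 0 || divergence_F >= 1) stop("divergence_F must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (length(ancestral_freq_range) != 2 || ancestral_freq_range[1] <= 0 ||
      ancestral_freq_range[2] >= 1 || diff(ancestral_freq_range) < 0)
    stop("ancestral_freq_range must be an interval within (0, 1)")
  structure(list(n_per_group = n_per_group, n_loci = as.integer(n_loci),
                 divergence_F = divergence_F,
                 n_diagnostic_per_race = as.integer(n_diagnostic_per_race),
                 missing_rate = missing_rate, hybrid_q = hybrid_q,
                 ancestral_freq_range = ancestral_freq_range,
                 hybrid_mode = hybrid_mode,
                 guard_diagnostic = isTRUE(guard_diagnostic),
                 seed = as.integer(seed)),
            class = "sim_config")
}

RACES <- c("M", "G", "WI")

# dominant (sampled-q) parent per hybrid class and the other parent
HYBRID_PARENTS <- list(GxM = c(dominant = "M", other = "G"),
                       GxWI = c(dominant = "WI", other = "G"))

#' Simulate a multi-race genotype panel with known ground truth
#'
#' @param cfg a [sim_config()].
#' @return a list with components `gm` ([genotype_matrix()]), `panel`
#'   ([sample_panel()]) and `truth`, a list of class `simulation_truth` with
#'   `race_freqs` (loci x 3 matrix of per-race alt frequencies),
#'   `diagnostic_loci` (data.frame: locus_id, race, allele, base) and
#'   `sample_q` (samples x 3 matrix of true ancestry proportions).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  Fst <- cfg$divergence_F

  p_anc <- stats::runif(L, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  freqs <- matrix(NA_real_, L, 3, dimnames = list(NULL, RACES))
  for (r in RACES) {
    freqs[, r] <- if (Fst == 0) p_anc else
      stats::rbeta(L, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
  }

  # planted race-diagnostic loci: fixed for the diagnostic allele in their
  # race, fixed for the other allele in the other two races
  diag_df <- data.frame(idx = integer(0), race = character(0),
                        allele = character(0), stringsAsFactors = FALSE)
  nd <- cfg$n_diagnostic_per_race
  if (nd > 0) {
    idx <- sort(sample.int(L, 3 * nd))
    race <- rep(RACES, length.out = 3 * nd)  # cycle races over the sorted loci
    allele <- rep(c("alt", "ref"), length.out = 3 * nd)
    for (k in seq_along(idx)) {
      own <- if (allele[k] == "alt") 1 else 0
      freqs[idx[k], ] <- 1 - own
      freqs[idx[k], race[k]] <- own
    }
    diag_df <- data.frame(idx = idx, race = race, allele = allele,
                          stringsAsFactors = FALSE)
  }

  # sample bookkeeping
  classes <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n <- length(classes)
  ids <- unlist(lapply(names(cfg$n_per_group), function(cl)
    sprintf("%s_%02d", cl, seq_len(cfg$n_per_group[[cl]]))), use.names = FALSE)

  q <- matrix(0, n, 3, dimnames = list(ids, RACES))
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl %in% RACES) {
      q[i, cl] <- 1
    } else {
      par <- HYBRID_PARENTS[[cl]]
      spec <- cfg$hybrid_q[[cl]]
      qd <- if (length(spec) == 2) stats::runif(1, spec[1], spec[2]) else spec
      if (cfg$hybrid_mode == "f1") qd <- 0.5
      q[i, par["dominant"]] <- qd
      q[i, par["other"]] <- 1 - qd
    }
  }

  draw_sample <- function(i, loci = seq_len(L)) {
    cl <- classes[i]
    f <- freqs[loci, , drop = FALSE]
    if (cl %in% RACES) {
      stats::rbinom(length(loci), 2L, f[, cl])
    } else if (cfg$hybrid_mode == "f1") {
      par <- HYBRID_PARENTS[[cl]]
      stats::rbinom(length(loci), 1L, f[, par["dominant"]]) +
        stats::rbinom(length(loci), 1L, f[, par["other"]])
    } else {
      d <- integer(length(loci))
      for (copy in 1:2) {
        src <- sample(RACES, length(loci), replace = TRUE, prob = q[i, ])
        d <- d + stats::rbinom(length(loci), 1L, f[cbind(seq_along(loci), match(src, RACES))])
      }
      d
    }
  }

  d <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) d[i, ] <- draw_sample(i)

  # guard: planted loci must be exactly the diagnostic answer set
  pure_idx <- lapply(RACES, function(r) which(classes == r))
  names(pure_idx) <- RACES
  if (cfg$guard_diagnostic && all(lengths(pure_idx) > 0)) {
    non_planted <- setdiff(seq_len(L), diag_df$idx)
    for (l in non_planted) {
      tries <- 0L
      while (is_diag_pattern(d[, l], pure_idx) && tries < 20L) {
        d[, l] <- vapply(seq_len(n), function(i) draw_sample(i, l), integer(1))
        tries <- tries + 1L
      }
      if (is_diag_pattern(d[, l], pure_idx)) {
        # deterministic fallback: break the pattern with one heterozygote
        d[pure_idx[[1]][1], l] <- 1L
      }
    }
  }

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(n * L) < cfg$missing_rate
    d[matrix(mask, n, L)] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  loc_ids <- sprintf("ctg1:%d:%s:%s", seq_len(L), ref, alt)
  dimnames(d) <- list(ids, loc_ids)
  rownames(freqs) <- loc_ids

  gm <- genotype_matrix(d, ref, alt)
  panel <- sample_panel(ids, classes)
  diag_out <- data.frame(locus_id = loc_ids[diag_df$idx],
                         race = diag_df$race, allele = diag_df$allele,
                         base = ifelse(diag_df$allele == "alt",
                                       alt[diag_df$idx], ref[diag_df$idx]),
                         stringsAsFactors = FALSE)
  truth <- structure(list(race_freqs = freqs, diagnostic_loci = diag_out,
                          sample_q = q),
                     class = "simulation_truth")
  list(gm = gm, panel = panel, truth = truth)
}

# does this genotype column show a perfect fixed difference among the pure
# accessions (one race all-homozygous for one allele, the other two races
# all-homozygous for the other)?
is_diag_pattern <- function(col, pure_idx) {
  for (r in names(pure_idx)) {
    own <- col[pure_idx[[r]]]
    oth <- col[unlist(pure_idx[setdiff(names(pure_idx), r)])]
    if (all(own == 2L) && all(oth == 0L)) return(TRUE)
    if (all(own == 0L) && all(oth == 2L)) return(TRUE)
  }
  FALSE
}

#' Simulate the 21-accession germplasm panel design
#'
#' Returns a synthetic panel with the class composition of the reference
#' germplasm collection — 2 Mexican, 2 Guatemalan, 3 West Indian, 7
#' Guatemalan x Mexican and 7 Guatemalan x West Indian accessions, named
#' after the corresponding cultivars — with per-hybrid dominant-parent
#' admixture proportions sampled uniformly from `[0.51, 0.84]` (the M
#' fraction for GxM, the WI fraction for GxWI), so that every GxWI accession
#' has a true WI fraction above 0.5. Optionally appends accessions that are
#' truly GxWI but labelled `UNKNOWN`, emulating unknown-race selections to be
#' classified.
#'
#' @param divergence_F race divergence parameter.
#' @param seed RNG seed.
#' @param n_loci,n_diagnostic_per_race,missing_rate,hybrid_mode passed to
#'   [sim_config()].
#' @param n_unknown number of extra truly-GxWI accessions labelled `UNKNOWN`.
#' @return as [simulate_panel()].
#' @export
mimic_paper_panel <- function(divergence_F = 0.2, seed = 1, n_loci = 5000,
                              n_diagnostic_per_race = 3, missing_rate = 0,
                              hybrid_mode = c("admixed", "f1"), n_unknown = 0) {
  hybrid_mode <- match.arg(hybrid_mode)
  cfg <- sim_config(
    n_per_group = c(M = 2, G = 2, WI = 3, GxM = 7, GxWI = 7 + n_unknown),
    n_loci = n_loci, divergence_F = divergence_F,
    n_diagnostic_per_race = n_diagnostic_per_race,
    missing_rate = missing_rate,
    hybrid_q = list(GxM = c(0.51, 0.84), GxWI = c(0.51, 0.84)),
    hybrid_mode = hybrid_mode, seed = seed)
  sim <- simulate_panel(cfg)

  names21 <- c("WalterHole", "Duke7",                       # M
               "Nabal", "Reed",                             # G
               "Pollock", "Donnie", "Simmonds",             # WI
               "Bacon", "Hass", "Pinkerton", "Zutano",      # GxM
               "Ettinger", "Fuerte", "Dusa",
               "Miguel", "Loretta", "Beta", "Choquette",    # GxWI
               "Lula", "Tonnage", "Guikenda2")
  new_ids <- c(names21, if (n_unknown > 0) sprintf("Unknown_%d", seq_len(n_unknown)))
  old_ids <- sample_ids(sim$gm)
  stopifnot(length(new_ids) == length(old_ids))
  rownames(sim$gm$dosage) <- new_ids
  rownames(sim$truth$sample_q) <- new_ids
  labels <- sim$panel$race_label
  if (n_unknown > 0) labels[seq(22, 21 + n_unknown)] <- "UNKNOWN"
  sim$panel <- sample_panel(new_ids, labels)
  sim
}

#' Synthesize flanking-sequence contexts for simulated loci
#'
#' Generates random flanking sequence around each locus in the bracketed-SNP
#' notation `...ACGT[R/A]TTGA...` used by [build_kasp_assays()]. Purely
#' synthetic: simulated panels have no real genomic context.
#'
#' @param gm a [genotype_matrix()].
#' @param loci locus ids (default all).
#' @param flank bases of context on each side of the SNP.
#' @param seed RNG seed.
#' @return named character vector of context strings.
#' @export
synthesize_contexts <- function(gm, loci = locus_ids(gm), flank = 60, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- vapply(loci, function(l) {
    up <- paste(sample(bases, flank, replace = TRUE), collapse = "")
    dn <- paste(sample(bases, flank, replace = TRUE), collapse = "")
    paste0(up, "[", gm$ref_allele[l], "/", gm$alt_allele[l], "]", dn)
  }, "")
  names(out) <- loci
  out
}
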