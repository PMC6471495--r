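#' Three-step discovery of race-diagnostic SNP loci
#'
#' Applies the three filtering steps in order over the non-`UNKNOWN`
#' accessions of the panel:
#'
#' 1. **Completeness** — retain loci with zero missing calls.
#' 2. **Fixed difference** — for each race R, retain loci where one allele
#'    has frequency 1.00 among the pure-R accessions (all homozygous for it)
#'    and frequency 0.00 among the pure accessions of the other two races.
#' 3. **Hybrid concordance** — M-specific loci must have the diagnostic
#'    allele present (>= 1 copy) in *all* GxM accessions; WI-specific in all
#'    GxWI accessions; G-specific in at least
#'    `ceiling(hybrid_min_frac * n_hybrids)` of the combined GxM + GxWI
#'    accessions (the default fraction 11/14 generalises the n >= 11-of-14
#'    rule to arbitrary hybrid counts). If the hybrid class required by a
#'    race is absent, that race's step-3 check is skipped with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [sample_panel()] covering the matrix samples, with at least
#'   one pure accession of each race.
#' @param hybrid_min_frac step-3 fraction for G-specific loci.
#' @return data.frame of class `race_specific_loci`, ordered by input locus
#'   order: `locus_id`, `race`, `diagnostic_allele` (`"ref"`/`"alt"`),
#'   `diagnostic_base`, `hybrid_support` (hybrid accessions carrying the
#'   diagnostic allele among those checked in step 3).
#' @export
find_race_specific_loci <- function(gm, panel, hybrid_min_frac = 11 / 14) {
  pan <- panel_for(panel, gm)
  known <- pan$sample_id[pan$race_label != "UNKNOWN"]
  pure <- lapply(RACES, function(r) pure_samples(pan, r))
  names(pure) <- RACES
  if (any(lengths(pure) == 0))
    stop("no pure accessions for race(s): ",
         paste(RACES[lengths(pure) == 0], collapse = ", "))
  gxm <- pure_samples(pan, "GxM")
  gxwi <- pure_samples(pan, "GxWI")

  d <- gm$dosage[known, , drop = FALSE]
  complete <- colSums(is.na(d)) == 0L   # step 1

  res <- list()
  for (r in RACES) {
    own <- d[pure[[r]], , drop = FALSE]
    oth <- d[unlist(pure[setdiff(RACES, r)]), , drop = FALSE]
    # step 2, both orientations of the diagnostic allele
    alt_diag <- complete & colSums(own != 2L) == 0L & colSums(oth != 0L) == 0L
    ref_diag <- complete & colSums(own != 0L) == 0L & colSums(oth != 2L) == 0L
    for (orient in c("alt", "ref")) {
      hit <- if (orient == "alt") alt_diag else ref_diag
      if (!any(hit)) next
      # carrier test: >= 1 copy of the diagnostic allele
      carries <- function(rows, cols) {
        if (length(rows) == 0) return(matrix(TRUE, 0, length(cols)))
        x <- d[rows, cols, drop = FALSE]
        if (orient == "alt") x >= 1L else x <= 1L
      }
      hyb <- switch(r, M = gxm, WI = gxwi, G = c(gxm, gxwi))
      cols <- which(hit)
      if (length(hyb) == 0) {
        warning("no hybrid accessions to apply step 3 for race ", r,
                "; check skipped")
        support <- rep(NA_integer_, length(cols))
        pass3 <- rep(TRUE, length(cols))
      } else {
        cmat <- carries(hyb, cols)
        support <- colSums(cmat)
        need <- if (r == "G") ceiling(hybrid_min_frac * length(hyb)) else length(hyb)
        pass3 <- support >= need
      }
      if (!any(pass3)) next
      res[[length(res) + 1]] <- data.frame(
        locus_id = locus_ids(gm)[cols[pass3]],
        race = r,
        diagnostic_allele = orient,
        diagnostic_base = if (orient == "alt") gm$alt_allele[cols[pass3]]
                          else gm$ref_allele[cols[pass3]],
        hybrid_support = support[pass3],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(locus_id = character(0), race = character(0),
               diagnostic_allele = character(0), diagnostic_base = character(0),
               hybrid_support = integer(0), stringsAsFactors = FALSE)
  out <- out[order(match(out$locus_id, locus_ids(gm))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("race_specific_loci", "data.frame")
  out
}

# verbatim KASP tail sequences (FAM / VIC compatible)
#' @rdname build_kasp_assays
#' @export
KASP_FAM_TAIL <- "GAAGGTGACCAAGTTCATGCT"
#' @rdname build_kasp_assays
#' @export
KASP_VIC_TAIL <- "GAAGGTCGGAGTCAACGGATT"

KASP_PCR_PROFILE <- paste(
  "hot start 94C 15 min;",
  "10 touchdown cycles: 94C 20 s, 61->58C 60 s (-0.8C per cycle);",
  "35 cycles: 94C 20 s, 57C 60 s")

#' Build KASP allele-specific assays for diagnostic loci
#'
#' Each assay carries two tailed allele-specific oligos — the FAM oligo
#' (tail `GAAGGTGACCAAGTTCATGCT`) reading the ref allele and the VIC oligo
#' (tail `GAAGGTCGGAGTCAACGGATT`) reading the alt allele — built as
#' tail + the `oligo_len - 1` bases immediately 5' of the SNP + the allele
#' base, so the target SNP is the 3' terminal base. The common (reverse)
#' primer is the reverse complement of `oligo_len` bases starting
#' `common_offset` bases 3' of the SNP; primer design is purely positional
#' (no thermodynamic optimisation). Assays are named `PaMsSNP` / `PaGsSNP` /
#' `PaWIsSNP` with a 1-based index per race, and carry the fixed touchdown
#' PCR profile as metadata.
#'
#' @param loci a `race_specific_loci` data.frame ([find_race_specific_loci()]).
#' @param contexts named character vector mapping locus_id to a flanking
#'   sequence containing the SNP in bracket notation, e.g.
#'   `"ACGT...[A/G]...TTAA"`; see [read_contexts_fasta()] and
#'   [synthesize_contexts()].
#' @param oligo_len length of each allele-specific 3' sequence and of the
#'   common primer.
#' @param common_offset bases skipped 3' of the SNP before the common-primer
#'   template.
#' @return data.frame of class `kasp_assays`: `assay_name`, `target_locus`,
#'   `race`, `diagnostic_allele`, `fam_oligo`, `vic_oligo`, `common_primer`,
#'   `pcr_profile`.
#' @export
build_kasp_assays <- function(loci, contexts, oligo_len = 21, common_offset = 10) {
  idx <- stats::setNames(integer(3), RACES)
  prefix <- c(M = "PaMsSNP", G = "PaGsSNP", WI = "PaWIsSNP")
  rows <- lapply(seq_len(nrow(loci)), function(k) {
    lid <- loci$locus_id[k]
    if (!lid %in% names(contexts))
      stop("no context sequence for locus ", lid)
    ctx <- contexts[[lid]]
    m <- regexec("^([ACGTNacgtn]*)\\[([A-Za-z])/([A-Za-z])\\]([ACGTNacgtn]*)$", ctx)
    parts <- regmatches(ctx, m)[[1]]
    if (length(parts) != 5) stop("malformed context for locus ", lid)
    up <- toupper(parts[2]); a1 <- toupper(parts[3]); a2 <- toupper(parts[4])
    dn <- toupper(parts[5])
    if (nchar(up) < oligo_len - 1)
      stop("insufficient 5' flank for locus ", lid)
    if (nchar(dn) < common_offset + oligo_len)
      stop("insufficient 3' flank for locus ", lid)
    allele_seq <- substr(up, nchar(up) - oligo_len + 2, nchar(up))
    tmpl <- substr(dn, common_offset + 1, common_offset + oligo_len)
    race <- loci$race[k]
    idx[race] <<- idx[race] + 1L
    data.frame(
      assay_name = paste0(prefix[race], idx[race]),
      target_locus = lid,
      race = race,
      diagnostic_allele = loci$diagnostic_allele[k],
      fam_oligo = paste0(KASP_FAM_TAIL, allele_seq, a1),
      vic_oligo = paste0(KASP_VIC_TAIL, allele_seq, a2),
      common_primer = revcomp(tmpl),
      pcr_profile = KASP_PCR_PROFILE,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(assay_name = character(0), target_locus = character(0),
                      race = character(0), diagnostic_allele = character(0),
                      fam_oligo = character(0), vic_oligo = character(0),
                      common_primer = character(0), pcr_profile = character(0))
  rownames(out) <- NULL
  class(out) <- c("kasp_assays", "data.frame")
  out
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

#' Read bracketed-SNP context sequences from FASTA
#'
#' Plain FASTA where each record is named by locus id and the sequence
#' contains the SNP in bracket notation `[A/G]`. Because the bracket
#' notation is not a standard nucleotide alphabet, this dialect is parsed
#' directly rather than through a DNA-string class.
#'
#' @param path FASTA file path.
#' @return named character vector of context strings.
#' @export
read_contexts_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  stats::setNames(unname(seqs), ids)
}

#' @rdname read_contexts_fasta
#' @param contexts named character vector of context strings.
#' @export
write_contexts_fasta <- function(contexts, path) {
  writeLines(as.vector(rbind(paste0(">", names(contexts)), contexts)), path)
  invisible(path)
}

#' Classify accessions by race from diagnostic markers
#'
#' For each sample and race R, computes the fraction of R-specific markers
#' (with a non-missing call in that sample) at which the sample carries at
#' least one copy of the diagnostic allele; R is *detected* when that
#' fraction reaches `agreement`. The call is:
#' * a single race, if exactly one race is detected **and** the sample is
#'   homozygous for the diagnostic allele at `>= agreement` of that race's
#'   markers;
#' * a hybrid of the two detected races (`GxM`, `GxWI` or `MxWI`) if exactly
#'   two are detected;
#' * `AMBIGUOUS` otherwise (0 or 3 detections, one detection without
#'   homozygosity, or no scoreable markers).
#'
#' @param gm a [genotype_matrix()].
#' @param markers a `race_specific_loci` data.frame with markers for at
#'   least 2 races.
#' @param samples sample ids to classify (default all).
#' @param agreement required per-race marker agreement fraction, in (0.5, 1].
#'   The default 1 requires all of a race's markers to concur, appropriate
#'   for small marker panels.
#' @return data.frame of class `race_calls`: `sample_id`, per-race carrier
#'   fractions `frac_M`, `frac_G`, `frac_WI`, `detected` (comma-joined), and
#'   `call`.
#' @export
classify_race <- function(gm, markers, samples = sample_ids(gm), agreement = 1) {
  if (nrow(markers) == 0 || length(unique(markers$race)) < 2)
    stop("markers must cover at least 2 races")
  if (agreement <= 0.5 || agreement > 1) stop("agreement must be in (0.5, 1]")
  miss_m <- setdiff(markers$locus_id, locus_ids(gm))
  if (length(miss_m))
    stop("marker loci absent from genotype matrix: ",
         paste(miss_m, collapse = ", "))
  rows <- lapply(samples, function(s) {
    frac <- hom <- stats::setNames(rep(NA_real_, 3), RACES)
    for (r in RACES) {
      mk <- markers[markers$race == r, , drop = FALSE]
      if (nrow(mk) == 0) next
      g <- gm$dosage[s, mk$locus_id]
      ok <- !is.na(g)
      if (!any(ok)) next  # all-missing for this race's markers
      diag_dose <- ifelse(mk$diagnostic_allele == "alt", g, 2L - g)[ok]
      frac[r] <- mean(diag_dose >= 1L)
      hom[r] <- mean(diag_dose == 2L)
    }
    det <- RACES[!is.na(frac) & frac >= agreement]
    call <- if (all(is.na(frac))) {
      "AMBIGUOUS"  # no scoreable markers at all
    } else if (length(det) == 1) {
      if (!is.na(hom[det]) && hom[det] >= agreement) det else "AMBIGUOUS"
    } else if (length(det) == 2) {
      paste(sort(factor(det, levels = c("G", "M", "WI"))), collapse = "x")
    } else "AMBIGUOUS"
    data.frame(sample_id = s, frac_M = frac["M"], frac_G = frac["G"],
               frac_WI = frac["WI"], detected = paste(det, collapse = ","),
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("race_calls", "data.frame")
  out
}
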