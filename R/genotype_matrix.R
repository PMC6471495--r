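#' Biallelic SNP genotype matrix
#'
#' The container consumed by every analysis stage. Genotypes are stored as an
#' alt-allele dosage matrix (samples in rows, loci in columns) with values
#' 0 (ref/ref), 1 (ref/alt), 2 (alt/alt) or `NA` (missing). Genotypes are
#' unphased and unordered: 0/1 and 1/0 are the same state. The dosage view and
#' the genotype-call view are mutually convertible with no information loss
#' for biallelic data.
#'
#' @param dosage integer matrix, samples x loci, with `dimnames` giving unique
#'   sample ids (rows) and locus ids (columns); entries in `{0, 1, 2, NA}`.
#' @param ref_allele,alt_allele single-character allele symbols per locus
#'   (recycled if scalar). When a locus id parses as `chrom:pos:ref:alt` these
#'   usually repeat its last two fields, but they are independent slots.
#' @return an object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, NA), 2, 2,
#'          dimnames = list(c("s1", "s2"), c("l1", "l2"))),
#'   ref_allele = "A", alt_allele = "G")
#' n_loci(gm)
#' @export
genotype_matrix <- function(dosage, ref_allele = "A", alt_allele = "B") {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  dn <- dimnames(dosage)
  if (is.null(dn)) dn <- list(NULL, NULL)
  if (is.null(dn[[1]]) && nrow(dosage) == 0L) dn[[1]] <- character(0)
  if (is.null(dn[[2]]) && ncol(dosage) == 0L) dn[[2]] <- character(0)
  if (is.null(dn[[1]]) || is.null(dn[[2]]))
    stop("`dosage` must have sample ids as rownames and locus ids as colnames")
  dimnames(dosage) <- dn
  if (anyDuplicated(dn[[1]])) stop("duplicated sample ids")
  if (anyDuplicated(dn[[2]])) stop("duplicated locus ids")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  L <- ncol(dosage)
  ref_allele <- rep_len(as.character(ref_allele), L)
  alt_allele <- rep_len(as.character(alt_allele), L)
  if (L > 0L) {
    if (any(nchar(ref_allele) != 1L) || any(nchar(alt_allele) != 1L))
      stop("alleles must be single-character symbols")
    if (any(ref_allele == alt_allele))
      stop("ref and alt allele must differ (loci are strictly biallelic)")
  }
  names(ref_allele) <- names(alt_allele) <- dn[[2]]
  structure(
    list(dosage = dosage, ref_allele = ref_allele, alt_allele = alt_allele),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d loci, %.1f%% missing\n",
              n_samples(x), n_loci(x),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Accessors for genotype_matrix objects
#'
#' @param gm a [genotype_matrix()].
#' @return `sample_ids`/`locus_ids` return character vectors; `n_samples`/
#'   `n_loci` counts; `dosage` the integer alt-dosage matrix.
#' @export
sample_ids <- function(gm) rownames(gm$dosage)

#' @rdname sample_ids
#' @export
locus_ids <- function(gm) colnames(gm$dosage)

#' @rdname sample_ids
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname sample_ids
#' @export
n_loci <- function(gm) ncol(gm$dosage)

#' @rdname sample_ids
#' @export
dosage <- function(gm) gm$dosage

#' Subset a genotype matrix by samples and/or loci
#'
#' Order of the `samples`/`loci` arguments is respected, so this also reorders.
#'
#' @param gm a [genotype_matrix()].
#' @param samples,loci character vectors of ids (or NULL to keep all).
#' @return a [genotype_matrix()].
#' @export
subset_gm <- function(gm, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- sample_ids(gm)
  if (is.null(loci)) loci <- locus_ids(gm)
  miss_s <- setdiff(samples, sample_ids(gm))
  if (length(miss_s)) stop("unknown sample ids: ", paste(miss_s, collapse = ", "))
  miss_l <- setdiff(loci, locus_ids(gm))
  if (length(miss_l)) stop("unknown locus ids: ", paste(miss_l, collapse = ", "))
  genotype_matrix(gm$dosage[samples, loci, drop = FALSE],
                  gm$ref_allele[loci], gm$alt_allele[loci])
}

#' Genotype-call view of a genotype matrix
#'
#' Renders each dosage as an unordered allele pair using the locus's ref/alt
#' symbols (`"A/A"`, `"A/G"`, `"G/G"`), with `"./."` for missing. Together
#' with [calls_to_dosage()] this is the lossless round-trip between the two
#' views.
#'
#' @param gm a [genotype_matrix()].
#' @return character matrix, samples x loci.
#' @export
gm_calls <- function(gm) {
  d <- gm$dosage
  out <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    r <- gm$ref_allele[j]; a <- gm$alt_allele[j]
    v <- d[, j]
    out[, j] <- ifelse(is.na(v), "./.",
                ifelse(v == 0L, paste0(r, "/", r),
                ifelse(v == 1L, paste0(r, "/", a), paste0(a, "/", a))))
  }
  out
}

#' Convert a call matrix back to alt-allele dosage
#'
#' @param calls character matrix as produced by [gm_calls()].
#' @param ref_allele,alt_allele per-locus allele symbols.
#' @return integer dosage matrix.
#' @export
calls_to_dosage <- function(calls, ref_allele, alt_allele) {
  out <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (j in seq_len(ncol(calls))) {
    r <- ref_allele[j]; a <- alt_allele[j]
    v <- calls[, j]
    out[, j] <- ifelse(v == paste0(r, "/", r), 0L,
                ifelse(v %in% c(paste0(r, "/", a), paste0(a, "/", r)), 1L,
                ifelse(v == paste0(a, "/", a), 2L, NA_integer_)))
  }
  out
}

# per-locus missing fraction; used by QC and the LD-prune tie-break
locus_missing_rate <- function(gm) colMeans(is.na(gm$dosage))
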