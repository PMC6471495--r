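#' Read a genotype matrix from VCF
#'
#' Reads a VCF v4.x file (GT field only) into a [genotype_matrix()]. Only
#' biallelic SNP records are retained; multiallelic or non-SNP records are
#' skipped with a warning (or rejected under `strict = TRUE`). GT values
#' `0/0`, `0/1`, `1/0`, `1/1` map to dosages 0/1/1/2; `./.` and `.` map to
#' missing; the phase separator `|` is treated as `/` (genotypes are
#' unphased throughout).
#'
#' Locus ids are taken from the VCF ID column when set, otherwise constructed
#' as `chrom:pos:ref:alt`. Parsing is delegated to
#' [VariantAnnotation::readVcf()].
#'
#' @param path VCF file path.
#' @param strict reject (error) rather than skip multiallelic/non-SNP records.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, strict = FALSE) {
  v <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop("failed to parse VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T", "a", "c", "g", "t", "N")
  if (any(!keep)) {
    bad <- names(rr)[!keep]
    msg <- paste0(sum(!keep), " multiallelic/non-SNP record(s) ",
                  if (strict) "rejected" else "skipped", ": ",
                  paste(utils::head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ...")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) {
    if (length(VariantAnnotation::samples(VariantAnnotation::header(v))) == 0L)
      gt <- matrix(character(0), nrow = length(ref), ncol = 0L,
                   dimnames = list(names(rr), NULL))
    else
      stop("VCF has samples but no GT field: ", path)
  }
  gt <- gt[keep, , drop = FALSE]
  ids <- names(rr)[keep]
  miss_id <- is.na(ids) | ids == "" | ids == "."
  if (any(miss_id))
    ids[miss_id] <- paste(as.character(GenomicRanges::seqnames(rr))[keep][miss_id],
                          GenomicRanges::start(rr)[keep][miss_id],
                          ref[keep][miss_id], alt1[keep][miss_id], sep = ":")
  d <- gt_to_dosage(gt)
  dimnames(d) <- list(ids, colnames(gt))
  genotype_matrix(t(d), ref[keep], alt1[keep])
}

# vectorised GT-string decoding; phase separator | treated as /
gt_to_dosage <- function(gt) {
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "./." = NA_integer_, "." = NA_integer_,
             "./" = NA_integer_, "/." = NA_integer_)
  g <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  idx <- match(g, names(codes))
  if (anyNA(idx))
    stop("unsupported GT value: ", g[which(is.na(idx))[1]])
  matrix(unname(codes[idx]), nrow = nrow(gt), ncol = ncol(gt))
}

#' Write a genotype matrix as minimal VCF v4.2
#'
#' Emits a GT-only VCF. When a locus id parses as `chrom:pos:ref:alt` the
#' coordinates are reused; otherwise a synthetic contig `ctg1` with positions
#' 1..L is written, and the locus id is preserved in the ID column so that
#' `read_vcf(write_vcf(gm))` is the identity on calls, locus order and sample
#' order.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_vcf <- function(gm, path) {
  ids <- locus_ids(gm)
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+):([A-Za-z]):([A-Za-z])$", ids))
  parsed <- lengths(m) == 5L
  chrom <- ifelse(parsed, vapply(m, function(x) if (length(x)) x[2] else "", ""), "ctg1")
  pos <- ifelse(parsed, vapply(m, function(x) if (length(x)) x[3] else "", ""),
                as.character(seq_along(ids)))
  gtmat <- matrix("./.", n_loci(gm), n_samples(gm))
  d <- t(gm$dosage)  # loci x samples
  gtmat[!is.na(d)] <- c("0/0", "0/1", "1/1")[d[!is.na(d)] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=racepop",
    "##contig=<ID=ctg1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t"))
  body <- if (n_loci(gm) == 0L) character(0) else
    paste(chrom, pos, ids, gm$ref_allele, gm$alt_allele, ".", "PASS", ".",
          "GT", apply(gtmat, 1, paste, collapse = "\t"), sep = "\t")
  if (n_samples(gm) == 0L && n_loci(gm) > 0L)
    body <- paste(chrom, pos, ids, gm$ref_allele, gm$alt_allele, ".", "PASS",
                  ".", "GT", sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read / write the dosage TSV dialect
#'
#' A plain TSV whose first column is the locus id and whose remaining columns
#' (one per sample, named in the header) hold alt-allele dosages in
#' `{0, 1, 2, NA}`. When locus ids parse as `chrom:pos:ref:alt`, the allele
#' symbols are recovered from the id; otherwise placeholder symbols `A`/`B`
#' are used (the TSV dialect carries no allele information).
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 1L) stop("empty dosage TSV: ", path)
  ids <- df[[1]]
  samples <- names(df)[-1]
  d <- matrix(NA_integer_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- df[[j + 1]]
    ok <- v %in% c("0", "1", "2", "NA", "")
    if (any(!ok))
      stop(sprintf("invalid dosage cell '%s' at row %d, column '%s' of %s",
                   v[which(!ok)[1]], which(!ok)[1], samples[j], path))
    d[, j] <- suppressWarnings(ifelse(v %in% c("NA", ""), NA_integer_,
                                      as.integer(v)))
  }
  m <- regmatches(ids, regexec("^([^:]+):([0-9]+):([A-Za-z]):([A-Za-z])$", ids))
  parsed <- lengths(m) == 5L
  ref <- ifelse(parsed, vapply(m, function(x) if (length(x)) x[4] else "", ""), "A")
  alt <- ifelse(parsed, vapply(m, function(x) if (length(x)) x[5] else "", ""), "B")
  genotype_matrix(t(d), ref, alt)
}

#' @rdname read_tsv_matrix
#' @param gm a [genotype_matrix()].
#' @export
write_tsv_matrix <- function(gm, path) {
  d <- t(gm$dosage)
  df <- data.frame(locus_id = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
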