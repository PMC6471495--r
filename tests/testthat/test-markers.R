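# small hand-built panel: 2 pure per race, 2 hybrids per class
hand_panel_gm <- function() {
  ids <- c("M1", "M2", "G1", "G2", "W1", "W2", "GM1", "GM2", "GW1", "GW2")
  # loci: 1 = M-diagnostic (alt), 2 = same allele everywhere (fails step 2),
  # 3 = would be WI-diagnostic but has one missing call (fails step 1),
  # 4 = G-diagnostic (ref), 5 = M-fixed but absent from one GxM (fails step 3)
  d <- rbind(
    M1  = c(2L, 2L, 0L, 2L, 2L),
    M2  = c(2L, 2L, 0L, 2L, 2L),
    G1  = c(0L, 2L, 0L, 0L, 0L),
    G2  = c(0L, 2L, 0L, 0L, 0L),
    W1  = c(0L, 2L, 2L, 2L, 0L),
    W2  = c(0L, 2L, NA, 2L, 0L),
    GM1 = c(1L, 2L, 0L, 1L, 1L),
    GM2 = c(1L, 2L, 0L, 1L, 0L),
    GW1 = c(0L, 2L, 1L, 1L, 0L),
    GW2 = c(0L, 2L, 1L, 1L, 0L))
  colnames(d) <- paste0("loc", 1:5)
  list(gm = genotype_matrix(d),
       panel = sample_panel(ids, c("M", "M", "G", "G", "WI", "WI",
                                   "GxM", "GxM", "GxWI", "GxWI")))
}

test_that("the three filter steps behave as stated on a hand-built panel", {
  h <- hand_panel_gm()
  mk <- find_race_specific_loci(h$gm, h$panel)
  expect_equal(mk$locus_id, c("loc1", "loc4"))
  expect_equal(mk$race, c("M", "G"))
  expect_equal(mk$diagnostic_allele, c("alt", "ref"))
  expect_equal(mk$hybrid_support, c(2L, 4L))
  # loc2: fixed same allele in all races -> step 2 rejection
  # loc3: one missing call -> step 1 rejection
  # loc5: M-fixed but a GxM lacks the allele -> step 3 rejection
  expect_false(any(c("loc2", "loc3", "loc5") %in% mk$locus_id))
})

test_that("discovery requires pure representatives and is order-invariant", {
  h <- hand_panel_gm()
  no_wi <- h$panel[h$panel$race_label != "WI", ]
  class(no_wi) <- c("sample_panel", "data.frame")
  expect_error(
    find_race_specific_loci(subset_gm(h$gm, samples = no_wi$sample_id), no_wi),
    "no pure accessions.*WI")
  set.seed(2)
  gm_perm <- subset_gm(h$gm, samples = sample(sample_ids(h$gm)))
  mk2 <- find_race_specific_loci(gm_perm, h$panel)
  expect_equal(mk2, find_race_specific_loci(h$gm, h$panel))
})

test_that("allele relabeling keeps diagnostics pointing at the same physical allele", {
  h <- hand_panel_gm()
  gm_flip <- genotype_matrix(2L - dosage(h$gm), h$gm$alt_allele, h$gm$ref_allele)
  mk <- find_race_specific_loci(h$gm, h$panel)
  mkf <- find_race_specific_loci(gm_flip, h$panel)
  expect_equal(mkf$locus_id, mk$locus_id)
  expect_equal(mkf$diagnostic_allele, ifelse(mk$diagnostic_allele == "alt",
                                             "ref", "alt"))
  expect_equal(mkf$diagnostic_base, mk$diagnostic_base)
})

test_that("planted diagnostics are recovered exactly from an F1 simulation", {
  sim <- mimic_paper_panel(seed = 21, n_loci = 1200, hybrid_mode = "f1")
  mk <- find_race_specific_loci(sim$gm, sim$panel)
  truth <- sim$truth$diagnostic_loci
  expect_setequal(mk$locus_id, truth$locus_id)
  idx <- match(mk$locus_id, truth$locus_id)
  expect_equal(mk$race, truth$race[idx])
  expect_equal(mk$diagnostic_allele, truth$allele[idx])
  # every reported locus passes an independent predicate re-check
  for (k in seq_len(nrow(mk)))
    expect_true(check_marker_predicates(sim$gm, sim$panel, mk$locus_id[k],
                                        mk$race[k], mk$diagnostic_allele[k]))
})

test_that("classification follows the detection rules", {
  sim <- mimic_paper_panel(seed = 22, n_loci = 1000, hybrid_mode = "f1",
                           n_unknown = 3)
  mk <- find_race_specific_loci(sim$gm, sim$panel)
  calls <- classify_race(sim$gm, mk)
  truth_class <- setNames(sim$panel$race_label, sim$panel$sample_id)
  truth_class[truth_class == "UNKNOWN"] <- "GxWI"  # unknowns simulated as GxWI
  expect_equal(setNames(calls$call, calls$sample_id), truth_class)

  # a sample heterozygous at markers of all three races is AMBIGUOUS
  d <- dosage(sim$gm)["Hass", , drop = FALSE]
  d[1, ] <- 0L
  d[1, mk$locus_id] <- 1L  # heterozygous carrier of all three diagnostic sets
  rownames(d) <- "odd"
  gm_odd <- genotype_matrix(d, sim$gm$ref_allele, sim$gm$alt_allele)
  expect_equal(classify_race(gm_odd, mk)$call, "AMBIGUOUS")

  # all-missing at every marker is AMBIGUOUS too
  d[1, mk$locus_id] <- NA_integer_
  gm_na <- genotype_matrix(d, sim$gm$ref_allele, sim$gm$alt_allele)
  expect_equal(classify_race(gm_na, mk)$call, "AMBIGUOUS")

  expect_error(classify_race(sim$gm, mk[mk$race == "M", ]), "at least 2 races")
  expect_error(classify_race(sim$gm, mk, agreement = 0.4), "agreement")
})

test_that("KASP assays follow the construction rules", {
  loci <- data.frame(locus_id = c("x1", "x2"), race = c("M", "WI"),
                     diagnostic_allele = c("alt", "ref"),
                     diagnostic_base = c("G", "T"),
                     hybrid_support = c(2L, 2L), stringsAsFactors = FALSE)
  up <- paste(rep("ACGT", 10), collapse = "")   # 40 bases
  dn <- paste(rep("TTGA", 10), collapse = "")
  contexts <- c(x1 = paste0(up, "[A/G]", dn), x2 = paste0(up, "[T/C]", dn))
  as <- build_kasp_assays(loci, contexts, oligo_len = 21, common_offset = 10)
  expect_equal(as$assay_name, c("PaMsSNP1", "PaWIsSNP1"))
  expect_true(all(startsWith(as$fam_oligo, "GAAGGTGACCAAGTTCATGCT")))
  expect_true(all(startsWith(as$vic_oligo, "GAAGGTCGGAGTCAACGGATT")))
  # 3' terminal base is the target allele; oligos differ only at that base
  expect_equal(substr(as$fam_oligo[1], nchar(as$fam_oligo[1]), nchar(as$fam_oligo[1])), "A")
  expect_equal(substr(as$vic_oligo[1], nchar(as$vic_oligo[1]), nchar(as$vic_oligo[1])), "G")
  strip <- function(x, tail) substr(x, nchar(tail) + 1, nchar(x) - 1)
  expect_equal(strip(as$fam_oligo[1], "GAAGGTGACCAAGTTCATGCT"),
               strip(as$vic_oligo[1], "GAAGGTCGGAGTCAACGGATT"))
  # allele-specific 3' sequence = last 20 context bases + allele
  expect_equal(as$fam_oligo[1],
               paste0("GAAGGTGACCAAGTTCATGCT", substr(up, 21, 40), "A"))
  # common primer: revcomp of 21 bases starting 10 bases 3' of the SNP
  tmpl <- substr(dn, 11, 31)
  expect_equal(as$common_primer[1],
               paste(rev(strsplit(chartr("ACGT", "TGCA", tmpl), "")[[1]]),
                     collapse = ""))
  expect_match(as$pcr_profile[1], "94C 15 min")

  # insufficient flank errors name the locus
  short <- c(x1 = "ACGT[A/G]TT", x2 = contexts[["x2"]])
  expect_error(build_kasp_assays(loci, short), "x1")
  expect_error(build_kasp_assays(loci, contexts[1]), "x2")
})

test_that("context FASTA round-trips through the bracket dialect", {
  ctx <- c(l1 = "ACGT[A/G]TTAA", l2 = "GGG[C/T]AAA")
  f <- withr::local_tempfile(fileext = ".fa")
  write_contexts_fasta(ctx, f)
  expect_equal(read_contexts_fasta(f), ctx)
})
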