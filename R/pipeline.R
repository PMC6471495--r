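#' Pipeline configuration
#'
#' Validates inputs and collects per-stage parameters for [run_pipeline()].
#' Stage seeds are derived deterministically from the global seed (seed +
#' fixed per-stage offset), so re-running a stage in isolation reproduces
#' its in-pipeline behaviour.
#'
#' @param genotypes path to a VCF (`.vcf`) or dosage TSV genotype matrix.
#' @param panel path to a sample-panel TSV.
#' @param out_dir output directory (created if needed).
#' @param contexts optional path to a bracketed-SNP context FASTA, enabling
#'   the KASP stage.
#' @param stages character vector of stages to run, in dependency order
#'   among `"prune"`, `"diversity"`, `"tree"`, `"pcoa"`, `"amova"`,
#'   `"ancestry"`, `"markers"`, `"kasp"`, `"classify"`.
#' @param prune a [prune_params()].
#' @param grouping grouping rule for diversity/AMOVA (see [race_grouping()]).
#' @param amova_perms permutations for the AMOVA test.
#' @param pcoa_axes retained PCoA axes.
#' @param agreement marker agreement threshold for [classify_race()].
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, panel, out_dir,
                            contexts = NULL,
                            stages = c("prune", "diversity", "tree", "pcoa",
                                       "amova", "ancestry", "markers",
                                       "kasp", "classify"),
                            prune = prune_params(),
                            grouping = "k2",
                            amova_perms = 999,
                            pcoa_axes = 3,
                            agreement = 1,
                            seed = 1) {
  known <- c("prune", "diversity", "tree", "pcoa", "amova", "ancestry",
             "markers", "kasp", "classify")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (p in c(genotypes, panel, contexts))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  if ("kasp" %in% stages && is.null(contexts) )
    stop("kasp stage requires a contexts FASTA")
  if ("kasp" %in% stages && !("markers" %in% stages))
    stop("kasp stage depends on markers")
  if ("classify" %in% stages && !("markers" %in% stages))
    stop("classify stage depends on markers")
  structure(list(genotypes = genotypes, panel = panel, out_dir = out_dir,
                 contexts = contexts, stages = stages, prune = prune,
                 grouping = grouping, amova_perms = amova_perms,
                 pcoa_axes = pcoa_axes, agreement = agreement,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — LD pruning, diversity,
#' IBS distance + UPGMA tree, PCoA, AMOVA, ancestry proportions,
#' race-diagnostic marker discovery, KASP assay construction, and race
#' classification of `UNKNOWN` accessions — writing plain-text outputs
#' (TSV / Newick) plus a JSON manifest recording every file with its stage,
#' parameters and md5 checksum. Identical config + inputs give identical
#' outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  gm <- if (grepl("\\.vcf$", cfg$genotypes)) read_vcf(cfg$genotypes)
        else read_tsv_matrix(cfg$genotypes)
  panel <- read_panel(cfg$panel)
  panel_for(panel, gm)  # validate coverage early
  manifest <- list()
  emit <- function(stage, file, writer, params = list()) {
    path <- file.path(cfg$out_dir, file)
    writer(path)
    manifest[[length(manifest) + 1]] <<- list(
      stage = stage, file = file, params = params,
      md5 = unname(tools::md5sum(path)))
    path
  }
  run <- function(stage) stage %in% cfg$stages
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  known_gm <- subset_gm(gm, samples = panel$sample_id[
    panel$race_label != "UNKNOWN" & panel$sample_id %in% sample_ids(gm)])

  # LD pruning feeds the ancestry (population-structure) stage only; all
  # other stages use the full SNP set, mirroring the workflow this package
  # models (pruned subset for structure inference, full set elsewhere)
  gm_struct <- gm
  if (run("prune")) tryCatch({
    gm_struct <- ld_prune(gm, cfg$prune)
    emit("prune", "pruned.tsv", function(p) write_tsv_matrix(gm_struct, p),
         unclass(cfg$prune))
  }, error = function(e) fail("prune", e))

  grouping <- race_grouping(panel, cfg$grouping)
  if (run("diversity")) tryCatch({
    div <- population_diversity(known_gm, grouping)
    emit("diversity", "diversity.tsv", function(p)
      utils::write.table(div, p, sep = "\t", quote = FALSE, row.names = FALSE),
      list(grouping = cfg$grouping))
  }, error = function(e) fail("diversity", e))

  dm <- NULL
  if (run("tree") || run("pcoa") || run("amova")) dm <- ibs_distance(gm)

  if (run("tree")) tryCatch({
    tr <- upgma(dm)
    emit("tree", "tree.nwk", function(p) write_newick(tr, p))
    emit("tree", "distances.tsv", function(p)
      utils::write.table(data.frame(sample_id = rownames(dm), dm,
                                    check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  }, error = function(e) fail("tree", e))

  if (run("pcoa")) tryCatch({
    pc <- pcoa(dm, cfg$pcoa_axes)
    tab <- data.frame(sample_id = pc$sample_ids, pc$coordinates,
                      check.names = FALSE)
    emit("pcoa", "pcoa.tsv", function(p) {
      con <- file(p, "w"); on.exit(close(con))
      writeLines(paste0("# pct_variance: ",
                        paste(sprintf("%.4f", pc$pct_variance), collapse = "\t")),
                 con)
      utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }, list(axes = cfg$pcoa_axes))
  }, error = function(e) fail("pcoa", e))

  if (run("amova")) tryCatch({
    am <- amova_two_level(dm, grouping, n_perm = cfg$amova_perms,
                          seed = cfg$seed + 101L)
    emit("amova", "amova.txt", function(p) {
      con <- file(p, "w"); on.exit(close(con))
      sink(con); print(am); sink()
    }, list(grouping = cfg$grouping, n_perm = cfg$amova_perms))
  }, error = function(e) fail("amova", e))

  if (run("ancestry")) tryCatch({
    rf <- reference_freqs(gm_struct, panel)
    qtab <- estimate_q_all(gm_struct, rf)
    emit("ancestry", "q.tsv", function(p)
      utils::write.table(qtab, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }, error = function(e) fail("ancestry", e))

  markers <- NULL
  if (run("markers")) tryCatch({
    markers <- find_race_specific_loci(gm, panel)
    emit("markers", "markers.tsv", function(p)
      utils::write.table(markers, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }, error = function(e) fail("markers", e))

  if (run("kasp")) tryCatch({
    assays <- build_kasp_assays(markers, read_contexts_fasta(cfg$contexts))
    emit("kasp", "assays.tsv", function(p)
      utils::write.table(assays, p, sep = "\t", quote = FALSE, row.names = FALSE))
  }, error = function(e) fail("kasp", e))

  if (run("classify")) tryCatch({
    unknowns <- panel$sample_id[panel$race_label == "UNKNOWN" &
                                panel$sample_id %in% sample_ids(gm)]
    if (length(unknowns) == 0) unknowns <- sample_ids(gm)
    calls <- classify_race(gm, markers, unknowns, cfg$agreement)
    emit("classify", "calls.tsv", function(p)
      utils::write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE),
      list(agreement = cfg$agreement))
  }, error = function(e) fail("classify", e))

  man_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         inputs = list(genotypes = unname(tools::md5sum(cfg$genotypes)),
                       panel = unname(tools::md5sum(cfg$panel))),
         outputs = manifest),
    man_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
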