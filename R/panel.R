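#' Sample panel: accession names with race labels
#'
#' Mirrors the germplasm table of a racially structured collection: each
#' accession carries one of six labels — the three pure ecological races
#' (`M` Mexican, `G` Guatemalan, `WI` West Indian), the two interracial hybrid
#' classes (`GxM`, `GxWI`), or `UNKNOWN` for accessions of unresolved race.
#' An optional free-form `population` column supplies groupings for AMOVA and
#' per-population diversity.
#'
#' @param sample_id character accession names (unique).
#' @param race_label labels, normalised case-insensitively (e.g. `"G x M"`,
#'   `"gxm"`, `"G×M"` all map to `"GxM"`).
#' @param population optional free-form group key (defaults to the race label).
#' @return a `data.frame` of class `sample_panel` with columns `sample_id`,
#'   `race_label`, `population`.
#' @export
sample_panel <- function(sample_id, race_label, population = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id in panel: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  race_label <- normalize_race_label(race_label)
  if (is.null(population)) population <- race_label
  out <- data.frame(sample_id = sample_id, race_label = race_label,
                    population = as.character(population),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_panel", "data.frame")
  out
}

#' @rdname sample_panel
#' @export
RACE_LEVELS <- c("M", "G", "WI", "GxM", "GxWI", "UNKNOWN")

normalize_race_label <- function(x) {
  key <- toupper(gsub("[[:space:]]", "", gsub("×", "x", as.character(x))))
  map <- c(M = "M", MEXICAN = "M",
           G = "G", GUATEMALAN = "G",
           WI = "WI", WESTINDIAN = "WI",
           GXM = "GxM", MXG = "GxM",
           GXWI = "GxWI", WIXG = "GxWI",
           UNKNOWN = "UNKNOWN", UNK = "UNKNOWN")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unknown race label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         "; admissible labels: ", paste(RACE_LEVELS, collapse = ", "))
  out
}

#' Read / write a sample panel TSV
#'
#' TSV with header columns `sample_id`, `race_label` and optionally
#' `population`.
#'
#' @param path file path.
#' @return [read_panel()]: a [sample_panel()]. [write_panel()]: invisibly,
#'   the path.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "race_label")
  if (!all(need %in% names(df)))
    stop("panel file must have columns sample_id and race_label: ", path)
  sample_panel(df$sample_id, df$race_label,
               if ("population" %in% names(df)) df$population else NULL)
}

#' @rdname read_panel
#' @param panel a [sample_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# panel rows for the samples of a genotype matrix, in matrix order;
# errors if any sample lacks a panel entry
panel_for <- function(panel, gm) {
  idx <- match(sample_ids(gm), panel$sample_id)
  if (anyNA(idx))
    stop("samples missing from panel: ",
         paste(sample_ids(gm)[is.na(idx)], collapse = ", "))
  panel[idx, , drop = FALSE]
}

# sample ids of the pure accessions of one race
pure_samples <- function(panel, race) panel$sample_id[panel$race_label == race]

#' Standard groupings of a panel for AMOVA / diversity
#'
#' `"race"` uses each race/hybrid class as its own population; `"k2"` mirrors
#' the two-section structure (West Indian related: `WI` + `GxWI`, versus
#' Mexican-Guatemalan related: `M` + `G` + `GxM`); `"k3"` splits the latter
#' into an M-related (`M` + `GxM`) and a G-related (`G`) group. `UNKNOWN`
#' samples are excluded.
#'
#' @param panel a [sample_panel()].
#' @param grouping one of `"race"`, `"k2"`, `"k3"`.
#' @return named character vector mapping sample_id to population.
#' @export
race_grouping <- function(panel, grouping = c("k2", "k3", "race")) {
  grouping <- match.arg(grouping)
  p <- panel[panel$race_label != "UNKNOWN", , drop = FALSE]
  g <- switch(grouping,
    race = p$race_label,
    k2 = ifelse(p$race_label %in% c("WI", "GxWI"), "WI-related", "MG-related"),
    k3 = ifelse(p$race_label %in% c("WI", "GxWI"), "WI-related",
         ifelse(p$race_label %in% c("M", "GxM"), "M-related", "G-related")))
  stats::setNames(g, p$sample_id)
}
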