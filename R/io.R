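# Plain-text input/output: every table travels as TSV, trees as Newick.

write_tsv0 <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv0 <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Serializes the output of [simulate_ci_dataset()]: the tree as Newick,
#' every table as TSV (genomes, tip states, orthologue counts, branch-site
#' p-values, localization profiles, benchmark pairs, pathway map and
#' events) and the planted truth as TSVs. All files round-trip through
#' [read_ci_dataset()].
#'
#' @param sim Output of [simulate_ci_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ci_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ciloss_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_tsv0(sim$states, file.path(dir, "states.tsv"))
  write_tsv0(sim$genomes, file.path(dir, "genomes.tsv"))
  cnt <- data.frame(family_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE)
  write_tsv0(cnt, file.path(dir, "counts.tsv"))
  write_tsv0(sim$ps_tables, file.path(dir, "ps_pvalues.tsv"))
  write_tsv0(sim$events, file.path(dir, "family_events.tsv"))
  write_tsv0(sim$profiles, file.path(dir, "localization.tsv"))
  write_tsv0(sim$pairs, file.path(dir, "pairs.tsv"))
  write_tsv0(sim$pathway_map, file.path(dir, "pathway_map.tsv"))
  write_tsv0(sim$pathway_events, file.path(dir, "pathway_events.tsv"))
  truth_clades <- data.frame(
    clade_id = rep(seq_along(sim$truth$loss_clades),
                   lengths(sim$truth$loss_clades)),
    species_id = unlist(sim$truth$loss_clades, use.names = FALSE))
  write_tsv0(truth_clades, file.path(dir, "truth_loss_clades.tsv"))
  ids <- function(x) if (length(x)) x else character(0)
  truth_ids <- rbind(
    data.frame(kind = "assoc_family", id = ids(sim$truth$assoc_family_ids)),
    data.frame(kind = "overlap_family", id = ids(sim$truth$overlap_family_ids)),
    data.frame(kind = "retargeted_pair", id = ids(sim$truth$retargeted_pair_ids)),
    data.frame(kind = "altered_pathway", id = ids(sim$truth$altered_pathway_ids)))
  write_tsv0(truth_ids, file.path(dir, "truth_ids.tsv"))
  invisible(dir)
}

#' Read a synthetic dataset written by [write_ci_dataset()]
#'
#' @param dir Directory written by [write_ci_dataset()].
#' @return A list with the same table components as
#'   [simulate_ci_dataset()] (config is not serialized).
#' @export
read_ci_dataset <- function(dir) {
  cnt <- read_tsv0(file.path(dir, "counts.tsv"))
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$family_id
  truth_clades <- read_tsv0(file.path(dir, "truth_loss_clades.tsv"))
  truth_ids <- read_tsv0(file.path(dir, "truth_ids.tsv"))
  pick <- function(kind) truth_ids$id[truth_ids$kind == kind]
  list(
    tree = ape::read.tree(file.path(dir, "tree.nwk")),
    states = read_tsv0(file.path(dir, "states.tsv")),
    genomes = read_tsv0(file.path(dir, "genomes.tsv")),
    counts = counts,
    ps_tables = read_tsv0(file.path(dir, "ps_pvalues.tsv")),
    events = read_tsv0(file.path(dir, "family_events.tsv")),
    profiles = read_tsv0(file.path(dir, "localization.tsv")),
    pairs = read_tsv0(file.path(dir, "pairs.tsv")),
    pathway_map = read_tsv0(file.path(dir, "pathway_map.tsv")),
    pathway_events = read_tsv0(file.path(dir, "pathway_events.tsv")),
    truth = list(
      loss_clades = unname(split(truth_clades$species_id,
                                 truth_clades$clade_id)),
      assoc_family_ids = pick("assoc_family"),
      overlap_family_ids = pick("overlap_family"),
      retargeted_pair_ids = pick("retargeted_pair"),
      altered_pathway_ids = pick("altered_pathway"))
  )
}
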