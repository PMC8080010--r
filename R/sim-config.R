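#' Configuration for the synthetic complex I loss dataset
#'
#' Bundles and validates all knobs of the synthetic-data generator. The
#' defaults define the study conditions the package is exercised under: a
#' 40-species tree carrying 6 independent CI loss events (the scale at which
#' clade-median copy-number comparisons have resolving power), 3 focal
#' CI-absent species for the event/selection/retargeting/pathway stages, and
#' effect sizes corresponding to clear biological signal (a +4 mean shift in
#' orthologue copy number for associated families, a 0.6 mitochondrial
#' probability gain for retargeted proteins).
#'
#' @param seed Integer global seed; all stages derive their own stream from
#'   it (see [stage seeds in the vignette][simulate_ci_dataset]).
#' @param n_species Number of species (tips) in the simulated tree.
#' @param n_loss_events Number of planted independent CI loss clades.
#' @param n_genomes_per_species Mitochondrial genome assemblies per species.
#' @param n_families Number of gene families in the orthologue count matrix.
#' @param n_planted_assoc_families Families whose copy number is shifted in
#'   CI-absent clades (targets of the KS association stage).
#' @param n_planted_overlap_families Families planted as positively selected
#'   in every focal CI-absent species (targets of the overlap test).
#' @param n_pathways Number of simulated pathways.
#' @param n_planted_pathways Pathways planted with convergent D/PS/MR
#'   alterations in the focal species.
#' @param n_retargeted_pairs,n_background_pairs Orthologue pairs with and
#'   without planted mitochondrial retargeting.
#' @param p_misannotation Per-subunit probability of corrupting the
#'   annotation/coverage evidence of a genome record.
#' @param p_incomplete Per-genome probability of emitting an incomplete
#'   assembly (fewer than 3 CDS annotations).
#' @param count_shift Added Poisson mean for planted associated families in
#'   CI-absent clades (baseline mean is 2).
#' @param mr_delta Planted gain in mitochondrial probability of retargeted
#'   proteins over their best sister (must exceed the 0.2 call threshold to
#'   be recoverable).
#'
#' @return An object of class `ciloss_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 42, n_species = 20, n_loss_events = 3)
#' cfg$n_loss_events
#' @export
sim_config <- function(seed = 1L,
                       n_species = 40L,
                       n_loss_events = 6L,
                       n_genomes_per_species = 3L,
                       n_families = 60L,
                       n_planted_assoc_families = 6L,
                       n_planted_overlap_families = 8L,
                       n_pathways = 20L,
                       n_planted_pathways = 3L,
                       n_retargeted_pairs = 10L,
                       n_background_pairs = 10L,
                       p_misannotation = 0.01,
                       p_incomplete = 0.05,
                       count_shift = 4,
                       mr_delta = 0.6) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0L),
    n_species = check_count(n_species, "n_species", min = 4L),
    n_loss_events = check_count(n_loss_events, "n_loss_events", min = 0L),
    n_genomes_per_species = check_count(n_genomes_per_species,
                                        "n_genomes_per_species"),
    n_families = check_count(n_families, "n_families"),
    n_planted_assoc_families = check_count(n_planted_assoc_families,
                                           "n_planted_assoc_families", 0L),
    n_planted_overlap_families = check_count(n_planted_overlap_families,
                                             "n_planted_overlap_families", 0L),
    n_pathways = check_count(n_pathways, "n_pathways", min = 2L),
    n_planted_pathways = check_count(n_planted_pathways,
                                     "n_planted_pathways", 0L),
    n_retargeted_pairs = check_count(n_retargeted_pairs,
                                     "n_retargeted_pairs", 0L),
    n_background_pairs = check_count(n_background_pairs,
                                     "n_background_pairs", 0L),
    p_misannotation = check_prob(p_misannotation, "p_misannotation"),
    p_incomplete = check_prob(p_incomplete, "p_incomplete"),
    count_shift = count_shift,
    mr_delta = mr_delta
  )
  if (!is.numeric(count_shift) || length(count_shift) != 1L || count_shift < 0)
    stop_field("count_shift", "must be a single non-negative number")
  if (!is.numeric(mr_delta) || length(mr_delta) != 1L)
    stop_field("mr_delta", "must be a single number")
  if (cfg$n_retargeted_pairs > 0L && mr_delta <= 0)
    stop_field("mr_delta",
               "must be > 0 when retargeted pairs are requested")
  if (cfg$n_loss_events >= cfg$n_species)
    stop_field("n_loss_events", "must be smaller than n_species")
  if (cfg$n_planted_assoc_families + cfg$n_planted_overlap_families >
      cfg$n_families)
    stop_field("n_planted_assoc_families",
               "planted family counts exceed n_families")
  if (cfg$n_planted_pathways > cfg$n_pathways)
    stop_field("n_planted_pathways", "exceeds n_pathways")
  class(cfg) <- "ciloss_config"
  cfg
}

#' @export
print.ciloss_config <- function(x, ...) {
  cat("Synthetic CI-loss dataset configuration\n")
  cat(sprintf("  %d species, %d planted loss events, seed %d\n",
              x$n_species, x$n_loss_events, x$seed))
  cat(sprintf("  %d families (%d assoc, %d PS-overlap), %d pathways (%d planted)\n",
              x$n_families, x$n_planted_assoc_families,
              x$n_planted_overlap_families, x$n_pathways,
              x$n_planted_pathways))
  cat(sprintf("  noise: misannotation %.3f, incomplete %.3f; effects: shift +%g, MR delta %g\n",
              x$p_misannotation, x$p_incomplete, x$count_shift, x$mr_delta))
  invisible(x)
}
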