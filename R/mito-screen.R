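# Complex I presence/absence calling from mitochondrial genome annotations.
#
# Rule set: a subunit counts as present when it is annotated or a homology
# prediction covers at least 50% of its coding region; genomes with fewer
# than 3 CDS annotations are discarded as incomplete; at most 50 genomes per
# species are retained (random subsample); a genome is CI-absent when it
# misses at least 5 of the 7 subunits.

#' Call presence of a single CI subunit from its evidence
#'
#' A subunit is present if it is annotated, or if a homology-based gene
#' prediction covers at least 50% of the protein-coding region (boundary
#' inclusive). Vectorized over evidence rows.
#'
#' @param annotated Logical: subunit annotated in the genome record.
#' @param coverage Numeric in \[0, 1\]: fraction of the coding region covered
#'   by the homology prediction.
#' @return Logical vector of presence calls.
#' @examples
#' call_subunit_presence(FALSE, 0.50)  # TRUE: boundary is inclusive
#' call_subunit_presence(FALSE, 0.49)  # FALSE
#' @export
call_subunit_presence <- function(annotated, coverage) {
  if (!is.logical(annotated) || anyNA(annotated))
    stop("`annotated` must be logical without NAs", call. = FALSE)
  if (!is.numeric(coverage) || anyNA(coverage) ||
      any(coverage < 0 | coverage > 1))
    stop("`coverage` must be in [0, 1]", call. = FALSE)
  annotated | coverage >= 0.5
}

#' Filter incomplete genomes and subsample large species
#'
#' Removes genomes with fewer than 3 CDS annotations (incomplete assemblies)
#' and, per species, retains at most `max_per_species` genomes, subsampled
#' uniformly at random under `seed` when more are available. Applying the
#' filter twice with the same seed is a no-op.
#'
#' @param genomes Long data.frame with columns genome_id, species_id, n_cds,
#'   subunit, annotated, coverage (7 rows per genome, as written by
#'   [simulate_mito_dataset()]).
#' @param max_per_species Maximum genomes retained per species (default 50).
#' @param seed Integer seed for the subsampling.
#' @return The filtered data.frame (same columns).
#' @export
filter_genomes <- function(genomes, max_per_species = 50L, seed = 1L) {
  if (nrow(genomes) == 0L) return(genomes)
  ginfo <- unique(genomes[, c("genome_id", "species_id", "n_cds")])
  keep <- ginfo$genome_id[ginfo$n_cds >= 3L]
  ginfo <- ginfo[ginfo$genome_id %in% keep, , drop = FALSE]
  with_seed(stage_seed(seed, "genome_subsample"), {
    retained <- unlist(lapply(split(ginfo$genome_id, ginfo$species_id),
                              function(g) {
      g <- sort(g)  # seed-reproducible regardless of input row order
      if (length(g) > max_per_species) sample(g, max_per_species) else g
    }), use.names = FALSE)
    out <- genomes[genomes$genome_id %in% retained, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Per-genome summary: number of missing subunits and genome-level call.
genome_calls <- function(genomes) {
  present <- call_subunit_presence(genomes$annotated, genomes$coverage)
  miss <- tapply(!present, genomes$genome_id, sum)
  sp <- genomes$species_id[match(names(miss), genomes$genome_id)]
  n_sub <- tapply(present, genomes$genome_id, length)
  if (any(n_sub != 7L))
    stop("each genome must carry exactly 7 subunit evidence rows",
         call. = FALSE)
  data.frame(genome_id = names(miss), species_id = sp,
             n_missing = as.integer(miss),
             call = ifelse(miss >= 5L, "absent", "present"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call species-level complex I status
#'
#' Counts missing subunits per genome via [call_subunit_presence()] and
#' aggregates to species level: `absent` when every retained genome misses
#' at least 5 of the 7 subunits, `present` when every genome misses at most
#' 2, and `conflicting` when genomes disagree (such species are excluded
#' from downstream monophyly analyses, mirroring the manual-curation step a
#' screen of public assemblies requires). Genomes missing 3-4 subunits are
#' counted as CI-present (the >= 5/7 rule is one-sided) but trigger a
#' warning.
#'
#' @param genomes A filtered genome data.frame (see [filter_genomes()]).
#' @param all_species Optional character vector of species to report;
#'   species with no retained genome get status `no_data`.
#' @return data.frame with species_id, status, n_missing_subunits (median
#'   across retained genomes), genomes_used.
#' @examples
#' g <- data.frame(genome_id = "g1", species_id = "spA", n_cds = 10,
#'                 subunit = CI_SUBUNITS,
#'                 annotated = c(TRUE, TRUE, rep(FALSE, 5)),
#'                 coverage = 0)
#' call_ci_status(g)$status  # "absent": 5 of 7 subunits missing
#' @export
call_ci_status <- function(genomes, all_species = NULL) {
  gc <- if (nrow(genomes)) genome_calls(genomes) else
    data.frame(genome_id = character(0), species_id = character(0),
               n_missing = integer(0), call = character(0))
  if (any(gc$n_missing %in% 3:4))
    warning(sprintf("%d genome(s) miss 3-4 subunits; treated as CI-present",
                    sum(gc$n_missing %in% 3:4)), call. = FALSE)
  sp_split <- split(gc, gc$species_id)
  res <- do.call(rbind, lapply(sp_split, function(d) {
    status <- if (all(d$call == "absent")) "absent"
              else if (all(d$call == "present")) "present"
              else "conflicting"
    data.frame(species_id = d$species_id[1L], status = status,
               n_missing_subunits = median(d$n_missing),
               genomes_used = nrow(d), stringsAsFactors = FALSE)
  }))
  if (!is.null(all_species)) {
    missing <- setdiff(all_species, gc$species_id)
    if (length(missing))
      res <- rbind(res, data.frame(species_id = missing, status = "no_data",
                                   n_missing_subunits = NA_real_,
                                   genomes_used = 0L,
                                   stringsAsFactors = FALSE))
    res <- res[match(all_species, res$species_id), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Histogram of present-subunit counts across genomes
#'
#' Tabulates, over all genomes in the input, how many of the 7 subunits are
#' present. On real mitochondrial data this distribution is strongly
#' bimodal (modes at 0-2 and 6-7), which motivates the >= 5/7 missing rule
#' for calling complex I loss.
#'
#' @param genomes Genome data.frame (filtered or not).
#' @return Named integer vector with names "0".."7"; entries sum to the
#'   number of genomes.
#' @export
subunit_count_histogram <- function(genomes) {
  h <- setNames(integer(8L), as.character(0:7))
  if (nrow(genomes) == 0L) return(h)
  gc <- genome_calls(genomes)
  tab <- table(factor(7L - gc$n_missing, levels = 0:7))
  h[] <- as.integer(tab)
  h
}
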