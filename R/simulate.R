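# Synthetic dataset generator with planted truth. Every downstream stage of
# the pipeline (CI screen, loss mapping, KS association, PS overlap,
# retargeting, pathway scoring) can be run against these data and its calls
# compared with the truth emitted alongside.

#' Simulate a rooted species tree with planted complex I losses
#'
#' Draws a random rooted binary tree, selects `n_loss_events` pairwise
#' disjoint clades (tips or small internal clades) and flips all their tips
#' to CI-absent. Genus labels are assigned so that roughly half of the
#' planted events span several genera (ancient-style losses) while the rest
#' sit inside a single genus that also contains a CI-present species
#' (recent-style losses). Supergroup labels partition the tips by the root's
#' child subtrees.
#'
#' @param config A [sim_config()] object.
#' @return A list with `tree` (an [ape::rtree()] phylo object), `states`
#'   (data.frame with species_id, status, genus, supergroup) and `truth`
#'   (list with `loss_clades`, a list of tip-label vectors, and
#'   `planted_recency`).
#' @examples
#' sim <- simulate_species_tree(sim_config(seed = 1, n_species = 12,
#'                                         n_loss_events = 2))
#' lengths(sim$truth$loss_clades)
#' @export
simulate_species_tree <- function(config) {
  stopifnot(inherits(config, "ciloss_config"))
  with_seed(stage_seed(config$seed, "tree"), {
    n <- config$n_species
    tree <- ape::rtree(n, tip.label = sprintf("sp%03d", seq_len(n)))
    tips <- tree$tip.label

    sets <- clade_tip_sets(tree)
    root <- ape::Ntip(tree) + 1L
    cand <- setdiff(which(lengths(sets) <= 4L), root)
    cand <- cand[sample.int(length(cand))]

    n_anc <- config$n_loss_events %/% 2L
    n_rec <- config$n_loss_events - n_anc
    budget <- n %/% 2L  # keep a CI+ majority
    par <- node_parents(tree)
    chosen <- integer(0)
    recency <- character(0)
    used <- integer(0)
    reserved <- integer(0)  # tips pinned CI+ so planted clades stay maximal
    pick <- function(node) {
      s <- sets[[node]]
      if (length(intersect(s, c(used, reserved))) ||
          length(used) + length(s) > budget) return(FALSE)
      # the parent clade must keep a CI+ tip, or the event would merge
      # with a neighbouring planted clade instead of being independent
      length(setdiff(sets[[par[node]]], c(s, used))) > 0L
    }
    take <- function(node) {
      used <<- c(used, sets[[node]])
      guard <- setdiff(sets[[par[node]]], c(sets[[node]], used))
      reserved <<- c(reserved, guard[1L])
    }
    for (node in cand) {  # ancient-style first: need clades of >= 2 tips
      if (length(recency[recency == "ancient"]) >= n_anc) break
      if (length(sets[[node]]) >= 2L && pick(node)) {
        chosen <- c(chosen, node); take(node)
        recency <- c(recency, "ancient")
      }
    }
    for (node in cand) {
      if (length(recency[recency == "recent"]) >= n_rec) break
      if (pick(node)) {
        chosen <- c(chosen, node); take(node)
        recency <- c(recency, "recent")
      }
    }
    if (length(chosen) < config$n_loss_events)
      stop_field("n_loss_events",
                 "exceeds the number of available disjoint clades on this tree")

    status <- setNames(rep("present", n), tips)
    for (node in chosen) status[sets[[node]]] <- "absent"

    genus <- setNames(rep(NA_character_, n), tips)
    g <- 0L
    for (i in seq_along(chosen)) {
      s <- sets[[chosen[i]]]
      if (recency[i] == "ancient") {
        for (tp in s) { g <- g + 1L; genus[tp] <- sprintf("gen%03d", g) }
      } else {
        g <- g + 1L
        genus[s] <- sprintf("gen%03d", g)
        free <- which(status == "present" & is.na(genus))
        if (length(free))  # CI+ congener makes the loss classifiable as recent
          genus[free[sample.int(length(free), 1L)]] <- sprintf("gen%03d", g)
      }
    }
    left <- which(is.na(genus))
    while (length(left)) {
      g <- g + 1L
      take <- left[seq_len(min(2L, length(left)))]
      genus[take] <- sprintf("gen%03d", g)
      left <- setdiff(left, take)
    }

    groups <- c("fungi", "plants", "protists")
    supergroup <- setNames(rep(groups[1L], n), tips)
    kids <- node_children(tree)[[root]]
    for (i in seq_along(kids))
      supergroup[sets[[kids[i]]]] <- groups[((i - 1L) %% 3L) + 1L]

    ord <- order(chosen)
    list(
      tree = tree,
      states = data.frame(species_id = tips, status = unname(status),
                          genus = unname(genus),
                          supergroup = unname(supergroup),
                          stringsAsFactors = FALSE),
      truth = list(
        loss_clades = lapply(chosen[ord], function(v) tips[sets[[v]]]),
        planted_recency = recency[ord]
      )
    )
  })
}

#' Simulate per-genome mitochondrial CI subunit evidence
#'
#' Emits `n_genomes_per_species` genome records per species. Genomes of
#' CI-present species carry 6-7 of the 7 mitochondrially encoded subunits
#' (each supported by an annotation or by a homology prediction covering at
#' least half of the coding region); genomes of CI-absent species carry 0-2.
#' With probability `p_incomplete` a genome is emitted with fewer than 3 CDS
#' annotations (the screen's incompleteness filter removes it); with
#' probability `p_misannotation` a subunit's evidence is corrupted.
#'
#' @param config A [sim_config()] object.
#' @param tree_sim Output of [simulate_species_tree()]; simulated afresh from
#'   `config` when omitted.
#' @return A list with `genomes` (long data.frame: genome_id, species_id,
#'   n_cds, subunit, annotated, coverage — 7 rows per genome), plus the
#'   `tree`, `states` and `truth` of the underlying tree simulation.
#' @export
simulate_mito_dataset <- function(config, tree_sim = NULL) {
  stopifnot(inherits(config, "ciloss_config"))
  if (is.null(tree_sim)) tree_sim <- simulate_species_tree(config)
  status <- setNames(tree_sim$states$status, tree_sim$states$species_id)
  with_seed(stage_seed(config$seed, "genomes"), {
    rows <- vector("list", length(status) * config$n_genomes_per_species)
    r <- 0L
    for (sp in names(status)) {
      for (j in seq_len(config$n_genomes_per_species)) {
        gid <- sprintf("%s_g%d", sp, j)
        incomplete <- runif(1) < config$p_incomplete
        n_cds <- if (incomplete) sample(0:2, 1L) else sample(8:40, 1L)
        n_present <- if (status[[sp]] == "absent") sample(0:2, 1L)
                     else sample(6:7, 1L)
        present <- CI_SUBUNITS %in% sample(CI_SUBUNITS, n_present)
        annotated <- ifelse(present, runif(7) < 0.8, FALSE)
        coverage <- ifelse(present,
                           ifelse(annotated, runif(7), runif(7, 0.5, 1)),
                           runif(7, 0, 0.49))
        flip <- runif(7) < config$p_misannotation
        annotated[flip] <- !present[flip]       # corrupt the evidence
        coverage[flip & present] <- runif(sum(flip & present), 0, 0.49)
        r <- r + 1L
        rows[[r]] <- data.frame(genome_id = gid, species_id = sp,
                                n_cds = n_cds, subunit = CI_SUBUNITS,
                                annotated = annotated, coverage = coverage,
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    c(list(genomes = out), tree_sim)
  })
}

# One Dirichlet draw over the 9 compartments with a dominant one.
rdirichlet_dom <- function(dominant, conc = 8) {
  alpha <- rep(0.3, length(LOC_COMPARTMENTS))
  alpha[match(dominant, LOC_COMPARTMENTS)] <- conc
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}

#' Simulate gene-family, selection, localization and pathway data
#'
#' Generates all inputs of the family-level stages, with planted truth:
#' orthologue counts whose planted families are Poisson-shifted (by
#' `count_shift`) in CI-absent clades; branch-site LRT p-value tables whose
#' planted families pass BH-FDR in every focal species; localization
#' profiles in which planted pairs exceed all their sisters' mitochondrial
#' probability by exactly `mr_delta` while background pairs stay within 0.1;
#' and a pathway map in which planted pathways carry convergent D/PS/MR
#' events in all focal CI-absent species.
#'
#' The focal species are one representative per planted loss clade (at most
#' three, mirroring a three-species convergence design); each focal species
#' is paired with its phylogenetically closest CI-present tip as sister.
#'
#' @param config A [sim_config()] object.
#' @param tree_sim Output of [simulate_species_tree()]; simulated afresh
#'   when omitted. Must contain at least one planted loss clade.
#' @return A list with `counts` (families x species matrix), `ps_tables`
#'   (species_id, gene_id, family_id, lrt_pvalue), `events` (family_id,
#'   species_id, L, D, PS, MR for the focal species), `profiles`
#'   (localization probability vectors), `pairs` (benchmark pairs with truth
#'   labels), `pathway_map`, `pathway_events`, `focal_species`,
#'   `sister_species`, and `truth`.
#' @export
simulate_family_data <- function(config, tree_sim = NULL) {
  stopifnot(inherits(config, "ciloss_config"))
  if (is.null(tree_sim)) tree_sim <- simulate_species_tree(config)
  states <- tree_sim$states
  if (!any(states$status == "absent") || !any(states$status == "present"))
    stop("tree must contain both CI+ and CI- tips", call. = FALSE)
  if (config$n_retargeted_pairs > 0L && config$mr_delta > 0.7)
    stop_field("mr_delta",
               "must be <= 0.7 so planted probabilities stay below 1")

  with_seed(stage_seed(config$seed, "families"), {
    tree <- tree_sim$tree
    species <- states$species_id
    ci_minus <- species[states$status == "absent"]
    ci_plus <- species[states$status == "present"]
    clades <- tree_sim$truth$loss_clades

    focal <- vapply(clades[seq_len(min(3L, length(clades)))],
                    `[[`, character(1), 1L)
    dmat <- stats::cophenetic(tree)
    sister <- vapply(focal, function(sp) {
      d <- dmat[sp, ci_plus]
      ci_plus[which.min(d)]
    }, character(1))

    fams <- sprintf("F%03d", seq_len(config$n_families))
    assoc <- sort(sample(fams, config$n_planted_assoc_families))
    overlap <- sort(sample(setdiff(fams, assoc),
                           config$n_planted_overlap_families))

    counts <- matrix(rpois(length(fams) * length(species), 2),
                     nrow = length(fams),
                     dimnames = list(fams, species))
    if (length(assoc))
      counts[assoc, ci_minus] <- rpois(length(assoc) * length(ci_minus),
                                       2 + config$count_shift)

    ps_tables <- do.call(rbind, lapply(focal, function(sp) {
      p <- runif(length(fams))
      p[fams %in% overlap] <- runif(sum(fams %in% overlap), 1e-8, 1e-4)
      data.frame(species_id = sp, gene_id = paste0(fams, "_", sp),
                 family_id = fams, lrt_pvalue = p, stringsAsFactors = FALSE)
    }))

    events <- do.call(rbind, lapply(focal, function(sp) {
      tab <- ps_tables[ps_tables$species_id == sp, ]
      ps <- p.adjust(tab$lrt_pvalue, "BH") < 0.05
      data.frame(family_id = fams, species_id = sp,
                 L = counts[, sp] == 0 & counts[, sister[[sp]]] >= 1,
                 D = runif(length(fams)) < 0.05,
                 PS = ps[match(fams, tab$family_id)],
                 MR = runif(length(fams)) < 0.02,
                 stringsAsFactors = FALSE)
    }))
    rownames(events) <- NULL

    ## localization profiles and benchmark pairs
    n_pairs <- config$n_retargeted_pairs + config$n_background_pairs
    prof <- list(); pair_rows <- list()
    for (k in seq_len(n_pairs)) {
      planted <- k <= config$n_retargeted_pairs
      pid <- sprintf("pair%02d", k)
      n_sis <- sample(1:3, 1L)
      sis_sp <- sample(ci_plus, n_sis, replace = TRUE)
      sis <- lapply(seq_len(n_sis), function(i) {
        p <- rdirichlet_dom("cytoplasm")
        while (p[1L] >= 0.3) p <- rdirichlet_dom("cytoplasm")
        p
      })
      max_mito <- max(vapply(sis, `[[`, numeric(1), 1L))
      tgt_mito <- if (planted) max_mito + config$mr_delta
                  else max(0, min(0.98, max_mito + runif(1, -0.1, 0.1)))
      base <- rdirichlet_dom("cytoplasm")
      tgt <- base; tgt[1L] <- 0
      tgt <- tgt / sum(tgt) * (1 - tgt_mito)
      tgt[1L] <- tgt_mito
      ids <- c(paste0(pid, "_t"), paste0(pid, "_s", seq_len(n_sis)))
      sps <- c(sample(focal, 1L), sis_sp)
      mat <- do.call(rbind, c(list(tgt), sis))
      colnames(mat) <- LOC_COMPARTMENTS
      prof[[k]] <- data.frame(protein_id = ids, species_id = sps,
                              mat, membrane = runif(n_sis + 1L),
                              stringsAsFactors = FALSE)
      pair_rows[[k]] <- data.frame(
        pair_id = pid, target_id = ids[1L],
        sister_ids = paste(ids[-1L], collapse = ";"),
        retargeted = planted, stringsAsFactors = FALSE)
    }
    profiles <- do.call(rbind, prof)
    pairs <- do.call(rbind, pair_rows)
    rownames(profiles) <- rownames(pairs) <- NULL

    ## pathway map and gene-level events
    pathways <- sprintf("P%02d", seq_len(config$n_pathways))
    planted_pw <- sort(sample(pathways, config$n_planted_pathways))
    map_rows <- list(); ev_rows <- list(); r <- 0L
    for (pw in pathways) {
      for (e in seq_len(5L)) {
        enz <- sprintf("%s_E%d", pw, e)
        convergent <- pw %in% planted_pw && runif(1) < 0.85
        for (sp in focal) {
          if (runif(1) > 0.9) next  # enzyme unmapped in this species
          r <- r + 1L
          gid <- paste(enz, sp, sep = "_")
          map_rows[[r]] <- data.frame(
            gene_id = gid, species_id = sp, enzyme_id = enz,
            pathway_id = pw,
            identity_class = if (runif(1) < 0.7) "high" else "low",
            stringsAsFactors = FALSE)
          ev <- c(PS = FALSE, MR = FALSE, D = FALSE, L = FALSE)
          if (convergent) {
            ev[sample(c("PS", "MR", "D"), 1L)] <- TRUE
          } else {
            if (runif(1) < 0.05) ev[sample(c("PS", "MR", "D"), 1L)] <- TRUE
            if (runif(1) < 0.03) ev["L"] <- TRUE
          }
          ev_rows[[r]] <- data.frame(gene_id = gid, species_id = sp,
                                     PS = ev[["PS"]], MR = ev[["MR"]],
                                     D = ev[["D"]], L = ev[["L"]],
                                     stringsAsFactors = FALSE)
        }
      }
    }
    pathway_map <- do.call(rbind, map_rows)
    pathway_events <- do.call(rbind, ev_rows)
    rownames(pathway_map) <- rownames(pathway_events) <- NULL

    list(
      counts = counts, ps_tables = ps_tables, events = events,
      profiles = profiles, pairs = pairs,
      pathway_map = pathway_map, pathway_events = pathway_events,
      focal_species = unname(focal), sister_species = sister,
      truth = list(assoc_family_ids = assoc, overlap_family_ids = overlap,
                   retargeted_pair_ids = pairs$pair_id[pairs$retargeted],
                   altered_pathway_ids = planted_pw)
    )
  })
}

#' Simulate the complete synthetic dataset
#'
#' Convenience wrapper running [simulate_species_tree()],
#' [simulate_mito_dataset()] and [simulate_family_data()] under one
#' configuration and merging their planted truths. All randomness derives
#' from `config$seed` through fixed per-stage offsets, so the same
#' configuration reproduces the dataset exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ciloss_sim` with components `config`, `tree`,
#'   `states`, `genomes`, `counts`, `ps_tables`, `events`, `profiles`,
#'   `pairs`, `pathway_map`, `pathway_events`, `focal_species`,
#'   `sister_species` and `truth`.
#' @examples
#' sim <- simulate_ci_dataset(sim_config(seed = 7, n_species = 16,
#'                                       n_loss_events = 3))
#' names(sim$truth)
#' @export
simulate_ci_dataset <- function(config = sim_config()) {
  tree_sim <- simulate_species_tree(config)
  mito <- simulate_mito_dataset(config, tree_sim)
  fam <- simulate_family_data(config, tree_sim)
  out <- list(config = config, tree = tree_sim$tree,
              states = tree_sim$states, genomes = mito$genomes,
              counts = fam$counts, ps_tables = fam$ps_tables,
              events = fam$events, profiles = fam$profiles,
              pairs = fam$pairs, pathway_map = fam$pathway_map,
              pathway_events = fam$pathway_events,
              focal_species = fam$focal_species,
              sister_species = fam$sister_species,
              truth = c(tree_sim$truth, fam$truth))
  class(out) <- "ciloss_sim"
  out
}

#' @export
print.ciloss_sim <- function(x, ...) {
  cat("Synthetic CI-loss dataset\n")
  cat(sprintf("  %d species (%d CI-), %d planted loss clades\n",
              nrow(x$states), sum(x$states$status == "absent"),
              length(x$truth$loss_clades)))
  cat(sprintf("  %d genomes, %d families, %d pathways, %d benchmark pairs\n",
              length(unique(x$genomes$genome_id)), nrow(x$counts),
              length(unique(x$pathway_map$pathway_id)), nrow(x$pairs)))
  invisible(x)
}
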