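# Mapping CI status on a species tree: independent losses are the maximal
# clades monophyletic for CI absence; each such clade represents one loss
# under parsimony with irreversible loss (CI comprises dozens of co-adapted
# subunits, so regain is not modelled).

# Per-node counts of known present/absent descendant tips. Tips with
# unknown/conflicting/no_data status are ignored for monophyly.
state_counts <- function(tree, status) {
  nt <- ape::Ntip(tree)
  n <- nt + tree$Nnode
  npres <- nabs <- integer(n)
  npres[seq_len(nt)] <- as.integer(status == "present")
  nabs[seq_len(nt)] <- as.integer(status == "absent")
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ed))) {
    npres[ed[k, 1L]] <- npres[ed[k, 1L]] + npres[ed[k, 2L]]
    nabs[ed[k, 1L]] <- nabs[ed[k, 1L]] + nabs[ed[k, 2L]]
  }
  list(npres = npres, nabs = nabs)
}

#' Enumerate independent complex I loss events on a species tree
#'
#' Finds the maximal clades whose known-status tips are all CI-absent (and
#' that contain at least one such tip); each is reported as one independent
#' loss event. Tips whose status is not `present`/`absent` (unknown,
#' conflicting, no mitochondrial data) are excluded from the monophyly
#' evaluation rather than breaking clades. Events are pairwise disjoint.
#' Polytomies are allowed; the topology is taken as given.
#'
#' @param tree A rooted `phylo` object.
#' @param states data.frame with columns species_id, status (and optionally
#'   genus, supergroup) covering every tip.
#' @return data.frame with one row per event: event_id, node (ape node id),
#'   n_tips, and a list-column `tips` of CI-absent tip labels.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' st <- data.frame(species_id = c("A", "B", "C", "D"),
#'                  status = c("absent", "present", "absent", "absent"))
#' find_independent_losses(tr, st)$n_tips  # one singleton, one cherry
#' @export
find_independent_losses <- function(tree, states) {
  st <- match_states(tree, states)
  status <- st$status
  if (!any(status %in% c("present", "absent")))
    stop("all tips have unknown CI status", call. = FALSE)
  cnt <- state_counts(tree, status)
  all_absent <- cnt$npres == 0L & cnt$nabs >= 1L
  par <- node_parents(tree)
  maximal <- which(all_absent &
                   (is.na(par) | !all_absent[ifelse(is.na(par), 1L, par)]))
  sets <- clade_tip_sets(tree)
  maximal <- maximal[order(maximal)]
  tips <- lapply(maximal, function(v) {
    labs <- tree$tip.label[sets[[v]]]
    labs[status[match(labs, tree$tip.label)] == "absent"]
  })
  data.frame(event_id = sprintf("loss%02d", seq_along(maximal)),
             node = maximal, n_tips = lengths(tips),
             tips = I(tips), stringsAsFactors = FALSE)
}

#' Classify loss events as recent or ancient
#'
#' A loss spanning species of two or more genera is `ancient`. A loss whose
#' species all belong to one genus is `recent` when that genus contains at
#' least one CI-present species elsewhere in the tree (the loss happened
#' after the genus diversified); when no CI-present congener exists the
#' recency cannot be confirmed from taxonomy alone and the event is
#' labelled `recent_unconfirmed`.
#'
#' @param events Output of [find_independent_losses()].
#' @param states States data.frame with a `genus` column for every species.
#' @return `events` augmented with columns n_genera and recency.
#' @export
classify_recency <- function(events, states) {
  if (!"genus" %in% names(states) || anyNA(states$genus))
    stop("`states` must provide a genus label for every species",
         call. = FALSE)
  genus <- setNames(states$genus, states$species_id)
  res <- lapply(events$tips, function(tp) {
    g <- unique(genus[tp])
    if (length(g) >= 2L) return(list(n = length(g), rec = "ancient"))
    congener <- states$species_id[states$genus == g &
                                  states$status == "present"]
    list(n = 1L,
         rec = if (length(congener)) "recent" else "recent_unconfirmed")
  })
  events$n_genera <- vapply(res, `[[`, integer(1), "n")
  events$recency <- vapply(res, `[[`, character(1), "rec")
  events
}

#' Count loss events per eukaryotic supergroup
#'
#' Assigns each event to the supergroup of its member species (majority
#' vote when tips map to several groups, alphabetical tie-break) and counts
#' events per group. Counts sum to the number of events.
#'
#' @param events Output of [find_independent_losses()].
#' @param groups Named character vector mapping species_id to supergroup.
#' @return Named integer vector of event counts (empty when no events).
#' @export
count_events_per_supergroup <- function(events, groups) {
  if (nrow(events) == 0L) return(setNames(integer(0), character(0)))
  gr <- vapply(events$tips, function(tp) {
    g <- groups[tp]
    if (anyNA(g))
      stop("unmapped species: ", paste(tp[is.na(g)], collapse = ", "),
           call. = FALSE)
    tab <- sort(table(g), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  tab <- table(gr)
  setNames(as.integer(tab), names(tab))
}

#' Maximal clades monophyletic for CI presence or absence
#'
#' Returns the maximal clades (possibly single tips) whose known-status
#' tips are uniformly CI-present or uniformly CI-absent. These are the
#' ancestral nodes over which clade-median orthologue counts are computed
#' in the copy-number association stage.
#'
#' @inheritParams find_independent_losses
#' @return A list with `node_tips` (named list: node id to member species
#'   with known status) and `node_states` (named character: "present" or
#'   "absent" per node).
#' @export
max_uniform_clades <- function(tree, states) {
  st <- match_states(tree, states)
  status <- st$status
  if (!any(status %in% c("present", "absent")))
    stop("all tips have unknown CI status", call. = FALSE)
  cnt <- state_counts(tree, status)
  par <- node_parents(tree)
  sets <- clade_tip_sets(tree)
  out_tips <- list(); out_states <- character(0)
  for (state in c("present", "absent")) {
    own <- if (state == "present") cnt$npres else cnt$nabs
    other <- if (state == "present") cnt$nabs else cnt$npres
    uni <- own >= 1L & other == 0L
    maximal <- which(uni & (is.na(par) | !uni[ifelse(is.na(par), 1L, par)]))
    for (v in sort(maximal)) {
      labs <- tree$tip.label[sets[[v]]]
      labs <- labs[status[match(labs, tree$tip.label)] == state]
      out_tips[[as.character(v)]] <- labs
      out_states <- c(out_states, setNames(state, as.character(v)))
    }
  }
  list(node_tips = out_tips, node_states = out_states)
}
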