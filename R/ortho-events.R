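# Per-family evolutionary events (duplication, loss) and the clade-median
# Kolmogorov-Smirnov association between orthologue copy number and CI
# status.

#' Detect duplication nodes in a gene tree by species overlap
#'
#' A gene-tree node is called a duplication when the species sets of its
#' child subtrees intersect (the species-overlap criterion). A species is
#' flagged as duplicated (`D`) when at least two of its genes descend from
#' some duplication node.
#'
#' @param gene_tree Rooted `phylo` whose tip labels encode the species
#'   either as `gene@species` or via `species_map`.
#' @param species_map Optional named character vector mapping tip labels to
#'   species ids; overrides the `gene@species` convention.
#' @return A list with `duplication_nodes` (ape node ids) and `d_flags`
#'   (named logical over all species in the tree).
#' @examples
#' gt <- ape::read.tree(text = "((a1@spX,a2@spX),b@spY);")
#' annotate_duplications(gt)$d_flags
#' @export
annotate_duplications <- function(gene_tree, species_map = NULL) {
  tips <- gene_tree$tip.label
  if (is.null(species_map)) {
    if (!all(grepl("@", tips)))
      stop("tips without species label: ",
           paste(tips[!grepl("@", tips)], collapse = ", "), call. = FALSE)
    species_map <- setNames(sub(".*@", "", tips), tips)
  } else {
    if (!all(tips %in% names(species_map)))
      stop("tips without species label: ",
           paste(setdiff(tips, names(species_map)), collapse = ", "),
           call. = FALSE)
  }
  sp <- unname(species_map[tips])
  nt <- ape::Ntip(gene_tree)
  ch <- node_children(gene_tree)
  sets <- clade_tip_sets(gene_tree)
  internal <- nt + seq_len(gene_tree$Nnode)
  dup <- internal[vapply(internal, function(v) {
    kid_sp <- lapply(ch[[v]], function(k) unique(sp[sets[[k]]]))
    sum(lengths(kid_sp)) > length(unique(unlist(kid_sp)))
  }, logical(1))]
  species <- unique(sp)
  d_flags <- setNames(rep(FALSE, length(species)), species)
  for (v in dup) {
    tab <- table(sp[sets[[v]]])
    d_flags[names(tab)[tab >= 2L]] <- TRUE
  }
  list(duplication_nodes = dup, d_flags = d_flags)
}

#' Flag family loss in a focal species
#'
#' A family counts as lost (`L`) in a focal species when that species has
#' zero orthologues while at least one species of the sister group retains
#' the family; shared absence (all sisters at zero) predates the focal
#' lineage and is not flagged.
#'
#' @param counts Named numeric vector of orthologue counts for one family.
#' @param focal Focal species id.
#' @param sisters Character vector of sister-group species ids (non-empty).
#' @return Logical loss flag.
#' @export
infer_family_loss <- function(counts, focal, sisters) {
  if (length(sisters) == 0L)
    stop("`sisters` must be non-empty", call. = FALSE)
  if (!focal %in% names(counts))
    stop("focal species not in counts: ", focal, call. = FALSE)
  if (!all(sisters %in% names(counts)))
    stop("sister species not in counts: ",
         paste(setdiff(sisters, names(counts)), collapse = ", "),
         call. = FALSE)
  counts[[focal]] == 0 && any(counts[sisters] >= 1)
}

#' Discard families evolving similarly in the CI+ sister group
#'
#' Changes shared between CI-absent species and their close CI-present
#' relatives are not specifically associated with CI loss. A family is
#' discarded when any event type (L, D, PS, MR) flagged in a CI-absent
#' species is also flagged, for the same type, in at least one sister-group
#' species.
#'
#' @param focal_events data.frame (family_id, species_id, L, D, PS, MR) for
#'   the CI-absent focal species.
#' @param sister_events Same shape, for the sister-group CI-present species.
#' @return data.frame (family_id, keep).
#' @export
filter_shared_with_sister <- function(focal_events, sister_events) {
  types <- c("L", "D", "PS", "MR")
  fam <- unique(focal_events$family_id)
  agg <- function(d) {
    out <- lapply(types, function(tp)
      tapply(d[[tp]], d$family_id, any))
    names(out) <- types
    out
  }
  f <- agg(focal_events)
  s <- agg(sister_events)
  keep <- vapply(fam, function(id) {
    !any(vapply(types, function(tp) {
      isTRUE(f[[tp]][[id]]) &&
        id %in% names(s[[tp]]) && isTRUE(s[[tp]][[id]])
    }, logical(1)))
  }, logical(1))
  data.frame(family_id = fam, keep = unname(keep), stringsAsFactors = FALSE)
}

#' Median orthologue counts at CI-uniform ancestral nodes
#'
#' For each ancestral node monophyletic for CI presence or absence (see
#' [max_uniform_clades()]), computes the median orthologue count over its
#' member species, per family. Even-sized medians are the mean of the two
#' central values.
#'
#' @param counts Families x species numeric matrix (dimnames required).
#' @param node_tips Named list: node id to member species.
#' @return Families x nodes matrix of medians.
#' @export
node_medians <- function(counts, node_tips) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  med <- vapply(names(node_tips), function(nd) {
    sp <- intersect(node_tips[[nd]], colnames(counts))
    if (length(sp) == 0L)
      stop("node with zero member species in counts: ", nd, call. = FALSE)
    apply(counts[, sp, drop = FALSE], 1L, median)
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) med <- matrix(med, nrow = 1L,
                                        dimnames = list(rownames(counts),
                                                        names(node_tips)))
  med
}

#' Copy-number association with CI loss (clade-median KS test)
#'
#' For each family, compares the median orthologue counts of the CI-absent
#' ancestral nodes against those of the CI-present nodes with a two-sided
#' two-sample Kolmogorov-Smirnov test (exact p-value whenever the product
#' of the two node counts is at most 10000, asymptotic otherwise).
#' Significance is declared at p < 0.05. The default compares one median
#' per node, as the clade-median design prescribes; `method = "pooled"`
#' instead pools the raw per-species counts of each side.
#'
#' @param counts Families x species matrix of orthologue counts.
#' @param node_tips,node_states Output of [max_uniform_clades()].
#' @param method `"node_median"` (default) or `"pooled"`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame: family_id, statistic (KS D), p_value, significant,
#'   direction of the CI-absent side ("higher"/"lower"/"none").
#' @export
ks_association <- function(counts, node_tips, node_states,
                           method = c("node_median", "pooled"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (!any(node_states == "absent") || !any(node_states == "present"))
    stop("need at least one CI+ and one CI- node", call. = FALSE)
  if (method == "node_median") {
    med <- node_medians(counts, node_tips)
    xs <- med[, names(node_states)[node_states == "absent"], drop = FALSE]
    ys <- med[, names(node_states)[node_states == "present"], drop = FALSE]
  } else {
    sp_abs <- unlist(node_tips[node_states == "absent"], use.names = FALSE)
    sp_pre <- unlist(node_tips[node_states == "present"], use.names = FALSE)
    xs <- counts[, intersect(sp_abs, colnames(counts)), drop = FALSE]
    ys <- counts[, intersect(sp_pre, colnames(counts)), drop = FALSE]
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    x <- as.numeric(xs[i, ]); y <- as.numeric(ys[i, ])
    kt <- suppressWarnings(
      ks.test(x, y, exact = length(x) * length(y) <= 10000))
    dir <- if (median(x) > median(y)) "higher"
           else if (median(x) < median(y)) "lower" else "none"
    data.frame(family_id = rownames(counts)[i],
               statistic = unname(kt$statistic),
               p_value = kt$p.value,
               significant = kt$p.value < alpha,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Ancestral copy number of a clade
#'
#' The ancestral orthologue count of a clade is approximated by the median
#' count across its extant member species.
#'
#' @param counts Named numeric vector (one family) or families x species
#'   matrix.
#' @param clade Character vector of member species (non-empty).
#' @return Median count (vector over families when `counts` is a matrix).
#' @export
ancestral_copy_number <- function(counts, clade) {
  if (length(clade) == 0L) stop("`clade` must be non-empty", call. = FALSE)
  if (is.matrix(counts)) {
    if (!all(clade %in% colnames(counts)))
      stop("clade species missing from counts", call. = FALSE)
    apply(counts[, clade, drop = FALSE], 1L, median)
  } else {
    if (!all(clade %in% names(counts)))
      stop("clade species missing from counts", call. = FALSE)
    median(counts[clade])
  }
}
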