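# Positive-selection calling (BH-FDR over branch-site LRT p-values), the
# cross-species family overlap, and its permutation null: each permutation
# reassigns, per species independently, the same number of PS calls to
# genes uniformly without replacement, and the overlap is recomputed.

#' Call positively selected genes from branch-site LRT p-values
#'
#' Benjamini-Hochberg adjusts the raw likelihood-ratio-test p-values within
#' one species and returns the genes with adjusted p below `alpha`.
#'
#' @param p Named numeric vector of raw p-values in \[0, 1\] (names = gene
#'   ids).
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector of PS gene ids.
#' @examples
#' call_ps(c(g1 = 0.001, g2 = 0.02, g3 = 0.8))  # g1, g2
#' @export
call_ps <- function(p, alpha = 0.05) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  names(p)[p.adjust(p, "BH") < alpha]
}

# Map gene ids to family ids, erroring on unmapped genes.
genes_to_families <- function(genes, gene2family) {
  fam <- gene2family[genes]
  if (anyNA(fam))
    stop("unmapped gene(s): ",
         paste(genes[is.na(fam)], collapse = ", "), call. = FALSE)
  unique(unname(fam))
}

#' Number of families under positive selection in every species
#'
#' A family is PS in a species when at least one of its member genes is
#' called PS there; the overlap is the number of families PS in all
#' species simultaneously.
#'
#' @param calls Named list (one element per species, at least two) of PS
#'   gene-id vectors.
#' @param gene2family Named character vector mapping gene ids to family ids.
#' @return Integer overlap count.
#' @export
observed_overlap <- function(calls, gene2family) {
  if (length(calls) < 2L)
    stop("need PS calls for at least two species", call. = FALSE)
  fams <- lapply(calls, genes_to_families, gene2family = gene2family)
  length(Reduce(intersect, fams))
}

#' One random reassignment of PS calls
#'
#' Draws, for each species independently, `n_calls` genes uniformly without
#' replacement from that species' tested genes. Used internally by
#' [permutation_pvalue()]; exported so the conservation of per-species call
#' totals can be verified directly.
#'
#' @param tested Named list of tested gene-id vectors per species.
#' @param n_calls Named integer vector of PS call totals per species.
#' @return Named list of resampled PS gene-id vectors.
#' @export
permute_ps_calls <- function(tested, n_calls) {
  stopifnot(all(names(n_calls) %in% names(tested)))
  out <- lapply(names(n_calls), function(sp) {
    if (n_calls[[sp]] > length(tested[[sp]]))
      stop("PS total exceeds number of tested genes for ", sp,
           call. = FALSE)
    tested[[sp]][sample.int(length(tested[[sp]]), n_calls[[sp]])]
  })
  names(out) <- names(n_calls)
  out
}

#' Permutation p-value for the cross-species PS overlap
#'
#' Models the null hypothesis that the observed overlap of positively
#' selected families across species is explained by chance: each of
#' `n_perm` draws randomly reassigns the per-species PS calls to genes
#' (keeping the total number of calls per species) and recomputes the
#' overlap. The p-value is the add-one estimate
#' `(#\{draws >= observed\} + 1) / (n_perm + 1)`, which never reports
#' exactly zero. With `unit = "family"` the reassignment operates on
#' families instead of genes (one call per family).
#'
#' @param tested Named list of tested gene-id vectors per species.
#' @param calls Named list of observed PS gene-id vectors per species
#'   (subset of `tested`).
#' @param gene2family Named character vector mapping gene ids to families.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param unit `"gene"` (default) or `"family"`.
#' @return Object of class `ci_overlap_perm`: list with observed_overlap,
#'   p_value, null (integer vector of permuted overlaps), n_permutations,
#'   seed, unit.
#' @export
permutation_pvalue <- function(tested, calls, gene2family,
                               n_perm = 10000L, seed = 1L,
                               unit = c("gene", "family")) {
  unit <- match.arg(unit)
  stopifnot(identical(sort(names(tested)), sort(names(calls))))
  for (sp in names(calls))
    if (!all(calls[[sp]] %in% tested[[sp]]))
      stop("PS calls not among tested genes for ", sp, call. = FALSE)
  obs <- observed_overlap(calls, gene2family)
  if (unit == "family") {
    tested_u <- lapply(tested, genes_to_families, gene2family = gene2family)
    calls_u <- lapply(calls, genes_to_families, gene2family = gene2family)
    fam_map <- setNames(unique(unname(gene2family)),
                        unique(unname(gene2family)))
  } else {
    tested_u <- tested
    calls_u <- calls
    fam_map <- gene2family
  }
  n_calls <- setNames(lengths(calls_u), names(calls_u))
  null <- integer(n_perm)
  with_seed(stage_seed(seed, "ps_permutation"), {
    for (b in seq_len(n_perm)) {
      draw <- permute_ps_calls(tested_u, n_calls)
      fams <- lapply(draw, genes_to_families, gene2family = fam_map)
      null[b] <- length(Reduce(intersect, fams))
    }
  })
  structure(list(observed_overlap = obs,
                 p_value = (sum(null >= obs) + 1) / (n_perm + 1),
                 null = null, n_permutations = n_perm,
                 seed = seed, unit = unit),
            class = "ci_overlap_perm")
}

#' @export
print.ci_overlap_perm <- function(x, ...) {
  cat("Cross-species PS overlap permutation test\n")
  cat(sprintf("  observed overlap: %d families\n", x$observed_overlap))
  cat(sprintf("  null: %d draws (unit = %s), mean %.3f, max %d\n",
              x$n_permutations, x$unit, mean(x$null), max(x$null)))
  cat(sprintf("  p-value (add-one): %.4g\n", x$p_value))
  invisible(x)
}
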