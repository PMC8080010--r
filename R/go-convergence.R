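# GO over-representation per CI-absent species and convergent enrichment
# across all losses. A term is convergently associated with CI loss when it
# is enriched (raw p < 0.05) in every focal species ("X" level); when the
# FDR-adjusted p is also below 0.05 everywhere, the call is "XX". Relying
# on raw p-values within species avoids false negatives in small gene
# categories; requiring the enrichment in all species acts as a biological
# correction for the false positives this admits.

#' Ancestor closure of an ontology term graph
#'
#' Computes, for every term, the set of its ancestors (following is_a /
#' part_of edges given as a term-to-parent table) including the term
#' itself. Annotations propagated through this closure make a gene
#' annotated to a term count for all its ancestors, as is standard in GO
#' enrichment.
#'
#' @param parents data.frame with columns term_id, parent_id.
#' @return Named list: term_id to character vector of term + ancestors.
#' @export
term_ancestors <- function(parents) {
  stopifnot(all(c("term_id", "parent_id") %in% names(parents)))
  up <- split(parents$parent_id, parents$term_id)
  terms <- unique(c(parents$term_id, parents$parent_id))
  memo <- new.env(parent = emptyenv())
  anc <- function(t, seen = character(0)) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (t %in% seen) stop("cycle in ontology at term ", t, call. = FALSE)
    res <- t
    for (p in up[[t]]) res <- union(res, anc(p, c(seen, t)))
    memo[[t]] <- res
    res
  }
  setNames(lapply(terms, anc), terms)
}

#' GO term over-representation in a study set
#'
#' One-sided hypergeometric test of over-representation of each term among
#' the study genes relative to the population (background) genes, with
#' Benjamini-Hochberg FDR across terms. Annotations are propagated to
#' ancestor terms when an ancestor closure is supplied.
#'
#' @param study Character vector of study gene ids (non-empty, subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param annotations data.frame with columns gene_id, term_id (and
#'   optionally namespace).
#' @param ancestors Optional output of [term_ancestors()]; when given,
#'   each gene's annotations are extended to all ancestors.
#' @return data.frame: term_id, study_count, pop_count, p_value, fdr (and
#'   namespace when present in `annotations`).
#' @export
go_enrich <- function(study, population, annotations, ancestors = NULL) {
  if (length(study) == 0L) stop("empty study set", call. = FALSE)
  if (!all(study %in% population))
    stop("study genes absent from population: ",
         paste(setdiff(study, population), collapse = ", "), call. = FALSE)
  ann <- annotations[annotations$gene_id %in% population, , drop = FALSE]
  g2t <- split(ann$term_id, ann$gene_id)
  if (!is.null(ancestors))
    g2t <- lapply(g2t, function(ts)
      unique(unlist(lapply(ts, function(t)
        if (t %in% names(ancestors)) ancestors[[t]] else t))))
  t2g <- split(rep(names(g2t), lengths(g2t)), unlist(g2t, use.names = FALSE))
  N <- length(unique(population))
  n <- length(unique(study))
  res <- do.call(rbind, lapply(names(t2g), function(t) {
    genes <- unique(t2g[[t]])
    K <- length(genes)
    k <- length(intersect(genes, study))
    data.frame(term_id = t, study_count = k, pop_count = K,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- p.adjust(res$p_value, "BH")
  if ("namespace" %in% names(annotations))
    res$namespace <- annotations$namespace[match(res$term_id,
                                                 annotations$term_id)]
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Terms convergently enriched in all CI losses
#'
#' Intersects per-species enrichment results: a term reaches level `"X"`
#' when its raw p-value is below `alpha` in every species, and level
#' `"XX"` when its FDR-adjusted p-value is also below `alpha` in every
#' species (so every XX term is also X). Terms absent from any species'
#' result table are excluded.
#'
#' @param results Named list of [go_enrich()] outputs, one per focal
#'   CI-absent species (all species required).
#' @param alpha Significance level (default 0.05).
#' @return data.frame: term_id, level ("X" or "XX").
#' @export
convergent_terms <- function(results, alpha = 0.05) {
  if (length(results) < 1L || is.null(names(results)) ||
      any(!nzchar(names(results))))
    stop("`results` must be a named list with one element per species",
         call. = FALSE)
  if (any(vapply(results, is.null, logical(1))))
    stop("missing enrichment results for: ",
         paste(names(results)[vapply(results, is.null, logical(1))],
               collapse = ", "), call. = FALSE)
  terms <- Reduce(intersect, lapply(results, `[[`, "term_id"))
  rows <- lapply(terms, function(t) {
    p <- vapply(results, function(r) r$p_value[r$term_id == t], numeric(1))
    q <- vapply(results, function(r) r$fdr[r$term_id == t], numeric(1))
    if (all(p < alpha))
      data.frame(term_id = t, level = if (all(q < alpha)) "XX" else "X",
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(0), level = character(0),
                      stringsAsFactors = FALSE)
  out[order(out$term_id), , drop = FALSE]
}
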