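# KEGG-pathway convergence scoring. Six positive parameters control the
# relative weight of the evidence layers:
#   p1, p2  enzyme co-occurrence: any gene under PS/MR/D in exactly two
#           (p1) or all (p2) focal CI-absent species;
#   p3      enzyme uniqueness: enzyme present in all focal species but no
#           sister CI+ species, or vice versa;
#   p4      gene under PS, MR or D (innovation, medium score);
#   p5      gene under loss only (lower score);
#   p6      penalty: gene with no event scores -p6, and each enzyme
#           unmapped in a species adds -p6 to that species' pathway score.
# Gene scores are multiplied by 10 (high-identity KEGG mapping) or 1 (low).
# Since no principled single choice of p1..p6 exists, pathways are scored
# under a 729-point grid and ranked by the mean z-score across grid points
# and species.

#' The six-parameter scoring grid (729 combinations)
#'
#' Each parameter takes three values — the lower bound, midpoint and upper
#' bound of its interval — with dependent bounds evaluated at the chosen
#' value of their parent parameter, in dependency order p5, p4, p6, p3,
#' p1, p2:
#' p5 in \[0.5, 5\]; p4, p6 in \[p5+1, 10\]; p3 in \[p4+5, 50\];
#' p1 in \[p3+10, 100\]; p2 in \[p1+20, 200\]. The Cartesian product gives
#' 3^6 = 729 parameter sets, all satisfying the dependency chain.
#'
#' @return data.frame with 729 rows and columns p1..p6.
#' @examples
#' nrow(parameter_grid())  # 729
#' @export
parameter_grid <- function() {
  vals <- function(lo, hi) c(lo, (lo + hi) / 2, hi)
  rows <- vector("list", 729L)
  r <- 0L
  for (p5 in vals(0.5, 5))
    for (p4 in vals(p5 + 1, 10))
      for (p6 in vals(p5 + 1, 10))
        for (p3 in vals(p4 + 5, 50))
          for (p1 in vals(p3 + 10, 100))
            for (p2 in vals(p1 + 20, 200)) {
              r <- r + 1L
              rows[[r]] <- c(p1 = p1, p2 = p2, p3 = p3,
                             p4 = p4, p5 = p5, p6 = p6)
            }
  as.data.frame(do.call(rbind, rows))
}

#' Score of a single gene
#'
#' Base score: `p4` when the gene is under PS, MR or D (innovation), `p5`
#' when under loss only, `-p6` otherwise; multiplied by 10 for
#' high-identity gene-to-KEGG-orthologue mappings and 1 for low-identity
#' ones. Vectorized over genes.
#'
#' @param ps,mr,d,l Logical event flags.
#' @param identity_class `"high"` or `"low"`.
#' @param params One row of [parameter_grid()] (or any list with p4, p5,
#'   p6).
#' @return Numeric score(s).
#' @examples
#' gene_score(FALSE, FALSE, TRUE, FALSE, "high", list(p4 = 5, p5 = 2, p6 = 2))
#' @export
gene_score <- function(ps, mr, d, l, identity_class, params) {
  base <- ifelse(ps | mr | d, params$p4, ifelse(l, params$p5, -params$p6))
  base * ifelse(identity_class == "high", 10, 1)
}

#' Score of a single enzyme
#'
#' Sum of the co-occurrence scores (`p1` when exactly two focal species
#' have a gene under PS/MR/D at this enzyme, `p2` when all `n_focal` do),
#' the uniqueness score (`p3` when the enzyme's presence/absence is
#' strictly coupled to CI loss) and the global gene score (sum of
#' [gene_score()] over all genes mapping to the enzyme, across species).
#'
#' @param genes data.frame with one row per mapped gene: species_id, PS,
#'   MR, D, L, identity_class. May have zero rows.
#' @param params One row of [parameter_grid()].
#' @param n_focal Number of focal CI-absent species (default 3).
#' @param uniqueness Logical: enzyme gained/lost with CI loss.
#' @return Numeric score.
#' @export
enzyme_score <- function(genes, params, n_focal = 3L, uniqueness = FALSE) {
  co <- 0
  if (nrow(genes)) {
    n_ev <- length(unique(genes$species_id[genes$PS | genes$MR | genes$D]))
    if (n_ev == 2L && n_focal > 2L) co <- params$p1
    if (n_ev >= n_focal) co <- co + params$p2
    gs <- sum(gene_score(genes$PS, genes$MR, genes$D, genes$L,
                         genes$identity_class, params))
  } else gs <- 0
  co + (if (uniqueness) params$p3 else 0) + gs
}

#' Raw pathway score for one species
#'
#' Sum of the scores of the pathway's enzymes, minus `p6` for every enzyme
#' with no gene mapped in the given species. Enzyme scores themselves pool
#' evidence across all focal species (co-occurrence is a cross-species
#' quantity); the species-resolved part of the pathway score is the
#' unmapped-enzyme penalty.
#'
#' @param genes data.frame of the pathway's mapped genes (enzyme_id,
#'   species_id, PS, MR, D, L, identity_class).
#' @param species Species whose pathway score is computed.
#' @param params One row of [parameter_grid()].
#' @param enzymes Character vector of the pathway's enzymes (defaults to
#'   those appearing in `genes`; must be non-empty).
#' @param n_focal Number of focal species (default 3).
#' @param uniqueness Named logical vector per enzyme (default all FALSE).
#' @return Numeric raw score.
#' @export
pathway_raw_score <- function(genes, species, params,
                              enzymes = unique(genes$enzyme_id),
                              n_focal = 3L, uniqueness = NULL) {
  if (length(enzymes) == 0L)
    stop("pathway must contain at least one enzyme", call. = FALSE)
  if (is.null(uniqueness))
    uniqueness <- setNames(rep(FALSE, length(enzymes)), enzymes)
  total <- 0
  for (e in enzymes) {
    ge <- genes[genes$enzyme_id == e, , drop = FALSE]
    total <- total + enzyme_score(ge, params, n_focal = n_focal,
                                  uniqueness = isTRUE(uniqueness[[e]]))
    if (!any(ge$species_id == species)) total <- total - params$p6
  }
  total
}

# Per-pathway score features. The raw score is linear in (p1..p6):
#   raw = p1*C2 + p2*C3 + p3*UQ + p4*A + p5*B - p6*(C + U_s)
# with C2/C3 co-occurrence enzyme counts, UQ unique enzymes, A/B/C the
# identity-weighted gene totals per category and U_s the per-species count
# of unmapped enzymes.
pathway_features <- function(map, events, focal_species, sister_map = NULL) {
  dat <- merge(map, events, by = c("gene_id", "species_id"), all.x = TRUE)
  for (tp in c("PS", "MR", "D", "L")) dat[[tp]][is.na(dat[[tp]])] <- FALSE
  dat <- dat[dat$species_id %in% focal_species, , drop = FALSE]
  n_focal <- length(focal_species)
  pw <- sort(unique(map$pathway_id))
  w <- ifelse(dat$identity_class == "high", 10, 1)
  ev <- dat$PS | dat$MR | dat$D
  lonly <- !ev & dat$L
  none <- !ev & !dat$L

  enz_key <- paste(dat$pathway_id, dat$enzyme_id)
  n_ev_sp <- tapply(ifelse(ev, dat$species_id, NA), enz_key,
                    function(x) length(unique(x[!is.na(x)])))
  enz_pw <- sub(" .*", "", names(n_ev_sp))

  uq <- setNames(rep(0, length(pw)), pw)
  if (!is.null(sister_map)) {
    all_enz <- unique(map[, c("pathway_id", "enzyme_id")])
    for (i in seq_len(nrow(all_enz))) {
      e <- all_enz$enzyme_id[i]
      in_focal <- unique(dat$species_id[dat$enzyme_id == e])
      in_sister <- any(sister_map$enzyme_id == e)
      if ((length(in_focal) == n_focal && !in_sister) ||
          (length(in_focal) == 0L && in_sister))
        uq[[all_enz$pathway_id[i]]] <- uq[[all_enz$pathway_id[i]]] + 1
    }
  }

  f <- function(v, key) {
    s <- tapply(v, key, sum)
    out <- setNames(rep(0, length(pw)), pw)
    out[names(s)] <- s
    out
  }
  A <- f(w * ev, dat$pathway_id)
  B <- f(w * lonly, dat$pathway_id)
  C <- f(w * none, dat$pathway_id)
  c2v <- tapply(n_ev_sp == 2L & n_focal > 2L, enz_pw, sum)
  c3v <- tapply(n_ev_sp >= n_focal, enz_pw, sum)
  C2 <- setNames(rep(0, length(pw)), pw); C2[names(c2v)] <- c2v
  C3 <- setNames(rep(0, length(pw)), pw); C3[names(c3v)] <- c3v

  enz_universe <- unique(map[, c("pathway_id", "enzyme_id")])
  U <- sapply(focal_species, function(sp) {
    mapped <- unique(paste(dat$pathway_id, dat$enzyme_id)[dat$species_id == sp])
    vapply(pw, function(p) {
      all_e <- paste(p, enz_universe$enzyme_id[enz_universe$pathway_id == p])
      sum(!all_e %in% mapped)
    }, numeric(1))
  })
  if (length(pw) == 1L) U <- matrix(U, nrow = 1L,
                                    dimnames = list(pw, focal_species))
  list(pathways = pw, C2 = C2, C3 = C3, UQ = uq, A = A, B = B, C = C, U = U)
}

#' Score and rank pathways under the full parameter grid
#'
#' Computes the raw score of every pathway for each focal species and each
#' of the 729 parameter sets, z-scores the raw scores across pathways
#' (per species and parameter set), averages the z-scores over the grid
#' into a per-species final score, averages across species, and ranks
#' pathways by descending mean final score. Pathways whose raw scores have
#' zero variance across pathways for some (species, parameter set) get
#' z = 0 there, with a warning.
#'
#' @param map data.frame mapping genes to enzymes and pathways: gene_id,
#'   species_id, enzyme_id, pathway_id, identity_class.
#' @param events data.frame of gene-level event flags: gene_id,
#'   species_id, PS, MR, D, L.
#' @param focal_species Character vector of focal CI-absent species.
#' @param params Parameter grid (default [parameter_grid()]).
#' @param sister_map Optional map of sister CI+ species genes, used for the
#'   enzyme-uniqueness score (p3); without it uniqueness is never awarded.
#' @param keep_z Passed to [final_scores()].
#' @return Object of class `ci_pathway_scores`: list with `table`
#'   (pathway_id, final score per species, mean_final, rank), `top10`,
#'   `n_params`, `focal_species`.
#' @export
score_pathways <- function(map, events, focal_species,
                           params = parameter_grid(), sister_map = NULL,
                           keep_z = FALSE) {
  ft <- pathway_features(map, events, focal_species, sister_map)
  if (length(ft$pathways) < 2L)
    stop("z-scores are undefined with fewer than two pathways",
         call. = FALSE)
  pm <- as.matrix(params[, c("p1", "p2", "p3", "p4", "p5", "p6")])
  raw <- lapply(focal_species, function(sp) {
    f_s <- cbind(ft$C2, ft$C3, ft$UQ, ft$A, ft$B, -(ft$C + ft$U[, sp]))
    m <- f_s %*% t(pm)
    rownames(m) <- ft$pathways
    m
  })
  names(raw) <- focal_species
  final_scores(raw, keep_z = keep_z)
}

#' Final z-score aggregation and top-10 ranking
#'
#' Takes per-species matrices of raw pathway scores (pathways x parameter
#' sets), z-scores each column (a species/parameter-set slice across
#' pathways), averages over parameter sets and then across species, and
#' ranks pathways by the resulting mean final score.
#'
#' @param raw Named list (per species) of pathways x parameter-sets
#'   matrices with identical row names.
#' @param keep_z Keep the per-species z-score matrices in the result
#'   (component `z`), e.g. for auditing the normalization.
#' @return Object of class `ci_pathway_scores` (see [score_pathways()]).
#' @export
final_scores <- function(raw, keep_z = FALSE) {
  stopifnot(is.list(raw), length(raw) >= 1L)
  pw <- rownames(raw[[1L]])
  if (length(pw) < 2L)
    stop("z-scores are undefined with fewer than two pathways",
         call. = FALSE)
  zero_var <- FALSE
  zmats <- lapply(raw, function(m) {
    mu <- colMeans(m)
    s <- apply(m, 2L, sd)
    z <- sweep(m, 2L, mu)
    pos <- s > 0
    z[, pos] <- sweep(z[, pos, drop = FALSE], 2L, s[pos], `/`)
    if (any(!pos)) { z[, !pos] <- 0; zero_var <<- TRUE }
    z
  })
  zfin <- vapply(zmats, rowMeans, numeric(length(pw)))
  if (zero_var)
    warning("zero-variance raw scores for some (species, parameter set); z set to 0",
            call. = FALSE)
  colnames(zfin) <- paste0("final_", names(raw))
  mean_final <- rowMeans(zfin)
  rk <- as.integer(rank(-mean_final, ties.method = "first"))
  tab <- data.frame(pathway_id = pw, zfin, mean_final = mean_final,
                    rank = rk, stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(c(list(table = tab,
                   top10 = head(tab$pathway_id, 10L),
                   n_params = ncol(raw[[1L]]),
                   focal_species = names(raw)),
              if (keep_z) list(z = zmats)),
            class = "ci_pathway_scores")
}

#' @export
print.ci_pathway_scores <- function(x, ...) {
  cat(sprintf("Pathway convergence scores (%d pathways, %d parameter sets, %d species)\n",
              nrow(x$table), x$n_params, length(x$focal_species)))
  cat("Top pathways by mean final z-score:\n")
  print(head(x$table[, c("pathway_id", "mean_final", "rank")], 10L),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.ci_pathway_scores <- function(object, ...) {
  cat(sprintf("%d pathways scored over %d parameter sets for species: %s\n",
              nrow(object$table), object$n_params,
              paste(object$focal_species, collapse = ", ")))
  print(summary(object$table$mean_final))
  invisible(object$table)
}
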