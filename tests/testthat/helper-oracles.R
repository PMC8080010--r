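# Independent oracles used to verify the implementation. Each is written
# from first principles (enumeration / brute force), not by calling the
# code under test.

# Minimum number of present->absent transitions on a rooted tree under
# irreversible loss, by exhaustive enumeration of internal-node states.
# The root hangs from a CI-present stem ancestor, so an absent root costs
# one transition. A present node may not descend from an absent one.
fitch_loss_count_oracle <- function(tree, status) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  par <- rep(NA_integer_, nt + nn)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  tip_state <- status[tree$tip.label] == "absent"  # TRUE = absent
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    node_state <- as.logical(bitwAnd(mask, 2^(0:(nn - 1))))  # TRUE = absent
    state <- c(tip_state, node_state)
    cost <- as.integer(state[nt + 1])  # stem transition if root absent
    ok <- TRUE
    for (v in seq_len(nt + nn)) {
      if (is.na(par[v])) next
      if (state[par[v]] && !state[v]) { ok <- FALSE; break }  # no regain
      if (!state[par[v]] && state[v]) cost <- cost + 1L
    }
    if (ok && cost < best) best <- cost
  }
  best
}

# Exact two-sample two-sided KS tail probability by enumeration of all
# splits of the pooled sample (handles ties).
ks_exact_oracle <- function(x, y) {
  ks_stat <- function(a, b) {
    g <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(g) - ecdf(b)(g)))
  }
  d_obs <- ks_stat(x, y)
  pool <- c(x, y)
  idx <- combn(length(pool), length(x))
  hits <- apply(idx, 2, function(i) ks_stat(pool[i], pool[-i]) >= d_obs - 1e-12)
  mean(hits)
}

# Exact tail probability P(overlap >= obs) for the PS-call reassignment
# null, by enumerating every combination of per-species call sets.
overlap_exact_oracle <- function(tested, n_calls, gene2family, obs) {
  sets <- lapply(names(tested), function(sp) {
    cmb <- combn(tested[[sp]], n_calls[[sp]], simplify = FALSE)
    lapply(cmb, function(g) unique(unname(gene2family[g])))
  })
  grid <- expand.grid(lapply(sets, seq_along))
  hits <- 0L
  for (r in seq_len(nrow(grid))) {
    fams <- lapply(seq_along(sets), function(j) sets[[j]][[grid[r, j]]])
    if (length(Reduce(intersect, fams)) >= obs) hits <- hits + 1L
  }
  hits / nrow(grid)
}

# Hypergeometric over-representation tail by enumerating all study subsets.
hyper_tail_oracle <- function(population, annotated, n_study, k_obs) {
  idx <- combn(length(population), n_study)
  hits <- apply(idx, 2, function(i)
    sum(population[i] %in% annotated) >= k_obs)
  mean(hits)
}

# Species-overlap duplication oracle: plain recursion over the tree,
# independent of the package's postorder bookkeeping.
dup_nodes_oracle <- function(gene_tree) {
  nt <- ape::Ntip(gene_tree)
  sp_of <- function(tips) unique(sub(".*@", "", gene_tree$tip.label[tips]))
  kids <- function(v) gene_tree$edge[gene_tree$edge[, 1] == v, 2]
  tipset <- function(v) {
    if (v <= nt) return(v)
    unlist(lapply(kids(v), tipset))
  }
  internal <- nt + seq_len(gene_tree$Nnode)
  internal[vapply(internal, function(v) {
    ss <- lapply(kids(v), function(k) sp_of(tipset(k)))
    any(duplicated(unlist(ss)))
  }, logical(1))]
}

# Confusion-matrix oracle for the retargeting threshold benchmark.
confusion_oracle <- function(deltas, labels, threshold) {
  pred <- deltas > threshold
  c(tp = sum(pred & labels), fp = sum(pred & !labels),
    fn = sum(!pred & labels), tn = sum(!pred & !labels))
}
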