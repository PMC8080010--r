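# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific seed from the global one so independent stages use
# independent, reproducible random streams. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single probability in [0, 1]")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

# children[[v]] = child node ids of v; nodes numbered as in ape (tips first).
node_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (k in seq_len(nrow(tree$edge)))
    ch[[tree$edge[k, 1L]]] <- c(ch[[tree$edge[k, 1L]]], tree$edge[k, 2L])
  ch
}

# Tip indices descending from each node (tips map to themselves).
clade_tip_sets <- function(tree) {
  nt <- ape::Ntip(tree)
  res <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) res[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ed)))
    res[[ed[k, 1L]]] <- c(res[[ed[k, 1L]]], res[[ed[k, 2L]]])
  res
}

# parent[v] = parent node id, NA for the root.
node_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

match_states <- function(tree, states) {
  if (!is.data.frame(states) || !all(c("species_id", "status") %in% names(states)))
    stop("`states` must be a data.frame with columns species_id and status",
         call. = FALSE)
  idx <- match(tree$tip.label, states$species_id)
  if (anyNA(idx))
    stop("tips missing from `states`: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  states[idx, , drop = FALSE]
}
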