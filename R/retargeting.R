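# Mitochondrial retargeting from subcellular-localization probability
# vectors: a CI-absent gene is called retargeted when its mitochondrial
# probability exceeds that of its sister CI+ orthologues by more than 0.2.

#' Validate and renormalize localization profiles
#'
#' The nine compartment probabilities of each profile must sum to 1 within
#' `tol` (predictor outputs are softmax-like but files may be rounded);
#' rows outside the tolerance are renormalized with a warning. The
#' membrane score lives outside the probability simplex and is left
#' untouched.
#'
#' @param profiles data.frame with the nine [LOC_COMPARTMENTS] columns
#'   (plus any id/membrane columns).
#' @param tol Allowed deviation of the row sum from 1 (default 0.01).
#' @return The validated (possibly renormalized) data.frame.
#' @export
normalize_profiles <- function(profiles, tol = 0.01) {
  miss <- setdiff(LOC_COMPARTMENTS, names(profiles))
  if (length(miss))
    stop("missing compartment columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(profiles[, LOC_COMPARTMENTS])
  if (any(m < 0 | m > 1))
    stop("compartment probabilities must be in [0, 1]", call. = FALSE)
  s <- rowSums(m)
  off <- abs(s - 1) > tol
  if (any(off)) {
    warning(sprintf("%d profile(s) deviate from sum 1 by more than %g; renormalized",
                    sum(off), tol), call. = FALSE)
    profiles[off, LOC_COMPARTMENTS] <- m[off, , drop = FALSE] / s[off]
  }
  profiles
}

#' Mitochondrial retargeting delta
#'
#' Difference between the target protein's mitochondrial probability and
#' that of its sister orthologues. The default (`quantifier = "all"`)
#' compares against the *maximum* sister probability, so a positive delta
#' means the target exceeds every sister — the conservative reading of
#' "greater than any of the sisters". `quantifier = "any"` compares against
#' the minimum instead.
#'
#' @param target Mitochondrial probability of the target protein (scalar in
#'   \[0, 1\]).
#' @param sisters Numeric vector of sister mitochondrial probabilities
#'   (non-empty).
#' @param quantifier `"all"` (default) or `"any"`.
#' @return Delta in \[-1, 1\].
#' @examples
#' mr_delta(0.9, c(0.1, 0.3))  # 0.6
#' @export
mr_delta <- function(target, sisters, quantifier = c("all", "any")) {
  quantifier <- match.arg(quantifier)
  if (length(sisters) == 0L)
    stop("`sisters` must be non-empty", call. = FALSE)
  if (any(c(target, sisters) < 0 | c(target, sisters) > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  ref <- if (quantifier == "all") max(sisters) else min(sisters)
  target - ref
}

#' Call mitochondrial retargeting from a delta
#'
#' Strictly greater-than rule: retargeted iff `delta > threshold`; a delta
#' of exactly 0.2 at the default threshold is *not* a call.
#'
#' @param delta Numeric delta(s) in \[-1, 1\].
#' @param threshold Call threshold (default 0.2).
#' @return Logical vector.
#' @export
call_mr <- function(delta, threshold = 0.2) {
  if (any(delta < -1 | delta > 1))
    stop("`delta` must be in [-1, 1]", call. = FALSE)
  delta > threshold
}

#' Retargeting calls for a table of orthologue pairs
#'
#' Convenience wrapper: looks up mitochondrial probabilities in a profile
#' table and applies [mr_delta()] and [call_mr()] to each target/sisters
#' pair.
#'
#' @param profiles Localization data.frame (see [normalize_profiles()])
#'   with a `protein_id` column.
#' @param pairs data.frame with columns target_id and sister_ids
#'   (";"-separated protein ids).
#' @param threshold,quantifier Passed to [call_mr()] / [mr_delta()].
#' @return `pairs` augmented with delta and retargeted columns.
#' @export
mr_calls <- function(profiles, pairs, threshold = 0.2,
                     quantifier = c("all", "any")) {
  quantifier <- match.arg(quantifier)
  profiles <- normalize_profiles(profiles)
  mito <- setNames(profiles$mitochondrion, profiles$protein_id)
  pairs$delta <- vapply(seq_len(nrow(pairs)), function(i) {
    sis <- strsplit(pairs$sister_ids[i], ";", fixed = TRUE)[[1L]]
    ids <- c(pairs$target_id[i], sis)
    if (!all(ids %in% names(mito)))
      stop("proteins missing from profiles: ",
           paste(setdiff(ids, names(mito)), collapse = ", "), call. = FALSE)
    mr_delta(mito[[pairs$target_id[i]]], unname(mito[sis]),
             quantifier = quantifier)
  }, numeric(1))
  pairs$retargeted <- call_mr(pairs$delta, threshold)
  pairs
}

#' Benchmark retargeting thresholds on labelled pairs
#'
#' Sweeps a threshold grid over pre-computed deltas of labelled
#' retargeted/not-retargeted pairs, reporting precision = TP/(TP+FP) and
#' sensitivity = TP/(TP+FN) per threshold. The selected threshold is the
#' one maximizing sensitivity among thresholds whose precision reaches
#' `precision_floor` (smallest threshold on ties); when no threshold
#' reaches the floor, `selected` is `NA` with a warning.
#'
#' @param deltas Numeric vector of predicted deltas.
#' @param labels Logical vector of true retargeting labels (at least one
#'   TRUE and one FALSE).
#' @param thresholds Threshold grid (default `seq(0, 0.95, by = 0.05)`).
#' @param precision_floor Minimum acceptable precision (default 0.7).
#' @return List with `table` (threshold, tp, fp, fn, tn, precision,
#'   sensitivity) and `selected`.
#' @export
benchmark_thresholds <- function(deltas, labels,
                                 thresholds = seq(0, 0.95, by = 0.05),
                                 precision_floor = 0.7) {
  stopifnot(length(deltas) == length(labels), is.logical(labels))
  if (!any(labels)) stop("no positive labels", call. = FALSE)
  if (all(labels)) stop("no negative labels", call. = FALSE)
  tab <- do.call(rbind, lapply(thresholds, function(t) {
    pred <- deltas > t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               sensitivity = tp / (tp + fn))
  }))
  ok <- !is.na(tab$precision) & tab$precision >= precision_floor
  selected <- NA_real_
  if (any(ok)) {
    best <- max(tab$sensitivity[ok])
    selected <- min(tab$threshold[ok & tab$sensitivity == best])
  } else {
    warning("no threshold reaches the precision floor", call. = FALSE)
  }
  list(table = tab, selected = selected)
}

#' Main subcellular localization(s) of a gene family
#'
#' Each protein's predicted compartment is the argmax of its nine
#' compartment probabilities (ties broken by the fixed [LOC_COMPARTMENTS]
#' order, mitochondrion first). The family's main localizations are the
#' compartments predicted for at least 50% of its proteins (inclusive; the
#' set may be empty or, at exactly 50/50, contain two compartments).
#'
#' @param profiles Localization data.frame (one row per protein).
#' @return Character vector of compartments (possibly empty).
#' @export
family_main_localization <- function(profiles) {
  if (nrow(profiles) == 0L)
    stop("need at least one profile", call. = FALSE)
  profiles <- normalize_profiles(profiles)
  m <- as.matrix(profiles[, LOC_COMPARTMENTS])
  pred <- LOC_COMPARTMENTS[apply(m, 1L, which.max)]
  frac <- table(factor(pred, levels = LOC_COMPARTMENTS)) / nrow(profiles)
  names(frac)[frac >= 0.5]
}
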