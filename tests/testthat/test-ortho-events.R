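# Family event flags and the clade-median KS association.

test_that("species-overlap duplication detection matches hand cases", {
  gt <- ape::read.tree(text = "((a1@spX,a2@spX),b@spY);")
  res <- annotate_duplications(gt)
  expect_length(res$duplication_nodes, 1L)
  expect_identical(res$d_flags, c(spX = TRUE, spY = FALSE))

  one_per_species <- ape::read.tree(text = "((a@spX,b@spY),c@spZ);")
  expect_length(annotate_duplications(one_per_species)$duplication_nodes, 0L)

  root_dup <- ape::read.tree(text = "((a@spX,b@spY),(c@spX,d@spY));")
  res <- annotate_duplications(root_dup)
  nt <- ape::Ntip(root_dup)
  expect_identical(res$duplication_nodes, nt + 1L)  # the root
  expect_identical(res$d_flags, c(spX = TRUE, spY = TRUE))

  unlabelled <- ape::read.tree(text = "((a,b@spY),c@spZ);")
  expect_error(annotate_duplications(unlabelled), "species label")
})

test_that("duplication calls agree with a recursive oracle on random trees", {
  set.seed(42)
  for (i in 1:25) {
    gt <- ape::rtree(8)
    gt$tip.label <- sprintf("g%d@sp%s", 1:8,
                            sample(c("A", "B", "C"), 8, replace = TRUE))
    expect_identical(annotate_duplications(gt)$duplication_nodes,
                     sort(dup_nodes_oracle(gt)))
  }
})

test_that("family loss requires a retaining sister", {
  counts <- c(focal = 0, s1 = 1, s2 = 2)
  expect_true(infer_family_loss(counts, "focal", c("s1", "s2")))
  expect_false(infer_family_loss(c(focal = 1, s1 = 1), "focal", "s1"))
  expect_false(infer_family_loss(c(focal = 0, s1 = 0, s2 = 0),
                                 "focal", c("s1", "s2")))
  expect_error(infer_family_loss(counts, "missing", "s1"), "missing")
  expect_error(infer_family_loss(counts, "focal", character(0)),
               "non-empty")
})

test_that("sister-shared events are discarded per event type", {
  focal <- data.frame(family_id = c("F1", "F2", "F3"),
                      species_id = "ciA",
                      L = c(FALSE, FALSE, TRUE),
                      D = c(TRUE, TRUE, FALSE),
                      PS = FALSE, MR = FALSE)
  sister <- data.frame(family_id = c("F1", "F3"), species_id = "sisB",
                       L = FALSE, D = c(TRUE, TRUE),
                       PS = FALSE, MR = FALSE)
  keep <- filter_shared_with_sister(focal, sister)
  expect_identical(keep$keep[keep$family_id == "F1"], FALSE) # D vs D
  expect_identical(keep$keep[keep$family_id == "F2"], TRUE)  # D only focal
  expect_identical(keep$keep[keep$family_id == "F3"], TRUE)  # L vs D
})

test_that("node medians use the mean-of-central-values convention", {
  counts <- matrix(c(1, 2, 4, 1, 2, 9), nrow = 2, byrow = TRUE,
                   dimnames = list(c("F1", "F2"), c("s1", "s2", "s3")))
  med <- node_medians(counts, list(n1 = c("s1", "s2", "s3")))
  expect_equal(unname(med[, "n1"]), c(2, 2))
  med2 <- node_medians(counts, list(n1 = c("s1", "s2")))
  expect_equal(unname(med2[, "n1"]), c(1.5, 1.5))
  med3 <- node_medians(counts, list(n1 = "s3"))
  expect_equal(unname(med3[, "n1"]), c(4, 9))
  expect_error(node_medians(counts, list(n1 = "nope")), "zero member")
})

test_that("ancestral copy number is the extant median", {
  expect_equal(ancestral_copy_number(c(a = 2, b = 2, c = 2),
                                     c("a", "b", "c")), 2)
  expect_equal(ancestral_copy_number(c(a = 0, b = 1, c = 5),
                                     c("a", "b", "c")), 1)
  expect_equal(ancestral_copy_number(c(a = 1, b = 3), c("a", "b")), 2)
  expect_error(ancestral_copy_number(c(a = 1), character(0)), "non-empty")
})

test_that("KS association matches exact enumeration and is order-invariant", {
  counts <- matrix(c(0, 0, 0, 0, 3, 3, 3, 3), nrow = 1,
                   dimnames = list("F1", paste0("s", 1:8)))
  nt <- setNames(as.list(paste0("s", 1:8)), paste0("n", 1:8))
  ns <- setNames(rep(c("absent", "present"), each = 4), names(nt))
  res <- ks_association(counts, nt, ns)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(res$p_value, ks_exact_oracle(rep(0, 4), rep(3, 4)),
               tolerance = 1e-12)
  expect_true(res$significant)
  expect_identical(res$direction, "lower")

  # node order must not matter
  perm <- sample(names(nt))
  res2 <- ks_association(counts, nt[perm], ns[perm])
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$statistic, res$statistic)

  # identical samples: D = 0, p = 1
  counts2 <- matrix(rep(2, 8), nrow = 1,
                    dimnames = list("F1", paste0("s", 1:8)))
  res3 <- ks_association(counts2, nt, ns)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  expect_false(res3$significant)
  expect_identical(res3$direction, "none")
})

test_that("exact KS p-values agree with enumeration on mixed ties", {
  x <- c(0, 1, 1)
  y <- c(2, 2, 3, 1)
  counts <- matrix(c(x, y), nrow = 1,
                   dimnames = list("F1", paste0("s", 1:7)))
  nt <- setNames(as.list(paste0("s", 1:7)), paste0("n", 1:7))
  ns <- setNames(c(rep("absent", 3), rep("present", 4)), names(nt))
  res <- ks_association(counts, nt, ns)
  expect_equal(res$p_value, ks_exact_oracle(x, y), tolerance = 1e-10)
})

test_that("a one-sided node set is rejected", {
  counts <- matrix(1:4, nrow = 1, dimnames = list("F1", paste0("s", 1:4)))
  nt <- setNames(as.list(paste0("s", 1:4)), paste0("n", 1:4))
  ns <- setNames(rep("present", 4), names(nt))
  expect_error(ks_association(counts, nt, ns), "CI\\+ and one CI-")
})

test_that("pooled-variant association uses raw per-species counts", {
  ts <- simulate_species_tree(sim_config(seed = 31))
  fam <- simulate_family_data(sim_config(seed = 31), ts)
  nd <- max_uniform_clades(ts$tree, ts$states)
  pooled <- ks_association(fam$counts, nd$node_tips, nd$node_states,
                           method = "pooled")
  expect_identical(nrow(pooled), nrow(fam$counts))
  expect_true(all(pooled$p_value > 0 & pooled$p_value <= 1))
  # pooled power on planted families should also be high
  expect_gt(mean(pooled$significant[pooled$family_id %in%
                                      fam$truth$assoc_family_ids]), 0.5)
})
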