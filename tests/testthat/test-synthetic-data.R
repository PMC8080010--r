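# Synthetic-data generator: determinism, validation, and the planted
# structure every downstream stage relies on.

test_that("identical config reproduces the dataset byte-identically", {
  cfg <- sim_config(seed = 11, n_species = 16, n_loss_events = 3)
  a <- simulate_ci_dataset(cfg)
  b <- simulate_ci_dataset(cfg)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$counts, b$counts)
  expect_identical(a$profiles, b$profiles)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  d <- simulate_ci_dataset(sim_config(seed = 12, n_species = 16,
                                      n_loss_events = 3))
  expect_false(identical(a$counts, d$counts))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_species = 3), "n_species")
  expect_error(sim_config(p_misannotation = 1.2), "p_misannotation")
  expect_error(sim_config(n_species = 10, n_loss_events = 10),
               "n_loss_events")
  expect_error(sim_config(n_families = 10, n_planted_assoc_families = 6,
                          n_planted_overlap_families = 6),
               "n_planted_assoc_families")
  expect_error(sim_config(n_planted_pathways = 30, n_pathways = 20),
               "n_planted_pathways")
  expect_error(sim_config(mr_delta = 0), "mr_delta")
  expect_error(sim_config(mr_delta = -0.3), "mr_delta")
})

test_that("noiseless genomes respect the bimodal subunit-count design", {
  sim <- simulate_mito_dataset(noiseless_config(seed = 3))
  status <- setNames(sim$states$status, sim$states$species_id)
  present <- call_subunit_presence(sim$genomes$annotated,
                                   sim$genomes$coverage)
  n_present <- tapply(present, sim$genomes$genome_id, sum)
  sp <- sim$genomes$species_id[match(names(n_present),
                                     sim$genomes$genome_id)]
  expect_true(all(n_present[status[sp] == "absent"] <= 2))
  expect_true(all(n_present[status[sp] == "present"] >= 6))
  h <- subunit_count_histogram(sim$genomes)
  expect_identical(sum(h), length(unique(sim$genomes$genome_id)))
  expect_identical(unname(h[c("3", "4", "5")]), c(0L, 0L, 0L))
})

test_that("planted loss clades are monophyletic, disjoint and labelled", {
  for (seed in c(2, 9, 23)) {
    ts <- simulate_species_tree(sim_config(seed = seed, n_species = 24,
                                           n_loss_events = 4))
    clades <- ts$truth$loss_clades
    expect_length(clades, 4L)
    # monophyly via an independent oracle
    for (cl in clades)
      expect_true(ape::is.monophyletic(ts$tree, cl))
    all_tips <- unlist(clades)
    expect_false(anyDuplicated(all_tips) > 0)
    st <- setNames(ts$states$status, ts$states$species_id)
    expect_true(all(st[all_tips] == "absent"))
    expect_true(all(st[setdiff(ts$tree$tip.label, all_tips)] == "present"))
  }
})

test_that("a zero-loss tree has all tips CI-present", {
  ts <- simulate_species_tree(sim_config(seed = 5, n_loss_events = 0))
  expect_true(all(ts$states$status == "present"))
  expect_length(ts$truth$loss_clades, 0L)
})

test_that("requesting more losses than the tree can host fails", {
  expect_error(simulate_species_tree(sim_config(seed = 1, n_species = 8,
                                                n_loss_events = 7)),
               "disjoint clades")
})

test_that("dataset round-trips through the plain-text serialization", {
  sim <- simulate_ci_dataset(sim_config(seed = 4, n_species = 12,
                                        n_loss_events = 2))
  dir <- withr::local_tempdir()
  write_ci_dataset(sim, dir)
  back <- read_ci_dataset(dir)
  expect_setequal(back$tree$tip.label, sim$tree$tip.label)
  # tip states survive the Newick + TSV round trip
  st0 <- setNames(sim$states$status, sim$states$species_id)
  st1 <- setNames(back$states$status, back$states$species_id)
  expect_identical(st1[names(st0)], st0)
  expect_equal(back$counts, sim$counts)
  expect_setequal(lapply(back$truth$loss_clades, sort),
                  lapply(sim$truth$loss_clades, sort))
  ev0 <- find_independent_losses(sim$tree, sim$states)
  ev1 <- find_independent_losses(back$tree, back$states)
  expect_setequal(lapply(ev0$tips, sort), lapply(ev1$tips, sort))
})

test_that("every planted id resolves to an emitted record", {
  sim <- simulate_ci_dataset(sim_config(seed = 6, n_species = 18,
                                        n_loss_events = 3))
  expect_true(all(sim$truth$assoc_family_ids %in% rownames(sim$counts)))
  expect_true(all(sim$truth$overlap_family_ids %in%
                    sim$ps_tables$family_id))
  expect_true(all(sim$truth$retargeted_pair_ids %in% sim$pairs$pair_id))
  expect_true(all(sim$truth$altered_pathway_ids %in%
                    sim$pathway_map$pathway_id))
  expect_true(all(unlist(sim$truth$loss_clades) %in% sim$tree$tip.label))
})

test_that("planted retargeted pairs exceed sisters by the configured delta", {
  sim <- simulate_ci_dataset(noiseless_config(seed = 8))
  mc <- mr_calls(sim$profiles, sim$pairs)
  planted <- mc$pair_id %in% sim$truth$retargeted_pair_ids
  expect_equal(mc$delta[planted],
               rep(sim$config$mr_delta, sum(planted)), tolerance = 1e-10)
  expect_true(all(mc$delta[!planted] <= 0.2))
})

test_that("localization vectors are valid probability profiles", {
  sim <- simulate_ci_dataset(sim_config(seed = 10))
  m <- as.matrix(sim$profiles[, LOC_COMPARTMENTS])
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-9)
  expect_silent(normalize_profiles(sim$profiles))
})
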