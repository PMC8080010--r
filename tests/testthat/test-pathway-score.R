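# Six-parameter pathway convergence scoring.

test_that("the grid has 729 combinations satisfying the dependency chain", {
  g <- parameter_grid()
  expect_identical(nrow(g), 729L)
  expect_identical(anyDuplicated(g), 0L)
  expect_true(all(g$p5 >= 0.5 & g$p5 <= 5))
  expect_true(all(g$p4 >= g$p5 + 1 & g$p4 <= 10))
  expect_true(all(g$p6 >= g$p5 + 1 & g$p6 <= 10))
  expect_true(all(g$p3 >= g$p4 + 5 & g$p3 <= 50))
  expect_true(all(g$p1 >= g$p3 + 10 & g$p1 <= 100))
  expect_true(all(g$p2 >= g$p1 + 20 & g$p2 <= 200))
  expect_setequal(unique(g$p5), c(0.5, 2.75, 5))
  expect_identical(parameter_grid(), g)  # deterministic regeneration
})

test_that("gene scores follow the category and identity rules", {
  par <- list(p4 = 5, p5 = 1, p6 = 2)
  expect_equal(gene_score(FALSE, FALSE, TRUE, FALSE, "high", par), 50)
  expect_equal(gene_score(FALSE, FALSE, FALSE, FALSE, "low", par), -2)
  expect_equal(gene_score(FALSE, FALSE, FALSE, TRUE, "low", par), 1)
  # innovation takes precedence over loss when both are flagged
  expect_equal(gene_score(TRUE, FALSE, FALSE, TRUE, "low", par), 5)
  expect_equal(gene_score(c(TRUE, FALSE), c(FALSE, FALSE),
                          c(FALSE, FALSE), c(FALSE, FALSE),
                          c("high", "low"), par), c(50, -2))
})

test_that("enzyme scores add co-occurrence, uniqueness and gene sums", {
  par <- parameter_grid()[1, ]
  genes3 <- data.frame(species_id = c("a", "b", "c"),
                       PS = TRUE, MR = FALSE, D = FALSE, L = FALSE,
                       identity_class = "low")
  expect_equal(enzyme_score(genes3, par), par$p2 + 3 * par$p4)
  genes2 <- genes3[1:2, ]
  expect_equal(enzyme_score(genes2, par), par$p1 + 2 * par$p4)
  none <- transform(genes3, PS = FALSE)
  expect_equal(enzyme_score(none, par), 3 * -par$p6)
  expect_equal(enzyme_score(none, par, uniqueness = TRUE),
               par$p3 + 3 * -par$p6)
  expect_equal(enzyme_score(genes3[0, ], par), 0)
})

test_that("pathway raw scores include per-species unmapped penalties", {
  par <- parameter_grid()[100, ]
  # all enzymes unmapped for the species: -k * p6 on top of enzyme scores
  genes <- data.frame(enzyme_id = character(0), species_id = character(0),
                      PS = logical(0), MR = logical(0), D = logical(0),
                      L = logical(0), identity_class = character(0))
  expect_equal(pathway_raw_score(genes, "a", par,
                                 enzymes = c("e1", "e2", "e3")),
               -3 * par$p6)
  expect_error(pathway_raw_score(genes, "a", par, enzymes = character(0)),
               "at least one")
  one <- data.frame(enzyme_id = "e1", species_id = "a", PS = TRUE,
                    MR = FALSE, D = FALSE, L = FALSE,
                    identity_class = "high")
  expect_equal(pathway_raw_score(one, "a", par),
               enzyme_score(one, par))
  # adding an innovation event to a no-event gene raises the raw score
  lo <- data.frame(enzyme_id = "e1", species_id = "a", PS = FALSE,
                   MR = FALSE, D = FALSE, L = FALSE,
                   identity_class = "low")
  hi <- transform(lo, D = TRUE)
  for (i in c(1, 365, 729)) {
    p <- parameter_grid()[i, ]
    expect_gt(pathway_raw_score(hi, "a", p), pathway_raw_score(lo, "a", p))
  }
})

test_that("vectorized scoring agrees with the per-enzyme route", {
  sim <- simulate_ci_dataset(sim_config(seed = 23, n_pathways = 6,
                                        n_planted_pathways = 2))
  grid <- parameter_grid()[c(1, 300, 729), ]
  dat <- merge(sim$pathway_map, sim$pathway_events,
               by = c("gene_id", "species_id"))
  ft <- ciloss:::pathway_features(sim$pathway_map, sim$pathway_events,
                                  sim$focal_species)
  pm <- as.matrix(grid)
  for (sp in sim$focal_species) {
    f_s <- cbind(ft$C2, ft$C3, ft$UQ, ft$A, ft$B, -(ft$C + ft$U[, sp]))
    fast <- f_s %*% t(pm)
    for (pw in ft$pathways) {
      genes <- dat[dat$pathway_id == pw, ]
      enz <- unique(sim$pathway_map$enzyme_id[
        sim$pathway_map$pathway_id == pw])
      for (j in seq_len(nrow(grid)))
        expect_equal(unname(fast[pw, j]),
                     pathway_raw_score(genes, sp, grid[j, ],
                                       enzymes = enz),
                     tolerance = 1e-9)
    }
  }
})

test_that("z-scores are exactly normalized and shift-invariant", {
  set.seed(3)
  raw <- list(a = matrix(rnorm(40), 8, 5,
                         dimnames = list(paste0("P", 1:8), NULL)),
              b = matrix(rnorm(40), 8, 5,
                         dimnames = list(paste0("P", 1:8), NULL)))
  fs <- final_scores(raw, keep_z = TRUE)
  for (z in fs$z) {
    expect_equal(colMeans(z), rep(0, ncol(z)), tolerance = 1e-9)
    expect_equal(apply(z, 2, sd), rep(1, ncol(z)), tolerance = 1e-9)
  }
  # adding a constant per (species, parameter set) leaves z unchanged
  raw2 <- lapply(raw, function(m) sweep(m, 2, seq_len(ncol(m)) * 10, `+`))
  fs2 <- final_scores(raw2, keep_z = TRUE)
  expect_equal(fs2$z, fs$z, tolerance = 1e-9)
  expect_equal(fs2$table$mean_final, fs$table$mean_final, tolerance = 1e-9)
})

test_that("degenerate inputs are handled: one pathway errors, zero variance warns", {
  raw1 <- list(a = matrix(1, 1, 3, dimnames = list("P1", NULL)))
  expect_error(final_scores(raw1), "fewer than two pathways")
  rawc <- list(a = matrix(5, 3, 2, dimnames = list(paste0("P", 1:3), NULL)))
  expect_warning(fs <- final_scores(rawc), "zero-variance")
  expect_equal(fs$table$mean_final, rep(0, 3))
})

test_that("raw scores are monotone in added innovation flags", {
  sim <- simulate_ci_dataset(sim_config(seed = 29, n_pathways = 5,
                                        n_planted_pathways = 1))
  ev <- sim$pathway_events
  flagless <- which(!(ev$PS | ev$MR | ev$D))[1:5]
  grid <- parameter_grid()
  base <- ciloss:::pathway_features(sim$pathway_map, ev, sim$focal_species)
  pm <- as.matrix(grid)
  raw_of <- function(ft, sp)
    cbind(ft$C2, ft$C3, ft$UQ, ft$A, ft$B, -(ft$C + ft$U[, sp])) %*% t(pm)
  for (i in flagless) {
    ev2 <- ev
    ev2$PS[i] <- TRUE
    ft2 <- ciloss:::pathway_features(sim$pathway_map, ev2,
                                     sim$focal_species)
    for (sp in sim$focal_species)
      expect_true(all(raw_of(ft2, sp) >= raw_of(base, sp) - 1e-9))
  }
})

test_that("planted convergently altered pathways top the ranking", {
  sim <- simulate_ci_dataset(sim_config(seed = 37))
  ps <- score_pathways(sim$pathway_map, sim$pathway_events,
                       sim$focal_species)
  rk <- ps$table$rank[match(sim$truth$altered_pathway_ids,
                            ps$table$pathway_id)]
  expect_true(all(rk <= length(sim$truth$altered_pathway_ids)))
  expect_identical(sort(ps$table$rank), seq_len(nrow(ps$table)))
  expect_length(ps$top10, 10L)
})
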