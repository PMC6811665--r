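test_that("simulation config validates its invariants", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(frac_complete = 0.8, frac_partial = 0.4))
  expect_error(simulation_config(n_compounds = 4, substrate_range = c(1, 3),
                                 product_range = c(1, 3)),
               "exceed n_compounds")
  expect_error(simulation_config(root_repertoire_size = 500, n_reactions = 100),
               "root_repertoire_size")
  expect_error(simulation_config(loss_rate = -1))
})

test_that("generated databases are deterministic and referentially sound", {
  cfg <- simulation_config(n_compounds = 50, n_reactions = 100, seed = 7)
  db1 <- generate_reaction_db(cfg)
  db2 <- generate_reaction_db(cfg)
  expect_identical(db1, db2)
  # every reaction's compounds exist in the compound table
  used <- unique(c(unlist(db1$substrates), unlist(db1$products)))
  expect_true(all(used %in% db1$compounds$compound_id))
  # substrate/product counts within the configured range, sides disjoint
  for (i in seq_len(nrow(db1$reactions))) {
    rid <- db1$reactions$reaction_id[i]
    if (startsWith(rid, "rxn_den")) next
    expect_true(length(db1$substrates[[i]]) %in% 1:3)
    expect_true(length(db1$products[[i]]) %in% 1:3)
    expect_length(intersect(db1$substrates[[i]], db1$products[[i]]), 0)
  }
  # subsystem labels drawn from the 13 categories
  expect_true(all(unlist(db1$subsystems) %in% mo_subsystem_categories))
  # denitrification block present by default
  expect_true(all(paste0("rxn_den", 1:4) %in% db1$reactions$reaction_id))
})

test_that("compound usage matches the uniform sampling design", {
  # with uniform sampling, compound usage counts should have the binomial
  # mean n_draws / n_compounds; check the aggregate over 20 seeds
  n_compounds <- 40
  counts <- numeric(n_compounds)
  total_draws <- 0
  for (seed in 1:20) {
    cfg <- simulation_config(n_compounds = n_compounds, n_reactions = 60,
                             include_denitrification = FALSE, seed = seed)
    db <- generate_reaction_db(cfg)
    used <- c(unlist(db$substrates, use.names = FALSE),
              unlist(db$products, use.names = FALSE))
    counts <- counts + as.numeric(
      table(factor(used, levels = sprintf("cpd%04d", 1:n_compounds))))
    total_draws <- total_draws + length(used)
  }
  expected <- total_draws / n_compounds
  # each compound within 5 sd of the binomial expectation
  sd_bin <- sqrt(total_draws * (1 / n_compounds) * (1 - 1 / n_compounds))
  expect_true(all(abs(counts - expected) < 5 * sd_bin))
})

test_that("random trees are valid, deterministic, and metric", {
  expect_error(generate_tree(1), "n_tips >= 2")
  nwk2 <- generate_tree(2, seed = 4)
  d2 <- cophenetic_matrix(nwk2)
  expect_equal(dim(d2), c(2, 2))
  expect_identical(generate_tree(15, seed = 9), generate_tree(15, seed = 9))
  # triangle inequality over a sample of random trees
  for (seed in 1:10) {
    d <- cophenetic_matrix(generate_tree(8, seed = seed))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
    }
  }
})

test_that("gene gain/loss limits behave as the process dictates", {
  cfg <- simulation_config(n_compounds = 60, n_reactions = 80,
                           root_repertoire_size = 40, seed = 21)
  db <- generate_reaction_db(cfg)
  nwk <- generate_tree(6, seed = 22)
  # no evolution: every tip identical to the root repertoire
  cfg0 <- cfg; cfg0$gain_rate <- 0; cfg0$loss_rate <- 0
  g0 <- evolve_genomes(nwk, db, cfg0, seed = 23)
  expect_length(unique(g0), 1)
  m0 <- overlap_matrix(g0, db)
  expect_true(all(m0[lower.tri(m0)] == m0[2, 1]))
  # determinism
  expect_identical(evolve_genomes(nwk, db, cfg, seed = 24),
                   evolve_genomes(nwk, db, cfg, seed = 24))
  # very large rates: repertoires approach the stationary gain/(gain+loss)
  # occupancy, independent across tips
  cfg_inf <- cfg; cfg_inf$gain_rate <- 50; cfg_inf$loss_rate <- 50
  set.seed(25)
  sizes <- lengths(unclass(evolve_genomes(nwk, db, cfg_inf, seed = NULL)))
  expect_true(all(abs(sizes - 40) < 20))  # stationary p = 0.5 of 80 reactions
})

test_that("default rates plant a negative distance-MO signal", {
  cfg <- simulation_config(n_compounds = 100, n_reactions = 150,
                           root_repertoire_size = 60, n_tips = 12)
  neg <- 0
  for (seed in 1:10) {
    nwk <- generate_tree(cfg$n_tips, seed = 300 + seed)
    g <- evolve_genomes(nwk, db <- generate_reaction_db(cfg, seed = 200 + seed),
                        cfg, seed = 400 + seed)
    m <- overlap_matrix(g, db)
    d <- cophenetic_matrix(nwk)[rownames(m), rownames(m)]
    r <- pairwise_scatter_correlation(d, unclass(m))$r
    if (!is.na(r) && r < 0) neg <- neg + 1
  }
  expect_gte(neg, 9)
})

test_that("metadata synthesis honours its contracts", {
  cfg <- simulation_config(n_compounds = 40, n_reactions = 50,
                           bp_per_reaction = 1e4, size_noise_sd = 0, seed = 31)
  db <- generate_reaction_db(cfg)
  g <- metoverlap:::new_genome_annotations(
    setNames(lapply(c(5, 10, 20), function(k) sample(db$reactions$reaction_id, k)),
             c("a", "b", "c")))
  meta <- generate_metadata(g, cfg, seed = 32)
  expect_equal(meta$genome_size_bp, c(5e4, 1e5, 2e5))
  expect_true(all(meta$completeness_pct >= 50 & meta$completeness_pct < 100))
  expect_identical(generate_metadata(g, cfg, seed = 33),
                   generate_metadata(g, cfg, seed = 33))
})

test_that("one survey call produces a bundle every module can consume", {
  od <- file.path(tempdir(), "survey_fixture")
  unlink(od, recursive = TRUE)
  s <- generate_survey(od, simulation_config(n_compounds = 80, n_reactions = 100,
                                             root_repertoire_size = 50),
                       n_studies = 4, n_tips_range = c(4, 8), seed = 101)
  expect_true(all(file.exists(unlist(s$paths))))
  db <- load_reaction_db(s$paths$reaction_db)
  ann <- load_genome_annotations(s$paths$annotations, db = db)
  meta <- load_genome_metadata(s$paths$metadata)
  comms <- suppressMessages(group_into_communities(ann, meta))
  expect_length(comms, 4)
  summ <- summarize_communities(comms, db)
  expect_true(all(is.finite(summ$normalized_mo)))
  pw <- load_pathway(s$paths$pathway)
  expect_equal(nrow(summarize_denitrifiers(comms, pw, by = "study")), 4)
  # same seed twice: byte-identical files
  od2 <- file.path(tempdir(), "survey_fixture2")
  unlink(od2, recursive = TRUE)
  generate_survey(od2, simulation_config(n_compounds = 80, n_reactions = 100,
                                         root_repertoire_size = 50),
                  n_studies = 4, n_tips_range = c(4, 8), seed = 101)
  for (f in c("reactions.tsv", "annotations.tsv", "metadata.tsv")) {
    expect_identical(readLines(file.path(od, f)), readLines(file.path(od2, f)))
  }
})
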