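test_that("the denitrification worked example gives MO = 2", {
  db <- toy_db(extra = FALSE)
  full <- reactant_profile(c("den1", "den2", "den3", "den4"), db)
  partial <- reactant_profile(c("den2", "den3"), db)
  expect_setequal(full, c("NO3", "NO2", "NO", "N2O"))
  expect_setequal(partial, c("NO2", "NO"))
  expect_equal(pairwise_mo(full, partial), 2)
  expect_equal(pairwise_mo(partial, full), 2)
  expect_equal(pairwise_mo(full, full), 4)
})

test_that("profiles are unions of reactant sets; empty genomes allowed", {
  db <- toy_db()
  expect_equal(reactant_profile(character(0), db), character(0))
  # union bound: |profile| <= sum of per-reaction reactant set sizes
  rxns <- c("den1", "den2", "sul2")
  prof <- reactant_profile(rxns, db)
  per <- sum(vapply(rxns, function(r) length(reactant_set(db, r)), 0L))
  expect_lte(length(prof), per)
  expect_equal(prof, oracle_profile(rxns, db))
  # unknown ids: ignored when lenient, error when strict
  expect_equal(reactant_profile(c("den1", "ghost"), db), "NO3")
  expect_error(reactant_profile(c("den1", "ghost"), db, strict = TRUE), "ghost")
})

test_that("pairwise MO matches the brute-force oracle on random profiles", {
  set.seed(101)
  cpds <- sprintf("c%03d", 1:80)
  for (i in 1:300) {
    a <- sample(cpds, sample(0:40, 1))
    b <- sample(cpds, sample(0:40, 1))
    expect_identical(pairwise_mo(a, b), oracle_pairwise_mo(a, b))
  }
  expect_equal(pairwise_mo(c("x", "y"), c("p", "q")), 0)
})

test_that("overlap matrix reproduces the two-genome worked example", {
  db <- toy_db(extra = FALSE)
  ann <- metoverlap:::new_genome_annotations(
    list(org1 = c("den1", "den2", "den3", "den4"), org2 = c("den2", "den3")))
  m <- overlap_matrix(ann, db)
  expect_equal(unclass(m)[, ],
               matrix(c(4L, 2L, 2L, 2L), 2, 2,
                      dimnames = list(c("org1", "org2"), c("org1", "org2"))),
               ignore_attr = "class")
  expect_error(overlap_matrix(ann[1], db), "at least 2")
})

test_that("overlap matrices satisfy their invariants on random communities", {
  set.seed(7)
  cfg <- simulation_config(n_compounds = 80, n_reactions = 120, seed = NULL)
  db <- generate_reaction_db(cfg, seed = 77)
  for (rep in 1:10) {
    ann <- random_annotations(sample(3:12, 1), db, min_rxn = 0, max_rxn = 40)
    m <- overlap_matrix(ann, db)
    expect_true(isSymmetric(unclass(m)))
    profiles <- lapply(ann, reactant_profile, db = db)
    expect_equal(unname(diag(m)), unname(lengths(profiles)))
    # min bound: MO(i,j) <= min(diagonal)
    for (i in seq_along(ann)) {
      for (j in seq_along(ann)) {
        expect_lte(m[i, j], min(m[i, i], m[j, j]))
      }
    }
  }
})

test_that("overlap matrix equals the oracle entrywise, identical genomes constant", {
  set.seed(13)
  db <- generate_reaction_db(simulation_config(n_compounds = 100,
                                               n_reactions = 150), seed = 5)
  for (rep in 1:5) {
    ann <- random_annotations(8, db, min_rxn = 1, max_rxn = 60)
    m <- overlap_matrix(ann, db)
    expect_identical(unclass(m)[, ], oracle_overlap_matrix(ann, db))
  }
  same <- metoverlap:::new_genome_annotations(
    list(a = c("rxn0001", "rxn0002"), b = c("rxn0001", "rxn0002"),
         c = c("rxn0001", "rxn0002")))
  ms <- overlap_matrix(same, db)
  expect_true(all(ms == ms[1, 1]))
})

test_that("adding reactions to one genome never decreases its MO", {
  set.seed(23)
  db <- generate_reaction_db(simulation_config(n_compounds = 60,
                                               n_reactions = 80), seed = 3)
  for (rep in 1:10) {
    ann <- random_annotations(5, db, min_rxn = 1, max_rxn = 30)
    m1 <- overlap_matrix(ann, db)
    extra <- sample(setdiff(db$reactions$reaction_id, ann$g1), 5)
    ann2 <- ann
    ann2$g1 <- c(ann$g1, extra)
    m2 <- overlap_matrix(ann2, db)
    expect_true(all(m2["g1", ] >= m1["g1", ]))
  }
})

test_that("subsystem-restricted MO never exceeds full MO", {
  set.seed(29)
  db <- generate_reaction_db(simulation_config(n_compounds = 80,
                                               n_reactions = 90), seed = 8)
  ann <- metoverlap:::new_genome_annotations(random_annotations(6, db, 5, 40))
  full <- overlap_matrix(ann, db)
  for (cat in c("Nitrogen", "Sulfur", "Carbohydrates")) {
    restr <- restrict_to_subsystem(ann, db, cat)
    mr <- overlap_matrix(restr, db)
    expect_true(all(mr <= full))
  }
})

test_that("community central MO excludes the diagonal", {
  db <- toy_db(extra = FALSE)
  ann <- metoverlap:::new_genome_annotations(
    list(org1 = c("den1", "den2", "den3", "den4"), org2 = c("den2", "den3")))
  m <- overlap_matrix(ann, db)
  expect_equal(community_mo(m), 2)
  m3 <- matrix(c(9, 1, 2, 1, 9, 9, 2, 9, 9), 3, 3)
  expect_equal(community_mo(m3, "median"), 2)
  expect_equal(community_mo(m3, "mean"), 4)
  expect_error(community_mo(m3[1, 1, drop = FALSE]), ">= 2")
})

test_that("normalized MO is exactly central MO over median genome size", {
  db <- toy_db(extra = FALSE)
  sizes <- c(2.5e6, 3.0e6, 3.5e6)
  ann <- metoverlap:::new_genome_annotations(
    list(g1 = c("den1", "den2"), g2 = c("den2", "den3"), g3 = c("den3", "den4")))
  meta <- data.frame(genome_id = names(ann), study_id = "s1",
                     ecosystem = "marine", genome_size_bp = sizes,
                     completeness_pct = 90, stringsAsFactors = FALSE)
  comm <- group_into_communities(ann, meta, 2)[[1]]
  s <- summarize_community(comm, db)
  expect_equal(s$normalized_mo, s$mo_central / 3.0e6)
  expect_equal(s$median_genome_size_bp, 3.0e6)
  # scaling law: doubling sizes halves normalized MO, central MO unchanged
  comm2 <- comm
  comm2$metadata$genome_size_bp <- 2 * sizes
  s2 <- summarize_community(comm2, db)
  expect_equal(s2$mo_central, s$mo_central)
  expect_equal(s2$normalized_mo, s$normalized_mo / 2)
  # the documented magnitude example: 150 / 3 Mbp = 5e-5
  expect_equal(150 / 3e6, 5e-5)
})

test_that("summary values recompute from the stored matrix", {
  set.seed(37)
  db <- generate_reaction_db(simulation_config(n_compounds = 60,
                                               n_reactions = 70), seed = 4)
  ann <- metoverlap:::new_genome_annotations(random_annotations(6, db, 5, 30))
  meta <- data.frame(genome_id = names(ann), study_id = "s1",
                     ecosystem = "soil",
                     genome_size_bp = round(runif(6, 1e6, 5e6)),
                     completeness_pct = 75, stringsAsFactors = FALSE)
  comm <- group_into_communities(ann, meta, 2)[[1]]
  s <- summarize_community(comm, db, statistic = "mean")
  m <- overlap_matrix(comm, db)
  expect_equal(s$mo_central, mean(m[lower.tri(m)]))
  expect_equal(s$normalized_mo,
               mean(m[lower.tri(m)]) / median(meta$genome_size_bp))
  expect_equal(s$n_genomes, 6)
})

test_that("square matrices round-trip through the TSV layout", {
  set.seed(41)
  db <- generate_reaction_db(simulation_config(n_compounds = 40,
                                               n_reactions = 50), seed = 2)
  ann <- metoverlap:::new_genome_annotations(random_annotations(5, db, 3, 20))
  m <- overlap_matrix(ann, db)
  tf <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tf)
  m2 <- read_matrix_tsv(tf)
  expect_equal(m2, unclass(m)[, ], ignore_attr = TRUE)
  expect_identical(rownames(m2), rownames(m))
})
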