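#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generator. The
#' defaults describe the study conditions the rest of the package is
#' exercised under: a 400-reaction universe over 300 compounds, communities
#' of 30 genomes evolved from a 150-reaction ancestral repertoire with gain
#' rate 0.05 and loss rate 0.3 per unit branch length, genome sizes of about
#' 10 kb per encoded reaction with 100 kb Gaussian noise, and denitrifier
#' planting fractions of 0.3 complete / 0.2 partial.
#'
#' @param n_compounds Number of compounds in the universe.
#' @param n_reactions Number of reactions.
#' @param substrate_range,product_range Integer range (length 2) of
#'   substrate / product counts sampled per reaction.
#' @param p_reversible Probability a reaction is reversible.
#' @param include_denitrification Append the five nitrogen compounds and
#'   four denitrification reactions (ids `rxn_den1`..`rxn_den4`, subsystem
#'   Nitrogen) so pathway planting has targets.
#' @param n_tips Number of genomes (tree tips) per community.
#' @param gain_rate,loss_rate Reaction gain / loss events per unit branch
#'   length.
#' @param root_repertoire_size Reactions in the ancestral genome (capped at
#'   `n_reactions`; 150 at the default universe size).
#' @param bp_per_reaction Base pairs of genome per encoded reaction.
#' @param size_noise_sd Gaussian noise (bp) added to synthesized sizes.
#' @param frac_complete,frac_partial Fractions of genomes planted as
#'   complete / partial denitrifiers.
#' @param seed Optional default seed used by the generators.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_compounds = 300, n_reactions = 400,
                              substrate_range = c(1, 3),
                              product_range = c(1, 3),
                              p_reversible = 0.2,
                              include_denitrification = TRUE,
                              n_tips = 30, gain_rate = 0.05, loss_rate = 0.3,
                              root_repertoire_size = min(150, n_reactions),
                              bp_per_reaction = 10000,
                              size_noise_sd = 100000,
                              frac_complete = 0.3, frac_partial = 0.2,
                              seed = NULL) {
  cfg <- list(n_compounds = n_compounds, n_reactions = n_reactions,
              substrate_range = substrate_range, product_range = product_range,
              p_reversible = p_reversible,
              include_denitrification = include_denitrification,
              n_tips = n_tips, gain_rate = gain_rate, loss_rate = loss_rate,
              root_repertoire_size = root_repertoire_size,
              bp_per_reaction = bp_per_reaction,
              size_noise_sd = size_noise_sd,
              frac_complete = frac_complete, frac_partial = frac_partial,
              seed = seed)
  with(cfg, {
    stopifnot(n_compounds >= 2, n_reactions >= 1, n_tips >= 2,
              gain_rate >= 0, loss_rate >= 0,
              root_repertoire_size >= 1, bp_per_reaction > 0,
              size_noise_sd >= 0, p_reversible >= 0, p_reversible <= 1,
              frac_complete >= 0, frac_partial >= 0,
              frac_complete + frac_partial <= 1,
              length(substrate_range) == 2, length(product_range) == 2,
              substrate_range[1] >= 1, product_range[1] >= 1)
    if (substrate_range[2] + product_range[2] > n_compounds) {
      stop("substrate + product counts exceed n_compounds")
    }
    if (root_repertoire_size > n_reactions) {
      stop("root_repertoire_size exceeds n_reactions")
    }
  })
  structure(cfg, class = "sim_config")
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' Generate a random reaction database
#'
#' Samples `n_reactions` reactions over `n_compounds` compounds: substrate
#' and product counts drawn uniformly from the configured ranges, compounds
#' sampled without replacement (so the two sides are disjoint), about
#' `p_reversible` of reactions reversible, subsystem labels assigned
#' round-robin from the 13 categories in [mo_subsystem_categories]. With
#' `include_denitrification` the five nitrogen species and the four
#' denitrification reactions are appended.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to `config$seed`); the same seed
#'   reproduces the database exactly.
#' @return A `reaction_db`.
#' @export
generate_reaction_db <- function(config = simulation_config(),
                                 seed = config$seed) {
  maybe_seed(seed)
  cpds <- sprintf("cpd%04d", seq_len(config$n_compounds))
  nr <- config$n_reactions
  ids <- sprintf("rxn%04d", seq_len(nr))
  subs <- vector("list", nr)
  prods <- vector("list", nr)
  for (i in seq_len(nr)) {
    ns <- sample(config$substrate_range[1]:config$substrate_range[2], 1)
    np <- sample(config$product_range[1]:config$product_range[2], 1)
    pick <- sample(cpds, ns + np)
    subs[[i]] <- pick[seq_len(ns)]
    prods[[i]] <- pick[ns + seq_len(np)]
  }
  dirs <- ifelse(stats::runif(nr) < config$p_reversible, "reversible", "forward")
  syss <- as.list(mo_subsystem_categories[((seq_len(nr) - 1) %% 13) + 1])
  if (config$include_denitrification) {
    nspecies <- list(c("NO3", "NO2"), c("NO2", "NO"), c("NO", "N2O"), c("N2O", "N2"))
    ids <- c(ids, paste0("rxn_den", 1:4))
    subs <- c(subs, lapply(nspecies, `[`, 1))
    prods <- c(prods, lapply(nspecies, `[`, 2))
    dirs <- c(dirs, rep("forward", 4))
    syss <- c(syss, rep(list("Nitrogen"), 4))
  }
  new_reaction_db(ids, dirs, subs, prods, syss)
}

#' Generate a random binary tree
#'
#' Sequentially joins random pairs of subtrees with exponential(1) branch
#' lengths until one tree remains; tips are labelled `g1..gN`. The output
#' is newick text parseable by [cophenetic_matrix()].
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @return Newick string with branch lengths.
#' @export
generate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("generate_tree needs n_tips >= 2")
  maybe_seed(seed)
  nodes <- paste0("g", seq_len(n_tips))
  while (length(nodes) > 1) {
    pick <- sample(length(nodes), 2)
    bl <- stats::rexp(2)
    joined <- sprintf("(%s:%.6f,%s:%.6f)",
                      nodes[pick[1]], bl[1], nodes[pick[2]], bl[2])
    nodes <- c(nodes[-pick], joined)
  }
  paste0(nodes, ";")
}

#' Evolve reaction repertoires along a tree
#'
#' The ancestral genome at the root is a random repertoire of
#' `root_repertoire_size` reactions. Along each branch every present
#' reaction is lost with probability `1 - exp(-loss_rate * branch_length)`
#' and every absent reaction gained with probability
#' `1 - exp(-gain_rate * branch_length)` (a two-state Markov process
#' integrated over the branch). Closely related tips therefore share more
#' of their repertoire, which is the signal behind the distance-decay of
#' metabolic overlap.
#'
#' @param tree A `phylo`, newick string, or newick file path.
#' @param db A `reaction_db` supplying the reaction universe.
#' @param config A `sim_config` (`gain_rate`, `loss_rate`,
#'   `root_repertoire_size`).
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return A `genome_annotations` object with one entry per tip.
#' @export
evolve_genomes <- function(tree, db, config = simulation_config(),
                           seed = config$seed) {
  tr <- as_phylo_tree(tree)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  maybe_seed(seed)
  rids <- db$reactions$reaction_id
  root_size <- min(config$root_repertoire_size, length(rids))
  n_tip <- length(tr$tip.label)
  tr <- ape::reorder.phylo(tr, "cladewise")  # parents before children
  states <- vector("list", n_tip + tr$Nnode)
  root <- n_tip + 1L
  states[[root]] <- sample(rids, root_size)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    bl <- tr$edge.length[e]
    present <- states[[parent]]
    p_loss <- 1 - exp(-config$loss_rate * bl)
    p_gain <- 1 - exp(-config$gain_rate * bl)
    kept <- present[stats::runif(length(present)) >= p_loss]
    absent <- setdiff(rids, present)
    gained <- absent[stats::runif(length(absent)) < p_gain]
    states[[child]] <- c(kept, gained)
  }
  out <- states[seq_len(n_tip)]
  names(out) <- tr$tip.label
  new_genome_annotations(out)
}

largest_remainder_counts <- function(n, fracs) {
  quota <- fracs * n
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Plant denitrification pathway states into genomes
#'
#' Assigns a `frac_complete` share of genomes all pathway steps (one
#' qualifying reaction per step), a `frac_partial` share a random proper
#' non-empty subset of steps (reactions of the other steps removed), and
#' purges all pathway reactions from the rest. Shares are rounded by
#' largest remainder, so the planted class counts are exact.
#'
#' @param genomes A `genome_annotations` object.
#' @param pathway A `pathway_definition`.
#' @param config A `sim_config` (`frac_complete`, `frac_partial`).
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return The modified `genome_annotations`.
#' @export
plant_denitrification <- function(genomes, pathway,
                                  config = simulation_config(),
                                  seed = config$seed) {
  stopifnot(inherits(pathway, "pathway_definition"))
  maybe_seed(seed)
  n <- length(genomes)
  counts <- largest_remainder_counts(
    n, c(config$frac_complete, config$frac_partial,
         1 - config$frac_complete - config$frac_partial))
  all_pathway_rxns <- unlist(pathway$steps, use.names = FALSE)
  representatives <- vapply(pathway$steps, function(s) s[1], "")
  n_steps <- length(pathway$steps)
  assignment <- sample(rep.int(c("complete", "partial", "absent"), counts))
  out <- unclass(genomes)
  for (i in seq_len(n)) {
    g <- setdiff(out[[i]], all_pathway_rxns)
    out[[i]] <- switch(assignment[i],
      complete = c(g, representatives),
      partial = {
        k <- if (n_steps > 1) sample(n_steps - 1, 1) else 1
        c(g, representatives[sample(n_steps, k)])
      },
      absent = g)
  }
  new_genome_annotations(out)
}

#' Synthesize genome metadata
#'
#' Genome size is `bp_per_reaction * |reactions| + N(0, size_noise_sd)`
#' rounded and floored at 1 bp, coupling size to repertoire size as
#' observed in real genomes; completeness is uniform on [50, 100), the
#' range typical of accepted metagenome-assembled genomes.
#'
#' @param genomes A `genome_annotations` object.
#' @param config A `sim_config`.
#' @param study_id,ecosystem Labels stamped on every record.
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return Metadata data frame as from [load_genome_metadata()].
#' @export
generate_metadata <- function(genomes, config = simulation_config(),
                              study_id = "s1", ecosystem = "unknown",
                              seed = config$seed) {
  maybe_seed(seed)
  n <- length(genomes)
  n_rxn <- vapply(genomes, length, 0L)
  size <- pmax(1, round(config$bp_per_reaction * n_rxn +
                          stats::rnorm(n, 0, config$size_noise_sd)))
  data.frame(genome_id = names(genomes), study_id = study_id,
             ecosystem = ecosystem, genome_size_bp = size,
             completeness_pct = stats::runif(n, 50, 100),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a complete multi-study synthetic survey
#'
#' One call produces everything the survey pipeline consumes: a shared
#' reaction database, per-study trees, reaction repertoires evolved on
#' them, planted denitrifiers, and metadata — written to `out_dir` in the
#' package's TSV/newick dialects together with a `config.yaml` that
#' [run_survey()] accepts directly and a manifest listing all paths and the
#' seed. Study richness varies over `n_tips_range`; with
#' `couple_richness` the loss rate is scaled proportionally to a study's
#' richness, programming the negative richness-MO dependence the survey
#' statistics are meant to detect.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A `sim_config`.
#' @param n_studies Number of studies (communities).
#' @param ecosystems Ecosystem labels recycled across studies.
#' @param n_tips_range Integer range of genomes per study.
#' @param couple_richness Scale loss rate with richness (see above).
#' @param include_singleton Add one single-genome study (to exercise the
#'   singleton-exclusion rule downstream).
#' @param seed Integer seed driving the whole survey.
#' @return Invisibly, a list with the in-memory objects and all file paths.
#' @export
generate_survey <- function(out_dir, config = simulation_config(),
                            n_studies = 8,
                            ecosystems = c("marine", "fresh_water", "soil",
                                           "animal", "engineered"),
                            n_tips_range = c(4, 16),
                            couple_richness = TRUE,
                            include_singleton = FALSE,
                            seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  maybe_seed(seed)
  db <- generate_reaction_db(config, seed = NULL)
  pathway <- denitrification_pathway(db)
  mean_tips <- mean(n_tips_range)
  all_ann <- list()
  all_meta <- list()
  tree_files <- character(0)
  study_ids <- sprintf("s%02d", seq_len(n_studies))
  for (k in seq_len(n_studies)) {
    sid <- study_ids[k]
    n_tips <- sample(n_tips_range[1]:n_tips_range[2], 1)
    cfg_k <- config
    if (couple_richness) {
      cfg_k$loss_rate <- config$loss_rate * n_tips / mean_tips
    }
    cfg_k$n_tips <- n_tips
    nwk <- generate_tree(n_tips, seed = NULL)
    nwk <- gsub("\\bg(\\d+):", sprintf("%s_g\\1:", sid), nwk)
    genomes <- evolve_genomes(nwk, db, cfg_k, seed = NULL)
    genomes <- plant_denitrification(genomes, pathway, cfg_k, seed = NULL)
    meta <- generate_metadata(genomes, cfg_k, study_id = sid,
                              ecosystem = ecosystems[((k - 1) %% length(ecosystems)) + 1],
                              seed = NULL)
    tree_path <- file.path(out_dir, "trees", paste0(sid, ".nwk"))
    writeLines(nwk, tree_path)
    tree_files[sid] <- tree_path
    all_ann <- c(all_ann, unclass(genomes))
    all_meta[[sid]] <- meta
  }
  if (include_singleton) {
    sid <- "s_single"
    genomes <- new_genome_annotations(
      list(s_single_g1 = sample(db$reactions$reaction_id, 20)))
    all_ann <- c(all_ann, unclass(genomes))
    all_meta[[sid]] <- generate_metadata(genomes, config, study_id = sid,
                                         ecosystem = ecosystems[1], seed = NULL)
  }
  annotations <- new_genome_annotations(all_ann)
  metadata <- do.call(rbind, all_meta)
  rownames(metadata) <- NULL
  paths <- list(
    reaction_db = file.path(out_dir, "reactions.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    pathway = file.path(out_dir, "pathway.tsv"),
    tree_manifest = file.path(out_dir, "tree_manifest.tsv"),
    config = file.path(out_dir, "config.yaml"),
    manifest = file.path(out_dir, "manifest.tsv"))
  write_reaction_db(db, paths$reaction_db)
  write_genome_annotations(annotations, paths$annotations)
  write_genome_metadata(metadata, paths$metadata)
  write_pathway(pathway, paths$pathway)
  utils::write.table(
    data.frame(study_id = names(tree_files), path = unname(tree_files),
               stringsAsFactors = FALSE),
    paths$tree_manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  survey_cfg <- list(reaction_db = paths$reaction_db, dialect = "native",
                     annotations = paths$annotations,
                     metadata = paths$metadata,
                     pathway = paths$pathway,
                     tree_manifest = paths$tree_manifest,
                     out_dir = file.path(out_dir, "results"),
                     min_completeness = 50, min_members = 2,
                     statistic = "median", subsystems = "all",
                     n_perm = 199, seed = seed, adjust = "holm")
  yaml::write_yaml(survey_cfg, paths$config)
  utils::write.table(
    data.frame(key = c("seed", names(paths)),
               value = c(seed, unlist(paths, use.names = FALSE)),
               stringsAsFactors = FALSE),
    paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(db = db, pathway = pathway, annotations = annotations,
                 metadata = metadata, tree_files = tree_files,
                 paths = paths, seed = seed))
}
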