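survey_defaults <- function() {
  list(dialect = "native", min_completeness = 50, min_members = 2,
       statistic = "median", subsystems = NULL, n_perm = 999,
       seed = NULL, adjust = "holm", pathway = NULL,
       tree = NULL, tree_manifest = NULL)
}

#' Run the full metabolic-overlap survey
#'
#' Orchestrates every stage over one input bundle: load the reaction
#' database, annotations and metadata; filter genomes by completeness;
#' group them into study communities (dropping singletons); compute
#' per-community overlap matrices and genome-size-normalized summaries;
#' optionally repeat the summaries restricted to metabolism subsystems;
#' classify denitrifiers; associate MO with cophenetic distance where trees
#' are given (Mantel test and pooled rank correlation side by side); and
#' run the contrast battery (richness-MO and size-MO correlations,
#' Kruskal-Wallis with Dunn post-hoc across ecosystems, genome-size ANOVA).
#' All outputs are written as TSV under `out_dir` together with a run log.
#'
#' @param config A named list or the path to a YAML file. Recognized keys:
#'   `reaction_db`, `dialect`, `annotations`, `metadata`, `out_dir`
#'   (required); `pathway` (TSV path; default: denitrification steps derived
#'   from the database), `tree` (one newick covering all genomes) or
#'   `tree_manifest` (TSV `study_id`, `path`), `subsystems` (`"all"` or a
#'   vector of category labels), `min_completeness`, `min_members`,
#'   `statistic`, `n_perm`, `seed`, `adjust`.
#' @param out_dir Overrides `config$out_dir`.
#' @return Invisibly, a list with all intermediate objects and result
#'   tables.
#' @export
run_survey <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(survey_defaults(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  for (key in c("reaction_db", "annotations", "metadata", "out_dir")) {
    if (is.null(cfg[[key]])) stop("survey config is missing: ", key)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "matrices"), showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("survey stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  log("metoverlap survey; seed = ", if (is.null(cfg$seed)) "none" else cfg$seed)

  db <- stage("load reaction db",
              load_reaction_db(cfg$reaction_db, dialect = cfg$dialect))
  log("reaction db: ", nrow(db$reactions), " reactions, ",
      nrow(db$compounds), " compounds")
  ann <- stage("load annotations", load_genome_annotations(cfg$annotations, db = db))
  log("annotations: ", length(ann), " genomes in")
  meta <- stage("load metadata", load_genome_metadata(cfg$metadata))
  ann <- stage("completeness filter",
               filter_by_completeness(ann, meta, cfg$min_completeness))
  log("completeness >= ", cfg$min_completeness, ": ", length(ann), " genomes kept")
  comms <- stage("community grouping",
                 suppressMessages(group_into_communities(ann, meta, cfg$min_members)))
  studies_in <- unique(meta$study_id[meta$genome_id %in% names(ann)])
  small <- setdiff(studies_in, names(comms))
  if (length(small)) {
    log("dropped ", length(small), " stud(ies) with < ", cfg$min_members,
        " members: ", paste(small, collapse = ", "))
  }
  log("communities with >= ", cfg$min_members, " members: ", length(comms))

  summaries <- stage("community summaries",
                     summarize_communities(comms, db, statistic = cfg$statistic))
  matrices <- lapply(comms, overlap_matrix, db = db)
  for (sid in names(matrices)) {
    write_matrix_tsv(matrices[[sid]],
                     file.path(cfg$out_dir, "matrices", paste0(sid, ".tsv")))
  }
  utils::write.table(summaries, file.path(cfg$out_dir, "summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("summaries: ", nrow(summaries), " communities")

  sub_summaries <- NULL
  if (!is.null(cfg$subsystems)) {
    cats <- cfg$subsystems
    if (identical(cats, "all")) {
      cats <- sort(unique(unlist(db$subsystems, use.names = FALSE)))
    }
    pieces <- lapply(cats, function(cat) {
      rows <- stage(paste0("subsystem MO (", cat, ")"), {
        restr <- lapply(comms, restrict_to_subsystem, db = db, category = cat)
        summarize_communities(restr, db, statistic = cfg$statistic)
      })
      rows$subsystem <- cat
      rows
    })
    sub_summaries <- do.call(rbind, pieces)
    utils::write.table(sub_summaries,
                       file.path(cfg$out_dir, "subsystem_summaries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("subsystem summaries: ", length(cats), " categories")
  }

  pathway <- stage("pathway definition", {
    if (!is.null(cfg$pathway)) load_pathway(cfg$pathway)
    else denitrification_pathway(db)
  })
  denitrifiers <- stage("denitrifier summary", {
    rbind(cbind(level = "study",
                summarize_denitrifiers(comms, pathway, by = "study")),
          cbind(level = "ecosystem",
                summarize_denitrifiers(comms, pathway, by = "ecosystem")))
  })
  utils::write.table(denitrifiers, file.path(cfg$out_dir, "denitrifiers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log("denitrifier summary written (pathway: ", pathway$name, ")")

  phylo_assoc <- NULL
  trees <- NULL
  if (!is.null(cfg$tree_manifest)) {
    man <- read_tsv_table(cfg$tree_manifest, c("study_id", "path"), "tree manifest")
    trees <- stats::setNames(as.list(man$path), man$study_id)
  } else if (!is.null(cfg$tree)) {
    trees <- lapply(names(comms), function(sid) cfg$tree)
    names(trees) <- names(comms)
  }
  if (!is.null(trees)) {
    rows <- list()
    for (sid in intersect(names(comms), names(trees))) {
      m <- matrices[[sid]]
      d <- stage(paste0("cophenetic (", sid, ")"), {
        suppressWarnings(cophenetic_matrix(trees[[sid]], tip_subset = rownames(m)))
      })
      common <- intersect(rownames(m), rownames(d))
      dropped <- length(rownames(m)) - length(common)
      if (dropped > 0) {
        log(sid, ": ", dropped, " genome(s) absent from the tree, dropped")
      }
      if (length(common) < 3) next
      mm <- m[common, common]
      dd <- d[common, common]
      mt <- mantel_test(dd, mm, n_perm = cfg$n_perm, seed = cfg$seed)
      sc <- pairwise_scatter_correlation(dd, mm)
      rows[[sid]] <- data.frame(
        study_id = sid, n_genomes = length(common),
        mantel_r = mt$r, mantel_p = mt$p_value,
        spearman_r = sc$r, spearman_p = sc$p_value,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      phylo_assoc <- do.call(rbind, rows)
      rownames(phylo_assoc) <- NULL
      utils::write.table(phylo_assoc, file.path(cfg$out_dir, "phylo_assoc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log("phylogeny association: ", nrow(phylo_assoc), " communities")
    }
  }

  stats_lines <- character(0)
  contrasts <- NULL
  if (nrow(summaries) >= 3) {
    rich <- richness_mo_correlation(summaries)
    sizec <- size_mo_correlation(summaries)
    stats_lines <- c(stats_lines,
      sprintf("richness_mo_kendall_tau\t%.6g\tp\t%.6g", rich$r, rich$p_value),
      sprintf("size_mo_spearman_r\t%.6g\tp\t%.6g", sizec$r, sizec$p_value))
  }
  eco_sizes <- table(summaries$ecosystem)
  if (length(eco_sizes) >= 2 && all(eco_sizes >= 2)) {
    ec <- stage("ecosystem contrasts",
                ecosystem_contrast(summaries, adjust = cfg$adjust))
    contrasts <- ec$contrasts
    utils::write.table(contrasts, file.path(cfg$out_dir, "contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    an <- genome_size_anova(meta[meta$genome_id %in% names(ann), , drop = FALSE])
    stats_lines <- c(stats_lines,
      sprintf("kruskal_wallis_chisq\t%.6g\tdf\t%d\tp\t%.6g",
              ec$omnibus$statistic, as.integer(ec$omnibus$df), ec$omnibus$p_value),
      sprintf("genome_size_anova_F\t%.6g\tp\t%.6g", an$F, an$p_value))
    log("contrasts: KW chi-squared = ", format(ec$omnibus$statistic, digits = 4))
  } else {
    log("contrast battery skipped: need >= 2 ecosystems with >= 2 communities")
  }
  writeLines(stats_lines, file.path(cfg$out_dir, "stats.txt"))

  log("---- survey complete ----")
  log("n_genomes\t", length(ann))
  log("n_communities\t", length(comms))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(config = cfg, db = db, annotations = ann, metadata = meta,
                 communities = comms, matrices = matrices,
                 summaries = summaries, subsystem_summaries = sub_summaries,
                 denitrifiers = denitrifiers, phylo_assoc = phylo_assoc,
                 contrasts = contrasts, stats_lines = stats_lines))
}
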