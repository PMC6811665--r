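#' Define a stepwise pathway
#'
#' A pathway is an ordered list of steps; each step is satisfied by any one
#' of a set of qualifying reaction ids.
#'
#' @param name Pathway label.
#' @param steps Named list of non-empty character vectors of reaction ids,
#'   in pathway order.
#' @return A `pathway_definition`.
#' @export
pathway_definition <- function(name, steps) {
  stopifnot(is.character(name), length(name) == 1,
            is.list(steps), length(steps) >= 1, !is.null(names(steps)))
  empty <- vapply(steps, length, 0L) == 0L
  if (any(empty)) {
    stop("pathway step(s) with no qualifying reactions: ",
         paste(names(steps)[empty], collapse = ", "))
  }
  structure(list(name = name,
                 steps = lapply(steps, function(x) sort(unique(as.character(x))))),
            class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("pathway_definition", x$name, ":", length(x$steps), "steps\n")
  for (s in names(x$steps)) {
    cat(" ", s, "->", paste(x$steps[[s]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default denitrification pathway from a reaction database
#'
#' Builds the four-step denitrification pathway — nitrate to nitrite,
#' nitrite to nitric oxide, nitric oxide to nitrous oxide, nitrous oxide to
#' dinitrogen — by scanning the database for reactions whose consumed /
#' produced sides match each step's compound pair (reversible reactions
#' qualify in either orientation). The compound ids are overridable because
#' databases differ in their naming of the nitrogen species.
#'
#' @param db A `reaction_db`.
#' @param compound_ids Named character vector with entries `nitrate`,
#'   `nitrite`, `nitric_oxide`, `nitrous_oxide`, `dinitrogen`.
#' @return A `pathway_definition` named `"denitrification"`.
#' @export
denitrification_pathway <- function(db,
    compound_ids = c(nitrate = "NO3", nitrite = "NO2", nitric_oxide = "NO",
                     nitrous_oxide = "N2O", dinitrogen = "N2")) {
  stopifnot(inherits(db, "reaction_db"))
  need <- c("nitrate", "nitrite", "nitric_oxide", "nitrous_oxide", "dinitrogen")
  if (!all(need %in% names(compound_ids))) {
    stop("compound_ids must name: ", paste(need, collapse = ", "))
  }
  pairs <- list(
    nitrate_reduction = c(compound_ids[["nitrate"]], compound_ids[["nitrite"]]),
    nitrite_reduction = c(compound_ids[["nitrite"]], compound_ids[["nitric_oxide"]]),
    nitric_oxide_reduction = c(compound_ids[["nitric_oxide"]], compound_ids[["nitrous_oxide"]]),
    nitrous_oxide_reduction = c(compound_ids[["nitrous_oxide"]], compound_ids[["dinitrogen"]])
  )
  rids <- db$reactions$reaction_id
  rev_dir <- db$reactions$direction == "reversible"
  steps <- lapply(pairs, function(p) {
    hit <- vapply(seq_along(rids), function(i) {
      fwd <- p[1] %in% db$substrates[[i]] && p[2] %in% db$products[[i]]
      bwd <- rev_dir[i] && p[1] %in% db$products[[i]] && p[2] %in% db$substrates[[i]]
      fwd || bwd
    }, TRUE)
    rids[hit]
  })
  empty <- vapply(steps, length, 0L) == 0L
  if (any(empty)) {
    stop("no reaction in the database matches denitrification step(s): ",
         paste(names(steps)[empty], collapse = ", "))
  }
  pathway_definition("denitrification", steps)
}

#' Load a pathway definition from TSV
#'
#' Expects columns `pathway`, `step`, `reaction_id`; one pathway per call
#' (pass `name` to pick one when the file holds several). Step order follows
#' first appearance in the file.
#'
#' @param path Path to TSV.
#' @param name Optional pathway name to select.
#' @return A `pathway_definition`.
#' @export
load_pathway <- function(path, name = NULL) {
  tab <- read_tsv_table(path, c("pathway", "step", "reaction_id"), "pathway")
  if (is.null(name)) name <- tab$pathway[1]
  tab <- tab[tab$pathway == name, , drop = FALSE]
  if (!nrow(tab)) stop("pathway not found in file: ", name)
  steps <- split(tab$reaction_id, factor(tab$step, levels = unique(tab$step)))
  pathway_definition(name, steps)
}

#' Write a pathway definition as TSV
#' @param pathway A `pathway_definition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(pathway, path) {
  tab <- data.frame(
    pathway = pathway$name,
    step = rep(names(pathway$steps), vapply(pathway$steps, length, 0L)),
    reaction_id = unlist(pathway$steps, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify genomes by pathway completeness
#'
#' A step is present iff the genome's reaction set intersects the step's
#' qualifying set. Status is `complete` when all steps are present,
#' `partial` when at least one but not all are, `absent` when none is.
#'
#' @param annotations A `genome_annotations` object (or a named list of
#'   reaction-id vectors).
#' @param pathway A `pathway_definition`.
#' @return Data frame with one row per genome: `genome_id`, `status`
#'   (factor complete/partial/absent), `n_steps_present`, and
#'   `steps_present` (semicolon-joined step labels).
#' @export
classify_pathway <- function(annotations, pathway) {
  stopifnot(inherits(pathway, "pathway_definition"))
  steps <- pathway$steps
  n_steps <- length(steps)
  rows <- lapply(names(annotations), function(g) {
    rxns <- annotations[[g]]
    present <- vapply(steps, function(q) any(q %in% rxns), TRUE)
    k <- sum(present)
    status <- if (k == n_steps) "complete" else if (k > 0) "partial" else "absent"
    data.frame(genome_id = g, status = status, n_steps_present = k,
               steps_present = paste(names(steps)[present], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$status <- factor(out$status, levels = c("complete", "partial", "absent"))
  out
}

#' Summarize pathway completeness per community or ecosystem
#'
#' Counts complete, partial and absent genomes per group; proportions use
#' the whole group (absent included) as denominator. The complete-to-partial
#' ratio is `Inf` when a group has complete but no partial genomes and is
#' flagged undefined (`NaN`) when it has neither.
#'
#' @param communities List of `mo_community` objects.
#' @param pathway A `pathway_definition`.
#' @param by Grouping: `"study"` (one row per community) or `"ecosystem"`
#'   (communities pooled by ecosystem label).
#' @return Data frame: `group_id`, `n_genomes`, `n_complete`, `n_partial`,
#'   `n_absent`, `prop_complete`, `prop_partial`,
#'   `ratio_complete_to_partial`, `ratio_defined`.
#' @export
summarize_denitrifiers <- function(communities, pathway,
                                   by = c("study", "ecosystem")) {
  by <- match.arg(by)
  calls <- lapply(communities, function(cm) {
    cl <- classify_pathway(cm$annotations, pathway)
    cl$group <- if (by == "study") cm$study_id else cm$ecosystem
    cl
  })
  calls <- do.call(rbind, calls)
  rows <- lapply(split(calls, calls$group), function(d) {
    n <- nrow(d)
    nc <- sum(d$status == "complete")
    np <- sum(d$status == "partial")
    na_ <- sum(d$status == "absent")
    ratio <- if (np > 0) nc / np else if (nc > 0) Inf else NaN
    data.frame(group_id = d$group[1], n_genomes = n,
               n_complete = nc, n_partial = np, n_absent = na_,
               prop_complete = nc / n, prop_partial = np / n,
               ratio_complete_to_partial = ratio,
               ratio_defined = nc > 0 || np > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
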