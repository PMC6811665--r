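# Genome annotations are a named list: genome_id -> sorted unique character
# vector of reaction ids. Kept deliberately plain so set operations stay cheap.

new_genome_annotations <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  x <- lapply(x, function(v) sort(unique(as.character(v))))
  structure(x, class = "genome_annotations")
}

#' @export
print.genome_annotations <- function(x, ...) {
  sizes <- vapply(x, length, 0L)
  cat("genome_annotations:", length(x), "genomes;",
      "reaction-set sizes", paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' @export
`[.genome_annotations` <- function(x, i) {
  new_genome_annotations(unclass(x)[i])
}

#' Load per-genome annotation tables
#'
#' Reads a long-format TSV with one row per genome-reaction pair (columns
#' `genome_id`, `reaction_id`; extra columns such as `role` or `subsystem`
#' are ignored here) and groups rows into deduplicated reaction sets per
#' genome. When a `reaction_db` is supplied, rows citing reaction ids
#' unknown to it are reported; by default they are kept with a warning,
#' since MAG annotations routinely cite deprecated ids, while
#' `strict = TRUE` drops them.
#'
#' @param path Path to TSV (plain or gzipped).
#' @param db Optional `reaction_db` used to validate reaction ids.
#' @param strict Drop rows with unknown reaction ids instead of keeping them.
#' @return A `genome_annotations` object (named list of reaction-id sets).
#' @export
load_genome_annotations <- function(path, db = NULL, strict = FALSE) {
  tab <- read_tsv_table(path, c("genome_id", "reaction_id"), "annotations")
  keep <- nzchar(tab$genome_id) & nzchar(tab$reaction_id)
  tab <- tab[keep, , drop = FALSE]
  if (!is.null(db)) {
    unknown <- !tab$reaction_id %in% db$reactions$reaction_id
    if (any(unknown)) {
      if (strict) {
        warning(sum(unknown), " row(s) with reaction ids not in the ",
                "reaction database were dropped (strict mode)")
        tab <- tab[!unknown, , drop = FALSE]
      } else {
        warning(sum(unknown), " row(s) cite reaction ids not in the ",
                "reaction database (kept)")
      }
    }
  }
  new_genome_annotations(split(tab$reaction_id, tab$genome_id))
}

#' Write genome annotations as long-format TSV
#'
#' @param annotations A `genome_annotations` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_annotations <- function(annotations, path) {
  tab <- data.frame(
    genome_id = rep(names(annotations), vapply(annotations, length, 0L)),
    reaction_id = unlist(annotations, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load genome metadata
#'
#' Reads and validates a TSV with columns `genome_id`, `study_id`,
#' `ecosystem`, `genome_size_bp` (positive integer, base pairs) and
#' `completeness_pct` (0-100, as estimated by CheckM-style tools).
#'
#' @param path Path to TSV (plain or gzipped).
#' @return A data frame of validated records.
#' @export
load_genome_metadata <- function(path) {
  tab <- read_tsv_table(path, c("genome_id", "study_id", "ecosystem",
                                "genome_size_bp", "completeness_pct"),
                        "metadata")
  size <- suppressWarnings(as.numeric(tab$genome_size_bp))
  comp <- suppressWarnings(as.numeric(tab$completeness_pct))
  bad <- which(is.na(size) | is.na(comp))
  if (length(bad)) {
    stop("metadata: non-numeric genome_size_bp or completeness_pct at row(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(size <= 0)) {
    stop("metadata: genome_size_bp must be positive (row(s) ",
         paste(which(size <= 0), collapse = ", "), ")")
  }
  out_of_range <- comp < 0 | comp > 100
  if (any(out_of_range)) {
    stop("metadata: completeness_pct outside [0, 100] at row(s): ",
         paste(which(out_of_range), collapse = ", "))
  }
  data.frame(genome_id = tab$genome_id, study_id = tab$study_id,
             ecosystem = tab$ecosystem, genome_size_bp = size,
             completeness_pct = comp, stringsAsFactors = FALSE)
}

#' Write genome metadata TSV
#' @param metadata Data frame as returned by [load_genome_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genomes by predicted completeness
#'
#' Keeps exactly the genomes whose metadata completeness is at least
#' `min_pct`, preserving input order. The default threshold 50 matches the
#' floor of completeness typically accepted for metagenome-assembled
#' genomes.
#'
#' @param annotations A `genome_annotations` object.
#' @param metadata Metadata data frame covering every genome.
#' @param min_pct Minimum completeness percentage.
#' @return Filtered `genome_annotations`.
#' @export
filter_by_completeness <- function(annotations, metadata, min_pct = 50) {
  ids <- names(annotations)
  idx <- match(ids, metadata$genome_id)
  orphans <- ids[is.na(idx)]
  if (length(orphans)) {
    stop("genome(s) without metadata: ", paste(orphans, collapse = ", "))
  }
  keep <- metadata$completeness_pct[idx] >= min_pct
  new_genome_annotations(unclass(annotations)[keep])
}

#' Group genomes into study communities
#'
#' Joins annotations to metadata on `genome_id` and forms one community per
#' `study_id`. Studies with fewer than `min_members` genomes are dropped
#' (singleton studies carry no pairwise overlap) and reported via a message.
#'
#' @param annotations A `genome_annotations` object.
#' @param metadata Metadata data frame covering every genome.
#' @param min_members Minimum community size (default 2).
#' @return A named list of `mo_community` objects, each holding `study_id`,
#'   `ecosystem`, member `annotations` and member `metadata`.
#' @export
group_into_communities <- function(annotations, metadata, min_members = 2) {
  ids <- names(annotations)
  idx <- match(ids, metadata$genome_id)
  orphans <- ids[is.na(idx)]
  if (length(orphans)) {
    stop("genome(s) without metadata: ", paste(orphans, collapse = ", "))
  }
  study <- metadata$study_id[idx]
  groups <- split(seq_along(ids), study)
  sizes <- vapply(groups, length, 0L)
  dropped <- names(groups)[sizes < min_members]
  if (length(dropped)) {
    message("dropped ", length(dropped), " stud(ies) with < ", min_members,
            " members: ", paste(dropped, collapse = ", "))
  }
  groups <- groups[sizes >= min_members]
  out <- lapply(names(groups), function(sid) {
    sel <- groups[[sid]]
    meta <- metadata[idx[sel], , drop = FALSE]
    rownames(meta) <- NULL
    structure(list(
      study_id = sid,
      ecosystem = meta$ecosystem[1],
      annotations = new_genome_annotations(unclass(annotations)[sel]),
      metadata = meta
    ), class = "mo_community")
  })
  names(out) <- names(groups)
  out
}

#' @export
print.mo_community <- function(x, ...) {
  cat("mo_community", x$study_id, "(", x$ecosystem, "):",
      length(x$annotations), "genomes\n")
  invisible(x)
}

#' Restrict annotations to one metabolism subsystem
#'
#' Intersects every genome's reaction set with the reactions carrying the
#' given subsystem label (matched case-insensitively). A label matching no
#' reaction in the database is an error, which distinguishes a typo from a
#' genome that genuinely lacks that metabolism.
#'
#' @param annotations A `genome_annotations` object (or a single
#'   `mo_community`, whose member annotations are restricted in place).
#' @param db A `reaction_db`.
#' @param category Subsystem label, e.g. `"Nitrogen"`.
#' @return Object of the same type with reaction sets restricted (possibly
#'   empty for some genomes).
#' @export
restrict_to_subsystem <- function(annotations, db, category) {
  stopifnot(inherits(db, "reaction_db"))
  if (inherits(annotations, "mo_community")) {
    annotations$annotations <- restrict_to_subsystem(annotations$annotations,
                                                     db, category)
    return(annotations)
  }
  hit <- vapply(db$subsystems, function(s) any(tolower(s) == tolower(category)), TRUE)
  if (!any(hit)) {
    stop("subsystem category matches no reaction in the database: ", category)
  }
  keep_ids <- db$reactions$reaction_id[hit]
  new_genome_annotations(lapply(unclass(annotations), intersect, y = keep_ids))
}
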