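#' Reactant profile of a genome
#'
#' The union of utilizable reactants over all reactions a genome encodes:
#' the compound set the genome can consume, which is the object metabolic
#' overlap is counted on.
#'
#' @param reaction_ids Character vector of reaction ids (one genome's
#'   repertoire).
#' @param db A `reaction_db`.
#' @param strict Error on reaction ids missing from `db` (default: silently
#'   ignore them, matching lenient annotation loading).
#' @param reversible Passed to [reactant_set()]: `"union"` counts both sides
#'   of reversible reactions.
#' @return Sorted character vector of compound ids (possibly empty).
#' @export
reactant_profile <- function(reaction_ids, db, strict = FALSE,
                             reversible = c("union", "substrates")) {
  reversible <- match.arg(reversible)
  stopifnot(inherits(db, "reaction_db"))
  reaction_ids <- unique(as.character(reaction_ids))
  known <- reaction_ids %in% db$reactions$reaction_id
  if (strict && any(!known)) {
    stop("reaction id(s) not in database: ",
         paste(reaction_ids[!known], collapse = ", "))
  }
  sets <- reactant_sets(db, reversible)
  out <- unlist(sets[reaction_ids[known]], use.names = FALSE)
  if (is.null(out)) character(0) else sort(unique(out))
}

#' Pairwise metabolic overlap
#'
#' MO between two genomes: the number of compounds both can utilize,
#' i.e. the size of the intersection of their reactant profiles. Symmetric;
#' `pairwise_mo(a, a)` equals the profile size.
#'
#' @param a,b Reactant profiles (character vectors of compound ids), as
#'   returned by [reactant_profile()].
#' @return Non-negative integer count of shared compounds.
#' @export
pairwise_mo <- function(a, b) {
  length(intersect(a, b))
}

#' Community overlap matrix
#'
#' All pairwise MO values for a community, stored as a symmetric genome x
#' genome integer matrix whose diagonal holds each genome's profile size.
#' Computed via the compound-incidence matrix (genome x compound membership,
#' then a cross-product), which is exactly intersection counting done in
#' bulk.
#'
#' @param x An `mo_community`, or a `genome_annotations` object / named list
#'   of reaction-id vectors with at least 2 genomes.
#' @param db A `reaction_db`.
#' @param ... Passed to [reactant_profile()] (`strict`, `reversible`).
#' @return Integer matrix of class `overlap_matrix` with genome ids as
#'   dimnames, in input member order.
#' @export
overlap_matrix <- function(x, db, ...) {
  if (inherits(x, "mo_community")) x <- x$annotations
  stopifnot(is.list(x), !is.null(names(x)))
  if (length(x) < 2) stop("a community needs at least 2 genomes")
  profiles <- lapply(unclass(x), reactant_profile, db = db, ...)
  cpds <- sort(unique(unlist(profiles, use.names = FALSE)))
  n <- length(x)
  if (length(cpds) == 0) {
    m <- matrix(0L, n, n)
  } else {
    inc <- vapply(profiles, function(p) cpds %in% p, logical(length(cpds)))
    m <- crossprod(inc)
    storage.mode(m) <- "integer"
  }
  dimnames(m) <- list(names(x), names(x))
  class(m) <- c("overlap_matrix", class(m))
  m
}

#' Central MO of a community
#'
#' The median (default) or mean over the n(n-1)/2 unique off-diagonal
#' entries of an overlap matrix; the diagonal (self-overlap) is excluded.
#'
#' @param matrix Square symmetric matrix from [overlap_matrix()].
#' @param statistic `"median"` or `"mean"`.
#' @return A single number.
#' @export
community_mo <- function(matrix, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (nrow(matrix) < 2) stop("community_mo needs a matrix from >= 2 genomes")
  vals <- matrix[lower.tri(matrix)]
  if (statistic == "median") stats::median(vals) else mean(vals)
}

#' Summarize one community
#'
#' Computes the overlap matrix, its central MO, and the genome-size
#' normalization: `normalized_mo = mo_central / median(genome_size_bp)`,
#' in compounds per base pair. Normalizing by the community's median genome
#' size makes communities of large- and small-genome organisms comparable.
#'
#' @param community An `mo_community` whose metadata carries
#'   `genome_size_bp` for every member.
#' @param db A `reaction_db`.
#' @param statistic Central statistic for [community_mo()].
#' @param ... Passed to [overlap_matrix()].
#' @return One-row data frame: `study_id`, `ecosystem`, `n_genomes`,
#'   `mo_central`, `median_genome_size_bp`, `normalized_mo`.
#' @export
summarize_community <- function(community, db,
                                statistic = c("median", "mean"), ...) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(community, "mo_community"))
  sizes <- community$metadata$genome_size_bp
  if (is.null(sizes) || anyNA(sizes)) {
    stop("every community member needs genome_size_bp")
  }
  m <- overlap_matrix(community, db, ...)
  mo <- community_mo(m, statistic)
  med_size <- stats::median(sizes)
  data.frame(study_id = community$study_id,
             ecosystem = community$ecosystem,
             n_genomes = length(community$annotations),
             mo_central = mo,
             median_genome_size_bp = med_size,
             normalized_mo = mo / med_size,
             stringsAsFactors = FALSE)
}

#' Summarize a collection of communities
#'
#' @param communities List of `mo_community` objects (see
#'   [group_into_communities()]).
#' @param db A `reaction_db`.
#' @param statistic Central statistic for [community_mo()].
#' @param ... Passed to [overlap_matrix()].
#' @return Data frame with one row per community.
#' @export
summarize_communities <- function(communities, db,
                                  statistic = c("median", "mean"), ...) {
  statistic <- match.arg(statistic)
  rows <- lapply(communities, summarize_community, db = db,
                 statistic = statistic, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap_matrix:", nrow(x), "genomes; off-diagonal MO range",
      paste(range(x[lower.tri(x)]), collapse = "-"), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Write a square matrix (MO or distance) as TSV
#'
#' Genome ids appear as both the first row and first column; the layout is
#' shared by overlap and cophenetic-distance matrices.
#'
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  tab <- data.frame(genome_id = rownames(m), unclass(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with genome ids as dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("not a square id-labelled matrix: ", path)
  }
  m
}
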