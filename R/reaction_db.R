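# -- internal constructor -----------------------------------------------------

# All loaders and generators funnel through this so that objects built from
# any source compare field-by-field (round-trip tests rely on it).
new_reaction_db <- function(reaction_id, direction, substrates, products,
                            subsystems, compound_names = NULL) {
  stopifnot(length(reaction_id) == length(direction))
  dup <- duplicated(reaction_id)
  if (any(dup)) {
    stop("duplicate reaction_id: ", paste(unique(reaction_id[dup]), collapse = ", "))
  }
  bad <- !direction %in% c("forward", "reverse", "reversible")
  if (any(bad)) {
    stop("unknown direction token: ", paste(unique(direction[bad]), collapse = ", "))
  }
  names(substrates) <- reaction_id
  names(products) <- reaction_id
  names(subsystems) <- reaction_id
  cpds <- sort(unique(c(unlist(substrates, use.names = FALSE),
                        unlist(products, use.names = FALSE))))
  compounds <- data.frame(compound_id = cpds,
                          name = rep(NA_character_, length(cpds)),
                          stringsAsFactors = FALSE)
  if (!is.null(compound_names)) {
    idx <- match(compounds$compound_id, names(compound_names))
    compounds$name <- unname(compound_names[idx])
  }
  structure(list(
    reactions = data.frame(reaction_id = reaction_id, direction = direction,
                           stringsAsFactors = FALSE),
    substrates = lapply(substrates, function(x) sort(unique(x))),
    products = lapply(products, function(x) sort(unique(x))),
    subsystems = lapply(subsystems, function(x) sort(unique(x))),
    compounds = compounds
  ), class = "reaction_db")
}

split_list_cell <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

read_tsv_table <- function(path, required, what) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "#", colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(what, ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' Load a reaction-compound database
#'
#' Reads the reaction universe from a TSV file in one of two dialects and
#' returns a validated `reaction_db` object. The native dialect has columns
#' `reaction_id`, `substrates`, `products`, `direction`, `subsystems`, with
#' semicolons separating compounds within a cell and `#` starting comment
#' lines. The `substrates` column always holds the consumed side of the
#' reaction; the `direction` token (`forward`, `reverse`, `reversible`) is
#' carried as metadata, with `reversible` meaning both sides are utilizable.
#' The ModelSEED-style dialect has columns `id` (or `reaction_id`) and
#' `equation`; equations are parsed with [parse_reaction_equation()] and
#' unparseable rows are skipped with a warning that reports the count.
#'
#' @param path Path to a TSV file (plain or gzip-compressed).
#' @param dialect `"native"` or `"modelseed"`.
#' @param subsystem_map Optional path to a two-column TSV (`reaction_id`,
#'   `subsystem`) attaching subsystem labels, mainly for the ModelSEED
#'   dialect which carries none.
#' @param exclude_compounds Optional character vector of compound ids (or
#'   path to a one-column file of ids) to strip from every reaction, e.g. a
#'   currency-compound list (water, protons, ATP). Nothing is excluded by
#'   default.
#' @return A `reaction_db` object: reaction table, per-reaction substrate /
#'   product / subsystem sets, and a compound table synthesized from all
#'   referenced ids.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("reaction_id\tsubstrates\tproducts\tdirection\tsubsystems",
#'              "R1\tNO3\tNO2\tforward\tNitrogen"), tf)
#' db <- load_reaction_db(tf)
#' reactant_set(db, "R1")
#' @export
load_reaction_db <- function(path, dialect = c("native", "modelseed"),
                             subsystem_map = NULL, exclude_compounds = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "native") {
    tab <- read_tsv_table(path, c("reaction_id", "substrates", "products",
                                  "direction", "subsystems"),
                          "reaction database")
    subs <- split_list_cell(tab$substrates)
    prods <- split_list_cell(tab$products)
    syss <- split_list_cell(tab$subsystems)
    if (nrow(tab) > 0) {
      empty <- vapply(subs, length, 0L) == 0L | vapply(prods, length, 0L) == 0L
      if (any(empty)) {
        stop("reaction(s) with empty substrate or product set: ",
             paste(tab$reaction_id[empty], collapse = ", "))
      }
    }
    db <- new_reaction_db(tab$reaction_id, tolower(tab$direction), subs, prods, syss)
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    idcol <- if ("id" %in% names(tab)) "id" else "reaction_id"
    if (!idcol %in% names(tab) || !"equation" %in% names(tab)) {
      stop("reaction database: missing required column(s): id, equation")
    }
    parsed <- lapply(tab$equation, function(eq) {
      tryCatch(parse_reaction_equation(eq), error = function(e) NULL)
    })
    ok <- !vapply(parsed, is.null, TRUE)
    n_skip <- sum(!ok)
    if (n_skip > 0) {
      warning("skipped ", n_skip, " unparseable equation row(s)")
    }
    parsed <- parsed[ok]
    ids <- tab[[idcol]][ok]
    syss <- rep(list(character(0)), length(ids))
    db <- new_reaction_db(ids,
                          vapply(parsed, `[[`, "", "direction"),
                          lapply(parsed, `[[`, "substrates"),
                          lapply(parsed, `[[`, "products"),
                          syss)
  }
  if (!is.null(subsystem_map)) {
    map <- read_tsv_table(subsystem_map, c("reaction_id", "subsystem"),
                          "subsystem map")
    sp <- split(map$subsystem, map$reaction_id)
    for (rid in intersect(names(sp), db$reactions$reaction_id)) {
      db$subsystems[[rid]] <- sort(unique(c(db$subsystems[[rid]], sp[[rid]])))
    }
  }
  if (!is.null(exclude_compounds)) {
    if (length(exclude_compounds) == 1 && file.exists(exclude_compounds)) {
      exclude_compounds <- readLines(exclude_compounds, warn = FALSE)
      exclude_compounds <- trimws(exclude_compounds)
      exclude_compounds <- exclude_compounds[nzchar(exclude_compounds) &
                                               !startsWith(exclude_compounds, "#")]
    }
    db$substrates <- lapply(db$substrates, setdiff, y = exclude_compounds)
    db$products <- lapply(db$products, setdiff, y = exclude_compounds)
    keep <- !db$compounds$compound_id %in% exclude_compounds
    db$compounds <- db$compounds[keep, , drop = FALSE]
    rownames(db$compounds) <- NULL
  }
  db
}

#' Write a reaction database as native-dialect TSV
#'
#' @param db A `reaction_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_db <- function(db, path) {
  stopifnot(inherits(db, "reaction_db"))
  join <- function(l) vapply(l, paste, "", collapse = ";")
  tab <- data.frame(reaction_id = db$reactions$reaction_id,
                    substrates = join(db$substrates),
                    products = join(db$products),
                    direction = db$reactions$direction,
                    subsystems = join(db$subsystems),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a ModelSEED-style reaction equation
#'
#' Splits an equation string on its arrow token (`<=>`, `=>`, or `<=`),
#' strips parenthesized stoichiometric coefficients and bracketed
#' compartment tags from each `+`-separated term, and returns the consumed
#' and produced compound sets. For `<=` the sides are swapped so that
#' `substrates` always holds the consumed side; `<=>` marks the reaction
#' reversible. Stoichiometry is discarded: overlap counting is
#' presence-based.
#'
#' @param equation Equation text, e.g. `"(1) cpd00001[0] + (2) cpd00002[0] => (1) cpd00003[0]"`.
#' @return A list with `substrates`, `products` (character vectors of
#'   compound ids, duplicates collapsed) and `direction`.
#' @examples
#' parse_reaction_equation("cpd_A <=> cpd_B")
#' @export
parse_reaction_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1)
  if (grepl("<=>", equation, fixed = TRUE)) {
    arrow <- "<=>"; direction <- "reversible"; swap <- FALSE
  } else if (grepl("=>", equation, fixed = TRUE)) {
    arrow <- "=>"; direction <- "forward"; swap <- FALSE
  } else if (grepl("<=", equation, fixed = TRUE)) {
    arrow <- "<="; direction <- "reverse"; swap <- TRUE
  } else {
    stop("no arrow token (<=>, =>, <=) in equation: ", equation)
  }
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("malformed equation: ", equation)
  parse_side <- function(side) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- sub("^\\([^)]*\\)\\s*", "", terms)     # coefficient
    terms <- sub("\\[[^]]*\\]$", "", terms)          # compartment tag
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (!length(terms)) stop("empty side in equation: ", equation)
    unique(terms)
  }
  left <- parse_side(sides[1])
  right <- parse_side(sides[2])
  if (swap) {
    list(substrates = right, products = left, direction = direction)
  } else {
    list(substrates = left, products = right, direction = direction)
  }
}

#' Utilizable reactants of a reaction
#'
#' The set of compounds a reaction lets an organism consume: the substrate
#' side for directed reactions, and by default both sides for reversible
#' reactions (a reversible enzyme can run either way). Set
#' `reversible = "substrates"` to count only the stored substrate side, a
#' sensitivity switch for the reversibility assumption.
#'
#' @param db A `reaction_db`.
#' @param reaction_id A single reaction id present in `db`.
#' @param reversible `"union"` (default) or `"substrates"`.
#' @return Character vector of compound ids.
#' @export
reactant_set <- function(db, reaction_id, reversible = c("union", "substrates")) {
  reversible <- match.arg(reversible)
  stopifnot(inherits(db, "reaction_db"))
  if (!reaction_id %in% db$reactions$reaction_id) {
    stop("unknown reaction id: ", reaction_id)
  }
  reactant_sets(db, reversible)[[reaction_id]]
}

# named list of reactant sets for every reaction in the db
reactant_sets <- function(db, reversible = c("union", "substrates")) {
  reversible <- match.arg(reversible)
  rev_dir <- db$reactions$direction == "reversible"
  out <- db$substrates
  if (reversible == "union" && any(rev_dir)) {
    idx <- which(rev_dir)
    out[idx] <- Map(function(s, p) sort(unique(c(s, p))),
                    db$substrates[idx], db$products[idx])
  }
  out
}

#' @export
print.reaction_db <- function(x, ...) {
  cat("reaction_db:", nrow(x$reactions), "reactions,",
      nrow(x$compounds), "compounds\n")
  sys <- sort(unique(unlist(x$subsystems, use.names = FALSE)))
  if (length(sys)) {
    cat("subsystems:", paste(utils::head(sys, 8), collapse = ", "),
        if (length(sys) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' The 13 metabolism subsystem categories used for subsystem-restricted MO
#'
#' Amino Acid through Sulfur; the default label set assigned by the
#' synthetic generator and matched case-insensitively by
#' [restrict_to_subsystem()].
#'
#' @export
mo_subsystem_categories <- c(
  "Amino Acid", "Aromatic", "Carbohydrates", "Cofactors", "Fatty Acids",
  "Nitrogen", "Nucleoside", "Nucleotide Sugars", "Phosphorus", "Protein",
  "Respiration", "Secondary Metabolism", "Sulfur"
)
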