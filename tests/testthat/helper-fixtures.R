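# Shared fixtures and independent oracles. The oracles deliberately use
# naive loops / textbook formulas so they share no code path with the
# package implementation they check.

# Native-dialect TSV for the toy denitrification example: one full
# denitrifier worth of reactions plus two unrelated sulfur reactions.
write_denitrification_db <- function(path = tempfile(fileext = ".tsv"),
                                     extra = TRUE) {
  lines <- c(
    "reaction_id\tsubstrates\tproducts\tdirection\tsubsystems",
    "den1\tNO3\tNO2\tforward\tNitrogen",
    "den2\tNO2\tNO\tforward\tNitrogen",
    "den3\tNO\tN2O\tforward\tNitrogen",
    "den4\tN2O\tN2\tforward\tNitrogen")
  if (extra) {
    lines <- c(lines,
      "sul1\tSO4\tSO3\tforward\tSulfur",
      "sul2\tSO3;H2\tH2S\treversible\tSulfur")
  }
  writeLines(lines, path)
  path
}

toy_db <- function(...) load_reaction_db(write_denitrification_db(...))

# Brute-force MO oracle: per-compound membership counting over the union of
# both profiles (no set operations from the implementation path).
oracle_pairwise_mo <- function(a, b) {
  universe <- unique(c(a, b))
  count <- 0L
  for (cpd in universe) {
    in_a <- any(a == cpd)
    in_b <- any(b == cpd)
    if (in_a && in_b) count <- count + 1L
  }
  count
}

# Brute-force reactant profile: loop over reactions, re-deriving the
# utilizable side from the db fields directly.
oracle_profile <- function(reaction_ids, db) {
  out <- character(0)
  for (rid in reaction_ids) {
    i <- which(db$reactions$reaction_id == rid)
    if (!length(i)) next
    r <- db$substrates[[i]]
    if (db$reactions$direction[i] == "reversible") {
      r <- c(r, db$products[[i]])
    }
    out <- c(out, r)
  }
  sort(unique(out))
}

oracle_overlap_matrix <- function(annotations, db) {
  profiles <- lapply(annotations, oracle_profile, db = db)
  n <- length(profiles)
  m <- matrix(0L, n, n, dimnames = list(names(annotations), names(annotations)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- oracle_pairwise_mo(profiles[[i]], profiles[[j]])
    }
  }
  m
}

# Cophenetic oracle: root-distance + ancestor-set LCA computed straight from
# the edge table.
oracle_cophenetic <- function(tree) {
  tr <- ape::read.tree(text = tree)
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tr$edge))
  blen_to_parent <- numeric(max(tr$edge))
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  blen_to_parent[tr$edge[, 2]] <- tr$edge.length
  path_to_root <- function(node) {
    nodes <- node
    while (node != root) {
      node <- parent_of[node]
      nodes <- c(nodes, node)
    }
    nodes
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + blen_to_parent[node]
      node <- parent_of[node]
    }
    d
  }
  m <- matrix(0, n_tip, n_tip, dimnames = list(tr$tip.label, tr$tip.label))
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      if (i == j) next
      anc_i <- path_to_root(i)
      anc_j <- path_to_root(j)
      lca <- anc_i[anc_i %in% anc_j][1]
      m[i, j] <- depth(i) + depth(j) - 2 * depth(lca)
    }
  }
  m
}

# Textbook Kruskal-Wallis H with tie correction.
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Random genome repertoires over a db.
random_annotations <- function(n_genomes, db, min_rxn = 5, max_rxn = NULL) {
  rids <- db$reactions$reaction_id
  if (is.null(max_rxn)) max_rxn <- length(rids)
  out <- lapply(seq_len(n_genomes), function(i) {
    sample(rids, sample(min_rxn:max_rxn, 1))
  })
  names(out) <- paste0("g", seq_len(n_genomes))
  out
}

random_symmetric_matrix <- function(n, ids = paste0("g", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}
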