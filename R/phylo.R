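as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1)
  tr <- if (grepl("(", tree, fixed = TRUE)) {
    tryCatch(suppressWarnings(ape::read.tree(text = tree)),
             error = function(e) NULL)
  } else {
    if (!file.exists(tree)) stop("tree file not found: ", tree)
    tryCatch(suppressWarnings(ape::read.tree(tree)), error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo")) stop("malformed newick tree")
  tr
}

#' Cophenetic (patristic) distance matrix from a tree
#'
#' Distances are sums of branch lengths along the tip-to-tip path, extracted
#' with `ape`'s cophenetic function; the diagonal is zero.
#'
#' @param tree A `phylo` object, a newick string, or a path to a newick
#'   file. Branch lengths are required.
#' @param tip_subset Optional tip labels to keep, in the given order; labels
#'   absent from the tree are dropped with a warning.
#' @return Square symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_matrix <- function(tree, tip_subset = NULL) {
  tr <- as_phylo_tree(tree)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tr)
  if (!is.null(tip_subset)) {
    missing <- setdiff(tip_subset, rownames(d))
    if (length(missing)) {
      warning("tip(s) not in tree, dropped: ", paste(missing, collapse = ", "))
    }
    keep <- tip_subset[tip_subset %in% rownames(d)]
    if (!length(keep)) stop("no requested tips present in the tree")
    d <- d[keep, keep, drop = FALSE]
  }
  d
}

align_matrices <- function(d1, d2) {
  ids1 <- rownames(d1)
  ids2 <- rownames(d2)
  if (is.null(ids1) || is.null(ids2)) stop("both matrices need id dimnames")
  if (!setequal(ids1, ids2)) {
    diff <- c(setdiff(ids1, ids2), setdiff(ids2, ids1))
    stop("matrix ids do not match; symmetric difference: ",
         paste(diff, collapse = ", "))
  }
  list(d1 = d1, d2 = d2[ids1, ids1, drop = FALSE])
}

assoc_result <- function(statistic_name, r, p_value, n, n_permutations = 0L,
                         seed = NA_integer_, degenerate = FALSE) {
  structure(list(statistic_name = statistic_name, r = unname(r),
                 p_value = unname(p_value), n = n,
                 n_permutations = n_permutations, seed = seed,
                 degenerate = degenerate),
            class = "mo_assoc")
}

#' @export
print.mo_assoc <- function(x, ...) {
  cat(x$statistic_name, "association: r =", format(x$r, digits = 4),
      ", p =", format(x$p_value, digits = 4), ", n =", x$n)
  if (x$n_permutations > 0) cat(" (", x$n_permutations, "permutations )")
  if (isTRUE(x$degenerate)) cat(" [degenerate: constant input]")
  cat("\n")
  invisible(x)
}

#' Mantel permutation test between two distance-like matrices
#'
#' Correlates the strict lower triangles of two square matrices over the
#' same genomes and assesses significance by simultaneously permuting the
#' rows and columns of the second matrix. The two-sided p-value uses the
#' add-one correction: `(#{|r_perm| >= |r_obs|} + 1) / (n_perm + 1)`.
#'
#' @param d_phylo,d_mo Square symmetric matrices with identical id sets as
#'   dimnames (order may differ; `d_mo` is aligned to `d_phylo`). At least
#'   3 genomes.
#' @param method Correlation method: `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed; recorded in the result so runs are
#'   reproducible.
#' @return An `mo_assoc` result (`r`, `p_value`, `n`, `n_permutations`,
#'   `seed`).
#' @export
mantel_test <- function(d_phylo, d_mo, method = c("spearman", "pearson"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  al <- align_matrices(d_phylo, d_mo)
  n <- nrow(al$d1)
  if (n < 3) stop("mantel_test needs at least 3 genomes")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(al$d1)
  x <- al$d1[lt]
  y <- al$d2[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(assoc_result(method, NA_real_, NA_real_, n, as.integer(n_perm),
                        if (is.null(seed)) NA_integer_ else seed,
                        degenerate = TRUE))
  }
  if (method == "spearman") { x <- rank(x); y0 <- al$d2 } else y0 <- al$d2
  r_obs <- if (method == "spearman") {
    stats::cor(x, rank(y))
  } else {
    stats::cor(x, y)
  }
  r_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- y0[p, p][lt]
    r_perm[i] <- if (method == "spearman") stats::cor(x, rank(yp)) else stats::cor(x, yp)
  }
  p_value <- (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1)
  assoc_result(method, r_obs, p_value, n, as.integer(n_perm),
               if (is.null(seed)) NA_integer_ else seed)
}

#' Plain rank correlation over pairwise comparisons
#'
#' Correlates the strict lower triangles of two matrices directly (no
#' permutation), as done when pooling pairwise genome comparisons into a
#' scatter of phylogenetic distance against MO; the p-value comes from the
#' standard large-sample approximation.
#'
#' @param d_phylo,d_mo As for [mantel_test()].
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return An `mo_assoc` result with `n_permutations = 0`. A constant
#'   input vector yields a flagged degenerate result with `NA` correlation.
#' @export
pairwise_scatter_correlation <- function(d_phylo, d_mo,
                                         method = c("spearman", "kendall")) {
  method <- match.arg(method)
  al <- align_matrices(d_phylo, d_mo)
  n <- nrow(al$d1)
  if (n < 3) stop("pairwise_scatter_correlation needs at least 3 genomes")
  lt <- lower.tri(al$d1)
  x <- al$d1[lt]
  y <- al$d2[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(assoc_result(method, NA_real_, NA_real_, n, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  assoc_result(method, ct$estimate, ct$p.value, n)
}
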