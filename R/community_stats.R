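rank_correlation <- function(x, y, method) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(assoc_result(method, NA_real_, NA_real_, n, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  assoc_result(method, ct$estimate, ct$p.value, n)
}

#' Correlation between community richness and MO
#'
#' Rank correlation between the number of genomes recovered per study and
#' the study's central MO, across communities. More diverse communities are
#' expected to show lower overlap (negative correlation).
#'
#' @param summaries Data frame from [summarize_communities()] (columns
#'   `n_genomes`, `mo_central`); at least 3 communities.
#' @param method `"kendall"` (default) or `"spearman"`.
#' @return An `mo_assoc` result; a constant MO vector yields a flagged
#'   degenerate result.
#' @export
richness_mo_correlation <- function(summaries, method = c("kendall", "spearman")) {
  method <- match.arg(method)
  rank_correlation(summaries$n_genomes, summaries$mo_central, method)
}

#' Correlation between genome size and MO
#'
#' Rank correlation of genome size against MO, either at the community
#' level (pass a summary data frame: `median_genome_size_bp` vs
#' `mo_central`) or on explicit vectors of genome-level sizes and MO values.
#'
#' @param size Summary data frame, or numeric vector of sizes in bp.
#' @param mo Numeric vector of MO values (ignored when `size` is a data
#'   frame).
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return An `mo_assoc` result.
#' @export
size_mo_correlation <- function(size, mo = NULL,
                                method = c("spearman", "kendall")) {
  method <- match.arg(method)
  if (is.data.frame(size)) {
    mo <- size$mo_central
    size <- size$median_genome_size_bp
  }
  rank_correlation(size, mo, method)
}

# Dunn post-hoc z statistics on the pooled ranks, with tie correction.
dunn_contrasts <- function(values, groups, adjust) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  labels <- names(mean_rank)
  pairs <- utils::combn(labels, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             statistic = z, p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = adjust),
             stringsAsFactors = FALSE)
}

#' Ecosystem contrasts of (normalized) MO
#'
#' Kruskal-Wallis omnibus test of a community summary response across
#' ecosystem groups, followed by Dunn z post-hoc tests on all group pairs
#' with multiplicity adjustment (Holm by default).
#'
#' @param summaries Data frame from [summarize_communities()] with an
#'   `ecosystem` column.
#' @param response Name of the response column (default `"normalized_mo"`).
#' @param adjust p-value adjustment for the contrasts: `"holm"`, `"BH"` or
#'   `"none"`.
#' @return A list of class `ecosystem_contrast`: `omnibus` (chi-squared H
#'   statistic, degrees of freedom, p-value, n) and `contrasts` (one row per
#'   unordered group pair).
#' @export
ecosystem_contrast <- function(summaries, response = "normalized_mo",
                               adjust = c("holm", "BH", "none")) {
  adjust <- match.arg(adjust)
  if (!response %in% names(summaries)) stop("no such response column: ", response)
  values <- summaries[[response]]
  groups <- factor(summaries$ecosystem)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 ecosystem groups")
  if (any(sizes < 2)) {
    stop("ecosystem group(s) with fewer than 2 communities: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  kw <- stats::kruskal.test(values, groups)
  structure(list(
    omnibus = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value,
                   n = length(values)),
    contrasts = dunn_contrasts(values, groups, adjust),
    response = response, adjust = adjust
  ), class = "ecosystem_contrast")
}

#' @export
print.ecosystem_contrast <- function(x, ...) {
  cat("Kruskal-Wallis on", x$response, ": chi-squared =",
      format(x$omnibus$statistic, digits = 4), ", df =", x$omnibus$df,
      ", p =", format(x$omnibus$p_value, digits = 4), "\n")
  cat("Dunn contrasts (", x$adjust, "adjustment ):\n")
  print(x$contrasts, ...)
  invisible(x)
}

#' One-way ANOVA of genome size across ecosystems
#'
#' Gaussian-theory F test of genome size against ecosystem label, a thin
#' companion to [ecosystem_contrast()] for the size covariate.
#'
#' @param metadata Data frame with `genome_size_bp` and `ecosystem` columns
#'   (genome-level metadata or community summaries with those names).
#' @return List with `F`, `df`, `df_residual`, `p_value`.
#' @export
genome_size_anova <- function(metadata) {
  groups <- factor(metadata$ecosystem)
  if (nlevels(groups) < 2) stop("need at least 2 ecosystem groups")
  ft <- stats::oneway.test(metadata$genome_size_bp ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), df = unname(ft$parameter[1]),
       df_residual = unname(ft$parameter[2]), p_value = ft$p.value)
}
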