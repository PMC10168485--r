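#' Per-gene variant-load matrix by phenotype group
#'
#' Sums qualifying variant alleles per gene within each phenotype group:
#' heterozygotes contribute 1 allele, homozygous alternates 2 (homoplasmic
#' mitochondrial calls having been coded homozygous upstream), missing
#' genotypes 0. A carrier-count mode (any alternate allele contributes 1)
#' is available behind `count = "carrier"`.
#'
#' @param consensus Integer consensus genotype matrix (variants x
#'   samples), e.g. `consensus_qc()$consensus`.
#' @param genes Character vector of gene symbols, one per variant row.
#'   Variants with `NA`/empty gene annotation are excluded and counted in
#'   the attribute `n_unannotated`.
#' @param groups Named character vector mapping sample id to group label;
#'   samples absent from `groups` are ignored.
#' @param count `"allele"` (default) or `"carrier"`.
#' @return Integer matrix genes x groups with attribute `n_unannotated`.
#' @export
count_variants_per_gene <- function(consensus, genes, groups,
                                    count = c("allele", "carrier")) {
  count <- match.arg(count)
  stopifnot(length(genes) == nrow(consensus))
  samples <- intersect(colnames(consensus), names(groups))
  g <- consensus[, samples, drop = FALSE]
  if (count == "carrier") g <- (g > 0L) * 1L
  g[is.na(g)] <- 0L
  annotated <- !is.na(genes) & genes != ""
  grp <- factor(groups[samples])
  # per-variant load per group, then sum within gene
  per_group <- matrix(0, nrow(g), nlevels(grp),
                      dimnames = list(NULL, levels(grp)))
  for (lv in levels(grp))
    per_group[, lv] <- rowSums(g[, grp == lv, drop = FALSE])
  out <- rowsum(per_group[annotated, , drop = FALSE], genes[annotated])
  storage.mode(out) <- "integer"
  attr(out, "n_unannotated") <- sum(!annotated)
  out
}

#' Regression-residual outlier genes between two phenotype groups
#'
#' Ordinary least squares of `response ~ predictor` across genes on the
#' per-gene variant loads, then a robust residual rule: with Q1 and Q3 the
#' first and third quartiles of the residuals (linear-interpolation
#' quantiles) and `D = Q3 - Q1` the interquartile distance, genes with
#' residuals above `Q3 + 6D` carry an exceptionally high load in the
#' response group, and genes below `Q1 - 6D` an exceptionally high load in
#' the predictor group.
#'
#' @param load Genes x groups count matrix from
#'   [count_variants_per_gene()].
#' @param predictor,response Group (column) labels.
#' @param k Multiplier of the interquartile distance (default 6,
#'   deliberately extreme so that only clear outliers are flagged).
#' @return A list of class `outlier_fit`: `comparison`, `slope`,
#'   `intercept`, `residuals` (named per gene), `Q1`, `Q3`, `D`,
#'   `upper_cut`, `lower_cut`, `high_in_response`, `high_in_predictor`.
#' @export
fit_outliers <- function(load, predictor, response, k = 6) {
  stopifnot(predictor %in% colnames(load), response %in% colnames(load))
  x <- as.numeric(load[, predictor])
  y <- as.numeric(load[, response])
  if (length(x) < 8L)
    stop("need at least 8 genes for stable residual quartiles")
  if (stats::var(x) == 0) stop("zero variance in predictor group loads")
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- stats::setNames(as.numeric(fit$residuals), rownames(load))
  cuts <- residual_cuts(res, k)
  # guard against pure floating-point noise when the fit is exact
  tol <- 1e-8 * max(1, max(abs(res)))
  structure(c(list(comparison = c(predictor = predictor,
                                  response = response),
                   slope = unname(fit$coefficients[2]),
                   intercept = unname(fit$coefficients[1]),
                   residuals = res),
              cuts,
              list(high_in_response =
                     names(res)[res > cuts$upper_cut + tol],
                   high_in_predictor =
                     names(res)[res < cuts$lower_cut - tol])),
            class = "outlier_fit")
}

# Quartiles (linear-interpolation definition), interquartile distance and
# the +/- k*D outlier cutpoints of a residual vector.
residual_cuts <- function(res, k = 6) {
  q <- stats::quantile(res, c(0.25, 0.75), names = FALSE, type = 7)
  d <- q[2] - q[1]
  list(Q1 = q[1], Q3 = q[2], D = d,
       upper_cut = q[2] + k * d, lower_cut = q[1] - k * d)
}

#' @export
print.outlier_fit <- function(x, ...) {
  cat(sprintf("outlier_fit: %s ~ %s over %d genes\n",
              x$comparison[["response"]], x$comparison[["predictor"]],
              length(x$residuals)))
  cat(sprintf("  slope %.3f, intercept %.3f; Q1 %.3f Q3 %.3f D %.3f\n",
              x$slope, x$intercept, x$Q1, x$Q3, x$D))
  cat(sprintf("  high in response: %d gene(s); high in predictor: %d gene(s)\n",
              length(x$high_in_response), length(x$high_in_predictor)))
  invisible(x)
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided over-representation p-value `P(X >= overlap)` for the overlap
#' between an outlier gene list and a curated gene set, both restricted to
#' the analysis universe (genes with at least one called variant).
#'
#' @param list_genes Character vector, the outlier list (must lie within
#'   `universe`).
#' @param universe Character vector of all genes assessed.
#' @param geneset Character vector, the curated set; intersected with
#'   `universe` before testing.
#' @return A one-row data frame: `list_size`, `universe_size`,
#'   `geneset_size`, `overlap`, `p_raw`.
#' @export
enrich_geneset <- function(list_genes, universe, geneset) {
  universe <- unique(universe)
  list_genes <- unique(list_genes)
  if (!all(list_genes %in% universe))
    stop("outlier list contains genes outside the universe")
  set_in_u <- unique(intersect(geneset, universe))
  overlap <- length(intersect(list_genes, set_in_u))
  n_u <- length(universe); n_s <- length(set_in_u)
  n_l <- length(list_genes)
  p <- if (n_l == 0L) 1 else
    stats::phyper(overlap - 1L, n_s, n_u - n_s, n_l, lower.tail = FALSE)
  data.frame(list_size = n_l, universe_size = n_u, geneset_size = n_s,
             overlap = overlap, p_raw = p)
}

#' Enrichment of several outlier lists against several gene sets
#'
#' Runs [enrich_geneset()] for every list x set pair and adjusts the
#' p-values across all tests in the run.
#'
#' @param lists Named list of outlier gene vectors.
#' @param universe Analysis universe.
#' @param genesets Named list of curated gene sets.
#' @param adjust Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @return Data frame with one row per list x set pair, columns `list`,
#'   `geneset`, the [enrich_geneset()] columns, `p_adjusted` and
#'   `adjust_method`.
#' @export
enrichment_table <- function(lists, universe, genesets,
                             adjust = "bonferroni") {
  rows <- list()
  for (ln in names(lists)) for (sn in names(genesets)) {
    r <- enrich_geneset(lists[[ln]], universe, genesets[[sn]])
    rows[[length(rows) + 1L]] <- cbind(data.frame(list = ln, geneset = sn,
                                                  stringsAsFactors = FALSE),
                                       r)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out$adjust_method <- adjust
  rownames(out) <- NULL
  out
}

#' Combine outlier lists and count Venn-region overlaps
#'
#' Unions the outlier lists within each named analysis, then computes the
#' size of every intersection region across analyses, plus membership
#' annotation against optional curated sets.
#'
#' @param analyses Named list; each element is a list/vector of gene
#'   vectors belonging to one analysis (e.g. one cohort).
#' @param annotate Optional named list of curated sets used to annotate
#'   the combined and common lists.
#' @return A list: `combined` (per-analysis union), `common`
#'   (intersection of all analyses), `venn` (named region counts,
#'   e.g. `"A&B"`), and `annotation` (counts of curated-set members in
#'   each per-analysis union and in `common`).
#' @export
combine_and_intersect <- function(analyses, annotate = NULL) {
  combined <- lapply(analyses, function(a)
    sort(unique(unlist(a, use.names = FALSE))))
  nm <- names(combined)
  if (is.null(nm) || any(nm == "")) stop("analyses must be named")
  regions <- list()
  for (size in seq_along(nm)) {
    for (combo in utils::combn(nm, size, simplify = FALSE)) {
      inside <- Reduce(intersect, combined[combo])
      outside <- unique(unlist(combined[setdiff(nm, combo)],
                               use.names = FALSE))
      regions[[paste(combo, collapse = "&")]] <-
        length(setdiff(inside, outside))
    }
  }
  common <- Reduce(intersect, combined)
  annotation <- NULL
  if (!is.null(annotate)) {
    tab <- c(combined, list(common = common))
    annotation <- sapply(annotate, function(set)
      vapply(tab, function(g) length(intersect(g, set)), integer(1)))
  }
  list(combined = combined, common = common,
       venn = unlist(regions), annotation = annotation)
}
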