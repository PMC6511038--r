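# Gene-set inference on the PLS-ranked gene list: median-rank resampling
# enrichment, sign-concordance with differential-expression labels, and
# edge-count permutation on an interaction network.

# Accepts either a gene_table (uses its rank column) or a character vector
# already in rank order (best first); returns ranks named by gene.
.gene_ranks <- function(ranked_genes) {
  if (inherits(ranked_genes, "gene_table") ||
      (is.data.frame(ranked_genes) && all(c("gene_id", "rank") %in%
                                          names(ranked_genes)))) {
    setNames(ranked_genes$rank, ranked_genes$gene_id)
  } else if (is.character(ranked_genes)) {
    setNames(seq_along(ranked_genes), ranked_genes)
  } else stop("`ranked_genes` must be a gene_table or a character vector",
              call. = FALSE)
}

#' Median-rank resampling enrichment test
#'
#' Tests whether a gene set sits unusually high (or low) in the PLS
#' ranking by comparing its observed median rank with the median ranks of
#' randomly drawn same-size sets from a background universe (e.g., all
#' brain-expressed genes). Ranks are recomputed within the universe, so
#' the test depends only on the ordering, not the underlying scores.
#'
#' @param ranked_genes a \code{gene_table} (from
#'   \code{\link{bootstrap_gene_weights}}) or a character vector of gene
#'   ids in rank order (best first).
#' @param target_set character vector of gene ids to test.
#' @param universe background gene universe; defaults to all ranked genes.
#'   The target is intersected with it; genes dropped in the intersection
#'   are reported in the result.
#' @param n_resample number of random sets (default 10000, minimum 100).
#' @param alternative \code{"low"}: target is nearer the top (small ranks)
#'   than chance; \code{"high"}: nearer the bottom; \code{"two.sided"}:
#'   doubles the smaller tail (capped at 1).
#' @param seed RNG seed.
#' @return list with \code{observed_median_rank}, \code{expected}
#'   (null mean), \code{p} (add-one convention), \code{n_target},
#'   \code{n_dropped}.
#' @export
median_rank_enrichment <- function(ranked_genes, target_set, universe = NULL,
                                   n_resample = 10000,
                                   alternative = c("low", "high", "two.sided"),
                                   seed = 1L) {
  alternative <- match.arg(alternative)
  if (n_resample < 100) stop("`n_resample` must be at least 100", call. = FALSE)
  ranks <- .gene_ranks(ranked_genes)
  if (is.null(universe)) universe <- names(ranks)
  universe <- intersect(universe, names(ranks))
  target <- intersect(target_set, universe)
  n_dropped <- length(target_set) - length(target)
  if (!length(target))
    stop("target set is disjoint from the universe", call. = FALSE)
  uranks <- rank(ranks[universe], ties.method = "first")
  names(uranks) <- universe
  k <- length(target)
  obs <- median(uranks[target])
  null <- with_seed(seed, replicate(n_resample,
    median(uranks[sample.int(length(uranks), k)])))
  p_low <- perm_pvalue(sum(null <= obs), n_resample)
  p_high <- perm_pvalue(sum(null >= obs), n_resample)
  p <- switch(alternative,
              low = p_low, high = p_high,
              two.sided = min(1, 2 * min(p_low, p_high)))
  list(observed_median_rank = unname(obs), expected = mean(null), p = p,
       n_target = k, n_dropped = n_dropped)
}

#' Median-rank enrichment over a collection of gene sets
#'
#' Applies \code{\link{median_rank_enrichment}} to each set of a GMT-style
#' collection and controls FDR across sets.
#'
#' @inheritParams median_rank_enrichment
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param q FDR level across sets.
#' @return data.frame: set, n_overlap, observed_median_rank, expected, p,
#'   fdr_significant.
#' @export
enrich_gene_sets <- function(ranked_genes, gene_sets, universe = NULL,
                             n_resample = 10000,
                             alternative = c("low", "high", "two.sided"),
                             q = 0.05, seed = 1L) {
  alternative <- match.arg(alternative)
  rows <- lapply(names(gene_sets), function(nm) {
    res <- median_rank_enrichment(ranked_genes, gene_sets[[nm]],
                                  universe = universe,
                                  n_resample = n_resample,
                                  alternative = alternative, seed = seed)
    data.frame(set = nm, n_overlap = res$n_target,
               observed_median_rank = res$observed_median_rank,
               expected = res$expected, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_significant <- fdr_bh(out$p, q = q)
  out
}

#' Sign-concordance test of PLS weights against labeled gene sets
#'
#' Two-sample Wilcoxon rank-sum test comparing the PLS1 Z-scores (or
#' weights) of genes labeled up-regulated versus down-regulated in an
#' external differential-expression study. A nonrandom split indicates
#' that the sign of a gene's PLS weight tracks the sign of its
#' case-control expression change.
#'
#' @param gene_table a \code{gene_table}.
#' @param up_set,down_set character vectors of gene ids carrying the
#'   external up/down labels.
#' @param value which column to compare: \code{"z_score"} (default) or
#'   \code{"pls1_weight"}.
#' @return list with \code{statistic} (rank-sum W), \code{p},
#'   \code{direction} (which label group has the lower values),
#'   \code{n_up}, \code{n_down}.
#' @export
sign_concordance_test <- function(gene_table, up_set, down_set,
                                  value = c("z_score", "pls1_weight")) {
  value <- match.arg(value)
  x <- setNames(gene_table[[value]], gene_table$gene_id)
  up <- x[intersect(up_set, names(x))]
  down <- x[intersect(down_set, names(x))]
  if (!length(up) || !length(down))
    stop("both label groups must intersect the analysis universe",
         call. = FALSE)
  wt <- suppressWarnings(wilcox.test(up, down))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = if (median(up) < median(down)) "up-labeled lower"
                   else "down-labeled lower",
       n_up = length(up), n_down = length(down))
}

# Normalize an edge list: two columns, character, no self-loops, one row
# per unordered pair.
.normalize_edges <- function(edges) {
  e <- data.frame(from = as.character(edges[[1]]),
                  to = as.character(edges[[2]]), stringsAsFactors = FALSE)
  e <- e[e$from != e$to, ]
  key <- ifelse(e$from < e$to, paste(e$from, e$to), paste(e$to, e$from))
  e[!duplicated(key), ]
}

#' Edge-count enrichment of a gene set in an interaction network
#'
#' Counts the interaction edges with both endpoints inside the gene set
#' and compares the count with a null built by drawing same-size sets
#' uniformly from the universe. A planted functional module yields more
#' internal edges than chance.
#'
#' @param edges two-column data.frame (or matrix) of undirected
#'   interactions; self-loops and duplicate pairs are removed, and edges
#'   with endpoints outside \code{universe} are dropped.
#' @param gene_set character vector, a subset of \code{universe}.
#' @param universe character vector of all candidate genes.
#' @param n_perm number of null sets (default 10000).
#' @param seed RNG seed.
#' @return list with \code{observed_edges}, \code{expected_edges} (null
#'   mean), \code{p} (upper tail, add-one convention), \code{n_set}.
#' @export
ppi_edge_enrichment <- function(edges, gene_set, universe, n_perm = 10000,
                                seed = 1L) {
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stop("`gene_set` must be a subset of `universe`", call. = FALSE)
  if (length(gene_set) > length(universe))
    stop("gene set larger than universe", call. = FALSE)
  e <- .normalize_edges(edges)
  ia <- match(e$from, universe)
  ib <- match(e$to, universe)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  member <- logical(length(universe))
  member[match(gene_set, universe)] <- TRUE
  observed <- sum(member[ia] & member[ib])
  k <- length(gene_set)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    m <- logical(length(universe))
    m[sample.int(length(universe), k)] <- TRUE
    sum(m[ia] & m[ib])
  }, numeric(1)))
  list(observed_edges = observed, expected_edges = mean(null),
       p = perm_pvalue(sum(null >= observed), n_perm), n_set = k)
}
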