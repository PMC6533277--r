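# Gene-set enrichment of DE lists and cross-disorder pathway comparisons.
#
# Over-representation is scored by the one-sided hypergeometric tail
# (Fisher's exact test for enrichment) against an explicit gene universe.
# Direction is handled by scoring up- and downregulated DE genes separately
# and reporting the net enrichment score
#   net = -log10(p_up) - ( -log10(p_down) ),
# positive when upregulated genes drive the enrichment.

#' Fisher's exact over-representation test for one gene set
#'
#' @param de Character vector of differentially expressed genes.
#' @param set Character vector of gene-set members.
#' @param universe Background gene list; `de` and `set` are intersected with
#'   it before testing.
#' @return List with `overlap`, `set_size` (in universe), `de_size`,
#'   `universe_size`, `p` (one-sided hypergeometric tail).
#' @export
#' @examples
#' fisher_enrichment(de = c("g1", "g2", "g3"), set = c("g1", "g2", "g9"),
#'                   universe = paste0("g", 1:20))
fisher_enrichment <- function(de, set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  de <- intersect(unique(as.character(de)), universe)
  set <- intersect(unique(as.character(set)), universe)
  k <- length(intersect(de, set))
  N <- length(universe); K <- length(set); n <- length(de)
  p <- if (n == 0 || K == 0) 1 else
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, set_size = K, de_size = n, universe_size = N,
       p = min(1, p))
}

#' Directional enrichment scores for one gene set
#'
#' Scores the up- and downregulated DE lists separately and reports
#' `score_up = -log10(p_up)`, `score_down = -log10(p_down)` and their
#' difference (`net_score`), positive when enrichment is driven by
#' upregulated genes.
#'
#' @param up,down Disjoint character vectors of up-/downregulated genes.
#' @param set Gene-set members.
#' @param universe Background gene list.
#' @return List with `score_up`, `score_down`, `net_score`, `p_up`,
#'   `p_down`, `overlap_up`, `overlap_down`.
#' @export
directional_scores <- function(up, down, set, universe) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both) > 0)
    stop_listing("genes appear in both the up and the down list", both)
  e_up <- fisher_enrichment(up, set, universe)
  e_down <- fisher_enrichment(down, set, universe)
  list(score_up = -log10(e_up$p), score_down = -log10(e_down$p),
       net_score = -log10(e_up$p) + log10(e_down$p),
       p_up = e_up$p, p_down = e_down$p,
       overlap_up = e_up$overlap, overlap_down = e_down$overlap)
}

#' Overlap test between two sets of enriched pathways
#'
#' Fisher's exact test (one-sided, over-representation) on the 2x2 table of
#' membership in `enrichedA` versus `enrichedB` across all tested pathways,
#' as used to ask whether two disorders share more enriched pathways than
#' chance.
#'
#' @param enrichedA,enrichedB Names of pathways enriched in each condition;
#'   must be subsets of `all_tested`.
#' @param all_tested Names of all pathways tested in both conditions.
#' @return List with `overlap`, `n_a`, `n_b`, `n_tested`, `p`,
#'   `significant` (p < 0.05).
#' @export
enriched_pathway_overlap <- function(enrichedA, enrichedB, all_tested) {
  all_tested <- unique(as.character(all_tested))
  if (length(all_tested) == 0) stop("empty set of tested pathways", call. = FALSE)
  enrichedA <- unique(as.character(enrichedA))
  enrichedB <- unique(as.character(enrichedB))
  badA <- setdiff(enrichedA, all_tested)
  if (length(badA) > 0) stop_listing("enrichedA pathway(s) not in all_tested", badA)
  badB <- setdiff(enrichedB, all_tested)
  if (length(badB) > 0) stop_listing("enrichedB pathway(s) not in all_tested", badB)
  inA <- all_tested %in% enrichedA
  inB <- all_tested %in% enrichedB
  k <- sum(inA & inB)
  tab <- matrix(c(k, sum(inA & !inB), sum(!inA & inB), sum(!inA & !inB)),
                nrow = 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(overlap = k, n_a = sum(inA), n_b = sum(inB),
       n_tested = length(all_tested), p = p, significant = p < 0.05)
}

#' Score a gene-set collection against DE lists for all conditions
#'
#' For every (set, diagnosis, region) combination, computes the pooled
#' enrichment p (up and down lists combined), the directional scores, and
#' the net enrichment score.
#'
#' @param de_lists Nested list from [select_de_genes()].
#' @param gsc A [gene_set_collection()].
#' @param universe Background genes (defaults to the collection's universe,
#'   which must then be set).
#' @return data.frame of class `"enrichment_result"` with one row per (set,
#'   diagnosis, region): overlap counts, sizes, `p`, `score`, `score_up`,
#'   `score_down`, `net_score`, `enriched` (p < 0.05).
#' @export
enrich_de_lists <- function(de_lists, gsc, universe = gsc$universe) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  if (is.null(universe)) stop("a gene universe is required", call. = FALSE)
  rows <- list()
  for (d in names(de_lists)) {
    for (r in names(de_lists[[d]])) {
      up <- de_lists[[d]][[r]]$up
      down <- de_lists[[d]][[r]]$down
      for (s in names(gsc$sets)) {
        set <- gsc$sets[[s]]
        pooled <- fisher_enrichment(c(up, down), set, universe)
        dir <- directional_scores(up, down, set, universe)
        rows[[length(rows) + 1L]] <- data.frame(
          set = s, diagnosis = d, region = r,
          overlap = pooled$overlap, set_size = pooled$set_size,
          de_size = pooled$de_size, universe_size = pooled$universe_size,
          p = pooled$p, score = -log10(pooled$p),
          score_up = dir$score_up, score_down = dir$score_down,
          net_score = dir$net_score, enriched = pooled$p < 0.05,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), diagnosis = character(0),
               region = character(0))
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Net-enrichment-score matrix for the top pathways
#'
#' Rows are the `top_n` pathways ranked by their maximum absolute net score
#' over the reference diagnosis' conditions (ties broken lexicographically
#' by set name); columns are all (diagnosis, region) conditions.
#'
#' @param results An `enrichment_result` from [enrich_de_lists()].
#' @param top_n Number of pathways to keep (default 50); truncated with a
#'   warning if fewer were tested.
#' @param reference_diagnosis Diagnosis whose conditions drive the ranking
#'   (default `"SCZ"`).
#' @return Numeric matrix (pathways x conditions) of net scores, column
#'   names `diagnosis.region`.
#' @export
net_score_matrix <- function(results, top_n = 50, reference_diagnosis = "SCZ") {
  stopifnot(nrow(results) > 0)
  sets <- sort(unique(results$set))
  conds <- unique(results[, c("diagnosis", "region")])
  conds <- conds[order(match(conds$diagnosis, DIAGNOSIS_LEVELS),
                       match(conds$region, REGION_LEVELS)), , drop = FALSE]
  cond_names <- paste(conds$diagnosis, conds$region, sep = ".")
  mat <- matrix(0, length(sets), nrow(conds),
                dimnames = list(sets, cond_names))
  for (i in seq_len(nrow(results)))
    mat[results$set[i],
        paste(results$diagnosis[i], results$region[i], sep = ".")] <-
      results$net_score[i]
  ref_cols <- which(conds$diagnosis == reference_diagnosis)
  if (length(ref_cols) == 0)
    stop("reference diagnosis ", reference_diagnosis, " not among the conditions")
  key <- apply(abs(mat[, ref_cols, drop = FALSE]), 1, max)
  ord <- order(-key, sets)
  if (top_n > length(sets)) {
    warning(sprintf("top_n = %d exceeds the %d pathways tested; truncating",
                    top_n, length(sets)))
    top_n <- length(sets)
  }
  mat[ord[seq_len(top_n)], , drop = FALSE]
}

#' Write a net-score matrix as TSV
#'
#' @param mat Matrix from [net_score_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_net_score_matrix <- function(mat, path) {
  df <- data.frame(pathway = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
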