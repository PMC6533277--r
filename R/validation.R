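# qRT-PCR validation arm: reference-gene stability selection, geometric-mean
# normalization, and mixed-model analysis of normalized quantities (or
# cytokine concentrations) via the shared ANCOVA machinery.

#' Construct a qPCR plate table
#'
#' @param df data.frame with columns `sample_id`, `gene`, `replicate`,
#'   `quantity` (positive, from a relative standard curve), `diagnosis`,
#'   `region`; at most 4 replicates per (sample, gene).
#' @return Validated data.frame of class `"qpcr_plate"`.
#' @export
qpcr_plate <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "replicate", "quantity", "diagnosis", "region")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop_listing("qPCR plate is missing required columns", missing_cols)
  if (any(!is.finite(df$quantity) | df$quantity <= 0))
    stop("quantities must be positive", call. = FALSE)
  reps <- tapply(df$replicate, paste(df$sample_id, df$gene), length)
  if (any(reps > 4))
    stop_listing("more than 4 replicates for well group(s)",
                 names(reps)[reps > 4])
  class(df) <- c("qpcr_plate", "data.frame")
  df
}

# Collapse replicate wells to their mean quantity per (sample, gene), with
# diagnosis/region carried along.
collapse_replicates <- function(plate) {
  agg <- aggregate(quantity ~ sample_id + gene + diagnosis + region,
                   data = as.data.frame(plate), FUN = mean)
  agg
}

#' Rank candidate reference genes by expression stability
#'
#' Model-based stability in the NormFinder spirit: log-transformed
#' replicate-averaged quantities are centered per sample (removing sample
#' loading), decomposed into gene, group, and gene-by-group (intergroup
#' bias) terms, and each gene's bias estimates are shrunken by a moment
#' estimator of the between-gene bias variance. The stability value is the
#' mean over groups of `|shrunken bias| + sqrt(intragroup variance / n_g)`;
#' lower is more stable. Ties are broken by lower mean intragroup variance.
#'
#' @param plate A [qpcr_plate()] restricted to the candidate genes; every
#'   gene must be measured in every group.
#' @param group_col Column defining the groups (default `"diagnosis"`).
#' @return data.frame sorted ascending by `stability` with columns `gene`,
#'   `stability`, `intergroup_bias` (mean |shrunken bias|),
#'   `intragroup_var` (mean within-group variance).
#' @export
stability_rank <- function(plate, group_col = "diagnosis") {
  dat <- collapse_replicates(plate)
  dat$group <- dat[[group_col]]
  genes <- sort(unique(dat$gene))
  groups <- sort(unique(dat$group))
  if (length(genes) < 2) stop("need at least 2 candidate genes", call. = FALSE)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  cover <- table(dat$gene, dat$group)
  if (any(cover == 0)) {
    bad <- which(cover == 0, arr.ind = TRUE)
    stop(sprintf("gene %s has no measurements in group %s",
                 rownames(cover)[bad[1, 1]], colnames(cover)[bad[1, 2]]),
         call. = FALSE)
  }
  dat$logq <- log10(dat$quantity)
  # Remove the per-sample loading term (mean over genes within sample).
  sample_mean <- tapply(dat$logq, dat$sample_id, mean)
  dat$z <- dat$logq - sample_mean[dat$sample_id]

  grand <- mean(dat$z)
  gene_mean <- tapply(dat$z, dat$gene, mean)
  group_mean <- tapply(dat$z, dat$group, mean)
  cell_mean <- tapply(dat$z, list(dat$gene, dat$group), mean)
  cell_var <- tapply(dat$z, list(dat$gene, dat$group), var)
  cell_var[is.na(cell_var)] <- 0
  cell_n <- table(dat$gene, dat$group)

  # Intergroup bias: interaction term of the two-way decomposition.
  d <- cell_mean -
    matrix(gene_mean[genes], length(genes), length(groups)) -
    matrix(group_mean[groups], length(genes), length(groups), byrow = TRUE) +
    grand
  d <- d[genes, groups, drop = FALSE]
  v_over_n <- (cell_var / cell_n)[genes, groups, drop = FALSE]
  # Moment estimator of the true between-gene bias variance.
  gamma2 <- max(0, sum(d^2) / length(d) - mean(v_over_n))
  shrink <- gamma2 / (gamma2 + v_over_n)
  shrink[!is.finite(shrink)] <- 0
  d_tilde <- d * shrink

  stability <- rowMeans(abs(d_tilde) + sqrt(v_over_n))
  intravar <- rowMeans(cell_var[genes, groups, drop = FALSE])
  out <- data.frame(gene = genes,
                    stability = stability,
                    intergroup_bias = rowMeans(abs(d_tilde)),
                    intragroup_var = intravar,
                    stringsAsFactors = FALSE)
  out <- out[order(out$stability, out$intragroup_var, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Select reference genes via a stability funnel
#'
#' Mirrors the two-step candidate screen: rank all candidates, keep the
#' `n_stage1` most stable, re-rank them, and return the `n_final` most
#' stable as the reference trio.
#'
#' @param plate A [qpcr_plate()] of candidate control genes.
#' @param n_stage1 Candidates retained after the first screen (default 6).
#' @param n_final Reference genes returned (default 3).
#' @param group_col Grouping column for the stability model.
#' @return Character vector of `n_final` reference gene names, most stable
#'   first.
#' @export
select_reference_genes <- function(plate, n_stage1 = 6, n_final = 3,
                                   group_col = "diagnosis") {
  rank1 <- stability_rank(plate, group_col)
  keep <- head(rank1$gene, min(n_stage1, nrow(rank1)))
  sub <- plate[plate$gene %in% keep, , drop = FALSE]
  rank2 <- stability_rank(sub, group_col)
  head(rank2$gene, min(n_final, nrow(rank2)))
}

#' Normalized quantity
#'
#' `NQ = GOI quantity / geometric mean of the reference-gene quantities`.
#'
#' @param goi Gene-of-interest quantity (positive scalar or vector).
#' @param refs Numeric vector (or matrix, one column per reference gene) of
#'   reference quantities.
#' @return Normalized quantity with the same length as `goi`.
#' @export
#' @examples
#' normalized_quantity(6, c(1, 2, 4))  # geometric mean 2 -> NQ 3
normalized_quantity <- function(goi, refs) {
  refs <- if (is.matrix(refs)) refs else matrix(refs, nrow = length(goi),
                                                ncol = length(refs),
                                                byrow = TRUE)
  if (any(!is.finite(goi) | goi <= 0) || any(!is.finite(refs) | refs <= 0))
    stop("quantities must be positive and finite", call. = FALSE)
  goi / exp(rowMeans(log(refs)))
}

#' Mixed-model analysis of validation measurements
#'
#' log10-transforms normalized qPCR quantities (or interpolated cytokine
#' concentrations) and runs the per-analyte tetrad mixed-model ANCOVA,
#' reporting disease-versus-control contrasts with fold changes relative to
#' the control least-squares mean and BH-FDR across analytes per diagnosis.
#'
#' @param values Named list or data.frame of positive per-sample values, one
#'   element/column per analyte, or a matrix analytes x samples.
#' @param meta Matching [sample_table()] (single region).
#' @param covariates Covariates to adjust for.
#' @return A `contrast_table` as from [de_analysis()], one row per
#'   (analyte, diagnosis), with `fold_change = 10^|estimate|`.
#' @export
analyze_validation <- function(values, meta,
                               covariates = DEFAULT_COVARIATES) {
  if (is.data.frame(values)) values <- as.list(values)
  if (is.list(values)) {
    mat <- do.call(rbind, values)
    rownames(mat) <- names(values)
  } else mat <- values
  if (any(!is.finite(mat) | mat <= 0))
    stop("validation values must be positive", call. = FALSE)
  colnames(mat) <- meta$subject_id
  study <- expression_study(log10(mat), meta)
  de_analysis(study)
}
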