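# Signed consensus weighted co-expression network.
#
# Pipeline: per region, a signed adjacency a_ij = ((1 + r_ij)/2)^beta from
# Pearson correlations; topological overlap (TOM) per region; per-region
# TOMs single-quantile scaled to a reference region and combined by the
# elementwise minimum (consensus TOM); average-linkage clustering of 1-TOM;
# a dynamic hybrid tree cut; eigengene-based module refinement (low-kME
# removal, disbanding of weakly supported modules, p-value-ratio
# reassignment); and iterative eigengene-dendrogram merging. Genes are
# optionally pre-assigned to blocks by consensus projective k-means so the
# TOM is only materialized within blocks.

#' Network construction configuration
#'
#' @param power Soft-thresholding power beta (default 12).
#' @param n_blocks Number of pre-clustering blocks (default 4; 1 disables
#'   blocking).
#' @param min_module_size Minimum genes per module for the tree cut
#'   (default 50).
#' @param deep_split Branch-splitting sensitivity 0-4 (default 4, most
#'   sensitive).
#' @param scale_quantile Quantile used for consensus TOM scaling
#'   (default 0.95).
#' @param me_cor_min Genes with own-module kME below this are removed
#'   (default 0.3).
#' @param disband_count,disband_cor A module is disbanded when fewer than
#'   `disband_count` genes have kME above `disband_cor` (defaults 17, 0.5).
#' @param reassign_factor A gene is reassigned when its correlation p-value
#'   to another eigengene is smaller than its own-module p-value by this
#'   factor (default 1e-4).
#' @param merge_cut Height at which the eigengene dendrogram is cut for
#'   module merging (default 0.15, i.e. eigengene correlation 0.85).
#' @param cut_height Absolute dissimilarity (1 - TOM) above which genes are
#'   never clustered (default 0.995).
#' @param reference_region Index of the region whose TOM quantile anchors
#'   the consensus scaling (default 1, first region in input order).
#' @return List of class `"network_config"`.
#' @export
network_config <- function(power = 12, n_blocks = 4, min_module_size = 50,
                           deep_split = 4, scale_quantile = 0.95,
                           me_cor_min = 0.3, disband_count = 17,
                           disband_cor = 0.5, reassign_factor = 1e-4,
                           merge_cut = 0.15, cut_height = 0.995,
                           reference_region = 1) {
  stopifnot(power >= 1, n_blocks >= 1, min_module_size >= 2,
            deep_split %in% 0:4,
            scale_quantile > 0, scale_quantile < 1,
            me_cor_min >= 0, me_cor_min <= 1,
            disband_count >= 1, disband_cor >= 0, disband_cor <= 1,
            reassign_factor > 0, reassign_factor <= 1,
            merge_cut >= 0, merge_cut <= 1,
            cut_height > 0, cut_height <= 1)
  structure(as.list(environment()), class = "network_config")
}

# Standardize gene rows (mean 0, sd 1 across samples); errors on
# zero-variance genes.
standardize_rows <- function(expr) {
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    stop_listing("zero-variance gene(s)", rownames(expr)[sds == 0])
  (expr - rowMeans(expr)) / sds
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + r_ij) / 2)^power` from Pearson correlations of gene
#' profiles; anti-correlated genes get adjacency near 0, so sign is encoded
#' rather than discarded.
#'
#' @param expr Genes x samples matrix (at least 4 samples; no zero-variance
#'   genes).
#' @param power Soft-thresholding power.
#' @return Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(expr, power = 12) {
  if (ncol(expr) < 4) stop("need at least 4 samples", call. = FALSE)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    stop_listing("zero-variance gene(s)", rownames(expr)[sds == 0])
  r <- cor(t(expr))
  a <- ((1 + r) / 2)^power
  a <- pmin(pmax(a, 0), 1)
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Connectivities `k_i = sum_{j != i} a_ij` are binned into equal-width
#' bins; the fit is the R-squared of regressing `log10 p(k)` on
#' `log10 mean(k)` over non-empty bins.
#'
#' @param adjacency Symmetric adjacency matrix (at least 50 genes).
#' @param n_bins Number of connectivity bins (default 10).
#' @return R-squared of the log-log regression.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  if (nrow(adjacency) < 50) stop("need at least 50 genes", call. = FALSE)
  k <- rowSums(adjacency) - diag(adjacency)
  if (sd(k) < 1e-12)
    stop("degenerate connectivity distribution: all connectivities equal",
         call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mean_k <- tapply(k, bin, mean)[levels(bin)]
  keep <- counts > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 3)
    stop("too few occupied connectivity bins for a fit", call. = FALSE)
  x <- log10(mean_k[keep])
  y <- log10(counts[keep] / length(k))
  summary(stats::lm(y ~ x))$r.squared
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivities excluding the diagonal; `TOM_ii = 1`.
#'
#' @param adjacency Symmetric adjacency matrix with values in `[0, 1]`.
#' @return Symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- adjacency
  diag(a) <- 0
  S <- a %*% a
  k <- rowSums(a)
  den <- outer(k, k, pmin) + 1 - a
  tom <- (S + a) / den
  tom <- pmin(pmax(tom, 0), 1)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Consensus TOM by quantile scaling and elementwise minimum
#'
#' Off-diagonal entries of each region's TOM are multiplied by
#' `Q_q(reference) / Q_q(region)` so that the chosen quantile matches the
#' reference region, then the elementwise minimum across regions is taken:
#' a gene pair is only as similar as it is in its least-similar region.
#'
#' @param toms List of TOM matrices with identical gene ordering.
#' @param q Scaling quantile (default 0.95).
#' @param reference Index of the reference region (default 1).
#' @return Consensus TOM, clipped to `[0, 1]`, unit diagonal.
#' @export
consensus_tom <- function(toms, q = 0.95, reference = 1) {
  stopifnot(length(toms) >= 1)
  dims <- vapply(toms, nrow, 1L)
  if (length(unique(dims)) != 1)
    stop("TOMs must have identical dimensions", call. = FALSE)
  gn <- lapply(toms, rownames)
  if (!all(vapply(gn, identical, TRUE, gn[[1]])))
    stop("TOMs must share an identical gene ordering", call. = FALSE)
  off <- upper.tri(toms[[reference]])
  q_ref <- quantile(toms[[reference]][off], q, names = FALSE)
  scaled <- lapply(toms, function(tm) {
    q_r <- quantile(tm[off], q, names = FALSE)
    f <- if (q_r > 0) q_ref / q_r else 1
    out <- tm * f
    diag(out) <- 1
    out
  })
  cons <- Reduce(pmin, scaled)
  cons <- pmin(pmax(cons, 0), 1)
  diag(cons) <- 1
  cons
}

#' Pre-assign genes to blocks by consensus projective k-means
#'
#' Gene profiles are standardized within region and concatenated across
#' regions; clustering uses the projective distance `1 - |r|` to a unit
#' centroid, updated as the sign-aligned mean profile of its members.
#' Several restarts are run and the assignment with the best objective
#' (summed |r| to assigned centroids) is kept. Deterministic given `seed`.
#'
#' @param expr_list List of genes x samples matrices (identical gene order).
#' @param k Number of blocks.
#' @param seed Integer seed for centroid initialization.
#' @param n_restarts,max_iter Restart and iteration caps.
#' @return Integer vector of block assignments (named by gene).
#' @export
preassign_blocks <- function(expr_list, k, seed = 1, n_restarts = 5,
                             max_iter = 30) {
  if (!is.list(expr_list)) expr_list <- list(expr_list)
  G <- nrow(expr_list[[1]])
  if (k > G) stop("k must not exceed the number of genes", call. = FALSE)
  genes <- rownames(expr_list[[1]])
  if (k == 1) return(setNames(rep(1L, G), genes))
  U <- do.call(cbind, lapply(expr_list, standardize_rows))
  U <- U - rowMeans(U)
  U <- U / sqrt(rowSums(U^2))
  with_seed(seed, {
    best_assign <- NULL
    best_obj <- -Inf
    for (restart in seq_len(n_restarts)) {
      centers <- U[sample.int(G, k), , drop = FALSE]
      assign <- rep(0L, G)
      for (iter in seq_len(max_iter)) {
        R <- U %*% t(centers)
        new_assign <- max.col(abs(R), ties.method = "first")
        if (identical(new_assign, assign)) break
        assign <- new_assign
        for (j in seq_len(k)) {
          idx <- which(assign == j)
          if (length(idx) == 0) {
            centers[j, ] <- U[sample.int(G, 1), ]
            next
          }
          s <- sign(R[cbind(idx, rep(j, length(idx)))])
          s[s == 0] <- 1
          v <- colSums(U[idx, , drop = FALSE] * s)
          nv <- sqrt(sum(v^2))
          centers[j, ] <- if (nv > 0) v / nv else U[sample.int(G, 1), ]
        }
      }
      R <- U %*% t(centers)
      obj <- sum(abs(R)[cbind(seq_len(G), assign)])
      if (obj > best_obj) {
        best_obj <- obj
        best_assign <- assign
      }
    }
    setNames(as.integer(best_assign), genes)
  })
}

# Relabel modules 1..M by decreasing size; ties broken by the
# lexicographically smallest member gene so labels are invariant to gene
# input order. Label 0 stays unassigned.
canonicalize_labels <- function(labels, genes = names(labels)) {
  mods <- setdiff(unique(labels), 0L)
  if (length(mods) == 0) return(labels)
  size <- vapply(mods, function(m) sum(labels == m), 1L)
  first_gene <- vapply(mods, function(m) min(genes[labels == m]), "")
  ord <- order(-size, first_gene)
  new <- labels
  for (i in seq_along(ord)) new[labels == mods[ord[i]]] <- i
  new
}

# Dynamic hybrid tree cut on an hclust tree built from a dissimilarity
# matrix. Branches below cut_height are recursively decomposed; a branch is
# accepted as a cluster when its children fail the validity criteria (size,
# merge gap, core scatter). Small side branches peeled during decomposition
# and all other unlabeled genes are assigned in a second stage to the
# nearest cluster if their mean dissimilarity to it is below the cluster's
# attachment height.
cutree_dynamic_hybrid <- function(hc, diss, min_size, deep_split,
                                  cut_height) {
  n <- nrow(diss)
  merge <- hc$merge
  height <- hc$height
  pos <- match(seq_len(n), hc$order)
  n_nodes <- n - 1L
  lo <- hi <- integer(n_nodes)
  size <- integer(n_nodes)
  core_heights <- vector("list", n_nodes)
  node_lo <- function(ch) if (ch < 0) pos[-ch] else lo[ch]
  node_hi <- function(ch) if (ch < 0) pos[-ch] else hi[ch]
  node_size <- function(ch) if (ch < 0) 1L else size[ch]
  node_core <- function(ch) if (ch < 0) numeric(0) else core_heights[[ch]]
  for (i in seq_len(n_nodes)) {
    c1 <- merge[i, 1]; c2 <- merge[i, 2]
    lo[i] <- min(node_lo(c1), node_lo(c2))
    hi[i] <- max(node_hi(c1), node_hi(c2))
    size[i] <- node_size(c1) + node_size(c2)
    hs <- sort(c(node_core(c1), node_core(c2), height[i]))
    core_heights[[i]] <- hs[seq_len(min(length(hs), min_size))]
  }
  parent <- rep(NA_integer_, n_nodes)
  for (i in seq_len(n_nodes)) for (ch in merge[i, ]) if (ch > 0) parent[ch] <- i

  leaves_of <- function(node) hc$order[lo[node]:hi[node]]
  top_height <- function(ch) if (ch < 0) 0 else height[ch]
  core_scatter <- function(ch) {
    hs <- node_core(ch)
    if (length(hs) == 0) 0 else mean(hs)
  }

  # Sensitivity mapping: deepSplit 0..4 interpolates the core-scatter cap
  # from 0.64 to 0.96 of the working height range; the required merge gap is
  # three quarters of the remainder.
  max_core_frac <- 0.64 + 0.08 * deep_split
  min_gap_frac <- (1 - max_core_frac) * 3 / 4
  hs_below <- height[height <= cut_height]
  ref_height <- if (length(hs_below) > 0)
    quantile(hs_below, 0.05, names = FALSE) else 0
  rng <- max(cut_height - ref_height, 1e-12)
  min_abs_gap <- min_gap_frac * rng
  max_abs_core <- ref_height + max_core_frac * rng

  valid <- function(ch, parent_height) {
    node_size(ch) >= min_size &&
      (parent_height - top_height(ch)) >= min_abs_gap &&
      core_scatter(ch) <= max_abs_core
  }

  # Maximal subtrees below cut_height.
  below <- height <= cut_height
  is_candidate <- below &
    vapply(seq_len(n_nodes), function(i)
      is.na(parent[i]) || !below[parent[i]], TRUE)
  candidates <- which(is_candidate & size >= min_size)

  labels <- rep(0L, n)
  cluster_nodes <- integer(0)
  next_label <- 0L
  for (cand in candidates) {
    stack <- cand
    while (length(stack) > 0) {
      node <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      c1 <- merge[node, 1]; c2 <- merge[node, 2]
      v1 <- valid(c1, height[node]); v2 <- valid(c2, height[node])
      if (v1 && v2) {
        stack <- c(stack, c1, c2)
      } else if (v1 && node_size(c2) < min_size) {
        stack <- c(stack, c1)           # peel the small side branch
      } else if (v2 && node_size(c1) < min_size) {
        stack <- c(stack, c2)
      } else {
        next_label <- next_label + 1L
        labels[leaves_of(node)] <- next_label
        cluster_nodes <- c(cluster_nodes, node)
      }
    }
  }

  # Hybrid assignment of unlabeled genes.
  if (next_label > 0L && any(labels == 0L)) {
    thresholds <- vapply(cluster_nodes, function(node) {
      ph <- if (is.na(parent[node])) Inf else height[parent[node]]
      min(ph, cut_height)
    }, 1)
    members <- lapply(seq_len(next_label), function(m) which(labels == m))
    un <- which(labels == 0L)
    dmat <- vapply(members, function(idx)
      rowMeans(diss[un, idx, drop = FALSE]), numeric(length(un)))
    dmat <- matrix(dmat, nrow = length(un))
    best <- max.col(-dmat, ties.method = "first")
    dist_best <- dmat[cbind(seq_along(un), best)]
    ok <- dist_best < thresholds[best]
    labels[un[ok]] <- best[ok]
  }
  labels
}

#' Cut a consensus TOM dendrogram into initial modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM` followed by a
#' dynamic hybrid tree cut honoring the minimum module size and the
#' deep-split sensitivity; label 0 marks unassigned genes.
#'
#' @param tom Consensus (or single-region) TOM with gene dimnames.
#' @param config A [network_config()].
#' @return Named integer vector of module labels (0 = unassigned), numbered
#'   by decreasing module size.
#' @export
cut_dendrogram <- function(tom, config = network_config()) {
  genes <- rownames(tom)
  if (nrow(tom) < config$min_module_size) {
    warning("fewer genes than min_module_size; nothing to cut")
    return(setNames(rep(0L, nrow(tom)), genes))
  }
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  labels <- cutree_dynamic_hybrid(hc, diss, config$min_module_size,
                                  config$deep_split, config$cut_height)
  labels <- setNames(labels, genes)
  canonicalize_labels(labels)
}

# First principal component of a module's standardized expression: the
# module eigengene (per-sample scores, unit norm), oriented so the mean kME
# of its own members is positive.
module_eigengenes <- function(expr_scaled, labels) {
  mods <- sort(setdiff(unique(labels), 0L))
  n_samples <- ncol(expr_scaled)
  ME <- matrix(NA_real_, n_samples, length(mods),
               dimnames = list(colnames(expr_scaled), as.character(mods)))
  varexp <- setNames(numeric(length(mods)), as.character(mods))
  for (i in seq_along(mods)) {
    idx <- which(labels == mods[i])
    M <- t(expr_scaled[idx, , drop = FALSE])   # samples x genes
    sv <- svd(M, nu = 1, nv = 0)
    me <- sv$u[, 1]
    if (mean(cor(M, me)) < 0) me <- -me
    ME[, i] <- me
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  kME <- if (length(mods) > 0) cor(t(expr_scaled), ME) else
    matrix(numeric(0), nrow(expr_scaled), 0)
  if (length(mods) > 0) rownames(kME) <- rownames(expr_scaled)
  list(ME = ME, kME = kME, varexp = varexp, modules = mods)
}

new_module_solution <- function(expr_scaled, labels, config,
                                sample_region = NULL, extras = list()) {
  labels <- canonicalize_labels(labels)
  eig <- module_eigengenes(expr_scaled, labels)
  out <- c(list(labels = labels, ME = eig$ME, kME = eig$kME,
                varexp = eig$varexp, expr = expr_scaled,
                sample_region = sample_region, config = config),
           extras)
  class(out) <- "module_solution"
  out
}

#' @export
print.module_solution <- function(x, ...) {
  mods <- setdiff(unique(x$labels), 0L)
  sizes <- sort(vapply(mods, function(m) sum(x$labels == m), 1L),
                decreasing = TRUE)
  cat(sprintf("module_solution: %d modules over %d genes (%d unassigned)\n",
              length(mods), length(x$labels), sum(x$labels == 0)))
  if (length(sizes) > 0)
    cat("sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Refine modules by eigengene membership
#'
#' Applies the eigengene-based cleanup rules: genes whose correlation to
#' their own module eigengene (kME) is below `me_cor_min` are removed;
#' modules with fewer than `disband_count` genes at kME above `disband_cor`
#' are disbanded; eigengenes are recomputed; finally, in a single pass,
#' genes whose correlation p-value to another eigengene is smaller than
#' their own-module p-value by `reassign_factor` are reassigned to the
#' closer module.
#'
#' @param expr_scaled Genes x samples matrix (standardized per region,
#'   regions concatenated along samples).
#' @param labels Initial module labels (0 = unassigned).
#' @param config A [network_config()].
#' @param sample_region Optional factor giving each sample's region.
#' @return A `module_solution`.
#' @export
refine_modules <- function(expr_scaled, labels, config = network_config(),
                           sample_region = NULL) {
  genes <- rownames(expr_scaled)
  if (is.null(names(labels))) names(labels) <- genes
  labels <- labels[genes]
  mods <- sort(setdiff(unique(labels), 0L))
  if (length(mods) > 0) {
    eig <- module_eigengenes(expr_scaled, labels)
    # Remove weak members.
    for (m in mods) {
      idx <- which(labels == m)
      own <- eig$kME[idx, as.character(m)]
      labels[idx[own < config$me_cor_min]] <- 0L
    }
    # Disband modules without a strong enough core.
    eig <- module_eigengenes(expr_scaled, labels)
    for (m in sort(setdiff(unique(labels), 0L))) {
      idx <- which(labels == m)
      strong <- sum(eig$kME[idx, as.character(m)] > config$disband_cor)
      if (strong < config$disband_count) labels[idx] <- 0L
    }
    # Single reassignment pass on the recomputed eigengenes.
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) > 1) {
      eig <- module_eigengenes(expr_scaled, labels)
      n <- ncol(expr_scaled)
      pmat <- fisher_z_p(eig$kME, n)
      assigned <- which(labels != 0L)
      own_col <- match(as.character(labels[assigned]), colnames(pmat))
      own_p <- pmat[cbind(assigned, own_col)]
      new_labels <- labels
      for (j in seq_along(assigned)) {
        g <- assigned[j]
        other_cols <- setdiff(seq_len(ncol(pmat)), own_col[j])
        if (length(other_cols) == 0) next
        best <- other_cols[which.min(pmat[g, other_cols])]
        if (pmat[g, best] < own_p[j] * config$reassign_factor)
          new_labels[g] <- as.integer(colnames(pmat)[best])
      }
      labels <- new_labels
    }
  }
  new_module_solution(expr_scaled, labels, config,
                      sample_region = sample_region)
}

#' Merge modules with correlated eigengenes
#'
#' Eigengenes are clustered by average linkage on `1 - cor(ME)`; all modules
#' on branches below `merge_cut` are merged, eigengenes recomputed, and the
#' process repeated until no modules merge (guaranteed to terminate: the
#' module count strictly decreases each round).
#'
#' @param solution A `module_solution`.
#' @param merge_cut Dendrogram cut height (default from the solution's
#'   config).
#' @return A `module_solution` with merged labels; `n_merge_iterations`
#'   records the number of merging rounds.
#' @export
merge_modules <- function(solution, merge_cut = solution$config$merge_cut) {
  labels <- solution$labels
  config <- solution$config
  iterations <- 0L
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2) break
    eig <- module_eigengenes(solution$expr, labels)
    cm <- cor(eig$ME)
    hc <- hclust(as.dist(1 - cm), method = "average")
    grp <- cutree(hc, h = merge_cut)
    if (max(grp) == length(mods)) break
    iterations <- iterations + 1L
    map <- setNames(grp, colnames(eig$ME))
    new_labels <- labels
    for (m in mods)
      new_labels[labels == m] <- as.integer(map[[as.character(m)]])
    labels <- new_labels
  }
  new_module_solution(solution$expr, labels, config,
                      sample_region = solution$sample_region,
                      extras = list(n_merge_iterations = iterations,
                                    blocks = solution$blocks,
                                    sf_r2 = solution$sf_r2))
}

#' Build a numeric trait matrix from sample metadata
#'
#' Diagnosis indicators (one per disorder) plus numeric covariates. With
#' `coding = "one_vs_rest"` each disorder indicator is 1 for that diagnosis
#' and 0 for everyone else; with `"one_vs_control"` non-control other
#' diagnoses are set to `NA` so correlations use only the disorder and
#' control samples.
#'
#' @param meta A [sample_table()] (rows aligned to the network samples).
#' @param coding Indicator coding for disorders.
#' @return Numeric matrix, samples x traits.
#' @export
build_trait_matrix <- function(meta, coding = c("one_vs_rest", "one_vs_control")) {
  coding <- match.arg(coding)
  out <- cbind(
    SCZ = as.numeric(meta$diagnosis == "SCZ"),
    BD = as.numeric(meta$diagnosis == "BD"),
    MDD = as.numeric(meta$diagnosis == "MDD"),
    age = meta$age, pmi = meta$pmi, ph = meta$ph,
    sex_M = as.numeric(meta$sex == "M"),
    tobacco = as.numeric(meta$tobacco == "yes"))
  if (coding == "one_vs_control") {
    for (d in c("SCZ", "BD", "MDD"))
      out[!(meta$diagnosis %in% c(d, "CTRL")), d] <- NA
  }
  rownames(out) <- meta$subject_id
  out
}

#' Module eigengene-trait statistics
#'
#' Pearson correlation of each module eigengene with each trait, the
#' asymptotic Fisher-z p-value, and BH-FDR across the whole module x trait
#' grid.
#'
#' @param solution A `module_solution` (or a numeric samples x modules ME
#'   matrix).
#' @param traits Numeric samples x traits matrix, rows aligned to the ME
#'   rows; `NA` trait entries are dropped pairwise.
#' @return data.frame with columns `module`, `trait`, `r`, `n`, `p`,
#'   `p_adj`.
#' @export
module_trait_stats <- function(solution, traits) {
  ME <- if (inherits(solution, "module_solution")) solution$ME else solution
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(ME))
    stop("traits must have one row per sample", call. = FALSE)
  if (nrow(ME) < 4) stop("need at least 4 samples", call. = FALSE)
  rows <- list()
  for (m in colnames(ME)) {
    for (tr in colnames(traits)) {
      ok <- !is.na(traits[, tr])
      n <- sum(ok)
      if (n < 4) stop("fewer than 4 complete samples for trait ", tr)
      tv <- traits[ok, tr]
      r <- if (sd(tv) == 0) 0 else cor(ME[ok, m], tv)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = r, n = n,
        p = if (r == 0) 1 else fisher_z_p(r, n),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Module-trait statistics per region
#'
#' Restricts the concatenated-sample eigengenes to each region's samples and
#' computes [module_trait_stats()] there; FDR is applied across the full
#' module x trait x region grid.
#'
#' @param solution A `module_solution` carrying `sample_region`.
#' @param meta_by_region Named list of [sample_table()]s, one per region,
#'   rows aligned to that region's samples in the solution.
#' @param coding Diagnosis indicator coding, see [build_trait_matrix()].
#' @return data.frame with columns `module`, `trait`, `region`, `r`, `n`,
#'   `p`, `p_adj`.
#' @export
module_trait_stats_by_region <- function(solution, meta_by_region,
                                         coding = "one_vs_rest") {
  stopifnot(inherits(solution, "module_solution"),
            !is.null(solution$sample_region))
  rows <- list()
  for (r in names(meta_by_region)) {
    sel <- solution$sample_region == r
    st <- module_trait_stats(solution$ME[sel, , drop = FALSE],
                             build_trait_matrix(meta_by_region[[r]], coding))
    st$p_adj <- NULL
    st$region <- r
    rows[[r]] <- st
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Fisher's exact DE enrichment of modules
#'
#' Tests each module's gene membership for over-representation of the DE
#' genes of each (diagnosis, region), delegating to [fisher_enrichment()].
#'
#' @param solution A `module_solution`.
#' @param de_lists Nested list from [select_de_genes()].
#' @param universe Background gene list (defaults to all network genes).
#' @return data.frame with columns `module`, `diagnosis`, `region`,
#'   `overlap`, `module_size`, `de_size`, `p`.
#' @export
module_de_enrichment <- function(solution, de_lists,
                                 universe = names(solution$labels)) {
  mods <- sort(setdiff(unique(solution$labels), 0L))
  rows <- list()
  for (d in names(de_lists)) {
    for (r in names(de_lists[[d]])) {
      de <- c(de_lists[[d]][[r]]$up, de_lists[[d]][[r]]$down)
      for (m in mods) {
        members <- names(solution$labels)[solution$labels == m]
        fe <- fisher_enrichment(de, members, universe)
        rows[[length(rows) + 1L]] <- data.frame(
          module = as.character(m), diagnosis = d, region = r,
          overlap = fe$overlap, module_size = fe$set_size,
          de_size = fe$de_size, p = fe$p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Signed consensus co-expression network, end to end
#'
#' Runs the whole consensus pipeline on a list of per-region studies sharing
#' one gene universe: block pre-assignment, per-block per-region signed
#' adjacency and TOM, quantile-scaled minimum consensus, average-linkage
#' clustering with the dynamic hybrid cut, eigengene-based refinement and
#' reassignment, and iterative eigengene merging.
#'
#' @param studies Named list of [expression_study()]s (one per region, same
#'   genes, samples aligned across regions).
#' @param config A [network_config()].
#' @param seed Seed for the block pre-assignment.
#' @return A `module_solution` with extra fields `blocks` (gene block
#'   assignment) and `sf_r2` (per-region scale-free fit at the configured
#'   power).
#' @export
consensus_modules <- function(studies, config = network_config(), seed = 1) {
  stopifnot(length(studies) >= 1)
  genes <- studies[[1]]$gene_ids
  for (s in studies)
    if (!identical(s$gene_ids, genes))
      stop("all studies must share an identical gene ordering", call. = FALSE)
  scaled_list <- lapply(studies, function(s) standardize_rows(s$expr))
  expr_concat <- do.call(cbind, scaled_list)
  colnames(expr_concat) <- paste(rep(names(studies),
                                     vapply(scaled_list, ncol, 1L)),
                                 colnames(expr_concat), sep = ".")
  sample_region <- factor(rep(names(studies),
                              vapply(scaled_list, ncol, 1L)),
                          levels = names(studies))
  blocks <- if (config$n_blocks > 1)
    preassign_blocks(scaled_list, config$n_blocks, seed = seed)
  else setNames(rep(1L, length(genes)), genes)

  sf_r2 <- vapply(scaled_list, function(e)
    tryCatch(scale_free_fit(signed_adjacency(e, config$power)),
             error = function(err) NA_real_), 1)

  labels <- setNames(rep(0L, length(genes)), genes)
  offset <- 0L
  for (b in sort(unique(blocks))) {
    idx <- which(blocks == b)
    if (length(idx) < config$min_module_size) next
    toms <- lapply(scaled_list, function(e)
      topological_overlap(signed_adjacency(e[idx, , drop = FALSE],
                                           config$power)))
    cons <- consensus_tom(toms, q = config$scale_quantile,
                          reference = config$reference_region)
    lab_b <- cut_dendrogram(cons, config)
    assigned <- lab_b > 0
    labels[idx[assigned]] <- lab_b[assigned] + offset
    offset <- offset + max(0L, max(lab_b))
  }

  refined <- refine_modules(expr_concat, labels, config,
                            sample_region = sample_region)
  refined$blocks <- blocks
  refined$sf_r2 <- sf_r2
  merged <- merge_modules(refined)
  merged
}
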