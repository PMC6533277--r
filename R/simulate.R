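# Synthetic tetrad-matched multi-region study generator.
#
# Emulates the matched case-control design the pipeline targets: T tetrads,
# each holding one control and one subject per diagnosis, profiled in three
# brain regions. Signal is planted at three levels: per-gene diagnosis
# effects with a graded regional burden, rank-one co-expression modules
# (optionally trait-associated so their eigengenes track a diagnosis), and
# sparse nuisance covariate effects the ANCOVA must absorb. Residual noise
# is Gaussian on the log10 scale.

#' Default planted differential-expression plan
#'
#' Fractions of genes affected per diagnosis and region, with the mean
#' absolute log10 effect. The schizophrenia fractions follow the reported
#' regional burden of the motivating cohort (9%/3%/2% of detected
#' transcripts in hippocampus/striatum/prefrontal cortex); bipolar and
#' depression fractions are set much smaller with the same regional
#' ordering.
#'
#' @return data.frame with columns `diagnosis`, `region`, `fraction`,
#'   `mean_effect`.
#' @export
default_de_plan <- function() {
  data.frame(
    diagnosis   = rep(c("SCZ", "BD", "MDD"), each = 3),
    region      = rep(c("HIP", "STR", "DLPFC"), times = 3),
    fraction    = c(0.09, 0.03, 0.02,
                    0.02, 0.01, 0.008,
                    0.005, 0.003, 0.002),
    mean_effect = c(0.20, 0.20, 0.20,
                    0.18, 0.18, 0.18,
                    0.18, 0.18, 0.18),
    stringsAsFactors = FALSE
  )
}

#' Default planted co-expression module plan
#'
#' Five rank-one modules with sizes spanning 60-250 genes plus one
#' inflammation-like module of 122 genes whose factor score is shifted
#' upwards in schizophrenia subjects in every region, so its eigengene
#' correlates positively with the SCZ indicator and its members are
#' upregulated in SCZ.
#'
#' @return data.frame with columns `module`, `size`, `cor` (target
#'   inter-gene correlation), `diagnosis` (associated diagnosis or `NA`),
#'   `shift` (factor-score shift for that diagnosis, in score SD units),
#'   `direction`.
#' @export
default_module_plan <- function() {
  data.frame(
    module    = paste0("M", 1:5),
    size      = c(122L, 250L, 150L, 80L, 60L),
    cor       = c(0.60, 0.55, 0.60, 0.50, 0.55),
    diagnosis = c("SCZ", NA, NA, NA, NA),
    shift     = c(2.5, 0, 0, 0, 0),
    direction = c("up", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param n_tetrads Number of matched quartets (default 19).
#' @param n_genes Number of genes (default 2000).
#' @param regions Brain regions profiled (default DLPFC, HIP, STR).
#' @param de_plan Planted per-gene effect plan, see [default_de_plan()].
#' @param module_plan Planted module plan, see [default_module_plan()].
#' @param covariate_effects List with `fraction` (share of genes carrying
#'   each nuisance effect) and per-covariate coefficient scales: `age` and
#'   `pmi` (log10 units per year/hour), `ph` (per pH unit), `sex`,
#'   `tobacco`, `manner` (additive shifts).
#' @param baseline_mean,baseline_sd Gene baseline distribution (log10).
#' @param tetrad_sd SD of the per-gene tetrad random intercept.
#' @param residual_sd Residual SD on the log10 scale (must be > 0).
#' @return Validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_tetrads = 19,
                              n_genes = 2000,
                              regions = c("DLPFC", "HIP", "STR"),
                              de_plan = default_de_plan(),
                              module_plan = default_module_plan(),
                              covariate_effects = list(
                                fraction = 0.05, age = 0.002, pmi = 0.003,
                                ph = 0.05, sex = 0.03, tobacco = 0.03,
                                manner = 0.02),
                              baseline_mean = 2.5,
                              baseline_sd = 0.3,
                              tetrad_sd = 0.05,
                              residual_sd = 0.1) {
  stopifnot(n_tetrads >= 1, n_genes >= 1, length(regions) >= 1)
  if (!all(regions %in% REGION_LEVELS))
    stop_listing("unknown region(s)", setdiff(regions, REGION_LEVELS))
  de_plan <- as.data.frame(de_plan)
  if (nrow(de_plan) > 0) {
    if (any(de_plan$fraction < 0 | de_plan$fraction > 1))
      stop("de_plan fractions must lie in [0, 1]", call. = FALSE)
    if (any(de_plan$mean_effect < 0))
      stop("de_plan mean effects must be non-negative", call. = FALSE)
  }
  module_plan <- as.data.frame(module_plan)
  if (nrow(module_plan) > 0) {
    if (sum(module_plan$size) > n_genes)
      stop("module sizes must sum to at most n_genes", call. = FALSE)
    if (any(module_plan$cor <= 0 | module_plan$cor >= 1))
      stop("module inter-gene correlations must lie in (0, 1)", call. = FALSE)
  }
  if (residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  if (tetrad_sd < 0) stop("tetrad_sd must be >= 0", call. = FALSE)
  structure(list(n_tetrads = as.integer(n_tetrads),
                 n_genes = as.integer(n_genes),
                 regions = regions,
                 de_plan = de_plan,
                 module_plan = module_plan,
                 covariate_effects = covariate_effects,
                 baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 tetrad_sd = tetrad_sd,
                 residual_sd = residual_sd),
            class = "simulation_config")
}

# Subject-level covariate and design draw (one stream, independent of gene
# count). Age and sex are matched within tetrad (tetrad-level base value with
# small per-subject jitter); tobacco, manner, PMI and pH vary per subject.
simulate_subjects <- function(config, seed) {
  with_seed(stage_seed(seed, 1L), {
    t_ids <- sprintf("T%02d", seq_len(config$n_tetrads))
    sex_t <- sample(SEX_LEVELS, config$n_tetrads, replace = TRUE)
    age_t <- rnorm(config$n_tetrads, 45, 10)
    rows <- list()
    for (i in seq_len(config$n_tetrads)) {
      for (d in DIAGNOSIS_LEVELS) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = paste0(t_ids[i], "_", d),
          tetrad_id = t_ids[i],
          diagnosis = d,
          age = round(pmax(20, age_t[i] + rnorm(1, 0, 2)), 1),
          sex = sex_t[i],
          tobacco = sample(TOBACCO_LEVELS, 1, prob = c(0.35, 0.65)),
          manner_of_death = sample(MANNER_LEVELS, 1,
                                   prob = c(0.25, 0.55, 0.20)),
          pmi = round(pmax(3, rnorm(1, 17, 5)), 1),
          ph = round(pmin(7.4, pmax(6.0, rnorm(1, 6.8, 0.25))), 2),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Numeric nuisance design for the generative model (continuous covariates
# centered so baselines stay interpretable).
subject_covariate_matrix <- function(subjects) {
  cbind(age = subjects$age - mean(subjects$age),
        pmi = subjects$pmi - mean(subjects$pmi),
        ph  = subjects$ph - mean(subjects$ph),
        sex = as.numeric(subjects$sex == "M") - 0.5,
        tobacco = as.numeric(subjects$tobacco == "yes") - 0.5,
        manner_natural = as.numeric(subjects$manner_of_death == "natural"),
        manner_suicide = as.numeric(subjects$manner_of_death == "suicide"))
}

#' Simulate a tetrad-matched multi-region expression study
#'
#' Generative model per gene g, subject s, region r:
#' `y = baseline_g + tetrad intercept (per gene, tetrad, region)
#'    + planted diagnosis effect + covariate effects
#'    + sum over modules of loading_g * score_{s,r} + N(0, residual_sd)`,
#' where module factor scores are standard normal, shifted by the module's
#' `shift` for its associated diagnosis. Deterministic given `seed`; the
#' subject-level draw, the gene-level draw and each region's noise draw use
#' separate streams derived from `seed`, so changing `n_genes` does not
#' reshuffle the covariates.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @return Object of class `"tetranet_simulation"`: list with `studies`
#'   (named list of per-region [expression_study()]), `truth` (planted
#'   effects: `de_genes`, `module_membership`, `trait_loadings`), `config`,
#'   `seed`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  subjects <- simulate_subjects(config, seed)
  n_subj <- nrow(subjects)
  covmat <- subject_covariate_matrix(subjects)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  G <- config$n_genes
  mp <- config$module_plan
  dp <- config$de_plan
  ce <- config$covariate_effects

  gene_draw <- with_seed(stage_seed(seed, 2L), {
    baseline <- rnorm(G, config$baseline_mean, config$baseline_sd)

    module_of <- rep(NA_character_, G)
    loading <- numeric(G)
    if (nrow(mp) > 0) {
      pool <- sample.int(G, sum(mp$size))
      off <- 0L
      for (m in seq_len(nrow(mp))) {
        idx <- pool[(off + 1L):(off + mp$size[m])]
        off <- off + mp$size[m]
        module_of[idx] <- mp$module[m]
        base_load <- config$residual_sd * sqrt(mp$cor[m] / (1 - mp$cor[m]))
        loading[idx] <- base_load * runif(mp$size[m], 0.85, 1.2)
      }
    }

    # Planted per-gene effects drawn from non-module genes so the two signal
    # layers stay disentangled in the ground truth.
    free <- which(is.na(module_of))
    de <- list()
    if (nrow(dp) > 0) {
      for (k in seq_len(nrow(dp))) {
        n_aff <- round(dp$fraction[k] * G)
        if (n_aff == 0) next
        idx <- sample(free, n_aff)
        mag <- pmax(dp$mean_effect[k] / 2,
                    rnorm(n_aff, dp$mean_effect[k], dp$mean_effect[k] / 5))
        sgn <- sample(c(-1, 1), n_aff, replace = TRUE)
        de[[length(de) + 1L]] <- data.frame(
          gene = genes[idx], diagnosis = dp$diagnosis[k],
          region = dp$region[k], effect = sgn * mag,
          stringsAsFactors = FALSE)
      }
    }
    de <- if (length(de)) do.call(rbind, de) else
      data.frame(gene = character(0), diagnosis = character(0),
                 region = character(0), effect = numeric(0))

    # Sparse nuisance coefficients per covariate column.
    covcoef <- matrix(0, G, ncol(covmat),
                      dimnames = list(genes, colnames(covmat)))
    scales <- c(age = ce$age, pmi = ce$pmi, ph = ce$ph, sex = ce$sex,
                tobacco = ce$tobacco, manner_natural = ce$manner,
                manner_suicide = ce$manner)
    for (cn in colnames(covmat)) {
      hit <- runif(G) < ce$fraction
      covcoef[hit, cn] <- rnorm(sum(hit), 0, scales[[cn]])
    }
    list(baseline = baseline, module_of = module_of, loading = loading,
         de = de, covcoef = covcoef)
  })

  # Module-induced diagnosis effects (same in every region for associated
  # modules) become part of the planted DE truth.
  de_truth <- gene_draw$de
  if (nrow(mp) > 0) {
    for (m in seq_len(nrow(mp))) {
      if (is.na(mp$diagnosis[m]) || mp$shift[m] == 0) next
      idx <- which(gene_draw$module_of == mp$module[m])
      sgn <- if (identical(mp$direction[m], "down")) -1 else 1
      for (r in config$regions) {
        de_truth <- rbind(de_truth, data.frame(
          gene = genes[idx], diagnosis = mp$diagnosis[m], region = r,
          effect = sgn * gene_draw$loading[idx] * mp$shift[m],
          stringsAsFactors = FALSE))
      }
    }
  }

  fixed_part <- gene_draw$baseline +
    gene_draw$covcoef %*% t(covmat)   # G x n_subj
  tetrad_index <- match(subjects$tetrad_id, unique(subjects$tetrad_id))

  studies <- list()
  for (ri in seq_along(config$regions)) {
    r <- config$regions[ri]
    y <- with_seed(stage_seed(seed, 10L + ri), {
      tet_int <- matrix(rnorm(G * config$n_tetrads, 0, config$tetrad_sd),
                        G, config$n_tetrads)
      y <- fixed_part + tet_int[, tetrad_index, drop = FALSE]
      # Only the per-gene plan is added directly; module-associated effects
      # enter through the shifted factor scores below (and are bookkept in
      # the returned truth alongside the per-gene rows).
      de_r <- gene_draw$de[gene_draw$de$region == r, , drop = FALSE]
      if (nrow(de_r) > 0) {
        gi <- match(de_r$gene, genes)
        for (d in unique(de_r$diagnosis)) {
          cols <- which(subjects$diagnosis == d)
          sel <- de_r$diagnosis == d
          y[gi[sel], cols] <- y[gi[sel], cols] + de_r$effect[sel]
        }
      }
      # Module-induced effects already enter through shifted factor scores;
      # remove their duplicate direct addition above by construction: the
      # planted per-gene plan never touches module genes, and module rows of
      # de_truth are excluded from the direct addition.
      if (nrow(mp) > 0) {
        for (m in seq_len(nrow(mp))) {
          idx <- which(gene_draw$module_of == mp$module[m])
          if (length(idx) == 0) next
          score <- rnorm(n_subj)
          if (!is.na(mp$diagnosis[m]) && mp$shift[m] != 0) {
            sgn <- if (identical(mp$direction[m], "down")) -1 else 1
            score <- score + sgn * mp$shift[m] *
              as.numeric(subjects$diagnosis == mp$diagnosis[m])
          }
          y[idx, ] <- y[idx, ] + outer(gene_draw$loading[idx], score)
        }
      }
      y + matrix(rnorm(G * n_subj, 0, config$residual_sd), G, n_subj)
    })
    dimnames(y) <- list(genes, subjects$subject_id)
    meta_r <- subjects
    meta_r$region <- r
    studies[[r]] <- expression_study(y, sample_table(meta_r))
  }

  truth <- list(
    de_genes = de_truth,
    module_membership = setNames(gene_draw$module_of, genes),
    trait_loadings = mp[!is.na(mp$diagnosis) & mp$shift != 0,
                        c("module", "diagnosis", "direction", "shift"),
                        drop = FALSE])
  structure(list(studies = studies, truth = truth, config = config,
                 seed = seed),
            class = "tetranet_simulation")
}

#' @export
print.tetranet_simulation <- function(x, ...) {
  cat(sprintf("tetranet_simulation: %d genes, %d tetrads, regions %s (seed %s)\n",
              x$config$n_genes, x$config$n_tetrads,
              paste(x$config$regions, collapse = "/"), x$seed))
  cat(sprintf("planted DE rows: %d; planted modules: %d\n",
              nrow(x$truth$de_genes), nrow(x$config$module_plan)))
  invisible(x)
}

#' Write a simulated study to disk as the pipeline's standard fixtures
#'
#' Emits one expression TSV per region (`expr_<REGION>.tsv`), a combined
#' metadata TSV (`metadata.tsv`, one row per subject per region), a GMT file
#' (`genesets.gmt`) containing the planted modules as sets plus random decoy
#' sets drawn without replacement from non-module genes, and the planted
#' truth tables (`truth_de.tsv`, `truth_modules.tsv`). Byte-identical across
#' re-runs with the same simulation and `seed`.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @param seed Seed for the decoy-set draw.
#' @param n_decoys Number of decoy sets.
#' @param decoy_size Genes per decoy set.
#' @return Invisibly, character vector of written paths.
#' @export
emit_fixture <- function(sim, dir, seed = 1, n_decoys = 10, decoy_size = 50) {
  stopifnot(inherits(sim, "tetranet_simulation"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  paths <- character(0)
  for (r in names(sim$studies)) {
    p <- file.path(dir, paste0("expr_", r, ".tsv"))
    write_expression_matrix(sim$studies[[r]]$expr, p)
    paths <- c(paths, p)
  }
  meta_all <- do.call(rbind, lapply(sim$studies, function(s) as.data.frame(s$metadata)))
  p <- file.path(dir, "metadata.tsv")
  write_sample_table(meta_all, p)
  paths <- c(paths, p)

  genes <- sim$studies[[1]]$gene_ids
  membership <- sim$truth$module_membership
  sets <- split(names(membership)[!is.na(membership)],
                membership[!is.na(membership)])
  nonmodule <- names(membership)[is.na(membership)]
  decoys <- with_seed(stage_seed(seed, 99L), {
    lapply(seq_len(n_decoys), function(i)
      sort(sample(nonmodule, min(decoy_size, length(nonmodule)))))
  })
  names(decoys) <- sprintf("DECOY%02d", seq_len(n_decoys))
  gsc <- gene_set_collection(c(sets, decoys))
  p <- file.path(dir, "genesets.gmt")
  write_gmt(gsc, p)
  paths <- c(paths, p)

  p <- file.path(dir, "truth_de.tsv")
  write.table(sim$truth$de_genes, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  mm <- data.frame(gene = names(membership),
                   module = ifelse(is.na(membership), "none", membership),
                   stringsAsFactors = FALSE)
  p <- file.path(dir, "truth_modules.tsv")
  write.table(mm, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
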