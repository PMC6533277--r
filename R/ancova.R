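# Per-gene mixed-model ANCOVA with a tetrad random intercept.
#
# Model per gene: y = X beta + b_tetrad + e, b ~ N(0, tau2), e ~ N(0, sigma2),
# fixed effects = diagnosis (+ region when pooled) + covariates. The fitter
# profiles the REML criterion over the variance ratio lambda = tau2/sigma2
# after an exact orthonormal within-tetrad transform: group-mean rows have
# marginal variance sigma2 * (1 + m * lambda), within-group contrast rows
# have variance sigma2, so each criterion evaluation is a small weighted
# least-squares solve. This makes genome-wide per-gene fitting cheap while
# remaining exact REML for the single-random-intercept structure.

DEFAULT_COVARIATES <- c("age", "sex", "tobacco", "manner_of_death", "pmi", "ph")

#' Build the ANCOVA design for a sample table
#'
#' Shared precomputation (fixed-effect matrix, rank check, within-tetrad
#' orthonormal transform) reused across all genes of a study.
#'
#' @param meta A [sample_table()] (single region unless `scope = "pooled"`).
#' @param scope `"region"` (diagnosis + covariates) or `"pooled"` (adds
#'   region as a fixed factor).
#' @param covariates Covariate columns to adjust for; constant columns are
#'   dropped with a message.
#' @return Internal design object.
#' @export
ancova_design <- function(meta, scope = c("region", "pooled"),
                          covariates = DEFAULT_COVARIATES) {
  scope <- match.arg(scope)
  meta <- as.data.frame(meta)
  diag_present <- intersect(DIAGNOSIS_LEVELS, unique(as.character(meta$diagnosis)))
  if (length(diag_present) < 2)
    stop("need at least 2 diagnosis levels", call. = FALSE)
  meta$diagnosis <- factor(meta$diagnosis, levels = diag_present)
  terms_vec <- "diagnosis"
  if (scope == "pooled") {
    if (length(unique(meta$region)) > 1) {
      meta$region <- factor(meta$region,
                            levels = intersect(REGION_LEVELS, unique(meta$region)))
      terms_vec <- c(terms_vec, "region")
    }
  } else if (length(unique(meta$region)) > 1) {
    stop("scope = 'region' requires samples from a single region; subset first or use scope = 'pooled'",
         call. = FALSE)
  }
  keep <- character(0); dropped <- character(0)
  for (v in covariates) {
    if (length(unique(meta[[v]])) < 2) { dropped <- c(dropped, v); next }
    if (v %in% c("sex", "tobacco", "manner_of_death"))
      meta[[v]] <- factor(meta[[v]])
    keep <- c(keep, v)
  }
  if (length(dropped) > 0)
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  form <- reformulate(c(terms_vec, keep))
  mf <- stats::model.frame(form, meta)
  X <- model.matrix(form, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_listing("singular design; aliased column(s)", aliased)
  }
  grp <- factor(meta$tetrad_id)
  n <- nrow(X)
  # Orthonormal block transform: one scaled group-mean row per tetrad plus
  # orthonormal within-group (Helmert) contrasts.
  Q <- matrix(0, n, n)
  mvec <- numeric(n)
  r <- 0L
  for (g in levels(grp)) {
    idx <- which(grp == g)
    m <- length(idx)
    r <- r + 1L
    Q[r, idx] <- 1 / sqrt(m)
    mvec[r] <- m
    if (m > 1) {
      H <- stats::contr.helmert(m)
      H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
      for (j in seq_len(m - 1)) {
        r <- r + 1L
        Q[r, idx] <- H[, j]
      }
    }
  }
  df <- max(1, n - ncol(X) - nlevels(grp) + 1)  # containment df
  structure(list(X = X, Q = Q, mvec = mvec, meta = meta, formula = form,
                 terms = attr(mf, "terms"), diag_levels = diag_present,
                 n = n, p = ncol(X), n_tetrads = nlevels(grp), df = df,
                 dropped_covariates = dropped, scope = scope),
            class = "ancova_design")
}

# Fit all columns of Y (samples x genes) under one design. Returns REML
# estimates per gene.
ancova_engine <- function(design, Y) {
  X <- design$X
  n <- design$n; p <- design$p
  stopifnot(nrow(Y) == n)
  G <- ncol(Y)
  Xt <- design$Q %*% X
  Yt <- design$Q %*% Y
  is_mean <- design$mvec > 0
  ms <- sort(unique(design$mvec[is_mean]))
  A_c <- crossprod(Xt[!is_mean, , drop = FALSE])
  B_c <- crossprod(Xt[!is_mean, , drop = FALSE], Yt[!is_mean, , drop = FALSE])
  s_c <- colSums(Yt[!is_mean, , drop = FALSE]^2)
  A_m <- list(); B_m <- list(); s_m <- list(); cnt_m <- list()
  for (m in ms) {
    key <- as.character(m)
    rows <- which(design$mvec == m)
    Xm <- Xt[rows, , drop = FALSE]
    A_m[[key]] <- crossprod(Xm)
    B_m[[key]] <- crossprod(Xm, Yt[rows, , drop = FALSE])
    s_m[[key]] <- colSums(Yt[rows, , drop = FALSE]^2)
    cnt_m[[key]] <- length(rows)
  }
  dfree <- n - p

  weighted_parts <- function(lam, g) {
    Aw <- A_c; bw <- B_c[, g]; sw <- s_c[g]; logdetD <- 0
    for (key in names(A_m)) {
      m <- as.numeric(key)
      w <- 1 / (1 + m * lam)
      Aw <- Aw + w * A_m[[key]]
      bw <- bw + w * B_m[[key]][, g]
      sw <- sw + w * s_m[[key]][g]
      logdetD <- logdetD + cnt_m[[key]] * log(1 + m * lam)
    }
    R <- chol(Aw)
    beta <- backsolve(R, forwardsolve(t(R), bw))
    rss <- max(sw - sum(bw * beta), 0)
    list(beta = beta, rss = rss, Aw = Aw,
         crit = dfree * log(max(rss, 1e-300)) + logdetD +
           2 * sum(log(diag(R))))
  }

  coef_out <- matrix(NA_real_, p, G, dimnames = list(colnames(X), colnames(Y)))
  vcov_out <- array(NA_real_, c(p, p, G),
                    dimnames = list(colnames(X), colnames(X), NULL))
  sigma2 <- tau2 <- lambda <- numeric(G)
  for (g in seq_len(G)) {
    opt <- optimize(function(tl) weighted_parts(exp(tl), g)$crit,
                    interval = c(log(1e-8), log(1e6)))
    c0 <- weighted_parts(0, g)
    lam <- if (c0$crit <= opt$objective) 0 else exp(opt$minimum)
    parts <- if (lam == 0) c0 else weighted_parts(lam, g)
    s2 <- parts$rss / dfree
    coef_out[, g] <- parts$beta
    vcov_out[, , g] <- s2 * chol2inv(chol(parts$Aw))
    sigma2[g] <- s2
    tau2[g] <- lam * s2
    lambda[g] <- lam
  }
  list(coef = coef_out, vcov = vcov_out, sigma2 = sigma2, tau2 = tau2,
       lambda = lambda, df = design$df, n = n, p = p)
}

# Least-squares-mean contrast rows: one row per diagnosis, covariates at
# their means, categorical covariates at equal level weights.
lsmean_rows <- function(design) {
  X <- design$X
  assign <- attr(X, "assign")
  labels <- attr(design$terms, "term.labels")
  L <- numeric(ncol(X))
  names(L) <- colnames(X)
  for (j in seq_along(L)) {
    a <- assign[j]
    if (a == 0) { L[j] <- 1; next }
    term <- labels[a]
    if (term == "diagnosis") next
    v <- design$meta[[term]]
    L[j] <- if (is.factor(v)) 1 / nlevels(v) else mean(X[, j])
  }
  out <- matrix(rep(L, each = length(design$diag_levels)),
                nrow = length(design$diag_levels),
                dimnames = list(design$diag_levels, colnames(X)))
  for (d in design$diag_levels) {
    col <- paste0("diagnosis", d)
    if (col %in% colnames(X)) out[d, col] <- 1
  }
  out
}

#' Fit the mixed-model ANCOVA for a single gene (or analyte)
#'
#' REML fit of a linear model with diagnosis (and, for pooled scope, region)
#' as fixed factors, nuisance covariates, and a tetrad random intercept.
#'
#' @param y Numeric response per sample, on the log10 scale.
#' @param meta Matching [sample_table()].
#' @param scope `"region"` or `"pooled"` (region added as fixed factor).
#' @param covariates Covariates to adjust for.
#' @param design Optional precomputed [ancova_design()] (for reuse).
#' @return Object of class `"ancova_fit"` with elements `coefficients`,
#'   `vcov`, `sigma2` (residual variance), `tau2` (tetrad variance), `df`
#'   (containment degrees of freedom), `lsmeans` (least-squares mean per
#'   diagnosis), `diag_levels`, `n`, `n_tetrads`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_tetrads = 5, n_genes = 10,
#'                                         regions = "HIP"), seed = 1)
#' st <- sim$studies$HIP
#' fit <- fit_gene_ancova(st$expr[1, ], st$metadata)
#' disease_contrasts(fit)
fit_gene_ancova <- function(y, meta, scope = "region",
                            covariates = DEFAULT_COVARIATES, design = NULL) {
  if (is.null(design)) design <- ancova_design(meta, scope, covariates)
  y <- as.numeric(y)
  if (length(y) != design$n) stop("length(y) must match the design")
  if (any(!is.finite(y))) stop("y must be finite")
  eng <- ancova_engine(design, matrix(y, ncol = 1))
  beta <- setNames(eng$coef[, 1], rownames(eng$coef))
  L <- lsmean_rows(design)
  structure(list(coefficients = beta,
                 vcov = eng$vcov[, , 1],
                 sigma2 = eng$sigma2[1],
                 tau2 = eng$tau2[1],
                 df = eng$df,
                 lsmeans = drop(L %*% beta),
                 diag_levels = design$diag_levels,
                 n = design$n,
                 n_tetrads = design$n_tetrads,
                 design = design),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("ancova_fit: n = %d, tetrads = %d, df = %d\n", x$n,
              x$n_tetrads, x$df))
  cat(sprintf("sigma2 = %.4g, tau2 = %.4g\n", x$sigma2, x$tau2))
  cat("LS means:\n"); print(round(x$lsmeans, 4))
  invisible(x)
}

# t statistic with zero-variance guards: exact fits give se = 0; a zero
# estimate (up to solver round-off) then carries no evidence (p = 1), a
# genuinely nonzero one is certain (p = 0).
safe_t <- function(est, se) {
  t <- ifelse(se > 0, est / se,
              ifelse(abs(est) < 1e-10, 0, sign(est) * Inf))
  t[is.na(t)] <- 0
  t
}

#' Disease-versus-control least-squares-mean contrasts
#'
#' For each disease group present, the LS-mean difference to controls with
#' its standard error and a two-tailed t test on containment degrees of
#' freedom.
#'
#' @param fit An [fit_gene_ancova()] result.
#' @return data.frame with columns `diagnosis`, `estimate`, `se`, `df`,
#'   `statistic`, `p_raw`.
#' @export
disease_contrasts <- function(fit) {
  stopifnot(inherits(fit, "ancova_fit"))
  if (!"CTRL" %in% fit$diag_levels)
    stop("no control (CTRL) group in the fit", call. = FALSE)
  missing <- setdiff(setdiff(DIAGNOSIS_LEVELS, "CTRL"), fit$diag_levels)
  if (length(missing) > 0)
    warning("diagnosis level(s) absent; contrast omitted: ",
            paste(missing, collapse = ", "))
  dis <- setdiff(fit$diag_levels, "CTRL")
  est <- se <- numeric(length(dis))
  for (i in seq_along(dis)) {
    col <- paste0("diagnosis", dis[i])
    est[i] <- fit$coefficients[[col]]
    se[i] <- sqrt(max(fit$vcov[col, col], 0))
  }
  t <- safe_t(est, se)
  data.frame(diagnosis = dis, estimate = est, se = se, df = fit$df,
             statistic = t, p_raw = 2 * pt(-abs(t), fit$df),
             stringsAsFactors = FALSE)
}

#' Tukey-Kramer adjusted pairwise diagnosis comparisons
#'
#' All pairwise LS-mean differences among the diagnosis groups, with p-values
#' from the studentized range distribution (`ptukey`) using the model-based
#' (unequal-n safe) standard error of each difference. With two groups this
#' reduces exactly to the two-sample t test.
#'
#' @param fit An [fit_gene_ancova()] result.
#' @return data.frame with columns `group1`, `group2`, `estimate`, `se`,
#'   `statistic`, `p_raw`, `p_adj`; empty when only one group is present.
#' @export
tukey_kramer <- function(fit) {
  stopifnot(inherits(fit, "ancova_fit"))
  k <- length(fit$diag_levels)
  if (k < 2)
    return(data.frame(group1 = character(0), group2 = character(0),
                      estimate = numeric(0), se = numeric(0),
                      statistic = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  pairs <- combn(fit$diag_levels, 2)
  cvec <- function(d) {
    v <- numeric(length(fit$coefficients))
    names(v) <- names(fit$coefficients)
    col <- paste0("diagnosis", d)
    if (col %in% names(v)) v[col] <- 1   # CTRL is the reference: zero vector
    v
  }
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    estimate = NA_real_, se = NA_real_,
                    statistic = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    cv <- cvec(pairs[1, i]) - cvec(pairs[2, i])
    out$estimate[i] <- sum(cv * fit$coefficients)
    out$se[i] <- sqrt(max(drop(cv %*% fit$vcov %*% cv), 0))
  }
  out$statistic <- safe_t(out$estimate, out$se)
  out$p_raw <- 2 * pt(-abs(out$statistic), fit$df)
  if (fit$df >= 2) {
    out$p_adj <- ptukey(sqrt(2) * abs(out$statistic), nmeans = k,
                        df = fit$df, lower.tail = FALSE)
  } else {
    # The studentized range distribution is numerically undefined at 1
    # residual df; report the unadjusted p rather than NaN.
    warning("fewer than 2 residual df; Tukey-Kramer adjustment unavailable, returning raw p")
    out$p_adj <- out$p_raw
  }
  out$p_adj[!is.finite(out$statistic)] <- 0
  out$p_raw[!is.finite(out$statistic)] <- 0
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment (monotone-enforced, capped at 1).
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`; `NA`/`NaN` are
#'   rejected.
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvals) {
  if (any(is.na(pvals))) stop("p-values must not contain NA/NaN", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

#' Genome-wide differential expression for one region
#'
#' Fits the per-gene mixed-model ANCOVA across all genes of a study,
#' computes disease-versus-control contrasts, Tukey-Kramer adjusted pairwise
#' p-values, fold changes (`10^|estimate|`, the response being log10), and
#' BH-FDR within each (region, diagnosis) contrast family.
#'
#' @param study An [expression_study()] (single region, or use `region` to
#'   subset a pooled study).
#' @param region Optional region to subset to.
#' @param covariates Covariates to adjust for.
#' @param omnibus_gate If `TRUE`, contrasts are only FDR-scored for genes
#'   whose diagnosis main-effect Wald F test has p < 0.05 (others get
#'   `p_adj = NA`); default off.
#' @return A `contrast_table` data.frame with columns `gene`, `region`,
#'   `diagnosis`, `estimate`, `se`, `df`, `p_raw`, `p_tukey`, `fold_change`,
#'   `direction`, `p_adj`, `significant`.
#' @export
de_analysis <- function(study, region = NULL,
                        covariates = DEFAULT_COVARIATES,
                        omnibus_gate = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  expr <- study$expr
  meta <- study$metadata
  if (!is.null(region)) {
    sel <- meta$region == region
    if (!any(sel)) stop("no samples in region ", region)
    expr <- expr[, sel, drop = FALSE]
    meta <- meta[sel, , drop = FALSE]
  }
  region_label <- unique(as.character(meta$region))
  if (length(region_label) != 1)
    stop("de_analysis runs per region; pass `region` to subset", call. = FALSE)
  design <- ancova_design(meta, scope = "region", covariates = covariates)
  eng <- ancova_engine(design, t(expr))
  genes <- rownames(expr)
  G <- length(genes)
  dis <- setdiff(design$diag_levels, "CTRL")
  k <- length(design$diag_levels)

  gate_pass <- rep(TRUE, G)
  if (omnibus_gate && length(dis) > 0) {
    cols <- paste0("diagnosis", dis)
    for (g in seq_len(G)) {
      V <- eng$vcov[cols, cols, g, drop = FALSE][, , 1]
      b <- eng$coef[cols, g]
      Fstat <- tryCatch(drop(b %*% solve(V, b)) / length(b),
                        error = function(e) Inf)
      p_omni <- stats::pf(Fstat, length(b), eng$df, lower.tail = FALSE)
      gate_pass[g] <- is.finite(Fstat) && p_omni < 0.05 ||
        (!is.finite(Fstat) && any(b != 0))
    }
  }

  out <- list()
  for (d in dis) {
    col <- paste0("diagnosis", d)
    est <- eng$coef[col, ]
    se <- sqrt(pmax(eng$vcov[col, col, ], 0))
    t <- safe_t(est, se)
    p_raw <- 2 * pt(-abs(t), eng$df)
    p_raw[!is.finite(t)] <- 0
    p_tukey <- if (eng$df >= 2)
      ptukey(sqrt(2) * abs(t), nmeans = k, df = eng$df, lower.tail = FALSE)
    else p_raw
    p_tukey[!is.finite(t)] <- 0
    p_adj <- rep(NA_real_, G)
    p_adj[gate_pass] <- bh_fdr(p_raw[gate_pass])
    out[[d]] <- data.frame(
      gene = genes, region = region_label, diagnosis = d,
      estimate = est, se = se, df = eng$df, p_raw = p_raw,
      p_tukey = p_tukey, fold_change = 10^abs(est),
      direction = ifelse(est >= 0, "up", "down"),
      p_adj = p_adj,
      significant = !is.na(p_adj) & p_adj < 0.05 & 10^abs(est) > 1.2,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_table", "data.frame")
  res
}

#' Select differentially expressed genes
#'
#' Strict fold-change threshold (`fold_change > fold_min`) combined with the
#' FDR threshold (`p_adj < fdr_max`); direction comes from the sign of the
#' LS-mean difference.
#'
#' @param contrasts A `contrast_table` from [de_analysis()] (tables from
#'   several regions may be `rbind`-ed).
#' @param fold_min Fold-change threshold, exclusive (default 1.2).
#' @param fdr_max FDR threshold, exclusive (default 0.05).
#' @return Nested list: `result[[diagnosis]][[region]]` is a list with
#'   character vectors `up` and `down`.
#' @export
select_de_genes <- function(contrasts, fold_min = 1.2, fdr_max = 0.05) {
  hit <- !is.na(contrasts$p_adj) & contrasts$p_adj < fdr_max &
    contrasts$fold_change > fold_min
  out <- list()
  for (d in unique(contrasts$diagnosis)) {
    out[[d]] <- list()
    for (r in unique(contrasts$region[contrasts$diagnosis == d])) {
      sel <- hit & contrasts$diagnosis == d & contrasts$region == r
      out[[d]][[r]] <- list(
        up = contrasts$gene[sel & contrasts$direction == "up"],
        down = contrasts$gene[sel & contrasts$direction == "down"])
    }
  }
  out
}
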