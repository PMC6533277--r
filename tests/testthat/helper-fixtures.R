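# Shared fixtures and independent oracles for the test suite.

# Simulation config with no planted signal (pure noise study).
null_config <- function(n_genes = 400, n_tetrads = 19,
                        regions = c("DLPFC", "HIP", "STR")) {
  simulation_config(n_tetrads = n_tetrads, n_genes = n_genes,
                    regions = regions,
                    de_plan = default_de_plan()[0, ],
                    module_plan = default_module_plan()[0, ])
}

# Small signal-free study for fitter tests.
small_noise_study <- function(seed = 1, n_tetrads = 6, n_genes = 10,
                              region = "HIP") {
  sim <- simulate_study(null_config(n_genes, n_tetrads, region), seed = seed)
  sim$studies[[region]]
}

# Metadata for a balanced toy design with constant covariates (which the
# fitter drops), so the model is diagnosis + tetrad intercept only.
toy_meta <- function(n_tetrads = 2) {
  rows <- expand.grid(diagnosis = c("CTRL", "SCZ", "BD", "MDD"),
                      tetrad_id = sprintf("T%02d", seq_len(n_tetrads)),
                      stringsAsFactors = FALSE)
  sample_table(data.frame(
    subject_id = paste(rows$tetrad_id, rows$diagnosis, sep = "_"),
    tetrad_id = rows$tetrad_id, region = "HIP", diagnosis = rows$diagnosis,
    age = 50, sex = "M", tobacco = "no", manner_of_death = "natural",
    pmi = 15, ph = 6.8, stringsAsFactors = FALSE))
}

# Exhaustive hypergeometric tail oracle: P(X >= k) for overlap X of a draw
# of size n from a universe of N with K marked, by direct enumeration of
# all achievable overlap values via log-binomial coefficients.
hyper_tail_enum <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(probs[ks >= k])
}

# Brute-force TOM oracle (double loop over the definition).
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# GLS solve from the explicit marginal covariance sigma2*I + tau2*ZZ'.
gls_oracle <- function(y, X, tetrad, tau2, sigma2) {
  Z <- model.matrix(~ 0 + factor(tetrad))
  V <- tau2 * Z %*% t(Z) + sigma2 * diag(length(y))
  W <- solve(V)
  drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% y))
}

# Planted two-block correlation structure: within-block correlation rho,
# zero across blocks; genes x samples.
planted_blocks_expr <- function(sizes, rho, n_samples, seed = 1,
                                noise_genes = 0) {
  stopifnot(rho > 0, rho < 1)
  tetranet:::with_seed(seed, {
    load <- sqrt(rho / (1 - rho))
    mats <- lapply(seq_along(sizes), function(b) {
      f <- rnorm(n_samples)
      t(sapply(seq_len(sizes[b]), function(i)
        load * f + rnorm(n_samples)))
    })
    out <- do.call(rbind, mats)
    if (noise_genes > 0)
      out <- rbind(out, matrix(rnorm(noise_genes * n_samples),
                               noise_genes, n_samples))
    rownames(out) <- sprintf("g%04d", seq_len(nrow(out)))
    colnames(out) <- sprintf("s%03d", seq_len(n_samples))
    out
  })
}

# qPCR plate with optional per-gene group bias (log10 scale) and noise sd.
toy_plate <- function(n_samples = 24, genes = paste0("g", 1:5),
                      bias = setNames(numeric(length(genes)), genes),
                      noise_sd = rep(0.05, length(genes)), seed = 1) {
  tetranet:::with_seed(seed, {
    samples <- paste0("S", seq_len(n_samples))
    grp <- rep(c("CTRL", "SCZ"), each = n_samples / 2)
    rows <- lapply(seq_along(genes), function(i) {
      lq <- rnorm(n_samples, 1, noise_sd[i]) + bias[[genes[i]]] * (grp == "SCZ")
      data.frame(sample_id = samples, gene = genes[i], replicate = 1L,
                 quantity = 10^lq, diagnosis = grp, region = "HIP",
                 stringsAsFactors = FALSE)
    })
    qpcr_plate(do.call(rbind, rows))
  })
}
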