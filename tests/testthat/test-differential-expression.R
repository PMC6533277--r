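# Mixed-model ANCOVA fitter, contrasts, multiplicity adjustments.

test_that("constant response gives zero effects, zero variances, p = 1", {
  meta <- toy_meta(2)
  fit <- suppressMessages(fit_gene_ancova(rep(3.14, nrow(meta)), meta))
  expect_lt(fit$sigma2, 1e-20)
  expect_lt(fit$tau2, 1e-20)
  ct <- disease_contrasts(fit)
  expect_equal(ct$estimate, rep(0, 3))
  expect_equal(ct$p_raw, rep(1, 3))
  tk <- tukey_kramer(fit)
  expect_equal(tk$p_adj, rep(1, 6))
})

test_that("a noiseless planted shift is recovered exactly", {
  meta <- toy_meta(2)
  delta <- 0.37
  y <- 1 + delta * (meta$diagnosis == "SCZ")
  fit <- suppressMessages(fit_gene_ancova(y, meta))
  ct <- disease_contrasts(fit)
  expect_lt(abs(ct$estimate[ct$diagnosis == "SCZ"] - delta), 1e-8)
  expect_equal(ct$estimate[ct$diagnosis != "SCZ"], rep(0, 2))
})

test_that("fixed effects match the explicit GLS oracle at fitted components", {
  for (seed in 1:3) {
    st <- small_noise_study(seed = seed, n_tetrads = 8, n_genes = 3)
    for (g in 1:3) {
      y <- st$expr[g, ]
      fit <- fit_gene_ancova(y, st$metadata)
      beta <- gls_oracle(y, fit$design$X, st$metadata$tetrad_id,
                         fit$tau2, fit$sigma2)
      expect_lt(max(abs(fit$coefficients - beta)), 1e-6)
    }
  }
})

test_that("REML estimates agree with lme4 on the same model", {
  st <- small_noise_study(seed = 5, n_tetrads = 10, n_genes = 4)
  d <- as.data.frame(st$metadata)
  d$diagnosis <- factor(d$diagnosis, levels = c("CTRL", "SCZ", "BD", "MDD"))
  for (g in 1:4) {
    d$y <- st$expr[g, ]
    fit <- fit_gene_ancova(d$y, st$metadata)
    lf <- lme4::lmer(
      y ~ diagnosis + age + sex + tobacco + manner_of_death + pmi + ph +
        (1 | tetrad_id), data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    fe <- lme4::fixef(lf)
    expect_lt(max(abs(fit$coefficients[names(fe)] - fe)), 1e-4)
    expect_lt(abs(fit$sigma2 - sigma(lf)^2), 1e-5)
    expect_lt(abs(fit$tau2 - as.numeric(lme4::VarCorr(lf)$tetrad_id)), 1e-5)
  }
})

test_that("singular designs are rejected naming the aliased columns", {
  meta <- as.data.frame(toy_meta(2))
  meta$age <- seq_len(nrow(meta))
  meta$pmi <- 2 * meta$age   # aliased with age
  expect_error(suppressMessages(ancova_design(sample_table(meta))), "pmi")
})

test_that("Tukey-Kramer reduces to the t test with two groups", {
  st <- small_noise_study(seed = 3, n_tetrads = 14, n_genes = 1)
  keep <- st$metadata$diagnosis %in% c("CTRL", "SCZ")
  meta2 <- st$metadata[keep, ]
  fit <- fit_gene_ancova(st$expr[1, keep], meta2)
  tk <- tukey_kramer(fit)
  expect_equal(nrow(tk), 1)
  expect_equal(tk$p_adj, tk$p_raw, tolerance = 1e-3)
})

test_that("Tukey-Kramer p is monotone in the planted shift and never below raw p", {
  meta <- toy_meta(5)
  p_seq <- vapply(c(0.05, 0.1, 0.2, 0.4), function(delta) {
    y <- 1 + delta * (meta$diagnosis == "SCZ") +
      tetranet:::with_seed(99, rnorm(nrow(meta), 0, 0.02))
    tk <- tukey_kramer(suppressMessages(fit_gene_ancova(y, meta)))
    tk$p_adj[tk$group1 == "CTRL" & tk$group2 == "SCZ"]
  }, 1)
  expect_true(all(diff(p_seq) < 0))

  st <- small_noise_study(seed = 7, n_tetrads = 5, n_genes = 50)
  design <- ancova_design(st$metadata)
  for (g in seq_len(50)) {
    fit <- fit_gene_ancova(st$expr[g, ], st$metadata, design = design)
    tk <- tukey_kramer(fit)
    expect_true(all(tk$p_adj >= tk$p_raw - 1e-12))
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  for (seed in 1:5) {
    p <- tetranet:::with_seed(seed, runif(50)^2)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("DE selection applies the strict fold cut and signed direction", {
  ct <- data.frame(
    gene = c("a", "b", "c"), region = "HIP", diagnosis = "SCZ",
    estimate = c(log10(1.2), -log10(1.5), log10(2)),
    fold_change = c(1.2, 1.5, 2),
    direction = c("up", "down", "up"),
    p_adj = c(0.001, 0.049, 0.2))
  sel <- select_de_genes(ct)
  expect_false("a" %in% c(sel$SCZ$HIP$up, sel$SCZ$HIP$down))  # fold == 1.2
  expect_equal(sel$SCZ$HIP$down, "b")
  expect_false("c" %in% sel$SCZ$HIP$up)                        # p_adj too big
})

test_that("contrast table is internally consistent on simulated data", {
  sim <- simulate_study(simulation_config(
    n_tetrads = 8, n_genes = 80, regions = "HIP",
    module_plan = default_module_plan()[0, ]), seed = 13)
  ct <- de_analysis(sim$studies$HIP)
  expect_equal(ct$fold_change, 10^abs(ct$estimate))
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-12))
  expect_true(all(ct$p_adj <= 1 & ct$p_adj >= 0))
  expect_setequal(unique(ct$diagnosis), c("SCZ", "BD", "MDD"))
})

test_that("null p-values are uniform in a small calibration run", {
  sim <- simulate_study(null_config(n_genes = 400, regions = "HIP"), seed = 21)
  ct <- de_analysis(sim$studies$HIP)
  for (d in c("SCZ", "BD", "MDD")) {
    ks <- suppressWarnings(stats::ks.test(ct$p_raw[ct$diagnosis == d], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the omnibus gate withholds FDR scoring, not raw p-values", {
  sim <- simulate_study(null_config(n_genes = 60, n_tetrads = 6,
                                    regions = "HIP"), seed = 3)
  ct <- de_analysis(sim$studies$HIP, omnibus_gate = TRUE)
  expect_true(any(is.na(ct$p_adj)))
  expect_true(all(!is.na(ct$p_raw)))
  expect_true(all(!ct$significant[is.na(ct$p_adj)]))
})
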