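# Synthetic study generator: determinism, validation, planted truth.

test_that("simulation is deterministic given config and seed", {
  cfg <- simulation_config(n_tetrads = 4, n_genes = 60,
                           module_plan = default_module_plan()[0, ])
  a <- simulate_study(cfg, seed = 11)
  b <- simulate_study(cfg, seed = 11)
  expect_identical(a$studies$HIP$expr, b$studies$HIP$expr)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(cfg, seed = 12)
  expect_false(identical(a$studies$HIP$expr, c$studies$HIP$expr))
})

test_that("subject covariates do not move when the gene count changes", {
  s1 <- simulate_study(null_config(n_genes = 20, n_tetrads = 5), seed = 4)
  s2 <- simulate_study(null_config(n_genes = 200, n_tetrads = 5), seed = 4)
  expect_identical(as.data.frame(s1$studies$HIP$metadata),
                   as.data.frame(s2$studies$HIP$metadata))
})

test_that("config invariants are enforced before sampling", {
  expect_error(simulation_config(de_plan = data.frame(
    diagnosis = "SCZ", region = "HIP", fraction = 1.2, mean_effect = 0.1)),
    "fractions")
  expect_error(simulation_config(n_genes = 100, module_plan = data.frame(
    module = "M1", size = 200, cor = 0.5, diagnosis = NA, shift = 0,
    direction = NA)), "module sizes")
  expect_error(simulation_config(residual_sd = 0), "residual_sd")
  expect_error(simulation_config(regions = "CEREBELLUM"), "CEREBELLUM")
})

test_that("planted truth is consistent with the plan", {
  cfg <- simulation_config(n_tetrads = 5, n_genes = 800)
  sim <- simulate_study(cfg, seed = 2)
  expect_true(all(sim$truth$de_genes$effect != 0))
  mm <- sim$truth$module_membership
  sizes <- table(mm[!is.na(mm)])
  expect_equal(sort(as.integer(sizes)),
               sort(default_module_plan()$size))
  # Module-associated diagnosis effects are bookkept for every region.
  m1 <- names(mm)[!is.na(mm) & mm == "M1"]
  for (r in cfg$regions) {
    rows <- sim$truth$de_genes[sim$truth$de_genes$region == r &
                                 sim$truth$de_genes$diagnosis == "SCZ", ]
    expect_true(all(m1 %in% rows$gene))
    expect_true(all(rows$effect[match(m1, rows$gene)] > 0))
  }
})

test_that("fixture emission writes the full inventory, byte-stable", {
  sim <- simulate_study(null_config(n_genes = 40, n_tetrads = 4), seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_fixture(sim, d1, seed = 3)
  emit_fixture(sim, d2, seed = 3)
  expect_setequal(basename(list.files(d1)),
                  c("expr_DLPFC.tsv", "expr_HIP.tsv", "expr_STR.tsv",
                    "metadata.tsv", "genesets.gmt", "truth_de.tsv",
                    "truth_modules.tsv"))
  for (f in basename(list.files(d1)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  expr <- read_expression_matrix(file.path(d1, "expr_STR.tsv"))
  expect_identical(expr, sim$studies$STR$expr)
})

test_that("decoy-set enrichment p-values are conservative under the null", {
  # Decoys are random non-module genes, so against a DE list they behave as
  # null sets: the one-sided Fisher p should be stochastically >= uniform.
  sim <- simulate_study(simulation_config(
    n_tetrads = 19, n_genes = 1000, regions = "HIP",
    de_plan = data.frame(diagnosis = "SCZ", region = "HIP",
                         fraction = 0.05, mean_effect = 0.2),
    module_plan = default_module_plan()[0, ]), seed = 8)
  dir <- withr::local_tempdir()
  emit_fixture(sim, dir, seed = 8, n_decoys = 40, decoy_size = 50)
  gsc <- read_gmt(file.path(dir, "genesets.gmt"))
  de <- select_de_genes(de_analysis(sim$studies$HIP))
  res <- enrich_de_lists(de["SCZ"], gsc,
                         universe = sim$studies$HIP$gene_ids)
  p <- res$p[grepl("^DECOY", res$set)]
  expect_length(p, 40)
  # conservative: no excess of small p beyond binomial slack
  expect_lte(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})
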