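# Signed consensus network: adjacency, TOM, consensus, blocks, tree cut,
# refinement, merging, module statistics.

test_that("signed adjacency matches its closed forms", {
  s <- seq_len(8)
  expr <- rbind(g1 = s + 0, g2 = 2 * s + 3,             # r = 1
                g3 = -s,                                # r = -1 with g1
                g4 = rep(c(1, -1), 4),                  # orthogonal pair:
                g5 = rep(c(1, 1, -1, -1), 2))           # r(g4, g5) = 0
  a <- signed_adjacency(expr, power = 12)
  expect_equal(a["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(a["g1", "g3"], 0, tolerance = 1e-12)
  expect_equal(a["g4", "g5"], 0.5^12, tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(diag(a), setNames(rep(1, 5), rownames(expr)))

  bad <- rbind(expr, g6 = rep(1, 8))
  expect_error(signed_adjacency(bad, 12), "g6")
})

test_that("scale-free fit is near 1 for a power-law toy and errors when degenerate", {
  # Rank-one adjacency: k_i proportional to c_i, c drawn from a power law.
  c_i <- tetranet:::with_seed(1, (runif(400, 0.05, 1))^(-1/1.5))
  c_i <- c_i / max(c_i)
  a <- outer(c_i, c_i)
  diag(a) <- 1
  rownames(a) <- colnames(a) <- paste0("g", seq_along(c_i))
  expect_gt(scale_free_fit(a), 0.9)

  eq <- matrix(0.3, 60, 60); diag(eq) <- 1
  expect_error(scale_free_fit(eq), "degenerate")
  expect_error(scale_free_fit(a[1:10, 1:10]), "50")
})

test_that("TOM matches the brute-force oracle and its fixed points", {
  id <- diag(5)
  dimnames(id) <- list(paste0("g", 1:5), paste0("g", 1:5))
  expect_equal(topological_overlap(id), id)

  pair <- diag(4); pair[1, 2] <- pair[2, 1] <- 1
  expect_equal(topological_overlap(pair)[1, 2], 1)

  for (seed in 1:5) {
    a <- tetranet:::with_seed(seed, {
      m <- matrix(runif(64), 8, 8); m <- (m + t(m)) / 2; diag(m) <- 1; m
    })
    dimnames(a) <- list(paste0("g", 1:8), paste0("g", 1:8))
    expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-12)
  }

  asym <- matrix(runif(16), 4, 4)
  expect_error(topological_overlap(asym), "symmetric")
})

test_that("consensus TOM scaling algebra and minimality hold", {
  a <- tetranet:::with_seed(2, {
    m <- matrix(runif(100, 0, 0.6), 10, 10); m <- (m + t(m)) / 2
    diag(m) <- 1; m
  })
  dimnames(a) <- list(paste0("g", 1:10), paste0("g", 1:10))
  expect_equal(consensus_tom(list(a, a, a)), a)

  half <- a / 2; diag(half) <- 1
  cons <- consensus_tom(list(a, half), q = 0.5)
  off <- upper.tri(a)
  expect_equal(cons[off], a[off], tolerance = 1e-12)

  b <- tetranet:::with_seed(3, {
    m <- matrix(runif(100, 0, 0.6), 10, 10); m <- (m + t(m)) / 2
    diag(m) <- 1; m
  })
  dimnames(b) <- dimnames(a)
  q_ref <- quantile(a[off], 0.95)
  scaled_b <- b * (q_ref / quantile(b[off], 0.95))
  cons <- consensus_tom(list(a, b), q = 0.95)
  expect_true(all(cons[off] <= a[off] + 1e-12))
  expect_true(all(cons[off] <= scaled_b[off] + 1e-12))

  expect_error(consensus_tom(list(a, b[1:5, 1:5])), "dimensions")
})

test_that("projective k-means separates profile shapes, not signs", {
  expect_equal(unname(preassign_blocks(planted_blocks_expr(c(10), 0.9, 30), 1)),
               rep(1L, 10))
  # Two families; second family is the sign-flip of an independent shape.
  e <- planted_blocks_expr(c(40, 40), 0.8, 40, seed = 5)
  e[41:80, ] <- -e[41:80, ]
  blocks <- preassign_blocks(e, 2, seed = 1)
  expect_equal(length(unique(blocks[1:40])), 1)
  expect_equal(length(unique(blocks[41:80])), 1)
  expect_false(blocks[[1]] == blocks[[41]])
  expect_identical(blocks, preassign_blocks(e, 2, seed = 1))
  expect_error(preassign_blocks(e, 100), "exceed")
})

test_that("the tree cut recovers planted partitions exactly", {
  e <- planted_blocks_expr(c(100, 100), 0.8, 60, seed = 2)
  tom <- topological_overlap(signed_adjacency(e, 12))
  labels <- cut_dendrogram(tom, network_config())
  expect_equal(length(setdiff(unique(labels), 0L)), 2)
  expect_equal(length(unique(labels[1:100])), 1)
  expect_equal(length(unique(labels[101:200])), 1)
  expect_false(labels[[1]] == labels[[101]])
})

test_that("pure-noise input yields no modules", {
  for (seed in 1:5) {
    e <- tetranet:::with_seed(seed,
      matrix(rnorm(300 * 76), 300, 76,
             dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:76))))
    tom <- topological_overlap(signed_adjacency(e, 12))
    labels <- cut_dendrogram(tom, network_config())
    expect_equal(sum(labels > 0), 0)
  }
})

test_that("gene-order permutation permutes labels identically", {
  e <- planted_blocks_expr(c(80, 60), 0.7, 50, seed = 4, noise_genes = 40)
  tom <- topological_overlap(signed_adjacency(e, 12))
  labels <- cut_dendrogram(tom, network_config())
  perm <- tetranet:::with_seed(1, sample.int(nrow(e)))
  labels_p <- cut_dendrogram(tom[perm, perm], network_config())
  expect_identical(labels_p, labels[perm])
})

test_that("eigengines are unit-norm, oriented, and explain the most variance", {
  e <- planted_blocks_expr(c(50), 0.7, 40, seed = 6)
  es <- tetranet:::standardize_rows(e)
  eig <- tetranet:::module_eigengenes(es, setNames(rep(1L, 50), rownames(e)))
  me <- eig$ME[, "1"]
  expect_equal(sum(me^2), 1, tolerance = 1e-12)
  expect_gt(mean(eig$kME[, "1"]), 0)
  # ME optimality: variance explained by the ME is at least that of the best
  # single standardized member profile.
  M <- t(es)
  total <- sum(M^2)
  ve_me <- sum((t(M) %*% me)^2) / total
  ve_genes <- vapply(seq_len(nrow(es)), function(i) {
    u <- M[, i] / sqrt(sum(M[, i]^2))
    sum((t(M) %*% u)^2) / total
  }, 1)
  expect_true(all(ve_me >= ve_genes - 1e-12))
})

test_that("refinement removes weak genes and disbands unsupported modules", {
  e <- planted_blocks_expr(c(60), 0.7, 80, seed = 7, noise_genes = 30)
  es <- tetranet:::standardize_rows(e)
  labels <- setNames(c(rep(1L, 60), rep(0L, 30)), rownames(e))
  sol <- refine_modules(es, labels, network_config())
  expect_equal(sum(sol$labels > 0), 60)   # clean module: nothing removed

  # Attaching noise genes to the module: they fall below kME 0.3 and go.
  labels_bad <- setNames(c(rep(1L, 60), rep(1L, 30)), rownames(e))
  sol <- refine_modules(es, labels_bad, network_config())
  expect_true(all(sol$labels[61:90] == 0))
  expect_true(all(sol$labels[1:60] == 1))

  # A 16-gene module cannot satisfy the >= 17 strong-gene rule.
  e16 <- planted_blocks_expr(c(16), 0.95, 80, seed = 8)
  sol <- refine_modules(tetranet:::standardize_rows(e16),
                        setNames(rep(1L, 16), rownames(e16)),
                        network_config())
  expect_true(all(sol$labels == 0))
})

test_that("genes loading far more strongly on another eigengene are reassigned", {
  tetranet:::with_seed(9, {
    fA <- rnorm(100); fB <- rnorm(100)
    strong <- sqrt(0.9 / 0.1)
    # The misfiled gene keeps kME to its assigned module above the 0.3
    # removal cut but correlates far more strongly with the other factor.
    e <- rbind(
      t(sapply(1:40, function(i) strong * fA + rnorm(100))),
      t(sapply(1:40, function(i) strong * fB + rnorm(100))),
      mis = 1.6 * fA + 3.5 * fB + rnorm(100, 0, 0.3))
    rownames(e) <- c(sprintf("a%02d", 1:40), sprintf("b%02d", 1:40), "mis")
    colnames(e) <- sprintf("s%03d", 1:100)
    labels <- setNames(c(rep(1L, 40), rep(2L, 40), 1L), rownames(e))
    sol <- refine_modules(tetranet:::standardize_rows(e), labels,
                          network_config())
    expect_equal(unname(sol$labels["mis"]), unname(sol$labels[["b01"]]))
  })
})

test_that("eigengene merging folds split modules and is idempotent", {
  # One factor split into two label groups: ME correlation ~ 1 -> merged.
  e <- planted_blocks_expr(c(120), 0.7, 60, seed = 10)
  es <- tetranet:::standardize_rows(e)
  labels <- setNames(c(rep(1L, 60), rep(2L, 60)), rownames(e))
  sol <- tetranet:::new_module_solution(es, labels, network_config())
  merged <- merge_modules(sol)
  expect_equal(length(setdiff(unique(merged$labels), 0L)), 1)
  expect_gte(merged$n_merge_iterations, 1)

  # Independent factors stay separate, and merging is a fixed point.
  e2 <- planted_blocks_expr(c(60, 60), 0.7, 60, seed = 11)
  es2 <- tetranet:::standardize_rows(e2)
  labels2 <- setNames(c(rep(1L, 60), rep(2L, 60)), rownames(e2))
  sol2 <- merge_modules(tetranet:::new_module_solution(es2, labels2,
                                                       network_config()))
  expect_equal(length(setdiff(unique(sol2$labels), 0L)), 2)
  again <- merge_modules(sol2)
  expect_identical(again$labels, sol2$labels)
})

test_that("module-trait statistics match the Fisher-z closed form", {
  expect_equal(fisher_z_p(0.5, 28), 2 * pnorm(-atanh(0.5) * 5))

  me <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1) / sqrt(8), ncol = 1,
               dimnames = list(NULL, "1"))
  flat <- matrix(c(1, 1, -1, -1, 1, 1, -1, -1), ncol = 1,
                 dimnames = list(NULL, "zero_r"))
  st <- module_trait_stats(me, flat)
  expect_equal(st$r, 0)
  expect_equal(st$p, 1)

  expect_error(module_trait_stats(me[1:3, , drop = FALSE],
                                  flat[1:3, , drop = FALSE]), "4")
})

test_that("module DE enrichment delegates to fisher_enrichment", {
  e <- planted_blocks_expr(c(30), 0.7, 40, seed = 12, noise_genes = 20)
  es <- tetranet:::standardize_rows(e)
  labels <- setNames(c(rep(1L, 30), rep(0L, 20)), rownames(e))
  sol <- tetranet:::new_module_solution(es, labels, network_config())
  de <- list(SCZ = list(HIP = list(up = rownames(e)[c(1:10, 41:45)],
                                   down = rownames(e)[11:15])))
  res <- module_de_enrichment(sol, de)
  direct <- fisher_enrichment(c(de$SCZ$HIP$up, de$SCZ$HIP$down),
                              rownames(e)[1:30], rownames(e))
  expect_equal(res$p, direct$p)
  expect_equal(res$overlap, direct$overlap)

  de_null <- list(SCZ = list(HIP = list(up = rownames(e)[41:44],
                                        down = character(0))))
  expect_gt(module_de_enrichment(sol, de_null)$p, 0.5)
})
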