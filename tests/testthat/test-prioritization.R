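module6 <- CoexpressionModule("mod6", sprintf("g%02d", 1:6))

test_that("module PCA matches an SVD oracle on a random fixture", {
  expr <- randomExpr(6, 8, seed = 42)
  pca <- modulePCA(expr, module6)
  ## oracle: full SVD of the standardized samples x genes submatrix
  X <- scale(t(exprValues(expr)))
  sv <- svd(X)$d
  ve_oracle <- sv^2 / sum(sv^2)
  expect_equal(varianceFractions(pca)[1:5], ve_oracle[1:5], tolerance = 1e-8)
  expect_equal(sum(varianceFractions(pca)) <= 1 + 1e-8, TRUE)
  ## sign convention: component scores correlate +/-1 with prcomp scores
  pr <- prcomp(X)
  for (k in 1:5)
    expect_equal(abs(cor(componentScores(pca)[, k], pr$x[, k])), 1,
                 tolerance = 1e-8)
})

test_that("a rank-1 module concentrates all variance on the first component", {
  base <- rnorm(8) + 8
  v <- matrix(rep(abs(base), 6), nrow = 6, byrow = TRUE,
              dimnames = list(sprintf("g%02d", 1:6), sprintf("s%02d", 1:8)))
  expr <- makeExpr(v)
  pca <- modulePCA(expr, module6)
  expect_equal(varianceFractions(pca)[1], 1, tolerance = 1e-6)
  expect_lt(sum(varianceFractions(pca)[2:5]), 1e-6)
  ## every gene correlates perfectly with the sole component -> score 1
  sc <- geneRankingScores(expr, pca, module6)
  expect_equal(sc$score, rep(1, 6), tolerance = 1e-6)
})

test_that("module PCA rejects degenerate and undersized inputs", {
  one_gene <- CoexpressionModule("m1", "g01")
  expect_error(modulePCA(randomExpr(6, 8), one_gene),
               class = "panelign_insufficient_data_error")
  v <- matrix(5, nrow = 6, ncol = 8,
              dimnames = list(sprintf("g%02d", 1:6), sprintf("s%02d", 1:8)))
  expect_error(modulePCA(makeExpr(v), module6),
               class = "panelign_degenerate_input_error")
  expect_error(modulePCA(randomExpr(6, 2), module6),
               class = "panelign_insufficient_data_error")
  expect_error(modulePCA(randomExpr(6, 8, unit = "raw_count"), module6),
               class = "panelign_contract_error")
})

test_that("ranking scores equal the direct correlation-weighted oracle", {
  expr <- randomExpr(6, 8, seed = 7)
  pca <- modulePCA(expr, module6)
  sc <- geneRankingScores(expr, pca, module6)
  v <- exprValues(expr)
  S <- componentScores(pca); ve <- varianceFractions(pca)
  for (i in seq_len(nrow(sc))) {
    r <- vapply(1:5, function(k) cor(v[sc$gene[i], ], S[, k]), numeric(1))
    expect_equal(sc$score[i], abs(sum(r * ve)), tolerance = 1e-8)
  }
  ## sorted descending, bounded by the total retained variance
  expect_false(is.unsorted(rev(sc$score)))
  expect_true(all(sc$score <= sum(ve) + 1e-8))
  ## sum-of-abs variant dominates abs-of-sum
  sc2 <- geneRankingScores(expr, pca, module6, variant = "sum_of_abs")
  expect_true(all(sc2$score[match(sc$gene, sc2$gene)] >= sc$score - 1e-12))
})

test_that("scores are invariant to positive rescaling and flag constant genes", {
  expr <- randomExpr(6, 8, seed = 9)
  pca <- modulePCA(expr, module6)
  sc <- geneRankingScores(expr, pca, module6)
  scaled <- makeExpr(exprValues(expr) * 3.7)
  pca2 <- modulePCA(scaled, module6)
  sc2 <- geneRankingScores(scaled, pca2, module6)
  expect_equal(sc2$score[match(sc$gene, sc2$gene)], sc$score,
               tolerance = 1e-8)

  v <- exprValues(expr)
  v["g03", ] <- 4  # constant gene in a varying module
  expr3 <- makeExpr(v)
  sc3 <- geneRankingScores(expr3, modulePCA(expr3, module6), module6)
  expect_equal(sc3$score[sc3$gene == "g03"], 0)

  other <- CoexpressionModule("other", sprintf("g%02d", 1:6))
  expect_error(geneRankingScores(expr, pca, other),
               class = "panelign_contract_error")
})

test_that("candidate filtering keeps expressed one-to-one orthologs in order", {
  scores <- data.frame(gene = sprintf("h%02d", 1:10), module_id = "m",
                       score = seq(1, 0.1, length.out = 10))
  ## 7 genes have orthologs; of those, 5 are expressed above threshold
  orth <- OrthologMap(data.frame(
    human_gene = sprintf("h%02d", 1:7),
    mouse_gene = sprintf("m%02d", 1:7), dn = 0.1, ds = 1))
  tpm <- matrix(rep(c(5, 5, 5, 5, 5, 0.2, 0.4), 2), ncol = 2,
                dimnames = list(sprintf("m%02d", 1:7), c("r1", "r2")))
  ref <- makeExpr(tpm, unit = "tpm")
  out <- filterCandidates(scores, orth, ref, tpm_threshold = 1)
  expect_equal(out$gene, sprintf("h%02d", 1:5))  # order preserved
  expect_error(filterCandidates(scores, orth,
                                makeExpr(tpm, unit = "raw_count"), 1),
               class = "panelign_contract_error")
})

test_that("top-fraction selection uses the ceiling rule", {
  scores200 <- data.frame(gene = sprintf("g%03d", 1:200), module_id = "m",
                          score = seq(200, 1))
  expect_length(selectTopFraction(scores200, 0.05), 10L)
  scores10 <- scores200[1:10, ]
  expect_equal(selectTopFraction(scores10, 0.05), "g001")  # ceiling(0.5)
  expect_length(selectTopFraction(scores200[0, ], 0.05), 0L)
  expect_error(selectTopFraction(scores10, 0), class = "panelign_contract_error")
  expect_error(selectTopFraction(scores10, 1.2), class = "panelign_contract_error")
})

test_that("panel assembly de-duplicates across modules and annotates unions", {
  orth <- OrthologMap(data.frame(human_gene = c("h1", "h2"),
                                 mouse_gene = c("m1", "m2"),
                                 dn = 0.1, ds = 1))
  sel <- list(A = data.frame(gene = "h1", score = 0.9),
              B = data.frame(gene = "h1", score = 0.7),
              C = data.frame(gene = c("h1", "h2"), score = c(0.5, 0.4)))
  panel <- assemblePanel(sel, orth, housekeeping = "Hk1", capacity = 10L)
  ann <- annotatedModules(panel)
  expect_setequal(ann[["m1"]], c("A", "B", "C"))
  ent <- panelEntries(panel)
  expect_equal(ent$score[ent$mouse_gene == "m1"], 0.9)  # max over modules
  expect_equal(nrow(ent), 3L)

  ## empty selections: exactly the housekeeping entries
  hk10 <- sprintf("Hk%02d", 1:10)
  p2 <- assemblePanel(list(), orth, housekeeping = hk10, capacity = 770L)
  expect_equal(nrow(panelEntries(p2)), 10L)
  expect_true(all(panelEntries(p2)$category == "housekeeping"))
})

test_that("capacity truncation drops the lowest-scoring key genes and reports", {
  n <- 900L
  orth <- OrthologMap(data.frame(human_gene = sprintf("h%03d", 1:n),
                                 mouse_gene = sprintf("m%03d", 1:n),
                                 dn = 0.1, ds = 1))
  sel <- list(M = data.frame(gene = sprintf("h%03d", 1:n),
                             score = seq(n, 1) / n))
  expect_message(
    panel <- assemblePanel(sel, orth, housekeeping = "Hk1", capacity = 770L),
    "truncated")
  ent <- panelEntries(panel)
  expect_equal(nrow(ent), 770L)
  ## 900 key + 1 housekeeping over capacity 770: 131 lowest-scoring drop
  expect_setequal(panel@truncated, sprintf("m%03d", (n - 130L):n))

  expect_error(assemblePanel(sel, orth, housekeeping = sprintf("Hk%d", 1:5),
                             drug_targets = sprintf("d%d", 1:6),
                             capacity = 10L),
               class = "panelign_contract_error")
})

test_that("housekeeping wins category collisions with a report", {
  orth <- OrthologMap(data.frame(human_gene = "h1", mouse_gene = "m1",
                                 dn = 0.1, ds = 1))
  sel <- list(A = data.frame(gene = "h1", score = 0.9))
  expect_message(
    panel <- assemblePanel(sel, orth, housekeeping = "m1", capacity = 10L),
    "housekeeping")
  ent <- panelEntries(panel)
  expect_equal(ent$category[ent$mouse_gene == "m1"], "housekeeping")
  expect_length(annotatedModules(panel)[["m1"]], 0L)
})

test_that("module probe coverage equals a set-intersection tally", {
  set.seed(5)
  mods <- simulateModules(simulationConfig(seed = 5, n_modules = 5,
                                           module_sizes = c(100, 50, 40, 30, 20)))
  orth <- simulateOrthology(mods, simulationConfig(seed = 5, n_modules = 5,
                                                   module_sizes = c(100, 50, 40, 30, 20)))
  sel <- lapply(setNames(moduleIds(mods), moduleIds(mods)), function(id) {
    g <- head(moduleMembers(mods, id), 10)
    data.frame(gene = g, score = seq_along(g))
  })
  panel <- assemblePanel(sel, orth$orthology, housekeeping = "Hk1",
                         capacity = 770L)
  cov <- moduleProbeCoverage(panel, mods)
  ## brute-force tally over annotations
  for (i in seq_len(nrow(cov))) {
    id <- cov$module_id[i]
    tally <- sum(vapply(annotatedModules(panel), function(a) id %in% a,
                        logical(1)))
    expect_equal(cov$probe_count[i], tally)
    expect_equal(cov$coverage_fraction[i],
                 tally / length(moduleMembers(mods, id)))
  }
  expect_equal(cov$coverage_fraction[1], 10 / 100)
})
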