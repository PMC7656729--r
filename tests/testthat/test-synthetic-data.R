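smallConfig <- function(seed = 3, ...) {
  simulationConfig(seed = seed, n_modules = 5, module_sizes = 40,
                   n_case = 25, n_control = 25, n_drug_targets = 5, ...)
}

test_that("module simulation is deterministic with the requested shapes", {
  cfg <- smallConfig()
  m1 <- simulateModules(cfg)
  m2 <- simulateModules(cfg)
  expect_equal(moduleIds(m1), moduleIds(m2))
  expect_equal(lapply(moduleIds(m1), function(id) moduleMembers(m1, id)),
               lapply(moduleIds(m2), function(id) moduleMembers(m2, id)))
  expect_length(m1, 5L)
  expect_true(all(vapply(moduleIds(m1), function(id)
    length(moduleMembers(m1, id)), integer(1)) == 40L))
  ## clusters cycle A-E
  expect_equal(vapply(moduleIds(m1), function(id) consensusCluster(m1, id),
                      character(1), USE.NAMES = FALSE),
               c("A", "B", "C", "D", "E"))
  ## membership table row count equals the size total
  path <- withr::local_tempfile()
  writeModuleTable(m1, path)
  expect_equal(nrow(read.delim(path)), 200L)
})

test_that("human cohort truth is loading x effect and empirically recoverable", {
  cfg0 <- smallConfig(module_effect_sizes = 0)
  mods <- simulateModules(cfg0)
  hum0 <- simulateHumanCohort(mods, cfg0)
  expect_true(all(logfcTable(hum0$truth)$logfc == 0))

  ## noiseless single-module check: the matrix is exactly baseline +
  ## loading x factor, so the case-control difference equals the factor
  ## mean difference times the loading
  cfg1 <- simulationConfig(seed = 5, n_modules = 1, module_sizes = 10,
                           n_case = 15, n_control = 15,
                           module_effect_sizes = 1, noise_sd = 0,
                           hub_loading_range = c(1, 1),
                           bg_loading_range = c(1, 1))
  mods1 <- simulateModules(cfg1)
  hum1 <- simulateHumanCohort(mods1, cfg1)
  v <- exprValues(hum1$expr)
  ann <- sampleAnnotations(hum1$expr)
  diff <- rowMeans(v[, ann$group == "case"]) -
    rowMeans(v[, ann$group == "control"])
  expect_equal(unname(diff - diff[1]), rep(0, 10), tolerance = 1e-10)

  ## at the stated cohort size the empirical logFC stays within the
  ## normal-theory band: the per-gene error combines the shared
  ## factor-mean noise (scaled by the loading) and the residual noise,
  ## sd_g = sqrt((loading^2 + sigma^2) * (1/n_case + 1/n_control))
  cfg <- smallConfig(seed = 11, module_effect_sizes = 1)
  mods <- simulateModules(cfg)
  hum <- simulateHumanCohort(mods, cfg)
  v <- exprValues(hum$expr)
  ann <- sampleAnnotations(hum$expr)
  emp <- rowMeans(v[, ann$group == "case"]) -
    rowMeans(v[, ann$group == "control"])
  truth <- logfcTable(hum$truth)
  loading <- truth$logfc  # effect = 1, so loading == true logFC
  sd_g <- sqrt((loading^2 + 1) * (1 / 25 + 1 / 25))
  close <- abs(emp[truth$gene] - truth$logfc) <= 2 * sd_g
  expect_gte(mean(close), 0.90)
})

test_that("mouse counts realize the planted concordance and flat housekeeping", {
  cfg <- simulationConfig(seed = 13, n_modules = 3, module_sizes = 150,
                          n_case = 30, n_control = 30,
                          module_effect_sizes = c(1, 0.8, -1),
                          module_concordance = c(0.6, 0, -0.6))
  mods <- simulateModules(cfg)
  hum <- simulateHumanCohort(mods, cfg)
  orth <- simulateOrthology(mods, cfg)
  mouse <- simulateMouseModels(mods, orth$orthology, hum$truth, cfg)
  truth <- logfcTable(mouse$ModelA$truth)
  ht <- logfcTable(hum$truth)
  ot <- orthologTable(orth$orthology)
  rho <- c(0.6, 0, -0.6)
  for (i in 1:3) {
    members <- moduleMembers(mods, sprintf("M%02d", i))
    mg <- ot$mouse_gene[match(members, ot$human_gene)]
    r <- cor(ht$logfc[match(members, ht$gene)],
             truth$logfc[match(mg, truth$gene)])
    ## normal-theory band: 3 x sd of a sample correlation at n = 150
    expect_lt(abs(r - rho[i]), 3 * (1 - rho[i]^2) / sqrt(147))
  }
  ## housekeeping genes carry exactly zero group effect by construction
  hk <- mouse$ModelA$housekeeping
  expect_equal(truth$logfc[match(hk, truth$gene)], rep(0, length(hk)))
  expect_equal(exprUnit(mouse$ModelA$counts), "raw_count")

  ## perfect concordance degenerates to proportionality per module
  cfg1 <- simulationConfig(seed = 13, n_modules = 1, module_sizes = 50,
                           module_concordance = 1)
  mods1 <- simulateModules(cfg1)
  hum1 <- simulateHumanCohort(mods1, cfg1)
  orth1 <- simulateOrthology(mods1, cfg1)
  m1 <- simulateMouseModels(mods1, orth1$orthology, hum1$truth, cfg1)
  t1 <- logfcTable(m1$ModelA$truth)
  members <- moduleMembers(mods1, "M01")
  mg <- orthologTable(orth1$orthology)$mouse_gene
  r <- cor(logfcTable(hum1$truth)$logfc[match(members, logfcTable(hum1$truth)$gene)],
           t1$logfc[match(mg, t1$gene)])
  expect_equal(r, 1, tolerance = 1e-10)
})

test_that("transcriptome plants GC content, shared motifs and poly-A islands", {
  cfg <- simulationConfig(seed = 17, n_modules = 1, module_sizes = 10,
                          transcript_length_range = c(1000L, 1000L))
  tx <- simulateTranscriptome(c("gA", "gB", "gC"), cfg,
                              off_target_pair = c("gA", "gB"),
                              polyA_genes = "gC")
  gc <- vapply(tx$sequence[tx$transcript_id == paste0(tx$gene, ".1")],
               function(s) {
                 ch <- strsplit(s, "")[[1]]
                 mean(ch %in% c("G", "C"))
               }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(abs(gc - 0.5) <= 0.05))
  a <- tx$sequence[tx$transcript_id == "gA.1"]
  b <- tx$sequence[tx$transcript_id == "gB.1"]
  ## the shared 40-nt motif occurs verbatim in both genes
  motif_at <- nchar(a) %/% 3
  motif <- substr(a, motif_at, motif_at + 39)
  expect_true(grepl(motif, b, fixed = TRUE))
  expect_true(grepl(strrep("A", 30), tx$sequence[tx$transcript_id == "gC.1"],
                    fixed = TRUE))

  ## same seed, same FASTA bytes
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeTranscriptFasta(simulateTranscriptome(c("gA", "gB"), cfg), f1)
  writeTranscriptFasta(simulateTranscriptome(c("gA", "gB"), cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("orthology plants the conservation link and stays one-to-one", {
  cfg <- smallConfig(seed = 19)
  mods <- simulateModules(cfg)
  orth <- simulateOrthology(mods, cfg)
  tb <- orthologTable(orth$orthology)
  expect_false(anyDuplicated(tb$human_gene) > 0)
  expect_false(anyDuplicated(tb$mouse_gene) > 0)
  ## module medians sit near their planted levels
  for (id in moduleIds(mods)) {
    med <- moduleMedianDnds(mods[[id]], orth$orthology)
    expect_lt(abs(med - orth$module_dnds[[id]]), 0.03)
  }
  ## degenerate dN/dS range -> all modules share the same median level
  cfg_flat <- smallConfig(seed = 19, dnds_range = c(0.2, 0.2))
  orth_flat <- simulateOrthology(simulateModules(cfg_flat), cfg_flat)
  expect_equal(unname(orth_flat$module_dnds), rep(0.2, 5))

  ## a mouse-namespace collision is refused
  bad <- ModuleSet(list(CoexpressionModule("M01", c("HGQ", "MGQ"))))
  expect_error(simulateOrthology(bad, cfg),
               class = "panelign_contract_error")
})

test_that("full dataset generation round-trips through the validators", {
  cfg <- smallConfig(seed = 23)
  dir <- withr::local_tempdir()
  simulateDataset(cfg, dir, transcript_genes = "panel-sized",
                  max_transcript_genes = 30L)
  expect_s4_class(readModuleTable(file.path(dir, "modules.tsv")), "ModuleSet")
  expect_s4_class(readOrthologyTable(file.path(dir, "orthology.tsv")),
                  "OrthologMap")
  h <- readExpressionMatrix(file.path(dir, "human_expr.tsv"),
                            file.path(dir, "human_annotations.tsv"),
                            "log_normalized")
  expect_equal(ncol(h), 50L)
  expect_equal(nrow(readTranscriptFasta(file.path(dir, "transcripts.fa"))) >= 40,
               TRUE)
  expect_length(readLines(file.path(dir, "housekeeping.txt")), 10L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 23L)
})
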