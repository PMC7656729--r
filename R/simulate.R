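## Seeded generators producing every input the pipeline consumes, with
## planted structure (module factors, case/control shifts, cross-species
## logFC concordance, sequence features, inverse dN/dS-expression link) so
## each stage has a ground truth to recover.

#' Simulation configuration
#'
#' The defaults define the synthetic study conditions used throughout the
#' package: 30 disjoint human modules of 100 genes in clusters A-E, 50
#' cases and 50 controls with one latent factor per module, per-module
#' case/control effects on the log2 scale, planted mouse-human logFC
#' concordance cycling through +0.6 / 0 / -0.6, negative-binomial mouse
#' counts, 10 near-constant housekeeping genes, desk-scale transcripts of
#' 250-600 nt and a strong inverse link between module median dN/dS and the
#' fraction of orthologs expressed in mouse brain.
#'
#' @param seed integer master seed; each generator derives a stage-local
#'   seed from it.
#' @param n_modules number of modules.
#' @param module_sizes integer vector of module sizes (recycled).
#' @param n_case,n_control human cohort sizes.
#' @param module_effect_sizes human case-vs-control factor shifts per
#'   module, log2 units (recycled).
#' @param module_concordance planted mouse-human logFC correlation per
#'   module, in [-1, 1] (recycled).
#' @param nb_dispersion negative-binomial dispersion of mouse counts.
#' @param transcript_length_range min/max transcript length, nt.
#' @param gc_target transcript G+C fraction.
#' @param dnds_range per-module median dN/dS range (modules spaced evenly
#'   across it).
#' @param dnds_link_intercept,dnds_link_slope,dnds_link_noise_sd linear
#'   link from module median dN/dS to the fraction of orthologs expressed
#'   in mouse brain.
#' @param hub_fraction fraction of each module's genes given high factor
#'   loadings.
#' @param hub_loading_range,bg_loading_range loading ranges for hub and
#'   background genes.
#' @param noise_sd residual expression noise, log2 units.
#' @param baseline human expression baseline, log2 units.
#' @param n_mouse_per_group mouse samples per group (model and B6).
#' @param mouse_models character vector of model names.
#' @param mouse_age_months age label for the mouse contrast.
#' @param mouse_logfc_sd scale of the planted mouse logFC draws.
#' @param housekeeping_n number of housekeeping genes.
#' @param n_ref_samples B6 whole-brain reference samples (TPM).
#' @param n_drug_targets nominated drug-target genes carried on the panel.
#' @return named list.
#' @export
simulationConfig <- function(seed = 1L, n_modules = 30L,
                             module_sizes = 100L,
                             n_case = 50L, n_control = 50L,
                             module_effect_sizes = seq(-1, 1, length.out = n_modules),
                             module_concordance = rep(c(0.6, 0, -0.6),
                                                      length.out = n_modules),
                             nb_dispersion = 0.1,
                             transcript_length_range = c(250L, 600L),
                             gc_target = 0.5,
                             dnds_range = c(0.05, 0.45),
                             dnds_link_intercept = 1.05,
                             dnds_link_slope = -2.2,
                             dnds_link_noise_sd = 0.03,
                             hub_fraction = 0.2,
                             hub_loading_range = c(0.8, 1),
                             bg_loading_range = c(0.2, 0.6),
                             noise_sd = 1, baseline = 8,
                             n_mouse_per_group = 10L,
                             mouse_models = "ModelA",
                             mouse_age_months = 6,
                             mouse_logfc_sd = 0.5,
                             housekeeping_n = 10L,
                             n_ref_samples = 6L,
                             n_drug_targets = 30L) {
  cfg <- list(seed = as.integer(seed), n_modules = as.integer(n_modules),
              module_sizes = rep_len(as.integer(module_sizes), n_modules),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              module_effect_sizes = rep_len(module_effect_sizes, n_modules),
              module_concordance = rep_len(module_concordance, n_modules),
              nb_dispersion = nb_dispersion,
              transcript_length_range = as.integer(transcript_length_range),
              gc_target = gc_target, dnds_range = dnds_range,
              dnds_link_intercept = dnds_link_intercept,
              dnds_link_slope = dnds_link_slope,
              dnds_link_noise_sd = dnds_link_noise_sd,
              hub_fraction = hub_fraction,
              hub_loading_range = hub_loading_range,
              bg_loading_range = bg_loading_range,
              noise_sd = noise_sd, baseline = baseline,
              n_mouse_per_group = as.integer(n_mouse_per_group),
              mouse_models = mouse_models,
              mouse_age_months = mouse_age_months,
              mouse_logfc_sd = mouse_logfc_sd,
              housekeeping_n = as.integer(housekeeping_n),
              n_ref_samples = as.integer(n_ref_samples),
              n_drug_targets = as.integer(n_drug_targets))
  if (any(cfg$module_sizes <= 0)) pa_contract_error("module sizes must be positive")
  if (any(abs(cfg$module_concordance) > 1))
    pa_contract_error("concordance must lie in [-1, 1]")
  if (cfg$transcript_length_range[1] < 100L)
    pa_contract_error("transcripts must be at least one window (100 nt) long")
  cfg
}

SIM_COHORTS <- c("ROSMAP", "Mayo", "MSSM")
SIM_REGIONS <- c("DLPFC", "TCX", "CBE", "STG", "IFG", "PHG", "FP")

#' Simulate the human module catalog
#'
#' Disjoint modules over a synthetic human gene namespace, assigned
#' round-robin to consensus clusters A-E and to cohort/brain-region
#' combinations.
#'
#' @param config from [simulationConfig()].
#' @return a [ModuleSet].
#' @export
simulateModules <- function(config = simulationConfig()) {
  sizes <- config$module_sizes
  total <- sum(sizes)
  genes <- sprintf("HG%05d", seq_len(total))
  stops <- cumsum(sizes); starts <- c(1L, head(stops, -1) + 1L)
  clusters <- rep_len(c("A", "B", "C", "D", "E"), config$n_modules)
  mods <- lapply(seq_len(config$n_modules), function(i) {
    CoexpressionModule(
      moduleId = sprintf("M%02d", i),
      members = genes[starts[i]:stops[i]],
      cohort = SIM_COHORTS[(i - 1L) %% length(SIM_COHORTS) + 1L],
      brainRegion = SIM_REGIONS[(i - 1L) %% length(SIM_REGIONS) + 1L],
      consensusCluster = clusters[i])
  })
  ModuleSet(mods)
}

#' Simulate the human cohort expression matrix and true logFC
#'
#' One latent factor per module; case samples receive the module's effect
#' size on the factor mean; gene value = baseline + loading x factor +
#' Gaussian noise (floored at zero).  The true log fold change of a gene is
#' loading x effect, to which the empirical case-control difference
#' converges as the cohort grows.
#'
#' @param modules a [ModuleSet] from [simulateModules()].
#' @param config from [simulationConfig()].
#' @return list: expr ([ExpressionMatrix], unit log_normalized), truth
#'   ([LogFCTable] of true logFC), hubs (named list of planted hub genes
#'   per module).
#' @export
simulateHumanCohort <- function(modules, config = simulationConfig()) {
  set.seed(deriveSeed(config$seed, "human_cohort"))
  n <- config$n_case + config$n_control
  samples <- c(sprintf("case_%03d", seq_len(config$n_case)),
               sprintf("ctrl_%03d", seq_len(config$n_control)))
  is_case <- rep(c(TRUE, FALSE), c(config$n_case, config$n_control))
  ids <- moduleIds(modules)
  genes <- unlist(lapply(ids, function(id) moduleMembers(modules, id)))
  values <- matrix(0, nrow = length(genes), ncol = n,
                   dimnames = list(genes, samples))
  truth <- numeric(length(genes)); names(truth) <- genes
  hubs <- list()
  for (i in seq_along(ids)) {
    members <- moduleMembers(modules, ids[i])
    eff <- config$module_effect_sizes[i]
    factor_scores <- rnorm(n, mean = ifelse(is_case, eff, 0), sd = 1)
    n_hub <- max(1L, ceiling(config$hub_fraction * length(members)))
    loading <- c(runif(n_hub, config$hub_loading_range[1],
                       config$hub_loading_range[2]),
                 runif(length(members) - n_hub, config$bg_loading_range[1],
                       config$bg_loading_range[2]))
    hubs[[ids[i]]] <- members[seq_len(n_hub)]
    values[members, ] <- config$baseline +
      outer(loading, factor_scores) +
      matrix(rnorm(length(members) * n, sd = config$noise_sd),
             nrow = length(members))
    truth[members] <- loading * eff
  }
  values <- pmax(values, 0)
  ann <- data.frame(sample_id = samples,
                    group = ifelse(is_case, "case", "control"),
                    model = "human", age_months = NA_real_,
                    sex = rep_len(c("F", "M"), n), lane = 1L,
                    stringsAsFactors = FALSE)
  expr <- ExpressionMatrix(values, ann, unit = "log_normalized")
  truth_tb <- data.frame(gene = genes, logfc = unname(truth),
                         p = NA_real_, adj_p = NA_real_,
                         stringsAsFactors = FALSE)
  list(expr = expr, truth = LogFCTable("human_case_vs_control", truth_tb),
       hubs = hubs)
}

#' Simulate mouse model counts with planted concordance to human logFC
#'
#' For each model, per-module true mouse logFC values are drawn from a
#' bivariate-normal construction so that their correlation with the human
#' true logFC equals the planted module concordance; counts follow a
#' negative binomial with a log2 link, and housekeeping genes are held at a
#' constant mean across groups and lanes.
#'
#' @param modules a [ModuleSet].
#' @param orthology an [OrthologMap] covering the module genes.
#' @param human_truth the human true [LogFCTable] from
#'   [simulateHumanCohort()].
#' @param config from [simulationConfig()].
#' @return named list (one element per model): counts ([ExpressionMatrix],
#'   raw_count), truth (mouse [LogFCTable]), housekeeping (gene names).
#' @export
simulateMouseModels <- function(modules, orthology, human_truth,
                                config = simulationConfig()) {
  tb <- orthologTable(orthology)
  ht <- logfcTable(human_truth)
  ids <- moduleIds(modules)
  hk <- sprintf("Hk%02d", seq_len(config$housekeeping_n))
  out <- list()
  for (model in config$mouse_models) {
    set.seed(deriveSeed(config$seed, paste0("mouse_", model)))
    genes <- character(0); true_lfc <- numeric(0)
    for (i in seq_along(ids)) {
      members <- moduleMembers(modules, ids[i])
      mg <- tb$mouse_gene[match(members, tb$human_gene)]
      keep <- !is.na(mg)
      members <- members[keep]; mgk <- mg[keep]
      if (!length(members)) next
      h <- ht$logfc[match(members, ht$gene)]
      rho <- config$module_concordance[i]
      hs <- if (sd(h) > 0) (h - mean(h)) / sd(h) else rep(0, length(h))
      z <- rnorm(length(h))
      m <- (rho * hs + sqrt(1 - rho^2) * z) * config$mouse_logfc_sd
      genes <- c(genes, mgk); true_lfc <- c(true_lfc, m)
    }
    n_grp <- config$n_mouse_per_group
    samples <- c(sprintf("%s_%02d", model, seq_len(n_grp)),
                 sprintf("B6_%02d", seq_len(n_grp)))
    in_model <- rep(c(1, 0), each = n_grp)
    base_log2 <- runif(length(genes), 4, 9)
    size <- 1 / config$nb_dispersion
    mu <- 2^(outer(base_log2, rep(0, 2 * n_grp), "+") +
               outer(true_lfc, in_model))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                     nrow = length(genes))
    ## housekeeping: constant mean, tight dispersion, no group effect
    hk_mu <- matrix(2^10, nrow = length(hk), ncol = 2 * n_grp)
    hk_counts <- matrix(rnbinom(length(hk_mu), mu = hk_mu, size = 200),
                        nrow = length(hk))
    values <- rbind(counts, hk_counts)
    values[values == 0] <- 1  # guard for geometric-mean normalization
    dimnames(values) <- list(c(genes, hk), samples)
    ann <- data.frame(sample_id = samples,
                      group = ifelse(in_model == 1, model, "B6"),
                      model = model,
                      age_months = config$mouse_age_months,
                      sex = rep_len(c("F", "M"), 2 * n_grp),
                      lane = seq_len(2 * n_grp), stringsAsFactors = FALSE)
    truth_tb <- data.frame(gene = c(genes, hk),
                           logfc = c(true_lfc, rep(0, length(hk))),
                           p = NA_real_, adj_p = NA_real_,
                           stringsAsFactors = FALSE)
    out[[model]] <- list(
      counts = ExpressionMatrix(values, ann, unit = "raw_count"),
      truth = LogFCTable(sprintf("%s_vs_B6", model), truth_tb),
      housekeeping = hk)
  }
  out
}

randomSequence <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulate a transcriptome with planted sequence features
#'
#' Per gene 1-4 isoforms (the first is the full sequence; others carry an
#' internal splice-like deletion).  Optional plants: a shared 40-nt motif
#' embedded verbatim in two genes (off-target fixture) and a poly-A island
#' (homopolymer-filter fixture).
#'
#' @param genes character vector of (mouse) gene ids.
#' @param config from [simulationConfig()].
#' @param off_target_pair optional length-2 gene vector sharing a motif.
#' @param polyA_genes genes given a 30-nt poly-A island.
#' @return data.frame with transcript_id, gene, sequence.
#' @export
simulateTranscriptome <- function(genes, config = simulationConfig(),
                                  off_target_pair = NULL,
                                  polyA_genes = character(0)) {
  set.seed(deriveSeed(config$seed, "transcriptome"))
  lr <- config$transcript_length_range
  motif <- if (!is.null(off_target_pair)) randomSequence(40L, config$gc_target)
  rows <- list()
  for (g in genes) {
    L <- sample(lr[1]:lr[2], 1L)
    base <- randomSequence(L, config$gc_target)
    if (!is.null(off_target_pair) && g %in% off_target_pair) {
      at <- max(1L, L %/% 3L)
      substr(base, at, at + 39L) <- motif
    }
    if (g %in% polyA_genes) {
      at <- max(1L, L %/% 2L)
      substr(base, at, at + 29L) <- strrep("A", 30L)
    }
    n_iso <- sample(1:4, 1L, prob = c(0.5, 0.3, 0.15, 0.05))
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = sprintf("%s.1", g), gene = g, sequence = base,
      stringsAsFactors = FALSE)
    if (n_iso > 1) for (j in 2:n_iso) {
      cut_len <- sample(30:80, 1L)
      cut_at <- sample(seq_len(max(1L, L - cut_len - 120L)) + 60L, 1L)
      iso <- paste0(substr(base, 1L, cut_at - 1L),
                    substr(base, cut_at + cut_len, L))
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = sprintf("%s.%d", g, j), gene = g, sequence = iso,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate one-to-one orthology with a planted conservation link
#'
#' Assigns each module an evenly spaced median dN/dS level and draws the
#' fraction of its orthologs expressed in mouse brain from the configured
#' linear link (plus noise), so that the module-level dN/dS-vs-expression
#' correlation is planted.  Also generates the matching B6 whole-brain
#' reference TPM matrix realizing those expressed fractions.
#'
#' @param modules a [ModuleSet].
#' @param config from [simulationConfig()].
#' @return list: orthology ([OrthologMap]), mouse_reference
#'   ([ExpressionMatrix], unit tpm), module_dnds (named numeric),
#'   module_fraction (named numeric planted expressed fractions).
#' @export
simulateOrthology <- function(modules, config = simulationConfig()) {
  set.seed(deriveSeed(config$seed, "orthology"))
  ids <- moduleIds(modules)
  K <- length(ids)
  mu <- if (K > 1)
    seq(config$dnds_range[1], config$dnds_range[2], length.out = K)
  else mean(config$dnds_range)
  names(mu) <- ids
  human <- character(0); mouse <- character(0); dnds <- numeric(0)
  frac <- setNames(numeric(K), ids)
  expressed_genes <- character(0)
  tpm_rows <- list()
  for (i in seq_len(K)) {
    members <- moduleMembers(modules, ids[i])
    mg <- sub("^HG", "MG", members)
    if (anyDuplicated(mg) || length(intersect(mg, mouse)))
      pa_contract_error("duplicated mouse gene in orthology request")
    g_dnds <- pmax(0.001, mu[i] + runif(length(members), -0.02, 0.02))
    f <- config$dnds_link_intercept + config$dnds_link_slope * mu[i] +
      rnorm(1, sd = config$dnds_link_noise_sd)
    f <- min(1, max(0.02, f))
    frac[i] <- f
    n_expr <- round(f * length(members))
    expr_idx <- if (n_expr > 0) sample(seq_along(mg), n_expr) else integer(0)
    expressed_genes <- c(expressed_genes, mg[expr_idx])
    human <- c(human, members); mouse <- c(mouse, mg)
    dnds <- c(dnds, g_dnds)
  }
  ds <- runif(length(human), 0.5, 2)
  orth <- OrthologMap(data.frame(human_gene = human, mouse_gene = mouse,
                                 dn = dnds * ds, ds = ds, dnds = dnds,
                                 stringsAsFactors = FALSE))
  n_ref <- config$n_ref_samples
  tpm <- matrix(runif(length(mouse) * n_ref, 0, 0.3),
                nrow = length(mouse),
                dimnames = list(mouse, sprintf("B6ref_%02d", seq_len(n_ref))))
  on <- rownames(tpm) %in% expressed_genes
  tpm[on, ] <- matrix(runif(sum(on) * n_ref, 5, 100), nrow = sum(on))
  ann <- data.frame(sample_id = colnames(tpm), group = "reference",
                    model = "B6", age_months = 6, sex = rep_len(c("F", "M"), n_ref),
                    lane = seq_len(n_ref), stringsAsFactors = FALSE)
  list(orthology = orth,
       mouse_reference = ExpressionMatrix(tpm, ann, unit = "tpm"),
       module_dnds = mu, module_fraction = frac)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs every generator under one master seed and writes the module table,
#' human matrix + annotations + true logFC, per-model mouse counts +
#' annotations + true logFC, orthology, B6 reference TPM, transcript
#' FASTA (for the mouse genes), housekeeping and drug-target lists and a
#' truth JSON.
#'
#' @param config from [simulationConfig()].
#' @param out_dir output directory (created if needed).
#' @param transcript_genes which mouse genes get transcripts: "panel-sized"
#'   writes transcripts for a deterministic subset capped at
#'   \code{max_transcript_genes}; "all" writes every mouse gene.
#' @param max_transcript_genes cap for "panel-sized".
#' @return (invisibly) list of all in-memory objects.
#' @export
simulateDataset <- function(config = simulationConfig(), out_dir,
                            transcript_genes = c("all", "panel-sized"),
                            max_transcript_genes = 400L) {
  transcript_genes <- match.arg(transcript_genes)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  modules <- simulateModules(config)
  human <- simulateHumanCohort(modules, config)
  orth <- simulateOrthology(modules, config)
  mouse <- simulateMouseModels(modules, orth$orthology, human$truth, config)
  hk <- mouse[[1]]$housekeeping
  mouse_genes <- orth$orthology@table$mouse_gene
  set.seed(deriveSeed(config$seed, "drug_targets"))
  drug_targets <- sort(sample(mouse_genes, config$n_drug_targets))
  tx_genes <- if (transcript_genes == "all") c(mouse_genes, hk)
  else c(head(mouse_genes, max_transcript_genes), hk)
  transcriptome <- simulateTranscriptome(tx_genes, config)
  p <- function(...) file.path(out_dir, ...)
  writeModuleTable(modules, p("modules.tsv"))
  writeExpressionMatrix(human$expr, p("human_expr.tsv"),
                        p("human_annotations.tsv"))
  writeLogfcTable(human$truth, p("human_logfc_true.tsv"))
  for (model in names(mouse)) {
    writeExpressionMatrix(mouse[[model]]$counts,
                          p(sprintf("mouse_counts_%s.tsv", model)),
                          p(sprintf("mouse_annotations_%s.tsv", model)))
    writeLogfcTable(mouse[[model]]$truth,
                    p(sprintf("mouse_logfc_true_%s.tsv", model)))
  }
  writeOrthologyTable(orth$orthology, p("orthology.tsv"))
  writeExpressionMatrix(orth$mouse_reference, p("mouse_reference_tpm.tsv"),
                        p("mouse_reference_annotations.tsv"))
  writeTranscriptFasta(transcriptome, p("transcripts.fa"))
  writeLines(hk, p("housekeeping.txt"))
  writeLines(drug_targets, p("drug_targets.txt"))
  jsonlite::write_json(
    list(seed = config$seed,
         module_effect_sizes = setNames(as.list(config$module_effect_sizes),
                                        moduleIds(modules)),
         module_concordance = setNames(as.list(config$module_concordance),
                                       moduleIds(modules)),
         module_dnds = as.list(orth$module_dnds),
         module_fraction_expressed = as.list(orth$module_fraction),
         hubs = human$hubs),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(modules = modules, human = human, orthology = orth,
                 mouse = mouse, transcriptome = transcriptome,
                 housekeeping = hk, drug_targets = drug_targets))
}
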