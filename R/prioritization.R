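## Gene prioritization within human co-expression modules: PCA of the
## module submatrix, correlation-weighted ranking scores, ortholog and
## expression filtering, top-fraction selection and panel assembly.

#' Principal components of a module's expression submatrix
#'
#' Samples are observations and module genes are variables; genes are
#' centered and unit-scaled before decomposition, so constant genes are
#' excluded.  Variance fractions are relative to the total variance of the
#' standardized submatrix.  Each component is oriented so its
#' largest-magnitude gene loading is positive, which makes downstream
#' gene-component correlations reproducible across linear-algebra backends.
#'
#' @param expr an [ExpressionMatrix] with unit tpm, normalized or
#'   log_normalized.
#' @param module a [CoexpressionModule].
#' @param n_components number of components to retain (default 5).
#' @return a [ModulePCA].
#' @export
modulePCA <- function(expr, module, n_components = 5L) {
  if (!exprUnit(expr) %in% c("tpm", "normalized", "log_normalized"))
    pa_contract_error("module PCA requires tpm/normalized/log_normalized input, got unit '%s'",
                      exprUnit(expr))
  v <- exprValues(expr)
  genes <- intersect(module@members, rownames(v))
  if (ncol(v) < 3L)
    pa_insufficient_data("module PCA needs at least 3 samples, got %d", ncol(v))
  X <- t(v[genes, , drop = FALSE])          # samples x genes
  sds <- apply(X, 2, sd)
  if (length(genes) >= 2L && all(sds == 0))
    pa_degenerate_input("module %s submatrix is constant", module@moduleId)
  usable <- sds > 0
  if (sum(usable) < 2L)
    pa_insufficient_data("module %s has %d usable (non-constant) genes in the matrix; need >= 2",
                         module@moduleId, sum(usable))
  X <- X[, usable, drop = FALSE]
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  ve_all <- pr$sdev^2 / sum(pr$sdev^2)
  scores <- pr$x
  ## orient: largest-|loading| positive per component
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[i, k] < 0) scores[, k] <- -scores[, k]
  }
  K <- as.integer(n_components)
  ncomp <- ncol(scores)
  out_scores <- matrix(0, nrow = nrow(scores), ncol = K,
                       dimnames = list(rownames(scores), paste0("PC", seq_len(K))))
  out_ve <- numeric(K)
  take <- min(K, ncomp)
  out_scores[, seq_len(take)] <- scores[, seq_len(take)]
  out_ve[seq_len(take)] <- ve_all[seq_len(take)]
  new("ModulePCA", moduleId = module@moduleId, scores = out_scores,
      varianceFractions = out_ve)
}

#' PCA-weighted gene ranking scores for one module
#'
#' Each module gene's score is the absolute value of the sum over retained
#' components of (Pearson correlation of the gene with the component's
#' sample scores) x (the component's variance fraction); with
#' \code{variant = "sum_of_abs"} the absolute values are summed instead.
#' High scores mark transcripts that are strongly positively or negatively
#' correlated with the dominant module components.  Constant genes score 0.
#'
#' @param expr the [ExpressionMatrix] the PCA was computed from.
#' @param pca a [ModulePCA] for the same module.
#' @param module the [CoexpressionModule].
#' @param variant "abs_of_sum" (default) or "sum_of_abs".
#' @return data.frame (gene, module_id, score) sorted by score descending,
#'   ties broken by gene identifier ascending.
#' @export
geneRankingScores <- function(expr, pca, module,
                              variant = c("abs_of_sum", "sum_of_abs")) {
  variant <- match.arg(variant)
  if (!identical(pca@moduleId, module@moduleId))
    pa_contract_error("PCA is for module '%s' but module '%s' was given",
                      pca@moduleId, module@moduleId)
  v <- exprValues(expr)
  genes <- intersect(module@members, rownames(v))
  S <- pca@scores
  if (nrow(S) != ncol(v))
    pa_contract_error("PCA sample scores do not match the expression matrix")
  ve <- pca@varianceFractions
  comp_sd <- apply(S, 2, sd)
  score <- vapply(genes, function(g) {
    x <- v[g, ]
    if (sd(x) == 0) return(0)
    r <- ifelse(comp_sd > 0, suppressWarnings(cor(x, S)), 0)
    r[is.na(r)] <- 0
    if (variant == "abs_of_sum") abs(sum(r * ve)) else sum(abs(r * ve))
  }, numeric(1))
  out <- data.frame(gene = genes, module_id = module@moduleId,
                    score = unname(score), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter scored genes to expressed one-to-one mouse orthologs
#'
#' Retains genes whose human gene has a one-to-one mouse ortholog with mean
#' TPM at or above the threshold across the mouse reference samples
#' (whole-brain B6 reference in the intended workflow); relative order is
#' preserved.
#'
#' @param scores score table from [geneRankingScores()].
#' @param orthology an [OrthologMap].
#' @param mouse_expr [ExpressionMatrix] with unit tpm.
#' @param tpm_threshold expression cutoff, mean TPM (default 1).
#' @return filtered score table, same columns and order.
#' @export
filterCandidates <- function(scores, orthology, mouse_expr,
                             tpm_threshold = 1) {
  if (exprUnit(mouse_expr) != "tpm")
    pa_contract_error("mouse reference must be in TPM, got unit '%s'",
                      exprUnit(mouse_expr))
  tb <- orthologTable(orthology)
  mean_tpm <- rowMeans(exprValues(mouse_expr))
  mg <- tb$mouse_gene[match(scores$gene, tb$human_gene)]
  expressed <- !is.na(mg) & !is.na(mean_tpm[mg]) &
    mean_tpm[mg] >= tpm_threshold
  out <- scores[expressed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-ranked fraction of scored genes
#'
#' @param scores score table sorted as produced by [geneRankingScores()].
#' @param fraction fraction in (0, 1]; the first ceiling(fraction * n) genes
#'   are returned (ceiling guarantees a nonempty selection for small
#'   modules).
#' @return character vector of selected genes.
#' @export
selectTopFraction <- function(scores, fraction = 0.05) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    pa_contract_error("fraction must lie in (0, 1], got %s",
                      format(fraction))
  n <- nrow(scores)
  if (!n) return(character(0))
  head(scores$gene, ceiling(fraction * n))
}

#' Assemble the capacity-bounded panel
#'
#' Maps per-module human selections to mouse genes via the orthology and
#' de-duplicates: a gene selected by several modules yields one entry
#' annotated with the union of module ids, carrying its maximum score as
#' the global score.  Housekeeping and drug-target entries are always
#' included; housekeeping wins category collisions (reported via message).
#' If the panel exceeds capacity, key entries are dropped
#' lowest-global-score-first until it fits and the truncation is recorded.
#'
#' @param per_module_selections named list (by module id) of data.frames
#'   with columns gene (human) and score.
#' @param orthology an [OrthologMap].
#' @param housekeeping nonempty character vector of mouse housekeeping
#'   genes.
#' @param drug_targets character vector of mouse drug-target genes.
#' @param capacity maximum panel size (default 770).
#' @return a [PanelDefinition].
#' @export
assemblePanel <- function(per_module_selections, orthology, housekeeping,
                          drug_targets = character(0), capacity = 770L) {
  capacity <- as.integer(capacity)
  if (!length(housekeeping))
    pa_contract_error("housekeeping list must be nonempty")
  housekeeping <- unique(housekeeping)
  drug_targets <- setdiff(unique(drug_targets), housekeeping)
  if (capacity < length(housekeeping) + length(drug_targets))
    pa_contract_error("capacity %d below the %d housekeeping + %d drug-target entries",
                      capacity, length(housekeeping), length(drug_targets))
  tb <- orthologTable(orthology)
  mods <- list(); score <- numeric(0)
  for (mid in names(per_module_selections)) {
    sel <- per_module_selections[[mid]]
    if (!nrow(sel %||% data.frame())) next
    mg <- tb$mouse_gene[match(sel$gene, tb$human_gene)]
    keep <- !is.na(mg)
    for (i in which(keep)) {
      g <- mg[i]
      mods[[g]] <- union(mods[[g]] %||% character(0), mid)
      score[g] <- max(score[g] %||% -Inf, sel$score[i], na.rm = TRUE)
    }
  }
  key_genes <- names(mods)
  hk_collisions <- intersect(housekeeping, c(key_genes, drug_targets))
  if (length(hk_collisions)) {
    message("housekeeping gene(s) also selected as key/drug-target; kept as housekeeping: ",
            paste(hk_collisions, collapse = ", "))
    key_genes <- setdiff(key_genes, housekeeping)
    mods[hk_collisions] <- NULL
  }
  category <- c(setNames(rep("key", length(key_genes)), key_genes),
                setNames(rep("drug_target", length(drug_targets))[
                  seq_along(drug_targets)], drug_targets))
  category[drug_targets] <- "drug_target"
  genes <- unique(c(key_genes, drug_targets))
  entries <- data.frame(
    mouse_gene = c(genes, housekeeping),
    category = c(unname(category[genes]),
                 rep("housekeeping", length(housekeeping))),
    score = c(ifelse(is.finite(score[genes]), score[genes], NA_real_),
              rep(NA_real_, length(housekeeping))),
    stringsAsFactors = FALSE)
  truncated <- character(0)
  if (nrow(entries) > capacity) {
    droppable <- which(entries$category == "key")
    ord <- droppable[order(entries$score[droppable], entries$mouse_gene[droppable])]
    n_drop <- nrow(entries) - capacity
    if (n_drop > length(ord))
      pa_contract_error("cannot fit panel into capacity %d", capacity)
    drop_idx <- ord[seq_len(n_drop)]
    truncated <- entries$mouse_gene[drop_idx]
    message(sprintf("panel truncated: dropped %d lowest-scoring key gene(s)",
                    n_drop))
    entries <- entries[-drop_idx, , drop = FALSE]
  }
  rownames(entries) <- NULL
  ann <- lapply(entries$mouse_gene, function(g) sort(mods[[g]] %||% character(0)))
  names(ann) <- entries$mouse_gene
  probes <- setNames(vector("list", nrow(entries)), entries$mouse_gene)
  new("PanelDefinition", entries = entries, annotatedModules = ann,
      probes = probes, capacity = capacity, truncated = truncated)
}

#' Per-module probe counts and coverage
#'
#' @param panel a [PanelDefinition].
#' @param modules a [ModuleSet].
#' @return data.frame (module_id, probe_count, coverage_fraction) where
#'   coverage is the probe count over the module size.
#' @export
moduleProbeCoverage <- function(panel, modules) {
  ann <- panel@annotatedModules
  all_ann <- unlist(ann, use.names = FALSE)
  counts <- table(all_ann)
  ids <- moduleIds(modules)
  probe_count <- as.integer(ifelse(ids %in% names(counts), counts[ids], 0L))
  size <- vapply(ids, function(id) length(moduleMembers(modules, id)),
                 integer(1))
  data.frame(module_id = ids, probe_count = probe_count,
             coverage_fraction = probe_count / size,
             stringsAsFactors = FALSE, row.names = NULL)
}
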