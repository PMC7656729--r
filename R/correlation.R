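## The core evaluation: per-module Pearson correlation between human and
## mouse per-gene log fold changes (case-vs-control against
## model-vs-age-matched-B6), and the contrast x module correlation grid.

#' Module-level correlation of human and mouse log fold changes
#'
#' Maps the module's human genes to mouse genes via the one-to-one
#' orthology (optionally restricted to a gene subset such as the panel
#' genes), pairs the per-gene log fold changes present in both contrasts
#' and reports Pearson's r with a two-sided p from the t-transform with
#' n - 2 degrees of freedom.
#'
#' @param human [LogFCTable] for the human contrast (case minus control).
#' @param mouse [LogFCTable] for the mouse contrast (model minus B6).
#' @param module a [CoexpressionModule] (human gene ids).
#' @param orthology an [OrthologMap].
#' @param gene_subset optional mouse gene subset (e.g. panel genes).
#' @param n_min minimum overlapping genes (default 5); smaller overlaps are
#'   returned flagged as insufficient rather than dropped.
#' @param alpha significance level for the mask.
#' @return one-row data.frame: module_id, contrast, r, p, n, significant,
#'   insufficient.
#' @export
moduleLogfcCorrelation <- function(human, mouse, module, orthology,
                                   gene_subset = NULL, n_min = 5L,
                                   alpha = 0.05) {
  tb <- orthologTable(orthology)
  mg <- tb$mouse_gene[match(module@members, tb$human_gene)]
  keep <- !is.na(mg)
  hg <- module@members[keep]; mg <- mg[keep]
  if (!is.null(gene_subset)) {
    keep <- mg %in% gene_subset
    hg <- hg[keep]; mg <- mg[keep]
  }
  ht <- logfcTable(human); mt <- logfcTable(mouse)
  h <- ht$logfc[match(hg, ht$gene)]
  m <- mt$logfc[match(mg, mt$gene)]
  ok <- !is.na(h) & !is.na(m)
  h <- h[ok]; m <- m[ok]
  n <- length(h)
  base <- data.frame(module_id = module@moduleId,
                     contrast = contrastLabel(mouse),
                     r = NA_real_, p = NA_real_, n = n,
                     significant = FALSE, insufficient = TRUE,
                     stringsAsFactors = FALSE)
  if (n < n_min) return(base)
  if (sd(h) == 0 || sd(m) == 0) return(base)  # degenerate pairing
  ct <- cor.test(h, m)
  base$r <- unname(ct$estimate)
  base$p <- ct$p.value
  base$significant <- base$p < alpha
  base$insufficient <- FALSE
  base
}

#' Contrast-by-module correlation grid
#'
#' One correlation per (mouse contrast x module); each module is correlated
#' against the human contrast of its own brain region.  Modules are ordered
#' by consensus cluster A-E (then "none"), then module id; the significance
#' mask uses the unadjusted p at \code{alpha} to mirror standard practice
#' for such grids, with a BH-adjusted column emitted alongside.
#'
#' @param mouse_contrasts list of mouse [LogFCTable]s.
#' @param human_contrasts named list of human [LogFCTable]s keyed by brain
#'   region.
#' @param modules a [ModuleSet].
#' @param orthology an [OrthologMap].
#' @param alpha significance level.
#' @param gene_subset optional mouse gene subset (e.g. panel genes).
#' @param n_min minimum overlapping genes per cell.
#' @return data.frame with one row per contrast x module: contrast,
#'   module_id, cluster, r, p, adj_p, n, significant, insufficient.
#' @export
correlationGrid <- function(mouse_contrasts, human_contrasts, modules,
                            orthology, alpha = 0.05, gene_subset = NULL,
                            n_min = 5L) {
  ids <- moduleIds(modules)
  cl <- vapply(ids, function(id) consensusCluster(modules, id), character(1))
  ord <- order(factor(cl, levels = VALID_CLUSTERS), ids)
  ids <- ids[ord]; cl <- cl[ord]
  rows <- list()
  for (mc in mouse_contrasts) {
    for (i in seq_along(ids)) {
      mod <- modules[[ids[i]]]
      hc <- human_contrasts[[mod@brainRegion]]
      if (is.null(hc))
        pa_contract_error("no human contrast for brain region '%s' (module %s)",
                          mod@brainRegion, mod@moduleId)
      r <- moduleLogfcCorrelation(hc, mc, mod, orthology,
                                  gene_subset = gene_subset,
                                  n_min = n_min, alpha = alpha)
      r$cluster <- cl[i]
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- p.adjust(out$p, "BH")
  out <- out[, c("contrast", "module_id", "cluster", "r", "p", "adj_p",
                 "n", "significant", "insufficient")]
  rownames(out) <- NULL
  out
}
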