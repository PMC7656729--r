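## Gene-set enrichment: hypergeometric over-representation with Bonferroni
## ranking (used to annotate consensus clusters) and a weighted-KS GSEA
## with gene-label permutation p-values.

#' Hypergeometric over-representation of a query in each gene set
#'
#' For each set, the p-value is the upper-tail hypergeometric probability
#' P(X >= overlap) of drawing at least the observed overlap when sampling
#' the query size from the universe.  Bonferroni (p x number of sets,
#' capped at 1) and BH columns are added; rows are sorted by Bonferroni p
#' ascending.
#'
#' @param query character vector of query genes, a subset of the universe.
#' @param collection a [PanelGeneSets].
#' @return data.frame: set_name, overlap, set_size, query_size,
#'   universe_size, p, bonferroni_p, bh_p.
#' @export
hypergeometricEnrichment <- function(query, collection) {
  query <- unique(query)
  outside <- setdiff(query, geneUniverse(collection))
  if (length(outside))
    pa_contract_error("query gene outside universe: %s", outside[1])
  N <- length(geneUniverse(collection))
  n <- length(query)
  sets <- geneSets(collection)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(query, sets[[nm]]))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- pmin(1, out$p * length(sets))
  out$bh_p <- p.adjust(out$p, "BH")
  out <- out[order(out$bonferroni_p, out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a consensus cluster by its top non-overlapping enriched terms
#'
#' Runs the hypergeometric enrichment on the cluster's gene union
#' (restricted to the collection's universe) and emits set labels in
#' Bonferroni rank order, skipping any set sharing at least half its genes
#' (Jaccard >= 0.5) with an already-emitted set.  The first label is the
#' cluster annotation.
#'
#' @param cluster_genes union of the cluster's module genes.
#' @param collection a [PanelGeneSets].
#' @param alpha Bonferroni significance cutoff (default 0.05).
#' @param jaccard_max overlap suppression threshold.
#' @return character vector of labels (possibly empty, with a warning).
#' @export
annotateCluster <- function(cluster_genes, collection, alpha = 0.05,
                            jaccard_max = 0.5) {
  query <- intersect(unique(cluster_genes), geneUniverse(collection))
  res <- hypergeometricEnrichment(query, collection)
  res <- res[res$bonferroni_p < alpha, , drop = FALSE]
  if (!nrow(res)) {
    warning("no gene set significant at Bonferroni ", alpha,
            "; cluster left unannotated")
    return(character(0))
  }
  sets <- geneSets(collection)
  labels <- character(0)
  for (nm in res$set_name) {
    dup <- any(vapply(labels, function(l) {
      a <- sets[[l]]; b <- sets[[nm]]
      length(intersect(a, b)) / length(union(a, b)) >= jaccard_max
    }, logical(1)))
    if (!dup) labels <- c(labels, nm)
  }
  labels
}

## Weighted-KS running sum for a ranked list.  `stat` are the ranking
## statistics in list order (descending), `hit` marks set members.
gseaRunningSum <- function(stat, hit, weight_p) {
  N <- length(stat); Nh <- sum(hit)
  w <- abs(stat)^weight_p
  NR <- sum(w[hit])
  inc <- if (NR > 0) w / NR else rep(1 / Nh, N)
  steps <- ifelse(hit, inc, -1 / (N - Nh))
  cumsum(steps)
}

#' Gene set enrichment analysis (weighted running-sum statistic)
#'
#' Genes are ordered by log fold change descending (ties by gene id); the
#' running sum gains |logFC|^weight_p (normalized over set hits) at each
#' hit and loses 1/(N - set size) at each miss; the enrichment score is the
#' extremum.  The null distribution comes from gene-label permutations
#' under a fixed seed; NES divides the ES by the mean |null ES| of the same
#' sign and the p-value uses +1 smoothing.
#'
#' @param ranked a [LogFCTable] providing the ranking statistic.
#' @param set character vector of set genes; the intersection with the
#'   ranked genes must be nonempty and proper.
#' @param weight_p weighting exponent (default 1, the classic weighted
#'   statistic; 0 gives the unweighted KS).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return one-row data.frame: es, nes, p, n_hits, n_perm, seed.
#' @export
gsea <- function(ranked, set, weight_p = 1, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L)
    pa_contract_error("n_perm must be >= 100 (got %d)", n_perm)
  tb <- logfcTable(ranked)
  ord <- order(-tb$logfc, tb$gene)
  genes <- tb$gene[ord]; stat <- tb$logfc[ord]
  hit <- genes %in% set
  Nh <- sum(hit)
  if (Nh == 0)
    pa_contract_error("gene set does not intersect the ranked list")
  if (Nh == length(genes))
    pa_contract_error("gene set covers the whole ranked list; no misses definable")
  run <- gseaRunningSum(stat, hit, weight_p)
  es <- run[which.max(abs(run))]
  null_es <- numeric(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    ph <- logical(length(genes))
    ph[sample.int(length(genes), Nh)] <- TRUE
    nr <- gseaRunningSum(stat, ph, weight_p)
    null_es[b] <- nr[which.max(abs(nr))]
  }
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  data.frame(es = es, nes = nes, p = p, n_hits = Nh,
             n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' GSEA over a collection of sets with BH adjustment
#'
#' @inheritParams gsea
#' @param collection a [PanelGeneSets]; sets that do not intersect the
#'   ranked list (or cover it entirely) are skipped.
#' @return data.frame with one row per evaluated set plus a bh_p column.
#' @export
gseaCollection <- function(ranked, collection, weight_p = 1,
                           n_perm = 1000L, seed = 1L) {
  sets <- geneSets(collection)
  rows <- list()
  for (nm in names(sets)) {
    r <- tryCatch(gsea(ranked, sets[[nm]], weight_p, n_perm, seed),
                  panelign_contract_error = function(e) NULL)
    if (!is.null(r)) {
      r$set_name <- nm
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows))
    pa_contract_error("no gene set intersects the ranked list")
  out <- do.call(rbind, rows)
  out$bh_p <- p.adjust(out$p, "BH")
  out[, c("set_name", "es", "nes", "p", "bh_p", "n_hits", "n_perm", "seed")]
}
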