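## Cross-species module conservation: per-module median dN/dS, fraction of
## genes with an expressed mouse ortholog, and their correlation across
## modules.

#' Median dN/dS of a module's orthologous genes
#'
#' The median is taken over module members with a one-to-one ortholog whose
#' dN/dS is defined (genes with dS = 0 are excluded); even counts take the
#' mean of the two central values.
#'
#' @param module a [CoexpressionModule].
#' @param orthology an [OrthologMap].
#' @return nonnegative median, or NA when no eligible gene exists.
#' @export
moduleMedianDnds <- function(module, orthology) {
  tb <- orthologTable(orthology)
  d <- tb$dnds[match(module@members, tb$human_gene)]
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  median(d)
}

#' Fraction of module genes with an expressed mouse ortholog
#'
#' Numerator: module genes whose one-to-one ortholog has mean TPM at or
#' above the threshold across the mouse reference samples; denominator: the
#' module size (genes without orthologs count as not expressed).  An
#' auxiliary ortholog-denominator variant is provided by
#' [conservationProfile()].
#'
#' @param module a [CoexpressionModule].
#' @param orthology an [OrthologMap].
#' @param mouse_expr [ExpressionMatrix] with unit tpm.
#' @param tpm_threshold detectability cutoff on the mean TPM (default 1).
#' @return fraction in [0, 1].
#' @export
moduleFractionExpressed <- function(module, orthology, mouse_expr,
                                    tpm_threshold = 1) {
  if (!length(module@members))
    pa_contract_error("module %s is empty", module@moduleId)
  if (exprUnit(mouse_expr) != "tpm")
    pa_contract_error("mouse reference must be in TPM, got unit '%s'",
                      exprUnit(mouse_expr))
  tb <- orthologTable(orthology)
  mg <- tb$mouse_gene[match(module@members, tb$human_gene)]
  mean_tpm <- rowMeans(exprValues(mouse_expr))
  expressed <- !is.na(mg) & !is.na(mean_tpm[mg]) &
    mean_tpm[mg] >= tpm_threshold
  sum(expressed) / length(module@members)
}

#' Module conservation profile and its cross-module correlation
#'
#' Computes, for every module, the median dN/dS, the fraction of genes with
#' an expressed mouse ortholog (module-size denominator; an
#' ortholog-denominator column is also emitted) and the ortholog count, then
#' correlates median dN/dS with the expressed fraction across modules
#' (Pearson, two-sided p from the t-transform).
#'
#' @param modules a [ModuleSet].
#' @param orthology an [OrthologMap].
#' @param mouse_expr [ExpressionMatrix] with unit tpm.
#' @param tpm_threshold detectability cutoff on the mean TPM.
#' @return list with \code{table} (module_id, median_dnds,
#'   fraction_expressed, fraction_expressed_of_orthologs, n_orthologs),
#'   \code{pearson_r} and \code{p}.
#' @export
conservationProfile <- function(modules, orthology, mouse_expr,
                                tpm_threshold = 1) {
  tb <- orthologTable(orthology)
  mean_tpm <- rowMeans(exprValues(mouse_expr))
  rows <- lapply(modules@modules, function(m) {
    mg <- tb$mouse_gene[match(m@members, tb$human_gene)]
    n_orth <- sum(!is.na(mg))
    expressed <- !is.na(mg) & !is.na(mean_tpm[mg]) &
      mean_tpm[mg] >= tpm_threshold
    data.frame(module_id = m@moduleId,
               median_dnds = moduleMedianDnds(m, orthology),
               fraction_expressed = sum(expressed) / length(m@members),
               fraction_expressed_of_orthologs =
                 if (n_orth) sum(expressed) / n_orth else NA_real_,
               n_orthologs = n_orth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  usable <- !is.na(out$median_dnds)
  if (sum(usable) < 3L)
    pa_insufficient_data("need >= 3 modules with defined median dN/dS, got %d",
                         sum(usable))
  ct <- cor.test(out$median_dnds[usable], out$fraction_expressed[usable])
  list(table = out, pearson_r = unname(ct$estimate), p = ct$p.value)
}
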