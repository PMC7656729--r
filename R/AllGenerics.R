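#' @include AllClasses.R
NULL

#' @export
setGeneric("moduleIds", function(x) standardGeneric("moduleIds"))
#' @export
setGeneric("moduleMembers", function(x, id) standardGeneric("moduleMembers"))
#' @export
setGeneric("consensusCluster", function(x, id) standardGeneric("consensusCluster"))
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))
#' @export
setGeneric("sampleAnnotations", function(x) standardGeneric("sampleAnnotations"))
#' @export
setGeneric("orthologTable", function(x) standardGeneric("orthologTable"))
#' @export
setGeneric("logfcTable", function(x) standardGeneric("logfcTable"))
#' @export
setGeneric("contrastLabel", function(x) standardGeneric("contrastLabel"))
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))
#' @export
setGeneric("panelCapacity", function(x) standardGeneric("panelCapacity"))
#' @export
setGeneric("annotatedModules", function(x) standardGeneric("annotatedModules"))
#' @export
setGeneric("panelProbes", function(x) standardGeneric("panelProbes"))
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @describeIn ModuleSet-class module identifiers, in storage order.
#' @export
setMethod("moduleIds", "ModuleSet", function(x)
  vapply(x@modules, slot, character(1), "moduleId"))

#' @describeIn ModuleSet-class member genes of module \code{id}.
#' @export
setMethod("moduleMembers", "ModuleSet", function(x, id) {
  if (!id %in% names(x@modules))
    pa_contract_error("unknown module id '%s'", id)
  x@modules[[id]]@members
})

#' @describeIn ModuleSet-class consensus-cluster label of module \code{id}.
#' @export
setMethod("consensusCluster", "ModuleSet", function(x, id) {
  if (!id %in% names(x@modules))
    pa_contract_error("unknown module id '%s'", id)
  x@modules[[id]]@consensusCluster
})

#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

#' @export
setMethod("[[", "ModuleSet", function(x, i) x@modules[[i]])

#' @describeIn ExpressionMatrix-class the gene x sample value matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x)
  SummarizedExperiment::assay(x, "values"))

#' @describeIn ExpressionMatrix-class the unit tag.
#' @export
setMethod("exprUnit", "ExpressionMatrix", function(x) x@unit)

#' @describeIn ExpressionMatrix-class per-sample annotation data.frame.
#' @export
setMethod("sampleAnnotations", "ExpressionMatrix", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn OrthologMap-class the orthology table.
#' @export
setMethod("orthologTable", "OrthologMap", function(x) x@table)

#' @export
setMethod("length", "OrthologMap", function(x) nrow(x@table))

#' @describeIn LogFCTable-class the per-gene table.
#' @export
setMethod("logfcTable", "LogFCTable", function(x) x@table)

#' @describeIn LogFCTable-class the contrast label.
#' @export
setMethod("contrastLabel", "LogFCTable", function(x) x@contrast)

#' @describeIn PanelDefinition-class entry table.
#' @export
setMethod("panelEntries", "PanelDefinition", function(x) x@entries)

#' @describeIn PanelDefinition-class capacity bound.
#' @export
setMethod("panelCapacity", "PanelDefinition", function(x) x@capacity)

#' @describeIn PanelDefinition-class named list of module annotations.
#' @export
setMethod("annotatedModules", "PanelDefinition", function(x) x@annotatedModules)

#' @describeIn PanelDefinition-class named list of probe pairs (or NULL).
#' @export
setMethod("panelProbes", "PanelDefinition", function(x) x@probes)

#' @describeIn ModulePCA-class per-component variance fractions.
#' @export
setMethod("varianceFractions", "ModulePCA", function(x) x@varianceFractions)

#' @describeIn ModulePCA-class sample x component score matrix.
#' @export
setMethod("componentScores", "ModulePCA", function(x) x@scores)

#' @describeIn PanelGeneSets-class named list of gene sets.
#' @export
setMethod("geneSets", "PanelGeneSets", function(x) x@sets)

#' @describeIn PanelGeneSets-class the gene universe.
#' @export
setMethod("geneUniverse", "PanelGeneSets", function(x) x@universe)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

#' @export
setMethod("show", "CoexpressionModule", function(object) {
  cat(sprintf("CoexpressionModule %s (%s, %s, cluster %s): %d genes\n",
              object@moduleId, object@cohort, object@brainRegion,
              object@consensusCluster, length(object@members)))
})

#' @export
setMethod("show", "ModuleSet", function(object) {
  cat(sprintf("ModuleSet with %d modules, %d distinct genes\n",
              length(object@modules),
              length(unique(unlist(lapply(object@modules, slot, "members"))))))
})

#' @export
setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              object@unit, nrow(object), ncol(object)))
})

#' @export
setMethod("show", "OrthologMap", function(object) {
  cat(sprintf("OrthologMap: %d one-to-one pairs (%d with defined dN/dS)\n",
              nrow(object@table), sum(!is.na(object@table$dnds))))
})

#' @export
setMethod("show", "LogFCTable", function(object) {
  cat(sprintf("LogFCTable '%s': %d genes\n", object@contrast, nrow(object@table)))
})

#' @export
setMethod("show", "ProbePair", function(object) {
  cat(sprintf("ProbePair %s/%s window %d: A[%d nt, Tm %.1f] + B[%d nt, Tm %.1f], xhyb %.2f, isoforms %.2f\n",
              object@gene, object@transcriptId, object@windowStart,
              nchar(object@seqA), object@tmA, nchar(object@seqB), object@tmB,
              object@crosshybScore, object@isoformCoverage))
})

#' @export
setMethod("show", "PanelDefinition", function(object) {
  tb <- table(factor(object@entries$category,
                     levels = c("key", "housekeeping", "drug_target")))
  cat(sprintf("PanelDefinition: %d/%d entries (key %d, housekeeping %d, drug_target %d)%s\n",
              nrow(object@entries), object@capacity,
              tb[["key"]], tb[["housekeeping"]], tb[["drug_target"]],
              if (length(object@truncated))
                sprintf("; %d truncated", length(object@truncated)) else ""))
})

#' @export
setMethod("show", "ModulePCA", function(object) {
  cat(sprintf("ModulePCA %s: %d components, variance fractions %s\n",
              object@moduleId, ncol(object@scores),
              paste(sprintf("%.3f", object@varianceFractions), collapse = " ")))
})

#' @export
setMethod("show", "PanelGeneSets", function(object) {
  cat(sprintf("PanelGeneSets: %d sets over a universe of %d genes\n",
              length(object@sets), length(object@universe)))
})
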