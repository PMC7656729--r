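#' @import methods
NULL

VALID_CLUSTERS <- c("A", "B", "C", "D", "E", "none")
VALID_UNITS    <- c("raw_count", "tpm", "normalized", "log_normalized")
ANNOTATION_KEYS <- c("group", "model", "age_months", "sex", "lane")

## ---------------------------------------------------------------------------
## CoexpressionModule / ModuleSet
## ---------------------------------------------------------------------------

#' Human co-expression module
#'
#' A fixed set of human genes with cohort and brain-region provenance and an
#' optional consensus-cluster label (A-E groupings of modules that share gene
#' content across cohorts and regions).
#'
#' @slot moduleId module identifier, unique within a [ModuleSet].
#' @slot cohort study cohort the module derives from.
#' @slot brainRegion brain region label.
#' @slot consensusCluster one of A-E or "none".
#' @slot members nonempty character vector of human gene identifiers.
#' @export
setClass("CoexpressionModule",
  slots = c(moduleId = "character", cohort = "character",
            brainRegion = "character", consensusCluster = "character",
            members = "character"))

setValidity("CoexpressionModule", function(object) {
  msgs <- character(0)
  if (length(object@moduleId) != 1L || !nzchar(object@moduleId))
    msgs <- c(msgs, "moduleId must be a single nonempty string")
  if (!length(object@members))
    msgs <- c(msgs, "members must be nonempty")
  if (anyDuplicated(object@members))
    msgs <- c(msgs, "members must be unique")
  if (!object@consensusCluster %in% VALID_CLUSTERS)
    msgs <- c(msgs, sprintf("invalid consensus cluster '%s'", object@consensusCluster))
  if (length(msgs)) msgs else TRUE
})

#' @param moduleId,cohort,brainRegion,consensusCluster,members see slots.
#' @rdname CoexpressionModule-class
#' @export
CoexpressionModule <- function(moduleId, members, cohort = "unknown",
                               brainRegion = "unknown",
                               consensusCluster = "none") {
  new("CoexpressionModule", moduleId = moduleId, cohort = cohort,
      brainRegion = brainRegion, consensusCluster = consensusCluster,
      members = unique(as.character(members)))
}

#' Collection of co-expression modules
#'
#' @slot modules list of [CoexpressionModule] objects with unique ids.
#' @export
setClass("ModuleSet", slots = c(modules = "list"))

setValidity("ModuleSet", function(object) {
  if (!all(vapply(object@modules, is, logical(1), "CoexpressionModule")))
    return("all elements must be CoexpressionModule objects")
  ids <- vapply(object@modules, slot, character(1), "moduleId")
  if (anyDuplicated(ids)) return("module ids must be unique")
  TRUE
})

#' @param modules list of [CoexpressionModule].
#' @rdname ModuleSet-class
#' @export
ModuleSet <- function(modules) {
  ids <- vapply(modules, slot, character(1), "moduleId")
  names(modules) <- ids
  new("ModuleSet", modules = modules)
}

## ---------------------------------------------------------------------------
## ExpressionMatrix
## ---------------------------------------------------------------------------

#' Gene-by-sample expression container
#'
#' A SummarizedExperiment carrying one assay of nonnegative finite values, a
#' unit tag (raw_count, tpm, normalized, log_normalized) and per-sample
#' annotations with the keys group, model, age_months, sex and lane.
#'
#' @slot unit expression unit tag.
#' @export
#' @import SummarizedExperiment
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(unit = "character"))

setValidity("ExpressionMatrix", function(object) {
  msgs <- character(0)
  if (length(object@unit) != 1L || !object@unit %in% VALID_UNITS)
    msgs <- c(msgs, sprintf("unit must be one of %s", paste(VALID_UNITS, collapse = ", ")))
  v <- SummarizedExperiment::assay(object, withDimnames = FALSE)
  if (any(!is.finite(v)))
    msgs <- c(msgs, "values must be finite")
  if (any(v < 0, na.rm = TRUE))
    msgs <- c(msgs, "values must be nonnegative")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "gene identifiers must be unique")
  missing_keys <- setdiff(ANNOTATION_KEYS, colnames(SummarizedExperiment::colData(object)))
  if (length(missing_keys))
    msgs <- c(msgs, sprintf("missing sample annotation key(s): %s",
                            paste(missing_keys, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @param values numeric gene x sample matrix with dimnames.
#' @param annotations data.frame keyed by sample id (rownames or a
#'   sample_id column) with columns group, model, age_months, sex, lane.
#' @param unit one of raw_count, tpm, normalized, log_normalized.
#' @rdname ExpressionMatrix-class
#' @export
ExpressionMatrix <- function(values, annotations, unit) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    pa_contract_error("expression values must carry gene and sample names")
  if (!is.null(annotations$sample_id))
    rownames(annotations) <- annotations$sample_id
  missing_samples <- setdiff(colnames(values), rownames(annotations))
  if (length(missing_samples))
    pa_validation_error("sample(s) lacking annotations: %s",
                        paste(missing_samples, collapse = ", "))
  ann <- annotations[colnames(values), ANNOTATION_KEYS, drop = FALSE]
  bad <- which(values < 0 | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    pa_validation_error("negative or non-finite value at gene %s, sample %s",
                        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    pa_validation_error("duplicate gene id: %s", dup[1])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = S4Vectors::DataFrame(ann))
  new("ExpressionMatrix", se, unit = unit)
}

## ---------------------------------------------------------------------------
## OrthologMap
## ---------------------------------------------------------------------------

#' One-to-one human-mouse orthology with dN/dS
#'
#' Each human gene and each mouse gene appears at most once.  dN/dS is NA
#' exactly when dS is zero (the ratio is undefined).
#'
#' @slot table data.frame with columns human_gene, mouse_gene, dn, ds, dnds.
#' @export
setClass("OrthologMap", slots = c(table = "data.frame"))

setValidity("OrthologMap", function(object) {
  tb <- object@table
  msgs <- character(0)
  need <- c("human_gene", "mouse_gene", "dn", "ds", "dnds")
  if (!all(need %in% colnames(tb)))
    return(sprintf("missing column(s): %s", paste(setdiff(need, colnames(tb)), collapse = ", ")))
  if (anyDuplicated(tb$human_gene)) msgs <- c(msgs, "human genes must be unique (one-to-one)")
  if (anyDuplicated(tb$mouse_gene)) msgs <- c(msgs, "mouse genes must be unique (one-to-one)")
  if (any(tb$dn < 0, na.rm = TRUE) || any(tb$ds < 0, na.rm = TRUE))
    msgs <- c(msgs, "dn and ds must be nonnegative")
  und <- is.na(tb$dnds)
  if (!all(und == (tb$ds == 0)))
    msgs <- c(msgs, "dnds must be NA exactly when ds == 0")
  if (length(msgs)) msgs else TRUE
})

#' @param table data.frame with columns human_gene, mouse_gene, dn, ds
#'   (dnds is derived: dn/ds, NA when ds == 0).
#' @rdname OrthologMap-class
#' @export
OrthologMap <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$dnds))
    table$dnds <- ifelse(table$ds == 0, NA_real_, table$dn / table$ds)
  rownames(table) <- NULL
  new("OrthologMap", table = table)
}

## ---------------------------------------------------------------------------
## LogFCTable
## ---------------------------------------------------------------------------

#' Per-gene contrast effects (log2 fold changes)
#'
#' @slot contrast contrast label, e.g. a human region case-vs-control or a
#'   mouse model/age/sex vs B6 comparison.
#' @slot table data.frame with columns gene, logfc, p, adj_p.
#' @export
setClass("LogFCTable", slots = c(contrast = "character", table = "data.frame"))

setValidity("LogFCTable", function(object) {
  tb <- object@table
  msgs <- character(0)
  need <- c("gene", "logfc", "p", "adj_p")
  if (!all(need %in% colnames(tb)))
    return(sprintf("missing column(s): %s", paste(setdiff(need, colnames(tb)), collapse = ", ")))
  if (anyDuplicated(tb$gene)) msgs <- c(msgs, "genes must be unique")
  if (any(tb$p < 0 | tb$p > 1, na.rm = TRUE)) msgs <- c(msgs, "p must lie in [0,1]")
  if (any(tb$adj_p < 0 | tb$adj_p > 1, na.rm = TRUE)) msgs <- c(msgs, "adj_p must lie in [0,1]")
  if (any(tb$adj_p + 1e-12 < tb$p, na.rm = TRUE)) msgs <- c(msgs, "adj_p must be >= p")
  if (length(msgs)) msgs else TRUE
})

#' @param contrast contrast label.
#' @param table data.frame with columns gene, logfc, p, adj_p.
#' @rdname LogFCTable-class
#' @export
LogFCTable <- function(contrast, table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  rownames(table) <- NULL
  new("LogFCTable", contrast = contrast, table = table)
}

## ---------------------------------------------------------------------------
## ProbePair
## ---------------------------------------------------------------------------

#' Designed probe pair for one transcript
#'
#' Two adjacent, non-overlapping probes (35-50 nt each) covering one 100-nt
#' target window: probe A ends at the window midpoint, probe B starts there.
#' Starts are 0-based on the transcript.
#'
#' @export
setClass("ProbePair",
  slots = c(gene = "character", transcriptId = "character",
            windowStart = "integer",
            seqA = "character", startA = "integer", tmA = "numeric",
            seqB = "character", startB = "integer", tmB = "numeric",
            crosshybScore = "numeric", isoformCoverage = "numeric"))

setValidity("ProbePair", function(object) {
  msgs <- character(0)
  la <- nchar(object@seqA); lb <- nchar(object@seqB)
  if (la < 35L || la > 50L || lb < 35L || lb > 50L)
    msgs <- c(msgs, "probe lengths must lie in [35,50]")
  if (object@startA + la != object@startB)
    msgs <- c(msgs, "probes must be adjacent and non-overlapping")
  if (object@startA < object@windowStart ||
      object@startB + lb > object@windowStart + 100L)
    msgs <- c(msgs, "probe pair must fit in its 100-nt window")
  if (object@isoformCoverage < 0 || object@isoformCoverage > 1)
    msgs <- c(msgs, "isoformCoverage must lie in [0,1]")
  if (object@crosshybScore < 0)
    msgs <- c(msgs, "crosshybScore must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## PanelDefinition
## ---------------------------------------------------------------------------

#' Assembled capacity-bounded panel
#'
#' @slot entries data.frame with columns mouse_gene, category (key,
#'   housekeeping or drug_target) and score (global ranking score; NA for
#'   housekeeping).
#' @slot annotatedModules named list (by mouse gene) of human module ids the
#'   entry's probe maps to; empty for housekeeping entries.
#' @slot probes named list (by mouse gene) of [ProbePair] or NULL.
#' @slot capacity maximum number of entries.
#' @slot truncated mouse genes dropped by capacity truncation.
#' @export
setClass("PanelDefinition",
  slots = c(entries = "data.frame", annotatedModules = "list",
            probes = "list", capacity = "integer", truncated = "character"))

setValidity("PanelDefinition", function(object) {
  msgs <- character(0)
  tb <- object@entries
  if (!all(c("mouse_gene", "category", "score") %in% colnames(tb)))
    return("entries must have columns mouse_gene, category, score")
  if (nrow(tb) > object@capacity)
    msgs <- c(msgs, "number of entries exceeds capacity")
  if (anyDuplicated(tb$mouse_gene))
    msgs <- c(msgs, "mouse genes must be unique across entries")
  if (!all(tb$category %in% c("key", "housekeeping", "drug_target")))
    msgs <- c(msgs, "invalid category")
  hk <- tb$mouse_gene[tb$category == "housekeeping"]
  if (any(lengths(object@annotatedModules[hk]) > 0))
    msgs <- c(msgs, "housekeeping entries must carry empty module annotations")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## GeneSetCollection
## ---------------------------------------------------------------------------

#' Named gene sets over a declared universe
#'
#' @slot universe gene identifier universe.
#' @slot sets named list of nonempty subsets of the universe.
#' @export
setClass("PanelGeneSets", slots = c(universe = "character", sets = "list"))

setValidity("PanelGeneSets", function(object) {
  msgs <- character(0)
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msgs <- c(msgs, "set names must be present and unique")
  if (any(lengths(object@sets) == 0))
    msgs <- c(msgs, "every set must be nonempty")
  stray <- unique(unlist(object@sets))
  stray <- setdiff(stray, object@universe)
  if (length(stray))
    msgs <- c(msgs, sprintf("set gene(s) outside universe: %s",
                            paste(head(stray, 3), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @param universe,sets see slots.
#' @rdname PanelGeneSets-class
#' @export
PanelGeneSets <- function(universe, sets) {
  new("PanelGeneSets", universe = unique(as.character(universe)),
      sets = lapply(sets, as.character))
}

## ---------------------------------------------------------------------------
## ModulePCA
## ---------------------------------------------------------------------------

#' Principal components of one module's expression submatrix
#'
#' @slot moduleId module identifier.
#' @slot scores sample x component matrix of component scores.
#' @slot varianceFractions fraction of total variance per component,
#'   non-increasing, summing to at most 1.
#' @export
setClass("ModulePCA",
  slots = c(moduleId = "character", scores = "matrix",
            varianceFractions = "numeric"))

setValidity("ModulePCA", function(object) {
  msgs <- character(0)
  if (sum(object@varianceFractions) > 1 + 1e-8)
    msgs <- c(msgs, "variance fractions must sum to at most 1")
  if (is.unsorted(rev(object@varianceFractions), strictly = FALSE))
    msgs <- c(msgs, "variance fractions must be non-increasing")
  if (ncol(object@scores) != length(object@varianceFractions))
    msgs <- c(msgs, "one variance fraction per score column required")
  if (length(msgs)) msgs else TRUE
})
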