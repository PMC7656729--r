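## Readers and writers for the tabular, sequence and panel formats the
## toolkit touches.  TSV is the canonical dialect; comma-separated input is
## accepted by sniffing the delimiter of the header line.

sniffDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) pa_format_error("empty file: %s", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t"
  else if (grepl(",", first, fixed = TRUE)) ","
  else "\t"
}

readTable <- function(path, required = character(0)) {
  if (!file.exists(path)) pa_format_error("file not found: %s", path)
  if (file.size(path) == 0) pa_format_error("empty file: %s", path)
  tb <- read.delim(path, sep = sniffDelim(path), header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, colnames(tb))
  if (length(missing))
    pa_format_error("missing required column '%s' in %s", missing[1], path)
  tb
}

#' Read a module membership table
#'
#' Expects TSV/CSV with header columns module_id, cohort, brain_region,
#' consensus_cluster, gene; one row per (module, gene).  Duplicate rows are
#' collapsed (membership is a set) and row order is irrelevant.
#'
#' @param path file path.
#' @return a [ModuleSet].
#' @export
readModuleTable <- function(path) {
  tb <- readTable(path, c("module_id", "cohort", "brain_region",
                          "consensus_cluster", "gene"))
  if (!nrow(tb)) pa_format_error("no rows in %s", path)
  mods <- lapply(split(tb, tb$module_id), function(d) {
    CoexpressionModule(moduleId = d$module_id[1], members = unique(d$gene),
                       cohort = d$cohort[1], brainRegion = d$brain_region[1],
                       consensusCluster = d$consensus_cluster[1])
  })
  ModuleSet(mods[order(names(mods))])
}

#' Write a module membership table
#' @param modules a [ModuleSet].
#' @param path output TSV path.
#' @export
writeModuleTable <- function(modules, path) {
  rows <- do.call(rbind, lapply(modules@modules, function(m)
    data.frame(module_id = m@moduleId, cohort = m@cohort,
               brain_region = m@brainRegion,
               consensus_cluster = m@consensusCluster,
               gene = sort(m@members), stringsAsFactors = FALSE)))
  rows <- rows[order(rows$module_id, rows$gene), ]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an expression matrix with its sample annotations
#'
#' The matrix file has gene ids in the first column and samples in the
#' remaining columns; the annotation file is keyed by sample id and must
#' carry group, model, age_months, sex and lane for every sample.
#'
#' @param path matrix TSV/CSV path.
#' @param annotations_path companion annotation table path.
#' @param unit declared unit (raw_count, tpm, normalized, log_normalized).
#' @return an [ExpressionMatrix].
#' @export
readExpressionMatrix <- function(path, annotations_path, unit) {
  tb <- readTable(path)
  genes <- as.character(tb[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) pa_validation_error("duplicate gene id: %s", dup[1])
  values <- as.matrix(tb[, -1, drop = FALSE])
  rownames(values) <- genes
  storage.mode(values) <- "double"
  ann <- readTable(annotations_path, c("sample_id", ANNOTATION_KEYS))
  ExpressionMatrix(values, ann, unit = unit)
}

#' Write an expression matrix (values + annotations)
#' @param m an [ExpressionMatrix].
#' @param path matrix output path.
#' @param annotations_path annotation output path.
#' @export
writeExpressionMatrix <- function(m, path, annotations_path) {
  v <- exprValues(m)
  out <- data.frame(gene = rownames(v), v, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- sampleAnnotations(m)
  ann <- data.frame(sample_id = rownames(ann), ann, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(ann, annotations_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read an orthology table
#'
#' TSV/CSV with columns human_gene, mouse_gene, dn, ds (dnds optional and
#' recomputed as dn/ds, undefined when ds is zero).
#'
#' @param path file path.
#' @return an [OrthologMap].
#' @export
readOrthologyTable <- function(path) {
  tb <- readTable(path, c("human_gene", "mouse_gene", "dn", "ds"))
  tb$dnds <- ifelse(tb$ds == 0, NA_real_, tb$dn / tb$ds)
  OrthologMap(tb)
}

#' Write an orthology table
#' @param orthology an [OrthologMap].
#' @param path output path.
#' @export
writeOrthologyTable <- function(orthology, path) {
  tb <- orthologTable(orthology)
  tb <- tb[order(tb$human_gene), ]
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(NULL)
}

#' Read a per-gene log fold change table
#' @param path TSV with columns gene, logfc, p, adj_p.
#' @param contrast contrast label (defaults to the file name).
#' @return a [LogFCTable].
#' @export
readLogfcTable <- function(path, contrast = basename(path)) {
  tb <- readTable(path, c("gene", "logfc", "p", "adj_p"))
  LogFCTable(contrast, tb)
}

#' Write a log fold change table
#' @param x a [LogFCTable].
#' @param path output path.
#' @export
writeLogfcTable <- function(x, path) {
  write.table(logfcTable(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

## ---------------------------------------------------------------------------
## RCC lane files
## ---------------------------------------------------------------------------

#' Read one RCC lane file
#'
#' RCC lanes are sectioned text: \code{<Section>} ... \code{</Section>} with
#' CSV rows inside.  Counts come from the Code_Summary section; the probe
#' class labels (Endogenous/Housekeeping/Positive/Negative) are preserved so
#' downstream normalization can pick its references.
#'
#' @param path RCC file path.
#' @return list with elements \code{counts} (data.frame: class, name, count)
#'   and \code{attributes} (named character from Sample_Attributes).
#' @export
readRccLane <- function(path) {
  if (!file.exists(path)) pa_format_error("file not found: %s", path)
  lines <- readLines(path)
  section <- NA_character_
  code_rows <- character(0)
  attr_rows <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    open <- regmatches(ln, regexec("^<([A-Za-z_]+)>$", ln))[[1]]
    close <- regmatches(ln, regexec("^</([A-Za-z_]+)>$", ln))[[1]]
    if (length(open) == 2) { section <- open[2]; next }
    if (length(close) == 2) { section <- NA_character_; next }
    if (identical(section, "Code_Summary")) code_rows <- c(code_rows, ln)
    if (identical(section, "Sample_Attributes")) attr_rows <- c(attr_rows, ln)
  }
  if (!length(code_rows))
    pa_format_error("no Code_Summary section in %s", path)
  fields <- strsplit(code_rows, ",", fixed = TRUE)
  header <- tolower(trimws(fields[[1]]))
  need <- c("codeclass", "name", "count")
  idx <- match(need, header)
  if (anyNA(idx))
    pa_format_error("Code_Summary header lacks %s in %s",
                    paste(need[is.na(idx)], collapse = ", "), path)
  body <- fields[-1]
  cls <- vapply(body, function(f) trimws(f[idx[1]]), character(1))
  nm <- vapply(body, function(f) trimws(f[idx[2]]), character(1))
  cnt_chr <- vapply(body, function(f) trimws(f[idx[3]]), character(1))
  bad <- which(!grepl("^[0-9]+$", cnt_chr))
  if (length(bad))
    pa_format_error("non-integer count '%s' for probe %s in %s",
                    cnt_chr[bad[1]], nm[bad[1]], path)
  attrs <- character(0)
  if (length(attr_rows)) {
    kv <- strsplit(attr_rows, ",", fixed = TRUE)
    attrs <- setNames(vapply(kv, function(f) trimws(paste(f[-1], collapse = ",")),
                             character(1)),
                      vapply(kv, function(f) trimws(f[1]), character(1)))
  }
  list(counts = data.frame(class = cls, name = nm,
                           count = as.integer(cnt_chr),
                           stringsAsFactors = FALSE),
       attributes = attrs)
}

#' Assemble a directory of RCC lanes into a raw-count matrix
#'
#' @param dir directory containing `.RCC` files (one lane per file).
#' @return list with the raw-count [ExpressionMatrix] (lane id = file stem)
#'   and the housekeeping-class gene names shared by all lanes.
#' @export
readRccDirectory <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.RCC$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) pa_format_error("no RCC files in %s", dir)
  lanes <- lapply(files, readRccLane)
  ids <- sub("\\.RCC$", "", basename(files), ignore.case = TRUE)
  genes <- lanes[[1]]$counts$name
  values <- vapply(lanes, function(l) {
    m <- match(genes, l$counts$name)
    if (anyNA(m)) pa_format_error("lanes disagree on probe content")
    as.numeric(l$counts$count[m])
  }, numeric(length(genes)))
  values <- matrix(values, nrow = length(genes),
                   dimnames = list(genes, ids))
  hk <- lanes[[1]]$counts$name[lanes[[1]]$counts$class == "Housekeeping"]
  ann <- data.frame(sample_id = ids, group = "unknown", model = "unknown",
                    age_months = NA_real_, sex = "unknown",
                    lane = seq_along(ids), stringsAsFactors = FALSE)
  list(matrix = ExpressionMatrix(values, ann, unit = "raw_count"),
       housekeeping = hk)
}

## ---------------------------------------------------------------------------
## Panel file
## ---------------------------------------------------------------------------

PANEL_MAGIC <- "#panelign-panel\tv1"

#' Write a panel definition
#'
#' Deterministic, sorted, structured-text serialization: a magic header, a
#' capacity line, then one TSV row per entry sorted by mouse gene.  Two
#' writes of equal panels are byte-identical and
#' \code{readPanel(writePanel(p))} reproduces \code{p}.
#'
#' @param panel a [PanelDefinition].
#' @param path output path.
#' @export
writePanel <- function(panel, path) {
  validObject(panel)
  tb <- panel@entries
  ord <- order(tb$mouse_gene)
  tb <- tb[ord, , drop = FALSE]
  fmt_probe <- function(pp) {
    if (is.null(pp)) return(rep(".", 9))
    c(pp@transcriptId, pp@windowStart,
      pp@seqA, pp@startA, sprintf("%.4f", pp@tmA),
      pp@seqB, pp@startB, sprintf("%.4f", pp@tmB),
      sprintf("%.6f|%.6f", pp@crosshybScore, pp@isoformCoverage))
  }
  rows <- vapply(seq_len(nrow(tb)), function(i) {
    g <- tb$mouse_gene[i]
    mods <- sort(panel@annotatedModules[[g]] %||% character(0))
    paste(c(g, tb$category[i],
            if (is.na(tb$score[i])) "." else sprintf("%.10g", tb$score[i]),
            if (length(mods)) paste(mods, collapse = ",") else ".",
            fmt_probe(panel@probes[[g]])),
          collapse = "\t")
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(PANEL_MAGIC,
               sprintf("#capacity\t%d", panel@capacity),
               sprintf("#truncated\t%s",
                       if (length(panel@truncated))
                         paste(sort(panel@truncated), collapse = ",") else "."),
               paste(c("mouse_gene", "category", "score", "modules",
                       "transcript", "window_start", "seq_a", "start_a",
                       "tm_a", "seq_b", "start_b", "tm_b", "scores"),
                     collapse = "\t"),
               rows), con = con)
  invisible(NULL)
}

#' Read a panel definition written by [writePanel()]
#' @param path panel file path.
#' @return a [PanelDefinition].
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) pa_format_error("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != PANEL_MAGIC)
    pa_format_error("not a panel file: %s", path)
  capacity <- as.integer(strsplit(lines[2], "\t")[[1]][2])
  trunc_field <- strsplit(lines[3], "\t")[[1]][2]
  truncated <- if (trunc_field == ".") character(0)
               else strsplit(trunc_field, ",")[[1]]
  body <- lines[-(1:4)]
  entries <- data.frame(mouse_gene = character(0), category = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  mods <- list(); probes <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    g <- f[1]
    entries <- rbind(entries, data.frame(
      mouse_gene = g, category = f[2],
      score = if (f[3] == ".") NA_real_ else as.numeric(f[3]),
      stringsAsFactors = FALSE))
    mods[[g]] <- if (f[4] == ".") character(0) else strsplit(f[4], ",")[[1]]
    if (f[5] != ".") {
      sc <- as.numeric(strsplit(f[13], "|", fixed = TRUE)[[1]])
      probes[[g]] <- new("ProbePair", gene = g, transcriptId = f[5],
                         windowStart = as.integer(f[6]),
                         seqA = f[7], startA = as.integer(f[8]),
                         tmA = as.numeric(f[9]),
                         seqB = f[10], startB = as.integer(f[11]),
                         tmB = as.numeric(f[12]),
                         crosshybScore = sc[1], isoformCoverage = sc[2])
    } else probes[g] <- list(NULL)
  }
  rownames(entries) <- NULL
  new("PanelDefinition", entries = entries, annotatedModules = mods,
      probes = probes, capacity = capacity, truncated = truncated)
}

## ---------------------------------------------------------------------------
## GMT gene sets and FASTA transcripts
## ---------------------------------------------------------------------------

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @param universe optional explicit universe; defaults to the union of all
#'   set members.
#' @return a [PanelGeneSets].
#' @export
readGmt <- function(path, universe = NULL) {
  if (!file.exists(path)) pa_format_error("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) pa_format_error("empty file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    pa_format_error("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  PanelGeneSets(universe %||% unique(unlist(sets)), sets)
}

#' Read transcript sequences from FASTA
#'
#' Header lines follow \code{>transcript_id gene=GENE}; isoform groups are
#' derived by shared gene.
#'
#' @param path FASTA path.
#' @return data.frame with columns transcript_id, gene, sequence.
#' @export
readTranscriptFasta <- function(path) {
  if (!file.exists(path)) pa_format_error("file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  gene <- rep(NA_character_, length(headers))
  hit <- regmatches(headers, regexpr("gene=[^ ]+", headers))
  has <- grepl("gene=", headers)
  gene[has] <- sub("^gene=", "", hit)
  if (anyNA(gene))
    pa_format_error("FASTA header lacking 'gene=' tag: %s",
                    headers[which(is.na(gene))[1]])
  if (anyDuplicated(ids))
    pa_validation_error("duplicate transcript id: %s", ids[duplicated(ids)][1])
  data.frame(transcript_id = ids, gene = gene,
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write transcripts to FASTA with \code{gene=} tags
#' @param transcripts data.frame with transcript_id, gene, sequence.
#' @param path output path.
#' @export
writeTranscriptFasta <- function(transcripts, path) {
  ss <- Biostrings::DNAStringSet(transcripts$sequence)
  names(ss) <- sprintf("%s gene=%s", transcripts$transcript_id,
                       transcripts$gene)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(NULL)
}
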