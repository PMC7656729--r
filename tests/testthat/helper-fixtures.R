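## Shared fixture builders.  All fixtures are generated in code; nothing is
## stored on disk.

## Minimal annotation frame for a set of sample ids.
makeAnnotations <- function(samples, group = "unknown") {
  data.frame(sample_id = samples,
             group = rep_len(group, length(samples)),
             model = "test", age_months = 6, sex = rep_len(c("F", "M"),
                                                           length(samples)),
             lane = seq_along(samples), stringsAsFactors = FALSE)
}

makeExpr <- function(values, unit = "log_normalized", group = "unknown") {
  ExpressionMatrix(values, makeAnnotations(colnames(values), group), unit)
}

## Random expression fixture: genes x samples, positive values.
randomExpr <- function(n_genes, n_samples, seed = 1, unit = "log_normalized") {
  set.seed(seed)
  v <- matrix(abs(rnorm(n_genes * n_samples, mean = 8, sd = 2)),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  makeExpr(v, unit)
}

randomDna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(s) panelign:::reverseComplement_chr(s)

## A syntactically valid ProbePair from two probe sequences (35-50 nt),
## placed in a fresh 100-nt window; used by panel-QC tests that only care
## about the sequences.
makeProbePair <- function(gene, seqA, seqB, window_start = 0L) {
  la <- nchar(seqA); lb <- nchar(seqB)
  startA <- window_start + 50L - la
  new("ProbePair", gene = gene, transcriptId = paste0(gene, ".1"),
      windowStart = as.integer(window_start),
      seqA = seqA, startA = as.integer(startA), tmA = 75,
      seqB = seqB, startB = as.integer(window_start + 50L), tmB = 75,
      crosshybScore = 0, isoformCoverage = 1)
}

## Panel whose entries carry the given probes (named list gene -> ProbePair).
makePanelWithProbes <- function(probes, capacity = 770L) {
  genes <- names(probes)
  entries <- data.frame(mouse_gene = genes, category = "key",
                        score = seq_along(genes), stringsAsFactors = FALSE)
  ann <- setNames(rep(list(character(0)), length(genes)), genes)
  new("PanelDefinition", entries = entries, annotatedModules = ann,
      probes = probes, capacity = as.integer(capacity),
      truncated = character(0))
}

## Write a minimal RCC lane file; returns the path.
writeRccFixture <- function(path, counts_block = NULL) {
  if (is.null(counts_block))
    counts_block <- c(
      "CodeClass,Name,Count",
      "Endogenous,GeneA,120",
      "Endogenous,GeneB,47",
      "Endogenous,GeneC,310",
      "Housekeeping,Hk1,1000",
      "Housekeeping,Hk2,900")
  writeLines(c("<Header>", "FileVersion,1.7", "</Header>",
               "<Sample_Attributes>", "ID,lane1", "Owner,test",
               "</Sample_Attributes>",
               "<Code_Summary>", counts_block, "</Code_Summary>"),
             path)
  path
}

## Closed-form Pearson r and two-sided p via the t-transform.
pearsonOracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

## Exact hypergeometric upper tail by combinatorial summation.
hyperOracle <- function(overlap, set_size, universe, query) {
  ks <- overlap:min(set_size, query)
  sum(choose(set_size, ks) * choose(universe - set_size, query - ks)) /
    choose(universe, query)
}

## Brute-force weighted-KS running sum and ES.
gseaOracle <- function(stat, hit, weight_p) {
  N <- length(stat); Nh <- sum(hit)
  w <- abs(stat)^weight_p
  nr <- sum(w[hit])
  run <- numeric(N); acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) w[i] / nr else -1 / (N - Nh)
    run[i] <- acc
  }
  run[which.max(abs(run))]
}
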