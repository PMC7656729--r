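## In-silico panel QC: screen every pair of panel probes for intramolecular
## duplex formation and iteratively swap in alternative probes until the
## panel is conflict-free.

## Entry-level interaction: strongest duplex over the four sequence
## combinations between two probe pairs.
entryInteraction <- function(pi, pj, config) {
  combos <- list(c(pi@seqA, pj@seqA), c(pi@seqA, pj@seqB),
                 c(pi@seqB, pj@seqA), c(pi@seqB, pj@seqB))
  best <- NULL
  for (cmb in combos) {
    r <- pairwiseInteraction(cmb[1], cmb[2], config)
    if (is.null(best) || r$delta_g < best$delta_g ||
        (r$delta_g == best$delta_g && r$duplex_tm > best$duplex_tm))
      best <- r
  }
  best
}

#' Screen a panel for probe-probe interactions
#'
#' Evaluates every unordered pair of panel entries carrying probes and
#' reports the pairs whose strongest duplex crosses the conflict thresholds.
#' An exact-complement 8-mer prefilter makes the scan cheap: any perfectly
#' complementary stretch of 8 nt or more implies a shared complementary
#' 8-mer, so the prefilter loses nothing.
#'
#' @param panel a [PanelDefinition] whose entries carry probes.
#' @param config configuration from [probeDesignConfig()].
#' @return data.frame of conflicts (gene_i, gene_j, delta_g, duplex_tm,
#'   stretch), ordered by panel entry order; zero rows when clean.
#' @export
screenPanel <- function(panel, config = probeDesignConfig()) {
  genes <- panel@entries$mouse_gene
  probes <- panel@probes[genes]
  has <- !vapply(probes, is.null, logical(1))
  genes <- genes[has]; probes <- probes[has]
  n <- length(genes)
  empty <- data.frame(gene_i = character(0), gene_j = character(0),
                      delta_g = numeric(0), duplex_tm = numeric(0),
                      stretch = integer(0), stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  fw <- lapply(probes, function(p)
    unique(c(kmers_chr(p@seqA, 8L), kmers_chr(p@seqB, 8L))))
  rc <- lapply(probes, function(p)
    unique(c(kmers_chr(reverseComplement_chr(p@seqA), 8L),
             kmers_chr(reverseComplement_chr(p@seqB), 8L))))
  ## invert: for each complementary 8-mer, which entries carry it forward /
  ## reverse-complemented
  fw_map <- split(rep(seq_len(n), lengths(fw)), unlist(fw))
  rows <- list()
  for (i in seq_len(n)) {
    partners <- unique(unlist(fw_map[rc[[i]]], use.names = FALSE))
    partners <- partners[partners > i]
    for (j in sort(partners)) {
      r <- entryInteraction(probes[[i]], probes[[j]], config)
      if (r$conflict)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_i = genes[i], gene_j = genes[j], delta_g = r$delta_g,
          duplex_tm = r$duplex_tm, stretch = r$stretch,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Resolve panel probe conflicts by substituting alternatives
#'
#' In each round every conflicting pair is visited in panel entry order; the
#' member with the worse composite rank key is replaced by its gene's
#' next-ranked alternative probe (falling back to the other member when the
#' worse gene has none left), then the panel is re-screened.  Replacement
#' only ever substitutes probes for the same gene.
#'
#' @param panel a [PanelDefinition] with probes.
#' @param alternatives named list (by mouse gene) of ranked [ProbePair]
#'   candidates, best first, as produced by [designProbeCandidates()].
#' @param max_rounds maximum screen/replace rounds.
#' @param config configuration from [probeDesignConfig()].
#' @return list with the conflict-free panel, the number of rounds used and
#'   a replacement log data.frame (round, gene, new window start).
#' @export
resolveConflicts <- function(panel, alternatives, max_rounds = 10L,
                             config = probeDesignConfig()) {
  ## position of each gene's current probe within its alternatives list
  pos <- setNames(integer(length(alternatives)), names(alternatives))
  for (g in names(alternatives)) {
    cur <- panel@probes[[g]]
    pos[g] <- 0L
    if (!is.null(cur)) {
      hit <- which(vapply(alternatives[[g]], function(a)
        a@windowStart == cur@windowStart && a@seqA == cur@seqA &&
          a@seqB == cur@seqB, logical(1)))
      if (length(hit)) pos[g] <- hit[1]
    }
  }
  advance <- function(g) {
    alts <- alternatives[[g]]
    if (is.null(alts) || pos[g] >= length(alts)) return(NULL)
    pos[g] <<- pos[g] + 1L
    alts[[pos[g]]]
  }
  log <- data.frame(round = integer(0), gene = character(0),
                    window_start = integer(0), stringsAsFactors = FALSE)
  for (round in seq_len(max_rounds)) {
    conflicts <- screenPanel(panel, config)
    if (!nrow(conflicts))
      return(list(panel = panel, rounds = round - 1L, replacements = log))
    replaced_this_round <- character(0)
    any_replacement <- FALSE
    for (ci in seq_len(nrow(conflicts))) {
      gi <- conflicts$gene_i[ci]; gj <- conflicts$gene_j[ci]
      if (gi %in% replaced_this_round || gj %in% replaced_this_round) next
      ki <- probeRankKey(panel@probes[[gi]], config$tm_target)
      kj <- probeRankKey(panel@probes[[gj]], config$tm_target)
      order_try <- if (rankKeyWorse(ki, kj)) c(gi, gj) else c(gj, gi)
      for (g in order_try) {
        nxt <- advance(g)
        if (!is.null(nxt)) {
          panel@probes[[g]] <- nxt
          replaced_this_round <- c(replaced_this_round, g)
          log <- rbind(log, data.frame(round = round, gene = g,
                                       window_start = nxt@windowStart,
                                       stringsAsFactors = FALSE))
          any_replacement <- TRUE
          break
        }
      }
    }
    if (!any_replacement) {
      pairs <- paste(conflicts$gene_i, conflicts$gene_j, sep = "/")
      pa_unresolvable("conflicts remain with no alternatives left: %s",
                      paste(pairs, collapse = ", "))
    }
  }
  conflicts <- screenPanel(panel, config)
  if (!nrow(conflicts))
    return(list(panel = panel, rounds = max_rounds, replacements = log))
  pa_nonconvergence("panel still has %d conflict(s) after %d rounds",
                    nrow(conflicts), max_rounds)
}
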