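## Probe-pair design: window a transcript, profile windows for sequence
## features, thermodynamically tune two adjacent half-window probes, score
## cross-hybridization and isoform coverage, and pick the best candidate.

#' Enumerate profiling windows along a transcript
#'
#' @param sequence transcript sequence.
#' @param window_length window length in nt (100 by default).
#' @param step stride in nt.
#' @return integer vector of 0-based window starts.
#' @export
enumerateWindows <- function(sequence, window_length = 100L, step = 1L) {
  n <- nchar(sequence)
  if (n < window_length)
    pa_no_candidate("sequence length %d shorter than window length %d",
                    n, window_length)
  seq.int(0L, n - window_length, by = step)
}

#' Profile one window for intrinsic sequence makeup
#'
#' Computes G/C fraction over canonical bases, the count of non-canonical
#' bases, the longest homopolymer run, direct/inverted repeat flags (two
#' disjoint occurrences of a k-mer, resp. of a k-mer and its reverse
#' complement) and the predicted window melting temperature.
#'
#' @param window_sequence the window sequence.
#' @param config configuration from [probeDesignConfig()].
#' @return list with gc_fraction, noncanonical_count, max_homopolymer_run,
#'   has_direct_repeat, has_inverted_repeat, window_tm.
#' @export
profileWindow <- function(window_sequence, config = probeDesignConfig()) {
  chars <- strsplit(window_sequence, "")[[1]]
  canonical <- chars %in% c("A", "C", "G", "T")
  n_canon <- sum(canonical)
  gc <- if (n_canon) sum(chars %in% c("G", "C")) / n_canon else NA_real_
  runs <- rle(chars)
  k <- config$k_rep
  kms <- kmers_chr(window_sequence, k)
  direct <- FALSE
  for (u in unique(kms[duplicated(kms)])) {
    if (diff(range(which(kms == u))) >= k) { direct <- TRUE; break }
  }
  ## k-mers of the reverse complement, reversed, are the per-position
  ## reverse complements of kms -- avoids one revcomp call per k-mer
  rc_kms <- rev(kmers_chr(reverseComplement_chr(window_sequence), k))
  inverted <- FALSE
  for (u in intersect(kms, rc_kms)) {
    pu <- which(kms == u)        # occurrences of u
    pv <- which(rc_kms == u)     # occurrences of revcomp(u)
    if (max(pu) - min(pv) >= k || max(pv) - min(pu) >= k) {
      inverted <- TRUE
      break
    }
  }
  tm <- if (all(canonical))
    meltingTemperature(window_sequence, config$na_molar,
                       config$strand_conc_molar) else NA_real_
  list(gc_fraction = gc,
       noncanonical_count = length(chars) - n_canon,
       max_homopolymer_run = max(runs$lengths),
       has_direct_repeat = direct,
       has_inverted_repeat = inverted,
       window_tm = tm)
}

#' Thermodynamically tune a probe within a region
#'
#' Among substrings of length 35-50 anchored at the region's 5' end (or,
#' with \code{anchor = "end"}, at its 3' end), returns the one whose melting
#' temperature is closest to the target; ties go to the shorter probe.
#'
#' @param region candidate region sequence (>= 35 nt, canonical bases).
#' @param tm_target target melting temperature, degrees C.
#' @param anchor "start" (5' anchored) or "end" (3' anchored).
#' @param config configuration from [probeDesignConfig()].
#' @return list with sequence, start (0-based within region), length, tm.
#' @export
tuneProbe <- function(region, tm_target = 78, anchor = c("start", "end"),
                      config = probeDesignConfig()) {
  anchor <- match.arg(anchor)
  n <- nchar(region)
  if (n < 35L)
    pa_no_candidate("region of %d nt is too short to tune a probe (min 35)", n)
  checkCanonical(region, 35L, "probe region")
  tm <- tmByLength(region, 35L, min(50L, n), anchor = anchor,
                   na_molar = config$na_molar,
                   strand_conc_molar = config$strand_conc_molar)
  lens <- as.integer(names(tm))
  best <- which.min(abs(tm - tm_target))  # first minimum = shortest length
  len <- lens[best]
  start <- if (anchor == "start") 0L else n - len
  list(sequence = substr(region, start + 1L, start + len),
       start = start, length = len, tm = unname(tm[best]))
}

## ---------------------------------------------------------------------------
## Cross-hybridization
## ---------------------------------------------------------------------------

#' Build an exact-seed index over a transcriptome
#'
#' @param transcriptome data.frame with transcript_id, gene, sequence (as
#'   from [readTranscriptFasta()]).
#' @param seed_length exact-match seed length.
#' @return an index object for [crosshybScore()].
#' @export
buildTranscriptomeIndex <- function(transcriptome, seed_length = 12L) {
  n <- nrow(transcriptome)
  km_l <- vector("list", n); pos_l <- vector("list", n)
  tx_l <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- kmers_chr(transcriptome$sequence[i], seed_length)
    km_l[[i]] <- ks
    pos_l[[i]] <- seq_along(ks)
    tx_l[[i]] <- rep.int(i, length(ks))
  }
  km <- unlist(km_l, use.names = FALSE)
  pos <- unlist(pos_l, use.names = FALSE)
  tx_idx <- unlist(tx_l, use.names = FALSE)
  hits <- split(seq_along(km), km)
  env <- list2env(hits, hash = TRUE, size = max(1L, length(hits)))
  list(env = env, tx = tx_idx, pos = pos,
       transcriptome = transcriptome, seed_length = seed_length)
}

#' Cross-hybridization score of a probe against off-target transcripts
#'
#' Seeds exact k-mer matches of the probe in transcripts of other genes and
#' extends each seed ungapped across the full probe; the score is the
#' maximal identity fraction (matches / probe length) over all off-target
#' hits, 0 with no seed hit and 1 for a perfect off-target duplicate.
#'
#' @param probe_sequence probe sequence (35-50 nt).
#' @param transcriptome data.frame with transcript_id, gene, sequence, or an
#'   index built by [buildTranscriptomeIndex()].
#' @param target_gene the probe's own gene (its transcripts are excluded).
#' @param config configuration from [probeDesignConfig()].
#' @return nonnegative identity fraction in [0, 1].
#' @export
crosshybScore <- function(probe_sequence, transcriptome, target_gene,
                          config = probeDesignConfig()) {
  plen <- nchar(probe_sequence)
  if (plen < 35L || plen > 50L)
    pa_contract_error("probe length must lie in [35,50] (got %d)", plen)
  index <- if (is.data.frame(transcriptome))
    buildTranscriptomeIndex(transcriptome, config$seed_length)
  else transcriptome
  k <- index$seed_length
  pv <- strsplit(probe_sequence, "")[[1]]
  seeds <- kmers_chr(probe_sequence, k)
  cand_tx <- integer(0); cand_off <- integer(0)
  for (i in seq_along(seeds)) {
    hit_idx <- index$env[[seeds[i]]]
    if (is.null(hit_idx)) next
    txs <- index$tx[hit_idx]
    offs <- index$pos[hit_idx] - i  # 0-based probe offset on the transcript
    keep <- index$transcriptome$gene[txs] != target_gene
    cand_tx <- c(cand_tx, txs[keep])
    cand_off <- c(cand_off, offs[keep])
  }
  if (!length(cand_tx)) return(0)
  key <- paste(cand_tx, cand_off)
  keep <- !duplicated(key)
  cand_tx <- cand_tx[keep]; cand_off <- cand_off[keep]
  best <- 0
  for (j in seq_along(cand_tx)) {
    s <- index$transcriptome$sequence[cand_tx[j]]
    off <- cand_off[j]
    lo <- max(0L, -off); hi <- min(plen - 1L, nchar(s) - 1L - off)
    if (hi < lo) next
    frag <- strsplit(substr(s, off + lo + 1L, off + hi + 1L), "")[[1]]
    m <- sum(pv[(lo + 1L):(hi + 1L)] == frag)
    best <- max(best, m / plen)
  }
  best
}

#' Splice-isoform coverage of a probe
#'
#' Fraction of a gene's isoform sequences that contain the probe's target
#' subsequence exactly.
#'
#' @param transcript_sequence sequence of the transcript the probe was
#'   designed on.
#' @param start 0-based probe start on that transcript.
#' @param length probe length in nt.
#' @param isoform_sequences character vector of all isoform sequences of the
#'   gene (including the design transcript).
#' @return coverage fraction in [0, 1].
#' @export
isoformCoverage <- function(transcript_sequence, start, length,
                            isoform_sequences) {
  if (start < 0 || start + length > nchar(transcript_sequence))
    pa_contract_error("probe coordinates [%d, %d) exceed transcript length %d",
                      start, start + length, nchar(transcript_sequence))
  sub <- substr(transcript_sequence, start + 1L, start + length)
  mean(vapply(isoform_sequences, grepl, logical(1), pattern = sub,
              fixed = TRUE, USE.NAMES = FALSE))
}

## ---------------------------------------------------------------------------
## Full design
## ---------------------------------------------------------------------------

## Rank key as an orderable data.frame: isoform coverage desc, crosshyb asc,
## worst per-pair |Tm - target| asc, window start asc.
rankCandidates <- function(cand) {
  cand[order(-cand$isoform_coverage, cand$crosshyb, cand$tm_dev,
             cand$window_start), , drop = FALSE]
}

#' Enumerate and rank all admissible probe-pair candidates for a transcript
#'
#' Windows failing the hard filters (non-canonical bases, homopolymer run of
#' \code{run_max} or more, direct or inverted repeat) are excluded; every
#' remaining window yields one tuned probe pair.  Candidates are ranked by
#' isoform coverage (descending), cross-hybridization score (ascending),
#' worst probe |Tm - target| (ascending) and window start (ascending).
#'
#' @param transcript_id transcript to design for.
#' @param transcriptome data.frame with transcript_id, gene, sequence.
#' @param config configuration from [probeDesignConfig()].
#' @param index optional prebuilt [buildTranscriptomeIndex()].
#' @param max_candidates cap on the number of ranked candidates returned.
#' @param min_start_separation when returning several candidates, require
#'   their window starts to differ by at least this many nt (0 keeps the
#'   plain ranking).  Useful for conflict-resolution alternatives, where a
#'   1-nt-shifted window is not a genuinely different probe.
#' @return list of [ProbePair], best first.
#' @export
designProbeCandidates <- function(transcript_id, transcriptome,
                                  config = probeDesignConfig(),
                                  index = NULL, max_candidates = Inf,
                                  min_start_separation = 0L) {
  row <- which(transcriptome$transcript_id == transcript_id)
  if (!length(row))
    pa_contract_error("unknown transcript id '%s'", transcript_id)
  seq <- transcriptome$sequence[row]
  gene <- transcriptome$gene[row]
  starts <- enumerateWindows(seq, config$window_length, config$step)
  wl <- config$window_length
  half <- wl %/% 2L
  tallies <- c(noncanonical = 0L, homopolymer = 0L, direct_repeat = 0L,
               inverted_repeat = 0L)
  if (is.null(index))
    index <- buildTranscriptomeIndex(transcriptome, config$seed_length)
  isoforms <- transcriptome$sequence[transcriptome$gene == gene]
  cand <- vector("list", length(starts))
  n_cand <- 0L
  for (ws in starts) {
    w <- substr(seq, ws + 1L, ws + wl)
    prof <- profileWindow(w, config)
    bad <- c(noncanonical = prof$noncanonical_count > 0L,
             homopolymer = prof$max_homopolymer_run >= config$run_max,
             direct_repeat = prof$has_direct_repeat,
             inverted_repeat = prof$has_inverted_repeat)
    if (any(bad)) {
      tallies <- tallies + bad
      next
    }
    tuneA <- tuneProbe(substr(w, 1L, half), config$tm_target, "end", config)
    tuneB <- tuneProbe(substr(w, half + 1L, wl), config$tm_target, "start",
                       config)
    startA <- ws + half - tuneA$length
    startB <- ws + half
    xh <- max(crosshybScore(tuneA$sequence, index, gene, config),
              crosshybScore(tuneB$sequence, index, gene, config))
    cov <- isoformCoverage(seq, startA, tuneA$length + tuneB$length, isoforms)
    n_cand <- n_cand + 1L
    cand[[n_cand]] <- c(
      window_start = ws, startA = startA, lenA = tuneA$length,
      tmA = tuneA$tm, startB = startB, lenB = tuneB$length, tmB = tuneB$tm,
      crosshyb = xh, isoform_coverage = cov,
      tm_dev = max(abs(tuneA$tm - config$tm_target),
                   abs(tuneB$tm - config$tm_target)))
  }
  if (!n_cand)
    pa_no_candidate(
      "no admissible window for %s (noncanonical %d, homopolymer %d, direct repeat %d, inverted repeat %d)",
      transcript_id, tallies[["noncanonical"]], tallies[["homopolymer"]],
      tallies[["direct_repeat"]], tallies[["inverted_repeat"]])
  cand <- rankCandidates(as.data.frame(do.call(rbind, cand[seq_len(n_cand)])))
  if (min_start_separation > 0L && nrow(cand) > 1L) {
    keep <- 1L
    for (i in 2:nrow(cand)) {
      if (all(abs(cand$window_start[i] - cand$window_start[keep]) >=
              min_start_separation))
        keep <- c(keep, i)
    }
    cand <- cand[keep, , drop = FALSE]
  }
  n <- min(nrow(cand), max_candidates)
  lapply(seq_len(n), function(i) {
    r <- cand[i, ]
    new("ProbePair", gene = gene, transcriptId = transcript_id,
        windowStart = as.integer(r$window_start),
        seqA = substr(seq, r$startA + 1L, r$startA + r$lenA),
        startA = as.integer(r$startA), tmA = r$tmA,
        seqB = substr(seq, r$startB + 1L, r$startB + r$lenB),
        startB = as.integer(r$startB), tmB = r$tmB,
        crosshybScore = r$crosshyb, isoformCoverage = r$isoform_coverage)
  })
}

#' Design the best probe pair for a transcript
#'
#' @inheritParams designProbeCandidates
#' @return the top-ranked [ProbePair].
#' @export
designProbePair <- function(transcript_id, transcriptome,
                            config = probeDesignConfig(), index = NULL) {
  designProbeCandidates(transcript_id, transcriptome, config, index,
                        max_candidates = 1L)[[1]]
}

## Composite rank key of an existing probe pair, comparable across pairs of
## the same gene (used by conflict resolution to decide which member of a
## conflicting pair is "worse").
probeRankKey <- function(pp, tm_target = 78) {
  c(-pp@isoformCoverage, pp@crosshybScore,
    max(abs(pp@tmA - tm_target), abs(pp@tmB - tm_target)),
    pp@windowStart)
}

## TRUE when key a ranks worse than key b (lexicographic).
rankKeyWorse <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}
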