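test_that("window enumeration covers the transcript with the declared stride", {
  expect_equal(enumerateWindows(randomDna(100, 1), 100, 1), 0L)
  expect_length(enumerateWindows(randomDna(109, 2), 100, 1), 10L)
  expect_error(enumerateWindows(randomDna(99, 3), 100, 1),
               class = "panelign_no_candidate_error")
  expect_equal(enumerateWindows(randomDna(120, 4), 100, 5), c(0L, 5L, 10L, 15L, 20L))
})

test_that("window profiling reports composition, runs and repeats", {
  p <- profileWindow(strrep("ACGT", 25))
  expect_equal(p$gc_fraction, 0.5)
  expect_equal(p$noncanonical_count, 0L)
  expect_equal(p$max_homopolymer_run, 1L)

  w <- paste0(randomDna(40, 5), "AAAAAAA", randomDna(53, 6))
  expect_gte(profileWindow(w)$max_homopolymer_run, 7L)

  s <- randomDna(50, 7)
  expect_true(profileWindow(paste0(s, s))$has_direct_repeat)

  ## planted inverted repeat: a 12-mer and its reverse complement, disjoint
  arm <- randomDna(12, 8)
  w2 <- paste0(randomDna(30, 9), arm, randomDna(20, 10), revcomp(arm),
               randomDna(26, 11))
  expect_true(profileWindow(w2)$has_inverted_repeat)

  wn <- paste0(strrep("ACGT", 24), "NNAT")
  expect_equal(profileWindow(wn)$noncanonical_count, 2L)
  expect_true(is.na(profileWindow(wn)$window_tm))
})

test_that("nearest-neighbor Tm matches independent oracle values", {
  ## frozen oracle values: unified NN table with entropic salt correction,
  ## 50 mM Na+, 0.25 uM total strands (independent recomputation)
  expect_equal(meltingTemperature("AGCTTGCCAGGTACGATCGA"), 57.708973,
               tolerance = 0.1)
  expect_equal(meltingTemperature("ATGCGTACCGTTAGCAATCGGATCGTTACGCATGGCTAAC"),
               69.042704, tolerance = 0.1)
  ## duplex symmetry: Tm(seq) == Tm(revcomp(seq))
  for (seed in 1:5) {
    s <- randomDna(30, seed)
    expect_equal(meltingTemperature(s), meltingTemperature(revcomp(s)),
                 tolerance = 1e-9)
  }
  expect_error(meltingTemperature("ACGTAC"), class = "panelign_contract_error")
  expect_error(meltingTemperature(strrep("ACGN", 5)),
               class = "panelign_contract_error")
})

test_that("duplex dG37 matches the hand-summed island oracle", {
  expect_equal(duplexDeltaG37("GATCCGGTACGCTAA"), -13.329236,
               tolerance = 0.1)
})

test_that("probe tuning equals brute force over all candidate lengths", {
  region <- randomDna(50, 12)
  tuned <- tuneProbe(region, tm_target = 78)
  tms <- vapply(35:50, function(L)
    meltingTemperature(substr(region, 1, L)), numeric(1))
  best <- (35:50)[which.min(abs(tms - 78))]
  expect_equal(tuned$length, best)
  expect_equal(tuned$sequence, substr(region, 1, best))
  expect_equal(tuned$tm, tms[best - 34L], tolerance = 1e-9)

  ## end-anchored tuning mirrors the oracle on suffixes
  tuned_end <- tuneProbe(region, 78, anchor = "end")
  tms_end <- vapply(35:50, function(L)
    meltingTemperature(substr(region, 51 - L, 50)), numeric(1))
  best_end <- (35:50)[which.min(abs(tms_end - 78))]
  expect_equal(tuned_end$length, best_end)
  expect_equal(tuned_end$start, 50L - best_end)

  ## an exact two-way tie resolves to the shorter probe
  tm35 <- meltingTemperature(substr(region, 1, 35))
  tm36 <- meltingTemperature(substr(region, 1, 36))
  expect_equal(tuneProbe(region, (tm35 + tm36) / 2)$length, 35L)

  expect_error(tuneProbe(randomDna(30, 13), 78),
               class = "panelign_no_candidate_error")
})

test_that("cross-hybridization scoring agrees with an exhaustive alignment oracle", {
  probe <- randomDna(40, 14)
  clean <- data.frame(
    transcript_id = c("t1", "t2"), gene = c("G1", "G2"),
    sequence = c(paste0(randomDna(50, 15), probe, randomDna(50, 16)),
                 randomDna(200, 17)), stringsAsFactors = FALSE)
  ## no shared 12-mer with the other gene -> 0
  expect_equal(crosshybScore(probe, clean, "G1"), 0)
  ## verbatim embedding in another gene -> 1
  dup <- rbind(clean, data.frame(transcript_id = "t3", gene = "G3",
                                 sequence = paste0(randomDna(10, 18), probe,
                                                   randomDna(30, 19))))
  expect_equal(crosshybScore(probe, dup, "G1"), 1)

  ## planted 30-match off-target: first 30 nt match, remaining 10 mismatch
  mism <- chartr("ACGT", "TGCA", substr(probe, 31, 40))
  offt <- rbind(clean, data.frame(transcript_id = "t4", gene = "G4",
                                  sequence = paste0(randomDna(20, 20),
                                                    substr(probe, 1, 30),
                                                    mism, randomDna(20, 21))))
  expect_equal(crosshybScore(probe, offt, "G1"), 0.75)

  ## oracle equivalence: ungapped scan over every offset of every
  ## off-target transcript
  oracle <- function(p, txdf, target) {
    pv <- strsplit(p, "")[[1]]
    best <- 0
    for (i in which(txdf$gene != target)) {
      sv <- strsplit(txdf$sequence[i], "")[[1]]
      for (off in (-(length(pv) - 1)):(length(sv) - 1)) {
        idx <- seq_along(pv) + off
        ok <- idx >= 1 & idx <= length(sv)
        if (sum(ok) < 12) next
        m <- sum(pv[ok] == sv[idx[ok]])
        ## count only alignments a 12-mer seed would find
        run <- rle(pv[ok] == sv[idx[ok]])
        if (max(c(0, run$lengths[run$values])) >= 12)
          best <- max(best, m / length(pv))
      }
    }
    best
  }
  expect_equal(crosshybScore(probe, offt, "G1"), oracle(probe, offt, "G1"))
  expect_equal(crosshybScore(probe, dup, "G1"), oracle(probe, dup, "G1"))
})

test_that("isoform coverage is the exact-containment fraction", {
  base <- randomDna(300, 22)
  iso <- c(base,
           paste0(substr(base, 1, 100), substr(base, 200, 300)),
           paste0(substr(base, 1, 80), substr(base, 210, 300)),
           paste0(substr(base, 1, 60), substr(base, 220, 300)))
  ## probe inside the spliced-out region: present in 1 of 4
  expect_equal(isoformCoverage(base, 120L, 40L, iso), 0.25)
  ## probe in the shared prefix: present in all 4
  expect_equal(isoformCoverage(base, 10L, 40L, iso), 1)
  expect_equal(isoformCoverage(base, 120L, 40L, base), 1)  # single isoform
  expect_error(isoformCoverage(base, 290L, 40L, iso),
               class = "panelign_contract_error")
})

test_that("probe-pair design picks the exhaustive-search winner", {
  set.seed(23)
  tx <- data.frame(
    transcript_id = c("t1", "t2"), gene = c("G1", "G2"),
    sequence = c(randomDna(400, 24), randomDna(300, 25)),
    stringsAsFactors = FALSE)
  config <- probeDesignConfig()
  pp <- designProbePair("t1", tx, config)
  expect_s4_class(pp, "ProbePair")
  expect_true(nchar(pp@seqA) >= 35 && nchar(pp@seqA) <= 50)
  expect_true(nchar(pp@seqB) >= 35 && nchar(pp@seqB) <= 50)
  expect_equal(pp@startA + nchar(pp@seqA), pp@startB)  # adjacency
  expect_lte(pp@startB + nchar(pp@seqB), pp@windowStart + 100L)
  expect_equal(pp@isoformCoverage, 1)
  expect_equal(pp@crosshybScore, 0)

  ## oracle: enumerate every admissible window by hand and rank by the same
  ## composite key
  seq1 <- tx$sequence[1]
  oracle_best <- NULL
  for (ws in enumerateWindows(seq1, 100, 1)) {
    w <- substr(seq1, ws + 1, ws + 100)
    prof <- profileWindow(w, config)
    if (prof$noncanonical_count > 0 || prof$max_homopolymer_run >= 6 ||
        prof$has_direct_repeat || prof$has_inverted_repeat) next
    a <- tuneProbe(substr(w, 1, 50), 78, "end", config)
    b <- tuneProbe(substr(w, 51, 100), 78, "start", config)
    xh <- max(crosshybScore(a$sequence, tx, "G1", config),
              crosshybScore(b$sequence, tx, "G1", config))
    cov <- isoformCoverage(seq1, ws + 50L - a$length,
                           a$length + b$length, seq1)
    key <- c(-cov, xh, max(abs(a$tm - 78), abs(b$tm - 78)), ws)
    if (is.null(oracle_best) || panelign:::rankKeyWorse(oracle_best$key, key))
      oracle_best <- list(key = key, ws = ws)
  }
  expect_equal(pp@windowStart, oracle_best$ws)

  ## homopolymer transcript has no admissible window
  allA <- data.frame(transcript_id = "tA", gene = "GA",
                     sequence = strrep("A", 200), stringsAsFactors = FALSE)
  expect_error(designProbePair("tA", allA),
               class = "panelign_no_candidate_error")
})

test_that("design is deterministic and crosshyb is monotone under duplication", {
  tx <- data.frame(transcript_id = c("t1", "t2"), gene = c("G1", "G2"),
                   sequence = c(randomDna(350, 26), randomDna(300, 27)),
                   stringsAsFactors = FALSE)
  p1 <- designProbePair("t1", tx)
  p2 <- designProbePair("t1", tx)
  expect_equal(p1@seqA, p2@seqA)
  expect_equal(p1@windowStart, p2@windowStart)

  ## adding an off-target duplicate of the chosen probe cannot decrease its
  ## cross-hybridization score
  before <- crosshybScore(p1@seqA, tx, "G1")
  tx2 <- rbind(tx, data.frame(transcript_id = "t3", gene = "G3",
                              sequence = paste0(randomDna(20, 28), p1@seqA,
                                                randomDna(20, 29))))
  expect_gte(crosshybScore(p1@seqA, tx2, "G1"), before)
  expect_equal(crosshybScore(p1@seqA, tx2, "G1"), 1)
})
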