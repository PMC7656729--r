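## Nearest-neighbor duplex thermodynamics.
##
## Unified DNA/DNA parameter set (SantaLucia-style): dH in kcal/mol, dS in
## cal/(mol K) at 1 M NaCl, with entropic salt correction
## dS' = dS + 0.368 * (N - 1) * ln[Na+] and two-state melting
## Tm = 1000 dH / (dS' + R ln(CT/4)) - 273.15 for non-self-complementary
## duplexes at equal strand concentrations.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
## Duplex initiation with a terminal G:C or A:T pair.
NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
GAS_CONSTANT <- 1.987  # cal / (mol K)

#' Default thermodynamic/design configuration
#'
#' @param na_molar monovalent cation concentration (mol/L).
#' @param strand_conc_molar total strand concentration (mol/L).
#' @param tm_target hybridization target melting temperature, degrees C.
#' @param window_length profiling window length, nt.
#' @param step window stride, nt.
#' @param k_rep repeat seed length for direct/inverted repeat flags.
#' @param run_max homopolymer runs of this length or longer are rejected.
#' @param seed_length exact-match seed length for cross-hybridization.
#' @param dg_threshold panel-QC conflict threshold on duplex dG37 (kcal/mol).
#' @param tm_threshold panel-QC conflict threshold on duplex Tm (degrees C).
#' @return named list of parameters.
#' @export
probeDesignConfig <- function(na_molar = 0.05, strand_conc_molar = 0.25e-6,
                              tm_target = 78, window_length = 100L,
                              step = 1L, k_rep = 8L, run_max = 6L,
                              seed_length = 12L,
                              dg_threshold = -18, tm_threshold = 40) {
  list(na_molar = na_molar, strand_conc_molar = strand_conc_molar,
       tm_target = tm_target, window_length = as.integer(window_length),
       step = as.integer(step), k_rep = as.integer(k_rep),
       run_max = as.integer(run_max), seed_length = as.integer(seed_length),
       dg_threshold = dg_threshold, tm_threshold = tm_threshold)
}

## Raw dH (kcal/mol) and dS (cal/mol/K) of a perfect duplex at 1 M Na+,
## including initiation terms.
nnSums <- function(seq) {
  n <- nchar(seq)
  steps <- substring(seq, 1:(n - 1), 2:n)
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[[substr(seq, 1, 1)]] +
    NN_INIT_DH[[substr(seq, n, n)]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[[substr(seq, 1, 1)]] +
    NN_INIT_DS[[substr(seq, n, n)]]
  c(dh = dh, ds = ds)
}

checkCanonical <- function(seq, min_len, what = "sequence") {
  if (nchar(seq) < min_len)
    pa_contract_error("%s must be at least %d nt (got %d)", what, min_len,
                      nchar(seq))
  if (grepl("[^ACGT]", seq))
    pa_contract_error("%s contains non-canonical base(s)", what)
}

#' Nearest-neighbor melting temperature
#'
#' Two-state melting temperature of a probe-target duplex under the unified
#' nearest-neighbor table with entropic salt correction.
#'
#' @param seq probe sequence (canonical bases, length >= 8).
#' @param na_molar monovalent cation concentration, mol/L.
#' @param strand_conc_molar total strand concentration, mol/L.
#' @return melting temperature in degrees C.
#' @export
meltingTemperature <- function(seq, na_molar = 0.05,
                               strand_conc_molar = 0.25e-6) {
  checkCanonical(seq, 8L)
  s <- nnSums(seq)
  ds_salt <- s[["ds"]] + 0.368 * (nchar(seq) - 1) * log(na_molar)
  1000 * s[["dh"]] / (ds_salt + GAS_CONSTANT * log(strand_conc_molar / 4)) -
    273.15
}

#' Nearest-neighbor free energy at 37 degrees C
#'
#' @inheritParams meltingTemperature
#' @return dG37 in kcal/mol (salt-corrected entropy).
#' @export
duplexDeltaG37 <- function(seq, na_molar = 0.05) {
  checkCanonical(seq, 2L)
  s <- nnSums(seq)
  ds_salt <- s[["ds"]] + 0.368 * (nchar(seq) - 1) * log(na_molar)
  s[["dh"]] - 310.15 * ds_salt / 1000
}

## Vectorized Tm for all prefix (anchor = "start") or suffix (anchor =
## "end") substrings of `region` with lengths in [lo, hi].  One cumulative
## pass over the nearest-neighbor steps serves all candidate lengths.
tmByLength <- function(region, lo, hi, anchor = c("start", "end"),
                       na_molar = 0.05, strand_conc_molar = 0.25e-6) {
  anchor <- match.arg(anchor)
  n <- nchar(region)
  hi <- min(hi, n)
  lens <- lo:hi
  steps <- substring(region, 1:(n - 1), 2:n)
  bases <- substring(region, 1:n, 1:n)
  if (anchor == "start") {
    cum_dh <- cumsum(NN_DH[steps]); cum_ds <- cumsum(NN_DS[steps])
    dh <- cum_dh[lens - 1] + NN_INIT_DH[bases[1]] + NN_INIT_DH[bases[lens]]
    ds <- cum_ds[lens - 1] + NN_INIT_DS[bases[1]] + NN_INIT_DS[bases[lens]]
  } else {
    cum_dh <- rev(cumsum(rev(NN_DH[steps])))
    cum_ds <- rev(cumsum(rev(NN_DS[steps])))
    dh <- cum_dh[n - lens + 1] + NN_INIT_DH[bases[n]] +
      NN_INIT_DH[bases[n - lens + 1]]
    ds <- cum_ds[n - lens + 1] + NN_INIT_DS[bases[n]] +
      NN_INIT_DS[bases[n - lens + 1]]
  }
  ds_salt <- ds + 0.368 * (lens - 1) * log(na_molar)
  tm <- 1000 * dh / (ds_salt + GAS_CONSTANT * log(strand_conc_molar / 4)) -
    273.15
  names(tm) <- lens
  tm
}

## ---------------------------------------------------------------------------
## Probe-probe interaction (panel QC primitive)
## ---------------------------------------------------------------------------

## Longest perfectly complementary stretch between probes a and b over all
## hybridization registers.  Complementarity between a and b is equivalent
## to a shared identical substring between a and reverseComplement(b); the
## scan below slides revcomp(b) along a and takes the longest match run of
## the best register.
longestComplementaryStretch <- function(a, b) {
  rb <- reverseComplement_chr(b)
  na <- nchar(a); nb <- nchar(rb)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(rb, "")[[1]]
  best_len <- 0L; best_sub <- ""
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, off + 1L); ib <- max(1L, 1L - off)
    len <- min(na - ia, nb - ib) + 1L
    if (len < 1L) next
    m <- av[ia:(ia + len - 1L)] == bv[ib:(ib + len - 1L)]
    r <- rle(m)
    runs <- which(r$values & r$lengths > best_len)
    if (length(runs)) {
      k <- runs[which.max(r$lengths[runs])]
      start_in_overlap <- if (k == 1) 0L else sum(r$lengths[1:(k - 1)])
      best_len <- r$lengths[k]
      s0 <- ia + start_in_overlap
      best_sub <- substr(a, s0, s0 + best_len - 1L)
    }
  }
  list(length = best_len, sequence = best_sub)
}

#' Duplex interaction between two probes
#'
#' Finds the best complementary register between two probe sequences by
#' exhaustive offset scan and scores the longest perfectly complementary
#' stretch with the nearest-neighbor model.  Stretches shorter than 8 nt do
#' not form a scoreable duplex (dG sentinel 0, Tm sentinel -Inf).
#'
#' @param a,b probe sequences (canonical bases, length >= 8).
#' @param config configuration from [probeDesignConfig()].
#' @return list with duplex_tm, delta_g, stretch (nt), sequence and the
#'   conflict flag (delta_g <= dg_threshold or duplex_tm >= tm_threshold).
#' @export
pairwiseInteraction <- function(a, b, config = probeDesignConfig()) {
  checkCanonical(a, 8L, "probe a")
  checkCanonical(b, 8L, "probe b")
  hit <- longestComplementaryStretch(a, b)
  if (hit$length < 8L) {
    return(list(duplex_tm = -Inf, delta_g = 0, stretch = hit$length,
                sequence = hit$sequence, conflict = FALSE))
  }
  tm <- meltingTemperature(hit$sequence, config$na_molar,
                           config$strand_conc_molar)
  dg <- duplexDeltaG37(hit$sequence, config$na_molar)
  list(duplex_tm = tm, delta_g = dg, stretch = hit$length,
       sequence = hit$sequence,
       conflict = dg <= config$dg_threshold || tm >= config$tm_threshold)
}
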