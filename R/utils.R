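## Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats cor cor.test median p.adjust prcomp pt rnorm rnbinom runif sd var setNames
#' @importFrom utils read.delim write.table head tail
NULL

## Typed conditions.  Every user-facing failure is signalled with a condition
## class so callers (and the CLI) can map it to an exit status without
## parsing messages.
pa_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "panelign_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

pa_format_error       <- function(msg, ...) pa_stop("panelign_format_error", msg, ...)
pa_validation_error   <- function(msg, ...) pa_stop("panelign_validation_error", msg, ...)
pa_contract_error     <- function(msg, ...) pa_stop("panelign_contract_error", msg, ...)
pa_data_error         <- function(msg, ...) pa_stop("panelign_data_error", msg, ...)
pa_insufficient_data  <- function(msg, ...) pa_stop("panelign_insufficient_data_error", msg, ...)
pa_degenerate_input   <- function(msg, ...) pa_stop("panelign_degenerate_input_error", msg, ...)
pa_no_candidate       <- function(msg, ...) pa_stop("panelign_no_candidate_error", msg, ...)
pa_unresolvable       <- function(msg, ...) pa_stop("panelign_unresolvable_error", msg, ...)
pa_nonconvergence     <- function(msg, ...) pa_stop("panelign_nonconvergence_error", msg, ...)
pa_usage_error        <- function(msg, ...) pa_stop("panelign_usage_error", msg, ...)

## Geometric mean of strictly positive values.
geometricMean <- function(x) exp(mean(log(x)))

## Deterministic string -> small integer hash (stage-local seed derivation).
## Polynomial rolling hash mod a prime below 2^31.
stableHash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

## Derive a stage-local seed from a global seed and a stage name.
deriveSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435761 + stableHash(stage)) %% 2147483629)
}

## Reverse complement for plain character DNA (canonical bases + N).
reverseComplement_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## All k-mers of a string as a character vector (1-based starts).
kmers_chr <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
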