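## Housekeeping geometric-mean normalization, log transform, and gene-wise
## differential expression with empirical-Bayes variance moderation.

#' Differential-expression configuration
#'
#' @param pseudocount added before the log2 transform.
#' @param shrinkage moderate gene-wise variances toward a scaled
#'   inverse-chi-square prior fitted by method of moments.
#' @param alpha significance level.
#' @export
deConfig <- function(pseudocount = 1, shrinkage = TRUE, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    pa_contract_error("alpha must lie in (0,1)")
  if (pseudocount < 0)
    pa_contract_error("pseudocount must be nonnegative")
  list(pseudocount = pseudocount, shrinkage = shrinkage, alpha = alpha)
}

#' Normalize counts by per-lane housekeeping geometric means
#'
#' Divides every value in a lane (sample) by the geometric mean of the
#' housekeeping genes' counts in that same lane; housekeeping rows are
#' retained.  After normalization each lane's housekeeping geometric mean
#' equals 1 by construction.
#'
#' @param counts [ExpressionMatrix] with unit raw_count.
#' @param housekeeping character vector of housekeeping genes; all must be
#'   present with strictly positive counts in every lane.
#' @return [ExpressionMatrix] with unit normalized.
#' @export
housekeepingNormalize <- function(counts, housekeeping) {
  if (exprUnit(counts) != "raw_count")
    pa_contract_error("normalization expects raw counts, got unit '%s'",
                      exprUnit(counts))
  v <- exprValues(counts)
  absent <- setdiff(housekeeping, rownames(v))
  if (length(absent))
    pa_contract_error("housekeeping gene absent from matrix: %s", absent[1])
  hk <- v[housekeeping, , drop = FALSE]
  bad <- which(hk <= 0, arr.ind = TRUE)
  if (nrow(bad))
    pa_data_error("nonpositive housekeeping count for gene %s in lane %s",
                  housekeeping[bad[1, 1]], colnames(v)[bad[1, 2]])
  gm <- apply(hk, 2, geometricMean)
  ExpressionMatrix(sweep(v, 2, gm, "/"), sampleAnnotations(counts),
                   unit = "normalized")
}

#' Log2 transform of normalized values
#'
#' @param m [ExpressionMatrix] with unit normalized.
#' @param pseudocount added before the log (default 1); a zero pseudocount
#'   with zero values is rejected rather than producing -Inf.
#' @return [ExpressionMatrix] with unit log_normalized.
#' @export
logTransform <- function(m, pseudocount = 1) {
  if (exprUnit(m) != "normalized")
    pa_contract_error("log transform expects normalized values, got unit '%s'",
                      exprUnit(m))
  v <- exprValues(m)
  if (pseudocount == 0 && any(v == 0))
    pa_contract_error("zero value with zero pseudocount would produce -Inf")
  ExpressionMatrix(log2(v + pseudocount), sampleAnnotations(m),
                   unit = "log_normalized")
}

## Method-of-moments fit of a scaled inverse-chi-square prior to gene-wise
## variances s2 observed with d residual df each.  Under the prior,
## s2 / s0^2 ~ F(d, d0); matching the first two moments of s2 gives d0 and
## s0^2.  When the observed dispersion of s2 does not exceed pure
## chi-square sampling noise, d0 = Inf (complete shrinkage to the mean).
fitVariancePrior <- function(s2, d) {
  m <- mean(s2)
  if (m == 0) return(list(d0 = Inf, s02 = 0))
  c_rel <- var(s2) / m^2
  if (!is.finite(c_rel) || c_rel * d <= 2)
    return(list(d0 = Inf, s02 = m))
  d0 <- (4 * c_rel * d + 2 * d - 4) / (c_rel * d - 2)
  if (d0 <= 4) d0 <- 4 + 1e-6  # moment solution boundary
  list(d0 = d0, s02 = m * (d0 - 2) / d0)
}

#' Gene-wise differential expression with moderated t-statistics
#'
#' For two explicit sample groups on log2-normalized values: per-gene log
#' fold change is mean(group_a) - mean(group_b); the pooled gene variance is
#' shrunk toward a scaled inverse-chi-square prior fitted across all genes
#' by method of moments, the moderated t uses d + d0 degrees of freedom, and
#' p-values are Benjamini-Hochberg adjusted across genes.  Genes with zero
#' pooled variance receive the prior variance.
#'
#' @param m [ExpressionMatrix] with unit log_normalized.
#' @param group_a,group_b disjoint sample id sets, each of size >= 2.
#' @param config from [deConfig()].
#' @param contrast contrast label for the result.
#' @return a [LogFCTable].
#' @export
differentialExpression <- function(m, group_a, group_b,
                                   config = deConfig(),
                                   contrast = "group_a_vs_group_b") {
  if (exprUnit(m) != "log_normalized")
    pa_contract_error("differential expression expects log-normalized values, got unit '%s'",
                      exprUnit(m))
  if (length(intersect(group_a, group_b)))
    pa_contract_error("groups overlap: %s",
                      paste(intersect(group_a, group_b), collapse = ", "))
  v <- exprValues(m)
  missing <- setdiff(c(group_a, group_b), colnames(v))
  if (length(missing))
    pa_contract_error("unknown sample id(s): %s", paste(missing, collapse = ", "))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    pa_insufficient_data("each group needs >= 2 samples (got %d and %d)", na, nb)
  A <- v[, group_a, drop = FALSE]; B <- v[, group_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  d <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / d
  logfc <- ma - mb
  if (config$shrinkage) {
    prior <- fitVariancePrior(s2, d)
    if (is.finite(prior$d0)) {
      post <- (d * s2 + prior$d0 * prior$s02) / (d + prior$d0)
      df <- d + prior$d0
    } else {
      post <- rep(prior$s02, length(s2))
      df <- 1e6  # effectively normal
    }
    post[s2 == 0] <- prior$s02
  } else {
    post <- s2
    df <- d
  }
  se2 <- post * (1 / na + 1 / nb)
  t <- ifelse(se2 > 0, logfc / sqrt(se2), ifelse(logfc == 0, 0, Inf))
  p <- 2 * pt(-abs(t), df = df)
  p[se2 == 0 & logfc == 0] <- 1
  p[se2 == 0 & logfc != 0] <- 0
  tb <- data.frame(gene = rownames(v), logfc = unname(logfc), p = unname(p),
                   adj_p = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  LogFCTable(contrast, tb)
}
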