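#' Fisher's log-series alpha diversity
#'
#' Solves the log-series defining equation `S = alpha * ln(1 + N/alpha)`
#' for alpha by bracketed root finding; the left-hand side is strictly
#' increasing in alpha, so the positive root is unique whenever
#' `0 < S < N`. Alpha is relatively insensitive to sample size, which is
#' why it is used to compare local communities with very different read
#' depths without rarefaction.
#'
#' @param S observed taxon richness (>= 1)
#' @param N total read count (> S)
#' @param tol residual tolerance on the defining equation (default 1e-10)
#' @return Fisher's alpha (vectorised over `S`, `N`); `NA` where
#'   undefined (S = 0 or N <= S)
#' @export
fisherAlpha <- function(S, N, tol = 1e-10) {
  n <- max(length(S), length(N))
  S <- rep_len(as.numeric(S), n); N <- rep_len(as.numeric(N), n)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(S[i]) || is.na(N[i]) || S[i] < 1 || N[i] <= S[i]) next
    f <- function(a) a * log1p(N[i] / a) - S[i]
    lo <- 1e-12
    hi <- max(S[i], 1)
    while (f(hi) < 0) hi <- hi * 2
    out[i] <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  }
  out
}

#' Per-sample diversity of whole, core and satellite fractions
#'
#' Computes Fisher's alpha for every local community (sample) of a
#' metacommunity, for the whole community and, when a partition is
#' supplied, separately for its core and satellite fractions.
#'
#' @param counts taxa-by-sample count matrix
#' @param partition optional [PartitionResult-class] for the same
#'   metacommunity
#' @return data.frame with `sample_id`, `fraction`, `S` (richness),
#'   `N` (reads), `alpha` (NA where undefined)
#' @export
diversityTable <- function(counts, partition = NULL) {
  counts <- as.matrix(counts)
  fr <- list(whole = rownames(counts))
  if (!is.null(partition)) {
    fr$core <- coreTaxa(partition)
    fr$satellite <- satelliteTaxa(partition)
  }
  out <- lapply(names(fr), function(f) {
    sub <- counts[rownames(counts) %in% fr[[f]], , drop = FALSE]
    S <- colSums(sub > 0)
    N <- colSums(sub)
    data.frame(sample_id = colnames(counts), fraction = f,
               S = as.integer(S), N = as.numeric(N),
               alpha = fisherAlpha(S, N), stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Two-sample t comparison of diversity between groups
#'
#' Classic two-sample t-tests of Fisher's alpha between the levels of a
#' grouping (site pairs, or sex within a site), per fraction. Pooled
#' (equal-variance) two-sided tests by default; Welch and one-sided
#' variants are available since published reports do not always state
#' which was used.
#'
#' @param records diversity table from [diversityTable()] with an added
#'   grouping column
#' @param groupCol name of the grouping column (two or more levels;
#'   all pairs are compared)
#' @param pooled use the pooled-variance statistic (default TRUE)
#' @param alternative passed to [stats::t.test()] (default "two.sided")
#' @return data.frame with one row per fraction and group pair:
#'   `fraction`, `group1`, `group2`, `n1`, `n2`, `t`, `df`, `P`,
#'   `P_one_sided`
#' @export
compareDiversity <- function(records, groupCol, pooled = TRUE,
                             alternative = "two.sided") {
  stopifnot(groupCol %in% names(records), "alpha" %in% names(records))
  records <- records[!is.na(records$alpha), , drop = FALSE]
  out <- NULL
  for (f in unique(records$fraction)) {
    rf <- records[records$fraction == f, , drop = FALSE]
    lev <- unique(as.character(rf[[groupCol]]))
    if (length(lev) < 2) next
    for (pair in utils::combn(lev, 2, simplify = FALSE)) {
      a <- rf$alpha[rf[[groupCol]] == pair[1]]
      b <- rf$alpha[rf[[groupCol]] == pair[2]]
      if (length(a) < 2 || length(b) < 2) next
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                   p.value = 1)
        if (!all(a[1] == b)) tt$p.value <- NA_real_  # degenerate, flagged
      } else {
        tt <- stats::t.test(a, b, var.equal = pooled,
                            alternative = alternative)
      }
      tval <- unname(tt$statistic)
      dfv <- unname(tt$parameter)
      out <- rbind(out, data.frame(
        fraction = f, group1 = pair[1], group2 = pair[2],
        n1 = length(a), n2 = length(b), t = tval, df = dfv,
        P = unname(tt$p.value),
        P_one_sided = stats::pt(abs(tval), dfv, lower.tail = FALSE),
        stringsAsFactors = FALSE, row.names = NULL))
    }
  }
  out
}
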