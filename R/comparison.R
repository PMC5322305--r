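#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)` for two non-negative abundance vectors;
#' 0 for identical communities, 1 for disjoint ones.
#'
#' @param x,y equal-length non-negative abundance vectors
#' @return dissimilarity in `[0,1]`
#' @export
brayCurtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param counts taxa-by-sample abundance matrix (samples compared
#'   column-wise)
#' @return symmetric dissimilarity matrix with zero diagonal
#' @export
brayCurtisMatrix <- function(counts) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- brayCurtis(counts[, i], counts[, j])
  d
}

# all distinct relabellings of a group vector (multiset permutations of
# which positions receive which label), as a list of index permutations
.labelPermutations <- function(groups, cap = 2e5) {
  groups <- as.character(groups)
  lev <- unique(groups)
  sizes <- as.integer(table(factor(groups, levels = lev)))
  nTotal <- length(groups)
  count <- exp(lgamma(nTotal + 1) - sum(lgamma(sizes + 1)))
  if (count > cap) return(NULL)
  assign <- function(free, remaining) {
    if (length(remaining) == 1)
      return(list(setNames(list(free), remaining)))
    out <- list()
    k <- sizes[match(remaining[1], lev)]
    for (pick in utils::combn(seq_along(free), k, simplify = FALSE)) {
      rest <- assign(free[-pick], remaining[-1])
      for (r in rest)
        out[[length(out) + 1]] <- c(setNames(list(free[pick]), remaining[1]), r)
    }
    out
  }
  assignments <- assign(seq_len(nTotal), lev)
  lapply(assignments, function(a) {
    g <- character(nTotal)
    for (l in names(a)) g[a[[l]]] <- l
    g
  })
}

.anosimR <- function(rankD, sameGroup, denom) {
  (mean(rankD[!sameGroup]) - mean(rankD[sameGroup])) / denom
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`
#' over the tied-midranked pairwise dissimilarities. `R = 1` when all
#' most-similar samples are within groups, 0 when grouping is
#' uninformative. P is obtained by random relabelling with the add-one
#' rule (ties counted as extreme), or by exhaustive enumeration of all
#' distinct relabellings when `exact = TRUE` and feasible.
#'
#' @param d dissimilarity matrix (square) or `dist`
#' @param groups group label per sample (>= 2 groups, each of size >= 2)
#' @param nPerm random permutations (default 9999)
#' @param seed integer seed
#' @param exact enumerate all distinct relabellings instead of sampling
#' @return an [AnosimResult-class]
#' @export
anosim <- function(d, groups, nPerm = 9999, seed = 1L, exact = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")

  lower <- which(lower.tri(d))
  rankD <- rank(d[lower])
  pairIdx <- which(lower.tri(d), arr.ind = TRUE)
  denom <- n * (n - 1) / 4
  same <- function(g) g[pairIdx[, 1]] == g[pairIdx[, 2]]
  obs <- .anosimR(rankD, same(groups), denom)

  between <- d[lower][!same(groups)]
  if (exact) {
    perms <- .labelPermutations(groups)
    if (is.null(perms)) stop("too many relabellings for exact enumeration")
    stat <- vapply(perms, function(g) .anosimR(rankD, same(g), denom),
                   numeric(1))
    p <- mean(stat >= obs - 1e-12)  # observed labelling is one of the perms
    nPerm <- length(perms)
  } else {
    set.seed(seed)
    stat <- replicate(nPerm, .anosimR(rankD, same(sample(groups)), denom))
    p <- (1 + sum(stat >= obs - 1e-12)) / (1 + nPerm)
  }
  methods::new("AnosimResult", statistic = obs, pValue = p,
               nPerm = as.integer(nPerm), exact = exact,
               groupSizes = as.integer(sizes),
               betweenMean = mean(between), betweenSd = stats::sd(between),
               seed = as.integer(seed))
}

#' @export
setMethod("show", "AnosimResult", function(object) {
  cat(sprintf("ANOSIM: R = %.3f, P = %.4g (%s%d permutations)\n",
              object@statistic, object@pValue,
              if (object@exact) "exact, " else "", object@nPerm))
  cat(sprintf("  group sizes: %s; between-group Bray-Curtis %.3f +/- %.3f\n",
              paste(object@groupSizes, collapse = "/"),
              object@betweenMean, object@betweenSd))
  invisible(NULL)
})

#' Similarity percentages (SIMPER)
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity into
#' per-taxon contributions: for every between-group sample pair the
#' taxon term is `|x_i - x_j| / sum_l(x_il + x_jl)`; a taxon's
#' contribution is the mean of its term over all pairs, and the
#' contributions sum exactly to the overall mean dissimilarity.
#' Operates on per-sample relative abundances by default, matching the
#' convention of reporting mean % abundances per group.
#'
#' @param counts taxa-by-sample abundance matrix
#' @param groups two-level group label per sample
#' @param relative convert each sample to relative abundances first
#'   (default TRUE)
#' @return a [SimperResult-class]; the table is sorted by decreasing
#'   contribution with contribution %, cumulative % and mean %
#'   abundance per group
#' @export
simper <- function(counts, groups, relative = TRUE) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("SIMPER compares exactly two groups")
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  if (length(i1) == 0 || length(i2) == 0) stop("a group has no samples")
  if (relative) counts <- sweep(counts, 2, colSums(counts), "/")

  contrib <- numeric(nrow(counts))
  nPairs <- 0
  for (i in i1) for (j in i2) {
    denom <- sum(counts[, i] + counts[, j])
    contrib <- contrib + abs(counts[, i] - counts[, j]) / denom
    nPairs <- nPairs + 1
  }
  contrib <- contrib / nPairs
  overall <- sum(contrib)
  ord <- order(contrib, decreasing = TRUE)
  tab <- data.frame(
    taxon = rownames(counts)[ord],
    contribution = contrib[ord],
    contribution_pct = 100 * contrib[ord] / overall,
    cumulative_pct = cumsum(100 * contrib[ord] / overall),
    mean_abundance_1 = 100 * rowMeans(counts[, i1, drop = FALSE])[ord],
    mean_abundance_2 = 100 * rowMeans(counts[, i2, drop = FALSE])[ord],
    stringsAsFactors = FALSE, row.names = NULL)
  names(tab)[5:6] <- paste0("mean_pct_", lev)
  methods::new("SimperResult", table = tab, overall = overall, groups = lev)
}

#' @export
setMethod("show", "SimperResult", function(object) {
  cat(sprintf("SIMPER %s vs %s: overall mean dissimilarity %.3f\n",
              object@groups[1], object@groups[2], object@overall))
  print(utils::head(object@table, 5), digits = 3)
  invisible(NULL)
})
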