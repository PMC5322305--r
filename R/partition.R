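#' Index of dispersion (variance-to-mean ratio)
#'
#' Computed over all samples of a metacommunity, zeros included, with the
#' unbiased (n-1) variance. Values near 1 are consistent with Poisson
#' (random) placement across local communities; values well above 1
#' indicate aggregated, non-random distributions.
#'
#' @param x numeric count vector for one taxon over all samples
#' @return variance/mean; `NA` (undefined) when the mean is zero
#' @examples
#' dispersionIndex(c(0, 0, 0, 8))  # mean 2, var 16 -> 8
#' @export
dispersionIndex <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::var(x) / m
}

#' Chi-squared confidence limit for the index of dispersion
#'
#' Under Poisson placement, `(n-1) * I` follows a chi-squared
#' distribution with `n-1` degrees of freedom. The returned limit is
#' that distribution's `1-tail` quantile divided by `n-1`, i.e. the
#' threshold on the `I` scale above which a taxon's dispersion is
#' declared non-random at the chosen tail probability.
#'
#' @param nSamples number of local communities (>= 2)
#' @param tail upper tail probability (default 0.025, the upper bound of
#'   the central 95% interval)
#' @return confidence limit on the variance/mean scale
#' @export
chi2ConfidenceLimit <- function(nSamples, tail = 0.025) {
  if (nSamples < 2) stop("nSamples must be at least 2")
  if (tail <= 0 || tail >= 0.5) stop("tail must lie in (0, 0.5)")
  stats::qchisq(1 - tail, df = nSamples - 1) / (nSamples - 1)
}

#' Occupancy vs log10 mean-abundance regression
#'
#' Ordinary least-squares fit of local-community occupancy on the log10
#' mean read abundance over all samples (zeros included). A significant
#' positive slope is the distribution-abundance relationship expected of
#' a coherent metacommunity.
#'
#' @param counts taxa-by-sample count matrix of one metacommunity
#' @return list with `slope`, `intercept`, `r2`, `F`, `df`, `P`
#' @export
occupancyAbundanceRegression <- function(counts) {
  counts <- as.matrix(counts)
  mean_ab <- rowMeans(counts)
  keep <- mean_ab > 0
  if (sum(keep) < 3) stop("need at least 3 taxa with nonzero mean")
  occ <- rowSums(counts[keep, , drop = FALSE] > 0)
  fit <- stats::lm(occ ~ log10(mean_ab[keep]))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       F = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[2:3]),
       P = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
}

.partitionMatrix <- function(counts, tail = 0.025) {
  counts <- as.matrix(counts)
  if (length(counts) == 0 || nrow(counts) == 0) stop("empty count table")
  n <- ncol(counts)
  if (n < 2) stop("need at least 2 samples")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("taxon_%d", seq_len(nrow(counts)))

  zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[zero]
  if (any(zero)) counts <- counts[!zero, , drop = FALSE]
  if (nrow(counts) == 0) stop("all taxa have zero counts")

  occ <- rowSums(counts > 0)
  mu <- rowMeans(counts)
  v <- apply(counts, 1, stats::var)
  disp <- v / mu
  limit <- chi2ConfidenceLimit(n, tail)
  crit <- stats::qchisq(1 - tail, df = n - 1)

  label <- rep("core", nrow(counts))
  reason <- rep(NA_character_, nrow(counts))
  single <- occ == 1
  random <- !single & (n - 1) * disp <= crit
  label[single] <- "satellite"; reason[single] <- "single_sample"
  label[random] <- "satellite"; reason[random] <- "random_dispersion"

  stats <- data.frame(taxon = rownames(counts), occupancy = as.integer(occ),
                      mean_abundance = mu, variance = v, dispersion = disp,
                      label = label, reason = reason,
                      stringsAsFactors = FALSE, row.names = NULL)
  coreShare <- sum(counts[label == "core", , drop = FALSE]) / sum(counts)
  reg <- if (sum(mu > 0) >= 3) occupancyAbundanceRegression(counts) else NULL
  methods::new("PartitionResult", stats = stats, chi2Limit = limit,
               tail = tail, nSamples = as.integer(n),
               regression = if (is.null(reg)) list() else reg,
               coreShare = coreShare, dropped = dropped)
}

#' Partition a metacommunity into core and satellite taxa
#'
#' Taxa occurring in a single sample are classed satellite outright
#' (their dispersion in space has no variance); remaining taxa are
#' satellite when their index of dispersion falls at or below the
#' chi-squared confidence limit (random placement) and core when it
#' exceeds it (non-random, aggregated). Taxa with zero reads everywhere
#' are dropped (recorded in `dropped`): they are not part of the
#' metacommunity.
#'
#' @param x taxa-by-sample count matrix, or a [MetacomExperiment-class]
#'   (optionally restricted with `site =`)
#' @param tail upper tail probability of the chi-squared limit
#'   (default 0.025)
#' @param site for a MetacomExperiment, analyse only this site
#' @param ... unused
#' @return a [PartitionResult-class]
#' @export
#' @rdname partitionCoreSatellite
setMethod("partitionCoreSatellite", "matrix",
          function(x, tail = 0.025, ...) .partitionMatrix(x, tail))

#' @rdname partitionCoreSatellite
#' @export
setMethod("partitionCoreSatellite", "MetacomExperiment",
          function(x, tail = 0.025, site = NULL, ...) {
            if (!is.null(site)) x <- siteExperiment(x, site)
            .partitionMatrix(counts(x), tail)
          })

#' Core/satellite bookkeeping from published metacommunity totals
#'
#' Applies the partition's accounting identity to printed summary
#' counts: of `nTaxa` metacommunity members, `nRandom` randomly
#' dispersed taxa plus `nSingle` single-sample taxa form the satellite
#' group and the remainder is core.
#'
#' @param nTaxa total taxa in the metacommunity
#' @param nRandom taxa with random (Poisson-consistent) dispersion
#' @param nSingle taxa found in a single sample only
#' @return list with `core`, `satellite`, `nTaxa`
#' @examples
#' partitionBookkeeping(291, 126, 69)  # core 96, satellite 195
#' @export
partitionBookkeeping <- function(nTaxa, nRandom, nSingle) {
  if (nRandom + nSingle > nTaxa) stop("satellite counts exceed total taxa")
  list(core = nTaxa - nRandom - nSingle, satellite = nRandom + nSingle,
       nTaxa = nTaxa)
}

#' @export
setMethod("show", "PartitionResult", function(object) {
  tb <- table(object@stats$label)
  cat("PartitionResult:", nrow(object@stats), "taxa over",
      object@nSamples, "samples\n")
  cat(sprintf("  core %d, satellite %d (single-sample %d); chi2 limit %.3f (tail %.3g)\n",
              sum(object@stats$label == "core"),
              sum(object@stats$label == "satellite"),
              sum(object@stats$reason %in% "single_sample"),
              object@chi2Limit, object@tail))
  cat(sprintf("  core relative-abundance share: %.1f%%\n", 100 * object@coreShare))
  if (length(object@regression))
    cat(sprintf("  occupancy ~ log10(abundance): slope %.2f, r2 %.2f, P %.3g\n",
                object@regression$slope, object@regression$r2,
                object@regression$P))
  invisible(NULL)
})
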