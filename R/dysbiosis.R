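#' Median split of hosts by helminth burden
#'
#' Hosts with burden strictly greater than the median form the
#' high-burden group; hosts at or below it the low-burden group.
#'
#' @param burden named numeric vector of helminth counts (names are host
#'   or sample identifiers)
#' @return a [BurdenSplit-class]
#' @examples
#' splitByMedian(c(a = 1, b = 2, c = 3, d = 4))  # median 2.5, high c,d
#' @export
splitByMedian <- function(burden) {
  burden <- burden[!is.na(burden)]
  if (length(unique(burden)) < 2)
    stop("need at least 2 distinct burden values (high group would be empty)")
  med <- stats::median(burden)
  methods::new("BurdenSplit", median = med,
               high = names(burden)[burden > med],
               low = names(burden)[burden <= med])
}

#' @export
setMethod("show", "BurdenSplit", function(object) {
  cat(sprintf("BurdenSplit: median %.1f; high n=%d, low n=%d\n",
              object@median, length(object@high), length(object@low)))
  invisible(NULL)
})

#' Burden dysbiosis: volcano fold changes and gained/lost taxa
#'
#' Splits the metacommunity's samples into high- and low-burden groups
#' and, for every taxon detected in both, computes the log2 fold change
#' of mean relative abundance (high vs low; positive = higher under high
#' burden) with a two-sample t-test on per-sample relative abundances.
#' No multiplicity correction is applied to the headline significance
#' flag (the volcano convention); Benjamini-Hochberg adjusted values are
#' emitted alongside. Taxa detected in exactly one group have infinite
#' fold change and are routed to the gained/lost accounting instead,
#' tagged core/satellite when a partition is supplied and ranked by mean
#' relative abundance in the group where they occur.
#'
#' @param counts taxa-by-sample count matrix of one metacommunity
#' @param split a [BurdenSplit-class] whose high/low ids name columns of
#'   `counts`
#' @param partition optional [PartitionResult-class] for core/satellite
#'   tags
#' @param alpha significance line (default 0.05)
#' @param pooled pooled-variance t-test (default TRUE)
#' @return a [DysbiosisReport-class]
#' @export
burdenDysbiosis <- function(counts, split, partition = NULL, alpha = 0.05,
                            pooled = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(methods::is(split, "BurdenSplit"))
  hi <- intersect(split@high, colnames(counts))
  lo <- intersect(split@low, colnames(counts))
  if (length(hi) == 0 || length(lo) == 0) stop("a burden group is empty")
  rel <- sweep(counts, 2, colSums(counts), "/")

  labels <- rep(NA_character_, nrow(counts))
  names(labels) <- rownames(counts)
  if (!is.null(partition)) {
    labels[coreTaxa(partition)] <- "core"
    labels[satelliteTaxa(partition)] <- "satellite"
  }

  totHi <- rowSums(counts[, hi, drop = FALSE])
  totLo <- rowSums(counts[, lo, drop = FALSE])
  inBoth <- totHi > 0 & totLo > 0
  gainedIdx <- totHi > 0 & totLo == 0
  lostIdx <- totLo > 0 & totHi == 0

  volcano <- NULL
  for (i in which(inBoth)) {
    a <- rel[i, hi]; b <- rel[i, lo]
    mh <- mean(a); ml <- mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tval <- 0; pval <- 1
    } else {
      tt <- stats::t.test(a, b, var.equal = pooled)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    volcano <- rbind(volcano, data.frame(
      taxon = rownames(counts)[i], fraction = labels[i],
      mean_rel_high = mh, mean_rel_low = ml,
      fold_change = mh / ml, log2_fold_change = log2(mh / ml),
      t = tval, P = pval, stringsAsFactors = FALSE, row.names = NULL))
  }
  if (is.null(volcano))
    volcano <- data.frame(taxon = character(0), fraction = character(0),
                          mean_rel_high = numeric(0), mean_rel_low = numeric(0),
                          fold_change = numeric(0),
                          log2_fold_change = numeric(0), t = numeric(0),
                          P = numeric(0), stringsAsFactors = FALSE)
  volcano$P_adj <- stats::p.adjust(volcano$P, method = "BH")
  volcano$significant <- volcano$P < alpha

  rankTable <- function(idx, cols) {
    if (!any(idx)) return(data.frame(taxon = character(0),
                                     fraction = character(0),
                                     mean_rel_abundance = numeric(0),
                                     stringsAsFactors = FALSE))
    ab <- rowMeans(rel[idx, cols, drop = FALSE])
    ord <- order(ab, decreasing = TRUE)
    data.frame(taxon = rownames(counts)[idx][ord],
               fraction = labels[idx][ord],
               mean_rel_abundance = ab[ord],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  methods::new("DysbiosisReport", volcano = volcano,
               gained = rankTable(gainedIdx, hi),
               lost = rankTable(lostIdx, lo), split = split)
}

#' @export
setMethod("show", "DysbiosisReport", function(object) {
  v <- object@volcano
  cat(sprintf("DysbiosisReport: %d taxa in volcano (%d significant), %d gained, %d lost\n",
              nrow(v), sum(v$significant), nrow(object@gained),
              nrow(object@lost)))
  if (nrow(v)) {
    byFrac <- table(v$fraction[v$significant], useNA = "ifany")
    if (length(byFrac))
      cat("  significant by fraction:",
          paste(sprintf("%s %d", names(byFrac), as.integer(byFrac)),
                collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @describeIn burdenDysbiosis volcano table accessor
#' @param report a DysbiosisReport
#' @export
volcanoTable <- function(report) report@volcano

#' @describeIn burdenDysbiosis taxa detected only under high burden
#' @export
gainedTaxa <- function(report) report@gained

#' @describeIn burdenDysbiosis taxa no longer detected under high burden
#' @export
lostTaxa <- function(report) report@lost
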