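#' Raup-Crick similarity for one pair of communities
#'
#' Monte Carlo probability that two communities share fewer taxa than
#' expected by chance, with ties counted half. Null communities preserve
#' each observed richness and draw taxa without replacement from the
#' metacommunity pool, with selection probability proportional to pool
#' occupancy frequency (or uniform under `equal_weight`). `S_RC` near 1
#' means the pair is more similar than chance (deterministic assembly),
#' near 0 more dissimilar.
#'
#' @param a,b presence/absence (logical or 0/1) vectors over the pool
#' @param poolWeights per-taxon selection weights (e.g. occupancy
#'   frequencies); uniform when NULL
#' @param nRand number of randomisations (default 1000)
#' @param seed integer seed
#' @return S_RC in `[0,1]`
#' @export
srcPair <- function(a, b, poolWeights = NULL, nRand = 1000, seed = 1L) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  G <- length(a)
  ra <- sum(a); rb <- sum(b)
  if (ra < 1 || rb < 1) stop("each community must contain at least one taxon")
  if (is.null(poolWeights)) poolWeights <- rep(1, G)
  if (sum(poolWeights > 0) < max(ra, rb))
    stop("richness exceeds the number of drawable pool taxa")
  obs <- sum(a & b)
  set.seed(seed)
  less <- 0; equal <- 0
  for (r in seq_len(nRand)) {
    na <- sample.int(G, ra, prob = poolWeights)
    nb <- sample.int(G, rb, prob = poolWeights)
    sh <- length(intersect(na, nb))
    if (sh < obs) less <- less + 1 else if (sh == obs) equal <- equal + 1
  }
  (less + 0.5 * equal) / nRand
}

#' Pairwise Raup-Crick similarity matrix for a metacommunity
#'
#' All unordered sample pairs of one metacommunity, sharing one set of
#' null community draws per randomisation (each sample's null community
#' is simulated once per randomisation at its observed richness, and
#' every pair is scored against it), which leaves each pair's marginal
#' null distribution unchanged while making the computation linear in
#' the number of samples.
#'
#' @param x taxa-by-sample count (or presence) matrix, or a
#'   [MetacomExperiment-class]
#' @param nRand randomisations (default 1000)
#' @param nullModel `"occupancy_weighted"` (default; draws proportional
#'   to observed occupancy) or `"equal_weight"`
#' @param seed integer seed (recorded in the result)
#' @param site for a MetacomExperiment, restrict to this site
#' @param taxa optional subset of taxa (e.g. a core or satellite
#'   fraction); samples left empty by the subset are dropped
#' @param ... unused
#' @return a [RaupCrickResult-class]
#' @export
#' @rdname raupCrick
setMethod("raupCrick", "matrix", function(x, nRand = 1000,
                                          nullModel = c("occupancy_weighted", "equal_weight"),
                                          seed = 1L, taxa = NULL, ...) {
  nullModel <- match.arg(nullModel)
  pres <- x > 0
  if (!is.null(taxa)) pres <- pres[rownames(pres) %in% taxa, , drop = FALSE]
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  n <- ncol(pres)
  if (n < 2) stop("need at least 2 non-empty samples")
  G <- nrow(pres)
  rich <- colSums(pres)
  w <- if (nullModel == "occupancy_weighted") rowSums(pres) else rep(1, G)
  if (sum(w > 0) < max(rich)) stop("richness exceeds drawable pool size")

  obsShared <- crossprod(pres)
  set.seed(seed)
  less <- matrix(0, n, n); equal <- matrix(0, n, n)
  Z <- matrix(FALSE, G, n)
  for (r in seq_len(nRand)) {
    Z[] <- FALSE
    for (j in seq_len(n)) Z[sample.int(G, rich[j], prob = w), j] <- TRUE
    sh <- crossprod(Z)
    less <- less + (sh < obsShared)
    equal <- equal + (sh == obsShared)
  }
  v <- (less + 0.5 * equal) / nRand
  v <- (v + t(v)) / 2  # exact: both triangles accumulated identically
  diag(v) <- NA_real_
  dimnames(v) <- list(colnames(pres), colnames(pres))
  methods::new("RaupCrickResult", values = v, nRand = as.integer(nRand),
               nullModel = nullModel, seed = as.integer(seed))
})

#' @rdname raupCrick
#' @export
setMethod("raupCrick", "MetacomExperiment",
          function(x, nRand = 1000,
                   nullModel = c("occupancy_weighted", "equal_weight"),
                   seed = 1L, site = NULL, taxa = NULL, ...) {
            if (!is.null(site)) x <- siteExperiment(x, site)
            raupCrick(counts(x), nRand = nRand,
                      nullModel = match.arg(nullModel), seed = seed,
                      taxa = taxa)
          })

#' Classify community assembly from a Raup-Crick matrix
#'
#' Pairs with `S_RC > 0.95` are deterministically similar (assembly more
#' similar than chance), `S_RC < 0.05` deterministically dissimilar, and
#' the remainder stochastic (no more or less similar than chance).
#'
#' @param rc a [RaupCrickResult-class]
#' @param binWidth histogram bin width on the S_RC scale (default 0.05)
#' @return list with `percentages` (named: det_similar, stochastic,
#'   det_dissimilar, summing to 100), `classes` (per-pair data.frame)
#'   and `histogram` (bin, count)
#' @export
classifyAssembly <- function(rc, binWidth = 0.05) {
  stopifnot(methods::is(rc, "RaupCrickResult"))
  v <- rc@values
  idx <- which(upper.tri(v), arr.ind = TRUE)
  s <- v[upper.tri(v)]
  if (length(s) == 0) stop("empty Raup-Crick matrix")
  cls <- ifelse(s > 0.95, "det_similar",
                ifelse(s < 0.05, "det_dissimilar", "stochastic"))
  pct <- 100 * c(det_similar = mean(cls == "det_similar"),
                 stochastic = mean(cls == "stochastic"),
                 det_dissimilar = mean(cls == "det_dissimilar"))
  breaks <- seq(0, 1, by = binWidth)
  h <- hist(s, breaks = breaks, plot = FALSE, include.lowest = TRUE,
            right = TRUE)
  list(percentages = pct,
       classes = data.frame(sample1 = rownames(v)[idx[, 1]],
                            sample2 = colnames(v)[idx[, 2]],
                            S_RC = s, class = cls, stringsAsFactors = FALSE),
       histogram = data.frame(bin_upper = h$breaks[-1], count = h$counts))
}

#' @export
setMethod("show", "RaupCrickResult", function(object) {
  n <- ncol(object@values)
  s <- object@values[upper.tri(object@values)]
  cat(sprintf("RaupCrickResult: %d samples, %d pairs (%s null, %d randomisations, seed %d)\n",
              n, length(s), object@nullModel, object@nRand, object@seed))
  cat(sprintf("  S_RC > 0.95: %.1f%%; < 0.05: %.1f%%; stochastic: %.1f%%\n",
              100 * mean(s > 0.95), 100 * mean(s < 0.05),
              100 * mean(s >= 0.05 & s <= 0.95)))
  invisible(NULL)
})

#' @importFrom graphics hist
NULL
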