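#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats var median qchisq quantile rnorm rlnorm rpois rnbinom
#'   rbinom rgamma runif lm pt t.test setNames complete.cases uniroot sd
#'   as.dist
#' @importFrom utils head read.delim write.table combn
NULL

#' MetacomExperiment: a microbiota metacommunity container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `counts`
#' assay holding non-negative integer read counts (taxa as rows, local
#' community samples as columns) and per-sample host covariates in
#' `colData` (typically `site`, `host_id`, `sex`, `mass_g`, `age_years`,
#' `chicks_fledged`, `phenology`, `nematode_count`).
#'
#' @slot metadata inherited; generator provenance (seed, config) is stored
#'   under `metadata(x)$generator` when the object was simulated.
#' @export
setClass("MetacomExperiment", contains = "SummarizedExperiment")

setValidity("MetacomExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(m)) return("counts must not contain NA")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(m != floor(m))) return("counts must be integers")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxon (row) names must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    return("sample (column) names must be present and unique")
  TRUE
})

#' Ground truth of a simulated metacommunity
#'
#' Per-site taxon labels and effects used by parameter-recovery tests:
#' which taxa were generated as core (overdispersed, high occupancy),
#' which as satellite (Poisson or single-sample), which respond to
#' helminth burden, and the site determinism scalar.
#'
#' @export
setClass("MetacomTruth", representation(
  siteTaxa = "list",          # site -> character vector of taxon ids
  coreTaxa = "list",          # site -> character
  satelliteTaxa = "list",     # site -> character
  responderEffects = "list",  # site -> named numeric (signed log-fold per sd burden)
  siteDeterminism = "numeric" # named per-site scalar in [0,1]
))

setValidity("MetacomTruth", function(object) {
  for (s in names(object@siteTaxa)) {
    co <- object@coreTaxa[[s]]; sa <- object@satelliteTaxa[[s]]
    if (length(intersect(co, sa)) > 0)
      return(sprintf("site %s: core and satellite truth sets overlap", s))
    if (!setequal(union(co, sa), object@siteTaxa[[s]]))
      return(sprintf("site %s: core + satellite must cover all site taxa", s))
  }
  if (any(object@siteDeterminism < 0 | object@siteDeterminism > 1))
    return("determinism must lie in [0,1]")
  TRUE
})

#' Core/satellite partition of a metacommunity
#'
#' Result of [partitionCoreSatellite()]: per-taxon occupancy, mean
#' abundance, variance and index of dispersion, the core/satellite label
#' with the reason a taxon was called satellite, the chi-squared
#' confidence limit used, and the occupancy vs log10 mean-abundance
#' regression.
#'
#' @export
setClass("PartitionResult", representation(
  stats = "data.frame",
  chi2Limit = "numeric",
  tail = "numeric",
  nSamples = "integer",
  regression = "list",
  coreShare = "numeric",
  dropped = "character"
))

setValidity("PartitionResult", function(object) {
  need <- c("taxon", "occupancy", "mean_abundance", "variance",
            "dispersion", "label", "reason")
  if (!all(need %in% names(object@stats)))
    return("stats must have taxon/occupancy/mean_abundance/variance/dispersion/label/reason")
  if (!all(object@stats$label %in% c("core", "satellite")))
    return("labels must be 'core' or 'satellite'")
  if (any(object@stats$occupancy < 0 | object@stats$occupancy > object@nSamples))
    return("occupancy out of range")
  TRUE
})

#' Pairwise Raup-Crick similarity matrix
#'
#' Monte Carlo Raup-Crick probability-based similarities for all
#' unordered sample pairs of one metacommunity. Values near 1 indicate
#' pairs more similar than the randomisation null (deterministic
#' assembly), near 0 more dissimilar; the diagonal is undefined (NA).
#'
#' @export
setClass("RaupCrickResult", representation(
  values = "matrix",
  nRand = "integer",
  nullModel = "character",
  seed = "integer"
))

setValidity("RaupCrickResult", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  off <- v[upper.tri(v)]
  if (any(!is.na(off) & (off < 0 | off > 1))) return("S_RC must lie in [0,1]")
  if (!isTRUE(all.equal(v[upper.tri(v)], t(v)[upper.tri(v)])))
    return("values must be symmetric")
  if (!object@nullModel %in% c("occupancy_weighted", "equal_weight"))
    return("nullModel must be occupancy_weighted or equal_weight")
  TRUE
})

#' ANOSIM result
#' @export
setClass("AnosimResult", representation(
  statistic = "numeric",
  pValue = "numeric",
  nPerm = "integer",
  exact = "logical",
  groupSizes = "integer",
  betweenMean = "numeric",
  betweenSd = "numeric",
  seed = "integer"
))

setValidity("AnosimResult", function(object) {
  if (object@statistic < -1 - 1e-12 || object@statistic > 1 + 1e-12)
    return("R must lie in [-1, 1]")
  if (object@pValue <= 0 || object@pValue > 1) return("P must lie in (0,1]")
  TRUE
})

#' SIMPER decomposition table
#' @export
setClass("SimperResult", representation(
  table = "data.frame",
  overall = "numeric",
  groups = "character"
))

setValidity("SimperResult", function(object) {
  if (!isTRUE(all.equal(sum(object@table$contribution), object@overall,
                        tolerance = 1e-8)))
    return("per-taxon contributions must sum to the overall mean dissimilarity")
  if (is.unsorted(object@table$cumulative_pct)) return("cumulative % must be non-decreasing")
  TRUE
})

#' CCA result with optional forward selection
#' @export
setClass("CcaResult", representation(
  eig = "numeric",
  totalInertia = "numeric",
  constrainedInertia = "numeric",
  variables = "character",
  selection = "data.frame",
  undetermined = "numeric",
  mode = "character",
  nPerm = "integer",
  alpha = "numeric",
  seed = "integer"
))

setValidity("CcaResult", function(object) {
  if (any(object@eig < -1e-10)) return("eigenvalues must be non-negative")
  if (length(object@eig) > 1 && is.unsorted(rev(object@eig), strictly = FALSE))
    return("eigenvalues must be non-increasing")
  if (!is.na(object@constrainedInertia) &&
      object@constrainedInertia > object@totalInertia * (1 + 1e-8))
    return("constrained inertia cannot exceed total inertia")
  TRUE
})

#' Median split of hosts by helminth burden
#' @export
setClass("BurdenSplit", representation(
  median = "numeric",
  high = "character",
  low = "character"
))

setValidity("BurdenSplit", function(object) {
  if (length(intersect(object@high, object@low)) > 0)
    return("high and low groups must be disjoint")
  TRUE
})

#' Burden dysbiosis report
#'
#' Volcano fold-change/t-test table for taxa present in both burden
#' groups, plus gained/lost accounting (taxa detected in exactly one
#' group) tagged with core/satellite labels.
#'
#' @export
setClass("DysbiosisReport", representation(
  volcano = "data.frame",
  gained = "data.frame",
  lost = "data.frame",
  split = "BurdenSplit"
))

setValidity("DysbiosisReport", function(object) {
  v <- object@volcano$taxon
  gl <- c(object@gained$taxon, object@lost$taxon)
  if (length(intersect(v, gl)) > 0)
    return("volcano taxa and gained/lost taxa must be disjoint")
  if (anyDuplicated(c(v, gl))) return("each taxon may appear only once")
  TRUE
})
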