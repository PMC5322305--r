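#' Construct a MetacomExperiment
#'
#' Bundles a taxa-by-sample integer count matrix with per-sample host
#' covariates into a validated container used by all downstream analyses.
#'
#' @param counts integer matrix, taxa as rows and samples as columns,
#'   with unique row and column names.
#' @param sampleData data.frame (or DataFrame) of per-sample covariates,
#'   one row per column of `counts`, in the same order or with matching
#'   row names. A `site` column identifies the microbiome each local
#'   community belongs to.
#' @return a [MetacomExperiment-class] object
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
#' md <- data.frame(site = "gut", row.names = colnames(m))
#' MetacomExperiment(m, md)
#' @export
MetacomExperiment <- function(counts, sampleData) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.null(rownames(sampleData))) {
    if (!setequal(rownames(sampleData), colnames(counts)))
      stop("sampleData row names must match count column names")
    sampleData <- sampleData[colnames(counts), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sampleData)
  )
  methods::new("MetacomExperiment", se)
}

#' @describeIn MetacomExperiment read counts assay
#' @param object,x a MetacomExperiment
#' @export
setMethod("counts", "MetacomExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' Subset a metacommunity to one site, dropping undetected taxa
#'
#' Taxa with zero total reads across the retained samples are removed:
#' a taxon never observed in a metacommunity is not part of it.
#'
#' @param x a MetacomExperiment
#' @param site site label matched against `colData(x)$site`
#' @param dropEmpty drop all-zero taxon rows (default TRUE)
#' @return a MetacomExperiment restricted to that metacommunity
#' @export
siteExperiment <- function(x, site, dropEmpty = TRUE) {
  stopifnot(methods::is(x, "MetacomExperiment"))
  keep <- SummarizedExperiment::colData(x)$site == site
  if (!any(keep)) stop("unknown site: ", site)
  out <- x[, keep]
  if (dropEmpty) out <- out[rowSums(counts(out)) > 0, ]
  out
}

#' @export
setMethod("show", "MetacomExperiment", function(object) {
  cm <- counts(object)
  cat("MetacomExperiment:", nrow(cm), "taxa x", ncol(cm), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if ("site" %in% names(cd)) {
    tb <- table(cd$site)
    cat("  sites:", paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
                          collapse = ", "), "\n")
  }
  cat("  reads/sample: median", stats::median(colSums(cm)), "\n")
  invisible(NULL)
})

#' @describeIn coreTaxa taxa labelled core by the partition
#' @export
setMethod("coreTaxa", "PartitionResult", function(x)
  x@stats$taxon[x@stats$label == "core"])

#' @describeIn satelliteTaxa taxa labelled satellite by the partition
#' @export
setMethod("satelliteTaxa", "PartitionResult", function(x)
  x@stats$taxon[x@stats$label == "satellite"])

#' @describeIn coreTaxa generator truth core set for one site
#' @param site site name
#' @export
setMethod("coreTaxa", "MetacomTruth", function(x, site) x@coreTaxa[[site]])

#' @describeIn satelliteTaxa generator truth satellite set for one site
#' @export
setMethod("satelliteTaxa", "MetacomTruth", function(x, site)
  x@satelliteTaxa[[site]])
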