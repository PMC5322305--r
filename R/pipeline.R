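#' Run the full metacommunity analysis pipeline
#'
#' Orchestrates, for every site (microbiome) of a metacommunity
#' experiment: core/satellite partitioning, Fisher's alpha diversity
#' with group comparisons, Raup-Crick assembly classification per
#' fraction (whole/core/satellite), CCA with permutation forward
#' selection of host variables per fraction, and median-burden
#' dysbiosis; plus between-site ANOSIM per fraction and pairwise SIMPER
#' of the whole microbiota. All randomised stages draw their seeds
#' deterministically from `seed`, so a re-run with the same inputs is
#' numerically identical.
#'
#' @param experiment a [MetacomExperiment-class] whose `colData` carries
#'   `site` and the host covariates (`sex`, `age_years`, `phenology`,
#'   `nematode_count`)
#' @param tail chi-squared tail for the partition (default 0.025)
#' @param nRand Raup-Crick randomisations (default 1000)
#' @param nPerm ANOSIM permutations (default 9999)
#' @param ccaPerm CCA forward-selection permutations (default 1000)
#' @param alpha CCA admission threshold (default 0.05)
#' @param seed master integer seed
#' @param fractions community fractions to analyse (default whole, core,
#'   satellite)
#' @return a list of class `metacomPipeline`: per-site results under
#'   `$sites`, cross-site comparisons under `$between`, and the
#'   parameters under `$params`
#' @export
runPipeline <- function(experiment, tail = 0.025, nRand = 1000,
                        nPerm = 9999, ccaPerm = 1000, alpha = 0.05,
                        seed = 1L,
                        fractions = c("whole", "core", "satellite")) {
  stopifnot(methods::is(experiment, "MetacomExperiment"))
  cd <- as.data.frame(SummarizedExperiment::colData(experiment))
  if (!"site" %in% names(cd)) stop("colData needs a site column")
  sites <- unique(cd$site)
  log <- c(sprintf("seed=%d tail=%g nRand=%d nPerm=%d ccaPerm=%d alpha=%g",
                   seed, tail, nRand, nPerm, ccaPerm, alpha))

  fractionTaxa <- function(part, f, allTaxa) switch(
    f, whole = allTaxa, core = coreTaxa(part), satellite = satelliteTaxa(part))

  siteRes <- list()
  k <- 0L
  for (s in sites) {
    se <- siteExperiment(experiment, s)
    m <- counts(se)
    md <- as.data.frame(SummarizedExperiment::colData(se))
    part <- partitionCoreSatellite(m, tail = tail)
    div <- diversityTable(m, part)
    div$site <- s
    div <- merge(div, md[, c("sample_id", "sex")], by = "sample_id",
                 sort = FALSE)

    rc <- list()
    for (f in fractions) {
      k <- k + 1L
      tx <- fractionTaxa(part, f, rownames(m))
      rcf <- raupCrick(m, nRand = nRand, seed = .deriveSeed(seed, k),
                       taxa = tx)
      rc[[f]] <- list(result = rcf, classification = classifyAssembly(rcf))
    }

    vars <- md[, c("age_years", "sex", "nematode_count", "phenology")]
    names(vars) <- c("age", "sex", "burden", "phenology")
    cca <- list()
    for (f in fractions) {
      k <- k + 1L
      tx <- fractionTaxa(part, f, rownames(m))
      sub <- m[rownames(m) %in% tx, , drop = FALSE]
      keep <- colSums(sub) > 0 & stats::complete.cases(vars)
      cca[[f]] <- forwardSelect(sub[, keep, drop = FALSE],
                                vars[keep, , drop = FALSE],
                                nPerm = ccaPerm, alpha = alpha,
                                seed = .deriveSeed(seed, k))
    }

    burden <- setNames(md$nematode_count, md$sample_id)
    if (anyNA(burden)) {
      log <- c(log, sprintf(
        "site %s: %d sample(s) without burden excluded from dysbiosis",
        s, sum(is.na(burden))))
      burden <- burden[!is.na(burden)]
    }
    split <- splitByMedian(burden)
    dys <- burdenDysbiosis(m, split, partition = part)

    siteRes[[s]] <- list(partition = part, diversity = div,
                         sexComparison = compareDiversity(div, "sex"),
                         raupcrick = rc, cca = cca, dysbiosis = dys)
  }

  # between-microbiome comparisons on the union taxon space per fraction
  divAll <- do.call(rbind, lapply(siteRes, `[[`, "diversity"))
  between <- list(diversity = compareDiversity(divAll, "site"))
  cm <- counts(experiment)
  rel <- sweep(cm, 2, colSums(cm), "/")
  for (f in fractions) {
    k <- k + 1L
    keepTaxa <- unique(unlist(lapply(sites, function(s)
      fractionTaxa(siteRes[[s]]$partition, f, rownames(cm)))))
    sub <- rel[rownames(rel) %in% keepTaxa, , drop = FALSE]
    keep <- colSums(sub) > 0
    d <- brayCurtisMatrix(sub[, keep, drop = FALSE])
    between$anosim[[f]] <- anosim(d, cd$site[keep], nPerm = nPerm,
                                  seed = .deriveSeed(seed, k))
  }
  between$simper <- list()
  for (pair in utils::combn(sites, 2, simplify = FALSE)) {
    idx <- cd$site %in% pair
    nm <- paste(pair, collapse = "_vs_")
    between$simper[[nm]] <- simper(cm[, idx, drop = FALSE], cd$site[idx])
  }

  structure(list(sites = siteRes, between = between, log = log,
                 params = list(tail = tail, nRand = nRand, nPerm = nPerm,
                               ccaPerm = ccaPerm, alpha = alpha,
                               seed = seed, fractions = fractions)),
            class = "metacomPipeline")
}

#' Write pipeline outputs as machine-readable TSV files
#'
#' One file per analysis and site, each with `#` header lines recording
#' the seed and parameters.
#'
#' @param results a `metacomPipeline` list from [runPipeline()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writePipelineOutputs <- function(results, dir) {
  stopifnot(inherits(results, "metacomPipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- results$params
  hdr <- sprintf("seed=%d tail=%g nRand=%d nPerm=%d ccaPerm=%d alpha=%g",
                 p$seed, p$tail, p$nRand, p$nPerm, p$ccaPerm, p$alpha)
  paths <- character(0)
  out <- function(x, name, extra = character(0)) {
    path <- file.path(dir, name)
    .writeTsv(x, path, header = c(hdr, extra))
    paths <<- c(paths, path)
  }
  for (s in names(results$sites)) {
    r <- results$sites[[s]]
    out(r$partition@stats, sprintf("%s_partition.tsv", s),
        sprintf("chi2_limit=%.6f core_share=%.6f", r$partition@chi2Limit,
                r$partition@coreShare))
    out(r$diversity, sprintf("%s_diversity.tsv", s))
    for (f in names(r$raupcrick)) {
      cl <- r$raupcrick[[f]]$classification
      out(cl$classes, sprintf("%s_%s_raupcrick.tsv", s, f),
          sprintf("pct_det_similar=%.4f pct_stochastic=%.4f pct_det_dissimilar=%.4f",
                  cl$percentages[["det_similar"]],
                  cl$percentages[["stochastic"]],
                  cl$percentages[["det_dissimilar"]]))
    }
    for (f in names(r$cca))
      out(r$cca[[f]]@selection, sprintf("%s_%s_cca.tsv", s, f),
          sprintf("total_inertia=%.6f undetermined_pct=%.4f",
                  r$cca[[f]]@totalInertia, r$cca[[f]]@undetermined))
    out(r$dysbiosis@volcano, sprintf("%s_volcano.tsv", s),
        sprintf("median_burden=%g", r$dysbiosis@split@median))
    out(rbind(cbind(status = "gained", r$dysbiosis@gained),
              cbind(status = "lost", r$dysbiosis@lost)),
        sprintf("%s_gained_lost.tsv", s))
  }
  an <- do.call(rbind, lapply(names(results$between$anosim), function(f) {
    a <- results$between$anosim[[f]]
    data.frame(fraction = f, R = a@statistic, P = a@pValue,
               n_perm = a@nPerm, between_mean = a@betweenMean,
               between_sd = a@betweenSd, stringsAsFactors = FALSE)
  }))
  out(an, "between_anosim.tsv")
  for (nm in names(results$between$simper))
    out(results$between$simper[[nm]]@table, sprintf("simper_%s.tsv", nm),
        sprintf("overall_mean_dissimilarity=%.6f",
                results$between$simper[[nm]]@overall))
  out(results$between$diversity, "between_diversity_ttests.tsv")
  writeLines(c(paste("#", hdr), results$log), file.path(dir, "run_log.txt"))
  invisible(paths)
}
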