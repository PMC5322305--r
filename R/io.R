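#' Read a taxa-by-sample count table
#'
#' Tab-delimited matrix with taxon identifiers in the first column and
#' sample identifiers as the header; lines starting with `#` are
#' metadata comments and are skipped. Files ending in `.biom` are read
#' through the biomformat package when it is available.
#'
#' @param path input file
#' @return numeric matrix, taxa as rows
#' @export
readCountTable <- function(path) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    return(as(biomformat::biom_data(b), "matrix"))
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a per-sample metadata table
#'
#' @param path tab-delimited file with a `sample_id` column; `#` lines
#'   are comments
#' @return data.frame with row names set to `sample_id`
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  rownames(df) <- df$sample_id
  df
}

# write a TSV with '#' metadata header lines (seed, parameters, ...)
.writeTsv <- function(x, path, header = character(0), rowNamesAs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  if (!is.null(rowNamesAs)) {
    x <- data.frame(setNames(list(rownames(x)), rowNamesAs),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a count table as TSV
#'
#' @param counts taxa-by-sample matrix
#' @param path output file
#' @param header character vector of metadata lines written as `#`
#'   comments (seed, parameters)
#' @export
writeCountTable <- function(counts, path, header = character(0)) {
  .writeTsv(as.matrix(counts), path, header, rowNamesAs = "taxon_id")
}

#' Write a generator configuration as a flat key-value file
#'
#' One `key = value` line per field (vectors comma-separated with
#' `name:value` pairs where named); round-trips losslessly through
#' [readGeneratorConfig()].
#'
#' @param config a [metacomConfig()] object
#' @param path output file
#' @export
writeGeneratorConfig <- function(config, path) {
  stopifnot(inherits(config, "metacomConfig"))
  fmt <- function(v) {
    if (!is.null(names(v)) && length(names(v)))
      paste(sprintf("%s:%.17g", names(v), as.numeric(v)), collapse = ",")
    else paste(sprintf("%.17g", as.numeric(v)), collapse = ",")
  }
  lines <- vapply(names(unclass(config)), function(k) {
    v <- config[[k]]
    if (is.logical(v)) sprintf("%s = %s", k, v) else
      sprintf("%s = %s", k, fmt(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a generator configuration from a flat key-value file
#'
#' @param path file written by [writeGeneratorConfig()]
#' @return a [metacomConfig()] object
#' @export
readGeneratorConfig <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  parse1 <- function(s) {
    if (s %in% c("TRUE", "FALSE")) return(as.logical(s))
    parts <- strsplit(s, ",")[[1]]
    if (all(grepl(":", parts))) {
      sp <- strsplit(parts, ":")
      setNames(as.numeric(vapply(sp, `[`, "", 2)),
               vapply(sp, `[`, "", 1))
    } else as.numeric(parts)
  }
  vals <- lapply(kv, function(p) parse1(p[2]))
  names(vals) <- vapply(kv, `[`, "", 1)
  do.call(metacomConfig, vals)
}
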