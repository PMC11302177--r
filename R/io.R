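# TSV / GMT / JSON / graph readers and writers used across the pipeline.

#' Read / write an abundance matrix as TSV
#'
#' Plain-text exchange format: first column the protein id
#' ("Symbol|UniProtID"), remaining columns one per sample, log2 abundances
#' with empty cells for missing values.
#'
#' @param x proteins x samples matrix (write) or file path (read).
#' @param path output file path.
#' @return \code{readAbundance} returns the matrix; \code{writeAbundance}
#'   returns the path invisibly.
#' @export
writeAbundance <- function(x, path) {
  df <- data.frame(protein = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAbundance
#' @export
readAbundance <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read / write a sample metadata table as TSV
#'
#' @param samples data.frame (write) or file path (read).
#' @param path output file path.
#' @return the table (read) or the path, invisibly (write).
#' @export
writeSampleTable <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleTable
#' @export
readSampleTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(df)) rownames(df) <- df$sample_id
  df
}

#' Read / write gene-set collections in GMT format
#'
#' Strict GMT: one set per line, \code{name TAB description TAB member...}.
#'
#' @param sets a \code{\link{GeneSets}} (write) or file path (read).
#' @param path output file path.
#' @return a \code{GeneSets} (read) or the path, invisibly (write).
#' @export
writeGMT <- function(sets, path) {
  stopifnot(is(sets, "GeneSets"))
  lines <- vapply(names(sets@sets), function(nm)
    paste(c(nm, sets@description[[nm]] %||% "", sets@sets[[nm]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         " (need name TAB description TAB at least one member)")
  sets <- lapply(parts, function(p) toupper(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  desc <- setNames(vapply(parts, `[[`, "", 2L), names(sets))
  new("GeneSets", sets = sets, description = desc, source = path)
}

#' Serialise a planted simulation truth to JSON
#'
#' @param truth a \code{\link{SimTruth}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTruthJSON <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  cfg <- truth@config
  for (nm in c("groups", "covariate_effects", "bottleneck_weights"))
    cfg[[nm]] <- as.list(cfg[[nm]])        # keep names through JSON
  obj <- list(
    membership = as.list(truth@membership),
    bottleneck_id = truth@bottleneckId,
    bottleneck_weights = as.list(truth@bottleneckWeights),
    group_effects = truth@groupEffects,
    loadings = as.list(truth@loadings),
    module_scores = truth@moduleScores,
    trait_table = truth@traitTable,
    config = cfg
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Export a thresholded TOM subgraph
#'
#' \code{writeEdgeList} writes the kept edges as a weighted TSV
#' (\code{from}, \code{to}, \code{weight}); \code{writeGraphML} writes a
#' minimal GraphML document with the edge weight as an attribute.
#'
#' @param graph a \code{tomGraph} (see \code{\link{tomSubgraph}}).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(inherits(graph, "tomGraph"))
  idx <- which(graph$edges & upper.tri(graph$edges), arr.ind = TRUE)
  df <- data.frame(from = graph$nodes[idx[, 1L]],
                   to = graph$nodes[idx[, 2L]],
                   weight = graph$weights[idx],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(graph, path) {
  stopifnot(inherits(graph, "tomGraph"))
  idx <- which(graph$edges & upper.tri(graph$edges), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="tom" edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', graph$nodes), con)
  writeLines(sprintf(
    '    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
    graph$nodes[idx[, 1L]], graph$nodes[idx[, 2L]], graph$weights[idx]), con)
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
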