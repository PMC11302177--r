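#' SimTruth: planted ground truth of a synthetic cohort
#'
#' Records everything the generator planted so that downstream stages can be
#' scored against it: module membership of every protein, the latent module
#' score matrix, per-protein loadings, the bottleneck protein's identity and
#' target-module weights, per-module group effects, and the generated
#' pathology traits.
#'
#' @slot membership named character; planted module ("M1", ...) per protein,
#'   "unassigned" for background proteins, "bottleneck" for the planted
#'   multi-module bottleneck.
#' @slot moduleScores numeric matrix, modules x samples, the latent scores.
#' @slot loadings named numeric; per-protein loading on its planted module
#'   (0 for unassigned; the bottleneck's per-target weights live in
#'   \code{bottleneckWeights}).
#' @slot bottleneckId character(1) protein id.
#' @slot bottleneckWeights named numeric; loading per target module.
#' @slot groupEffects numeric matrix, modules x diagnosis groups (latent
#'   units).
#' @slot traitTable data.frame of generated CERAD/Braak/LB per sample.
#' @slot config list; the generating configuration.
#' @export
setClass("SimTruth", representation(
  membership = "character",
  moduleScores = "matrix",
  loadings = "numeric",
  bottleneckId = "character",
  bottleneckWeights = "numeric",
  groupEffects = "matrix",
  traitTable = "data.frame",
  config = "list"
))

setValidity("SimTruth", function(object) {
  msg <- character(0)
  if (is.null(names(object@membership)))
    msg <- c(msg, "membership must be named by protein id")
  if (length(object@bottleneckId) == 1L &&
      !is.na(object@bottleneckId) &&
      length(object@bottleneckWeights) < 3L)
    msg <- c(msg, "bottleneck must load on at least 3 modules")
  if (anyDuplicated(names(object@membership)))
    msg <- c(msg, "membership must cover each protein exactly once")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimTruth compact summary
#' @param object a \code{SimTruth}
#' @export
setMethod("show", "SimTruth", function(object) {
  tab <- table(object@membership)
  cat("SimTruth:", length(object@membership), "proteins,",
      nrow(object@moduleScores), "planted modules,",
      ncol(object@moduleScores), "samples\n")
  cat("  bottleneck:", object@bottleneckId, "->",
      paste(names(object@bottleneckWeights), collapse = ", "), "\n")
  cat("  unassigned:", sum(object@membership == "unassigned"), "\n")
  invisible(tab)
})

#' GeneSets: a named collection of gene sets (GMT-style)
#'
#' @slot sets named list of character vectors (uppercased gene symbols).
#' @slot description named character, one per set.
#' @slot source character(1) provenance tag.
#' @export
setClass("GeneSets", representation(
  sets = "list",
  description = "character",
  source = "character"
))

setValidity("GeneSets", function(object) {
  msg <- character(0)
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must have unique names")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSets compact summary
#' @param object a \code{GeneSets}
#' @export
setMethod("show", "GeneSets", function(object) {
  cat("GeneSets:", length(object@sets), "sets,",
      "sizes", paste(range(lengths(object@sets)), collapse = "-"),
      if (nzchar(object@source)) paste0("[", object@source, "]"), "\n")
})

#' CoexpressionNetwork: a signed weighted co-expression network
#'
#' Container for every layer of the network build: the robust correlation
#' matrix, signed soft-thresholded adjacency, mean-denominator topological
#' overlap matrix (TOM), the average-linkage dendrogram, cleaned module
#' labels, module eigenproteins with variance explained, and the full kME
#' (module-membership) table. Use the accessors rather than slots.
#'
#' @slot corr proteins x proteins robust correlation matrix.
#' @slot adjacency signed adjacency \eqn{((1+r)/2)^\beta}.
#' @slot tom topological overlap matrix.
#' @slot tree the \code{hclust} dendrogram on \code{1 - TOM}.
#' @slot labels named integer module number per protein (0 = unassigned).
#' @slot colors named character colour alias per protein ("grey" =
#'   unassigned).
#' @slot eigenproteins modules x samples eigenprotein matrix.
#' @slot varExplained numeric, per-module variance explained by the
#'   eigenprotein.
#' @slot kme proteins x modules signed bicor module membership.
#' @slot kmeP matching p-value matrix.
#' @slot config list of build parameters.
#' @slot provenance list (seed, package version, timings).
#' @export
setClass("CoexpressionNetwork", representation(
  corr = "matrix",
  adjacency = "matrix",
  tom = "matrix",
  tree = "ANY",
  labels = "integer",
  colors = "character",
  eigenproteins = "matrix",
  varExplained = "numeric",
  kme = "matrix",
  kmeP = "matrix",
  config = "list",
  provenance = "list"
))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character(0)
  p <- nrow(object@corr)
  if (ncol(object@corr) != p)
    msg <- c(msg, "corr must be square")
  if (!all(dim(object@adjacency) == c(p, p)))
    msg <- c(msg, "adjacency dimensions must match corr")
  if (!all(dim(object@tom) == c(p, p)))
    msg <- c(msg, "TOM dimensions must match corr")
  if (length(object@labels) != p)
    msg <- c(msg, "labels must cover every protein")
  if (length(object@labels) && any(object@labels < 0L, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative (0 = unassigned)")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoexpressionNetwork compact summary
#' @param object a \code{CoexpressionNetwork}
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
  n_mod <- length(setdiff(unique(object@labels), 0L))
  cat("CoexpressionNetwork:", nrow(object@corr), "proteins,",
      n_mod, "modules",
      sprintf("(%d unassigned)", sum(object@labels == 0L)), "\n")
  cat("  beta =", object@config$beta,
      "| TOM denominator =", object@config$tomDenominator %||% "mean",
      "| merge cut =", object@config$mergeCutHeight %||% 0.07, "\n")
  sz <- sort(table(object@labels[object@labels > 0L]), decreasing = TRUE)
  if (length(sz))
    cat("  module sizes:", paste(head(as.integer(sz), 10L), collapse = ", "),
        if (length(sz) > 10L) "...", "\n")
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
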