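# Accessor generics for the network container.

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("moduleColors", function(x) standardGeneric("moduleColors"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("eigenproteins", function(x) standardGeneric("eigenproteins"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("kmeTable", function(x) standardGeneric("kmeTable"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("networkCorrelation",
           function(x) standardGeneric("networkCorrelation"))

#' Accessors for CoexpressionNetwork objects
#'
#' \code{moduleLabels} returns the named integer module assignment (0 =
#' unassigned); \code{moduleColors} the colour aliases; \code{moduleSizes}
#' a table of member counts per module; \code{eigenproteins} the module x
#' sample eigenprotein matrix; \code{kmeTable} a data.frame of per-protein
#' module membership (own-module kME and p, plus the full kME matrix as
#' attributes); \code{tomMatrix}, \code{adjacencyMatrix} and
#' \code{networkCorrelation} the dense matrix layers.
#'
#' @param x a \code{\link{CoexpressionNetwork}}.
#' @return see description per accessor.
#' @name CoexpressionNetwork-accessors
NULL

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("moduleLabels", "CoexpressionNetwork", function(x) x@labels)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("moduleColors", "CoexpressionNetwork", function(x) x@colors)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("moduleSizes", "CoexpressionNetwork", function(x) {
  lbl <- x@labels[x@labels > 0L]
  tab <- table(factor(paste0("M", lbl), levels = paste0("M", sort(unique(lbl)))))
  tab
})

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("eigenproteins", "CoexpressionNetwork", function(x) x@eigenproteins)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("kmeTable", "CoexpressionNetwork", function(x) {
  own <- paste0("M", x@labels)
  own[x@labels == 0L] <- NA_character_
  idx <- match(own, colnames(x@kme))
  kme_own <- ifelse(is.na(idx), NA_real_,
                    x@kme[cbind(seq_along(idx), idx)])
  p_own <- ifelse(is.na(idx), NA_real_,
                  x@kmeP[cbind(seq_along(idx), idx)])
  out <- data.frame(
    protein = names(x@labels),
    module = x@labels,
    color = x@colors,
    kME = kme_own,
    p = p_own,
    stringsAsFactors = FALSE
  )
  attr(out, "kme") <- x@kme
  attr(out, "kmeP") <- x@kmeP
  out
})

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@tom)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("networkCorrelation", "CoexpressionNetwork", function(x) x@corr)
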