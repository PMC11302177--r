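# Internal helpers shared across modules.

# module colour aliases, ordered by module number (M1 = first colour);
# "grey" is reserved for unassigned proteins
.MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen", "skyblue3",
  "plum1", "orangered4", "mediumpurple3", "lightsteelblue1"
)

moduleColorOf <- function(module_number) {
  out <- rep("grey", length(module_number))
  pos <- !is.na(module_number) & module_number > 0
  idx <- ((module_number[pos] - 1L) %% length(.MODULE_COLORS)) + 1L
  out[pos] <- .MODULE_COLORS[idx]
  out
}

.checkAbundanceMatrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance matrix must be a numeric matrix (proteins x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix must have protein row names and sample column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate protein ids in abundance matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids in abundance matrix")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("abundance matrix needs at least 2 proteins and 2 samples")
  if (any(is.infinite(x)))
    stop("abundance matrix contains non-finite (infinite) values")
  invisible(x)
}

# first token of "Symbol|UniProtID" ids, uppercased for set matching
proteinSymbol <- function(ids) {
  toupper(sub("\\|.*$", "", ids))
}

.rowSdsNA <- function(x) {
  apply(x, 1L, sd, na.rm = TRUE)
}

.rowMediansNA <- function(x) {
  apply(x, 1L, median, na.rm = TRUE)
}

.colMediansNA <- function(x) {
  apply(x, 2L, median, na.rm = TRUE)
}

# draw a derived, reproducible sub-seed below 2^31
.subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + (offset %% 1000L)
}

.stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
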