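#' Module-trait correlation grid
#'
#' Correlates each module eigenprotein with numeric traits and, when a
#' diagnosis factor is given, with a 0/1 indicator per diagnosis group.
#' Heat-map-ready: one row per (module, trait) with significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param E modules x samples eigenprotein matrix.
#' @param traits data.frame of numeric traits aligned to the samples.
#' @param diagnosis optional factor per sample; expanded to per-group 0/1
#'   indicator traits.
#' @param method \code{"bicor"} (default) or \code{"pearson"}.
#' @return data.frame (module, trait, r, p, stars, flag).
#' @export
moduleTraitCorrelation <- function(E, traits, diagnosis = NULL,
                                   method = c("bicor", "pearson")) {
  method <- match.arg(method)
  traits <- as.data.frame(traits)
  if (nrow(traits) != ncol(E))
    stop("traits must be aligned to the eigenprotein samples")
  if (!is.null(diagnosis)) {
    diagnosis <- factor(diagnosis)
    for (g in levels(diagnosis))
      traits[[paste0("dx_", g)]] <- as.integer(diagnosis == g)
  }
  out <- list()
  for (tr in colnames(traits)) {
    v <- as.numeric(traits[[tr]])
    tc <- traitCorrelation(E, v, method = method)
    out[[tr]] <- data.frame(module = rownames(E), trait = tr,
                            r = tc$r, p = tc$p, n = tc$n,
                            stars = .stars(tc$p), flag = tc$flag,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call module hub proteins
#'
#' Ranks each module's members by their own-module kME (descending) and
#' flags the top \code{ceiling(hub_percentile * size)} as hubs. Ties are
#' broken deterministically: higher whole-network connectivity first, then
#' lexicographic protein id.
#'
#' @param labels named integer module labels.
#' @param kme proteins x modules kME matrix (columns "M<k>").
#' @param connectivity optional named connectivity vector used for
#'   tie-breaking.
#' @param hub_percentile fraction of members called hubs (default 0.20, the
#'   top 20% of module members by kME).
#' @return data.frame (protein, module, kME, rank, is_hub).
#' @export
callHubs <- function(labels, kme, connectivity = NULL, hub_percentile = 0.2) {
  if (hub_percentile <= 0 || hub_percentile > 1)
    stop("hub_percentile must be in (0, 1]")
  mods <- sort(unique(labels[labels > 0L]))
  if (is.null(connectivity))
    connectivity <- setNames(rep(0, length(labels)), names(labels))
  out <- list()
  for (m in mods) {
    ids <- names(labels)[labels == m]
    k <- kme[ids, paste0("M", m)]
    ord <- order(-k, -connectivity[ids], ids)
    ids <- ids[ord]
    n_hub <- ceiling(hub_percentile * length(ids))
    out[[as.character(m)]] <- data.frame(
      protein = ids, module = m, kME = k[ord],
      rank = seq_along(ids),
      is_hub = seq_along(ids) <= n_hub,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fisher exact gene-set enrichment per module
#'
#' One-tailed (greater) Fisher exact test of each gene set against each
#' module's membership over the network background; this equals the
#' hypergeometric upper tail of the 2x2 overlap table. Protein ids are
#' collapsed to primary gene symbols (the token before "|", uppercased)
#' before matching. Reports the sample odds ratio, Benjamini-Hochberg q
#' across the full module x set grid, and the one-sided normal z transform
#' of p (capped at 38 for p underflow).
#'
#' @param labels named integer module labels (0 = unassigned).
#' @param sets a \code{\link{GeneSets}} collection.
#' @param background character vector of background symbols; default all
#'   network proteins (assigned or not).
#' @return data.frame (module, set, overlap, module_size, set_size,
#'   background, odds_ratio, p, q, z).
#' @export
fisherEnrichment <- function(labels, sets, background = NULL) {
  stopifnot(is(sets, "GeneSets"))
  sym <- proteinSymbol(names(labels))
  keep <- !duplicated(sym)                 # collapse multi-protein symbols
  sym <- sym[keep]
  lab <- labels[keep]
  if (is.null(background)) background <- sym
  background <- unique(toupper(background))
  N <- length(background)
  mods <- sort(unique(lab[lab > 0L]))
  out <- list()
  for (m in mods) {
    mod_sym <- intersect(sym[lab == m], background)
    n_mod <- length(mod_sym)
    for (s in names(sets@sets)) {
      set_sym <- intersect(unique(toupper(sets@sets[[s]])), background)
      K <- length(set_sym)
      k <- length(intersect(mod_sym, set_sym))
      p <- phyper(k - 1, K, N - K, n_mod, lower.tail = FALSE)
      or <- if (k == 0) 0 else {
        b <- K - k; c_ <- n_mod - k; d <- N - K - n_mod + k
        if (b == 0 || c_ == 0) Inf else (k * d) / (b * c_)
      }
      out[[paste(m, s)]] <- data.frame(
        module = paste0("M", m), set = s, overlap = k,
        module_size = n_mod, set_size = K, background = N,
        odds_ratio = or, p = p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- bhCorrect(res$p)
  res$z <- pmin(qnorm(res$p, lower.tail = FALSE), 38)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control with monotonicity
#' enforcement (thin wrapper over \code{p.adjust(method = "BH")}).
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values.
#' @export
bhCorrect <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Risk-gene enrichment per module
#'
#' Gene-level surrogate for GWAS module association: consumes precomputed
#' per-gene disease-association p-values, filters them at \code{p_filter},
#' and tests each module for enrichment of the filtered risk genes by
#' one-tailed Fisher exact test against the network background, reporting
#' the one-sided normal z. Significance is called at \code{z >= 1.28},
#' mirroring the reporting convention for this analysis (1.28 is the
#' one-sided 10% normal quantile; see the vignette for the caveat).
#'
#' @param labels named integer module labels.
#' @param risk_genes named numeric vector: association p per gene symbol.
#' @param p_filter association filter (default 0.05).
#' @param z_threshold significance call threshold (default 1.28).
#' @return data.frame (module, overlap, n_risk, odds_ratio, p, q, z,
#'   significant).
#' @export
riskGeneEnrichment <- function(labels, risk_genes, p_filter = 0.05,
                               z_threshold = 1.28) {
  if (is.null(names(risk_genes)))
    stop("risk_genes must be named by gene symbol")
  filtered <- toupper(names(risk_genes)[risk_genes < p_filter])
  if (!length(filtered))
    stop("no risk genes pass the association filter")
  sets <- new("GeneSets",
              sets = list(RISK = filtered),
              description = c(RISK = "filtered risk genes"),
              source = "user")
  res <- fisherEnrichment(labels, sets)
  res$significant <- !is.na(res$z) & res$z >= z_threshold
  res$set <- NULL
  res
}
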