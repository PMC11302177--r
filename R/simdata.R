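#' Configuration for the synthetic multi-batch TMT cohort generator
#'
#' Defines a cohort that mimics a multi-batch isobaric-label (TMT) brain
#' proteomic study: diagnosis groups of stated sizes, batches with one pooled
#' global-internal-standard (GIS) channel each, planted co-expression modules
#' whose latent scores shift by diagnosis group, additive per-protein batch
#' offsets, age/sex/PMI covariate effects, semi-quantitative pathology traits
#' derived from weighted module scores, completely-at-random missingness, and
#' one planted bottleneck protein loading moderately on several modules.
#'
#' The defaults describe the study conditions used throughout the package's
#' validation: 1,000 proteins in 8 modules of 40-200 members, a
#' 47/33/47/11 CTL/PD/PDD/DLB case mix, 10 batches of 16 channels (15
#' biological + 1 GIS), residual noise tuned so that within-module pairwise
#' correlations are about 0.6, batch standard deviation 0.5 and 15%
#' missingness.
#'
#' @param n_proteins total proteins including unassigned background and the
#'   bottleneck.
#' @param module_sizes integer vector of planted module sizes (M1, M2, ...).
#' @param groups named integer vector of biological sample counts per
#'   diagnosis group; the first group is the control/reference.
#' @param n_batches number of TMT batches.
#' @param channels_per_batch channels per batch; one is reserved for the GIS.
#' @param group_effects modules x groups matrix of latent mean shifts
#'   (first column must be 0); \code{NULL} for the built-in default.
#' @param loading_range interval in (0, 1] for per-protein module loadings.
#' @param noise_sd residual log2 noise SD.
#' @param batch_sd SD of the per-(protein, batch) additive batch offset.
#' @param covariate_effects named numeric \code{c(age=, sex=, pmi=)} in log2
#'   units (per year / offset / per hour).
#' @param trait_loadings modules x 3 matrix (columns cerad, braak,
#'   lb_score) of weights linking module scores to latent trait scores;
#'   \code{NULL} for the default.
#' @param missing_rate MCAR missingness fraction, must be < 0.5 so the
#'   default 50% presence filter keeps planted proteins.
#' @param bottleneck_targets integer indices of the bottleneck's target
#'   modules (at least 3).
#' @param bottleneck_weights latent-unit loading of the bottleneck on each
#'   target module (positive; not restricted to (0,1] — these are weights on
#'   independent latent scores, chosen so the bottleneck's kME to each
#'   target lands in the moderate 0.55-0.75 band).
#' @param seed integer seed governing all randomness.
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(n_proteins = 1000L,
                      module_sizes = c(200L, 160L, 130L, 110L, 90L, 70L, 55L, 40L),
                      groups = c(CTL = 47L, PD = 33L, PDD = 47L, DLB = 11L),
                      n_batches = 10L,
                      channels_per_batch = 16L,
                      group_effects = NULL,
                      loading_range = c(0.4, 1.0),
                      noise_sd = 0.6,
                      batch_sd = 0.5,
                      covariate_effects = c(age = 0.02, sex = 0.2, pmi = 0.01),
                      trait_loadings = NULL,
                      missing_rate = 0.15,
                      bottleneck_targets = c(1L, 2L, 5L),
                      bottleneck_weights = c(2, 2, 2),
                      seed = 1L) {
  k <- length(module_sizes)
  if (is.null(group_effects))
    group_effects <- .defaultGroupEffects(k, names(groups))
  if (is.null(trait_loadings))
    trait_loadings <- .defaultTraitLoadings(k)
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    module_sizes = as.integer(module_sizes),
    n_unassigned = as.integer(n_proteins - sum(module_sizes) - 1L),
    groups = groups,
    n_batches = as.integer(n_batches),
    channels_per_batch = as.integer(channels_per_batch),
    group_effects = group_effects,
    loading_range = loading_range,
    noise_sd = noise_sd,
    batch_sd = batch_sd,
    covariate_effects = covariate_effects,
    trait_loadings = trait_loadings,
    missing_rate = missing_rate,
    bottleneck_targets = as.integer(bottleneck_targets),
    bottleneck_weights = bottleneck_weights,
    seed = as.integer(seed)
  )
  class(cfg) <- "simConfig"
  .validateSimConfig(cfg)
  cfg
}

.defaultGroupEffects <- function(k, group_names) {
  ng <- length(group_names)
  # latent-unit severity curves (none < sparse < moderate < severe): early
  # modules increase with disease severity, the next block decreases,
  # trailing modules are null -- mirroring disease-correlated and stable
  # biology
  base <- list(
    c(0, 0.3, 0.8, 1.0), c(0, 0.2, 0.6, 0.8), c(0, -0.3, -0.8, -1.0),
    c(0, -0.2, -0.5, -0.7), c(0, 0.1, 0.4, 0.5), c(0, -0.1, -0.4, -0.5)
  )
  # map each diagnosis label to its place on the severity curve; unknown
  # labels are spread evenly
  sev <- c(CTL = 1L, AsymLB = 2L, PD = 2L, PDD = 3L, DLB = 4L, LBD = 4L,
           AD = 4L)
  idx <- unname(sev[group_names])
  if (anyNA(idx)) idx <- round(seq(1L, 4L, length.out = ng))
  eff <- matrix(0, nrow = k, ncol = ng,
                dimnames = list(paste0("M", seq_len(k)), group_names))
  for (m in seq_len(min(k, length(base))))
    eff[m, ] <- base[[m]][idx]
  eff[, 1L] <- 0
  eff
}

.defaultTraitLoadings <- function(k) {
  tl <- matrix(0, nrow = k, ncol = 3L,
               dimnames = list(paste0("M", seq_len(k)),
                               c("cerad", "braak", "lb_score")))
  if (k >= 5L) {
    tl["M5", "cerad"] <- 1.0
    tl["M3", "cerad"] <- -0.5
    tl["M5", "braak"] <- 0.7
    tl["M1", "braak"] <- 0.4
    tl["M1", "lb_score"] <- 1.0
    tl["M3", "lb_score"] <- -0.6
  } else {
    tl[1L, ] <- c(1.0, 0.7, 1.0)
  }
  tl
}

.validateSimConfig <- function(cfg) {
  with(cfg, {
    if (sum(module_sizes) + n_unassigned + 1L != n_proteins)
      stop("module_sizes + n_unassigned + 1 (bottleneck) must equal n_proteins")
    if (n_unassigned < 0L)
      stop("module sizes exceed n_proteins")
    if (any(groups <= 0L))
      stop("all group sample counts must be positive")
    if (noise_sd < 0 || batch_sd < 0)
      stop("noise_sd and batch_sd must be non-negative")
    if (missing_rate < 0 || missing_rate >= 0.5)
      stop("missing_rate must be in [0, 0.5)")
    if (loading_range[1] <= 0 || loading_range[2] > 1 ||
        loading_range[1] > loading_range[2])
      stop("loading_range must be an interval within (0, 1]")
    if (length(bottleneck_targets) < 3L)
      stop("bottleneck must target at least 3 modules")
    if (any(bottleneck_targets > length(module_sizes)))
      stop("bottleneck target module index out of range")
    if (length(bottleneck_weights) != length(bottleneck_targets))
      stop("one bottleneck weight per target module required")
    if (any(bottleneck_weights <= 0))
      stop("bottleneck weights must be positive")
    if (n_batches * (channels_per_batch - 1L) < sum(groups))
      stop("batch capacity (channels_per_batch - 1 per batch) too small ",
           "for the requested samples")
    if (nrow(group_effects) != length(module_sizes) ||
        ncol(group_effects) != length(groups))
      stop("group_effects must be modules x groups")
    if (any(group_effects[, 1L] != 0))
      stop("the first (reference) group's effects must be 0")
  })
  invisible(cfg)
}

#' Generate a synthetic multi-batch TMT-like cohort
#'
#' Draws a full cohort under the model
#' \deqn{x_{is} = \mu_i + \lambda_i m_{M(i),s} + a_{age} age_s + a_{sex}
#' sex_s + a_{pmi} pmi_s + \delta_{i,b(s)} + \epsilon_{is}}
#' with module scores \eqn{m_{M,s} = \Delta_{M,g(s)} + \eta}, \eqn{\eta \sim
#' N(0,1)}, residual noise \eqn{\epsilon \sim N(0, noise\_sd^2)} and
#' per-(protein, batch) offsets \eqn{\delta \sim N(0, batch\_sd^2)}.
#' Unassigned proteins have \eqn{\lambda = 0}; the bottleneck protein loads
#' on each of its target modules with its stated weight. Each batch carries
#' one pooled GIS sample equal to the protein-wise mean of that batch's
#' biological samples plus \eqn{N(0, noise\_sd/4)} noise. Pathology traits
#' (CERAD 0-3, Braak 0-6, frontal LB score 0-3) are monotone rank
#' discretisations of weighted module scores. Missing cells are set
#' completely at random. All randomness derives from \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{SummarizedExperiment}: assay \code{"log2"} (proteins x
#'   samples, GIS channels included), \code{colData} with batch / channel /
#'   GIS flag / diagnosis / covariates / traits, \code{rowData} with planted
#'   membership and loading, and \code{metadata(se)$truth} a
#'   \code{\link{SimTruth}}.
#' @examples
#' cfg <- simConfig(n_proteins = 120, module_sizes = c(40, 30, 25),
#'                  groups = c(CTL = 10, DLB = 10), n_batches = 2,
#'                  channels_per_batch = 11,
#'                  bottleneck_targets = 1:3, seed = 7)
#' se <- simulateCohort(cfg)
#' se
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  .validateSimConfig(config)
  set.seed(config$seed)
  membership <- .drawMembership(config)
  loadings <- .drawLoadings(config, membership)
  .simEngine(config, membership, loadings)
}

.drawMembership <- function(cfg) {
  k <- length(cfg$module_sizes)
  lab <- c(rep(paste0("M", seq_len(k)), cfg$module_sizes),
           rep("unassigned", cfg$n_unassigned))
  lab <- sample(lab)                       # decouple row order from modules
  lab <- c(lab, "bottleneck")              # bottleneck is the last protein
  ids <- sprintf("P%04d|U%05d", seq_len(cfg$n_proteins),
                 seq_len(cfg$n_proteins))
  ids[cfg$n_proteins] <- sprintf("BNECK|U%05d", cfg$n_proteins)
  names(lab) <- ids
  lab
}

.drawLoadings <- function(cfg, membership) {
  lam <- numeric(length(membership))
  names(lam) <- names(membership)
  in_mod <- !membership %in% c("unassigned", "bottleneck")
  lam[in_mod] <- runif(sum(in_mod), cfg$loading_range[1], cfg$loading_range[2])
  lam
}

# core generator; also used for replication cohorts with frozen
# membership/loadings
.simEngine <- function(cfg, membership, loadings, group_effects = NULL,
                       scramble_modules = character(0)) {
  if (is.null(group_effects))
    group_effects <- cfg$group_effects
  k <- nrow(group_effects)
  nP <- length(membership)
  ids <- names(membership)

  ## samples ----------------------------------------------------------------
  nS <- sum(cfg$groups)
  sample_id <- sprintf("S%03d", seq_len(nS))
  diagnosis <- rep(names(cfg$groups), cfg$groups)
  ord <- sample.int(nS)
  slots <- rep(seq_len(cfg$n_batches),
               each = cfg$channels_per_batch - 1L)[seq_len(nS)]
  batch <- integer(nS)
  batch[ord] <- slots
  channel <- integer(nS)
  for (b in seq_len(cfg$n_batches))
    channel[batch == b] <- seq_len(sum(batch == b))
  age <- pmin(pmax(rnorm(nS, 75, 8), 55), 95)
  sex <- rbinom(nS, 1L, 0.5)
  pmi <- pmax(rnorm(nS, 12, 6), 1)

  ## latent module scores ---------------------------------------------------
  m <- group_effects[, diagnosis, drop = FALSE] +
    matrix(rnorm(k * nS), nrow = k)
  dimnames(m) <- list(rownames(group_effects), sample_id)

  ## traits: monotone rank discretisation of weighted module scores ---------
  lat <- t(cfg$trait_loadings) %*% m               # 3 x nS
  cerad <- .discretize(lat["cerad", ], 4L)
  braak <- .discretize(lat["braak", ], 7L)
  lb_score <- .discretize(lat["lb_score", ], 4L)

  ## protein signal ---------------------------------------------------------
  mu <- rnorm(nP, 0, 0.5)                          # protein baselines
  signal <- matrix(0, nrow = nP, ncol = nS, dimnames = list(ids, sample_id))
  for (mod in rownames(group_effects)) {
    rows <- which(membership == mod)
    if (length(rows))
      signal[rows, ] <- outer(loadings[rows], m[mod, ])
  }
  b_row <- which(membership == "bottleneck")
  bw <- cfg$bottleneck_weights
  names(bw) <- rownames(group_effects)[cfg$bottleneck_targets]
  if (length(b_row) == 1L)
    signal[b_row, ] <- as.numeric(bw %*% m[names(bw), , drop = FALSE])

  if (length(scramble_modules)) {
    # destroy the listed modules' co-expression: members become pure noise
    rows <- which(membership %in% scramble_modules)
    signal[rows, ] <- 0
  }

  cov_term <- cfg$covariate_effects["age"] * age +
    cfg$covariate_effects["sex"] * sex +
    cfg$covariate_effects["pmi"] * pmi
  delta <- matrix(rnorm(nP * cfg$n_batches, 0, cfg$batch_sd), nrow = nP)
  x <- mu + signal +
    matrix(cov_term, nrow = nP, ncol = nS, byrow = TRUE) +
    delta[, batch, drop = FALSE] +
    matrix(rnorm(nP * nS, 0, cfg$noise_sd), nrow = nP)
  dimnames(x) <- list(ids, sample_id)

  ## GIS channels: protein-wise mean of each batch's biological samples -----
  gis_ids <- sprintf("GIS.b%02d", seq_len(cfg$n_batches))
  gis <- sapply(seq_len(cfg$n_batches), function(b)
    rowMeans(x[, batch == b, drop = FALSE]) +
      rnorm(nP, 0, cfg$noise_sd / 4))
  colnames(gis) <- gis_ids
  full <- cbind(x, gis)

  ## MCAR missingness -------------------------------------------------------
  if (cfg$missing_rate > 0) {
    miss <- runif(length(full)) < cfg$missing_rate
    full[miss] <- NA_real_
  }

  samples <- data.frame(
    sample_id = c(sample_id, gis_ids),
    cohort = "SIM",
    batch = paste0("b", sprintf("%02d", c(batch, seq_len(cfg$n_batches)))),
    channel = c(paste0("C", sprintf("%02d", channel)),
                rep("GIS", cfg$n_batches)),
    is_gis = c(rep(FALSE, nS), rep(TRUE, cfg$n_batches)),
    diagnosis = c(diagnosis, rep("GIS", cfg$n_batches)),
    age = c(age, rep(NA_real_, cfg$n_batches)),
    sex = c(sex, rep(NA_integer_, cfg$n_batches)),
    pmi = c(pmi, rep(NA_real_, cfg$n_batches)),
    cerad = c(cerad, rep(NA_integer_, cfg$n_batches)),
    braak = c(braak, rep(NA_integer_, cfg$n_batches)),
    lb_score = c(lb_score, rep(NA_integer_, cfg$n_batches)),
    row.names = c(sample_id, gis_ids),
    stringsAsFactors = FALSE
  )

  truth <- new("SimTruth",
    membership = membership,
    moduleScores = m,
    loadings = loadings,
    bottleneckId = if (length(b_row)) ids[b_row] else NA_character_,
    bottleneckWeights = bw,
    groupEffects = group_effects,
    traitTable = data.frame(sample_id = sample_id, cerad = cerad,
                            braak = braak, lb_score = lb_score,
                            stringsAsFactors = FALSE),
    config = unclass(cfg)
  )

  SummarizedExperiment(
    assays = list(log2 = full),
    colData = DataFrame(samples),
    rowData = DataFrame(membership = membership,
                        loading = loadings,
                        row.names = ids),
    metadata = list(truth = truth, config = unclass(cfg))
  )
}

.discretize <- function(z, nlevels) {
  r <- rank(z, ties.method = "first")
  as.integer(floor((r - 1) * nlevels / length(z)))
}

#' Generate a replication cohort from an existing planted truth
#'
#' Draws new samples (new module scores, noise, batches, covariates, traits)
#' while keeping the planted module memberships, per-protein loadings and
#' bottleneck weights from a prior \code{\link{simulateCohort}} run -- the
#' situation of an independent cohort measuring the same underlying biology.
#' Group effects can be overridden (e.g. opposite-signed disease effects),
#' and listed modules can be scrambled into pure noise to model biology that
#' does not replicate.
#'
#' @param truth a \code{\link{SimTruth}} from \code{simulateCohort}.
#' @param groups named sample counts (default: same design as the original).
#' @param n_batches,channels_per_batch batch layout (default: original).
#' @param group_effects optional modules x groups override matrix.
#' @param scramble_modules character vector of module names whose planted
#'   co-expression is destroyed in the replication cohort.
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment} as for \code{simulateCohort}.
#' @export
simulateReplication <- function(truth, groups = NULL, n_batches = NULL,
                                channels_per_batch = NULL,
                                group_effects = NULL,
                                scramble_modules = character(0),
                                seed = 2L) {
  stopifnot(is(truth, "SimTruth"))
  cfg <- truth@config
  class(cfg) <- "simConfig"
  if (!is.null(groups)) {
    if (any(groups <= 0L) || length(groups) == 0L)
      stop("all group sample counts must be positive")
    cfg$groups <- groups
    if (is.null(group_effects)) {
      keep <- intersect(names(groups), colnames(truth@groupEffects))
      if (length(keep) < length(groups))
        stop("new groups must match the planted group effects, or supply ",
             "a group_effects override")
      cfg$group_effects <- truth@groupEffects[, names(groups), drop = FALSE]
    }
  }
  if (!is.null(group_effects)) {
    if (nrow(group_effects) != nrow(truth@groupEffects))
      stop("group_effects override must keep the planted module count")
    cfg$group_effects <- group_effects
  }
  if (!is.null(n_batches)) cfg$n_batches <- as.integer(n_batches)
  if (!is.null(channels_per_batch))
    cfg$channels_per_batch <- as.integer(channels_per_batch)
  cfg$seed <- as.integer(seed)
  .validateSimConfig(cfg)
  bad <- setdiff(scramble_modules, rownames(truth@groupEffects))
  if (length(bad))
    stop("unknown module(s) in scramble_modules: ", paste(bad, collapse = ", "))
  set.seed(cfg$seed)
  .simEngine(cfg, truth@membership, truth@loadings,
             group_effects = cfg$group_effects,
             scramble_modules = scramble_modules)
}

#' Generate marker gene sets matched to planted modules
#'
#' Builds one GMT-style set per planted module containing a stated fraction
#' of its member symbols plus random filler symbols, together with decoy
#' sets drawn uniformly from the background -- a controlled stand-in for
#' cell-type marker or ontology collections when validating enrichment.
#'
#' @param truth a \code{\link{SimTruth}}.
#' @param overlap_frac fraction in (0, 1] of each module's members included
#'   in its marker set.
#' @param n_decoy_sets number of uniform decoy sets.
#' @param filler_frac fillers added per set, as a fraction of module size.
#' @param seed integer seed.
#' @return a \code{\link{GeneSets}} collection.
#' @export
simulateMarkerSets <- function(truth, overlap_frac = 0.8, n_decoy_sets = 10L,
                               filler_frac = 0.2, seed = 3L) {
  stopifnot(is(truth, "SimTruth"))
  if (overlap_frac <= 0 || overlap_frac > 1)
    stop("overlap_frac must be in (0, 1]")
  set.seed(seed)
  symbols <- proteinSymbol(names(truth@membership))
  mods <- rownames(truth@groupEffects)
  sets <- list()
  desc <- character(0)
  for (mod in mods) {
    members <- symbols[truth@membership == mod]
    n_in <- max(1L, round(overlap_frac * length(members)))
    n_fill <- round(filler_frac * length(members))
    fill <- sample(setdiff(symbols, members), n_fill)
    sets[[paste0("MARKER_", mod)]] <- c(sample(members, n_in), fill)
    desc[paste0("MARKER_", mod)] <- paste("planted markers for", mod)
  }
  med_size <- max(2L, round(median(lengths(sets))))
  for (d in seq_len(n_decoy_sets)) {
    nm <- sprintf("DECOY_%02d", d)
    sets[[nm]] <- sample(symbols, med_size)
    desc[nm] <- "uniform decoy set"
  }
  new("GeneSets", sets = sets, description = desc, source = "simulated")
}
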