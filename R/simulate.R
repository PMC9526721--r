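#' Simulate a two-group expression dataset with planted modules
#'
#' Seeded generator emulating a summarized two-group microarray experiment
#' on a log-like Gaussian scale. Per module a latent eigengene is drawn per
#' sample from a standard normal; for trait-linked modules a mean shift of
#' `treatmentEffect` (in latent SD units) is added to the treated samples,
#' with the shift sign alternating (+, -, +, -, ...) across trait modules
#' so that both up- and down-regulated planted gene sets exist. A gene of
#' module m is `rho * e_m + sqrt(1 - rho^2) * noise`; background genes are
#' pure noise of standard deviation `noiseSd`. A per-gene baseline drawn
#' once from Unif(6, 12) mimics microarray intensity levels. Optionally one
#' treated sample is corrupted by permuting its values within the sample
#' (destroying its correlation with the others), as a planted QC outlier.
#'
#' @param nGenes total genes (default 10000).
#' @param nModules number of planted modules (default 6).
#' @param moduleSize genes per module (default 150).
#' @param nTraitModules leading modules that respond to treatment
#'   (default 4).
#' @param withinModuleCor target gene-eigengene correlation `rho`
#'   (default 0.8).
#' @param treatmentEffect latent mean shift in SD units (default 2).
#' @param samplesPerGroup samples per group (default 3).
#' @param noiseSd idiosyncratic noise SD (default 1).
#' @param outlierSample plant one corrupted treated sample (default FALSE).
#' @param latents `"iid"` draws module latents independently;
#'   `"orthogonal"` orthogonalizes them across samples (requires
#'   `nModules <= 2 * samplesPerGroup`), which makes modules exactly
#'   separable and is useful for clustering tests.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return List with elements `dataset` ([ExpressionDataset-class]) and
#'   `truth` (list: `assignment` gene -> planted label with
#'   `"background"` for noise genes, `traitModules`, `directions`,
#'   `upGenes`, `downGenes`, `outlierSample`).
#' @export
simulateExpression <- function(nGenes = 10000, nModules = 6,
                               moduleSize = 150, nTraitModules = 4,
                               withinModuleCor = 0.8, treatmentEffect = 2,
                               samplesPerGroup = 3, noiseSd = 1,
                               outlierSample = FALSE,
                               latents = c("iid", "orthogonal"),
                               seed = 1) {
  latents <- match.arg(latents)
  stopifnot(nModules * moduleSize <= nGenes,
            nTraitModules <= nModules,
            withinModuleCor >= 0, withinModuleCor <= 1,
            samplesPerGroup >= 1, noiseSd >= 0)
  withSeed_(seed, {
    ns <- 2 * samplesPerGroup
    grp <- rep(c(0, 1), each = samplesPerGroup)
    samples <- c(paste0("vehicle_", seq_len(samplesPerGroup)),
                 paste0("treated_", seq_len(samplesPerGroup)))
    genes <- paste0("g", seq_len(nGenes))
    rho <- withinModuleCor
    x <- matrix(rnorm(nGenes * ns, 0, noiseSd), nGenes, ns,
                dimnames = list(genes, samples))
    assignment <- setNames(rep("background", nGenes), genes)
    dirs <- integer(0)
    if (nModules > 0) {
      E <- matrix(rnorm(ns * nModules), ns, nModules)
      if (latents == "orthogonal") {
        if (nModules > ns)
          stop("orthogonal latents need nModules <= sample count")
        E <- scale(qr.Q(qr(E)))
      }
      dirs <- rep_len(c(1L, -1L), nModules)
      dirs[seq_len(nModules) > nTraitModules] <- 0L
      for (m in seq_len(nModules)) {
        e <- E[, m] + dirs[m] * treatmentEffect * grp
        idx <- ((m - 1) * moduleSize + 1):(m * moduleSize)
        x[idx, ] <- rho * matrix(e, moduleSize, ns, byrow = TRUE) +
          sqrt(1 - rho^2) *
          matrix(rnorm(moduleSize * ns, 0, noiseSd), moduleSize, ns)
        assignment[idx] <- paste0("P", m)
      }
    }
    baseline <- runif(nGenes, 6, 12)
    x <- x + baseline
    outlier <- NA_character_
    if (outlierSample) {
      outlier <- samples[samplesPerGroup + 1]  # first treated sample
      x[, outlier] <- sample(x[, outlier])
    }
    groups <- setNames(rep(c("vehicle", "treated"), each = samplesPerGroup),
                       samples)
    traitLabels <- paste0("P", seq_len(nTraitModules))
    list(
      dataset = ExpressionDataset(x, groups),
      truth = list(
        assignment = assignment,
        traitModules = traitLabels,
        directions = if (nModules > 0)
          setNames(dirs, paste0("P", seq_len(nModules)))
        else setNames(integer(0), character(0)),
        upGenes = genes[assignment %in%
                          traitLabels[dirs[seq_len(nTraitModules)] > 0]],
        downGenes = genes[assignment %in%
                            traitLabels[dirs[seq_len(nTraitModules)] < 0]],
        outlierSample = outlier))
  })
}

## Draw one ranked profile by exponential tilting: genes get independent
## Gumbel keys shifted by lambda * c (c = +1 for up genes, -1 for down),
## then rank 1 goes to the largest key. lambda = 0 gives a uniform
## permutation; large lambda pushes up genes to the top ranks.
tiltedRanks_ <- function(universe, upGenes, downGenes, lambda) {
  n <- length(universe)
  shift <- numeric(n)
  shift[universe %in% upGenes] <- lambda
  shift[universe %in% downGenes] <- -lambda
  keys <- -log(-log(runif(n))) + shift
  r <- integer(n)
  r[order(keys, decreasing = TRUE)] <- seq_len(n)
  r
}

#' Simulate a ranked reference compendium
#'
#' Seeded generator of a compound reference library in the ranked-profile
#' format of [RankedCompendium-class]. Ordinary compounds get uniformly
#' random rank permutations per instance. "Mimic" compounds bias the
#' planted up genes toward top ranks and down genes toward bottom ranks
#' with concordance strength `lambda` (exponential tilting; `lambda = 0`
#' is indistinguishable from random); "reverser" compounds swap the two
#' roles.
#'
#' @param universe character vector of gene identifiers (must match the
#'   expression dataset the signature comes from).
#' @param upGenes,downGenes planted signature gene sets (e.g. from the
#'   `truth` of [simulateExpression()]).
#' @param nCompounds total number of compounds (default 50), including the
#'   planted ones.
#' @param instancesPerCompound instances per compound (default 3).
#' @param mimics named numeric vector, compound name -> lambda
#'   (default `c(mimic_1 = 3)`).
#' @param reversers named numeric vector for reverser compounds
#'   (default `c(reverser_1 = 3)`).
#' @param seed integer seed.
#' @return List with elements `compendium` ([RankedCompendium-class]) and
#'   `truth` (list: `mimics`, `reversers`).
#' @export
simulateCompendium <- function(universe, upGenes, downGenes,
                               nCompounds = 50, instancesPerCompound = 3,
                               mimics = c(mimic_1 = 3),
                               reversers = c(reverser_1 = 3),
                               seed = 1) {
  bad <- setdiff(c(upGenes, downGenes), universe)
  if (length(bad))
    stop("universe mismatch: planted gene(s) not in universe: ",
         paste(head(bad, 5), collapse = ", "))
  nPlanted <- length(mimics) + length(reversers)
  stopifnot(nCompounds >= nPlanted, instancesPerCompound >= 1)
  compounds <- c(names(mimics), names(reversers),
                 sprintf("cmpd_%03d", seq_len(nCompounds - nPlanted)))
  if ((length(mimics) && is.null(names(mimics))) ||
      (length(reversers) && is.null(names(reversers))))
    stop("mimics and reversers must be named by compound")
  lambda <- setNames(numeric(length(compounds)), compounds)
  if (length(mimics)) lambda[names(mimics)] <- mimics
  if (length(reversers)) lambda[names(reversers)] <- -reversers
  withSeed_(seed, {
    info <- data.frame(
      instance_id = as.vector(t(outer(compounds,
                                      seq_len(instancesPerCompound),
                                      function(a, b) paste0(a, "_i", b)))),
      compound = rep(compounds, each = instancesPerCompound),
      stringsAsFactors = FALSE)
    rk <- vapply(seq_len(nrow(info)), function(i) {
      l <- lambda[[info$compound[i]]]
      if (l >= 0) tiltedRanks_(universe, upGenes, downGenes, l)
      else tiltedRanks_(universe, downGenes, upGenes, -l)
    }, integer(length(universe)))
    rownames(rk) <- universe
    colnames(rk) <- info$instance_id
    list(compendium = RankedCompendium(rk, info),
         truth = list(mimics = names(mimics), reversers = names(reversers)))
  })
}
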