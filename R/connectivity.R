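#' Tag-set Kolmogorov-Smirnov statistic on a ranked profile
#'
#' The build-02 style enrichment statistic of a tag set within one ranked
#' gene profile. With `V(1) < ... < V(t)` the sorted ranks of the `t` tags
#' in a universe of `n` genes,
#' `a = max_j (j/t - V(j)/n)` and `b = max_j (V(j)/n - (j-1)/t)`;
#' the statistic is `a` if `a > b`, else `-b`. Values near +1 mean the tags
#' concentrate at the top of the profile (most up-regulated), near -1 at
#' the bottom.
#'
#' @param tags character vector of tag genes (`1 <= length(tags) < n`).
#' @param ranks named integer vector: the profile's rank (1 = most
#'   up-regulated) for every gene of the universe.
#' @return A scalar in `[-1, 1]`.
#' @export
ksTagStatistic <- function(tags, ranks) {
  n <- length(ranks)
  t <- length(tags)
  stopifnot(t >= 1, t < n)
  missing <- setdiff(tags, names(ranks))
  if (length(missing))
    stop("tag(s) outside the profile universe: ",
         paste(head(missing, 5), collapse = ", "))
  v <- sort.int(as.numeric(ranks[tags]))
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Raw connectivity score of one instance
#'
#' Combines the up- and down-tag KS statistics of one ranked profile: when
#' the two statistics have the same sign the instance carries no consistent
#' signal and the raw score is 0 (a "null" instance); otherwise the score is
#' `ks_up - ks_down`.
#'
#' @param up,down disjoint character vectors of up and down tags.
#' @param ranks named rank vector of one instance (see [ksTagStatistic()]).
#' @return List with elements `ks_up`, `ks_down`, `raw`.
#' @export
instanceRawScore <- function(up, down, ranks) {
  if (length(intersect(up, down)))
    stop("up and down tags must be disjoint")
  ku <- ksTagStatistic(up, ranks)
  kd <- ksTagStatistic(down, ranks)
  s <- if (sign(ku) == sign(kd)) 0 else ku - kd
  list(ks_up = ku, ks_down = kd, raw = s)
}

#' Scale raw connectivity scores to the interval from -1 to +1
#'
#' With `p` the maximum and `q` the minimum raw score across the instance
#' set, positive scores are divided by `p` and negative scores by `|q|`;
#' zeros stay zero. The strongest concordant instance thus scores exactly
#' +1 and the strongest discordant one exactly -1. If every raw score is 0
#' a warning is emitted and all scaled scores are 0.
#'
#' @param raw numeric vector of per-instance raw scores.
#' @return Numeric vector of scaled scores in `[-1, 1]`.
#' @export
scaleConnectivityScores <- function(raw) {
  stopifnot(length(raw) >= 1)
  if (all(raw == 0)) {
    warning("all raw connectivity scores are zero")
    return(raw)
  }
  p <- max(raw)
  q <- min(raw)
  out <- numeric(length(raw))
  out[raw > 0] <- raw[raw > 0] / p
  out[raw < 0] <- raw[raw < 0] / abs(q)
  out
}

## Raw scores of a signature against a set of instance columns.
rawScores_ <- function(up, down, ranks) {
  apply(ranks, 2, function(col) {
    r <- setNames(col, rownames(ranks))
    instanceRawScore(up, down, r)$raw
  })
}

#' Score a compendium against a query signature
#'
#' Computes per-instance KS statistics, raw scores and compendium-wide
#' scaled scores, plus each compound's mean scaled score and percent
#' non-null. Permutation p-values, specificity and the final ranking are
#' added by [connectivityScreen()].
#'
#' @param sig a [QuerySignature-class].
#' @param compendium a [RankedCompendium-class] whose universe contains all
#'   tags.
#' @return A [ConnectivityReport-class] (without `p_perm`/`rank` columns).
#' @export
scoreCompendium <- function(sig, compendium) {
  rk <- compendiumRanks(compendium)
  info <- instanceInfo(compendium)
  genes <- rownames(rk)
  st <- lapply(seq_len(ncol(rk)), function(j) {
    instanceRawScore(sig@upTags, sig@downTags, setNames(rk[, j], genes))
  })
  inst <- data.frame(
    instance_id = info$instance_id,
    compound = info$compound,
    ks_up = vapply(st, `[[`, 0, "ks_up"),
    ks_down = vapply(st, `[[`, 0, "ks_down"),
    raw = vapply(st, `[[`, 0, "raw"),
    stringsAsFactors = FALSE)
  inst$scaled <- suppressWarnings(scaleConnectivityScores(inst$raw))
  cmp <- compoundSummary(inst)
  methods::new("ConnectivityReport", instances = inst, compounds = cmp,
               signature = sig)
}

#' Per-compound summary of instance scores
#'
#' Arithmetic mean of the scaled scores over each compound's instances,
#' plus the percent non-null ([percentNonnull()]).
#'
#' @param instances per-instance data.frame with columns `compound` and
#'   `scaled` (as in [ConnectivityReport-class]).
#' @return data.frame with columns `compound`, `n_instances`, `mean_score`,
#'   `percent_nonnull`.
#' @export
compoundSummary <- function(instances) {
  sp <- split(instances$scaled, instances$compound)
  data.frame(
    compound = names(sp),
    n_instances = vapply(sp, length, 0L),
    mean_score = vapply(sp, mean, 0),
    percent_nonnull = vapply(sp, percentNonnull, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent non-null instances of a compound
#'
#' The percentage of a compound's instances whose nonzero scaled score has
#' the same sign as the compound's mean scaled score; defined as 0 when the
#' mean is 0.
#'
#' @param scaled numeric vector of the compound's scaled instance scores.
#' @return Percentage in `[0, 100]`.
#' @export
percentNonnull <- function(scaled) {
  m <- mean(scaled)
  if (m == 0) return(0)
  100 * sum(scaled != 0 & sign(scaled) == sign(m)) / length(scaled)
}

#' Permutation p-value of a compound's connectivity
#'
#' Null model: `B` random query signatures with the same up/down tag counts
#' are drawn uniformly (disjoint, without replacement) from the universe and
#' the compound's mean scaled score is recomputed against its own instances,
#' with scaling over that same instance set; the observed mean is computed
#' identically so observed and null are exchangeable under the null. The
#' add-one estimator `p = (1 + #{|null| >= |observed|}) / (B + 1)` is
#' returned, so p is never 0.
#'
#' @param compound compound name present in the compendium.
#' @param sig a [QuerySignature-class].
#' @param compendium a [RankedCompendium-class].
#' @param B number of permutations (default 1000).
#' @param seed integer seed for the tag draws (optional but recommended).
#' @return List with elements `p`, `observed`, `null` (vector of B null
#'   means).
#' @export
permutationPvalue <- function(compound, sig, compendium, B = 1000,
                              seed = NULL) {
  stopifnot(B >= 1)
  rk <- compendiumRanks(compendium)
  info <- instanceInfo(compendium)
  cols <- which(info$compound == compound)
  if (!length(cols)) stop("unknown compound: ", compound)
  sub <- rk[, cols, drop = FALSE]
  nu <- length(sig@upTags)
  nd <- length(sig@downTags)
  genes <- rownames(rk)
  if (length(genes) < nu + nd)
    stop("universe smaller than the combined tag counts")
  meanScaled <- function(up, down) {
    raw <- rawScores_(up, down, sub)
    mean(suppressWarnings(scaleConnectivityScores(raw)))
  }
  obs <- meanScaled(sig@upTags, sig@downTags)
  null <- withSeed_(seed, vapply(seq_len(B), function(b) {
    tags <- sample(genes, nu + nd)
    meanScaled(tags[seq_len(nu)], tags[nu + seq_len(nd)])
  }, 0))
  p <- (1 + sum(abs(null) >= abs(obs))) / (B + 1)
  list(p = p, observed = obs, null = null)
}

#' Specificity of a compound's score against decoy signatures
#'
#' Fraction of decoy signatures whose absolute mean scaled score for the
#' compound (scaled within the full compendium, like the observed score) is
#' at least the observed absolute mean. Lower values mean the compound's
#' connectivity is specific to the query.
#'
#' @param compound compound name.
#' @param sig the query [QuerySignature-class].
#' @param decoys list of decoy [QuerySignature-class] objects (>= 1).
#' @param compendium a [RankedCompendium-class].
#' @return Fraction in `[0, 1]`.
#' @export
specificityScore <- function(compound, sig, decoys, compendium) {
  if (!length(decoys)) stop("at least one decoy signature is required")
  obsMean <- function(s) {
    rep <- scoreCompendium(s, compendium)
    cmp <- compoundScores(rep)
    cmp$mean_score[cmp$compound == compound]
  }
  obs <- abs(obsMean(sig))
  dec <- vapply(decoys, function(d) abs(obsMean(d)), 0)
  mean(dec >= obs)
}

#' Rank compounds of a connectivity report
#'
#' Stable ordering by permutation p-value (ascending), then mean scaled
#' score (descending, signed), then compound name. The signed tie-break
#' reflects the screen's goal of finding compounds that mimic the query
#' signature: among equally significant compounds, strong positive
#' connectivity outranks strong negative (signature-reversing)
#' connectivity.
#'
#' @param report a [ConnectivityReport-class] whose compound table has a
#'   `p_perm` column.
#' @return The report with a `rank` column added and the compound table
#'   sorted.
#' @export
rankSmallMolecules <- function(report) {
  cmp <- compoundScores(report)
  if (!"p_perm" %in% colnames(cmp))
    stop("permutation p-values missing; run connectivityScreen()")
  o <- order(cmp$p_perm, -cmp$mean_score, cmp$compound)
  cmp <- cmp[o, , drop = FALSE]
  cmp$rank <- seq_len(nrow(cmp))
  rownames(cmp) <- NULL
  methods::initialize(report, compounds = cmp)
}

#' Full connectivity screen of a compendium
#'
#' [scoreCompendium()] plus per-compound permutation p-values (per-compound
#' seeds derived deterministically from `seed`), optional specificity
#' against decoy signatures, and the final ranking
#' ([rankSmallMolecules()]).
#'
#' @param sig a [QuerySignature-class].
#' @param compendium a [RankedCompendium-class].
#' @param B permutations per compound (default 1000).
#' @param seed integer seed driving all permutation draws.
#' @param decoys optional list of decoy [QuerySignature-class] objects for
#'   [specificityScore()].
#' @return A ranked [ConnectivityReport-class].
#' @export
connectivityScreen <- function(sig, compendium, B = 1000, seed = 1,
                               decoys = NULL) {
  report <- scoreCompendium(sig, compendium)
  cmp <- compoundScores(report)
  cmp$p_perm <- vapply(cmp$compound, function(cp)
    permutationPvalue(cp, sig, compendium, B = B,
                      seed = deriveSeed(seed, paste0("perm:", cp)))$p, 0)
  if (!is.null(decoys))
    cmp$specificity <- vapply(cmp$compound, function(cp)
      specificityScore(cp, sig, decoys, compendium), 0)
  report <- methods::initialize(report, compounds = cmp)
  rankSmallMolecules(report)
}

#' Read / write a ranked compendium
#'
#' The rank matrix is a TSV of integer ranks (genes x instances, first
#' column `gene`); the metadata table a TSV with columns `instance_id` and
#' `compound`. By default reading requires tie-free rank columns that are
#' exact permutations; `breakTies = TRUE` instead breaks ties by stable
#' input order with a logged warning.
#'
#' @param ranksPath,metaPath file paths.
#' @param breakTies break tied ranks by input order instead of erroring.
#' @return `readCompendium`: a [RankedCompendium-class].
#' @export
readCompendium <- function(ranksPath, metaPath, breakTies = FALSE) {
  tab <- read.delim(ranksPath, header = TRUE, sep = "\t",
                    comment.char = "#", check.names = FALSE)
  genes <- as.character(tab[[1]])
  rk <- as.matrix(tab[, -1, drop = FALSE])
  rownames(rk) <- genes
  meta <- read.delim(metaPath, header = TRUE, sep = "\t",
                     comment.char = "#", check.names = FALSE,
                     colClasses = "character")
  if (breakTies) {
    n <- nrow(rk)
    for (j in seq_len(ncol(rk))) {
      if (anyDuplicated(rk[, j])) {
        logMsg_("tied ranks in instance '", colnames(rk)[j],
                "' broken by input order")
        rk[, j] <- rank(rk[, j], ties.method = "first")
      }
    }
  }
  RankedCompendium(rk, meta)
}

#' @rdname readCompendium
#' @param compendium a [RankedCompendium-class].
#' @export
writeCompendium <- function(compendium, ranksPath, metaPath) {
  rk <- compendiumRanks(compendium)
  df <- data.frame(gene = rownames(rk), rk, check.names = FALSE)
  write.table(df, ranksPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(instanceInfo(compendium), metaPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(ranksPath)
}

#' Write a connectivity report
#'
#' Writes the per-instance and per-compound tables as TSV and, optionally,
#' the whole report as JSON.
#'
#' @param report a [ConnectivityReport-class].
#' @param instancePath,compoundPath TSV output paths.
#' @param jsonPath optional JSON output path.
#' @return Invisibly, `compoundPath`.
#' @export
writeConnectivityReport <- function(report, instancePath, compoundPath,
                                    jsonPath = NULL) {
  write.table(instanceScores(report), instancePath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(compoundScores(report), compoundPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(instances = instanceScores(report),
                              compounds = compoundScores(report),
                              up_tags = upTags(report@signature),
                              down_tags = downTags(report@signature)),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(compoundPath)
}
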