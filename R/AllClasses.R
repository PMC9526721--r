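#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor sd var pt phyper p.adjust rnorm runif setNames ave
#' @importFrom utils read.delim write.table head
NULL

#' Two-group expression dataset
#'
#' `ExpressionDataset` is a thin extension of
#' [SummarizedExperiment::SummarizedExperiment] holding a single
#' gene-by-sample matrix (assay `"exprs"`) together with a per-sample group
#' label (`colData` column `"group"`, e.g. `"vehicle"` / `"treated"`).
#' Validity requires unique gene and sample identifiers, all-finite values
#' and a group label for every sample.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [ExpressionDataset()], [readExpressionMatrix()]
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!identical(a, "exprs"))
    msgs <- c(msgs, "assay must be a single matrix named 'exprs'")
  m <- SummarizedExperiment::assay(object, withDimnames = TRUE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "gene and sample identifiers are required")
  if (anyDuplicated(rownames(m)))
    msgs <- c(msgs, "duplicate gene identifiers")
  if (anyDuplicated(colnames(m)))
    msgs <- c(msgs, "duplicate sample identifiers")
  if (!is.numeric(m) || any(!is.finite(m)))
    msgs <- c(msgs, "expression values must be finite numbers")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msgs <- c(msgs, "colData must contain a 'group' column")
  } else if (any(is.na(cd$group)) || any(!nzchar(as.character(cd$group)))) {
    msgs <- c(msgs, "every sample needs a non-missing group label")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param groups group labels: either a character vector named by sample, or
#'   an unnamed vector in column order of `values`.
#' @return A validated [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- ExpressionDataset(m, rep(c("vehicle", "treated"), each = 2))
#' @export
ExpressionDataset <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("'groups' must have one label per sample")
    names(groups) <- colnames(values)
  }
  miss <- setdiff(colnames(values), names(groups))
  if (length(miss))
    stop("annotation error: no group label for sample(s) ",
         paste(miss, collapse = ", "))
  groups <- as.character(groups[colnames(values)])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(values)))
  methods::new("ExpressionDataset", se)
}

#' Per-sample correlation quality-control report
#'
#' Produced by [sampleQC()]. Samples whose mean inter-sample Pearson
#' correlation falls more than `k` standard deviations below the average
#' mean correlation are flagged as outliers.
#'
#' @slot meanCorrelation named numeric, mean correlation of each sample with
#'   all other samples.
#' @slot mean,sd scalar mean and sample standard deviation (n-1 denominator)
#'   of `meanCorrelation`.
#' @slot k standard-deviation multiplier used for flagging.
#' @slot outliers character vector of flagged sample identifiers.
#' @export
setClass("SampleQCReport",
         representation(meanCorrelation = "numeric", mean = "numeric",
                        sd = "numeric", k = "numeric",
                        outliers = "character"))

setValidity("SampleQCReport", function(object) {
  mc <- object@meanCorrelation
  if (any(mc < -1 - 1e-12 | mc > 1 + 1e-12))
    return("mean correlations must lie in [-1, 1]")
  expected <- names(mc)[mc < object@mean - object@k * object@sd]
  if (!setequal(object@outliers, expected))
    return("outlier set inconsistent with the mean - k*sd rule")
  TRUE
})

#' Co-expression network parameters
#'
#' Container for the tunable parameters of [detectModules()] and
#' [adjacencyMatrix()].
#'
#' @slot beta soft-threshold power (>= 1).
#' @slot adjacencyType `"signed"` (`((1+r)/2)^beta`) or `"unsigned"`
#'   (`|r|^beta`).
#' @slot minModuleSize smallest cluster retained as a module (>= 2).
#' @slot cutHeightFraction static dendrogram cut, as a fraction of the
#'   maximal merge height, in (0, 1].
#' @slot mergeDissThreshold eigengene dissimilarity (1 - cor) below which
#'   modules are merged.
#' @seealso [networkParams()]
#' @export
setClass("NetworkParams",
         representation(beta = "numeric", adjacencyType = "character",
                        minModuleSize = "numeric",
                        cutHeightFraction = "numeric",
                        mergeDissThreshold = "numeric"))

setValidity("NetworkParams", function(object) {
  msgs <- character()
  if (length(object@beta) != 1 || object@beta < 1)
    msgs <- c(msgs, "beta must be a single value >= 1")
  if (!object@adjacencyType %in% c("signed", "unsigned"))
    msgs <- c(msgs, "adjacencyType must be 'signed' or 'unsigned'")
  if (object@minModuleSize < 2)
    msgs <- c(msgs, "minModuleSize must be >= 2")
  if (object@cutHeightFraction <= 0 || object@cutHeightFraction > 1)
    msgs <- c(msgs, "cutHeightFraction must be in (0, 1]")
  if (object@mergeDissThreshold < 0)
    msgs <- c(msgs, "mergeDissThreshold must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Network parameter constructor
#'
#' Defaults follow the analysis this package implements: a signed network at
#' soft power 16, minimum module size 100, and eigengene merge threshold 0.1.
#' The static cut height defaults to 0.95 of the maximal merge height; see
#' the methods vignette for the rationale.
#'
#' @param beta soft-threshold power.
#' @param adjacencyType `"signed"` or `"unsigned"`.
#' @param minModuleSize minimum number of genes per retained module.
#' @param cutHeightFraction fraction of the maximal dendrogram merge height
#'   at which the tree is cut.
#' @param mergeDissThreshold eigengene-dissimilarity merge threshold.
#' @return A [NetworkParams-class] object.
#' @export
networkParams <- function(beta = 16,
                          adjacencyType = c("signed", "unsigned"),
                          minModuleSize = 100,
                          cutHeightFraction = 0.95,
                          mergeDissThreshold = 0.1) {
  adjacencyType <- match.arg(adjacencyType)
  methods::new("NetworkParams", beta = beta, adjacencyType = adjacencyType,
               minModuleSize = minModuleSize,
               cutHeightFraction = cutHeightFraction,
               mergeDissThreshold = mergeDissThreshold)
}

#' Module decomposition of a co-expression network
#'
#' Result of [detectModules()]: a gene-to-module assignment (label
#' `"unassigned"` for genes not in any retained module), one unit-norm
#' eigengene per module (samples x modules matrix), and the log of eigengene
#' merges performed.
#'
#' @slot assignment named character vector, gene -> module label.
#' @slot eigengenes numeric matrix, samples in rows, modules in columns.
#' @slot mergeLog data.frame with columns `moduleA`, `moduleB`,
#'   `dissimilarity`, one row per merge in order.
#' @slot params the [NetworkParams-class] used.
#' @export
setClass("ModuleDecomposition",
         representation(assignment = "character", eigengenes = "matrix",
                        mergeLog = "data.frame", params = "NetworkParams"))

setValidity("ModuleDecomposition", function(object) {
  msgs <- character()
  mods <- setdiff(unique(object@assignment), "unassigned")
  if (!setequal(mods, colnames(object@eigengenes)))
    msgs <- c(msgs, "eigengene columns must match module labels")
  if (length(mods)) {
    sizes <- table(object@assignment[object@assignment != "unassigned"])
    if (any(sizes < object@params@minModuleSize))
      msgs <- c(msgs, "a retained module is smaller than minModuleSize")
    nrm <- sqrt(colSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6))
      msgs <- c(msgs, "eigengenes must have unit Euclidean norm")
  }
  if (length(msgs)) msgs else TRUE
})

#' Up/down query signature
#'
#' Ordered up-regulated and down-regulated tag lists extracted from a
#' differential-expression table at significance threshold `alpha`
#' (see [buildQuerySignature()]).
#'
#' @slot upTags,downTags ordered character vectors of gene identifiers;
#'   disjoint and individually duplicate-free.
#' @slot alpha the p-value threshold used to build the signature.
#' @export
setClass("QuerySignature",
         representation(upTags = "character", downTags = "character",
                        alpha = "numeric"))

setValidity("QuerySignature", function(object) {
  msgs <- character()
  if (anyDuplicated(object@upTags) || anyDuplicated(object@downTags))
    msgs <- c(msgs, "tag lists must not contain duplicates")
  if (length(intersect(object@upTags, object@downTags)))
    msgs <- c(msgs, "up and down tag lists must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Compendium of ranked reference profiles
#'
#' A reference library in the Connectivity-Map style: one ranked
#' gene profile per treatment instance, with rank 1 the most up-regulated
#' gene of that instance, and a table mapping instances to compounds.
#'
#' @slot ranks integer matrix, genes x instances; every column is a
#'   permutation of `1..nrow`.
#' @slot instanceInfo data.frame with columns `instance_id` and `compound`,
#'   one row per column of `ranks`.
#' @seealso [RankedCompendium()], [readCompendium()], [simulateCompendium()]
#' @export
setClass("RankedCompendium",
         representation(ranks = "matrix", instanceInfo = "data.frame"))

setValidity("RankedCompendium", function(object) {
  r <- object@ranks
  n <- nrow(r)
  if (is.null(rownames(r)) || anyDuplicated(rownames(r)))
    return("ranks must have unique gene rownames")
  if (ncol(r) != nrow(object@instanceInfo))
    return("instanceInfo must have one row per instance column")
  if (!all(c("instance_id", "compound") %in% colnames(object@instanceInfo)))
    return("instanceInfo needs 'instance_id' and 'compound' columns")
  if (!identical(colnames(r), as.character(object@instanceInfo$instance_id)))
    return("rank columns must be named by instance_id, in order")
  for (j in seq_len(ncol(r))) {
    cj <- r[, j]
    if (length(cj) != n || any(sort.int(cj) != seq_len(n)))
      return(sprintf("column '%s' is not a permutation of 1..%d",
                     colnames(r)[j], n))
  }
  TRUE
})

#' Construct a RankedCompendium
#'
#' @param ranks integer matrix of per-instance gene ranks (genes x
#'   instances); each column must be a permutation of `1..nrow(ranks)`.
#' @param instanceInfo data.frame with columns `instance_id`, `compound`.
#' @return A validated [RankedCompendium-class].
#' @export
RankedCompendium <- function(ranks, instanceInfo) {
  storage.mode(ranks) <- "integer"
  instanceInfo <- as.data.frame(instanceInfo)
  instanceInfo$instance_id <- as.character(instanceInfo$instance_id)
  instanceInfo$compound <- as.character(instanceInfo$compound)
  if (is.null(colnames(ranks))) colnames(ranks) <- instanceInfo$instance_id
  methods::new("RankedCompendium", ranks = ranks, instanceInfo = instanceInfo)
}

#' Connectivity screening report
#'
#' Result of [connectivityScreen()] (or [scoreCompendium()] for the
#' per-instance part): tag-KS statistics, raw and scaled scores per
#' instance, and per-compound summaries (mean scaled score, permutation
#' p-value, percent non-null, optional specificity, final rank).
#'
#' @slot instances data.frame: `instance_id`, `compound`, `ks_up`,
#'   `ks_down`, `raw`, `scaled`.
#' @slot compounds data.frame: `compound`, `mean_score`, `percent_nonnull`,
#'   and when computed `p_perm`, `specificity`, `rank`.
#' @slot signature the [QuerySignature-class] that was queried.
#' @export
setClass("ConnectivityReport",
         representation(instances = "data.frame", compounds = "data.frame",
                        signature = "QuerySignature"))

setValidity("ConnectivityReport", function(object) {
  sc <- object@instances$scaled
  if (!is.null(sc) && any(sc < -1 - 1e-12 | sc > 1 + 1e-12))
    return("scaled scores must lie in [-1, 1]")
  TRUE
})

## -- show methods -----------------------------------------------------------

setMethod("show", "ExpressionDataset", function(object) {
  g <- table(sampleGroups(object))
  cat("ExpressionDataset:", nrow(object), "genes x", ncol(object),
      "samples\n")
  cat("groups:", paste(sprintf("%s (%d)", names(g), g), collapse = ", "),
      "\n")
})

setMethod("show", "SampleQCReport", function(object) {
  cat("SampleQCReport:", length(object@meanCorrelation), "samples;",
      sprintf("mean correlation %.4f (sd %.4f), k = %g\n",
              object@mean, object@sd, object@k))
  if (length(object@outliers)) {
    cat("outliers:", paste(object@outliers, collapse = ", "), "\n")
  } else cat("outliers: none\n")
})

setMethod("show", "NetworkParams", function(object) {
  cat(sprintf(paste0("NetworkParams: %s adjacency, beta = %g, ",
                     "minModuleSize = %g,\n  cutHeightFraction = %g, ",
                     "mergeDissThreshold = %g\n"),
              object@adjacencyType, object@beta, object@minModuleSize,
              object@cutHeightFraction, object@mergeDissThreshold))
})

setMethod("show", "ModuleDecomposition", function(object) {
  mods <- setdiff(unique(object@assignment), "unassigned")
  sizes <- sort(table(object@assignment[object@assignment != "unassigned"]),
                decreasing = TRUE)
  cat("ModuleDecomposition:", length(mods), "modules over",
      length(object@assignment), "genes;",
      sum(object@assignment == "unassigned"), "unassigned\n")
  if (length(mods))
    cat("sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                        collapse = ", "), "\n")
  if (nrow(object@mergeLog))
    cat("merges performed:", nrow(object@mergeLog), "\n")
})

setMethod("show", "QuerySignature", function(object) {
  cat(sprintf("QuerySignature: %d up tags, %d down tags (alpha = %g)\n",
              length(object@upTags), length(object@downTags), object@alpha))
})

setMethod("show", "RankedCompendium", function(object) {
  cat("RankedCompendium:", nrow(object@ranks), "genes,",
      ncol(object@ranks), "instances,",
      length(unique(object@instanceInfo$compound)), "compounds\n")
})

setMethod("show", "ConnectivityReport", function(object) {
  cat("ConnectivityReport:", nrow(object@instances), "instances,",
      nrow(object@compounds), "compounds\n")
  cmp <- object@compounds
  if ("rank" %in% colnames(cmp)) {
    cmp <- cmp[order(cmp$rank), , drop = FALSE]
    print(head(cmp, 8), row.names = FALSE)
  }
})
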