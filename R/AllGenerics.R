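#' Accessors for package classes
#'
#' Small family of accessor generics: `exprValues()` returns the
#' gene-by-sample matrix of an [ExpressionDataset-class]; `sampleGroups()`
#' its named group labels; `moduleAssignment()`, `eigengenes()` and
#' `mergeLog()` the components of a [ModuleDecomposition-class];
#' `upTags()`/`downTags()` the tag lists of a [QuerySignature-class];
#' `compendiumRanks()` and `instanceInfo()` the parts of a
#' [RankedCompendium-class]; `instanceScores()` and `compoundScores()` the
#' tables of a [ConnectivityReport-class].
#'
#' @param x an object of the matching class.
#' @return The component named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("moduleAssignment",
           function(x) standardGeneric("moduleAssignment"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setGeneric("mergeLog", function(x) standardGeneric("mergeLog"))

#' @rdname accessors
#' @export
setGeneric("upTags", function(x) standardGeneric("upTags"))

#' @rdname accessors
#' @export
setGeneric("downTags", function(x) standardGeneric("downTags"))

#' @rdname accessors
#' @export
setGeneric("compendiumRanks",
           function(x) standardGeneric("compendiumRanks"))

#' @rdname accessors
#' @export
setGeneric("instanceInfo", function(x) standardGeneric("instanceInfo"))

#' @rdname accessors
#' @export
setGeneric("instanceScores", function(x) standardGeneric("instanceScores"))

#' @rdname accessors
#' @export
setGeneric("compoundScores", function(x) standardGeneric("compoundScores"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionDataset", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionDataset", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$group),
           colnames(x)))

#' @rdname accessors
#' @export
setMethod("moduleAssignment", "ModuleDecomposition",
          function(x) x@assignment)

#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleDecomposition", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setMethod("mergeLog", "ModuleDecomposition", function(x) x@mergeLog)

#' @rdname accessors
#' @export
setMethod("upTags", "QuerySignature", function(x) x@upTags)

#' @rdname accessors
#' @export
setMethod("downTags", "QuerySignature", function(x) x@downTags)

#' @rdname accessors
#' @export
setMethod("compendiumRanks", "RankedCompendium", function(x) x@ranks)

#' @rdname accessors
#' @export
setMethod("instanceInfo", "RankedCompendium", function(x) x@instanceInfo)

#' @rdname accessors
#' @export
setMethod("instanceScores", "ConnectivityReport", function(x) x@instances)

#' @rdname accessors
#' @export
setMethod("compoundScores", "ConnectivityReport", function(x) x@compounds)
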