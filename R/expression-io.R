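#' Read an expression matrix and its sample annotation
#'
#' Reads a tab-separated gene-by-sample matrix (header row of sample
#' identifiers, first column of gene identifiers, `#`-prefixed comment lines
#' ignored) together with a two-column annotation table
#' (`sample<TAB>group`) and returns a validated [ExpressionDataset-class].
#' Row and column order of the matrix file are preserved.
#'
#' @param path path of the matrix TSV.
#' @param annotationPath path of the two-column sample annotation TSV.
#' @return An [ExpressionDataset-class].
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path, annotationPath) {
  stopifnot(file.exists(path), file.exists(annotationPath))
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("format error: matrix file needs an ID column and >= 1 sample")
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    stop("format error: duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples))
    stop("format error: duplicate sample identifier(s)")
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1]]))
    bad <- which(is.na(v) & !is.na(tab[[j + 1]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value in row '%s', column '%s'",
                   genes[bad[1]], samples[j]))
    vals[, j] <- v
  }
  ann <- read.delim(annotationPath, header = FALSE, sep = "\t",
                    comment.char = "#", colClasses = "character")
  ## tolerate an optional header line
  if (nrow(ann) && identical(tolower(ann[1, 1]), "sample"))
    ann <- ann[-1, , drop = FALSE]
  if (ncol(ann) < 2) stop("annotation error: expected 'sample<TAB>group'")
  groups <- setNames(ann[[2]], ann[[1]])
  ExpressionDataset(vals, groups)
}

#' Write an expression matrix and annotation to TSV
#'
#' Inverse of [readExpressionMatrix()]; the written files round-trip to a
#' bitwise-identical dataset.
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output path for the matrix TSV.
#' @param annotationPath output path for the annotation TSV (optional).
#' @return Invisibly, `path`.
#' @export
writeExpressionMatrix <- function(ds, path, annotationPath = NULL) {
  m <- exprValues(ds)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath)) {
    g <- sampleGroups(ds)
    write.table(data.frame(names(g), unname(g)), annotationPath,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Flag outlier samples by mean inter-sample correlation
#'
#' Computes each sample's mean Pearson correlation with all other samples
#' and flags samples falling more than `k` standard deviations (sample SD,
#' n-1 denominator) below the average as outliers. The rule is applied in a
#' single pass on the full matrix; no re-estimation after removal.
#'
#' @param ds an [ExpressionDataset-class] with at least 3 samples.
#' @param k standard-deviation multiplier (default 3).
#' @return A [SampleQCReport-class].
#' @export
sampleQC <- function(ds, k = 3) {
  m <- exprValues(ds)
  if (ncol(m) < 3)
    stop("insufficient data: sample QC requires >= 3 samples")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "),
         "; correlations are undefined")
  cc <- cor(m)
  diag(cc) <- NA
  mc <- rowMeans(cc, na.rm = TRUE)
  mu <- mean(mc)
  s <- sd(mc)
  methods::new("SampleQCReport", meanCorrelation = mc, mean = mu, sd = s,
               k = k, outliers = names(mc)[mc < mu - k * s])
}

#' Write a sample QC report as JSON
#'
#' @param report a [SampleQCReport-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(
    list(mean_correlation = as.list(report@meanCorrelation),
         mean = report@mean, sd = report@sd, k = report@k,
         outliers = report@outliers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Remove flagged outlier samples
#'
#' Convenience: drops the samples flagged by [sampleQC()] from the dataset.
#'
#' @param ds an [ExpressionDataset-class].
#' @param report the matching [SampleQCReport-class].
#' @return The dataset without outlier samples.
#' @export
dropOutlierSamples <- function(ds, report) {
  keep <- setdiff(colnames(ds), report@outliers)
  if (length(keep) == ncol(ds)) return(ds)
  logMsg_("dropping ", ncol(ds) - length(keep), " outlier sample(s): ",
          paste(report@outliers, collapse = ", "))
  ExpressionDataset(exprValues(ds)[, keep, drop = FALSE],
                    sampleGroups(ds)[keep])
}

#' Quantile-normalize an expression dataset
#'
#' Forces every sample (column) onto the identical value distribution: the
#' per-rank mean of the sorted input columns. Within-column rank order is
#' preserved; tied values receive the mean of the reference values across
#' their tied ranks. The operation is an exact fixed point: applying it a
#' second time leaves values unchanged.
#'
#' @param ds an [ExpressionDataset-class] with at least 2 samples.
#' @return The normalized [ExpressionDataset-class].
#' @export
quantileNormalize <- function(ds) {
  m <- exprValues(ds)
  if (ncol(m) < 2) stop("quantile normalization requires >= 2 samples")
  srt <- apply(m, 2, sort.int, method = "radix")
  ref <- rowMeans(srt)
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    g <- m[o, j]
    ## runs of tied values share the mean of the reference over their ranks
    runs <- cumsum(c(TRUE, g[-1] != g[-length(g)]))
    out[o, j] <- ave(ref, runs)
  }
  ExpressionDataset(out, sampleGroups(ds))
}

#' Keep the most variable genes
#'
#' Retains the `n` genes with the largest sample variance (ties broken by
#' input order); rows keep their original relative order. If the dataset has
#' fewer than `n` genes, all are returned with a warning.
#'
#' @param ds an [ExpressionDataset-class].
#' @param n number of genes to keep (default 10000).
#' @return The filtered [ExpressionDataset-class].
#' @export
selectMostVariableGenes <- function(ds, n = 10000) {
  stopifnot(n >= 1)
  m <- exprValues(ds)
  if (nrow(m) <= n) {
    if (nrow(m) < n)
      warning(sprintf("only %d genes available; returning all", nrow(m)))
    return(ds)
  }
  v <- rowVars_(m)
  keep <- sort.int(order(-v, seq_along(v))[seq_len(n)])
  ExpressionDataset(m[keep, , drop = FALSE], sampleGroups(ds))
}

#' Collapse probe-level rows to gene level
#'
#' For genes measured by multiple probes, keeps the probe with the maximal
#' sample variance and renames the row to the gene identifier. Probes absent
#' from the mapping are dropped (count logged).
#'
#' @param ds an [ExpressionDataset-class] with probe-level row identifiers.
#' @param mapping data.frame (or 2-column matrix) with columns `probe` and
#'   `gene`.
#' @return A gene-level [ExpressionDataset-class].
#' @export
collapseProbesToGenes <- function(ds, mapping) {
  mapping <- as.data.frame(mapping)
  if (!all(c("probe", "gene") %in% colnames(mapping)))
    colnames(mapping)[1:2] <- c("probe", "gene")
  m <- exprValues(ds)
  mapping <- mapping[mapping$probe %in% rownames(m), , drop = FALSE]
  if (!nrow(mapping))
    stop("mapping error: no probe in the mapping matches the dataset")
  dropped <- sum(!rownames(m) %in% mapping$probe)
  if (dropped) logMsg_(dropped, " unmapped probe(s) dropped")
  v <- rowVars_(m)
  ## keep the max-variance probe per gene (ties by input order)
  ord <- order(match(mapping$gene, unique(mapping$gene)),
               -v[mapping$probe], match(mapping$probe, rownames(m)))
  mapping <- mapping[ord, , drop = FALSE]
  sel <- mapping[!duplicated(mapping$gene), , drop = FALSE]
  out <- m[sel$probe, , drop = FALSE]
  rownames(out) <- sel$gene
  ExpressionDataset(out, sampleGroups(ds))
}
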