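#' Soft-thresholded co-expression adjacency
#'
#' Computes the weighted adjacency of the gene co-expression network from
#' Pearson correlations across samples. With correlation `r`, the signed
#' adjacency is `((1 + r)/2)^beta` and the unsigned adjacency `|r|^beta`;
#' the diagonal is set to 1.
#'
#' @param ds an [ExpressionDataset-class] with >= 3 samples and no
#'   zero-variance gene.
#' @param params a [NetworkParams-class] (see [networkParams()]).
#' @return A symmetric gene-by-gene matrix with entries in `[0, 1]`.
#' @export
adjacencyMatrix <- function(ds, params = networkParams()) {
  m <- exprValues(ds)
  if (ncol(m) < 3) stop("adjacency requires >= 3 samples")
  v <- rowVars_(m)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(m)[v == 0], 5), collapse = ", "))
  r <- cor(t(m))
  a <- if (params@adjacencyType == "signed") {
    ((1 + r) / 2)^params@beta
  } else {
    abs(r)^params@beta
  }
  a[a > 1] <- 1  # guard against rounding just above 1
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Converts an adjacency matrix into the topological overlap similarity
#' `TOM[i,j] = (sum_u A[i,u] A[u,j] + A[i,j]) / (min(k_i, k_j) + 1 - A[i,j])`
#' (sum over `u != i, j`; `k_i` the connectivity of gene `i` excluding
#' itself), with unit diagonal. Pairs with non-positive denominator
#' (isolated pairs) get overlap 0 and are logged.
#'
#' @param A symmetric adjacency matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @return The symmetric TOM with entries in `[0, 1]`.
#' @export
topologicalOverlap <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (min(A) < -1e-12 || max(A) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]")
  A0 <- A
  diag(A0) <- 0
  num <- A0 %*% A0 + A0        # off-diagonal: shared neighbors + direct link
  k <- colSums(A0)
  den <- outer(k, k, pmin) + 1 - A0
  bad <- den <= 0
  diag(bad) <- FALSE
  tom <- num / den
  if (any(bad)) {
    logMsg_(sum(bad) / 2, " isolated pair(s); overlap set to 0")
    tom[bad] <- 0
  }
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Module eigengene of a gene set
#'
#' The eigengene is the first right-singular vector of the gene-standardized
#' (zero mean, unit variance per gene) expression submatrix: a unit-norm
#' per-sample summary of the module. Its sign is chosen so that the
#' correlation with the module's mean standardized profile is non-negative.
#' The fraction of variance explained by the first component is attached as
#' attribute `"varExplained"`.
#'
#' @param ds an [ExpressionDataset-class].
#' @param genes character vector (>= 2) of gene identifiers in `ds`.
#' @return Named numeric vector over samples with attribute `varExplained`.
#' @export
moduleEigengene <- function(ds, genes) {
  stopifnot(length(genes) >= 2)
  m <- exprValues(ds)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("unknown gene(s): ", paste(head(missing, 5), collapse = ", "))
  sub <- m[genes, , drop = FALSE]
  if (any(rowVars_(sub) == 0))
    stop("zero-variance gene in module; cannot standardize")
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 0, nv = min(dim(z)))
  if (sv$d[1] <= 0) stop("rank-0 module submatrix")
  v <- sv$v[, 1]
  profile <- colMeans(z)
  if (sum(v * profile) < 0) v <- -v   # sign convention
  names(v) <- colnames(m)
  attr(v, "varExplained") <- sv$d[1]^2 / sum(sv$d^2)
  v
}

## Compute the eigengene matrix (samples x modules) for an assignment.
eigengeneMatrix_ <- function(ds, assignment) {
  mods <- setdiff(unique(assignment), "unassigned")
  me <- vapply(mods,
               function(md) as.numeric(
                 moduleEigengene(ds, names(assignment)[assignment == md])),
               numeric(ncol(ds)))
  if (length(mods) == 1) me <- matrix(me, ncol = 1)
  dimnames(me) <- list(colnames(ds), mods)
  me
}

#' Detect co-expression modules
#'
#' Full module-detection pipeline: soft-thresholded adjacency
#' ([adjacencyMatrix()]), topological overlap ([topologicalOverlap()]),
#' average-linkage hierarchical clustering of the dissimilarity `1 - TOM`, a
#' static cut at `cutHeightFraction` of the maximal merge height, removal of
#' clusters smaller than `minModuleSize` (their genes become
#' `"unassigned"`), eigengene computation, and iterative merging of module
#' pairs whose eigengene dissimilarity `1 - cor` falls below
#' `mergeDissThreshold` (closest pair first, eigengenes recomputed after
#' every merge, until no pair qualifies). Final modules are labelled
#' `"M1"`, `"M2"`, ... by decreasing size.
#'
#' @param ds a filtered, normalized [ExpressionDataset-class].
#' @param params a [NetworkParams-class].
#' @return A [ModuleDecomposition-class].
#' @export
detectModules <- function(ds, params = networkParams()) {
  m <- exprValues(ds)
  A <- adjacencyMatrix(ds, params)
  tom <- topologicalOverlap(A)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = params@cutHeightFraction * max(hc$height))
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= params@minModuleSize])
  assignment <- setNames(ifelse(cl %in% keep, paste0("C", cl), "unassigned"),
                         rownames(m))
  mergeLog <- data.frame(moduleA = character(), moduleB = character(),
                         dissimilarity = numeric(),
                         stringsAsFactors = FALSE)
  mods <- setdiff(unique(assignment), "unassigned")
  if (length(mods)) {
    me <- eigengeneMatrix_(ds, assignment)
    while (ncol(me) >= 2) {
      d <- 1 - cor(me)
      diag(d) <- Inf
      if (min(d) >= params@mergeDissThreshold) break
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      a <- colnames(me)[ij[1]]
      b <- colnames(me)[ij[2]]
      mergeLog <- rbind(mergeLog,
                        data.frame(moduleA = a, moduleB = b,
                                   dissimilarity = min(d),
                                   stringsAsFactors = FALSE))
      assignment[assignment == b] <- a
      me <- eigengeneMatrix_(ds, assignment)
    }
    ## stable final labels: M1, M2, ... by decreasing size
    sizes <- sort(table(assignment[assignment != "unassigned"]),
                  decreasing = TRUE)
    relabel <- setNames(paste0("M", seq_along(sizes)), names(sizes))
    assignment[assignment != "unassigned"] <-
      relabel[assignment[assignment != "unassigned"]]
    me <- eigengeneMatrix_(ds, assignment)
  } else {
    me <- matrix(numeric(0), nrow = ncol(m), ncol = 0,
                 dimnames = list(colnames(m), NULL))
  }
  methods::new("ModuleDecomposition", assignment = assignment,
               eigengenes = me, mergeLog = mergeLog, params = params)
}

#' Module-trait association statistics
#'
#' Pearson correlation of each module eigengene with a per-sample trait
#' (for two-group designs encode vehicle/treated as 0/1), with p-values from
#' the t-distribution (`t = r * sqrt((n-2)/(1-r^2))`, `n - 2` df) and
#' Bonferroni adjustment over the number of assigned modules. A module is
#' flagged significant when the adjusted p-value is below `alpha`.
#'
#' @param decomp a [ModuleDecomposition-class].
#' @param trait numeric vector, one value per sample.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with columns `module`, `r`, `p`, `p_bonf`,
#'   `significant`.
#' @export
moduleTraitRelationships <- function(decomp, trait, alpha = 0.05) {
  me <- eigengenes(decomp)
  if (!ncol(me))
    return(data.frame(module = character(), r = numeric(), p = numeric(),
                      p_bonf = numeric(), significant = logical()))
  if (length(trait) != nrow(me))
    stop("trait length must equal the sample count")
  if (sd(trait) == 0) stop("constant trait: correlation undefined")
  n <- nrow(me)
  r <- as.numeric(cor(me, trait))
  p <- vapply(r, function(ri) {
    if (abs(ri) >= 1) return(0)
    tt <- ri * sqrt((n - 2) / (1 - ri^2))
    2 * pt(-abs(tt), n - 2)
  }, numeric(1))
  m <- ncol(me)
  pb <- pmin(1, m * p)
  data.frame(module = colnames(me), r = r, p = p, p_bonf = pb,
             significant = pb < alpha, stringsAsFactors = FALSE)
}

#' Gene-set over-representation for a module
#'
#' One-sided hypergeometric upper-tail test of the overlap between a
#' module's genes and each supplied gene set (both intersected with the
#' universe), with Benjamini-Hochberg adjustment across sets.
#'
#' @param moduleGenes character vector of genes, a subset of `universe`.
#' @param geneSets named list of character vectors.
#' @param universe character vector of all considered genes.
#' @return data.frame with columns `set`, `overlap`, `size`, `p`, `p_adj`,
#'   ordered as supplied.
#' @export
moduleEnrichment <- function(moduleGenes, geneSets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (length(setdiff(moduleGenes, universe)))
    stop("moduleGenes must be a subset of the universe")
  moduleGenes <- unique(moduleGenes)
  k <- length(moduleGenes)
  N <- length(universe)
  res <- lapply(names(geneSets), function(nm) {
    s <- intersect(geneSets[[nm]], universe)
    ov <- length(intersect(moduleGenes, s))
    p <- phyper(ov - 1, length(s), N - length(s), k, lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, size = length(s), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return `readGmt`: named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  out
}

#' @rdname readGmt
#' @param geneSets named list of character vectors.
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, "na", geneSets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write module assignment / eigengenes as TSV
#'
#' @param decomp a [ModuleDecomposition-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeModuleAssignment <- function(decomp, path) {
  a <- moduleAssignment(decomp)
  write.table(data.frame(gene = names(a), module = unname(a)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModuleAssignment
#' @export
writeEigengenes <- function(decomp, path) {
  me <- t(eigengenes(decomp))  # modules x samples
  df <- data.frame(module = rownames(me), me, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
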