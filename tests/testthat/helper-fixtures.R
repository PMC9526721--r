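## Shared fixtures and independent oracles.

## Independent tag-KS oracle: scans the empirical CDF of the tag ranks
## against the uniform CDF at every multiple of 1/n, taking the one-sided
## sups with proper left limits. Mechanically distinct from the sorted-rank
## formula used by the implementation.
ksOracle <- function(tagRanks, n) {
  v <- sort(tagRanks)
  t <- length(v)
  ks <- seq_len(n)
  G <- vapply(ks, function(k) sum(v <= k) / t, 0)
  a <- max(G - ks / n)
  Gleft <- c(0, G[-n])
  b <- max(ks / n - Gleft)
  if (a > b) a else -b
}

## Named rank vector over a toy universe.
namedRanks <- function(perm, genes = paste0("g", seq_along(perm))) {
  setNames(as.integer(perm), genes)
}

## Small random ExpressionDataset (two groups).
randomDataset <- function(nGenes = 20, perGroup = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * 2 * perGroup), nGenes, 2 * perGroup,
              dimnames = list(paste0("g", seq_len(nGenes)),
                              paste0("s", seq_len(2 * perGroup))))
  ExpressionDataset(m, rep(c("vehicle", "treated"), each = perGroup))
}

## Dataset from an explicit matrix; groups default to one per column.
matrixDataset <- function(m, groups = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(groups))
    groups <- rep(c("vehicle", "treated"), length.out = ncol(m))
  ExpressionDataset(m, groups)
}

## Partition agreement up to relabeling.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
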