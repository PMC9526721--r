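#' Two-group differential expression
#'
#' Per-gene two-sample t-test between the two sample groups. The default is
#' the pooled-variance Student test; Welch's unequal-variance test is
#' available via `method = "welch"`. Genes whose pooled variance is exactly
#' zero get `t = 0`, `p = 1`. The reported `diff` is mean(treated) -
#' mean(control).
#'
#' @param ds an [ExpressionDataset-class] with exactly two groups, each of
#'   at least 2 samples.
#' @param treated,control group labels; by default `"treated"`/`"vehicle"`
#'   when present, otherwise the alphabetically later/earlier label.
#' @param method `"pooled"` (default) or `"welch"`.
#' @return data.frame with columns `gene`, `diff`, `t`, `p`, `direction`
#'   (`up`/`down`/`none` at `p < 0.005` by default; [buildQuerySignature()]
#'   re-derives direction at its own threshold).
#' @export
differentialExpression <- function(ds, treated = NULL, control = NULL,
                                   method = c("pooled", "welch")) {
  method <- match.arg(method)
  g <- sampleGroups(ds)
  lv <- sort(unique(g))
  if (length(lv) != 2)
    stop("exactly two sample groups are required (got ",
         length(lv), ")")
  if (is.null(treated) || is.null(control)) {
    if (setequal(lv, c("treated", "vehicle"))) {
      treated <- "treated"; control <- "vehicle"
    } else {
      control <- lv[1]; treated <- lv[2]
      logMsg_("groups not named treated/vehicle; using '", control,
              "' as control and '", treated, "' as treated")
    }
  }
  if (!all(c(treated, control) %in% lv))
    stop("groups '", treated, "'/'", control, "' not found")
  m <- exprValues(ds)
  i1 <- which(g == treated)
  i0 <- which(g == control)
  n1 <- length(i1); n0 <- length(i0)
  if (n1 < 2 || n0 < 2) stop("each group needs >= 2 samples")
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m0 <- rowMeans(m[, i0, drop = FALSE])
  v1 <- rowVars_(m[, i1, drop = FALSE])
  v0 <- rowVars_(m[, i0, drop = FALSE])
  diff <- m1 - m0
  if (method == "pooled") {
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- ifelse(se == 0, 0, diff / se)
  p <- ifelse(se == 0, 1, 2 * pt(-abs(t), df))
  direction <- ifelse(p < 0.005 & diff > 0, "up",
                      ifelse(p < 0.005 & diff < 0, "down", "none"))
  data.frame(gene = rownames(m), diff = diff, t = t, p = p,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build an up/down query signature
#'
#' Selects genes with `p < alpha`: positive differences become up tags,
#' negative ones down tags, each list ordered by ascending p-value (ties by
#' input order). Errors if either list ends up empty.
#'
#' @param de a differential-expression table from
#'   [differentialExpression()].
#' @param alpha p-value threshold (default 0.005).
#' @return A [QuerySignature-class].
#' @export
buildQuerySignature <- function(de, alpha = 0.005) {
  stopifnot(all(c("gene", "diff", "p") %in% colnames(de)))
  up <- de[de$p < alpha & de$diff > 0, , drop = FALSE]
  dn <- de[de$p < alpha & de$diff < 0, , drop = FALSE]
  if (!nrow(up) || !nrow(dn))
    stop("empty-signature error: ", if (!nrow(up)) "no up tags"
         else "no down tags", " at alpha = ", alpha,
         "; consider a larger alpha")
  up <- up$gene[order(up$p)]
  dn <- dn$gene[order(dn$p)]
  methods::new("QuerySignature", upTags = up, downTags = dn, alpha = alpha)
}

#' Write / read a query signature as GRP files
#'
#' GRP format: one gene identifier per line, `#`-prefixed comment lines
#' ignored. `writeSignature()` writes `<base>_up.grp` and
#' `<base>_down.grp`; `readSignature()` is its inverse and errors if the
#' two lists overlap or either is empty.
#'
#' @param sig a [QuerySignature-class].
#' @param base output path prefix.
#' @return `writeSignature`: invisibly, the two paths written.
#' @export
writeSignature <- function(sig, base) {
  paths <- paste0(base, c("_up.grp", "_down.grp"))
  writeLines(c(sprintf("# up tags (alpha = %g)", sig@alpha), sig@upTags),
             paths[1])
  writeLines(c(sprintf("# down tags (alpha = %g)", sig@alpha),
               sig@downTags), paths[2])
  invisible(paths)
}

#' @rdname writeSignature
#' @param upPath,downPath GRP file paths.
#' @param alpha threshold to record on the signature (default `NA`).
#' @return `readSignature`: a [QuerySignature-class].
#' @export
readSignature <- function(upPath, downPath, alpha = NA_real_) {
  rd <- function(p) {
    x <- trimws(readLines(p))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  up <- rd(upPath)
  dn <- rd(downPath)
  if (!length(up) || !length(dn))
    stop("empty-signature error: ",
         if (!length(up)) "up" else "down", " tag file is empty")
  if (length(intersect(up, dn)))
    stop("format error: gene(s) present in both tag lists: ",
         paste(head(intersect(up, dn), 5), collapse = ", "))
  methods::new("QuerySignature", upTags = up, downTags = dn, alpha = alpha)
}

#' Write a differential-expression table as TSV
#'
#' @param de table from [differentialExpression()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeDifferentialExpression <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
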