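#' Log-transform RPKM expression with the zero-reset rule
#'
#' Computes `log2(rpkm)` after replacing zero RPKM values by the minimum
#' non-zero RPKM, so no gene drops out of the log scale. The reset minimum is
#' taken per sample by default (each sample's own floor) or globally.
#'
#' @param expr long expression table with columns `gene_id`, `sample_id`,
#'   `rpkm` (non-negative).
#' @param zero_reset `"sample"` (default) or `"global"`: scope of the
#'   minimum non-zero RPKM used to replace zeros.
#' @return The table with added column `log2_expr`.
#' @export
log_expression <- function(expr, zero_reset = c("sample", "global")) {
  zero_reset <- match.arg(zero_reset)
  dt <- as.data.table(expr)
  stopifnot(all(c("gene_id", "sample_id", "rpkm") %in% names(dt)))
  if (any(dt$rpkm < 0, na.rm = TRUE)) stop("RPKM must be non-negative")
  if (zero_reset == "global") {
    nz <- dt$rpkm[dt$rpkm > 0]
    if (length(nz) == 0L) stop("all RPKM values are zero")
    dt[, w := pmax(rpkm, min(nz))]
  } else {
    allzero <- dt[, list(az = all(rpkm == 0)), by = sample_id]
    if (any(allzero$az)) {
      stop("sample(s) with all-zero RPKM: ",
           paste(allzero$sample_id[allzero$az], collapse = ", "))
    }
    dt[, w := pmax(rpkm, min(rpkm[rpkm > 0])), by = sample_id]
  }
  dt[, log2_expr := log2(w)]
  dt[, w := NULL]
  as.data.frame(dt)
}

#' Genes x samples matrix of log2 expression
#'
#' @param expr output of [log_expression()].
#' @param genes optional gene order for the rows.
#' @return Numeric matrix, rows = genes, columns = samples.
#' @export
expression_matrix <- function(expr, genes = NULL) {
  dt <- as.data.table(expr)
  wide <- data.table::dcast(dt, gene_id ~ sample_id, value.var = "log2_expr")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  m
}

.pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2L) return(list(r = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = n))
  }
  list(r = cor(x, y), n = n)
}

#' Methylation-expression Pearson correlation per stage and region/bin
#'
#' For every developmental stage and every region or bin label, computes the
#' Pearson correlation across genes between the stage-level methylation and
#' the stage-level log2 expression, over pairwise-complete genes. A result
#' with fewer than `min_n` genes, or with a constant methylation or
#' expression vector, is reported with `r = NA`; `reliable` flags results
#' with `n >= min_n`.
#'
#' @param stage_meth a `stage_summary` from [stage_average()], or a 3-d array
#'   genes x labels x stages.
#' @param expr_mat genes x stages matrix of log2 expression
#'   ([expression_matrix()]); column names must cover the stages.
#' @param min_n minimum pairwise-complete genes for a reliable estimate
#'   (default 3).
#' @return `data.frame` with columns `stage`, `label`, `r`, `n`, `reliable`.
#' @export
stage_correlation <- function(stage_meth, expr_mat, min_n = 3L) {
  arr <- if (inherits(stage_meth, "stage_summary")) stage_meth$meth
         else stage_meth
  stages <- dimnames(arr)[[3]]
  labels <- dimnames(arr)[[2]]
  genes <- dimnames(arr)[[1]]
  if (!all(stages %in% colnames(expr_mat))) {
    stop("expression matrix lacks stages: ",
         paste(setdiff(stages, colnames(expr_mat)), collapse = ", "))
  }
  common <- intersect(genes, rownames(expr_mat))
  rbindlist(lapply(stages, function(st) {
    e <- expr_mat[common, st]
    rbindlist(lapply(labels, function(lb) {
      p <- .pearson(arr[common, lb, st], e)
      data.table(stage = st, label = lb, r = p$r, n = p$n,
                 reliable = p$n >= min_n)
    }))
  })) |> as.data.frame()
}

#' PCA over promoter-bin correlation profiles
#'
#' Treats each promoter bin as an observation whose features are its
#' methylation-expression correlations across the stages, centres the
#' features and returns the first two principal-component scores with their
#' explained-variance fractions. Bins that behave alike across development
#' (e.g. the TSS-proximal block) land close together. The sign of each
#' component is fixed by making its largest-magnitude loading positive.
#'
#' @param r_mat complete numeric matrix, rows = bins, columns = stages, of
#'   Pearson r values (assemble from [stage_correlation()] output).
#' @return List with `scores` (bins x 2), `var_explained` (length 2),
#'   `loadings` (stages x 2).
#' @export
bin_pca <- function(r_mat) {
  r_mat <- as.matrix(r_mat)
  if (anyNA(r_mat)) {
    stop("correlation matrix has missing cells; impute or drop the ",
         "affected bins/stages before PCA")
  }
  p <- prcomp(r_mat, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  for (j in seq_len(k)) {
    load <- p$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      p$rotation[, j] <- -load
      p$x[, j] <- -p$x[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)],
       loadings = p$rotation[, seq_len(k), drop = FALSE])
}
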