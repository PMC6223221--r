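#' Configuration for the differential-methylation gene filters
#'
#' The four filters applied at promoter bin 1 between two stages (A, e.g.
#' ICM; B, e.g. post-implantation): (i) methylation fold change above
#' `fold_change_min` in the configured `direction` (default: decrease from A
#' to B); (ii) Welch two-sample t-test on the replicate values with
#' `p < p_max`; (iii) the gene's bin-1 methylation at stage A above the
#' cohort mean at stage A; (iv) expression increase from A to B. The `p_max`
#' default of 0.5 mirrors the printed protocol; 0.05 is the conventional
#' choice and can be set explicitly.
#'
#' @param fold_change_min minimum methylation fold change (> 1; default 2).
#' @param p_max t-test p-value cut-off (default 0.5).
#' @param require_above_mean apply filter (iii) (default `TRUE`).
#' @param require_expression_increase apply filter (iv) (default `TRUE`).
#' @param direction `"decrease"` (A high, B low; default) or `"increase"`.
#' @param untestable how genes with fewer than two replicates in either
#'   stage fare on the t-test filter: `"fail"` (default) or `"pass"`.
#' @return List of class `diff_filter_config`.
#' @export
diff_filter_config <- function(fold_change_min = 2, p_max = 0.5,
                               require_above_mean = TRUE,
                               require_expression_increase = TRUE,
                               direction = c("decrease", "increase"),
                               untestable = c("fail", "pass")) {
  if (fold_change_min <= 1) stop("fold_change_min must exceed 1")
  if (p_max <= 0 || p_max > 1) stop("p_max must lie in (0, 1]")
  structure(list(
    fold_change_min = fold_change_min, p_max = p_max,
    require_above_mean = require_above_mean,
    require_expression_increase = require_expression_increase,
    direction = match.arg(direction),
    untestable = match.arg(untestable)
  ), class = "diff_filter_config")
}

.welch_p <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Select differentially methylated genes at promoter bin 1
#'
#' Evaluates the four filters of [diff_filter_config()] for every gene and
#' reports each filter's outcome alongside the overall pass flag. Genes with
#' no replicate methylation data in either stage, or missing expression, get
#' `NA` flags and never pass.
#'
#' @param meth_a,meth_b numeric matrices of bin-1 methylation, genes x
#'   replicates, for stages A and B (same rownames; `NA` for missing
#'   replicates).
#' @param expr_a,expr_b named numeric vectors of stage-level expression
#'   (log2 or RPKM scale; only the direction of change is used).
#' @param cfg a [diff_filter_config()].
#' @return `data.frame` with per-gene means, fold change, Welch p-value, the
#'   four filter flags (`pass_fold`, `pass_ttest`, `pass_mean`, `pass_expr`)
#'   and `pass`.
#' @export
select_diff_genes <- function(meth_a, meth_b, expr_a, expr_b,
                              cfg = diff_filter_config()) {
  stopifnot(inherits(cfg, "diff_filter_config"),
            identical(rownames(meth_a), rownames(meth_b)))
  genes <- rownames(meth_a)
  mean_a <- rowMeans(meth_a, na.rm = TRUE)
  mean_b <- rowMeans(meth_b, na.rm = TRUE)
  mean_a[!is.finite(mean_a)] <- NA
  mean_b[!is.finite(mean_b)] <- NA
  if (cfg$direction == "decrease") {
    hi <- mean_a; lo <- mean_b
  } else {
    hi <- mean_b; lo <- mean_a
  }
  fold <- hi / lo
  pass_fold <- !is.na(hi) & !is.na(lo) & hi > lo & fold > cfg$fold_change_min
  pval <- vapply(seq_along(genes), function(i) {
    .welch_p(meth_a[i, ], meth_b[i, ])
  }, numeric(1))
  pass_ttest <- ifelse(is.na(pval), cfg$untestable == "pass",
                       pval < cfg$p_max)
  cohort_mean <- mean(mean_a, na.rm = TRUE)
  pass_mean <- if (cfg$require_above_mean) {
    !is.na(mean_a) & mean_a > cohort_mean
  } else rep(TRUE, length(genes))
  ea <- expr_a[genes]
  eb <- expr_b[genes]
  pass_expr <- if (cfg$require_expression_increase) {
    !is.na(ea) & !is.na(eb) & eb > ea
  } else rep(TRUE, length(genes))
  complete <- !is.na(mean_a) & !is.na(mean_b)
  pass <- complete & pass_fold & pass_ttest & pass_mean & pass_expr
  data.frame(
    gene_id = genes, mean_a = mean_a, mean_b = mean_b,
    fold_change = fold, p_value = pval,
    pass_fold = pass_fold, pass_ttest = pass_ttest,
    pass_mean = pass_mean, pass_expr = pass_expr, pass = pass,
    row.names = NULL
  )
}

#' Write a plain gene list (one identifier per line)
#'
#' Suitable for upload to external enrichment tools.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(gene_ids, path) {
  writeLines(as.character(gene_ids), path)
  invisible(path)
}
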