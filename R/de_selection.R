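# Benjamini-Hochberg FDR adjustment and differential-expression selection.
#
# Selection uses the thresholds of the source analysis: a modular (absolute)
# linear fold change of at least 1.5 and a BH-adjusted p-value of at most
# 0.01, both inclusive. Figure legends of some studies state the stricter
# |log2FC| >= 1 (linear 2.0) instead; both are exposed as parameters.

#' Construct and validate a differential-expression table
#'
#' A DE table is a plain `data.frame` with one row per feature and columns
#' `feature_id`, `feature_class` (one of `"gene"`, `"miRNA"`, `"lncRNA"`),
#' `log2fc`, `pvalue` and optionally `qvalue`. When `qvalue` is absent it is
#' filled in with [bh_adjust()] applied per feature class.
#'
#' @param feature_id character vector of unique (within class) identifiers.
#' @param feature_class `"gene"`, `"miRNA"` or `"lncRNA"` (recycled).
#' @param log2fc numeric log2 fold changes.
#' @param pvalue raw p-values in `[0, 1]`.
#' @param qvalue optional BH-adjusted p-values; computed when missing.
#' @return a validated `data.frame` of class `de_table`.
#' @export
#' @examples
#' de_table("GENE1", "gene", log2fc = 1.2, pvalue = 0.003)
de_table <- function(feature_id, feature_class, log2fc, pvalue, qvalue = NULL) {
  tab <- data.frame(
    feature_id = as.character(feature_id),
    feature_class = as.character(feature_class),
    log2fc = as.numeric(log2fc),
    pvalue = as.numeric(pvalue),
    stringsAsFactors = FALSE
  )
  if (is.null(qvalue)) {
    tab$qvalue <- rep(NA_real_, nrow(tab))
    for (cl in unique(tab$feature_class)) {
      sel <- tab$feature_class == cl
      tab$qvalue[sel] <- bh_adjust(tab$pvalue[sel])
    }
  } else {
    tab$qvalue <- as.numeric(qvalue)
  }
  validate_de_table(tab)
}

#' @rdname de_table
#' @param tab a data frame with the DE-table columns.
#' @export
validate_de_table <- function(tab) {
  req <- c("feature_id", "feature_class", "log2fc", "pvalue", "qvalue")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    abort_validation(paste0("DE table lacks column(s): ",
                            paste(missing_cols, collapse = ", ")))
  bad_class <- setdiff(unique(tab$feature_class), c("gene", "miRNA", "lncRNA"))
  if (length(bad_class))
    abort_validation(paste0("unknown feature_class value(s): ",
                            paste(bad_class, collapse = ", ")))
  for (col in c("pvalue", "qvalue")) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      abort_validation(sprintf("'%s' outside [0, 1]", col))
  }
  dup <- duplicated(tab[c("feature_class", "feature_id")])
  if (any(dup))
    abort_validation(paste0("duplicate feature_id within a class: ",
                            paste(unique(tab$feature_id[dup]), collapse = ", ")))
  class(tab) <- unique(c("de_table", class(tab)))
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up definition directly: with the `m` non-missing
#' p-values sorted ascending, `q_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1 and mapped back to input order. `NA`/`NaN` p-values are excluded from
#' `m` (silently including them would corrupt the adjustment) and returned
#' as `NA`; when any are present the number dropped is reported via the
#' `"n_dropped"` attribute.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (!is.numeric(pvalues)) abort_validation("p-values must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    abort_validation("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  m <- sum(ok)
  if (m > 0L) {
    p <- pvalues[ok]
    o <- order(p)
    qs <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    qok <- numeric(m)
    qok[o] <- qs
    q[ok] <- qok
  }
  if (any(!ok)) attr(q, "n_dropped") <- sum(!ok)
  q
}

#' Select differentially expressed features
#'
#' Retains rows with modular linear fold change `2^|log2fc| >=
#' fc_linear_min` and `qvalue <= q_max`; both comparisons are inclusive and
#' the fold-change test is performed on the log2 scale to avoid boundary
#' artefacts from `2^x` round-trips. Rows are returned in input order.
#'
#' @param table a [de_table()].
#' @param fc_linear_min minimum modular linear fold change (default 1.5).
#' @param q_max maximum BH-adjusted p-value (default 0.01).
#' @return the retained subset, same class and column layout.
#' @export
select_de <- function(table, fc_linear_min = 1.5, q_max = 0.01) {
  table <- validate_de_table(table)
  stopifnot_scalar_number(fc_linear_min, "fc_linear_min", min = 0)
  if (fc_linear_min <= 0) abort_parameter("'fc_linear_min' must be positive")
  stopifnot_scalar_number(q_max, "q_max", min = 0, max = 1)
  keep <- !is.na(table$log2fc) & !is.na(table$qvalue) &
    abs(table$log2fc) >= log2(fc_linear_min) - 1e-12 &
    table$qvalue <= q_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simple two-group Welch test for synthetic end-to-end runs
#'
#' A convenience per-feature Welch t-test on (already log-scale) expression
#' matrices, for exercising the pipeline on simulated data. It is
#' deliberately not a moderated-statistics (limma/DESeq2) re-implementation
#' and should not be used on real count data.
#'
#' @param x,y numeric matrices (features x replicates) on the log2 scale,
#'   identical rownames.
#' @param feature_class class label for the resulting table.
#' @return a [de_table()] with `log2fc = rowMeans(y) - rowMeans(x)`.
#' @export
two_group_test <- function(x, y, feature_class = "gene") {
  if (!identical(rownames(x), rownames(y)))
    abort_validation("'x' and 'y' must share rownames")
  p <- vapply(seq_len(nrow(x)), function(i) {
    stats::t.test(y[i, ], x[i, ])$p.value
  }, numeric(1))
  de_table(rownames(x), feature_class,
           log2fc = rowMeans(y) - rowMeans(x), pvalue = p)
}
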