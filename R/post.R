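# Downstream surfaces: per-protein standardized expression, hierarchical
# clustering of DE proteins (Pearson dissimilarity, complete linkage) and
# volcano tables.

#' Row-standardize an expression matrix
#'
#' Per-protein z-scores: `(value - row mean) / row sd` (n-1 denominator), the
#' scale on which clustered heatmaps of DE proteins are drawn. Rows with zero
#' sd become all-zero and are flagged.
#'
#' @param x Numeric matrix (proteins x samples), each row with >= 2 values.
#' @return Standardized matrix; accessions of zero-sd rows are attached as
#'   attribute `"constant_rows"`.
#' @export
standardize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x), ncol(x) >= 2L)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  out <- (x - mu) / sd
  constant <- which(sd == 0)
  if (length(constant)) {
    out[constant, ] <- 0
    message(length(constant), " constant row(s) standardized to zero")
  }
  attr(out, "constant_rows") <- rownames(x)[constant] %||% character()
  out
}

#' Hierarchical clustering of proteins
#'
#' Complete-linkage agglomeration on the Pearson dissimilarity
#' `d = 1 - cor` between protein rows. Rows with zero variance have no
#' defined correlation and are excluded with a message. Rows are ordered
#' lexicographically by accession before clustering so that equal-height
#' merges resolve deterministically.
#'
#' @param x Numeric matrix (typically [standardize()]d) with >= 2 rows.
#' @return A `clustering_result`: list with `hclust`, the `standardized`
#'   matrix actually clustered, `leaf_order` (accessions in dendrogram
#'   order), and `excluded` (zero-variance accessions).
#' @export
cluster_proteins <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%04d", seq_len(nrow(x)))
  variances <- apply(x, 1, stats::var)
  excluded <- rownames(x)[variances == 0]
  if (length(excluded)) {
    message(length(excluded), " zero-variance row(s) excluded from clustering")
    x <- x[variances > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("at least 2 non-constant proteins required", call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc, standardized = x,
                 leaf_order = rownames(x)[hc$order], excluded = excluded),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Clustering: %d proteins (%d excluded), complete linkage on 1 - Pearson r\n",
              nrow(x$standardized), length(x$excluded)))
  invisible(x)
}

#' Volcano table for one contrast
#'
#' One row per protein with the log2 difference, signed fold change,
#' -log10 p and the strict threshold flags used by the consensus rule
#' (p strictly below alpha; |FC| strictly above fc_abs).
#'
#' @param results Contrast result table (e.g. one dataset's rows from
#'   [analyze_dataset()]).
#' @param contrast Contrast id, `"short"` or `"long"`.
#' @param dataset Dataset id to plot (default 1).
#' @param thresholds [de_thresholds()].
#' @return Data frame: accession, delta_log2, fc, p, neg_log10_p, pass_p,
#'   pass_fc, candidate (both flags).
#' @export
volcano_table <- function(results, contrast, dataset = 1L,
                          thresholds = de_thresholds()) {
  r <- results[results$contrast == contrast & results$dataset == dataset, ,
               drop = FALSE]
  if (!nrow(r)) stop("no results for that contrast/dataset", call. = FALSE)
  pass_p <- !is.na(r$p) & r$p < thresholds$alpha
  pass_fc <- !is.na(r$fc) & abs(r$fc) > thresholds$fc_abs
  data.frame(accession = r$accession, delta_log2 = r$delta_log2, fc = r$fc,
             p = r$p, neg_log10_p = -log10(r$p),
             pass_p = pass_p, pass_fc = pass_fc,
             candidate = pass_p & pass_fc,
             stringsAsFactors = FALSE, row.names = NULL)
}
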