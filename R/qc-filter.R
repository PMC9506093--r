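#' Per-entity and dataset expression summary
#'
#' For each barcode: total UMIs and number of detected genes (count > 0).
#' Dataset-level: median detected genes per entity and the total number of
#' expressed genes (genes with at least one count in at least one barcode).
#' These are the headline depth statistics that separate whole-cell from
#' single-nucleus libraries: nuclei yield far fewer detected genes per
#' entity at comparable gene totals.
#'
#' @param matrix a [count_matrix()]
#' @return a `qc_summary` list: `per_barcode` (data.frame: barcode,
#'   total_umis, detected_genes), `median_detected_genes`,
#'   `total_expressed_genes`, `n_retained`, `n_removed`, `modality`
#' @export
qc_summarize <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  m <- matrix$counts
  if (nrow(m) == 0) {
    message("qc_summarize: empty matrix, returning empty summary")
    return(new_qc_summary(data.frame(barcode = character(0),
                                     total_umis = numeric(0),
                                     detected_genes = integer(0)),
                          NA_real_, 0L, 0L, 0L, matrix$modality))
  }
  per <- data.frame(barcode = rownames(m),
                    total_umis = Matrix::rowSums(m),
                    detected_genes = Matrix::rowSums(m > 0),
                    row.names = NULL)
  new_qc_summary(per,
                 median_detected = stats::median(per$detected_genes),
                 total_expressed = sum(Matrix::colSums(m) > 0),
                 n_retained = nrow(m), n_removed = 0L,
                 modality = matrix$modality)
}

new_qc_summary <- function(per, median_detected, total_expressed,
                           n_retained, n_removed, modality) {
  structure(list(per_barcode = per,
                 median_detected_genes = median_detected,
                 total_expressed_genes = total_expressed,
                 n_retained = n_retained, n_removed = n_removed,
                 modality = modality),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(paste0("<qc_summary> %d retained, %d removed; median detected ",
                     "genes %s; total expressed genes %d (modality=%s)\n"),
              x$n_retained, x$n_removed,
              format(x$median_detected_genes), x$total_expressed_genes,
              x$modality))
  invisible(x)
}

#' Remove outlier barcodes by a central 95% interval rule
#'
#' Applies a two-sided interval filter on two per-barcode metrics — total
#' UMIs and detected genes. A barcode is removed if either metric falls
#' strictly outside the central `level` interval of that metric's empirical
#' distribution. With `method = "percentile"` (default) the interval is
#' \[(1-level)/2, 1-(1-level)/2\] empirical percentiles with linear
#' interpolation between order statistics; `method = "gaussian"` uses
#' mean +/- z * sd with `z = qnorm(1 - (1-level)/2)`. The percentile rule is
#' the default because per-barcode UMI totals are heavy-tailed and a
#' Gaussian band is dragged by the very outliers it should exclude.
#' Survivor order is preserved.
#'
#' @param matrix a [count_matrix()]
#' @param level central coverage of the kept interval, in (0, 1)
#' @param method `"percentile"` or `"gaussian"`
#' @return list with `matrix` (filtered [count_matrix()]) and `summary`
#'   (a `qc_summary` of the retained barcodes, with `n_removed` set)
#' @examples
#' sim <- simulate_counts(sim_config(n_clusters = 2, cells_per_cluster = 30,
#'                                   n_genes = 80, n_pairs = 0, seed = 7))
#' filt <- filter_outliers(sim$matrix, level = 0.95)
#' filt$summary$n_removed
#' @export
filter_outliers <- function(matrix, level = 0.95,
                            method = c("percentile", "gaussian")) {
  stopifnot(inherits(matrix, "count_matrix"))
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop_config("filter_outliers: level must lie strictly in (0, 1)")
  if (nrow(matrix$counts) == 0)
    stop_format("filter_outliers: empty matrix")
  totals <- Matrix::rowSums(matrix$counts)
  detected <- Matrix::rowSums(matrix$counts > 0)
  keep <- in_central_interval(totals, level, method) &
    in_central_interval(detected, level, method)
  kept <- matrix[which(keep), ]
  summ <- qc_summarize(kept)
  summ$n_removed <- sum(!keep)
  summ$removed_barcodes <- rownames(matrix$counts)[!keep]
  list(matrix = kept, summary = summ)
}

in_central_interval <- function(x, level, method) {
  alpha <- (1 - level) / 2
  if (method == "percentile") {
    b <- percentile(x, c(alpha, 1 - alpha))
  } else {
    z <- stats::qnorm(1 - alpha)
    b <- mean(x) + c(-1, 1) * z * stats::sd(x)
  }
  x >= b[1] & x <= b[2]
}
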