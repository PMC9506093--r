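#' Library-size normalize a count matrix
#'
#' Scales each barcode's counts to sum to `scale` (default 1e4) and applies
#' `log1p` — the standard normalization of single-cell toolkits. Barcodes
#' with zero total counts are left at zero and reported via a message.
#'
#' @param matrix a [count_matrix()]
#' @param scale target per-barcode total on the de-logged scale
#' @return a sparse barcodes x genes matrix of log-normalized expression,
#'   with attribute `norm_scale`
#' @export
normalize_counts <- function(matrix, scale = 1e4) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!is.numeric(scale) || scale <= 0)
    stop_config("normalize_counts: scale must be positive")
  m <- matrix$counts
  totals <- Matrix::rowSums(m)
  zero <- totals == 0
  if (any(zero))
    message("normalize_counts: ", sum(zero),
            " zero-total barcode(s) left at zero")
  fac <- ifelse(zero, 0, scale / totals)
  norm <- Matrix::Diagonal(x = fac) %*% m
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm <- methods::as(norm, "CsparseMatrix")
  attr(norm, "norm_scale") <- scale
  norm
}

#' Per-cluster average expression profile
#'
#' For each cluster, the per-gene mean over its entities of
#' `expm1(normalized expression)` — i.e. averaging happens on the de-logged
#' normalized scale, matching the default behavior of the average-expression
#' utilities in mainstream single-cell toolkits. Set `de_log = FALSE` to
#' average the values as given (used for raw-count averaging: pass the raw
#' counts and `de_log = FALSE`).
#'
#' @param normalized barcodes x genes matrix (output of
#'   [normalize_counts()], or raw counts with `de_log = FALSE`)
#' @param assignment a [cluster_assignment()]
#' @param de_log apply `expm1` before averaging (default TRUE)
#' @return a `cluster_profile`: list with `avg` (genes x clusters dense
#'   matrix), `n_entities` (named vector), `norm_scale`
#' @export
average_by_cluster <- function(normalized, assignment, de_log = TRUE) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  bc <- intersect(rownames(normalized), names(assignment$labels))
  if (length(bc) == 0)
    stop_format("average_by_cluster: no barcode shared between matrix and ",
                "assignment")
  labs <- assignment$labels[bc]
  m <- normalized[bc, , drop = FALSE]
  if (de_log) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- expm1(m@x)
  }
  present <- assignment$cluster_ids[assignment$cluster_ids %in% labs]
  dropped <- setdiff(assignment$cluster_ids, present)
  if (length(dropped))
    warning("average_by_cluster: dropping cluster(s) with no matched ",
            "barcodes: ", paste(dropped, collapse = ", "))
  # cluster indicator / n  gives group means in one sparse product
  fac <- factor(labs, levels = present)
  ind <- Matrix::sparseMatrix(i = as.integer(fac), j = seq_along(labs),
                              x = 1 / tabulate(fac)[as.integer(fac)],
                              dims = c(length(present), length(labs)))
  avg <- t(as.matrix(ind %*% m))
  dimnames(avg) <- list(colnames(normalized), present)
  structure(list(avg = avg,
                 n_entities = stats::setNames(as.integer(table(fac)[present]),
                                              present),
                 norm_scale = attr(normalized, "norm_scale") %||% NA_real_),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf("<cluster_profile> %d genes x %d clusters (entities: %s)\n",
              nrow(x$avg), ncol(x$avg),
              paste(x$n_entities, collapse = ", ")))
  invisible(x)
}

#' Dot-plot statistics per gene and cluster
#'
#' For each requested gene and each cluster: the percentage of entities
#' with a nonzero raw count (`pct_expressing`, the circle size of a marker
#' dot plot) and the mean expression on the log-normalized scale
#' (`mean_expression`, the circle color). Genes absent from the matrix are
#' omitted and listed in the attached `missing` attribute.
#'
#' @param matrix a [count_matrix()] (raw counts; defines "expressing")
#' @param normalized matching output of [normalize_counts()]
#' @param assignment a [cluster_assignment()]
#' @param genes_of_interest character vector of gene ids
#' @return a `dotplot_stat` data.frame: `gene`, `cluster`, `pct_expressing`
#'   in \[0, 100\], `mean_expression`
#' @export
dotplot_stats <- function(matrix, normalized, assignment, genes_of_interest) {
  stopifnot(inherits(matrix, "count_matrix"),
            inherits(assignment, "cluster_assignment"))
  known <- genes_of_interest %in% genes(matrix)
  if (any(!known))
    message("dotplot_stats: omitting ", sum(!known), " unknown gene(s): ",
            paste(utils::head(genes_of_interest[!known], 5), collapse = ", "))
  gg <- genes_of_interest[known]
  bc <- intersect(barcodes(matrix), names(assignment$labels))
  labs <- assignment$labels[bc]
  present <- assignment$cluster_ids[assignment$cluster_ids %in% labs]
  out <- list()
  for (k in present) {
    cells <- bc[labs == k]
    raw <- matrix$counts[cells, gg, drop = FALSE]
    nrm <- normalized[cells, gg, drop = FALSE]
    out[[k]] <- data.frame(
      gene = gg, cluster = k,
      pct_expressing = 100 * Matrix::colSums(raw > 0) / length(cells),
      mean_expression = Matrix::colMeans(nrm),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, missing = genes_of_interest[!known],
            class = c("dotplot_stat", "data.frame"))
}

#' Annotate clusters from marker dot-plot statistics
#'
#' Scores each (cluster, cell type) as the mean over the type's markers of
#' the across-cluster z-score of `mean_expression`; each cluster receives
#' the top-scoring cell type. Markers with zero variance across clusters
#' contribute a z-score of 0. Ties are broken by higher mean
#' `pct_expressing` over the type's markers, then by lexicographic label. A
#' cluster in which every marker gene has zero mean expression is labeled
#' `"unassigned"`.
#'
#' @param stats a [dotplot_stats()] result covering the marker genes
#' @param markers a [marker_table()]
#' @return a `cluster_annotation` data.frame: `cluster`, `cell_type`,
#'   `score`, `n_markers`, plus attribute `scores` (clusters x cell types
#'   score matrix)
#' @export
annotate_clusters <- function(stats, markers) {
  stopifnot(inherits(markers, "marker_table"))
  mk <- markers[markers$gene %in% stats$gene, , drop = FALSE]
  if (nrow(mk) == 0)
    stop_format("annotate_clusters: no marker gene present in stats")
  clusters <- unique(stats$cluster)
  types <- sort(unique(mk$cell_type))
  mean_mat <- stat_matrix(stats, "mean_expression", clusters)
  pct_mat <- stat_matrix(stats, "pct_expressing", clusters)
  zs <- apply(mean_mat, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })                                    # clusters x genes
  score <- matrix(NA_real_, length(clusters), length(types),
                  dimnames = list(clusters, types))
  pct_score <- score
  for (ty in types) {
    gset <- mk$gene[mk$cell_type == ty]
    score[, ty] <- rowMeans(zs[, gset, drop = FALSE])
    pct_score[, ty] <- rowMeans(t(pct_mat[gset, , drop = FALSE]))
  }
  res <- lapply(clusters, function(k) {
    if (all(mean_mat[mk$gene, k] == 0))
      return(data.frame(cluster = k, cell_type = "unassigned",
                        score = NA_real_, n_markers = 0L))
    best <- which(score[k, ] == max(score[k, ]))
    if (length(best) > 1) {
      best <- best[pct_score[k, best] == max(pct_score[k, best])]
      best <- best[order(types[best])][1]   # lexicographic last resort
    }
    ty <- types[best]
    data.frame(cluster = k, cell_type = ty, score = score[k, ty],
               n_markers = sum(mk$cell_type == ty))
  })
  out <- do.call(rbind, res)
  structure(out, scores = score,
            class = c("cluster_annotation", "data.frame"))
}

stat_matrix <- function(stats, col, clusters) {
  genes <- unique(stats$gene)
  m <- matrix(0, length(genes), length(clusters),
              dimnames = list(genes, clusters))
  m[cbind(stats$gene, stats$cluster)] <- stats[[col]]
  m
}

#' Transfer cell-type labels between clusterings via shared barcodes
#'
#' Given a source clustering with cell-type annotations and a target
#' clustering of (a subset of) the same barcodes — e.g. a re-clustering on
#' a restricted gene set — each target cluster receives the majority
#' cell-type label among its barcodes' source annotations, with the
#' majority fraction reported as `purity`. Ties go to the lexicographically
#' smallest label; target clusters sharing no barcode with the source are
#' labeled `"unassigned"` with purity `NA`.
#'
#' @param source_assignment source [cluster_assignment()]
#' @param source_annotation [annotate_clusters()] result for the source
#' @param target_assignment target [cluster_assignment()]
#' @return a `cluster_annotation`-style data.frame: `cluster`, `cell_type`,
#'   `purity`, `n_shared`
#' @export
transfer_labels <- function(source_assignment, source_annotation,
                            target_assignment) {
  stopifnot(inherits(source_assignment, "cluster_assignment"),
            inherits(target_assignment, "cluster_assignment"))
  shared <- intersect(names(source_assignment$labels),
                      names(target_assignment$labels))
  if (length(shared) == 0)
    stop_format("transfer_labels: source and target share no barcode")
  type_of_cluster <- stats::setNames(source_annotation$cell_type,
                                     source_annotation$cluster)
  src_type <- stats::setNames(
    unname(type_of_cluster[source_assignment$labels[shared]]), shared)
  res <- lapply(target_assignment$cluster_ids, function(k) {
    in_k <- shared[target_assignment$labels[shared] == k]
    if (length(in_k) == 0)
      return(data.frame(cluster = k, cell_type = "unassigned",
                        purity = NA_real_, n_shared = 0L))
    tab <- table(src_type[in_k])
    win <- sort(names(tab)[tab == max(tab)])[1]
    data.frame(cluster = k, cell_type = win,
               purity = as.numeric(max(tab)) / length(in_k),
               n_shared = length(in_k))
  })
  out <- do.call(rbind, res)
  structure(out, class = c("cluster_annotation", "data.frame"))
}
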