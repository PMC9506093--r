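#' Null-model configuration
#'
#' @param n_pairs pairs per null replicate; default `NULL` means "match the
#'   size of the true pair table"
#' @param n_draws number of independent null replicates. The original
#'   single-random-set control corresponds to `n_draws = 1`; the default of
#'   25 exposes the null's sampling variability.
#' @param seed integer seed for the pair draws
#' @param exclude_true_pairs drop the true pairs from the sampling space
#'   (default TRUE — a cleaner null)
#' @param gene_universe `"expressed_genes"` (default; genes with nonzero
#'   average in at least one cluster) or `"all_genes"`
#' @return a `null_config` list
#' @export
null_config <- function(n_pairs = NULL, n_draws = 25L, seed = 1L,
                        exclude_true_pairs = TRUE,
                        gene_universe = c("expressed_genes", "all_genes")) {
  if (!is.null(n_pairs) && n_pairs < 1)
    stop_config("null_config: n_pairs must be positive")
  if (n_draws < 1) stop_config("null_config: n_draws must be positive")
  structure(list(n_pairs = n_pairs, n_draws = as.integer(n_draws),
                 seed = as.integer(seed),
                 exclude_true_pairs = isTRUE(exclude_true_pairs),
                 gene_universe = match.arg(gene_universe)),
            class = "null_config")
}

#' Draw replicates of random gene pairs
#'
#' Each replicate is `n_pairs` distinct unordered pairs sampled uniformly
#' without replacement from the universe, excluding self-pairs and (if
#' configured) the true pairs; within-pair order is then randomized so the
#' null is symmetric in the correlation axes. Deterministic under the
#' config seed.
#'
#' @param universe character vector of candidate gene ids
#' @param true_pairs the true `pair_table` (sizes the draw and, optionally,
#'   the exclusion set)
#' @param config a [null_config()]
#' @return list of `pair_table` objects, one per replicate
#' @export
draw_random_pairs <- function(universe, true_pairs, config = null_config()) {
  stopifnot(inherits(config, "null_config"))
  universe <- unique(as.character(universe))
  n_genes <- length(universe)
  n_pairs <- config$n_pairs %||% nrow(true_pairs)
  excluded <- character(0)
  if (config$exclude_true_pairs && nrow(true_pairs) > 0)
    excluded <- unordered_key(match(true_pairs$geneA, universe),
                              match(true_pairs$geneB, universe), n_genes)
  n_available <- n_genes * (n_genes - 1) / 2 - length(unique(excluded))
  if (n_pairs > n_available)
    stop_config("draw_random_pairs: ", n_pairs, " pairs requested but only ",
                n_available, " distinct unordered pairs available")
  set.seed(config$seed)
  lapply(seq_len(config$n_draws), function(rep) {
    chosen <- matrix(integer(0), 0, 2)
    keys <- character(0)
    # rejection sampling; the feasibility check above guarantees progress
    while (length(keys) < n_pairs) {
      need <- n_pairs - length(keys)
      i <- sample.int(n_genes, 2 * need, replace = TRUE)
      j <- sample.int(n_genes, 2 * need, replace = TRUE)
      ok <- i != j
      k <- unordered_key(i[ok], j[ok], n_genes)
      fresh <- !(k %in% keys) & !(k %in% excluded) & !duplicated(k)
      keys <- c(keys, k[fresh])
      chosen <- rbind(chosen, cbind(i[ok][fresh], j[ok][fresh]))
    }
    keep <- seq_len(n_pairs)
    pair_table(universe[chosen[keep, 1]], universe[chosen[keep, 2]],
               source = sprintf("null_replicate_%d", rep))
  })
}

unordered_key <- function(i, j, n) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  paste(lo, hi, sep = "_")
}

#' Run the co-expression pipeline on null replicates
#'
#' Pushes each random-pair replicate through [coexpressed_pairs()] with the
#' *same* configuration as the true analysis — one shared code path — and
#' summarizes the per-cluster null distribution of r and co-expressed-pair
#' counts.
#'
#' @param profile a [average_by_cluster()] result
#' @param replicates list of `pair_table`s from [draw_random_pairs()]
#' @param config a [coexpr_config()] (identical to the true run's)
#' @return a `null_summary`: list with `per_replicate` (data.frame:
#'   `replicate`, `cluster`, `n_coexpressed`, `pearson_r`) and `per_cluster`
#'   (data.frame: `cluster`, `mean_r`, `sd_r`, `min_r`, `max_r`,
#'   `mean_n_coexpressed`, `n_defined`)
#' @export
null_coexpression <- function(profile, replicates, config = coexpr_config()) {
  if (!length(replicates))
    stop_format("null_coexpression: no replicates supplied")
  per_rep <- do.call(rbind, lapply(seq_along(replicates), function(r) {
    res <- coexpressed_pairs(profile, replicates[[r]], config)
    cbind(replicate = r,
          res$per_cluster[, c("cluster", "n_coexpressed", "pearson_r")])
  }))
  agg <- lapply(split(per_rep, per_rep$cluster), function(d) {
    def <- !is.na(d$pearson_r)
    data.frame(cluster = d$cluster[1],
               mean_r = if (any(def)) mean(d$pearson_r[def]) else NA_real_,
               sd_r = if (sum(def) > 1) stats::sd(d$pearson_r[def])
                      else NA_real_,
               min_r = if (any(def)) min(d$pearson_r[def]) else NA_real_,
               max_r = if (any(def)) max(d$pearson_r[def]) else NA_real_,
               mean_n_coexpressed = mean(d$n_coexpressed),
               n_defined = sum(def))
  })
  per_cluster <- do.call(rbind, agg)
  rownames(per_cluster) <- NULL
  structure(list(per_replicate = per_rep, per_cluster = per_cluster),
            class = "null_summary")
}

#' Compare a true co-expression result against its null
#'
#' @param true_result [coexpressed_pairs()] on the true pair table
#' @param null_summary [null_coexpression()] on the random replicates
#' @return data.frame per cluster: `cluster`, `r_true`, `mean_r_null`,
#'   `delta_r` (= r_true - mean_r_null), `n_coexpressed_true`,
#'   `mean_n_coexpressed_null`
#' @export
compare_to_null <- function(true_result, null_summary) {
  stopifnot(inherits(true_result, "pair_coexpr"),
            inherits(null_summary, "null_summary"))
  tr <- true_result$per_cluster
  nl <- null_summary$per_cluster
  m <- merge(tr[, c("cluster", "n_coexpressed", "pearson_r")], nl,
             by = "cluster", sort = FALSE)
  data.frame(cluster = m$cluster, r_true = m$pearson_r,
             mean_r_null = m$mean_r, delta_r = m$pearson_r - m$mean_r,
             n_coexpressed_true = m$n_coexpressed,
             mean_n_coexpressed_null = m$mean_n_coexpressed)
}
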