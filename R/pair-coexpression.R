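#' Co-expression filter configuration
#'
#' @param min_expression minimum per-cluster average expression both genes
#'   of a pair must reach (inclusive) for the pair to count as co-expressed
#'   in that cluster; default 0.15
#' @param pair_order `"as_given"` (default): the pair's first gene is the x
#'   axis of the per-cluster correlation and the second the y axis, exactly
#'   as listed; `"symmetrized"`: within-pair order is canonicalized by
#'   sorting gene ids, making the statistic order-invariant
#' @param mode `"within_cluster"` (default): Pearson r computed within each
#'   cluster across its retained pairs (x = geneA average, y = geneB
#'   average); `"across_clusters"`: per-pair r across clusters — an
#'   alternative reading, not the default
#' @param rounding decimals for reported percentages (half-up)
#' @return a validated `coexpr_config` list
#' @export
coexpr_config <- function(min_expression = 0.15,
                          pair_order = c("as_given", "symmetrized"),
                          mode = c("within_cluster", "across_clusters"),
                          rounding = 1L) {
  if (!is.numeric(min_expression) || min_expression < 0)
    stop_config("coexpr_config: min_expression must be >= 0")
  structure(list(min_expression = min_expression,
                 pair_order = match.arg(pair_order),
                 mode = match.arg(mode),
                 rounding = as.integer(rounding)),
            class = "coexpr_config")
}

#' Per-cluster co-expressed interaction pairs and correlation
#'
#' The pipeline's core statistic. A pair is co-expressed in a cluster iff
#' both genes' per-cluster average expression is at least
#' `min_expression` (inclusive on the boundary). Per cluster, Pearson's r
#' is computed over exactly that cluster's retained pairs, with x the first
#' gene's average and y the second gene's average. Clusters retaining fewer
#' than 2 pairs, or with zero variance on either axis, get `r = NA`
#' (undefined — never imputed as 0). Pair genes missing from the profile
#' are treated as zero expression and reported via a message.
#'
#' @param profile a [average_by_cluster()] result
#' @param pairs a `pair_table`
#' @param config a [coexpr_config()]
#' @return a `pair_coexpr` object: list with `per_cluster` (data.frame:
#'   `cluster`, `n_coexpressed`, `pct_coexpressed`, `pearson_r`),
#'   `retained` (named list of per-cluster retained pair indices),
#'   `n_pairs_total`, `union_count`, `union_pct`, `config`
#' @examples
#' avg <- matrix(c(1, 2, 0.1, 3,  2, 4, 5, 6), 4, 2,
#'               dimnames = list(paste0("g", 1:4), c("c1", "c2")))
#' prof <- structure(list(avg = avg, n_entities = c(c1 = 5, c2 = 5),
#'                        norm_scale = 1e4), class = "cluster_profile")
#' coexpressed_pairs(prof, pair_table(c("g1", "g3"), c("g2", "g4")),
#'                   coexpr_config())
#' @export
coexpressed_pairs <- function(profile, pairs, config = coexpr_config()) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(config, "coexpr_config"))
  if (!inherits(pairs, "pair_table") || nrow(pairs) == 0)
    stop_format("coexpressed_pairs: empty or invalid pair table")
  if (config$pair_order == "symmetrized") {
    swap <- pairs$geneA > pairs$geneB
    tmp <- pairs$geneA[swap]
    pairs$geneA[swap] <- pairs$geneB[swap]
    pairs$geneB[swap] <- tmp
  }
  missing <- setdiff(unique(c(pairs$geneA, pairs$geneB)), rownames(profile$avg))
  if (length(missing))
    message("coexpressed_pairs: ", length(missing),
            " pair gene(s) absent from profile, treated as zero expression")
  clusters <- colnames(profile$avg)
  look <- function(g, k) {
    v <- numeric(length(g))
    hit <- g %in% rownames(profile$avg)
    v[hit] <- profile$avg[g[hit], k]
    v
  }
  retained <- list()
  rows <- lapply(clusters, function(k) {
    xa <- look(pairs$geneA, k)
    xb <- look(pairs$geneB, k)
    keep <- xa >= config$min_expression & xb >= config$min_expression
    retained[[k]] <<- which(keep)
    r <- pearson_or_na(xa[keep], xb[keep])
    data.frame(cluster = k, n_coexpressed = sum(keep),
               pct_coexpressed = round_half_up(100 * sum(keep) / nrow(pairs),
                                               config$rounding),
               pearson_r = r)
  })
  per_cluster <- do.call(rbind, rows)
  if (config$mode == "across_clusters")
    per_cluster <- across_cluster_table(profile, pairs, config, per_cluster)
  union_idx <- sort(unique(unlist(retained)))
  structure(list(per_cluster = per_cluster, retained = retained,
                 n_pairs_total = nrow(pairs),
                 union_count = length(union_idx),
                 union_pct = round_half_up(
                   100 * length(union_idx) / nrow(pairs), config$rounding),
                 config = config),
            class = "pair_coexpr")
}

# per-pair correlation of the two genes' averages across clusters,
# restricted per pair to clusters where the pair passed the filter
across_cluster_table <- function(profile, pairs, config, per_cluster) {
  avg <- profile$avg
  look <- function(g) {
    m <- matrix(0, length(g), ncol(avg))
    hit <- g %in% rownames(avg)
    m[hit, ] <- avg[g[hit], , drop = FALSE]
    m
  }
  xa <- look(pairs$geneA)
  xb <- look(pairs$geneB)
  r <- vapply(seq_len(nrow(pairs)), function(p) {
    keep <- xa[p, ] >= config$min_expression & xb[p, ] >= config$min_expression
    pearson_or_na(xa[p, keep], xb[p, keep])
  }, numeric(1))
  attr(per_cluster, "per_pair_r") <-
    data.frame(geneA = pairs$geneA, geneB = pairs$geneB, pearson_r = r)
  per_cluster
}

pearson_or_na <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' @export
print.pair_coexpr <- function(x, ...) {
  cat(sprintf("<pair_coexpr> %d pairs; union co-expressed %d (%s%%)\n",
              x$n_pairs_total, x$union_count, format(x$union_pct)))
  print(x$per_cluster, row.names = FALSE)
  invisible(x)
}

#' Percentage of a count, rounded half-up
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places —
#' the convention under which 516 of 1752 pairs prints as 29.5%.
#'
#' @param numerator,denominator counts; denominator must be positive
#' @param decimals decimal places
#' @return a number
#' @examples
#' pct(516, 1752)   # 29.5
#' pct(1099, 1752)  # 62.7
#' @export
pct <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop_config("pct: denominator must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Summary table of per-cluster correlations
#'
#' @param result a [coexpressed_pairs()] result
#' @return list with `table` (cluster, n_coexpressed, pearson_r) and
#'   `r_min`, `r_max` over clusters with defined r; empty table with a
#'   warning when no cluster has a defined correlation
#' @export
correlation_summary <- function(result) {
  stopifnot(inherits(result, "pair_coexpr"))
  tab <- result$per_cluster[, c("cluster", "n_coexpressed", "pearson_r")]
  def <- !is.na(tab$pearson_r)
  if (!any(def)) {
    warning("correlation_summary: no cluster has a defined correlation")
    return(list(table = tab[0, ], r_min = NA_real_, r_max = NA_real_))
  }
  list(table = tab,
       r_min = min(tab$pearson_r[def]),
       r_max = max(tab$pearson_r[def]))
}
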