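# Independent dense brute-force implementations used as oracles.
# Deliberately naive: explicit loops, textbook formulas, no shared code with
# the package internals they check.

# Pearson correlation from the raw-sums textbook formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  if (den == 0) return(NA_real_)
  num / den
}

# type-7 quantile by explicit sort + linear interpolation
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# two-metric central-interval survivor set, fully explicit
oracle_qc_keep <- function(dense, level) {
  tot <- rowSums(dense)
  det <- rowSums(dense > 0)
  a <- (1 - level) / 2
  keep <- rep(TRUE, nrow(dense))
  for (m in list(tot, det)) {
    lo <- oracle_quantile(m, a)
    hi <- oracle_quantile(m, 1 - a)
    keep <- keep & m >= lo & m <= hi
  }
  keep
}

oracle_normalize <- function(dense, scale = 1e4) {
  out <- dense
  for (i in seq_len(nrow(dense))) {
    s <- sum(dense[i, ])
    out[i, ] <- if (s == 0) 0 else log1p(dense[i, ] / s * scale)
  }
  out
}

oracle_cluster_avg <- function(norm_dense, labels) {
  cl <- unique(unname(labels[rownames(norm_dense)]))
  avg <- matrix(0, ncol(norm_dense), length(cl),
                dimnames = list(colnames(norm_dense), cl))
  for (k in cl) {
    cells <- rownames(norm_dense)[labels[rownames(norm_dense)] == k]
    for (g in colnames(norm_dense))
      avg[g, k] <- mean(expm1(norm_dense[cells, g]))
  }
  avg
}

oracle_dotplot <- function(raw_dense, norm_dense, labels, gene, cluster) {
  cells <- names(labels)[labels == cluster]
  c(pct = 100 * sum(raw_dense[cells, gene] > 0) / length(cells),
    mean = mean(norm_dense[cells, gene]))
}

# co-expression counts and per-cluster r straight from the definition
oracle_coexpr <- function(avg, pairs, min_expr) {
  clusters <- colnames(avg)
  res <- list()
  union_idx <- integer(0)
  for (k in clusters) {
    keep <- logical(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      a <- if (pairs$geneA[p] %in% rownames(avg)) avg[pairs$geneA[p], k] else 0
      b <- if (pairs$geneB[p] %in% rownames(avg)) avg[pairs$geneB[p], k] else 0
      keep[p] <- a >= min_expr && b >= min_expr
    }
    union_idx <- union(union_idx, which(keep))
    xa <- avg[pairs$geneA[keep], k]
    xb <- avg[pairs$geneB[keep], k]
    res[[k]] <- list(n = sum(keep), r = oracle_pearson(xa, xb))
  }
  list(per_cluster = res, union_count = length(union_idx))
}

# small random fixture: dense counts + cluster labels, no planted structure
random_fixture <- function(seed, n_barcodes = 60, n_genes = 40,
                           n_clusters = 3) {
  set.seed(seed)
  dense <- matrix(rnbinom(n_barcodes * n_genes, mu = 2, size = 1),
                  n_barcodes, n_genes,
                  dimnames = list(sprintf("bc%03d", seq_len(n_barcodes)),
                                  sprintf("g%03d", seq_len(n_genes))))
  labels <- setNames(sample(sprintf("cl%d", seq_len(n_clusters)),
                            n_barcodes, replace = TRUE),
                     rownames(dense))
  list(dense = dense,
       matrix = count_matrix(dense, modality = "cell"),
       assignment = cluster_assignment(labels),
       labels = labels)
}

# tiny simulated dataset for structure-aware tests
tiny_sim <- function(seed = 1, ...) {
  args <- list(n_clusters = 3, cells_per_cluster = 60, n_genes = 300,
               n_pairs = 20, markers_per_cluster = 3, seed = seed)
  args[names(list(...))] <- list(...)
  simulate_counts(do.call(sim_config, args))
}
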