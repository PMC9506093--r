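make_profile <- function(avg) {
  structure(list(avg = avg,
                 n_entities = setNames(rep(10L, ncol(avg)), colnames(avg)),
                 norm_scale = 1e4),
            class = "cluster_profile")
}

test_that("the 0.15 boundary is inclusive and requires both genes", {
  avg <- matrix(c(0.15, 0.15, 0.149, 0.15), 4, 1,
                dimnames = list(paste0("g", 1:4), "c1"))
  pairs <- pair_table(c("g1", "g3"), c("g2", "g4"))
  res <- coexpressed_pairs(make_profile(avg), pairs, coexpr_config())
  expect_equal(res$per_cluster$n_coexpressed, 1L)  # (0.15, 0.15) retained
  expect_equal(res$retained$c1, 1L)                # (0.149, 0.15) is not
})

test_that("all-below-threshold gives union 0 and undefined r everywhere", {
  avg <- matrix(0.1, 4, 2, dimnames = list(paste0("g", 1:4), c("c1", "c2")))
  res <- coexpressed_pairs(make_profile(avg),
                           pair_table(c("g1", "g3"), c("g2", "g4")))
  expect_equal(res$union_count, 0L)
  expect_true(all(is.na(res$per_cluster$pearson_r)))
  expect_equal(res$per_cluster$n_coexpressed, c(0L, 0L))
})

test_that("toy profiles match the brute-force oracle exactly", {
  for (seed in 1:4) {
    set.seed(seed)
    n_genes <- 60
    avg <- matrix(rexp(n_genes * 4, rate = 2), n_genes, 4,
                  dimnames = list(sprintf("g%02d", 1:n_genes),
                                  paste0("c", 1:4)))
    idx <- matrix(sample(n_genes, 100, replace = TRUE), ncol = 2)
    idx <- utils::head(idx[idx[, 1] != idx[, 2], , drop = FALSE], 30)
    pairs <- pair_table(rownames(avg)[idx[, 1]], rownames(avg)[idx[, 2]])
    res <- coexpressed_pairs(make_profile(avg), pairs, coexpr_config())
    oracle <- oracle_coexpr(avg, pairs, 0.15)
    for (k in colnames(avg)) {
      expect_equal(res$per_cluster$n_coexpressed[res$per_cluster$cluster == k],
                   oracle$per_cluster[[k]]$n, info = paste(seed, k))
      expect_equal(res$per_cluster$pearson_r[res$per_cluster$cluster == k],
                   oracle$per_cluster[[k]]$r, tolerance = 1e-12)
    }
    expect_equal(res$union_count, oracle$union_count)
    expect_gte(res$union_count, max(res$per_cluster$n_coexpressed))
  }
})

test_that("missing pair genes count as zero expression", {
  avg <- matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  pairs <- pair_table(c("g1", "g1"), c("g2", "gAbsent"))
  expect_message(res <- coexpressed_pairs(make_profile(avg), pairs),
                 "absent from profile")
  expect_equal(res$per_cluster$n_coexpressed, 1L)
})

test_that("r is undefined (NA), never imputed, for <2 pairs or zero variance", {
  avg <- matrix(c(1, 1, 0.1, 0.1), 4, 1,
                dimnames = list(paste0("g", 1:4), "c1"))
  res <- coexpressed_pairs(make_profile(avg),
                           pair_table(c("g1", "g3"), c("g2", "g4")))
  expect_equal(res$per_cluster$n_coexpressed, 1L)
  expect_true(is.na(res$per_cluster$pearson_r))
  # zero variance on one axis
  avg2 <- matrix(c(1, 1, 1, 2, 1, 3), 3, 2, byrow = FALSE,
                 dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  avg2[] <- c(1, 2, 3, 1, 1, 1)  # c2: all y equal
  rownames(avg2) <- c("x1", "x2", "x3")
  pairs2 <- pair_table(c("x1", "x2"), c("x3", "x3"))
  res2 <- coexpressed_pairs(make_profile(avg2), pairs2)
  expect_true(is.na(res2$per_cluster$pearson_r[
    res2$per_cluster$cluster == "c2"]))
})

test_that("raising min_expression never increases any count", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    avg <- matrix(rexp(50 * 3), 50, 3,
                  dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:3)))
    pairs <- pair_table(sprintf("g%02d", 1:20), sprintf("g%02d", 21:40))
    prev <- NULL
    for (thr in c(0, 0.15, 0.5, 1, 2)) {
      res <- coexpressed_pairs(make_profile(avg), pairs,
                               coexpr_config(min_expression = thr))
      cur <- c(res$per_cluster$n_coexpressed, res$union_count)
      if (!is.null(prev)) expect_true(all(cur <= prev),
                                      info = paste("seed", seed, "thr", thr))
      prev <- cur
    }
  }
})

test_that("within-pair order behaves as documented in both modes", {
  set.seed(5)
  avg <- matrix(runif(30, 0.2, 3), 15, 2,
                dimnames = list(sprintf("g%02d", 1:15), c("c1", "c2")))
  pairs <- pair_table(sprintf("g%02d", 1:7), sprintf("g%02d", 8:14))
  swapped <- pair_table(sprintf("g%02d", 8:14), sprintf("g%02d", 1:7))
  r_orig <- coexpressed_pairs(make_profile(avg), pairs,
                              coexpr_config())$per_cluster$pearson_r
  r_swap <- coexpressed_pairs(make_profile(avg), swapped,
                              coexpr_config())$per_cluster$pearson_r
  # as_given: swapping all pairs swaps the axes; Pearson r is symmetric
  expect_equal(r_swap, r_orig, tolerance = 1e-12)
  # symmetrized mode is invariant by construction
  r_sym1 <- coexpressed_pairs(make_profile(avg), pairs,
                              coexpr_config(pair_order = "symmetrized")
                              )$per_cluster$pearson_r
  r_sym2 <- coexpressed_pairs(make_profile(avg), swapped,
                              coexpr_config(pair_order = "symmetrized")
                              )$per_cluster$pearson_r
  expect_identical(r_sym1, r_sym2)
})

test_that("percentages round half-up as reported", {
  expect_identical(pct(516, 1752, 1), 29.5)
  expect_identical(pct(1099, 1752, 1), 62.7)
  expect_identical(pct(0, 1752, 1), 0)
  expect_identical(pct(1, 8, 0), 13)        # 12.5 rounds up, not to even
  expect_error(pct(1, 0), "denominator")
})

test_that("correlation_summary reports per-cluster r and its range", {
  # affine pairs: geneB average = geneA average + constant -> r exactly 1
  set.seed(6)
  x <- runif(10, 0.5, 2)
  avg <- matrix(c(x, x + 0.3), 20, 1,
                dimnames = list(sprintf("g%02d", 1:20), "c1"))
  pairs <- pair_table(sprintf("g%02d", 1:10), sprintf("g%02d", 11:20))
  res <- coexpressed_pairs(make_profile(avg), pairs)
  s <- correlation_summary(res)
  expect_equal(s$table$pearson_r, 1)
  expect_equal(s$r_min, 1)
  # no defined r anywhere -> empty table with warning
  avg0 <- matrix(0, 20, 1, dimnames = dimnames(avg))
  res0 <- coexpressed_pairs(make_profile(avg0), pairs)
  expect_warning(s0 <- correlation_summary(res0), "no cluster")
  expect_equal(nrow(s0$table), 0L)
})

test_that("across-clusters mode computes per-pair correlations", {
  avg <- matrix(c(1, 2, 3,  2, 4, 6,  5, 5, 5), 3, 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:3)))
  res <- coexpressed_pairs(make_profile(avg), pair_table("gA", "gB"),
                           coexpr_config(mode = "across_clusters"))
  pp <- attr(res$per_cluster, "per_pair_r")
  expect_equal(pp$pearson_r, 1)  # proportional profiles across clusters
})

test_that("empty pair table is an error", {
  avg <- matrix(1, 2, 1, dimnames = list(c("g1", "g2"), "c1"))
  expect_error(coexpressed_pairs(make_profile(avg),
                                 pair_table(character(0), character(0))),
               "empty")
})
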