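test_that("normalization scales, logs, and conserves per-barcode totals", {
  dense <- matrix(c(1L, 1L, 2L), 1, 3,
                  dimnames = list("b1", c("g1", "g2", "g3")))
  norm <- normalize_counts(count_matrix(dense), scale = 4)
  expect_equal(expm1(as.numeric(norm)), c(1, 1, 2))  # already at scale
  fix <- random_fixture(2)
  norm <- normalize_counts(fix$matrix)
  totals <- rowSums(expm1(as.matrix(norm)))
  nonzero <- rowSums(fix$dense) > 0
  expect_equal(unname(totals[nonzero]), rep(1e4, sum(nonzero)))
  expect_equal(as.matrix(norm), oracle_normalize(fix$dense),
               tolerance = 1e-12)
})

test_that("zero-total barcodes stay at zero and are reported", {
  dense <- matrix(c(0L, 0L, 3L, 1L), 2, 2, byrow = TRUE,
                  dimnames = list(c("b1", "b2"), c("g1", "g2")))
  expect_message(norm <- normalize_counts(count_matrix(dense)), "zero-total")
  expect_equal(as.numeric(norm["b1", ]), c(0, 0))
})

test_that("average_by_cluster matches the dense group-mean oracle", {
  fix <- random_fixture(9, n_barcodes = 50, n_genes = 20)
  norm <- normalize_counts(fix$matrix)
  prof <- average_by_cluster(norm, fix$assignment)
  oracle <- oracle_cluster_avg(as.matrix(norm), fix$labels)
  expect_equal(prof$avg[, colnames(oracle)], oracle, tolerance = 1e-12)
  expect_equal(sum(prof$n_entities), 50L)
})

test_that("single-entity and duplicated-profile clusters average trivially", {
  dense <- matrix(c(2L, 0L, 4L,  2L, 0L, 4L,  1L, 1L, 1L), 3, 3, byrow = TRUE,
                  dimnames = list(c("b1", "b2", "b3"), c("g1", "g2", "g3")))
  asn <- cluster_assignment(c(b1 = "X", b2 = "X", b3 = "Y"))
  norm <- normalize_counts(count_matrix(dense), scale = 6)
  prof <- average_by_cluster(norm, asn)
  # two identical entities: cluster average equals the shared profile
  expect_equal(prof$avg[, "X"], expm1(norm["b1", ]))
  # single-entity cluster: average is that entity's profile
  expect_equal(prof$avg[, "Y"], expm1(norm["b3", ]))
})

test_that("cluster averaging is equivariant under relabeling", {
  fix <- random_fixture(10)
  norm <- normalize_counts(fix$matrix)
  p1 <- average_by_cluster(norm, fix$assignment)
  relabel <- setNames(paste0("renamed_", fix$labels), names(fix$labels))
  p2 <- average_by_cluster(norm, cluster_assignment(relabel))
  expect_equal(unname(p2$avg[, paste0("renamed_", colnames(p1$avg))]),
               unname(p1$avg))
})

test_that("restricting to a gene subset leaves those averages unchanged", {
  fix <- random_fixture(11)
  norm <- normalize_counts(fix$matrix)
  full <- average_by_cluster(norm, fix$assignment)
  subset_genes <- colnames(fix$dense)[1:10]
  sub <- average_by_cluster(norm[, subset_genes, drop = FALSE],
                            fix$assignment)
  expect_equal(sub$avg, full$avg[subset_genes, ])
})

test_that("clusters without matched barcodes are dropped with a warning", {
  fix <- random_fixture(12)
  labels <- c(fix$labels, orphan = "ghost_cluster")
  expect_warning(
    prof <- average_by_cluster(normalize_counts(fix$matrix),
                               cluster_assignment(labels)),
    "ghost_cluster")
  expect_false("ghost_cluster" %in% colnames(prof$avg))
  expect_error(average_by_cluster(normalize_counts(fix$matrix),
                                  cluster_assignment(c(zz = "A"))),
               "no barcode shared")
})

test_that("dotplot stats match brute-force counting", {
  fix <- random_fixture(13, n_barcodes = 40, n_genes = 15)
  norm <- normalize_counts(fix$matrix)
  gg <- colnames(fix$dense)[c(1, 5, 9)]
  st <- dotplot_stats(fix$matrix, norm, fix$assignment, gg)
  expect_true(all(st$pct_expressing >= 0 & st$pct_expressing <= 100))
  for (i in seq_len(nrow(st))) {
    o <- oracle_dotplot(fix$dense, as.matrix(norm), fix$labels,
                        st$gene[i], st$cluster[i])
    expect_equal(st$pct_expressing[i], unname(o["pct"]))
    expect_equal(st$mean_expression[i], unname(o["mean"]), tolerance = 1e-12)
  }
})

test_that("dotplot edge cases: absent gene, ubiquitous gene, unknown gene", {
  dense <- matrix(c(0L, 0L, 5L, 3L), 2, 2, byrow = FALSE,
                  dimnames = list(c("b1", "b2"), c("gZero", "gAll")))
  mat <- count_matrix(dense)
  asn <- cluster_assignment(c(b1 = "K", b2 = "K"))
  norm <- normalize_counts(mat)
  expect_message(
    st <- dotplot_stats(mat, norm, asn, c("gZero", "gAll", "gNope")),
    "unknown gene")
  expect_equal(st$pct_expressing[st$gene == "gZero"], 0)
  expect_equal(st$mean_expression[st$gene == "gZero"], 0)
  expect_equal(st$pct_expressing[st$gene == "gAll"], 100)
  expect_identical(attr(st, "missing"), "gNope")
})

test_that("planted markers drive annotation to the ground-truth cell type", {
  sim <- tiny_sim(seed = 21, marker_fold = 10)
  asn <- cluster_assignment(sim$truth$cluster_of)
  norm <- normalize_counts(sim$matrix)
  st <- dotplot_stats(sim$matrix, norm, asn, names(sim$truth$marker_map))
  mk <- marker_table(names(sim$truth$marker_map),
                     unname(sim$truth$marker_map))
  ann <- annotate_clusters(st, mk)
  expect_identical(setNames(ann$cell_type, ann$cluster)[names(sim$truth$cell_type_of)],
                   sim$truth$cell_type_of)
})

test_that("annotation handles single-type and tie cases deterministically", {
  st <- structure(data.frame(gene = c("g1", "g1"), cluster = c("c1", "c2"),
                             pct_expressing = c(50, 50),
                             mean_expression = c(1, 2)),
                  class = c("dotplot_stat", "data.frame"))
  ann <- annotate_clusters(st, marker_table("g1", "only_type"))
  expect_equal(unique(ann$cell_type), "only_type")
  # two cell types with identical marker stats: lexicographic winner
  st2 <- structure(data.frame(gene = rep(c("g1", "g2"), each = 2),
                              cluster = rep(c("c1", "c2"), 2),
                              pct_expressing = 40,
                              mean_expression = rep(c(1, 3), 2)),
                   class = c("dotplot_stat", "data.frame"))
  ann2 <- annotate_clusters(st2, marker_table(c("g1", "g2"),
                                              c("beta", "alpha")))
  expect_equal(unique(ann2$cell_type), "alpha")
})

test_that("clusters whose markers are all silent become 'unassigned'", {
  st <- structure(data.frame(gene = c("g1", "g1"), cluster = c("c1", "c2"),
                             pct_expressing = c(0, 80),
                             mean_expression = c(0, 2)),
                  class = c("dotplot_stat", "data.frame"))
  ann <- annotate_clusters(st, marker_table("g1", "tp"))
  expect_equal(ann$cell_type[ann$cluster == "c1"], "unassigned")
  expect_equal(ann$cell_type[ann$cluster == "c2"], "tp")
})

test_that("label transfer: identity, ties, and disjoint-barcode error", {
  src <- cluster_assignment(setNames(rep(c("s1", "s2"), each = 4),
                                     paste0("b", 1:8)))
  ann <- data.frame(cluster = c("s1", "s2"),
                    cell_type = c("epidermis", "cortex"))
  # identical target: labels carried over with purity 1
  out <- transfer_labels(src, ann, src)
  expect_identical(out$cell_type, c("epidermis", "cortex"))
  expect_equal(out$purity, c(1, 1))
  # target cluster mixing two types equally: documented tie-break + purity 0.5
  tgt <- cluster_assignment(setNames(rep("t1", 8), paste0("b", 1:8)))
  out2 <- transfer_labels(src, ann, tgt)
  expect_equal(out2$cell_type, "cortex")   # lexicographically smallest
  expect_equal(out2$purity, 0.5)
  # unmatched target cluster -> unassigned; fully disjoint -> error
  tgt2 <- cluster_assignment(c(b1 = "t1", zz = "t2"))
  out3 <- transfer_labels(src, ann, tgt2)
  expect_equal(out3$cell_type[out3$cluster == "t2"], "unassigned")
  expect_error(transfer_labels(src, ann,
                               cluster_assignment(c(q1 = "x"))),
               "share no barcode")
})
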