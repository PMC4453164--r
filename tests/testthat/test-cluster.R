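# Gene filter, dZ distances, complete-linkage agglomeration (vs brute
# force and stats::hclust), similarity cut and tree export.

make_scores <- function(z_chtog_pm, z_chtog_mp = NULL, n = NULL) {
  n <- n %||% length(z_chtog_pm)
  z_chtog_mp <- z_chtog_mp %||% rep(0, n)
  genes <- paste0("G", seq_len(n))
  do.call(rbind, lapply(seq_along(DZ <- c("pct_multipolar", "mean_poles",
                                          "n_cells", "mitotic_index",
                                          "pct_multinucleate")),
                        function(i) {
    zc <- switch(DZ[i], pct_multipolar = z_chtog_pm,
                 mean_poles = z_chtog_mp, rep(0.1, n))
    data.frame(gene = genes, feature = DZ[i], z_ns = seq_len(n) / 10,
               z_chtog = zc, dz = seq_len(n) / 10 - zc,
               stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the inclusion filter applies |Z_chTOG| > 1 strictly on either feature", {
  sc <- make_scores(c(1.2, 0.5, -1.0, 0.2),
                    z_chtog_mp = c(0, 0.5, 0, 1.01))
  m <- filter_genes(sc)
  expect_setequal(rownames(m), c("G1", "G4"))   # G3 at -1.0 exactly: dropped
  expect_identical(colnames(m), c("pct_multipolar", "mean_poles",
                                  "n_cells", "mitotic_index",
                                  "pct_multinucleate"))
  expect_error(filter_genes(make_scores(c(0.2, 0.3))), "no gene")
})

test_that("uncentred Pearson and city-block distances match their formulas", {
  m <- rbind(a = c(1, 2, 0, 0, 0), b = c(2, 4, 0, 0, 0),
             c = c(0, 0, 3, 0, 0))
  d <- pairwise_distance(m, "uncentred_pearson")
  expect_equal(d["a", "b"], 0)        # proportional rows: similarity 1
  expect_equal(d["a", "c"], 1)        # orthogonal rows: similarity 0
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  # 3-gene hand oracle
  m2 <- rbind(x = c(1, 1, 1, 0, 0), y = c(1, -1, 0, 2, 0),
              z = c(0.5, 0.2, -3, 1, 1))
  d2 <- pairwise_distance(m2, "uncentred_pearson")
  hand <- function(u, v) 1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  expect_equal(d2["x", "y"], hand(m2[1, ], m2[2, ]))
  expect_equal(d2["x", "z"], hand(m2[1, ], m2[3, ]))
  expect_equal(d2["y", "z"], hand(m2[2, ], m2[3, ]))
  dc <- pairwise_distance(m2, "cityblock")
  expect_equal(dc["x", "y"], sum(abs(m2[1, ] - m2[2, ])))
  # all-zero row is undefined under uncentred Pearson
  expect_error(pairwise_distance(rbind(a = rep(0, 5), b = 1:5)),
               "all-zero")
})

test_that("complete linkage matches exhaustive agglomeration for n <= 8", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(paste0("g", 1:n), NULL))
    metric <- sample(c("uncentred_pearson", "cityblock"), 1)
    d <- pairwise_distance(m, metric)
    tree <- cluster_complete(d)
    oracle <- oracle_complete_linkage(d)
    expect_equal(tree$height, oracle$heights, tolerance = 1e-12)
    # final partitions at several cuts agree
    for (h in quantile(tree$height, c(0.25, 0.5, 0.9))) {
      got <- partition_from_assignments(
        cut_clusters(tree, h, mode = "distance")$assignments)
      expect_identical(got, oracle_cut(d, h))
    }
  }
})

test_that("complete-linkage heights agree with stats::hclust on tie-free data", {
  set.seed(23)
  m <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("g", 1:12), NULL))
  d <- pairwise_distance(m, "cityblock")
  tree <- cluster_complete(d)
  hc <- hclust(as.dist(d), method = "complete")
  expect_equal(sort(tree$height), sort(hc$height), tolerance = 1e-12)
})

test_that("two genes merge at their distance; duplicates merge at height zero first", {
  m <- rbind(a = c(1, 0, 0, 0, 0), b = c(0, 1, 1, 0, 0))
  tree <- cluster_complete(pairwise_distance(m, "cityblock"))
  expect_equal(tree$height, 3)
  m2 <- rbind(a = c(1, 2, 0, 1, 0), b = c(1, 2, 0, 1, 0),
              c = c(5, 5, 5, 5, 5))
  tree2 <- cluster_complete(pairwise_distance(m2, "cityblock"))
  expect_equal(tree2$height[1], 0)
  expect_identical(sort(tree2$merge[1, ]), c(-2L, -1L))
})

test_that("the similarity cut behaves at its extremes and on constructed groups", {
  set.seed(3)
  # two tight groups: within-similarity > 0.9, between < 0.3
  g1 <- t(replicate(3, c(5, 4, 3, 0, 0) + rnorm(5, 0, 0.1)))
  g2 <- t(replicate(3, c(-4, 5, -3, 1, 0) + rnorm(5, 0, 0.1)))
  m <- rbind(g1, g2)
  rownames(m) <- paste0("g", 1:6)
  sim <- 1 - pairwise_distance(m, "uncentred_pearson")
  expect_true(all(sim[1:3, 1:3] > 0.9) && all(sim[4:6, 4:6] > 0.9))
  expect_true(all(sim[1:3, 4:6] < 0.3))
  tree <- cluster_complete(pairwise_distance(m, "uncentred_pearson"))
  cl <- cut_clusters(tree, 0.7)
  expect_equal(cl$n_clusters, 2)
  expect_equal(unname(cl$assignments), c(1, 1, 1, 2, 2, 2))
  # cut at similarity 1: all singletons (no exact duplicates here)
  expect_equal(cut_clusters(tree, 1)$n_clusters, 6)
  # cut at similarity 0 keeps clusters whose merges stay below distance 1;
  # anti-correlated groups (distance > 1) remain separate
  expect_equal(cut_clusters(tree, 0)$n_clusters, 2)
  expect_error(cut_clusters(tree, 1.4), "\\[0, 1\\]")
})

test_that("raising the similarity cut never merges separate clusters", {
  set.seed(29)
  m <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("g", 1:10), NULL))
  tree <- cluster_complete(pairwise_distance(m, "uncentred_pearson"))
  cuts <- seq(0, 1, by = 0.1)
  prev <- NULL
  for (ct in cuts) {
    ids <- cut_clusters(tree, ct)$assignments
    if (!is.null(prev)) {
      # refinement: genes separated at the lower cut stay separated
      for (i in 1:9) for (j in (i + 1):10)
        if (prev[i] != prev[j]) expect_true(ids[i] != ids[j])
    }
    prev <- ids
  }
})

test_that("permuting gene order changes labels only, never the partition", {
  set.seed(31)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8), NULL))
  cl <- cut_clusters(cluster_complete(pairwise_distance(m)), 0.7)
  perm <- sample(8)
  clp <- cut_clusters(cluster_complete(pairwise_distance(m[perm, ])), 0.7)
  for (i in 1:7) for (j in (i + 1):8) {
    g_i <- rownames(m)[i]; g_j <- rownames(m)[j]
    expect_equal(cl$assignments[g_i] == cl$assignments[g_j],
                 clp$assignments[g_i] == clp$assignments[g_j],
                 ignore_attr = TRUE)
  }
})

test_that("CDT/GTR/Newick export is structurally sound and round-trips", {
  m <- rbind(a = c(1, 2, 0, 1, 0), b = c(2, 1, 0, 0, 1))
  colnames(m) <- c("pct_multipolar", "mean_poles", "n_cells",
                   "mitotic_index", "pct_multinucleate")
  tree <- cluster_complete(pairwise_distance(m))
  dir <- withr::local_tempdir()
  paths <- export_tree(tree, m, dir)
  cdt <- readLines(paths["cdt"])
  expect_length(cdt, 4)            # header + EWEIGHT + 2 gene rows
  gtr <- readLines(paths["gtr"])
  expect_length(gtr, 1)            # single merge node
  expect_match(gtr, "^NODE1X\tGENE")
  expect_equal(read_cdt(paths["cdt"])[rownames(m), ], m)
  # Newick leaves are exactly the gene set
  phy <- ape::read.tree(paths["nwk"])
  expect_setequal(phy$tip.label, rownames(m))
  m8 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("g", 1:8), colnames(m)))
  t8 <- cluster_complete(pairwise_distance(m8))
  p8 <- export_tree(t8, m8, dir, "eight")
  expect_equal(read_cdt(p8["cdt"])[rownames(m8), ], m8)
  expect_setequal(ape::read.tree(p8["nwk"])$tip.label, rownames(m8))
})
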