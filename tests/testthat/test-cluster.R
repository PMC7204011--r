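make_blob_matrix <- function(sizes, within, between, seed = 1L) {
  set.seed(seed)
  ids <- unlist(Map(function(b, s) sprintf("b%d_%02d", b, seq_len(s)),
                    seq_along(sizes), sizes))
  lab <- rep(seq_along(sizes), sizes)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    base <- if (lab[i] == lab[j]) within else between
    d[i, j] <- d[j, i] <- min(1, max(0, base + runif(1L, -0.03, 0.03)))
  }
  list(d = d, labels = setNames(sprintf("g%d", lab), ids))
}

test_that("pairwise distance matrix is symmetric and matches batch output", {
  p <- rand_plot(40L, 20L, seed = 1L)
  same <- list(a = p, b = p, c = p)
  expect_true(all(pairwiseMatrix(same) == 0))
  plots <- list(x = rand_plot(40L, 18L, seed = 2L),
                y = rand_plot(52L, 22L, seed = 3L),
                z = rand_plot(47L, 15L, seed = 4L))
  d <- pairwiseMatrix(plots)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 3L), names(plots)))
  tab <- compareBatch(plots)
  for (r in seq_len(nrow(tab)))
    expect_equal(d[tab$id_a[r], tab$id_b[r]], tab$jd[r])
})

test_that("planted blobs are recovered at mid heights under every linkage", {
  blob <- make_blob_matrix(c(6L, 6L), within = 0.1, between = 0.9)
  for (lk in c("mcquitty", "average", "complete", "single", "ward")) {
    hc <- hierarchicalClusters(blob$d, linkage = lk, cutLevels = 50L,
                               labels = blob$labels)
    mid <- which.min(abs(hc$levels$height - 0.5))
    a <- hc$assignments[, mid]
    expect_equal(length(unique(a)), 2L, label = lk)
    expect_equal(unname(clusterPurity(a, blob$labels)$purity), 1,
                 label = lk)
  }
  expect_error(hierarchicalClusters(blob$d, linkage = "nosuch"),
               "unknown linkage")
})

test_that("WPGMA linkage update matches the hand-computed merge", {
  d <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.8,
                0.8, 0.8, 0), 3L, 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- hierarchicalClusters(d, linkage = "mcquitty", cutLevels = 5L)
  # first merge {A,B} at 0.2; WPGMA distance of {A,B} to C = (0.8+0.8)/2
  expect_equal(hc$tree$height, c(0.2, 0.8))
  expect_equal(sort(hc$tree$labels[-hc$tree$merge[1L, ]]), c("A", "B"))
})

test_that("single chains and permutations are handled", {
  d1 <- matrix(0, 1L, 1L, dimnames = list("only", "only"))
  hc1 <- hierarchicalClusters(d1, cutLevels = 3L)
  expect_equal(unname(hc1$assignments[1L, ]), rep(1L, 3L))
  blob <- make_blob_matrix(c(5L, 5L), 0.1, 0.9, seed = 2L)
  perm <- sample(rownames(blob$d))
  hcA <- hierarchicalClusters(blob$d, cutLevels = 20L)
  hcB <- hierarchicalClusters(blob$d[perm, perm], cutLevels = 20L)
  mid <- 10L
  aA <- hcA$assignments[perm, mid]
  aB <- hcB$assignments[perm, mid]
  # same partition up to relabeling
  expect_equal(length(unique(paste(aA, aB))), length(unique(aA)))
})

test_that("top-k sparsification keeps complete small graphs and hub spokes", {
  blob <- make_blob_matrix(c(5L), 0.2, 0.2, seed = 3L)
  sim <- 1 - blob$d; diag(sim) <- 0
  g <- sparsifyTopK(sim, k = 4L)
  expect_equal(igraph::ecount(g), 10L)  # complete on 5 nodes, unchanged
  # hub similar to 10 spokes; spokes dissimilar to each other
  ids <- c("hub", sprintf("s%02d", 1:10))
  sim2 <- matrix(0, 11L, 11L, dimnames = list(ids, ids))
  sim2["hub", -1L] <- sim2[-1L, "hub"] <- seq(0.5, 0.95, length.out = 10L)
  g2 <- sparsifyTopK(sim2, k = 2L)
  # union rule: the hub keeps its top-2 but every spoke retains the hub
  expect_equal(igraph::ecount(g2), 10L)
  expect_equal(unname(igraph::degree(g2, "hub")), 10L)
  # with k at least n-1 the dense graph is reproduced exactly
  gAll <- sparsifyTopK(sim, k = 1400L)
  expect_equal(igraph::ecount(gAll), sum(sim[upper.tri(sim)] > 0))
})

test_that("Markov clustering separates disconnected cliques and planted blocks", {
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  adj <- matrix(0, 10L, 10L, dimnames = list(ids, ids))
  adj[1:5, 1:5] <- 0.8; adj[6:10, 6:10] <- 0.8; diag(adj) <- 0
  for (infl in c(1.5, 2)) {
    res <- mclCluster(adj, inflation = infl)
    expect_equal(length(unique(res$assignment)), 2L)
    expect_equal(length(unique(res$assignment[1:5])), 1L)
    expect_true(res$converged)
  }
  blob <- make_blob_matrix(c(6L, 6L, 6L), 0.2, 0.95, seed = 4L)
  sim <- 1 - blob$d; diag(sim) <- 0
  res3 <- mclCluster(sim)
  expect_equal(length(unique(res3$assignment)), 3L)
  expect_equal(unname(clusterPurity(res3$assignment, blob$labels)$purity), 1)
})

test_that("clusters of four or fewer members are flagged singleton", {
  ids <- sprintf("c%d", 1:4)
  adj <- matrix(0.7, 4L, 4L, dimnames = list(ids, ids)); diag(adj) <- 0
  res <- mclCluster(adj)
  expect_equal(length(unique(res$assignment)), 1L)
  expect_true(all(res$singleton))
})

test_that("MCL on a disjoint union equals the union of component results", {
  blobA <- make_blob_matrix(c(5L), 0.2, 0.2, seed = 5L)
  blobB <- make_blob_matrix(c(6L), 0.25, 0.25, seed = 6L)
  simA <- 1 - blobA$d; diag(simA) <- 0
  rownames(simA) <- colnames(simA) <- sprintf("A%d", 1:5)
  simB <- 1 - blobB$d; diag(simB) <- 0
  rownames(simB) <- colnames(simB) <- sprintf("B%d", 1:6)
  both <- matrix(0, 11L, 11L,
                 dimnames = list(c(rownames(simA), rownames(simB)),
                                 c(rownames(simA), rownames(simB))))
  both[1:5, 1:5] <- simA; both[6:11, 6:11] <- simB
  resU <- mclCluster(both)
  resA <- mclCluster(simA); resB <- mclCluster(simB)
  # partition restricted to each component matches the standalone result
  expect_equal(length(unique(resU$assignment[1:5])),
               length(unique(resA$assignment)))
  expect_equal(length(unique(resU$assignment[6:11])),
               length(unique(resB$assignment)))
  expect_equal(length(unique(resU$assignment)),
               length(unique(resA$assignment)) +
                 length(unique(resB$assignment)))
})

test_that("medoids minimize total intra-cluster distance deterministically", {
  blob <- make_blob_matrix(c(7L), 0.3, 0.3, seed = 7L)
  d <- blob$d
  expect_equal(findMedoid("b1_03", d), "b1_03")
  med <- findMedoid(rownames(d), d)
  expect_equal(med, rownames(d)[which.min(rowSums(d))])
  expect_true(all(rowSums(d)[med] <= rowSums(d)))
  # hand-built: center equidistant, others far apart
  d3 <- matrix(c(0, 1, 0.4, 1, 0, 0.4, 0.4, 0.4, 0), 3L, 3L,
               dimnames = list(c("p", "q", "ctr"), c("p", "q", "ctr")))
  expect_equal(findMedoid(c("p", "q", "ctr"), d3), "ctr")
})

test_that("cluster tables report membership, medoids, and singleton flags", {
  blob <- make_blob_matrix(c(6L, 3L), 0.1, 0.9, seed = 8L)
  hc <- hierarchicalClusters(blob$d, cutLevels = 20L)
  a <- hc$assignments[, 10L]
  tab <- clusterTable(a, blob$d)
  expect_equal(nrow(tab), 9L)
  expect_equal(sum(tab$is_medoid), length(unique(a)))
  expect_true(all(tab$singleton == (tab$cluster_size <= 4L)))
})
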