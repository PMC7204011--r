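# Clustering of fingerprint collections: dense hierarchical clustering for
# curated sets, sparsified Markov clustering for large sets.

#' Pairwise Jaccard distance matrix
#'
#' Slide-compares all unordered pairs and assembles the symmetric J_D
#' matrix (diagonal 0).
#'
#' @param plots named list of [DotPlot] objects
#' @return symmetric numeric matrix with dimnames = plot ids
#' @export
pairwiseMatrix <- function(plots) {
  .check_plot_list(plots)
  ids <- names(plots)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  tab <- compareBatch(plots)
  d[cbind(tab$id_a, tab$id_b)] <- tab$jd
  d[cbind(tab$id_b, tab$id_a)] <- tab$jd
  d
}

.linkage_method <- function(linkage) {
  map <- c(mcquitty = "mcquitty", wpgma = "mcquitty", average = "average",
           upgma = "average", complete = "complete", single = "single",
           ward = "ward.D2", ward.D2 = "ward.D2")
  m <- map[tolower(linkage)]
  if (is.na(m))
    stop("unknown linkage '", linkage, "'; use one of ",
         paste(unique(names(map)), collapse = ", "), call. = FALSE)
  unname(m)
}

#' Hierarchical clustering of a fingerprint distance matrix
#'
#' Agglomerative clustering under the named linkage. McQuitty (WPGMA) is
#' the default: when two clusters merge, the new cluster's distance to any
#' other cluster is the unweighted mean of the two merged clusters'
#' distances to it. The dendrogram is cut at \code{cutLevels} evenly spaced
#' heights; when reference labels are supplied each level also reports
#' purity (the fraction of clusters whose members all share one label) and
#' the member-weighted majority-label fraction.
#'
#' @param d symmetric distance matrix (e.g. from [pairwiseMatrix]) or a
#'   \code{dist} object
#' @param linkage one of mcquitty/wpgma, average/upgma, complete, single,
#'   ward
#' @param cutLevels number of evenly spaced cut heights (default 50)
#' @param labels optional named reference labels (chain id -> group) for
#'   purity scoring
#' @return list with \code{tree} (an \code{hclust}), \code{assignments}
#'   (matrix: chains x levels), and \code{levels} (data.frame: height,
#'   nClusters, and purity columns when labels are given)
#' @export
hierarchicalClusters <- function(d, linkage = "mcquitty", cutLevels = 50L,
                                 labels = NULL) {
  cutLevels <- .assert_scalar_int(cutLevels, "cutLevels", min = 1L)
  if (is.matrix(d) && nrow(d) == 1L) {
    # a single chain is one trivial cluster at every level
    assignments <- matrix(1L, 1L, cutLevels,
                          dimnames = list(rownames(d),
                                          sprintf("h%03d", seq_len(cutLevels))))
    lv <- data.frame(height = rep(0, cutLevels), nClusters = 1L)
    if (!is.null(labels)) { lv$purity <- 1; lv$majorityFraction <- 1 }
    return(list(tree = NULL, assignments = assignments, levels = lv))
  }
  if (!inherits(d, "dist")) {
    if (!is.matrix(d) || nrow(d) != ncol(d) || !isSymmetric(unname(d)))
      stop("'d' must be a symmetric matrix or a dist object", call. = FALSE)
    d <- stats::as.dist(d)
  }
  tree <- stats::hclust(d, method = .linkage_method(linkage))
  heights <- seq(0, max(tree$height), length.out = cutLevels)
  assignments <- vapply(heights, function(h) stats::cutree(tree, h = h),
                        integer(attr(d, "Size")))
  rownames(assignments) <- tree$labels
  colnames(assignments) <- sprintf("h%03d", seq_along(heights))
  lv <- data.frame(height = heights,
                   nClusters = apply(assignments, 2L, function(a)
                     length(unique(a))))
  if (!is.null(labels)) {
    pur <- t(apply(assignments, 2L, function(a)
      unlist(clusterPurity(a, labels))))
    lv <- cbind(lv, pur)
  }
  list(tree = tree, assignments = assignments, levels = lv)
}

#' Purity of a clustering against reference labels
#'
#' @param assignment named cluster ids (chain id -> cluster)
#' @param labels named reference labels (chain id -> group)
#' @return list with \code{purity} (fraction of clusters whose members all
#'   share one label) and \code{majorityFraction} (member-weighted mean of
#'   each cluster's majority-label fraction)
#' @export
clusterPurity <- function(assignment, labels) {
  ids <- names(assignment)
  if (is.null(ids) || !all(ids %in% names(labels)))
    stop("every assigned chain needs a reference label", call. = FALSE)
  byCluster <- split(labels[ids], assignment)
  pure <- vapply(byCluster, function(l) length(unique(l)) == 1L, logical(1L))
  majo <- vapply(byCluster, function(l) max(table(l)) / length(l), numeric(1L))
  size <- lengths(byCluster)
  list(purity = mean(pure),
       majorityFraction = sum(majo * size) / sum(size))
}

#' Sparsify a similarity matrix by top-k neighbors
#'
#' For each chain only its \code{k} largest-similarity edges are retained
#' as candidates; the candidate sets are then union-symmetrized (an edge
#' survives if either endpoint retained it), so strong one-sided neighbors
#' are never lost. Zero-similarity pairs and self-pairs are never stored.
#'
#' @param sim symmetric J_X similarity matrix with dimnames
#' @param k neighbors kept per chain before symmetrization (default 1400)
#' @return an undirected weighted \code{igraph} graph; edge attribute
#'   \code{weight} holds J_X
#' @export
sparsifyTopK <- function(sim, k = 1400L) {
  k <- .assert_scalar_int(k, "k", min = 1L)
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) || is.null(rownames(sim)))
    stop("'sim' must be a square matrix with dimnames", call. = FALSE)
  n <- nrow(sim)
  ids <- rownames(sim)
  keep <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    w <- sim[v, ]
    w[v] <- -Inf
    cand <- which(w > 0)
    if (length(cand) > k)
      cand <- cand[order(w[cand], decreasing = TRUE)[seq_len(k)]]
    keep[v, cand] <- TRUE
  }
  keep <- keep | t(keep)  # union symmetrization
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  e <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[e[, 1L]], to = ids[e[, 2L]],
               weight = sim[e]),
    directed = FALSE, vertices = ids)
  g
}

#' Markov clustering of a similarity graph
#'
#' Desk-scale MCL: the weighted adjacency matrix (with unit self-loops, the
#' standard regularization that prevents period-two oscillation) is column
#' normalized, then expansion (matrix squaring) and inflation (element-wise
#' power \code{inflation} followed by column renormalization) alternate
#' until the matrix changes by less than \code{tol}, entries below 1e-12
#' being pruned each sweep. Clusters are the connected components of the
#' converged matrix's support. Clusters of 4 or fewer members are flagged
#' as singletons.
#'
#' @param graph weighted undirected \code{igraph} graph (e.g. from
#'   [sparsifyTopK]) or a symmetric similarity matrix with dimnames
#' @param inflation inflation exponent (default 2.0, the MCL convention)
#' @param maxIter iteration cap (default 100)
#' @param tol convergence threshold on the max absolute change
#' @return list with \code{assignment} (named cluster ids, clusters
#'   numbered by decreasing size), \code{sizes}, \code{singleton} (logical
#'   per cluster, size <= 4), \code{converged}, \code{iterations}
#' @export
mclCluster <- function(graph, inflation = 2.0, maxIter = 100L, tol = 1e-6) {
  if (inflation <= 1) stop("'inflation' must exceed 1", call. = FALSE)
  if (methods::is(graph, "igraph")) {
    a <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  } else if (is.matrix(graph) && isSymmetric(unname(graph))) {
    a <- graph
  } else stop("'graph' must be an igraph graph or symmetric matrix",
              call. = FALSE)
  if (nrow(a) == 0L) stop("empty graph", call. = FALSE)
  ids <- rownames(a)
  diag(a) <- pmax(diag(a), 1)
  m <- sweep(a, 2L, colSums(a), "/")
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    m2 <- m %*% m          # expansion
    m2 <- m2^inflation     # inflation
    m2[m2 < 1e-12] <- 0
    m2 <- sweep(m2, 2L, colSums(m2), "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", maxIter,
            " iterations; returning best-effort clustering")
  support <- (m > 1e-6) | t(m > 1e-6)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    support, mode = "undirected", diag = FALSE))$membership
  # renumber clusters by decreasing size, ties by first member id
  sizes <- table(comp)
  ord <- order(-as.integer(sizes),
               vapply(split(ids, comp), min, character(1L))[names(sizes)])
  renum <- stats::setNames(seq_along(ord), names(sizes)[ord])
  assignment <- stats::setNames(as.integer(renum[as.character(comp)]), ids)
  sizes <- table(assignment)
  list(assignment = assignment,
       sizes = as.integer(sizes),
       singleton = as.integer(sizes) <= 4L,
       converged = converged, iterations = it)
}

#' Medoid of a cluster
#'
#' The member minimizing the summed distance to all other members; ties are
#' broken by lexicographic id so outputs are deterministic.
#'
#' @param members chain ids of the cluster
#' @param d symmetric distance matrix covering the members
#' @return the medoid chain id
#' @export
findMedoid <- function(members, d) {
  if (length(members) == 0L) stop("empty cluster", call. = FALSE)
  if (length(members) == 1L) return(members)
  if (!all(members %in% rownames(d)))
    stop("distance matrix does not cover all members", call. = FALSE)
  sub <- d[members, members]
  tot <- rowSums(sub)
  members[order(tot, members)][1L]
}

#' Cluster assignment table with medoids
#'
#' @param assignment named cluster ids (chain id -> cluster)
#' @param d symmetric distance matrix covering all chains
#' @return data.frame with columns chain, cluster, is_medoid, cluster_size,
#'   singleton (cluster size <= 4), sorted by (cluster, chain)
#' @export
clusterTable <- function(assignment, d) {
  rows <- lapply(split(names(assignment), assignment), function(ids) {
    med <- findMedoid(ids, d)
    data.frame(chain = sort(ids), cluster = assignment[[ids[1L]]],
               is_medoid = sort(ids) == med,
               cluster_size = length(ids),
               singleton = length(ids) <= 4L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cluster, out$chain), , drop = FALSE]
}
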