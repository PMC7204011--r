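# Consensus fingerprints for families of related proteins.

#' Trim gap-rich columns from a multiple sequence alignment
#'
#' Columns in which at least \code{gapFraction} of the sequences carry a
#' gap are removed; the edited sequences stay equal length. Gap symbols in
#' surviving columns are retained (they score 0 in fingerprinting, the
#' neutral-character rule).
#'
#' @param msa aligned sequences: named character vector or
#'   \code{AAStringSet}, all the same length, gap character \code{-}
#' @param gapFraction column-removal threshold (default 0.20: a column goes
#'   when 20\% or more of the sequences have a gap there)
#' @return named character vector of edited equal-length sequences
#' @export
trimAlignment <- function(msa, gapFraction = 0.20) {
  seqs <- .as_sequence_set(msa, aligned = TRUE)
  lens <- vapply(seqs, nchar, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must all have the same length", call. = FALSE)
  mat <- do.call(rbind, strsplit(unlist(seqs), "", fixed = TRUE))
  gapFrac <- colMeans(mat == "-")
  keep <- gapFrac < gapFraction
  stats::setNames(apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""),
                  names(seqs))
}

#' Pad sequence termini with gap spaces
#'
#' Prepends and appends \code{pad} gap symbols to every sequence. The
#' default of 25 matches the scoring window, so windows that straddle a
#' terminus see only neutral characters, suppressing edge effects of
#' alignment editing.
#'
#' @param seqs named character vector (or \code{AAStringSet}) of
#'   equal-length sequences
#' @param pad number of gap symbols per terminus (default 25)
#' @return named character vector, each of length original + 2 * pad
#' @export
padTermini <- function(seqs, pad = 25L) {
  pad <- .assert_scalar_int(pad, "pad", min = 0L)
  seqs <- .as_sequence_set(seqs, aligned = TRUE)
  wing <- strrep("-", pad)
  stats::setNames(vapply(seqs, function(s) paste0(wing, s, wing),
                         character(1L)), names(seqs))
}

#' Consensus fingerprint of an aligned protein family
#'
#' Computes each member's windowed grey matrix on the edited, padded,
#' equal-length sequences, averages them cell-wise, and binarizes the
#' average at the black point. Signal present across the family survives
#' the average; member-specific noise is diluted below the black point.
#'
#' @param seqs at least two equal-length sequences (named character vector
#'   or \code{AAStringSet}), typically from [trimAlignment] + [padTermini]
#' @param matrix substitution matrix
#' @param window,blackPoint fingerprint parameters
#' @return a [ConsensusPlot]
#' @export
consensusPlot <- function(seqs, matrix = loadSubstitutionMatrix(),
                          window = 25L, blackPoint = 31L) {
  seqs <- .as_sequence_set(seqs, aligned = TRUE)
  if (length(seqs) < 2L)
    stop("a consensus needs at least 2 member sequences", call. = FALSE)
  lens <- vapply(seqs, nchar, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("member sequences must all have the same length", call. = FALSE)
  greys <- lapply(seqs, function(s)
    greyValues(selfScoreMatrix(s, matrix, window)))
  meanGrey <- Reduce(`+`, greys) / length(greys)
  n <- nrow(meanGrey)
  hit <- which(upper.tri(meanGrey) & meanGrey >= blackPoint, arr.ind = TRUE)
  plot <- .new_dotplot(n, window, blackPoint,
                       cbind(hit[, 1L] - 1L, hit[, 2L] - 1L))
  methods::new("ConsensusPlot", meanGrey = meanGrey, plot = plot,
               members = names(seqs))
}

#' Per-residue consensus score profile
#'
#' For each alignment position, the maximum averaged grey score found
#' anywhere in its row or column of the consensus matrix (the diagonal is
#' ignored). Thresholding this profile at cutoffs in multiples of 10 up to
#' 50 with [repeatSegments] deconvolutes the consensus pattern into the
#' family's repeat residue spans.
#'
#' @param x a [ConsensusPlot]
#' @return numeric vector of length n
#' @export
consensusProfile <- function(x) {
  stopifnot(methods::is(x, "ConsensusPlot"))
  g <- x@meanGrey
  diag(g) <- 0
  apply(g, 1L, max)
}

#' Detect coherent consensus groups among fingerprints
#'
#' Pairwise sliding Jaccard distances between the member plots are
#' hierarchically clustered under each candidate linkage; every dendrogram
#' is cut at \code{cutLevels} evenly spaced heights. Coherent clusters are
#' clusters of two or more members whose aggregated pairwise distance is at
#' most \code{coherence}; each (linkage, height) grouping is scored by the
#' number of members covered by coherent clusters, coarser partitions
#' winning ties (scoring by the bare count of coherent clusters would
#' reward fragmenting one family into many coherent pairs). The
#' top-scoring grouping is returned, with a consensus
#' fingerprint for every coherent cluster when the members' aligned
#' (edited + padded) sequences are supplied.
#'
#' @param plots named list of member [DotPlot]s (fingerprints of the
#'   edited, padded family sequences)
#' @param seqs optional named equal-length sequences matching
#'   \code{names(plots)}; required to build consensus plots
#' @param coherence maximal aggregated within-cluster J_D (default 0.875)
#' @param cutLevels number of evenly spaced cut heights (default 50)
#' @param linkages candidate linkage methods (see [hierarchicalClusters])
#' @param statistic within-cluster aggregator of pairwise J_D:
#'   \code{"median"} (default), \code{"max"}, or \code{"mean"}
#' @param matrix,window,blackPoint parameters for the consensus
#'   fingerprints
#' @return list with \code{assignment} (named cluster ids), \code{linkage},
#'   \code{height}, \code{nCoherent}, \code{coverage} (members inside
#'   coherent clusters), \code{coherent} (ids of coherent clusters),
#'   \code{clusterStat} (aggregated J_D per cluster), and
#'   \code{consensus} (named list of [ConsensusPlot], when \code{seqs}
#'   given)
#' @export
detectConsensusGroups <- function(plots, seqs = NULL, coherence = 0.875,
                                  cutLevels = 50L,
                                  linkages = c("mcquitty", "average",
                                               "complete", "single", "ward"),
                                  statistic = c("median", "max", "mean"),
                                  matrix = loadSubstitutionMatrix(),
                                  window = 25L, blackPoint = 31L) {
  .check_plot_list(plots)
  statistic <- match.arg(statistic)
  agg <- switch(statistic, median = stats::median, max = max, mean = mean)
  jd <- pairwiseMatrix(plots)
  best <- NULL
  for (lk in linkages) {
    tree <- stats::hclust(stats::as.dist(jd), method = .linkage_method(lk))
    heights <- seq(0, max(tree$height), length.out = cutLevels)
    for (h in heights) {
      cl <- stats::cutree(tree, h = h)
      stat <- .cluster_stats(cl, jd, agg)
      cohIds <- names(stat)[!is.na(stat) & stat <= coherence]
      coverage <- sum(cl %in% as.integer(cohIds))
      better <- is.null(best) || coverage > best$coverage ||
        (coverage == best$coverage &&
           length(unique(cl)) < length(unique(best$assignment)))
      if (better) {
        best <- list(assignment = cl, linkage = lk, height = h,
                     nCoherent = length(cohIds), coverage = coverage,
                     clusterStat = stat)
      }
    }
  }
  coh <- names(best$clusterStat)[!is.na(best$clusterStat) &
                                   best$clusterStat <= coherence]
  best$coherent <- coh
  if (!is.null(seqs) && length(coh) > 0L) {
    seqs <- .as_sequence_set(seqs, aligned = TRUE)
    if (!all(names(plots) %in% names(seqs)))
      stop("'seqs' must cover every plot id", call. = FALSE)
    best$consensus <- stats::setNames(lapply(coh, function(cid) {
      ids <- names(best$assignment)[best$assignment == as.integer(cid)]
      consensusPlot(seqs[ids], matrix, window, blackPoint)
    }), coh)
  }
  best
}

# aggregated pairwise distance per cluster; NA for singletons (a cluster of
# one carries no pairwise evidence and is never counted coherent)
.cluster_stats <- function(assignment, d, agg) {
  vapply(split(names(assignment), assignment), function(ids) {
    if (length(ids) < 2L) return(NA_real_)
    sub <- d[ids, ids]
    agg(sub[upper.tri(sub)])
  }, numeric(1L))
}
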