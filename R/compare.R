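# Sliding Jaccard comparison of dot-plot fingerprints.
#
# Two plots are aligned on their self-identity diagonals; the smaller plot
# is slid along the larger plot's diagonal and at each shift the Jaccard
# index of the two pixel sets is computed. The maximum over all shifts is
# the similarity J_X; J_D = 1 - J_X is the corresponding distance.

# intersection counts for every diagonal shift of `small` against `large`.
# Pixels can only coincide when they sit on the same off-diagonal d = j - i,
# so counts are accumulated per diagonal: each (large, small) pixel pair on
# a shared diagonal matches at exactly one shift, i_large - i_small.
.offset_counts <- function(small, large) {
  offMin <- -(small@n - 1L)
  offMax <- large@n - 1L
  offsets <- offMin:offMax
  counts <- integer(length(offsets))
  ps <- small@pixels
  pl <- large@pixels
  if (nrow(ps) > 0L && nrow(pl) > 0L) {
    ssplit <- split(ps[, 1L], ps[, 2L] - ps[, 1L])
    lsplit <- split(pl[, 1L], pl[, 2L] - pl[, 1L])
    common <- intersect(names(ssplit), names(lsplit))
    if (length(common) > 0L) {
      diffs <- unlist(lapply(common, function(d)
        as.vector(outer(lsplit[[d]], ssplit[[d]], "-"))), use.names = FALSE)
      counts <- tabulate(diffs - offMin + 1L, nbins = length(offsets))
    }
  }
  list(offsets = offsets, counts = counts)
}

.order_plots <- function(a, b) {
  stopifnot(methods::is(a, "DotPlot"), methods::is(b, "DotPlot"))
  if (b@n <= a@n) list(small = b, large = a) else list(small = a, large = b)
}

#' Jaccard index of two fingerprints at a fixed diagonal shift
#'
#' Every pixel (i, j) of the smaller plot is translated to
#' (i + offset, j + offset); the intersection is the number of translated
#' pixels coinciding with pixels of the larger plot, and the union counts
#' all pixels of both plots (pixels outside the overlap window still count
#' toward the union, which penalizes size mismatch). Self-identity diagonal
#' cells never participate since fingerprints do not store them. When both
#' plots are empty the index is 0 by convention: two information-free plots
#' carry no evidence of similarity.
#'
#' @param a,b [DotPlot] objects; the one with fewer residues is translated
#' @param offset integer shift (residues) along the self-identity diagonal;
#'   must leave at least one residue of overlap
#' @return list with \code{jaccard}, \code{nIntersection}, \code{nUnion}
#' @export
jaccardAtOffset <- function(a, b, offset) {
  offset <- .assert_scalar_int(offset, "offset")
  pr <- .order_plots(a, b)
  if (offset < -(pr$small@n - 1L) || offset > pr$large@n - 1L)
    stop(sprintf("offset %d leaves no diagonal overlap (valid range %d..%d)",
                 offset, -(pr$small@n - 1L), pr$large@n - 1L), call. = FALSE)
  ps <- pr$small@pixels
  pl <- pr$large@pixels
  inter <- 0L
  if (nrow(ps) > 0L && nrow(pl) > 0L) {
    key <- function(i, j) i * 2^20 + j
    inter <- sum(key(ps[, 1L] + offset, ps[, 2L] + offset) %in%
                   key(pl[, 1L], pl[, 2L]))
  }
  union <- nrow(ps) + nrow(pl) - inter
  list(jaccard = if (union > 0L) inter / union else 0,
       nIntersection = as.integer(inter), nUnion = as.integer(union))
}

#' Slide two fingerprints to their optimal diagonal alignment
#'
#' Evaluates the Jaccard index at every diagonal shift that leaves at least
#' one residue of overlap and returns the maximum, which compensates for
#' length differences and terminal insertions/deletions between the two
#' proteins. Ties are broken toward the smallest absolute shift, then the
#' negative one, so comparing identical plots always reports shift 0.
#'
#' @param a,b [DotPlot] objects
#' @return a [SlideResult]; the offset refers to the smaller plot's origin
#'   on the larger plot's self-identity diagonal
#' @examples
#' m <- loadSubstitutionMatrix("BLOSUM62")
#' fp <- fingerprint(strrep("WLKDYFPAVQEMIRH", 8), m)
#' slideCompare(fp, fp)  # J_X = 1 at offset 0
#' @export
slideCompare <- function(a, b) {
  pr <- .order_plots(a, b)
  oc <- .offset_counts(pr$small, pr$large)
  nTot <- nrow(pr$small@pixels) + nrow(pr$large@pixels)
  union <- nTot - oc$counts
  jx <- ifelse(union > 0L, oc$counts / union, 0)
  best <- order(-jx, abs(oc$offsets), oc$offsets > 0L)[1L]
  methods::new("SlideResult",
               offset = as.integer(oc$offsets[best]),
               jaccard = as.numeric(jx[best]),
               nIntersection = as.integer(oc$counts[best]),
               nUnion = as.integer(union[best]))
}

#' Jaccard distance between two fingerprints
#'
#' \code{J_D = 1 - J_X} where \code{J_X} is the maximal sliding Jaccard
#' similarity from [slideCompare]. Symmetric in its arguments; 0 for
#' identical plots, 1 for plots sharing no pixels at any shift.
#'
#' @param a,b [DotPlot] objects
#' @return numeric distance in [0, 1]
#' @export
jaccardDistance <- function(a, b) {
  1 - slideCompare(a, b)@jaccard
}

#' Global sequence identity and similarity
#'
#' Needleman-Wunsch global alignment with affine gap penalties (NCBI
#' convention: a gap of length L costs \code{-gapOpen + (L-1) * -gapExtend}).
#' Identity is the fraction of alignment columns with identical residues;
#' similarity the fraction with a positive substitution score. Both are
#' percentages of the full alignment length, gap columns included in the
#' denominator.
#'
#' @param a,b protein sequences (character or \code{AAString})
#' @param matrix substitution matrix (default BLOSUM62)
#' @param gapOpen,gapExtend gap penalties, NCBI convention (defaults -11, -1)
#' @return list with \code{identity} and \code{similarity} (percent), plus
#'   the alignment \code{score}
#' @export
globalSimilarity <- function(a, b, matrix = loadSubstitutionMatrix(),
                             gapOpen = -11, gapExtend = -1) {
  a <- .check_sequence(a, "a")
  b <- .check_sequence(b, "b")
  # Biostrings charges opening + L * extension for a length-L gap; NCBI
  # charges open + (L-1) * extend, hence the conversion
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix,
    gapOpening = -(gapOpen - gapExtend), gapExtension = -gapExtend,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  len <- length(sa)
  aligned <- sa != "-" & sb != "-"
  ident <- sum(aligned & sa == sb)
  pos <- sum(matrix[cbind(sa[aligned], sb[aligned])] > 0)
  list(identity = 100 * ident / len, similarity = 100 * pos / len,
       score = Biostrings::score(pa))
}

#' Pairwise sliding comparison of a fingerprint collection
#'
#' All unordered pairs are slide-compared; results come back as a
#' long-format table sorted by (id_a, id_b) so the output is independent of
#' evaluation order.
#'
#' @param plots named list of [DotPlot] objects
#' @return data.frame with columns id_a, id_b, offset, jx, jd
#' @seealso [pairwiseMatrix] for the square distance-matrix form
#' @export
compareBatch <- function(plots) {
  .check_plot_list(plots)
  ids <- names(plots)
  pairs <- utils::combn(seq_along(plots), 2L)
  res <- apply(pairs, 2L, function(pq) {
    s <- slideCompare(plots[[pq[1L]]], plots[[pq[2L]]])
    data.frame(id_a = ids[pq[1L]], id_b = ids[pq[2L]],
               offset = s@offset, jx = s@jaccard, jd = 1 - s@jaccard,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res[order(res$id_a, res$id_b), , drop = FALSE]
}

.check_plot_list <- function(plots, min = 2L) {
  if (!is.list(plots) || length(plots) < min)
    stop(sprintf("need a list of at least %d DotPlot objects", min),
         call. = FALSE)
  if (is.null(names(plots)) || any(!nzchar(names(plots))) ||
      anyDuplicated(names(plots)) > 0L)
    stop("plots must be uniquely named", call. = FALSE)
  ok <- vapply(plots, methods::is, logical(1L), class2 = "DotPlot")
  if (!all(ok)) stop("all elements must be DotPlot objects", call. = FALSE)
  invisible(plots)
}
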