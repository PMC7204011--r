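#' Windowed self-similarity score matrix
#'
#' Scores every residue pair (i, j) of a sequence against itself by summing
#' substitution scores over a window of length \code{window} centered on
#' (i, j) and running parallel to the self-identity diagonal:
#' \deqn{G(i,j) = \mathrm{clamp}\Big(\sum_{k=-h}^{h} M(s_{i+k}, s_{j+k}),\ 0,\ 255\Big)}
#' with \eqn{h = (window - 1)/2}. Windows are truncated at the sequence ends
#' (only in-range offsets are summed), so the matrix is defined everywhere
#' without inventing padding residues. Repeated stretches light up as
#' diagonal-parallel lines of high score.
#'
#' @param seq a protein sequence (character scalar, \code{AAString}, or
#'   length-1 \code{AAStringSet}); every character must have a row in
#'   \code{matrix} (gap symbols are allowed when the matrix carries a
#'   \code{-} row, as the matrices from [loadSubstitutionMatrix] do)
#' @param matrix substitution matrix from [loadSubstitutionMatrix]
#' @param window odd window length in residues (default 25, the standard
#'   dot-plot scoring window)
#' @return a [GreyMatrix]
#' @seealso [binarize], [fingerprint]
#' @export
selfScoreMatrix <- function(seq, matrix = loadSubstitutionMatrix(),
                            window = 25L) {
  window <- .assert_scalar_int(window, "window", min = 1L)
  if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
  seq <- .as_sequence(seq)
  n <- nchar(seq)
  if (n < 1L) stop("sequence is empty", call. = FALSE)
  idx <- .residue_index(matrix)[utf8ToInt(seq)]
  if (any(idx == 0L)) {
    bad <- which(idx == 0L)[1L]
    stop(sprintf("character '%s' at position %d is not in the substitution matrix",
                 substr(seq, bad, bad), bad), call. = FALSE)
  }
  # P[i, j] = M(s_i, s_j); the windowed sum is a diagonal-wise moving sum,
  # computed as a shift-and-add over window offsets (truncation for free)
  p <- matrix(matrix[idx, idx], n, n)
  h <- (window - 1L) %/% 2L
  g <- matrix(0L, n, n)
  for (k in -h:h) {
    len <- n - abs(k)
    if (len < 1L) next
    if (k >= 0L) {
      src <- seq_len(len) + k
      g[seq_len(len), seq_len(len)] <- g[seq_len(len), seq_len(len), drop = FALSE] +
        p[src, src, drop = FALSE]
    } else {
      dst <- seq_len(len) - k
      g[dst, dst] <- g[dst, dst, drop = FALSE] + p[seq_len(len), seq_len(len), drop = FALSE]
    }
  }
  g[g < 0L] <- 0L
  g[g > 255L] <- 255L
  methods::new("GreyMatrix", values = g, window = window)
}

#' Binarize a grey matrix into a dot-plot fingerprint
#'
#' Cells of the strict upper triangle with grey value at or above
#' \code{blackPoint} become pixels; the self-identity diagonal is always
#' excluded (it only records trivial self-matches). Raising the black point
#' can only remove pixels, never add them.
#'
#' @param grey a [GreyMatrix]
#' @param blackPoint integer threshold in [1, 255]; the default 31 splits
#'   windowed scores into black (>= 31) and white (<= 30)
#' @return a [DotPlot]
#' @export
binarize <- function(grey, blackPoint = 31L) {
  stopifnot(methods::is(grey, "GreyMatrix"))
  blackPoint <- .assert_scalar_int(blackPoint, "blackPoint", min = 1L)
  if (blackPoint > 255L) stop("'blackPoint' must be <= 255", call. = FALSE)
  v <- grey@values
  n <- nrow(v)
  hit <- which(upper.tri(v) & v >= blackPoint, arr.ind = TRUE)
  .new_dotplot(n, grey@window, blackPoint,
               cbind(hit[, 1L] - 1L, hit[, 2L] - 1L))
}

#' Compute a dot-plot fingerprint in one step
#'
#' Convenience wrapper: [selfScoreMatrix] followed by [binarize].
#'
#' @inheritParams selfScoreMatrix
#' @inheritParams binarize
#' @return a [DotPlot]
#' @examples
#' m <- loadSubstitutionMatrix("BLOSUM62")
#' fp <- fingerprint(strrep("ACDEFGHIKL", 5), m)
#' pixelDensity(fp)
#' @export
fingerprint <- function(seq, matrix = loadSubstitutionMatrix(),
                        window = 25L, blackPoint = 31L) {
  binarize(selfScoreMatrix(seq, matrix, window), blackPoint)
}

#' Pixel density of a fingerprint
#'
#' Off-diagonal information content: upper-triangle black pixels per residue.
#' This is the statistic the repeat census thresholds at 0.42 pixels/residue.
#'
#' @param plot a [DotPlot]
#' @return numeric, pixels per residue
#' @export
pixelDensity <- function(plot) {
  stopifnot(methods::is(plot, "DotPlot"))
  nrow(plot@pixels) / plot@n
}
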