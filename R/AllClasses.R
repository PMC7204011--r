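#' GreyMatrix: windowed self-similarity score matrix
#'
#' Dense symmetric integer matrix of windowed substitution scores of a
#' sequence against itself, clamped to the greyscale range [0, 255].
#' Rows/columns are residue positions (0-based externally; the matrix itself
#' is an ordinary R matrix indexed from 1).
#'
#' @slot values integer matrix, n x n, entries in [0, 255]
#' @slot window odd window length in residues
#' @exportClass GreyMatrix
setClass("GreyMatrix",
  representation(values = "matrix", window = "integer"))

setValidity("GreyMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("score matrix must be square")
  if (any(v < 0L) || any(v > 255L)) return("grey values must lie in [0, 255]")
  if (!isSymmetric(unname(v))) return("grey matrix must be symmetric")
  w <- object@window
  if (length(w) != 1L || w < 1L || w %% 2L == 0L)
    return("window must be a single odd integer >= 1")
  TRUE
})

#' DotPlot: sparse binarized dot-plot fingerprint
#'
#' The set of "black" cells of a [GreyMatrix] at or above the black point.
#' Only the strict upper triangle is stored (the self-identity diagonal is
#' always excluded); coordinates are 0-based residue indices with i < j.
#'
#' @slot n sequence length in residues
#' @slot window window length used for scoring
#' @slot blackPoint binarization threshold (grey value >= blackPoint is black)
#' @slot pixels two-column integer matrix (i, j), 0-based, i < j
#' @exportClass DotPlot
setClass("DotPlot",
  representation(n = "integer", window = "integer", blackPoint = "integer",
                 pixels = "matrix"))

setValidity("DotPlot", function(object) {
  p <- object@pixels
  if (ncol(p) != 2L) return("pixels must be a two-column matrix")
  n <- object@n
  if (length(n) != 1L || n < 1L) return("n must be a positive integer")
  if (nrow(p) > 0L) {
    if (any(p[, 1L] >= p[, 2L]))
      return("pixels must satisfy i < j (diagonal and lower triangle excluded)")
    if (any(p < 0L) || any(p[, 2L] >= n))
      return("pixel coordinates must lie in [0, n)")
    if (anyDuplicated(p[, 1L] * as.numeric(n) + p[, 2L]) > 0L)
      return("duplicate pixels")
  }
  if (object@blackPoint < 1L || object@blackPoint > 255L)
    return("blackPoint must lie in [1, 255]")
  TRUE
})

#' SlideResult: optimal diagonal alignment of two fingerprints
#'
#' @slot offset shift (residues) of the smaller plot's origin along the
#'   larger plot's self-identity diagonal at the Jaccard optimum
#' @slot jaccard maximal Jaccard similarity J_X in [0, 1]
#' @slot nIntersection matching pixel count at the optimum
#' @slot nUnion union pixel count at the optimum
#' @exportClass SlideResult
setClass("SlideResult",
  representation(offset = "integer", jaccard = "numeric",
                 nIntersection = "integer", nUnion = "integer"))

#' ConsensusPlot: family-averaged fingerprint
#'
#' Cell-wise mean of the grey matrices of a trimmed, terminally padded
#' protein family, re-binarized at the black point.
#'
#' @slot meanGrey numeric matrix of averaged grey values
#' @slot plot the binarized consensus [DotPlot]
#' @slot members chain identifiers that entered the average
#' @exportClass ConsensusPlot
setClass("ConsensusPlot",
  representation(meanGrey = "matrix", plot = "DotPlot", members = "character"))

setValidity("ConsensusPlot", function(object) {
  m <- object@meanGrey
  if (nrow(m) != ncol(m)) return("meanGrey must be square")
  if (any(m < 0) || any(m > 255)) return("meanGrey entries must lie in [0, 255]")
  if (nrow(m) != object@plot@n) return("meanGrey and plot dimensions disagree")
  TRUE
})

# ---- constructors -----------------------------------------------------------

#' @noRd
.new_dotplot <- function(n, window, blackPoint, pixels) {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("i", "j")))
  if (nrow(pixels) > 1L) {
    ord <- order(pixels[, 1L], pixels[, 2L])
    pixels <- pixels[ord, , drop = FALSE]
  }
  methods::new("DotPlot", n = as.integer(n), window = as.integer(window),
               blackPoint = as.integer(blackPoint), pixels = pixels)
}

#' Construct a dot-plot fingerprint from explicit pixels
#'
#' Mostly useful for tests and for assembling plots from external data;
#' ordinary fingerprints come from [fingerprint] or [readDotPlot].
#'
#' @param n sequence length in residues
#' @param pixels two-column matrix of (i, j) pairs, 0-based, i < j; or an
#'   empty matrix/NULL for a pixel-free plot
#' @param window window length to record (default 25)
#' @param blackPoint black point to record (default 31)
#' @return a [DotPlot]
#' @export
dotPlot <- function(n, pixels = NULL, window = 25L, blackPoint = 31L) {
  if (is.null(pixels) || length(pixels) == 0L)
    pixels <- matrix(integer(0L), ncol = 2L)
  .new_dotplot(n, window, blackPoint, pixels)
}

# ---- accessors --------------------------------------------------------------

#' Number of black pixels in a fingerprint
#' @param plot a [DotPlot]
#' @return integer pixel count (upper triangle only)
#' @export
pixelCount <- function(plot) {
  stopifnot(methods::is(plot, "DotPlot"))
  nrow(plot@pixels)
}

#' Pixel coordinates of a fingerprint
#' @param plot a [DotPlot]
#' @return two-column integer matrix (i, j), 0-based, i < j
#' @export
pixels <- function(plot) {
  stopifnot(methods::is(plot, "DotPlot"))
  plot@pixels
}

#' Sequence length behind a fingerprint
#' @param plot a [DotPlot]
#' @return integer number of residues
#' @export
plotLength <- function(plot) {
  stopifnot(methods::is(plot, "DotPlot"))
  plot@n
}

#' @describeIn pixelCount black point (binarization threshold) of a plot
#' @export
blackPoint <- function(plot) {
  stopifnot(methods::is(plot, "DotPlot"))
  plot@blackPoint
}

#' Grey values of a GreyMatrix
#' @param grey a [GreyMatrix]
#' @return the underlying integer matrix
#' @export
greyValues <- function(grey) {
  stopifnot(methods::is(grey, "GreyMatrix"))
  grey@values
}

#' Members of a consensus plot
#' @param x a [ConsensusPlot]
#' @return character vector of chain ids
#' @export
consensusMembers <- function(x) {
  stopifnot(methods::is(x, "ConsensusPlot"))
  x@members
}

#' Binary fingerprint of a consensus plot
#' @param x a [ConsensusPlot]
#' @return the consensus [DotPlot]
#' @export
consensusFingerprint <- function(x) {
  stopifnot(methods::is(x, "ConsensusPlot"))
  x@plot
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "GreyMatrix", function(object) {
  cat(sprintf("GreyMatrix: %d x %d, window %d, grey range [%d, %d]\n",
              nrow(object@values), ncol(object@values), object@window,
              min(object@values), max(object@values)))
})

setMethod("show", "DotPlot", function(object) {
  cat(sprintf(
    "DotPlot: n = %d residues, window %d, black point %d, %d pixels (%.3f px/residue)\n",
    object@n, object@window, object@blackPoint, nrow(object@pixels),
    nrow(object@pixels) / object@n))
})

setMethod("show", "SlideResult", function(object) {
  cat(sprintf("SlideResult: J_X = %.4f at offset %d (%d / %d pixels)\n",
              object@jaccard, object@offset, object@nIntersection,
              object@nUnion))
})

setMethod("show", "ConsensusPlot", function(object) {
  cat(sprintf("ConsensusPlot: %d members, n = %d, %d consensus pixels\n",
              length(object@members), object@plot@n, nrow(object@plot@pixels)))
})

#' Plot a dot-plot fingerprint
#'
#' Draws the stored upper-triangle pixels and their mirror image, the way a
#' full dot plot is conventionally displayed.
#'
#' @param x a [DotPlot]
#' @param y ignored
#' @param ... further arguments passed to [graphics::plot]
#' @export
setMethod("plot", signature(x = "DotPlot", y = "missing"), function(x, y, ...) {
  p <- x@pixels
  graphics::plot(NA, xlim = c(0, x@n), ylim = c(x@n, 0), asp = 1,
                 xlab = "residue", ylab = "residue", ...)
  if (nrow(p) > 0L) {
    graphics::points(p[, 1L] + 0.5, p[, 2L] + 0.5, pch = 15, cex = 0.3)
    graphics::points(p[, 2L] + 0.5, p[, 1L] + 0.5, pch = 15, cex = 0.3)
  }
  graphics::abline(0, 1, col = "grey70")
  invisible(x)
})
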