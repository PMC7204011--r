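# Repeat detection and dot-plot deconvolution.

#' Classify a chain as repeat-containing from its fingerprint
#'
#' A chain passes the repeat census when it is long enough and its
#' fingerprint carries enough off-diagonal information: length >=
#' \code{minLength} and pixel density >= \code{densityCutoff}. The defaults
#' (121 residues, 0.42 pixels/residue) are the census settings calibrated on
#' known repeat structures versus non-repeat controls; the smaller-scale
#' benchmark experiments used a lower length floor (> 100 residues), so both
#' are exposed as parameters.
#'
#' @param plot a [DotPlot]
#' @param minLength minimum chain length in residues (default 121)
#' @param densityCutoff minimum pixels per residue (default 0.42)
#' @return logical
#' @export
classifyRepeat <- function(plot, minLength = 121L, densityCutoff = 0.42) {
  stopifnot(methods::is(plot, "DotPlot"))
  plot@n >= minLength && pixelDensity(plot) >= densityCutoff
}

#' Per-residue pixel profile
#'
#' Deconvolution step one: for each residue, count the pixels anywhere in
#' its row or column of the dot plot (the diagonal is never stored, so
#' trivial self-matches do not contribute). Residues inside repeats
#' accumulate high counts; the profile sums to twice the pixel count.
#'
#' @param plot a [DotPlot]
#' @return integer vector of length n; element r + 1 is the count for
#'   residue r (0-based)
#' @export
residueProfile <- function(plot) {
  stopifnot(methods::is(plot, "DotPlot"))
  p <- plot@pixels
  tabulate(c(p[, 1L], p[, 2L]) + 1L, nbins = plot@n)
}

#' Repeat segments from a residue profile
#'
#' Residues whose profile count reaches \code{cutoff} are repeat members;
#' maximal runs of members, after closing gaps of at most \code{maxGap}
#' non-member residues, become segments, and runs shorter than
#' \code{minSegment} are discarded (small tolerances that avoid
#' salt-and-pepper segmentation). For consensus-plot deconvolution the
#' cutoff is conventionally swept in multiples of 10 up to 50.
#'
#' @param profile integer vector from [residueProfile] (or a consensus
#'   profile)
#' @param cutoff minimum profile count for repeat membership (>= 1)
#' @param minSegment shortest reported segment, residues (default 3)
#' @param maxGap longest run of sub-cutoff residues absorbed into a segment
#'   (default 2)
#' @return integer matrix with columns \code{start}, \code{end}; 0-based
#'   half-open intervals, sorted and non-overlapping
#' @export
repeatSegments <- function(profile, cutoff, minSegment = 3L, maxGap = 2L) {
  cutoff <- .assert_scalar_int(cutoff, "cutoff", min = 1L)
  member <- profile >= cutoff
  out <- matrix(integer(0L), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (!any(member)) return(out)
  r <- rle(member)
  # close short FALSE runs strictly between member runs
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inner <- which(!r$values & r$lengths <= maxGap &
                   seq_along(r$values) > 1L &
                   seq_along(r$values) < length(r$values))
  member[unlist(Map(seq.int, starts[inner], ends[inner]))] <- TRUE
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= minSegment)
  if (length(keep) == 0L) return(out)
  cbind(start = starts[keep] - 1L, end = ends[keep])
}

#' Estimate repeat periods from a fingerprint
#'
#' Deconvolution step two: tandem repeats of unit length u produce pixel
#' lines at off-diagonal distances u, 2u, 3u, ... Pixels are histogrammed
#' by distance d = j - i, adjacent distances (within 1 residue, the blur
#' introduced by windowed scoring) are merged into peaks, and the
#' \code{topK} peaks by pixel support are reported at their support-weighted
#' center distance.
#'
#' @param plot a [DotPlot]
#' @param topK number of peaks to report (default 3)
#' @return data.frame with columns \code{period} (residues) and
#'   \code{support} (pixel count), strongest first; zero rows for an empty
#'   plot
#' @export
estimatePeriods <- function(plot, topK = 3L) {
  stopifnot(methods::is(plot, "DotPlot"))
  topK <- .assert_scalar_int(topK, "topK", min = 1L)
  p <- plot@pixels
  if (nrow(p) == 0L)
    return(data.frame(period = numeric(0L), support = integer(0L)))
  d <- p[, 2L] - p[, 1L]
  counts <- tabulate(d, nbins = max(d))
  occupied <- which(counts > 0L)
  # merge runs of adjacent occupied distances into single peaks
  grp <- cumsum(c(1L, diff(occupied) > 1L))
  period <- vapply(split(occupied, grp), function(ds)
    sum(ds * counts[ds]) / sum(counts[ds]), numeric(1L))
  support <- vapply(split(occupied, grp), function(ds)
    sum(counts[ds]), integer(1L))
  ord <- order(-support, period)
  k <- min(topK, length(ord))
  data.frame(period = unname(period[ord[seq_len(k)]]),
             support = unname(support[ord[seq_len(k)]]))
}

#' Scan sequences for repeat proteins
#'
#' End-to-end per-chain summary: fingerprint each sequence and report
#' length, pixel count, density, the census classification, and the top
#' repeat periods.
#'
#' @param seqs named character vector or \code{AAStringSet}
#' @param matrix substitution matrix
#' @param window,blackPoint fingerprint parameters
#' @param minLength,densityCutoff census parameters, see [classifyRepeat]
#' @return data.frame with one row per chain: id, length, pixels, density,
#'   is_repeat, periods (comma-separated "period:support")
#' @export
scanRepeats <- function(seqs, matrix = loadSubstitutionMatrix(),
                        window = 25L, blackPoint = 31L,
                        minLength = 121L, densityCutoff = 0.42) {
  seqs <- .as_sequence_set(seqs)
  rows <- lapply(names(seqs), function(id) {
    fp <- fingerprint(seqs[[id]], matrix, window, blackPoint)
    per <- estimatePeriods(fp)
    data.frame(id = id, length = fp@n, pixels = pixelCount(fp),
               density = pixelDensity(fp),
               is_repeat = classifyRepeat(fp, minLength, densityCutoff),
               periods = paste(sprintf("%.1f:%d", per$period, per$support),
                               collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# named list of validated plain character sequences
.as_sequence_set <- function(seqs, aligned = FALSE, mapToX = FALSE) {
  if (methods::is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.list(seqs)) seqs <- unlist(seqs)
  if (!is.character(seqs) || is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be a named character vector or AAStringSet",
         call. = FALSE)
  if (anyDuplicated(names(seqs)) > 0L)
    stop("duplicate sequence ids: ",
         names(seqs)[anyDuplicated(names(seqs))], call. = FALSE)
  out <- vapply(names(seqs), function(id)
    .check_sequence(seqs[[id]], id, aligned = aligned, mapToX = mapToX),
    character(1L))
  as.list(out)
}
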