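# File formats: FASTA input, the sparse dot-plot text format, MCL ABC edge
# lists, PNG raster export.

#' Read protein sequences from a FASTA file
#'
#' The identifier is the description line up to the first whitespace.
#' Records are validated against the 20-letter alphabet (plus X); ambiguity
#' codes (B, Z, U, O, J) are rejected unless \code{mapToX = TRUE}, which
#' maps them to the placeholder X. Duplicate ids are an error.
#'
#' @param path FASTA file (plain text)
#' @param mapToX map ambiguity codes to X instead of rejecting the record
#' @param aligned allow the gap character \code{-} (aligned FASTA)
#' @return \code{AAStringSet} with validated names
#' @export
readFasta <- function(path, mapToX = FALSE, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' has no records",
                              call. = FALSE)
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set)) > 0L)
    stop("duplicate id in '", path, "': ",
         names(set)[anyDuplicated(names(set))], call. = FALSE)
  seqs <- .as_sequence_set(set, aligned = aligned, mapToX = mapToX)
  Biostrings::AAStringSet(unlist(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector or \code{AAStringSet}
#' @param path output file
#' @return the path, invisibly
#' @export
writeFasta <- function(seqs, path) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a fingerprint in the sparse dot-plot text format
#'
#' Plain-text, diff-friendly serialization: a header line
#' \code{#n=<int> window=<int> black_point=<int>} (plus
#' \code{#members=<comma-separated ids>} for consensus plots), then one
#' \code{i<TAB>j} pixel per line, 0-based, i < j.
#'
#' @param plot a [DotPlot] or [ConsensusPlot]
#' @param path output file
#' @return the path, invisibly
#' @export
writeDotPlot <- function(plot, path) {
  members <- NULL
  if (methods::is(plot, "ConsensusPlot")) {
    members <- plot@members
    plot <- plot@plot
  }
  stopifnot(methods::is(plot, "DotPlot"))
  header <- sprintf("#n=%d window=%d black_point=%d", plot@n, plot@window,
                    plot@blackPoint)
  if (!is.null(members))
    header <- c(header, paste0("#members=", paste(members, collapse = ",")))
  p <- plot@pixels
  body <- if (nrow(p) > 0L) sprintf("%d\t%d", p[, 1L], p[, 2L]) else character(0L)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a fingerprint from the sparse dot-plot text format
#'
#' @param path file written by [writeDotPlot]
#' @return a [DotPlot]; consensus member ids, when present, are attached as
#'   attribute \code{members}
#' @export
readDotPlot <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#n=", lines[1L]))
    stop("'", path, "' is not a dot-plot file (missing '#n=' header)",
         call. = FALSE)
  hd <- regmatches(lines[1L],
    regexec("^#n=(\\d+) window=(\\d+) black_point=(\\d+)$", lines[1L]))[[1L]]
  if (length(hd) != 4L)
    stop("malformed dot-plot header: ", lines[1L], call. = FALSE)
  n <- as.integer(hd[2L]); window <- as.integer(hd[3L])
  blackPoint <- as.integer(hd[4L])
  members <- NULL
  body <- lines[-1L]
  if (length(body) > 0L && grepl("^#members=", body[1L])) {
    members <- strsplit(sub("^#members=", "", body[1L]), ",")[[1L]]
    body <- body[-1L]
  }
  body <- body[nzchar(body)]
  px <- matrix(integer(0L), ncol = 2L)
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed pixel line in '", path, "'", call. = FALSE)
    px <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2L,
                 byrow = TRUE)
    if (anyNA(px)) stop("non-integer pixel in '", path, "'", call. = FALSE)
    if (any(px[, 1L] >= px[, 2L]) || any(px < 0L) || any(px[, 2L] >= n))
      stop("pixel out of range in '", path,
           "' (need 0 <= i < j < n; the diagonal is never stored)",
           call. = FALSE)
  }
  plot <- .new_dotplot(n, window, blackPoint, px)
  if (!is.null(members)) attr(plot, "members") <- members
  plot
}

#' Read all dot-plot files in a directory
#'
#' @param dir directory containing \code{*.dp} files
#' @param pattern file-name pattern (default \code{"\\\\.dp$"})
#' @return named list of [DotPlot]s, names = file names without extension
#' @export
readDotPlotDir <- function(dir, pattern = "\\.dp$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L)
    stop("no dot-plot files under '", dir, "'", call. = FALSE)
  plots <- lapply(files, readDotPlot)
  names(plots) <- sub(pattern, "", basename(files))
  plots
}

#' Export a similarity matrix or graph as an MCL ABC edge list
#'
#' One \code{a<TAB>b<TAB>J_X} line per undirected edge, for interoperation
#' with external MCL/HipMCL implementations. Zero-similarity pairs are
#' omitted.
#'
#' @param sim symmetric J_X matrix with dimnames, or a weighted
#'   \code{igraph} graph
#' @param path output file
#' @return the path, invisibly
#' @export
exportMCL <- function(sim, path) {
  if (methods::is(sim, "igraph")) {
    df <- igraph::as_data_frame(sim, what = "edges")
    lines <- sprintf("%s\t%s\t%.6g", df$from, df$to, df$weight)
  } else {
    stopifnot(is.matrix(sim), !is.null(rownames(sim)))
    idx <- which(upper.tri(sim) & sim > 0, arr.ind = TRUE)
    lines <- sprintf("%s\t%s\t%.6g", rownames(sim)[idx[, 1L]],
                     colnames(sim)[idx[, 2L]], sim[idx])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a fingerprint as a PNG raster
#'
#' Black pixels on white, both triangles drawn, for visual inspection.
#' Requires the \pkg{png} package.
#'
#' @param plot a [DotPlot]
#' @param path output PNG file
#' @return the path, invisibly
#' @export
exportPNG <- function(plot, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("PNG export needs the 'png' package", call. = FALSE)
  stopifnot(methods::is(plot, "DotPlot"))
  img <- matrix(1, plot@n, plot@n)
  p <- plot@pixels
  if (nrow(p) > 0L) {
    img[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] <- 0
    img[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] <- 0
  }
  png::writePNG(img, path)
  invisible(path)
}
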