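#' Load a substitution matrix for fingerprinting
#'
#' Returns a symmetric integer score matrix over the 20 canonical amino
#' acids, extended with neutral rows/columns for the placeholder \code{X}
#' and the gap symbol \code{-}: both score 0 against everything, so neither
#' creates nor destroys dot-plot signal (this matters for gap-padded
#' consensus sequences). The built-in \code{"BLOSUM62"} is the canonical
#' NCBI matrix as distributed with Biostrings.
#'
#' @param source either the name of a built-in matrix (currently
#'   \code{"BLOSUM62"}) or the path to a matrix file in NCBI text format
#'   (whitespace-separated, a header row of residue letters, one labeled row
#'   per residue, \code{#} comments).
#' @return symmetric integer matrix with dimnames over the residue alphabet,
#'   including \code{X} and \code{-}
#' @examples
#' m <- loadSubstitutionMatrix("BLOSUM62")
#' m["A", "A"]  # 4
#' m["E", "K"]  # 1
#' @export
loadSubstitutionMatrix <- function(source = "BLOSUM62") {
  if (length(source) != 1L || !is.character(source))
    stop("'source' must be a matrix name or a file path", call. = FALSE)
  if (identical(toupper(source), "BLOSUM62") && !file.exists(source)) {
    m <- .blosum62_core()
  } else {
    if (!file.exists(source))
      stop("no built-in matrix or file named '", source, "'", call. = FALSE)
    m <- .read_ncbi_matrix(source)
  }
  .extend_neutral(m)
}

# canonical 20x20 BLOSUM62 block, reordered to the package alphabet
.blosum62_core <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "integer"
  m
}

# append zero-scoring X and "-" rows/columns (overriding any X scores the
# source file carries: neutral characters must not generate signal)
.extend_neutral <- function(m) {
  .check_symmetric(m)
  keep <- intersect(rownames(m), AA20)
  m <- m[keep, keep, drop = FALSE]
  ext <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L,
                dimnames = list(c(rownames(m), "X", "-"),
                                c(colnames(m), "X", "-")))
  ext[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  storage.mode(ext) <- "integer"
  ext
}

.check_symmetric <- function(m) {
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("substitution matrix must have matching row and column labels",
         call. = FALSE)
  bad <- which(m != t(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("substitution matrix is asymmetric: scores(%s,%s) != scores(%s,%s)",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 colnames(m)[bad[1L, 2L]], rownames(m)[bad[1L, 1L]]),
         call. = FALSE)
  invisible(m)
}

# NCBI text format: optional '#' comment lines, a header row of single-letter
# codes, then one row per residue: label followed by integer scores
.read_ncbi_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix file '", path, "' has no data lines", call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  ncols <- length(header)
  rows <- vector("list", length(lines) - 1L)
  labels <- character(length(lines) - 1L)
  for (r in seq_along(rows)) {
    fields <- strsplit(trimws(lines[r + 1L]), "\\s+")[[1L]]
    if (length(fields) != ncols + 1L)
      stop(sprintf("malformed matrix line %d: expected %d scores, got %d (%s)",
                   r + 1L, ncols, length(fields) - 1L, lines[r + 1L]),
           call. = FALSE)
    labels[r] <- fields[1L]
    vals <- suppressWarnings(as.integer(fields[-1L]))
    if (anyNA(vals))
      stop(sprintf("malformed matrix line %d: non-integer score (%s)",
                   r + 1L, lines[r + 1L]), call. = FALSE)
    rows[[r]] <- vals
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, header)
  if (!setequal(labels, header) || anyDuplicated(labels) > 0L)
    stop("matrix row labels do not match column labels", call. = FALSE)
  m <- m[, labels, drop = FALSE]  # align column order to row order
  .check_symmetric(m)
  storage.mode(m) <- "integer"
  m
}

# integer lookup table: residue character -> matrix row index, 0 for unknown
.residue_index <- function(matrix) {
  idx <- integer(256L)
  codes <- utf8ToInt(paste(rownames(matrix), collapse = ""))
  idx[codes] <- seq_along(codes)
  idx
}
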