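# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (triple loops, exhaustive scans) so they
# stay independent of the package's optimized implementations.

BL62 <- loadSubstitutionMatrix("BLOSUM62")

# naive windowed self-score: literal triple loop over cells and offsets
oracle_self_score <- function(seq, m = BL62, window = 25L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  h <- (window - 1L) %/% 2L
  g <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0L
    for (k in -h:h) {
      ii <- i + k; jj <- j + k
      if (ii >= 1L && ii <= n && jj >= 1L && jj <= n)
        s <- s + m[chars[ii], chars[jj]]
    }
    g[i, j] <- min(max(s, 0L), 255L)
  }
  g
}

# exhaustive per-offset sliding Jaccard with plain set operations
oracle_slide <- function(a, b) {
  small <- if (plotLength(b) <= plotLength(a)) b else a
  large <- if (plotLength(b) <= plotLength(a)) a else b
  ps <- pixels(small); pl <- pixels(large)
  lkey <- paste(pl[, 1L], pl[, 2L])
  best <- list(jaccard = -1, offset = NA_integer_)
  for (o in -(plotLength(small) - 1L):(plotLength(large) - 1L)) {
    inter <- if (nrow(ps) > 0L && nrow(pl) > 0L)
      sum(paste(ps[, 1L] + o, ps[, 2L] + o) %in% lkey) else 0L
    uni <- nrow(ps) + nrow(pl) - inter
    j <- if (uni > 0L) inter / uni else 0
    if (j > best$jaccard + 1e-12) best <- list(jaccard = j, offset = o)
  }
  best
}

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

rand_plot <- function(n, npix, seed = NULL, window = 25L, blackPoint = 31L) {
  if (!is.null(seed)) set.seed(seed)
  cells <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  pick <- cells[sample.int(nrow(cells), min(npix, nrow(cells))), , drop = FALSE]
  dotPlot(n, cbind(pick[, 1L] - 1L, pick[, 2L] - 1L), window, blackPoint)
}

# exact tandem repeat sequence: `copies` copies of a fixed random unit
exact_tandem <- function(unit = 25L, copies = 4L, flank = 0L, seed = 1L) {
  set.seed(seed)
  u <- rand_seq(unit)
  paste0(rand_seq(flank), strrep(u, copies), rand_seq(flank))
}
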