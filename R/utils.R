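# Internal helpers shared across modules.

# canonical 20-letter amino-acid alphabet, alphabetical one-letter codes
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues accepted outside alignment contexts: the 20 canonical plus X
AA_PLAIN <- c(AA20, "X")
# alignment contexts additionally allow the gap symbol
AA_ALIGNED <- c(AA_PLAIN, "-")

# ambiguity / rare codes that are rejected unless mapped to X
AA_NONSTANDARD <- c("B", "Z", "U", "O", "J")

#' @noRd
.assert_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Coerce sequence input (character scalar, AAString, length-1 AAStringSet)
# to an uppercase character scalar, keeping any name.
.as_sequence <- function(x) {
  if (methods::is(x, "AAStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence; got an AAStringSet of length ",
           length(x), call. = FALSE)
    s <- as.character(x)
    return(stats::setNames(toupper(unname(s)), names(s)))
  }
  if (methods::is(x, "AAString")) return(toupper(as.character(x)))
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("cannot interpret input as a protein sequence", call. = FALSE)
}

# Validate residues; 'aligned' admits the gap symbol. mapToX = TRUE maps
# ambiguity codes (B, Z, U, O, J) to X instead of rejecting the record.
.check_sequence <- function(seq, id = "sequence", aligned = FALSE,
                            mapToX = FALSE) {
  seq <- .as_sequence(seq)
  if (nchar(seq) < 1L) stop(sprintf("'%s' is empty", id), call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (mapToX) {
    chars[chars %in% AA_NONSTANDARD] <- "X"
    seq <- paste(chars, collapse = "")
  }
  allowed <- if (aligned) AA_ALIGNED else AA_PLAIN
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0L)
    stop(sprintf("record '%s' has illegal character '%s' at position %d",
                 id, chars[bad[1L]], bad[1L]), call. = FALSE)
  seq
}

# run expr under a temporary RNG state seeded with 'seed' (NULL = use the
# current stream); restores the caller's .Random.seed afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  .assert_scalar_int(seed, "seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic child seeds below 2^31, for splitting one user seed across
# independent experiment arms
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
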