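# Synthetic sequence generators with ground truth, for benchmarking every
# other module without external data.

#' BLOSUM62 background amino-acid frequencies
#'
#' The marginal residue frequencies underlying the BLOSUM62 matrix; used as
#' the default composition of all generators so the scoring model and the
#' generated sequences share one statistical background.
#'
#' @return named numeric vector over the 20 residues, summing to 1
#' @export
blosum62Frequencies <- function() {
  c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047, G = 0.074,
    H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
    P = 0.039, Q = 0.034, R = 0.052, S = 0.057, T = 0.051, V = 0.073,
    W = 0.013, Y = 0.032)
}

.check_composition <- function(composition) {
  if (is.null(composition)) composition <- blosum62Frequencies()
  if (!setequal(names(composition), AA20) || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-6)
    stop("'composition' must be a frequency table over the 20 residues summing to 1",
         call. = FALSE)
  composition[AA20]
}

.random_chars <- function(n, composition) {
  sample(AA20, n, replace = TRUE, prob = composition)
}

# substitute each position independently with probability `divergence`,
# replacements drawn from the kernel row of the original residue
.diverge_chars <- function(chars, divergence, kernel) {
  hit <- which(stats::runif(length(chars)) < divergence)
  for (p in hit)
    chars[p] <- sample(AA20, 1L, prob = kernel[chars[p], ])
  chars
}

#' Specification of a synthetic tandem repeat protein
#'
#' @param unitLength repeat unit length in residues (default 25)
#' @param copies number of tandem copies (default 6)
#' @param unitDivergence expected fraction of substituted positions per
#'   copy, relative to the ancestral unit (default 0.2)
#' @param flankLength random flank length on each side, residues (default 25)
#' @param insertionRate expected single-residue insertions per copy
#'   (Poisson; default 0)
#' @param composition amino-acid frequencies (default
#'   [blosum62Frequencies])
#' @return validated list of class \code{RepeatSpec}
#' @export
repeatSpec <- function(unitLength = 25L, copies = 6L, unitDivergence = 0.2,
                       flankLength = 25L, insertionRate = 0,
                       composition = NULL) {
  unitLength <- .assert_scalar_int(unitLength, "unitLength", min = 1L)
  copies <- .assert_scalar_int(copies, "copies", min = 1L)
  flankLength <- .assert_scalar_int(flankLength, "flankLength", min = 0L)
  if (unitDivergence < 0 || unitDivergence > 1)
    stop("'unitDivergence' must lie in [0, 1]", call. = FALSE)
  if (insertionRate < 0) stop("'insertionRate' must be >= 0", call. = FALSE)
  structure(list(unitLength = unitLength, copies = copies,
                 unitDivergence = unitDivergence, flankLength = flankLength,
                 insertionRate = insertionRate,
                 composition = .check_composition(composition)),
            class = "RepeatSpec")
}

#' Generate a tandem repeat protein with ground truth
#'
#' Draws a random ancestral unit from the composition, then emits
#' \code{copies} tandem copies, each independently substituted at the
#' specified divergence (substitutions drawn from the BLOSUM62-derived
#' kernel of [substitutionKernel]) with optional single-residue insertions,
#' flanked by random sequence. Ground truth reports each realized copy's
#' residue interval (0-based half-open) and the ancestral unit length as
#' the period.
#'
#' @param spec a [repeatSpec]
#' @param id sequence identifier (default "tandem")
#' @param kernel substitution kernel (default from BLOSUM62)
#' @param seed optional RNG seed
#' @return list with \code{seq} (named character scalar), \code{units}
#'   (integer matrix, columns start/end), \code{period}, \code{spec}
#' @export
makeTandemProtein <- function(spec = repeatSpec(), id = "tandem",
                              kernel = substitutionKernel(), seed = NULL) {
  stopifnot(inherits(spec, "RepeatSpec"))
  .with_seed(seed, {
    unit <- .random_chars(spec$unitLength, spec$composition)
    copies <- lapply(seq_len(spec$copies), function(cpy) {
      ch <- .diverge_chars(unit, spec$unitDivergence, kernel)
      nIns <- if (spec$insertionRate > 0) stats::rpois(1L, spec$insertionRate)
              else 0L
      for (ins in seq_len(nIns)) {
        at <- sample.int(length(ch) + 1L, 1L)
        ch <- append(ch, .random_chars(1L, spec$composition), after = at - 1L)
      }
      ch
    })
    lens <- lengths(copies)
    starts <- spec$flankLength + c(0L, cumsum(lens))[seq_len(spec$copies)]
    chars <- c(.random_chars(spec$flankLength, spec$composition),
               unlist(copies),
               .random_chars(spec$flankLength, spec$composition))
    list(seq = stats::setNames(paste(chars, collapse = ""), id),
         units = cbind(start = as.integer(starts),
                       end = as.integer(starts + lens)),
         period = spec$unitLength,
         spec = spec)
  })
}

#' Generate a non-repeat random protein
#'
#' Residues drawn i.i.d. from the composition; the negative control for
#' repeat classification benchmarks.
#'
#' @param length sequence length in residues
#' @param composition amino-acid frequencies (default
#'   [blosum62Frequencies])
#' @param id sequence identifier (default "random")
#' @param seed optional RNG seed
#' @return named character scalar
#' @export
makeNonrepeatProtein <- function(length, composition = NULL, id = "random",
                                 seed = NULL) {
  length <- .assert_scalar_int(length, "length", min = 1L)
  composition <- .check_composition(composition)
  .with_seed(seed,
    stats::setNames(paste(.random_chars(length, composition), collapse = ""),
                    id))
}

#' Generate a star-phylogeny protein family
#'
#' Each member is independently derived from the ancestor by positionwise
#' substitution at the given expected divergence (substitutions only, so a
#' columnwise alignment of the family is trivially correct).
#'
#' @param ancestor ancestral protein sequence (character scalar)
#' @param members number of family members (>= 2)
#' @param divergence expected substituted fraction per member branch
#' @param kernel substitution kernel
#' @param prefix member id prefix (ids are prefix1, prefix2, ...)
#' @param seed optional RNG seed
#' @return named character vector of member sequences
#' @export
makeFamily <- function(ancestor, members = 10L, divergence = 0.15,
                       kernel = substitutionKernel(), prefix = "m",
                       seed = NULL) {
  ancestor <- .check_sequence(ancestor, "ancestor")
  members <- .assert_scalar_int(members, "members", min = 2L)
  if (divergence < 0 || divergence > 1)
    stop("'divergence' must lie in [0, 1]", call. = FALSE)
  chars <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  .with_seed(seed, {
    stats::setNames(vapply(seq_len(members), function(m)
      paste(.diverge_chars(chars, divergence, kernel), collapse = ""),
      character(1L)), paste0(prefix, seq_len(members)))
  })
}

#' Composition-matched shuffle of a sequence
#'
#' Random permutation of the residues; destroys repeat structure while
#' preserving length and composition exactly. The standard negative
#' control matched to a repeat protein.
#'
#' @param seq protein sequence
#' @param id identifier for the shuffled sequence
#' @param seed optional RNG seed
#' @return named character scalar
#' @export
shuffleSequence <- function(seq, id = "shuffle", seed = NULL) {
  seq <- .check_sequence(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  .with_seed(seed,
    stats::setNames(paste(sample(chars), collapse = ""), id))
}

#' Generate the standard synthetic benchmark set
#'
#' A RepeatsDB-like collection of tandem repeat proteins for decay and
#' insertion experiments: unit length uniform over 20-40 residues, 4-8
#' copies, 35-residue flanks (chain lengths 150-390), and per-copy unit
#' divergence uniform over 0.35-0.55. The divergence range is calibrated so
#' the set's pixel-density distribution matches the census statistics of
#' natural repeat proteins of known structure (mean about 0.66
#' pixels/residue) rather than the much denser plots of designed repeat
#' arrays.
#'
#' @param n number of proteins (default 20)
#' @param seed optional RNG seed
#' @return named list of generator outputs (see [makeTandemProtein])
#' @export
makeStandardSet <- function(n = 20L, seed = NULL) {
  n <- .assert_scalar_int(n, "n", min = 1L)
  .with_seed(seed, {
    out <- lapply(seq_len(n), function(k) {
      spec <- repeatSpec(unitLength = sample(20:40, 1L),
                        copies = sample(4:8, 1L),
                        unitDivergence = stats::runif(1L, 0.35, 0.55),
                        flankLength = 35L)
      makeTandemProtein(spec, id = sprintf("std%02d", k))
    })
    names(out) <- vapply(out, function(x) names(x$seq), character(1L))
    out
  })
}

#' Serialize generator ground truth as JSON
#'
#' Machine-readable sidecar for a generated tandem protein: unit intervals
#' (0-based half-open), period, and generator parameters.
#'
#' @param truth list from [makeTandemProtein]
#' @param path output file
#' @return the path, invisibly
#' @export
writeGroundTruth <- function(truth, path) {
  spec <- truth$spec
  spec$composition <- as.list(spec$composition)
  jsonlite::write_json(
    list(id = names(truth$seq), length = nchar(truth$seq[[1L]]),
         period = truth$period,
         units = apply(truth$units, 1L, function(r)
           list(start = r[[1L]], end = r[[2L]]), simplify = FALSE),
         spec = unclass(spec)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
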