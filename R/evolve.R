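# In-silico sequence evolution and fingerprint decay experiments.

#' Substitution kernel from a score matrix
#'
#' Converts half-bit log-odds scores back to conditional substitution
#' probabilities: the probability of mutating residue a into b (b != a) is
#' proportional to \eqn{2^{M(a,b)/2}}. Self-substitutions are excluded so
#' every mutation round changes a residue; identity is therefore measured
#' from the sequences, not inferred from the round count.
#'
#' @param matrix substitution matrix from [loadSubstitutionMatrix]
#' @return 20 x 20 row-stochastic matrix with zero diagonal; rows index the
#'   original residue, columns the replacement
#' @export
substitutionKernel <- function(matrix = loadSubstitutionMatrix()) {
  m <- matrix[AA20, AA20]
  k <- 2^(m / 2)
  diag(k) <- 0
  k / rowSums(k)
}

#' Mutate one residue of a sequence
#'
#' One uniformly random position is replaced by a different residue drawn
#' from the substitution kernel row of the original residue; length is
#' unchanged. Uses the current RNG stream; seed at the experiment level.
#'
#' @param seq protein sequence (character scalar over the 20-letter alphabet)
#' @param kernel substitution kernel from [substitutionKernel]
#' @return the mutated sequence (character scalar)
#' @export
mutateOnce <- function(seq, kernel = substitutionKernel()) {
  chars <- strsplit(.check_sequence(seq), "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), 1L)
  chars[pos] <- sample(AA20, 1L, prob = kernel[chars[pos], ])
  paste(chars, collapse = "")
}

# in-place mutation on a character vector (internal fast path)
.mutate_chars <- function(chars, kernel) {
  pos <- sample.int(length(chars), 1L)
  chars[pos] <- sample(AA20, 1L, prob = kernel[chars[pos], ])
  chars
}

#' Substitution decay of a fingerprint
#'
#' Each replicate subjects the sequence to cumulative rounds of single
#' point mutations ([mutateOnce]); at recorded rounds the mutant
#' fingerprint is slide-compared against the original and positionwise
#' percent identity is measured. Means across replicates per round form a
#' decay curve of J_X against sequence identity loss, the input to
#' [fitExponential]. The default round count equals the sequence length.
#'
#' @param seq protein sequence
#' @param matrix substitution matrix
#' @param rounds number of mutation rounds per replicate (default: sequence
#'   length)
#' @param replicates number of independent replicates (default 1001)
#' @param window,blackPoint fingerprint parameters
#' @param recordEvery record the curve every this many rounds (the final
#'   round is always recorded); 1 records every round
#' @param seed optional RNG seed for the whole experiment
#' @return data.frame with columns \code{step}, \code{meanJx},
#'   \code{meanIdentity}; row one is round 0 (J_X = 1, identity = 100).
#'   Attributes \code{replicates} and \code{seed} record the run.
#' @export
decayExperiment <- function(seq, matrix = loadSubstitutionMatrix(),
                            rounds = NULL, replicates = 1001L,
                            window = 25L, blackPoint = 31L,
                            recordEvery = 1L, seed = NULL) {
  seq <- .check_sequence(seq)
  n <- nchar(seq)
  if (is.null(rounds)) rounds <- n
  rounds <- .assert_scalar_int(rounds, "rounds", min = 1L)
  replicates <- .assert_scalar_int(replicates, "replicates", min = 1L)
  recordEvery <- .assert_scalar_int(recordEvery, "recordEvery", min = 1L)
  kernel <- substitutionKernel(matrix)
  orig <- fingerprint(seq, matrix, window, blackPoint)
  chars0 <- strsplit(seq, "", fixed = TRUE)[[1L]]
  steps <- sort(unique(c(seq(recordEvery, rounds, by = recordEvery), rounds)))
  sumJx <- numeric(length(steps))
  sumId <- numeric(length(steps))
  .with_seed(seed, {
    for (rep in seq_len(replicates)) {
      chars <- chars0
      si <- 1L
      for (r in seq_len(rounds)) {
        chars <- .mutate_chars(chars, kernel)
        if (si <= length(steps) && r == steps[si]) {
          fp <- fingerprint(paste(chars, collapse = ""), matrix, window,
                            blackPoint)
          sumJx[si] <- sumJx[si] + slideCompare(orig, fp)@jaccard
          sumId[si] <- sumId[si] + 100 * mean(chars == chars0)
          si <- si + 1L
        }
      }
    }
  })
  curve <- data.frame(step = c(0L, steps),
                      meanJx = c(1, sumJx / replicates),
                      meanIdentity = c(100, sumId / replicates))
  attr(curve, "replicates") <- replicates
  attr(curve, "seed") <- seed
  curve
}

#' Fit an exponential decay law to a decay curve
#'
#' Nonlinear least squares of \eqn{J_X = e^{-bz}} where z is the percent
#' identity loss (100 - mean identity). Reports the decay constant b, the
#' half-life \eqn{z_{50} = \ln 2 / b} (percent identity loss at which half
#' the Jaccard similarity is gone), and \eqn{R^2}; a fit is flagged clean
#' when \eqn{R^2 \ge 0.98}.
#'
#' @param curve data.frame from [decayExperiment] (columns \code{meanJx},
#'   \code{meanIdentity})
#' @return list with \code{b}, \code{z50}, \code{rSquared}, \code{clean},
#'   and \code{nPoints}; a non-decaying curve yields \code{clean = FALSE}
#'   and \code{z50 = NA}
#' @export
fitExponential <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("meanJx", "meanIdentity") %in%
                                        names(curve)))
  z <- 100 - curve$meanIdentity
  jx <- curve$meanJx
  keep <- is.finite(z) & is.finite(jx)
  z <- z[keep]; jx <- jx[keep]
  if (sum(z > 0) < 5L)
    stop("need at least 5 curve points with identity loss > 0", call. = FALSE)
  # log-linear start value, then NLS on the original scale
  pos <- z > 0 & jx > 0
  b0 <- if (any(pos)) max(1e-4, -stats::coef(stats::lm(log(jx[pos]) ~ 0 + z[pos]))[[1L]])
        else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(jx ~ exp(-b * z), start = list(b = b0),
                      lower = c(b = -1), control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(b = NA_real_, z50 = NA_real_, rSquared = NA_real_,
                clean = FALSE, nPoints = length(z)))
  }
  b <- stats::coef(fit)[["b"]]
  res <- jx - exp(-b * z)
  r2 <- 1 - sum(res^2) / sum((jx - mean(jx))^2)
  decaying <- b > 0
  list(b = b,
       z50 = if (decaying) log(2) / b else NA_real_,
       rSquared = r2,
       clean = decaying && r2 >= 0.98,
       nPoints = length(z))
}

#' Insertion decay of a fingerprint
#'
#' Each replicate gradually inserts single residues at uniform random
#' positions, up to \code{maxFraction} of the original length; inserted
#' residues are drawn from the original sequence's composition (or
#' uniformly over the 20 residues). After each recorded insertion the grown
#' sequence's fingerprint is slide-compared against the original. The
#' half-loss insertion rate is the percent of original length inserted at
#' which mean J_X first drops to 0.5 (linearly interpolated between
#' bracketing measurements).
#'
#' @param seq protein sequence
#' @param matrix substitution matrix
#' @param maxFraction maximum inserted fraction of the original length
#'   (default 0.20)
#' @param replicates number of replicates (default 100)
#' @param window,blackPoint fingerprint parameters
#' @param composition \code{"sequence"} (default) or \code{"uniform"}
#' @param recordEvery record every this many insertions
#' @param seed optional RNG seed
#' @return list with \code{curve} (data.frame: insertions, rate, meanJx)
#'   and \code{halfLossRate} (percent of original length; NA when the curve
#'   never reaches 0.5)
#' @export
insertionExperiment <- function(seq, matrix = loadSubstitutionMatrix(),
                                maxFraction = 0.20, replicates = 100L,
                                window = 25L, blackPoint = 31L,
                                composition = c("sequence", "uniform"),
                                recordEvery = 1L, seed = NULL) {
  seq <- .check_sequence(seq)
  composition <- match.arg(composition)
  if (maxFraction <= 0 || maxFraction > 1)
    stop("'maxFraction' must lie in (0, 1]", call. = FALSE)
  replicates <- .assert_scalar_int(replicates, "replicates", min = 1L)
  recordEvery <- .assert_scalar_int(recordEvery, "recordEvery", min = 1L)
  n <- nchar(seq)
  mIns <- max(1L, floor(maxFraction * n))
  chars0 <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pool <- if (composition == "sequence") chars0 else AA20
  orig <- fingerprint(seq, matrix, window, blackPoint)
  steps <- sort(unique(c(seq(recordEvery, mIns, by = recordEvery), mIns)))
  sumJx <- numeric(length(steps))
  .with_seed(seed, {
    for (rep in seq_len(replicates)) {
      chars <- chars0
      si <- 1L
      for (t in seq_len(mIns)) {
        at <- sample.int(length(chars) + 1L, 1L)
        chars <- append(chars, sample(pool, 1L), after = at - 1L)
        if (si <= length(steps) && t == steps[si]) {
          fp <- fingerprint(paste(chars, collapse = ""), matrix, window,
                            blackPoint)
          sumJx[si] <- sumJx[si] + slideCompare(orig, fp)@jaccard
          si <- si + 1L
        }
      }
    }
  })
  curve <- data.frame(insertions = c(0L, steps),
                      rate = 100 * c(0L, steps) / n,
                      meanJx = c(1, sumJx / replicates))
  attr(curve, "replicates") <- replicates
  attr(curve, "seed") <- seed
  list(curve = curve, halfLossRate = .half_loss(curve$rate, curve$meanJx))
}

# first rate at which the mean curve crosses 0.5, linear interpolation
.half_loss <- function(rate, jx, level = 0.5) {
  k <- which(jx <= level)[1L]
  if (is.na(k)) return(NA_real_)
  if (k == 1L) return(rate[1L])
  r0 <- rate[k - 1L]; r1 <- rate[k]
  j0 <- jx[k - 1L]; j1 <- jx[k]
  if (j0 == j1) return(r1)
  r0 + (j0 - level) / (j0 - j1) * (r1 - r0)
}

#' Alphabet-permutation Monte Carlo
#'
#' Searches for a bijective residue replacement dictionary that minimizes
#' the BLOSUM-scored similarity between a sequence and its letter-remapped
#' counterpart, then asks whether the dot-plot pattern nevertheless
#' survives the remapping. Moves swap the values of two randomly chosen
#' keys; a move is accepted when it lowers the per-residue similarity score
#' or by the Metropolis criterion \eqn{e^{-\Delta/kT}}. The lowest-scoring
#' dictionary across \code{restarts} independent chains is kept, and the
#' fingerprints of the original and remapped sequences are slide-compared.
#'
#' @param seq protein sequence
#' @param matrix substitution matrix
#' @param steps Monte Carlo steps per restart (default 10000)
#' @param kT acceptance temperature on the per-residue score scale
#'   (default 0.04)
#' @param restarts independent chains (default 10)
#' @param window,blackPoint fingerprint parameters
#' @param init optional starting dictionary (named character vector mapping
#'   each of the 20 residues to a residue); default random
#' @param seed optional RNG seed
#' @return list with \code{map} (the best dictionary), \code{score}
#'   (per-residue similarity of mapped vs original), \code{identity}
#'   (percent of positions left unchanged by the map), \code{mappedSeq},
#'   and \code{jx} (sliding Jaccard of the two fingerprints)
#' @export
shuffleAlphabetMC <- function(seq, matrix = loadSubstitutionMatrix(),
                              steps = 10000L, kT = 0.04, restarts = 10L,
                              window = 25L, blackPoint = 31L,
                              init = NULL, seed = NULL) {
  seq <- .check_sequence(seq)
  steps <- .assert_scalar_int(steps, "steps", min = 0L)
  restarts <- .assert_scalar_int(restarts, "restarts", min = 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  counts <- table(factor(chars, levels = AA20))
  m20 <- matrix[AA20, AA20]
  # score(V) = sum_a count(a) * M(a, V(a)) / n : O(20) per evaluation
  scoreOf <- function(vidx) sum(counts * m20[cbind(seq_len(20L), vidx)]) / n
  if (!is.null(init)) {
    if (!setequal(names(init), AA20) || !setequal(unname(init), AA20))
      stop("'init' must be a bijection over the 20 amino acids", call. = FALSE)
    initIdx <- match(init[AA20], AA20)
  }
  best <- NULL
  .with_seed(seed, {
    for (rs in seq_len(restarts)) {
      vidx <- if (!is.null(init)) initIdx else sample.int(20L)
      s <- scoreOf(vidx)
      chainBest <- list(vidx = vidx, score = s)
      if (steps > 0L) {
        for (st in seq_len(steps)) {
          pair <- sample.int(20L, 2L)
          prop <- vidx
          prop[pair] <- prop[rev(pair)]
          sp <- scoreOf(prop)
          if (sp < s || stats::runif(1L) < exp(-(sp - s) / kT)) {
            vidx <- prop
            s <- sp
            if (s < chainBest$score) chainBest <- list(vidx = vidx, score = s)
          }
        }
      }
      if (is.null(best) || chainBest$score < best$score) best <- chainBest
    }
  })
  map <- stats::setNames(AA20[best$vidx], AA20)
  mapped <- paste(map[chars], collapse = "")
  fpA <- fingerprint(seq, matrix, window, blackPoint)
  fpB <- fingerprint(mapped, matrix, window, blackPoint)
  list(map = map, score = best$score,
       identity = 100 * sum(counts[map == AA20]) / n,
       mappedSeq = mapped,
       jx = slideCompare(fpA, fpB)@jaccard)
}
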