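test_that("substitution kernel is a proper BLOSUM back-transform", {
  k <- substitutionKernel(BL62)
  expect_equal(rowSums(k), setNames(rep(1, 20L), rownames(k)))
  expect_true(all(diag(k) == 0))
  # half-bit back-transform: q(b|a) proportional to 2^(M(a,b)/2)
  expect_equal(k["W", "Y"] / k["W", "P"], 2^(BL62["W", "Y"] / 2) /
                 2^(BL62["W", "P"] / 2))
})

test_that("single mutations change exactly one position, BLOSUM-weighted", {
  expect_true(mutateOnce("A") != "A")
  set.seed(1); m1 <- mutateOnce("ACDEFGHIKL")
  set.seed(1); m2 <- mutateOnce("ACDEFGHIKL")
  expect_identical(m1, m2)
  expect_equal(sum(strsplit(m1, "")[[1L]] != strsplit("ACDEFGHIKL", "")[[1L]]),
               1L)
  # draws from W hit Y (score 2) far more often than P (score -4)
  set.seed(2)
  draws <- replicate(4000L, mutateOnce("W"))
  nY <- sum(draws == "Y"); nP <- sum(draws == "P")
  expect_gt(nY, nP)
  k <- substitutionKernel(BL62)
  expect_equal(nY / 4000, k["W", "Y"], tolerance = 0.15)
})

test_that("decay curves start at (1, 100) and decrease under mutation", {
  s <- exact_tandem(unit = 20L, copies = 4L, seed = 12L)  # n = 80
  curve <- decayExperiment(s, BL62, rounds = 40L, replicates = 20L,
                           recordEvery = 5L, seed = 99L)
  expect_equal(curve$meanJx[1L], 1)
  expect_equal(curve$meanIdentity[1L], 100)
  expect_true(all(diff(curve$meanJx) <= 0.05))       # non-increasing + noise
  expect_true(all(diff(curve$meanIdentity) <= 0))    # identity strictly decays
  # reproducible under a fixed seed
  again <- decayExperiment(s, BL62, rounds = 40L, replicates = 20L,
                           recordEvery = 5L, seed = 99L)
  expect_identical(curve, again)
})

test_that("measured identity matches the exact per-site Markov oracle", {
  s <- exact_tandem(unit = 20L, copies = 5L, seed = 13L)  # n = 100
  n <- nchar(s)
  r <- 50L
  reps <- 40L
  curve <- decayExperiment(s, BL62, rounds = r, replicates = reps,
                           recordEvery = r, seed = 7L)
  # oracle: each site is hit Binomial(r, 1/n) times; given k hits the
  # probability of showing the original residue is (K^k)[a, a]
  k <- substitutionKernel(BL62)
  chars <- strsplit(s, "")[[1L]]
  pk <- diag(20L); dimnames(pk) <- dimnames(k)
  stay <- numeric(n)
  for (hits in 0:r) {
    w <- dbinom(hits, r, 1 / n)
    stay <- stay + w * diag(pk)[chars]
    pk <- pk %*% k
  }
  expected <- 100 * mean(stay)
  se <- 100 * sqrt(mean(stay * (1 - stay)) / (n * reps))
  expect_lt(abs(curve$meanIdentity[nrow(curve)] - expected), 3 * se)
})

test_that("exponential fits recover planted decay constants", {
  z <- 1:30
  clean <- data.frame(meanJx = exp(-0.1 * z), meanIdentity = 100 - z)
  f <- fitExponential(clean)
  expect_equal(f$b, 0.1, tolerance = 1e-6)
  expect_equal(f$rSquared, 1, tolerance = 1e-9)
  expect_true(f$clean)
  # half-life consistency: b = ln2 / 8.2 gives z50 = 8.2
  f2 <- fitExponential(data.frame(meanJx = exp(-(log(2) / 8.2) * z),
                                  meanIdentity = 100 - z))
  expect_equal(f2$z50, 8.2, tolerance = 1e-6)
  # noisy recovery stays within the stated band
  set.seed(14)
  noisy <- data.frame(meanJx = exp(-0.1 * z) + rnorm(30L, 0, 0.01),
                      meanIdentity = 100 - z)
  fn <- fitExponential(noisy)
  expect_gte(fn$b, 0.08); expect_lte(fn$b, 0.12)
  expect_gte(fn$rSquared, 0.98)
})

test_that("non-decaying curves are flagged rather than fitted", {
  z <- 1:20
  rising <- data.frame(meanJx = 0.95 + 0.004 * z, meanIdentity = 100 - z)
  f <- fitExponential(rising)
  expect_false(f$clean)
  expect_true(is.na(f$z50))  # best-fit b <= 0: no half-life
  # a curve hovering near a low plateau is flagged unclean even though the
  # least-squares decay constant comes out positive
  plateau <- data.frame(meanJx = 0.2 + 0.01 * z, meanIdentity = 100 - z)
  expect_false(fitExponential(plateau)$clean)
  expect_error(fitExponential(data.frame(meanJx = c(1, 0.5),
                                         meanIdentity = c(100, 90))),
               "at least 5")
})

test_that("insertions degrade the fingerprint and report rates in percent", {
  s <- exact_tandem(unit = 20L, copies = 5L, seed = 15L)  # n = 100
  res <- insertionExperiment(s, BL62, maxFraction = 0.1, replicates = 5L,
                             seed = 21L)
  expect_equal(res$curve$meanJx[1L], 1)
  expect_equal(res$curve$rate, 100 * res$curve$insertions / 100)
  expect_true(all(diff(res$curve$meanJx) <= 0.1))
  expect_true(is.finite(res$halfLossRate) || all(res$curve$meanJx > 0.5))
  # reproducible under seed
  again <- insertionExperiment(s, BL62, maxFraction = 0.1, replicates = 5L,
                               seed = 21L)
  expect_identical(res, again)
})

test_that("half-loss interpolation is linear between bracketing points", {
  # 4 insertions into a 417-residue chain is a 0.959% insertion rate
  expect_equal(100 * 4 / 417, 0.959, tolerance = 1e-3)
  expect_equal(dotprint:::.half_loss(c(0, 0.5, 1.0), c(1, 0.6, 0.4)), 0.75)
  expect_true(is.na(dotprint:::.half_loss(c(0, 1), c(1, 0.9))))
})

test_that("alphabet shuffling keeps bijectivity and the identity start", {
  s <- exact_tandem(unit = 25L, copies = 8L, seed = 16L)  # n = 200
  idmap <- setNames(dotprint:::AA20, dotprint:::AA20)
  r0 <- shuffleAlphabetMC(s, BL62, steps = 0L, restarts = 1L, init = idmap,
                          seed = 1L)
  expect_identical(r0$mappedSeq, s)
  expect_equal(r0$jx, 1)
  r <- shuffleAlphabetMC(s, BL62, steps = 300L, restarts = 2L, seed = 2L)
  expect_setequal(unname(r$map), dotprint:::AA20)
  expect_equal(length(unique(r$map)), 20L)
})

test_that("repetitive patterns survive alphabet permutation", {
  s <- exact_tandem(unit = 25L, copies = 8L, seed = 17L)
  hits <- 0L
  for (sd in 1:3) {
    r <- shuffleAlphabetMC(s, BL62, steps = 3000L, restarts = 3L, seed = sd)
    if (r$identity <= 10 && r$jx >= 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
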