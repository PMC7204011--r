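test_that("gap-rich columns are trimmed at the 20% threshold", {
  msa <- c(a = "ACDEF", b = "AC-EF", c = "ACDEF", d = "ACDEF", e = "ACDEF")
  out <- trimAlignment(msa)  # one gap of five = 20%: column 3 goes
  expect_equal(unname(nchar(out)), rep(4L, 5L))
  expect_equal(out[["a"]], "ACEF")
  # gapless alignments are untouched
  clean <- c(x = "ACDEF", y = "ACDEY")
  expect_equal(trimAlignment(clean), c(x = "ACDEF", y = "ACDEY"))
  # 3 sequences, gaps in columns 2 and 5 of one (33% each): 4 columns left
  toy <- c(p = "ACDEFG", q = "A-DE-G", r = "ACDEFG")
  expect_equal(unname(nchar(trimAlignment(toy))), rep(4L, 3L))
  expect_error(trimAlignment(c(u = "ACD", v = "ACDE")), "same length")
})

test_that("terminal padding adds neutral gap wings", {
  seqs <- setNames(replicate(3L, rand_seq(100L)), c("a", "b", "c"))
  padded <- padTermini(seqs, 25L)
  expect_equal(unname(nchar(padded)), rep(150L, 3L))
  expect_equal(padTermini(seqs, 0L), seqs)
  # no pixel can have both coordinates inside an all-gap pad
  fp <- fingerprint(padded[["a"]], BL62)
  p <- pixels(fp)
  if (nrow(p) > 0L) {
    inPad <- (p[, 2L] < 25L) | (p[, 1L] >= 125L)
    expect_false(any(inPad))
  }
})

test_that("consensus of identical members equals any member's plot", {
  s <- exact_tandem(unit = 20L, copies = 4L, seed = 31L)
  fam <- setNames(rep(s, 3L), c("m1", "m2", "m3"))
  cp <- consensusPlot(fam, BL62)
  member <- fingerprint(s, BL62)
  expect_equal(pixels(consensusFingerprint(cp)), pixels(member))
  expect_equal(consensusMembers(cp), c("m1", "m2", "m3"))
  expect_error(consensusPlot(fam[1L], BL62), "at least 2")
})

test_that("consensus averages grey values before binarizing", {
  s1 <- exact_tandem(unit = 20L, copies = 4L, seed = 32L)
  s2 <- shuffleSequence(s1, seed = 33L)[[1L]]
  cp <- consensusPlot(c(a = s1, b = s2), BL62)
  manual <- (greyValues(selfScoreMatrix(s1, BL62)) +
               greyValues(selfScoreMatrix(s2, BL62))) / 2
  hit <- which(upper.tri(manual) & manual >= 31, arr.ind = TRUE)
  expect_equal(nrow(pixels(consensusFingerprint(cp))), nrow(hit))
  # a strong member cell averaged with a weak one can drop below the black
  # point: consensus pixels need not be a union of member pixels
  expect_lte(pixelCount(consensusFingerprint(cp)),
             pixelCount(fingerprint(s1, BL62)))
})

test_that("unanimous grey signal survives averaging; unanimous zero does not", {
  anc <- makeTandemProtein(repeatSpec(unitLength = 25L, copies = 5L,
                                      unitDivergence = 0), seed = 34L)
  fam <- makeFamily(anc$seq, members = 4L, divergence = 0.1, seed = 35L)
  greys <- lapply(fam, function(s) greyValues(selfScoreMatrix(s, BL62)))
  cp <- consensusPlot(fam, BL62)
  cpx <- paste(pixels(consensusFingerprint(cp))[, 1L],
               pixels(consensusFingerprint(cp))[, 2L])
  allHigh <- Reduce(`&`, lapply(greys, function(g) g >= 31))
  allZero <- Reduce(`&`, lapply(greys, function(g) g == 0))
  hi <- which(allHigh & upper.tri(allHigh), arr.ind = TRUE)
  zo <- which(allZero & upper.tri(allZero), arr.ind = TRUE)
  expect_true(all(paste(hi[, 1L] - 1L, hi[, 2L] - 1L) %in% cpx))
  expect_false(any(paste(zo[, 1L] - 1L, zo[, 2L] - 1L) %in% cpx))
})

test_that("consensus is invariant to member order", {
  anc <- makeTandemProtein(repeatSpec(unitLength = 20L, copies = 5L,
                                      unitDivergence = 0), seed = 36L)
  fam <- makeFamily(anc$seq, members = 5L, divergence = 0.15, seed = 37L)
  cp1 <- consensusPlot(fam, BL62)
  cp2 <- consensusPlot(rev(fam), BL62)
  expect_equal(pixels(consensusFingerprint(cp1)),
               pixels(consensusFingerprint(cp2)))
})

test_that("family averaging denoises toward the ancestral pattern", {
  anc <- makeTandemProtein(repeatSpec(unitLength = 25L, copies = 6L,
                                      unitDivergence = 0.35,
                                      flankLength = 0L), seed = 38L)
  fam <- makeFamily(anc$seq, members = 10L, divergence = 0.15, seed = 39L)
  ancPlot <- fingerprint(anc$seq, BL62)
  memberPlots <- lapply(fam, fingerprint, matrix = BL62)
  cp <- consensusPlot(fam, BL62)
  consJx <- slideCompare(consensusFingerprint(cp), ancPlot)@jaccard
  pairJx <- compareBatch(memberPlots)$jx
  expect_gte(consJx, mean(pairJx))
})

test_that("coherent groups are recovered from planted families", {
  # all-identical plots form one coherent cluster
  p <- rand_plot(60L, 30L, seed = 40L)
  same <- list(a = p, b = p, c = p)
  g1 <- detectConsensusGroups(same, cutLevels = 10L)
  expect_equal(g1$nCoherent, 1L)
  expect_equal(length(unique(g1$assignment)), 1L)
  # two planted families: exactly two coherent clusters
  anc1 <- makeTandemProtein(repeatSpec(unitLength = 24L, copies = 6L,
                                       unitDivergence = 0), seed = 41L)
  anc2 <- makeTandemProtein(repeatSpec(unitLength = 31L, copies = 5L,
                                       unitDivergence = 0), seed = 42L)
  fam <- c(makeFamily(anc1$seq, 4L, 0.1, prefix = "f1_", seed = 43L),
           makeFamily(anc2$seq, 4L, 0.1, prefix = "f2_", seed = 44L))
  plots <- lapply(fam, fingerprint, matrix = BL62)
  g2 <- detectConsensusGroups(plots, seqs = fam, cutLevels = 25L)
  expect_equal(g2$nCoherent, 2L)
  split1 <- g2$assignment[startsWith(names(g2$assignment), "f1_")]
  expect_equal(length(unique(split1)), 1L)
  expect_equal(length(g2$consensus), 2L)
  expect_s4_class(g2$consensus[[1L]], "ConsensusPlot")
  # two disjoint plots (J_D = 1) yield no coherent cluster
  d1 <- dotPlot(30L, rbind(c(0L, 5L)))
  d2 <- dotPlot(30L, rbind(c(10L, 28L)))
  g3 <- detectConsensusGroups(list(x = d1, y = d2), cutLevels = 10L)
  expect_equal(g3$nCoherent, 0L)
})

test_that("consensus deconvolution recovers planted repeat units", {
  # 7-unit family: consensus profile segments should cover >= 6 of the 7
  # planted unit spans at >= 50% overlap for some cutoff in 10..50
  anc <- makeTandemProtein(repeatSpec(unitLength = 25L, copies = 7L,
                                      unitDivergence = 0.3,
                                      flankLength = 25L), seed = 45L)
  fam <- makeFamily(anc$seq, members = 8L, divergence = 0.15, seed = 46L)
  pad <- 25L
  padded <- padTermini(trimAlignment(fam), pad)
  cp <- consensusPlot(padded, BL62)
  prof <- consensusProfile(cp)  # averaged grey score, 0-255 scale
  best <- 0L
  for (ct in seq(10L, 50L, by = 10L)) {
    segs <- repeatSegments(prof, ct)
    if (nrow(segs) == 0L) next
    rec <- 0L
    for (u in seq_len(nrow(anc$units))) {
      us <- anc$units[u, "start"] + pad
      ue <- anc$units[u, "end"] + pad
      ov <- sum(pmax(0L, pmin(segs[, "end"], ue) - pmax(segs[, "start"], us)))
      if (ov >= 0.5 * (ue - us)) rec <- rec + 1L
    }
    best <- max(best, rec)
  }
  expect_gte(best, 6L)
})
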