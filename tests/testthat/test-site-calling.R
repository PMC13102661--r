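mkAln <- function(sequence, count, precursor, start, bodyLen,
                  mmPos = NA_integer_, mmRef = "", mmAlt = "",
                  tail = "", weight = 1) {
  data.frame(sequence = sequence, count = count, precursor = precursor,
             start = start, bodyLen = bodyLen, mmPos = mmPos,
             mmRef = mmRef, mmAlt = mmAlt, tail = tail, weight = weight)
}

test_that("pileups accumulate matches, mismatches and tail bases", {
  ps <- toyPrecursor()
  seqs <- precursorSequences(ps)
  prec <- as.character(seqs[[1]])
  body <- substr(prec, 5, 26)

  # 50 identical perfect reads -> ref count 50 at positions 5..26
  aln <- mkAln(body, 50L, "toy-mir-1", 5L, 22L)
  p <- buildPileups(aln, ps)
  expect_equal(nrow(p), 22L)
  expect_true(all(p$w == 50))
  expect_true(all(p$nt == p$ref))

  # 10 reads with G at templated position 14 among 100 covering
  ref14 <- substr(prec, 14, 14)
  alt14 <- setdiff(c("A", "C", "G", "T"), ref14)[1]
  mm <- strsplit(body, "")[[1]]
  mm[14 - 5 + 1] <- alt14
  aln2 <- rbind(mkAln(body, 90L, "toy-mir-1", 5L, 22L),
                mkAln(paste(mm, collapse = ""), 10L, "toy-mir-1", 5L,
                      22L, mmPos = 14L, mmRef = ref14, mmAlt = alt14))
  p2 <- buildPileups(aln2, ps)
  at14 <- p2[p2$position == 14L, ]
  expect_equal(at14$w[at14$nt == ref14], 90)
  expect_equal(at14$w[at14$nt == alt14], 10)

  # tail base lands one past the body end
  nxt <- substr(prec, 27, 27)
  tailNt <- setdiff(c("A", "C", "G", "T"), nxt)[1]
  aln3 <- mkAln(paste0(body, tailNt), 7L, "toy-mir-1", 5L, 22L,
                tail = tailNt)
  p3 <- buildPileups(aln3, ps)
  expect_equal(p3$w[p3$position == 27L & p3$nt == tailNt], 7)
  # overhang beyond the precursor end is tallied, not site-callable
  endBody <- substr(prec, 59, 80)
  aln4 <- mkAln(paste0(endBody, "AA"), 3L, "toy-mir-1", 59L, 22L,
                tail = "AA")
  p4 <- buildPileups(aln4, ps)
  expect_false(any(p4$position > 80L))
  expect_equal(attr(p4, "overhang"), 6)
})

test_that("editing level is the weighted alt fraction", {
  expect_equal(editingLevel(c(A = 90, G = 10), "G"), 0.1)
  expect_equal(editingLevel(c(A = 0, G = 10), "G"), 1)
  expect_equal(editingLevel(c(A = 45, G = 5, T = 0, C = 0), "G"), 0.1)
  expect_error(editingLevel(c(A = 0, G = 0), "G"), "zero coverage")
})

test_that("binomial survival p-value matches closed forms and oracles", {
  expect_equal(binomialSitePvalue(0, 100), 1)
  expect_equal(binomialSitePvalue(10, 10), 1e-30, tolerance = 1e-12)
  expect_equal(binomialSitePvalue(1, 1000), 1 - 0.999^1000,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(50, 1)
    k <- sample.int(n + 1L, 1L) - 1L
    got <- binomialSitePvalue(k, n)
    expect_equal(got, binomSurvivalOracle(k, n, 1e-3),
                 tolerance = 1e-12)
    expect_equal(got, pbinom(k - 1, n, 1e-3, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(binomialSitePvalue(5, 3), "k and n")
  expect_error(binomialSitePvalue(1, 10, e = 2), "error rate")
})

test_that("BH adjustment is the step-up minimum, order preserved", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.05), 0.05)
  p <- c(0.8, 0.001, 0.04, 0.3)
  expect_equal(bhAdjust(p), bruteBH(p))
  expect_equal(bhAdjust(p), p.adjust(p, "BH"))
  sorted <- sort(runif(20))
  expect_true(all(diff(bhAdjust(sorted)) >= 0))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("significance needs level, support and adjusted p together", {
  ps <- toyPrecursor()
  prec <- as.character(precursorSequences(ps)[[1]])
  mkPile <- function(rawK, rawN, pos = 14L) {
    ref <- substr(prec, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    data.frame(precursor = "toy-mir-1", position = pos,
               ref = ref, nt = c(ref, alt),
               w = c(rawN - rawK, rawK), raw = c(rawN - rawK, rawK))
  }
  # support rule: 9 alt reads of 1000 fails regardless of p
  c1 <- callSites(mkPile(9L, 1000L))
  expect_false(any(c1$significant))
  # 10 of 100: level 0.10, p << 1e-15 -> significant
  c2 <- callSites(mkPile(10L, 100L))
  expect_true(all(c2$significant))
  expect_lt(c2$p, 1e-15)
  expect_equal(c2$level, 0.1)
  # level rule: 10 of 250 is 4% < 5%
  c3 <- callSites(mkPile(10L, 250L))
  expect_false(any(c3$significant))
})

test_that("nine-type classification follows the decision order", {
  ps <- toyPrecursor()
  prec <- as.character(precursorSequences(ps)[[1]])
  mkCall <- function(pos, ref, alt, level = 0.3, meanWeight = 1) {
    data.frame(precursor = "toy-mir-1", position = pos, ref = ref,
               alt = alt,
               site = formatSiteName("toy-mir-1", pos, ref, alt),
               level = level, k = level * 100, n = 100,
               rawK = as.integer(level * 100), rawN = 100L,
               meanWeight = meanWeight, p = 1e-20, pAdj = 1e-19,
               significant = TRUE)
  }
  # seed region of the 5p arm (positions 6..12): A>G is A-to-I
  expect_equal(classifySites(mkCall(8L, "A", "G"), ps)$type, "A-to-I")
  expect_equal(classifySites(mkCall(20L, "C", "T"), ps)$type, "C-to-U")
  expect_equal(classifySites(mkCall(20L, "G", "T"), ps)$type, "Other")
  # one past the 5p arm 3' end (position 27): keyed by the added base
  expect_equal(classifySites(mkCall(27L, "T", "A"), ps)$type, "3'-A")
  expect_equal(classifySites(mkCall(27L, "A", "T"), ps)$type, "3'-U")
  expect_equal(classifySites(mkCall(27L, "A", "C"), ps)$type, "3'-Other")
  # past the 3p arm end
  expect_equal(classifySites(mkCall(76L, "C", "A"), ps)$type, "3'-A")
  # before every mature 5' start
  expect_equal(classifySites(mkCall(3L, "G", "A"), ps)$type,
               "5'-editing")
  # low mean cross-mapping weight -> Pseudo, trumping position rules
  expect_equal(classifySites(mkCall(8L, "A", "G", meanWeight = 0.2),
                             ps)$type, "Pseudo")
  # catalog match at 100% level -> SNP, trumping everything
  snp <- data.frame(chrom = "chr1", position = 1001 + 8 - 1,
                    id = "rs9", ref = "A", alt = "G")
  call <- mkCall(8L, "A", "G", level = 1)
  expect_equal(classifySites(call, ps, snp = snp)$type, "SNP")
  # same catalog entry but level < 100% anywhere -> not a SNP
  expect_equal(classifySites(mkCall(8L, "A", "G", level = 0.9),
                             ps, snp = snp)$type, "A-to-I")
  # cohort context: this sample 0.9 but some cohort cell at 1.0
  expect_equal(classifySites(mkCall(8L, "A", "G", level = 0.9), ps,
                             snp = snp,
                             maxLevel = c("toy-mir-1_8_A_g" = 1))$type,
               "SNP")
})

test_that("TPTM is linear depth normalization", {
  expect_equal(tptm(5, 1e6), 50)
  expect_equal(tptm(0, 1e6), 0)
  expect_equal(tptm(14, 2e6), 2 * tptm(7, 2e6))
  expect_error(tptm(5, 0), "positive")
})
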