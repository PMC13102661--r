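# small, fast configuration used throughout
smallConfig <- function(seed = 1, cellsPerType = 2L, ...) {
  simConfig(seed = seed, cellsPerType = cellsPerType, meanReads = 60, ...)
}

test_that("the reference simulator is deterministic and self-consistent", {
  cfg <- smallConfig()
  d1 <- file.path(tempdir(), "ref1"); d2 <- file.path(tempdir(), "ref2")
  r1 <- simulateReference(cfg, dir = d1)
  r2 <- simulateReference(cfg, dir = d2)
  expect_identical(readLines(file.path(d1, "precursors.fa")),
                   readLines(file.path(d2, "precursors.fa")))
  expect_identical(readLines(file.path(d1, "precursors.gff3")),
                   readLines(file.path(d2, "precursors.gff3")))
  expect_equal(length(r1$precursors), 20L)
  gff <- readLines(file.path(d1, "precursors.gff3"))
  expect_equal(sum(grepl("miRNA_primary_transcript", gff)), 20L)
  expect_gte(sum(grepl("\tmiRNA\t", gff)), 20L)

  # reading the written files back reproduces the in-memory annotation
  ps <- readMirnaGff3(file.path(d1, "precursors.gff3"),
                      readPrecursorFasta(file.path(d1, "precursors.fa")))
  expect_identical(as.character(precursorSequences(ps)),
                   as.character(precursorSequences(r1$precursors)))
  m1 <- as.data.frame(matureAnnotations(ps))
  m2 <- as.data.frame(matureAnnotations(r1$precursors))
  o1 <- order(m1$precursor, m1$start); o2 <- order(m2$precursor, m2$start)
  expect_equal(m1$start[o1], m2$start[o2])
  expect_equal(m1$end[o1], m2$end[o2])

  # every mature subsequence is extractable at its coordinates
  w <- Biostrings::width(precursorSequences(ps))[
    match(m1$precursor, precursorNames(ps))]
  expect_true(all(m1$start >= 1 & m1$end <= w))

  # the SNP catalog round-trips through the VCF reader
  snp <- readSnpCatalog(file.path(d1, "snp.vcf"))
  expect_equal(snp$position, r1$snp$position)
  expect_equal(snp$ref, r1$snp$ref)
})

test_that("planted edits appear at the planted rates", {
  # deterministic limit: error-free, one site at level 1 -> every covering
  # read carries the alternative base
  roster <- defaultSiteRoster()
  cfg <- smallConfig(errorRate = 0, contamination = 0)
  ref <- simulateReference(cfg)
  sim <- simulateCells(cfg, ref)
  snpSite <- ref$sites[ref$sites$intendedType == "SNP", ]
  prec <- as.character(
    precursorSequences(ref$precursors)[[snpSite$precursor]])
  arm <- subset(as.data.frame(matureAnnotations(ref$precursors)),
                precursor == snpSite$precursor & arm == "3p")
  body <- substr(prec, arm$start, arm$end)
  off <- snpSite$position - arm$start + 1
  unedited <- substr(body, off - 3, off + 3)
  edited <- unedited
  substr(edited, 4, 4) <- snpSite$alt
  for (cell in c("GBM_01", "nESC_02")) {
    rd <- as.character(sim$reads[[cell]])
    # every read covering the level-1 site carries the alternative base
    expect_false(any(grepl(unedited, rd, fixed = TRUE)))
    expect_gt(sum(grepl(edited, rd, fixed = TRUE)), 0L)
  }

  # binomial concentration: one central site at level ~0.3, high coverage
  cfg2 <- simConfig(seed = 5, cellsPerType = 1L, meanReads = 400,
                    errorRate = 0, contamination = 0)
  ref2 <- simulateReference(cfg2)
  sim2 <- simulateCells(cfg2, ref2)
  src <- ref2$sites[ref2$sites$precursor == "sim-mir-19", ]
  lam <- sim2$lambda[src$site, "GBM_01"]
  prec2 <- as.character(
    precursorSequences(ref2$precursors)[["sim-mir-19"]])
  arm2 <- subset(as.data.frame(matureAnnotations(ref2$precursors)),
                 precursor == "sim-mir-19" & arm == "3p")
  off2 <- src$position - arm2$start + 1
  ctx <- substr(prec2, src$position - 4, src$position + 4)
  edited <- ctx; substr(edited, 5, 5) <- src$alt
  rd2 <- as.character(sim2$reads[["GBM_01"]])
  nRef <- sum(grepl(ctx, rd2, fixed = TRUE))
  nAlt <- sum(grepl(edited, rd2, fixed = TRUE))
  n <- nRef + nAlt
  expect_gt(n, 100)
  expect_lt(abs(nAlt / n - lam), 3 * sqrt(lam * (1 - lam) / n))
})

test_that("cell simulation is reproducible and respects the read contract", {
  cfg <- smallConfig(seed = 3)
  ref <- simulateReference(cfg)
  s1 <- simulateCells(cfg, ref)
  s2 <- simulateCells(cfg, ref)
  expect_identical(lapply(s1$reads, as.character),
                   lapply(s2$reads, as.character))
  expect_identical(s1$truth, s2$truth)

  allReads <- unlist(lapply(s1$reads, Biostrings::width))
  expect_true(all(allReads >= 19L))
  # truth-table conservation: one row per planted site per cell
  expect_equal(nrow(s1$truth), nrow(ref$sites) * nrow(s1$cells))
  expect_true(all(s1$truth$level >= 0 & s1$truth$level <= 1))

  # outside the contamination fraction, reads pass the Q30 filter
  kept <- qualifyReads(s1$reads[[1]])
  frac <- length(kept) / length(s1$reads[[1]])
  expect_gt(frac, 1 - cfg$contamination - 3 * sqrt(cfg$contamination /
                                                     length(s1$reads[[1]])))
})

test_that("enzyme expression couples only where configured", {
  cfg <- smallConfig(seed = 4, cellsPerType = 30L)
  ref <- simulateReference(cfg)
  sim <- simulateCells(cfg, ref)
  e1 <- simulateEnzymeExpression(cfg, sim, ref)
  e2 <- simulateEnzymeExpression(cfg, sim, ref)
  expect_identical(e1$expression, e2$expression)
  expect_equal(nrow(e1$expression), length(tentEnzymes()))

  leuk <- sim$cells$cellId[sim$cells$cellType == "Leuk"]
  for (i in seq_len(nrow(e1$couplings))) {
    enz <- e1$couplings$enzyme[i]
    lam <- sim$lambda[e1$couplings$site[i], leuk]
    r <- cor(log(e1$expression[enz, leuk]), lam)
    expect_gt(r, 0.5)
  }
  # an uncoupled enzyme stays near zero correlation with the coupled site
  lam <- sim$lambda[e1$couplings$site[1], leuk]
  rNull <- cor(log(e1$expression["TENT5D", leuk]), lam)
  expect_lt(abs(rNull), 0.45)

  # zero slope means no coupling (and no division blow-up)
  cfg0 <- smallConfig(seed = 4, cellsPerType = 30L)
  cfg0$couplings <- data.frame(enzyme = "TENT2", siteIndex = 17L,
                               intercept = 0.45, slope = 0,
                               noiseSd = 0.1)
  e0 <- simulateEnzymeExpression(cfg0, sim, ref)
  lam0 <- sim$lambda[e0$couplings$site[1], leuk]
  expect_lt(abs(cor(log(e0$expression["TENT2", leuk]), lam0)), 0.45)

  # vanishing noise drives the coupled correlation to 1
  cfgP <- smallConfig(seed = 6, cellsPerType = 30L)
  cfgP$couplings <- data.frame(enzyme = "TUT7", siteIndex = 18L,
                               intercept = 0.45, slope = 0.18,
                               noiseSd = 1e-6)
  refP <- simulateReference(cfgP)
  simP <- simulateCells(cfgP, refP)
  eP <- simulateEnzymeExpression(cfgP, simP, refP)
  leukP <- simP$cells$cellId[simP$cells$cellType == "Leuk"]
  lamP <- simP$lambda[eP$couplings$site[1], leukP]
  expect_gt(cor(log(eP$expression["TUT7", leukP]), lamP), 0.999)
})
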