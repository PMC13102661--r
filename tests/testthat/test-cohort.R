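test_that("prevalence threshold matches the published arithmetic", {
  expect_identical(minSamples(448), 23L)
  expect_identical(minSamples(100), 5L)
  expect_identical(minSamples(19), 1L)
  expect_error(minSamples(0), "positive")
  expect_error(minSamples(100, 0), "fraction")
})

test_that("combining profiles applies prevalence, coverage and NA rules", {
  # 40 cells -> threshold ceiling(0.05 * 40) = 2
  sites <- c("p_10_A_g", "p_20_C_u")
  cover <- data.frame(precursor = "p", position = c(10L, 20L),
                      n = 100, rawN = 100L)
  profiles <- lapply(1:40, function(i) {
    sig <- c(i <= 2, i == 1)     # site 1 significant twice, site 2 once
    lvl <- c(ifelse(i <= 2, 0.4, 0), ifelse(i == 1, 0.3, 0))
    cov <- if (i == 40) cover[1, , drop = FALSE] else cover
    fakeProfile(sprintf("c%02d", i), "T1", sites, lvl, sig, cov)
  })
  ee <- combineSamples(profiles)
  expect_s4_class(ee, "EditingExperiment")
  expect_identical(rownames(ee), "p_10_A_g")
  lv <- editingLevels(ee)
  expect_equal(lv["p_10_A_g", "c01"], 0.4)
  expect_equal(lv["p_10_A_g", "c03"], 0)    # covered but unedited
  # cell 40 covers position 10, so still 0 there; drop coverage entirely:
  profiles[[40]]@coverage <- cover[0, ]
  profiles[[40]]@calls <- profiles[[40]]@calls[0, ]
  ee2 <- combineSamples(profiles)
  expect_true(is.na(editingLevels(ee2)["p_10_A_g", "c40"]))

  profiles[[2]]@sampleId <- "c01"
  expect_error(combineSamples(profiles), "duplicate")
})

test_that("PCA separates planted clusters and is reproducible", {
  set.seed(3)
  m <- matrix(runif(10 * 30, 0, 0.02), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("c", 1:30)))
  m["s1", 16:30] <- m["s1", 16:30] + 0.8   # one separating site
  pc <- pcaEditing(m, 3)
  expect_gt(pc$varianceExplained[1], 0.5)
  thr <- mean(pc$scores[, 1])
  side <- pc$scores[, 1] > thr
  expect_true(all(side[16:30]) || all(!side[16:30]))
  expect_true(all(side[1:15] != side[16]))
  # duplicated cells get identical scores
  m2 <- cbind(m, dup = m[, 1])
  pc2 <- pcaEditing(m2, 2)
  expect_equal(pc2$scores["dup", ], pc2$scores["c1", ])
  # variance fractions are non-increasing and sum to <= 1
  expect_true(all(diff(pc$varianceExplained) <= 1e-12))
  expect_lte(sum(pc$varianceExplained), 1 + 1e-12)
})

test_that("biclustering recovers block structure deterministically", {
  set.seed(4)
  m <- matrix(runif(6 * 20, 0, 0.05), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:20)))
  m[1:3, 1:10] <- m[1:3, 1:10] + 0.7
  bc <- hierBicluster(m)
  groups <- cutree(bc$colDend, k = 2)
  expect_equal(length(unique(groups[1:10])), 1L)
  expect_equal(length(unique(groups[11:20])), 1L)
  expect_false(groups[1] == groups[11])
  # identical cells merge at height 0
  m2 <- m; m2[, 2] <- m2[, 1]
  bc2 <- hierBicluster(m2)
  expect_equal(min(bc2$colDend$height), 0)
  # permuting columns does not change the tree topology (cophenetic)
  perm <- sample(20)
  bc3 <- hierBicluster(m[, perm])
  d1 <- as.matrix(cophenetic(bc$colDend))
  d3 <- as.matrix(cophenetic(bc3$colDend))
  expect_equal(d3[colnames(d1), colnames(d1)], d1)
  # Newick export round-trips through ape
  nwk <- dendrogramNewick(bc$colDend)
  expect_setequal(ape::read.tree(text = nwk)$tip.label, colnames(m))
})

test_that("indicator correlation flags planted type-exclusive sites", {
  set.seed(6)
  types <- rep(paste0("T", 1:5), each = 10)
  ann <- data.frame(cellId = paste0("c", 1:50), cellType = types)
  m <- matrix(0, nrow = 3, ncol = 50,
              dimnames = list(c("planted", "uniform", "constant"),
                              ann$cellId))
  m["planted", types == "T2"] <- rnorm(10, 0.8, 0.05)
  m["uniform", ] <- runif(50, 0.2, 0.4)
  m["constant", ] <- 0.5
  res <- cellTypeSpecificSites(m, ann)
  pl <- res[res$site == "planted" & res$cellType == "T2", ]
  expect_true(pl$specific)
  # r agrees with the brute-force covariance formula
  expect_equal(pl$r, brutePearson(m["planted", ],
                                  as.numeric(types == "T2")))
  expect_false(any(res$specific[res$site == "constant"]))
  expect_true(all(is.na(res$r[res$site == "constant"])))
  # indicator-identical levels give r = 1
  m2 <- rbind(ind = as.numeric(types == "T3"))
  colnames(m2) <- ann$cellId
  res2 <- cellTypeSpecificSites(m2, ann)
  expect_equal(res2$r[res2$cellType == "T3"], 1)
  expect_true(res2$specific[res2$cellType == "T3"])
})

test_that("variance tiers split at 0.2 and 0.3 with boundaries downward", {
  ann <- data.frame(cellId = c("a", "b"), cellType = "T1")
  fix <- rbind(high = c(0, 0.68),     # population std 0.34
               medium = c(0, 0.42),   # 0.21
               low = c(0, 0.20),      # 0.10
               zero = c(0.3, 0.3),
               atLow = c(0, 0.40),    # exactly 0.20 -> low
               atHigh = c(0, 0.60))   # exactly 0.30 -> medium
  colnames(fix) <- ann$cellId
  vg <- varianceGroups(fix, ann)
  got <- setNames(vg$group, vg$site)
  expect_equal(unname(got[c("high", "medium", "low", "zero",
                            "atLow", "atHigh")]),
               c("high", "medium", "low", "zero", "low", "medium"))
  expect_equal(vg$std[vg$site == "high"], 0.34)
  expect_equal(vg$std[vg$site == "medium"], 0.21)
  expect_equal(vg$std[vg$site == "low"], 0.10)
  expect_warning(
    varianceGroups(fix[, 1, drop = FALSE],
                   data.frame(cellId = "a", cellType = "T1")),
    "fewer than 2")
})

test_that("Mann-Whitney exact branch matches enumeration; ties fall back", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, enumMannWhitney(c(1, 2, 3), c(4, 5, 6)))
  # identical multisets: p = 1 within tolerance (tie branch)
  expect_gte(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # exact and approximate branches agree for n = m = 8
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    pe <- mannWhitneyU(x, y, exactMax = 16L)$p
    pa <- mannWhitneyU(x, y, exactMax = 0L)$p
    expect_lt(abs(pe - pa), 0.02)
  }
  expect_error(mannWhitneyU(numeric(), 1), "non-empty")
})

test_that("differential editing finds planted shifts vs the reference", {
  set.seed(9)
  ann <- data.frame(cellId = paste0("c", 1:60),
                    cellType = rep(c("GBM", "nESC"), each = 30))
  m <- rbind(shift = c(rnorm(30, 0.6, 0.05), rnorm(30, 0.05, 0.02)),
             flat = runif(60, 0.2, 0.25))
  colnames(m) <- ann$cellId
  de <- differentialEditing(m, ann, referenceType = "nESC")
  sh <- de[de$site == "shift", ]
  expect_true(sh$significant)
  expect_identical(sh$direction, "higher")
  expect_false(de$significant[de$site == "flat"])
  # BH preserves p-value ranks within the comparison
  expect_equal(order(de$p), order(de$pAdj))
  expect_error(differentialEditing(m, ann, referenceType = "absent"),
               "not present")
})

test_that("adjusted Rand index behaves at its anchors", {
  a <- rep(1:3, each = 5)
  set.seed(10)
  perm <- sample(a)
  expect_equal(adjustedRandIndex(a, a), 1)
  expect_equal(adjustedRandIndex(a, perm), adjustedRandIndex(perm, a))
  b <- rep(1, 15)
  expect_lte(abs(adjustedRandIndex(a, b)), 1e-12)
})
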