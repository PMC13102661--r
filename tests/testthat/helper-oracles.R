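# Independent oracles (brute-force / enumeration / closed-form) used to
# freeze expected values. These never call the implementation they check.

# BH step-up by its definition: adj_i = min over j with p_j >= p_i of
# min(1, m * p_j / rank_j), computed from the sorted vector.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of all group
# assignments of the pooled sample (no ties assumed).
enumMannWhitney <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  us <- apply(splits, 2L, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  pLow <- mean(us <= u)
  pHigh <- mean(us >= u)
  min(1, 2 * min(pLow, pHigh))
}

# Binomial survival probability by direct summation with exact binomial
# coefficients (choose() is exact in doubles for n <= 50).
binomSurvivalOracle <- function(k, n, e) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * e^i * (1 - e)^(n - i))
}

# Pearson r straight from the covariance formula.
brutePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive read-vs-precursor decomposition oracle: at each offset, try
# every body length from longest to shortest and keep the first valid one.
# Valid: <= maxMm mismatches in the body, the body's final base matches the
# template (terminal mismatch runs are tail, never body), and the tail
# (<= maxTail bases) is empty, overhangs the hairpin end, or starts with a
# mismatch.
bruteAlign <- function(read, prec, maxMm = 1L, maxTail = 3L) {
  L <- nchar(read); P <- nchar(prec)
  rc <- strsplit(read, "")[[1]]
  pc <- strsplit(prec, "")[[1]]
  out <- NULL
  for (s in seq_len(P)) {
    bCap <- min(L, P - s + 1L)
    for (b in rev(seq_len(bCap))) {
      if (L - b > maxTail) break
      body <- rc[seq_len(b)]
      tmpl <- pc[s:(s + b - 1L)]
      if (sum(body != tmpl) > maxMm) next
      if (body[b] != tmpl[b]) next
      tailOk <- b == L || s + b > P || rc[b + 1L] != pc[s + b]
      if (!tailOk) next
      out <- rbind(out, data.frame(start = s, bodyLen = b,
                                   tail = substr(read, b + 1L, L)))
      break
    }
  }
  out
}

# A deterministic toy hairpin with two annotated arms for classification
# tests: 80 nt, 5p arm 5..26, 3p arm 53..74.
toyPrecursor <- function() {
  set.seed(99)
  seqs <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
          collapse = ""))
  names(seqs) <- "toy-mir-1"
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(1001, width = 80),
                                 strand = "+")
  names(loci) <- "toy-mir-1"
  matures <- data.frame(
    precursor = "toy-mir-1",
    name = c("toy-miR-1-5p", "toy-miR-1-3p"),
    start = c(5L, 53L), end = c(26L, 74L), arm = c("5p", "3p"))
  PrecursorSet(seqs, loci = loci, matures = matures)
}

# Minimal SampleProfile for combine tests: `sig` is a named logical of
# sites significant in this cell; `levels` named levels; `coverage` a
# data.frame of covered positions.
fakeProfile <- function(id, cellType, sites, levels, sig, coverage) {
  key <- parseSiteName(sites)
  calls <- data.frame(
    precursor = key$precursor, position = key$position, ref = key$ref,
    alt = key$alt, site = sites, level = levels, k = levels * 100,
    n = 100, rawK = as.integer(levels * 100), rawN = 100L,
    meanWeight = 1, p = 1e-20, pAdj = 1e-19, significant = sig,
    type = "A-to-I")
  new("SampleProfile", sampleId = id, cellType = cellType,
      calls = calls, coverage = coverage,
      nReads = c(raw = 1e4, qualified = 1e4, unique = 100,
                 mapped = 95, unmapped = 5))
}

# FASTQ-in-memory builder.
readsWithQuality <- function(seqs, quals) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- sprintf("r%03d", seq_along(seqs))
  x
}
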