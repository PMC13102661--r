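#' @include enzyme.R
NULL

#' Synthetic-cohort configuration
#'
#' Describes the full stated world of a synthetic single-cell small-RNA
#' study: reference hairpins, cell types, planted M/E sites with per-type
#' editing-level distributions, a negative-binomial coverage model, the
#' sequencing-error and quality model, and enzyme couplings. All generator
#' functions are bit-reproducible given \code{seed}.
#'
#' @param seed Base RNG seed (keep below 2^31 - 10).
#' @param nPrecursors Number of hairpins, including one cross-mapping decoy
#'   (default 20; minimum 20 for the default site roster).
#' @param precursorLength Range of hairpin lengths (default 70-90 nt).
#' @param armLength Mature arm length (default 22 nt).
#' @param cellTypes Cell-type names (default the five-type study design).
#' @param cellsPerType Cells per type (default 20).
#' @param meanReads Negative-binomial mean reads per precursor per cell
#'   (default 200).
#' @param dispersion Negative-binomial size parameter; smaller values give
#'   the large cell-to-cell spread in valid reads seen in real single-cell
#'   sRNA data (default 6).
#' @param errorRate Per-base sequencing error (default 1e-3, matching Q30).
#' @param contamination Fraction of reads planted with one low-quality base
#'   among the first 25, so the Q30 filter has work to do (default 0.02).
#' @param ext3 Probability that a read carries a +1 3' isoform end
#'   (templated extension, or the non-templated addition at a planted 3'
#'   site) (default 0.5).
#' @param ext5 Probability of a -1 templated 5' isoform start (default
#'   0.35).
#' @param sites Optional site-specification \code{data.frame}; \code{NULL}
#'   installs the default ~30-site roster spanning all nine classes (see
#'   [defaultSiteRoster()]).
#' @param enzymes Enzyme panel (default [tentEnzymes()]).
#' @param expressionCellType Cell type with paired expression profiles
#'   (default \code{"Leuk"}, the co-sequenced population).
#' @param couplings \code{data.frame} of enzyme-site couplings with columns
#'   \code{enzyme}, \code{siteIndex}, \code{intercept}, \code{slope},
#'   \code{noiseSd}; \code{NULL} installs the defaults (TENT2 to the
#'   Leuk-specific 3'-A site, TUT7 to the 3'-U site, noise sd 0.11).
#' @param logMean,logSd Log-normal expression scale for the enzyme panel.
#' @return A \code{SimConfig} list.
#' @export
simConfig <- function(seed = 1L, nPrecursors = 20L,
                      precursorLength = c(70L, 90L), armLength = 22L,
                      cellTypes = c("GBM", "HEK293FT", "Leuk", "pESC",
                                    "nESC"),
                      cellsPerType = 20L, meanReads = 200,
                      dispersion = 6, errorRate = 1e-3,
                      contamination = 0.02, ext3 = 0.5, ext5 = 0.35,
                      sites = NULL, enzymes = tentEnzymes(),
                      expressionCellType = "Leuk", couplings = NULL,
                      logMean = 3, logSd = 0.5) {
  if (meanReads <= 0) stop("coverage mean must be positive")
  if (armLength + 6L > precursorLength[1L])
    stop("arm length exceeds the shortest precursor")
  cfg <- list(seed = as.integer(seed), nPrecursors = as.integer(nPrecursors),
              precursorLength = as.integer(precursorLength),
              armLength = as.integer(armLength), cellTypes = cellTypes,
              cellsPerType = as.integer(cellsPerType),
              meanReads = meanReads, dispersion = dispersion,
              errorRate = errorRate, contamination = contamination,
              ext3 = ext3, ext5 = ext5, sites = sites, enzymes = enzymes,
              expressionCellType = expressionCellType,
              couplings = couplings, logMean = logMean, logSd = logSd)
  class(cfg) <- "SimConfig"
  cfg
}

# Beta draw parameterized by mean and standard deviation. A normal truncated
# to [0,1] cannot exceed sd ~0.289, so the high-variance tier (sd 0.35) needs
# a genuinely [0,1]-supported family; Beta matches the requested moments
# exactly and reproduces the bimodal high-variance sites seen in real data.
.rLevel <- function(n, mean, sd) {
  if (sd == 0 || mean <= 0 || mean >= 1) {
    return(rep(min(max(mean, 0), 1), n))
  }
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("level sd ", sd, " infeasible for mean ", mean)
  nu <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * nu, (1 - mean) * nu)
}

#' Default planted-site roster
#'
#' The default synthetic world: ~30 sites across 20 precursors spanning all
#' nine M/E classes. Eighteen cell-type-exclusive 3' addition sites (mostly
#' 3'-U/3'-A, the dominant specific classes in single-cell data), six
#' shared central sites in three variance tiers (sd 0.05 / 0.25 / 0.35),
#' one seed-region A-to-I site elevated in the GBM-like type, one C-to-U
#' site, one 5'-editing site, one central Other site, one SNP-like site at
#' level 1 with a catalog entry, and one A-to-I site on a precursor whose 3p
#' arm is duplicated into a read-less decoy hairpin (yielding a Pseudo call
#' on the decoy). Mean levels vary across types so that shared sites carry
#' cell-type structure, as differential-editing analyses expect.
#'
#' @param cellTypes The five cell-type names, in order.
#' @return Site-specification \code{data.frame} with columns \code{precIdx},
#'   \code{arm}, \code{region}, \code{ref}, \code{alt}, \code{tail},
#'   \code{intendedType}, and per-type \code{mean_*} / \code{sd_*} columns.
#' @export
defaultSiteRoster <- function(cellTypes = c("GBM", "HEK293FT", "Leuk",
                                            "pESC", "nESC")) {
  stopifnot(length(cellTypes) == 5L)
  rows <- list()
  addSite <- function(precIdx, arm, region, ref, alt, tail, intendedType,
                      means, sds) {
    rows[[length(rows) + 1L]] <<- data.frame(
      precIdx = precIdx, arm = arm, region = region, ref = ref, alt = alt,
      tail = tail, intendedType = intendedType,
      t(stats::setNames(means, paste0("mean_", cellTypes))),
      t(stats::setNames(sds, paste0("sd_", cellTypes))))
  }
  exclusive <- function(type, mean, sd = 0.08) {
    means <- rep(0, 5); sds <- rep(0, 5)
    i <- match(type, cellTypes)
    means[i] <- mean; sds[i] <- sd
    list(means = means, sds = sds)
  }
  # cell-type-exclusive 3' sites (position resolved to armEnd + 1 later)
  spec <- list(
    list("GBM", 1L, "3p", "A", 0.85), list("GBM", 2L, "5p", "T", 0.80),
    list("GBM", 3L, "3p", "T", 0.75), list("GBM", 4L, "5p", "A", 0.80),
    list("GBM", 5L, "3p", "A", 0.70),
    list("nESC", 6L, "3p", "T", 0.85), list("nESC", 7L, "5p", "A", 0.80),
    list("nESC", 8L, "3p", "A", 0.75), list("nESC", 9L, "5p", "T", 0.70),
    list("nESC", 10L, "3p", "T", 0.80),
    list("HEK293FT", 11L, "5p", "A", 0.85),
    list("HEK293FT", 12L, "3p", "T", 0.70),
    list("HEK293FT", 13L, "3p", "C", 0.75),
    list("pESC", 14L, "3p", "A", 0.80), list("pESC", 15L, "5p", "T", 0.70),
    list("pESC", 16L, "3p", "A", 0.65))
  for (s in spec) {
    ex <- exclusive(s[[1L]], s[[5L]])
    tp <- switch(s[[4L]], A = "3'-A", T = "3'-U", "3'-Other")
    addSite(s[[2L]], s[[3L]], "3prime", NA, s[[4L]], TRUE, tp,
            ex$means, ex$sds)
  }
  # Leuk-exclusive coupled 3' sites (wider spread so expression coupling
  # has dynamic range)
  exA <- exclusive("Leuk", 0.45, 0.18)
  addSite(17L, "3p", "3prime", NA, "A", TRUE, "3'-A", exA$means, exA$sds)
  exU <- exclusive("Leuk", 0.45, 0.18)
  addSite(18L, "3p", "3prime", NA, "T", TRUE, "3'-U", exU$means, exU$sds)
  # shared central sites in three variance tiers
  addSite(1L, "5p", "central", "A", "G", FALSE, "A-to-I",
          c(.20, .20, .20, .55, .55), rep(.05, 5))
  addSite(2L, "5p", "central", "C", "T", FALSE, "C-to-U",
          c(.50, .30, .40, .15, .15), rep(.05, 5))
  addSite(3L, "5p", "central", "A", "G", FALSE, "A-to-I",
          rep(.5, 5), rep(.25, 5))
  addSite(4L, "5p", "central", "C", "T", FALSE, "C-to-U",
          c(.35, .60, .35, .50, .50), rep(.25, 5))
  addSite(5L, "5p", "central", "A", "G", FALSE, "A-to-I",
          rep(.5, 5), rep(.35, 5))
  addSite(6L, "5p", "central", "C", "T", FALSE, "C-to-U",
          c(.50, .45, .55, .50, .50), rep(.35, 5))
  # seed-region A-to-I site elevated in the GBM-like type
  addSite(7L, "5p", "seed", "A", "G", FALSE, "A-to-I",
          c(.55, .18, .18, .15, .12), rep(.08, 5))
  # further single-class sites
  addSite(8L, "5p", "central", "C", "T", FALSE, "C-to-U",
          c(.45, .20, .30, .10, .10), rep(.08, 5))
  addSite(9L, "5p", "5prime", "G", "A", FALSE, "5'-editing",
          c(.45, .40, .35, .40, .40), rep(.05, 5))
  addSite(10L, "5p", "central", "G", "T", FALSE, "Other",
          c(.15, .40, .25, .30, .30), rep(.08, 5))
  addSite(11L, "3p", "central", "A", "G", FALSE, "SNP",
          rep(1, 5), rep(0, 5))
  # cross-mapping pair: source on precursor 19, decoy duplicated arm on 20
  addSite(19L, "3p", "central", "A", "G", FALSE, "A-to-I",
          rep(.3, 5), rep(.05, 5))
  addSite(20L, "3p", "central", "A", "G", FALSE, "Pseudo",
          rep(.3, 5), rep(.05, 5))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the reference: hairpins, annotation, SNP catalog
#'
#' Generates random hairpin-like sequences with annotated 5p/3p arms on a
#' toy genome (every seventh hairpin on the minus strand, to exercise
#' strand-aware coordinate logic), resolves the planted-site roster to
#' concrete positions (forcing the required reference bases), duplicates
#' the penultimate hairpin's 3p arm into the decoy hairpin, and derives the
#' one-record SNP catalog for the SNP-class site. Deterministic per
#' \code{config$seed}.
#'
#' @param config A [simConfig()] object.
#' @param dir Optional output directory; writes \code{precursors.fa},
#'   \code{precursors.gff3} and \code{snp.vcf}.
#' @return List with \code{precursors} (\linkS4class{PrecursorSet}),
#'   \code{sites} (resolved site table with codec names) and \code{snp}
#'   (catalog \code{data.frame}).
#' @export
simulateReference <- function(config, dir = NULL) {
  set.seed(config$seed)
  np <- config$nPrecursors
  if (is.null(config$sites)) {
    if (np < 20L) stop("the default site roster needs >= 20 precursors")
    roster <- defaultSiteRoster(config$cellTypes)
  } else roster <- config$sites
  aLen <- config$armLength
  plen <- sample(seq(config$precursorLength[1L],
                     config$precursorLength[2L]), np, replace = TRUE)
  nm <- sprintf("sim-mir-%02d", seq_len(np))
  seqs <- vapply(plen, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), "")
  s5 <- rep(4L, np); e5 <- s5 + aLen - 1L
  e3 <- plen - 3L; s3 <- e3 - aLen + 1L

  # resolve site positions and force reference bases
  roster$precursor <- nm[roster$precIdx]
  armStart <- ifelse(roster$arm == "5p", s5[roster$precIdx],
                     s3[roster$precIdx])
  armEnd <- ifelse(roster$arm == "5p", e5[roster$precIdx],
                   e3[roster$precIdx])
  roster$position <- integer(nrow(roster))
  seqChars <- strsplit(seqs, "")
  for (i in seq_len(nrow(roster))) {
    p <- roster$precIdx[i]
    roster$position[i] <- switch(roster$region[i],
      "3prime" = armEnd[i] + 1L,
      "5prime" = armStart[i] - 1L,
      "seed" = armStart[i] + 3L,
      "central" = armStart[i] + 9L + (p %% 5L))
    pos <- roster$position[i]
    if (roster$tail[i]) {
      # ensure the templated continuation differs from the added base
      if (seqChars[[p]][pos] == roster$alt[i])
        seqChars[[p]][pos] <- setdiff(DNA_BASES, roster$alt[i])[1L]
      roster$ref[i] <- seqChars[[p]][pos]
    } else {
      seqChars[[p]][pos] <- roster$ref[i]
    }
  }
  # decoy: duplicate the 3p arm (and its planted bases) of hairpin np-1
  # into hairpin np, which will receive no reads of its own
  src <- np - 1L; dec <- np
  seqChars[[dec]][(s3[dec] - 1L):(e3[dec] + 1L)] <-
    seqChars[[src]][(s3[src] - 1L):(e3[src] + 1L)]
  decRow <- which(roster$precIdx == dec)
  srcRow <- which(roster$precIdx == src)
  if (length(decRow) && length(srcRow)) {
    off <- roster$position[srcRow[1L]] - s3[src]
    roster$position[decRow] <- s3[dec] + off
    roster$ref[decRow] <- roster$ref[srcRow[1L]]
  }
  seqs <- vapply(seqChars, paste, "", collapse = "")

  strand <- ifelse(seq_len(np) %% 7L == 0L, "-", "+")
  gStart <- 1000L + (seq_len(np) - 1L) * 500L
  loci <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(gStart, width = plen), strand = strand)
  names(loci) <- nm
  matures <- S4Vectors::DataFrame(
    precursor = rep(nm, each = 2L),
    name = paste0(rep(nm, each = 2L), c("-5p", "-3p")),
    start = as.integer(rbind(s5, s3)),
    end = as.integer(rbind(e5, e3)),
    arm = rep(c("5p", "3p"), np))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- nm
  precursors <- PrecursorSet(dna, loci = loci, matures = matures)

  roster$site <- formatSiteName(roster$precursor, roster$position,
                                roster$ref, roster$alt)
  snpIdx <- which(roster$intendedType == "SNP")
  snp <- NULL
  if (length(snpIdx)) {
    proj <- .projectGenomic(precursors, roster$precursor[snpIdx],
                            roster$position[snpIdx])
    snp <- data.frame(
      chrom = proj$chrom, position = proj$gPos,
      id = sprintf("snp%d", seq_along(snpIdx)),
      ref = ifelse(proj$neg, .complement(roster$ref[snpIdx]),
                   roster$ref[snpIdx]),
      alt = ifelse(proj$neg, .complement(roster$alt[snpIdx]),
                   roster$alt[snpIdx]))
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(dna, file.path(dir, "precursors.fa"))
    .writeMirbaseGff3(precursors, file.path(dir, "precursors.gff3"),
                      seed = config$seed)
    if (!is.null(snp)) .writeSnpVcf(snp, file.path(dir, "snp.vcf"))
  }
  list(precursors = precursors, sites = roster, snp = snp)
}

# miRBase-dialect GFF3 writer (ID/Name/Derives_from attributes)
.writeMirbaseGff3 <- function(precursors, path, seed = NA) {
  loci <- precursorLoci(precursors)
  mat <- as.data.frame(matureAnnotations(precursors))
  nm <- names(loci)
  primId <- paste0("MI_", seq_along(nm))
  pStart <- GenomicRanges::start(loci)
  pEnd <- GenomicRanges::end(loci)
  str <- as.character(GenomicRanges::strand(loci))
  i <- match(mat$precursor, nm)
  neg <- str[i] == "-"
  mgS <- ifelse(neg, pEnd[i] - mat$end + 1L, pStart[i] + mat$start - 1L)
  mgE <- ifelse(neg, pEnd[i] - mat$start + 1L, pStart[i] + mat$end - 1L)
  gr <- c(
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(loci),
      IRanges::IRanges(pStart, pEnd), strand = str,
      type = "miRNA_primary_transcript", ID = primId, Name = nm,
      Derives_from = NA_character_),
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(loci))[i],
      IRanges::IRanges(mgS, mgE), strand = str[i],
      type = "miRNA", ID = paste0("MIMAT_", seq_len(nrow(mat))),
      Name = mat$name, Derives_from = primId[i]))
  rtracklayer::export(gr, path, format = "gff3")
  if (!is.na(seed))
    cat("# simulation seed:", seed, "\n", file = path, append = TRUE)
  invisible(path)
}

# minimal single-sample-free VCF 4.2 writer for the toy SNP catalog
.writeSnpVcf <- function(snp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=scMirEdit-simulator",
               paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                   "QUAL", "FILTER", "INFO"),
                                 collapse = "\t"))), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                     snp$chrom, snp$position, snp$id, snp$ref, snp$alt),
             con)
  invisible(path)
}

#' Simulate per-cell reads and ground truth
#'
#' For each cell: per-precursor coverage is drawn from the negative-binomial
#' model; each read copies a mature arm with small templated 5'/3' isoform
#' offsets; planted substitution sites are applied per read with probability
#' equal to that cell's true level (drawn once per (site, cell) from the
#' site's per-type Beta distribution); 3' addition sites turn the +1
#' isoform's last base into the non-templated nucleotide with that
#' probability; uniform sequencing error is applied per base; quality
#' strings are Q40 except a contamination fraction carrying one Q20 base in
#' the first 25. The decoy hairpin receives no reads of its own. Truth
#' tables record every (site, cell) true level and intended class.
#'
#' @param config A [simConfig()] object.
#' @param reference Output of [simulateReference()].
#' @param dir Optional output directory; writes per-cell FASTQ files under
#'   \code{cells/}, \code{cell_annotation.tsv} and \code{truth_sites.tsv}.
#' @return List with \code{reads} (named list of
#'   \link[Biostrings]{QualityScaledDNAStringSet}), \code{cells}
#'   (annotation \code{data.frame}), \code{truth} (per (site, cell) levels
#'   and classes) and \code{fastq} (paths, when \code{dir} is given).
#' @export
simulateCells <- function(config, reference, dir = NULL) {
  if (config$meanReads <= 0) stop("coverage mean must be positive")
  set.seed(config$seed + 1L)
  precursors <- reference$precursors
  sites <- reference$sites
  seqs <- as.character(precursorSequences(precursors))
  plen <- nchar(seqs)
  nm <- names(seqs)
  mat <- as.data.frame(matureAnnotations(precursors))
  types <- config$cellTypes
  cells <- data.frame(
    cellId = paste0(rep(types, each = config$cellsPerType), "_",
                    sprintf("%02d", seq_len(config$cellsPerType))),
    cellType = rep(types, each = config$cellsPerType))
  nCells <- nrow(cells)

  # per-(site, cell) true levels
  lambda <- matrix(0, nrow = nrow(sites), ncol = nCells,
                   dimnames = list(sites$site, cells$cellId))
  for (i in seq_len(nrow(sites))) {
    for (tp in types) {
      cols <- which(cells$cellType == tp)
      lambda[i, cols] <- .rLevel(length(cols),
                                 sites[[paste0("mean_", tp)]][i],
                                 sites[[paste0("sd_", tp)]][i])
    }
  }
  # the decoy site mirrors its source (same reads, remapped)
  decRow <- which(sites$intendedType == "Pseudo")
  if (length(decRow) == 1L) {
    srcRow <- which(sites$precIdx == sites$precIdx[decRow] - 1L &
                      !sites$tail & sites$region == "central")
    if (length(srcRow) == 1L) lambda[decRow, ] <- lambda[srcRow, ]
  }
  decoyPrec <- if (length(decRow)) sites$precursor[decRow] else character()

  armTable <- split(mat, mat$precursor)
  subSites <- sites[!sites$tail & sites$intendedType != "Pseudo", ,
                    drop = FALSE]
  tailSites <- sites[sites$tail, , drop = FALSE]

  reads <- vector("list", nCells)
  names(reads) <- cells$cellId
  for (ci in seq_len(nCells)) {
    seqAcc <- character(0)
    for (p in setdiff(nm, decoyPrec)) {
      arms <- armTable[[p]]
      nr <- stats::rnbinom(1L, mu = config$meanReads,
                           size = config$dispersion)
      if (nr == 0L) next
      armIdx <- sample(nrow(arms), nr, replace = TRUE)
      for (ai in seq_len(nrow(arms))) {
        n <- sum(armIdx == ai)
        if (n == 0L) next
        aS <- arms$start[ai]; aE <- arms$end[ai]
        start <- aS - as.integer(stats::runif(n) < config$ext5 & aS > 1L)
        ext <- stats::runif(n) < config$ext3 & aE < plen[p]
        end <- aE + as.integer(ext)
        rd <- substring(seqs[p], start, end)
        # non-templated 3' additions at a planted tail site
        ts <- tailSites[tailSites$precursor == p &
                          tailSites$position == aE + 1L, , drop = FALSE]
        if (nrow(ts) == 1L) {
          lam <- lambda[ts$site, ci]
          nta <- ext & stats::runif(n) < lam
          if (any(nta))
            substr(rd[nta], end[nta] - start[nta] + 1L,
                   end[nta] - start[nta] + 1L) <- ts$alt
        }
        # planted substitutions covered by these reads
        ss <- subSites[subSites$precursor == p &
                         subSites$position >= min(start) &
                         subSites$position <= max(end), , drop = FALSE]
        for (si in seq_len(nrow(ss))) {
          pos <- ss$position[si]
          cov <- start <= pos & end >= pos
          hit <- cov & stats::runif(n) < lambda[ss$site[si], ci]
          if (any(hit))
            substr(rd[hit], pos - start[hit] + 1L,
                   pos - start[hit] + 1L) <- ss$alt[si]
        }
        seqAcc <- c(seqAcc, rd)
      }
    }
    # uniform sequencing error
    w <- nchar(seqAcc)
    nErr <- stats::rbinom(length(seqAcc), w, config$errorRate)
    for (ri in which(nErr > 0L)) {
      for (pos in sample.int(w[ri], nErr[ri])) {
        old <- substr(seqAcc[ri], pos, pos)
        substr(seqAcc[ri], pos, pos) <-
          sample(setdiff(DNA_BASES, old), 1L)
      }
    }
    qual <- strrep("I", w)
    contam <- stats::runif(length(seqAcc)) < config$contamination
    for (ri in which(contam)) {
      pos <- sample.int(min(25L, w[ri]), 1L)
      substr(qual[ri], pos, pos) <- "5"
    }
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqAcc),
      Biostrings::PhredQuality(qual))
    names(x) <- sprintf("%s_r%05d", cells$cellId[ci],
                        seq_along(seqAcc))
    reads[[ci]] <- x
  }

  truth <- data.frame(
    site = rep(sites$site, nCells),
    cell = rep(cells$cellId, each = nrow(sites)),
    cellType = rep(cells$cellType, each = nrow(sites)),
    level = as.vector(lambda),
    type = rep(sites$intendedType, nCells))

  fastq <- NULL
  if (!is.null(dir)) {
    cellDir <- file.path(dir, "cells")
    dir.create(cellDir, recursive = TRUE, showWarnings = FALSE)
    fastq <- file.path(cellDir, paste0(cells$cellId, ".fastq"))
    names(fastq) <- cells$cellId
    for (ci in seq_len(nCells))
      Biostrings::writeQualityScaledXStringSet(reads[[ci]], fastq[ci])
    utils::write.table(cells, file.path(dir, "cell_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste("seed", config$seed),
               file.path(dir, "sim_seed.txt"))
  }
  list(reads = reads, cells = cells, truth = truth, lambda = lambda,
       fastq = fastq)
}

#' Simulate enzyme expression coupled to 3' editing
#'
#' Uncoupled enzymes get independent log-normal expression. For each coupled
#' enzyme the linear model \eqn{level = intercept + slope \cdot \hat e +
#' \epsilon} (with \eqn{\hat e} the z-scored log expression and
#' \eqn{\epsilon \sim N(0, noiseSd)}) is inverted: given the truth levels of
#' the coupled site, \eqn{\hat e = (level - intercept - \epsilon)/slope},
#' and expression is \eqn{exp(logMean + logSd \cdot \hat e)}. Expression is
#' emitted for the cells of \code{config$expressionCellType} only (the
#' population with paired RNA-seq).
#'
#' @param config A [simConfig()] object.
#' @param truth Output of [simulateCells()] (the \code{truth}/\code{lambda}
#'   components are used).
#' @param reference Output of [simulateReference()] (for the default
#'   coupling targets).
#' @param dir Optional output directory; writes \code{expression.tsv}.
#' @return List with \code{expression} (enzymes x cells matrix) and
#'   \code{couplings} (the coupling table with site names).
#' @export
simulateEnzymeExpression <- function(config, truth, reference,
                                     dir = NULL) {
  set.seed(config$seed + 2L)
  cells <- truth$cells
  keep <- cells$cellId[cells$cellType == config$expressionCellType]
  nc <- length(keep)
  enz <- config$enzymes
  couplings <- config$couplings
  if (is.null(couplings)) {
    sites <- reference$sites
    leukA <- which(sites$intendedType == "3'-A" &
                     sites[[paste0("mean_", config$expressionCellType)]] >
                     0)[1L]
    leukU <- which(sites$intendedType == "3'-U" &
                     sites[[paste0("mean_", config$expressionCellType)]] >
                     0)[1L]
    couplings <- data.frame(
      enzyme = c("TENT2", "TUT7"),
      siteIndex = c(leukA, leukU),
      intercept = 0.45, slope = 0.18, noiseSd = 0.11)
    couplings <- couplings[!is.na(couplings$siteIndex), , drop = FALSE]
  }
  couplings$site <- reference$sites$site[couplings$siteIndex]

  expr <- matrix(exp(stats::rnorm(length(enz) * nc, config$logMean,
                                  config$logSd)),
                 nrow = length(enz), dimnames = list(enz, keep))
  for (i in seq_len(nrow(couplings))) {
    e <- couplings$enzyme[i]
    if (!e %in% enz) next
    if (couplings$slope[i] == 0) next  # no coupling: expression stays noise
    lam <- truth$lambda[couplings$site[i], keep]
    eps <- stats::rnorm(nc, 0, couplings$noiseSd[i])
    ehat <- (lam - couplings$intercept[i] - eps) / couplings$slope[i]
    forward <- couplings$intercept[i] + couplings$slope[i] * ehat + eps
    if (mean(forward < 0 | forward > 1) > 0.5)
      warning("coupling for ", e,
              " drives most levels outside [0, 1]; check slope/intercept")
    expr[e, ] <- exp(config$logMean + config$logSd * ehat)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out <- cbind(gene = rownames(expr),
                 as.data.frame(formatC(expr, format = "f", digits = 4)))
    utils::write.table(out, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(expression = expr, couplings = couplings)
}

#' Simulate a complete synthetic study
#'
#' Reference, per-cell reads, ground truth and enzyme expression in one
#' call.
#'
#' @param config A [simConfig()] object.
#' @param dir Optional output directory (files as in the component
#'   functions).
#' @return List combining the outputs of [simulateReference()],
#'   [simulateCells()] and [simulateEnzymeExpression()].
#' @export
simulateCohort <- function(config = simConfig(), dir = NULL) {
  reference <- simulateReference(config, dir = dir)
  cellsOut <- simulateCells(config, reference, dir = dir)
  enzOut <- simulateEnzymeExpression(config, cellsOut, reference,
                                     dir = dir)
  c(reference, cellsOut, enzOut)
}
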