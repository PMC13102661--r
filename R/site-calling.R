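#' @include align.R
NULL

SITE_TYPES <- c("A-to-I", "C-to-U", "3'-A", "3'-U", "3'-Other",
                "5'-editing", "Other", "SNP", "Pseudo")

#' Build weighted position pileups
#'
#' Aggregates weighted alignments into per-position nucleotide counts. A body
#' match adds the read's \code{count * weight} to the templated nucleotide;
#' the (at most one) body mismatch adds to the alternative nucleotide; tail
#' base \eqn{j} of a read whose body ends at position \eqn{e} adds to
#' position \eqn{e + j} when that position still lies on the precursor.
#' Tail bases overhanging the precursor 3' end are tallied separately and are
#' not site-callable (a site needs a templated reference nucleotide).
#'
#' @param alignments Weighted alignments from [crossMappingWeights()].
#' @param precursors A \linkS4class{PrecursorSet} or named
#'   \link[Biostrings]{DNAStringSet}.
#' @return \code{data.frame} with one row per (precursor, position,
#'   nucleotide): \code{precursor}, \code{position}, \code{ref}, \code{nt},
#'   \code{w} (weighted count), \code{raw} (integer read count). Attribute
#'   \code{"overhang"} counts tail bases beyond the precursor end.
#' @export
buildPileups <- function(alignments, precursors) {
  seqs <- if (is(precursors, "PrecursorSet"))
    precursorSequences(precursors) else precursors
  if (nrow(alignments) == 0L) {
    out <- data.frame(precursor = character(), position = integer(),
                      ref = character(), nt = character(),
                      w = numeric(), raw = integer())
    attr(out, "overhang") <- 0
    return(out)
  }
  if (anyNA(alignments$weight))
    stop("alignments carry no weights; run crossMappingWeights() first")
  precChar <- as.character(seqs)
  plen <- nchar(precChar)
  bigChars <- strsplit(paste(precChar, collapse = ""), "")[[1L]]
  offset <- stats::setNames(cumsum(c(0L, utils::head(plen, -1L))),
                            names(seqs))

  a <- alignments
  pid <- match(a$precursor, names(seqs))
  wgt <- a$count * a$weight

  # body events
  bl <- a$bodyLen
  rowRep <- rep.int(seq_len(nrow(a)), bl)
  pos <- rep.int(a$start, bl) + sequence(bl) - 1L
  nt <- bigChars[offset[pid][rowRep] + pos]
  isMm <- !is.na(a$mmPos[rowRep]) & pos == a$mmPos[rowRep]
  nt[isMm] <- a$mmAlt[rowRep][isMm]
  ev <- data.frame(
    precursor = a$precursor[rowRep], position = pos, nt = nt,
    w = wgt[rowRep], raw = a$count[rowRep])

  # tail events
  tl <- nchar(a$tail)
  overhang <- 0
  if (any(tl > 0L)) {
    tRep <- rep.int(seq_len(nrow(a)), tl)
    tPos <- rep.int(a$start + a$bodyLen - 1L, tl) + sequence(tl)
    tNt <- substring(a$tail[tRep], sequence(tl), sequence(tl))
    onPrec <- tPos <= plen[pid][tRep]
    overhang <- sum(a$count[tRep][!onPrec])
    if (any(onPrec)) {
      ev <- rbind(ev, data.frame(
        precursor = a$precursor[tRep][onPrec], position = tPos[onPrec],
        nt = tNt[onPrec], w = wgt[tRep][onPrec],
        raw = a$count[tRep][onPrec]))
    }
  }

  key <- paste(ev$precursor, ev$position, ev$nt, sep = "\r")
  agg <- rowsum(cbind(w = ev$w, raw = ev$raw), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    precursor = vapply(parts, `[`, "", 1L),
    position = as.integer(vapply(parts, `[`, "", 2L)),
    nt = vapply(parts, `[`, "", 3L),
    w = agg[, "w"], raw = as.integer(agg[, "raw"]),
    row.names = NULL)
  out$ref <- bigChars[offset[match(out$precursor, names(seqs))] +
                        out$position]
  out <- out[order(out$precursor, out$position, out$nt),
             c("precursor", "position", "ref", "nt", "w", "raw")]
  rownames(out) <- NULL
  attr(out, "overhang") <- overhang
  out
}

#' Relative editing level
#'
#' The fraction of (cross-mapping-weighted) reads carrying the alternative
#' nucleotide among all reads covering the position.
#'
#' @param counts Named numeric vector of per-nucleotide weighted counts at
#'   one position.
#' @param alt The alternative nucleotide.
#' @return Editing level in [0, 1].
#' @export
#' @examples
#' editingLevel(c(A = 90, G = 10), "G")  # 0.1
editingLevel <- function(counts, alt) {
  n <- sum(counts)
  if (n <= 0) stop("editing level undefined at zero coverage")
  v <- counts[alt]
  if (is.na(v)) v <- 0
  unname(v) / n
}

#' Binomial sequencing-error p-value
#'
#' Probability of observing at least \code{k} alternative reads among
#' \code{n} under the sequencing-error null \eqn{X \sim Binomial(n, e)},
#' computed as a numerically stable survival sum in log space. The default
#' error rate derives from the read-score threshold Q30:
#' \eqn{e = 10^{-30/10} = 10^{-3}}.
#'
#' @param k Integer alt-read support (vectorized).
#' @param n Integer coverage (vectorized).
#' @param e Per-base error rate in (0, 1).
#' @return P(X >= k).
#' @export
#' @examples
#' binomialSitePvalue(10, 10)          # 1e-30
#' binomialSitePvalue(1, 1000)         # 1 - 0.999^1000
binomialSitePvalue <- function(k, n, e = 1e-3) {
  if (length(e) != 1L || is.na(e) || e <= 0 || e >= 1)
    stop("error rate e must lie strictly between 0 and 1")
  if (anyNA(k) || anyNA(n) || any(k < 0) || any(k > n) ||
      any(k != round(k)) || any(n != round(n)))
    stop("k and n must be integers with 0 <= k <= n")
  k <- as.numeric(k); n <- as.numeric(n)
  vapply(seq_along(k), function(i) {
    if (k[i] == 0) return(1)
    ii <- k[i]:n[i]
    lt <- lchoose(n[i], ii) + ii * log(e) + (n[i] - ii) * log1p(-e)
    m <- max(lt)
    min(1, exp(m) * sum(exp(lt - m)))
  }, numeric(1L))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call M/E sites in one sample
#'
#' Every (position, alternative nucleotide) with at least one supporting
#' read becomes a candidate. Its editing level uses cross-mapping-weighted
#' counts; the binomial p-value and the support rule use raw integer read
#' counts (a conservative reading of "at least 10 reads"). P-values are
#' BH-adjusted across all candidates within the sample, and a candidate is
#' significant iff level >= \code{minLevel}, raw support >=
#' \code{minSupport} and adjusted p < \code{alpha}. All candidates are
#' returned with their significance flag.
#'
#' @param pileups Pileup table from [buildPileups()].
#' @param errorRate Binomial error rate (default \code{1e-3}, from Q30).
#' @param minLevel Minimum relative editing level (default 0.05).
#' @param minSupport Minimum raw read support (default 10).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return \code{data.frame} of candidate calls in deterministic order
#'   (precursor, position, alt): columns \code{precursor}, \code{position},
#'   \code{ref}, \code{alt}, \code{site}, \code{level}, \code{k}, \code{n},
#'   \code{rawK}, \code{rawN}, \code{meanWeight}, \code{p}, \code{pAdj},
#'   \code{significant}.
#' @export
callSites <- function(pileups, errorRate = 1e-3, minLevel = 0.05,
                      minSupport = 10L, alpha = 0.05) {
  empty <- data.frame(
    precursor = character(), position = integer(), ref = character(),
    alt = character(), site = character(), level = numeric(),
    k = numeric(), n = numeric(), rawK = integer(), rawN = integer(),
    meanWeight = numeric(), p = numeric(), pAdj = numeric(),
    significant = logical())
  if (nrow(pileups) == 0L) return(empty)
  posKey <- paste(pileups$precursor, pileups$position, sep = "\r")
  wTot <- rowsum(pileups$w, posKey)
  rawTot <- rowsum(pileups$raw, posKey)
  idx <- match(posKey, rownames(wTot))
  cand <- pileups$nt != pileups$ref & pileups$nt %in% DNA_BASES &
    pileups$raw >= 1L
  if (!any(cand)) return(empty)
  cc <- pileups[cand, , drop = FALSE]
  n <- wTot[idx[cand], 1L]
  rawN <- rawTot[idx[cand], 1L]
  out <- data.frame(
    precursor = cc$precursor, position = cc$position, ref = cc$ref,
    alt = cc$nt,
    site = formatSiteName(cc$precursor, cc$position, cc$ref, cc$nt),
    level = cc$w / n, k = cc$w, n = n,
    rawK = cc$raw, rawN = as.integer(rawN),
    meanWeight = cc$w / cc$raw,
    p = binomialSitePvalue(cc$raw, rawN, errorRate))
  out$pAdj <- bhAdjust(out$p)
  out$significant <- out$level >= minLevel & out$rawK >= minSupport &
    out$pAdj < alpha
  out <- out[order(out$precursor, out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify candidate sites into the nine M/E types
#'
#' Decision order per candidate: (1) \code{SNP} when the site's genomic
#' projection matches a catalog record (position and both alleles,
#' strand-aware) and its editing level reaches 100\% in at least one cohort
#' sample; (2) \code{Pseudo} when the mean cross-mapping weight of the
#' supporting reads is below 0.5 (the reads mostly belong elsewhere);
#' (3) 3' types when the position lies beyond the 3' end of the nearest
#' upstream mature arm, keyed by the added nucleotide (\code{3'-A},
#' \code{3'-U}, \code{3'-Other}); (4) \code{5'-editing} when the position
#' precedes every mature 5' start; (5) within the mature body, A>G is
#' \code{A-to-I}, C>T is \code{C-to-U}, anything else \code{Other}.
#'
#' @param calls Candidate table from [callSites()].
#' @param precursors A \linkS4class{PrecursorSet} (mature annotations and
#'   genomic loci are needed).
#' @param snp Optional SNP catalog from [readSnpCatalog()].
#' @param maxLevel Optional named vector (site name -> maximum editing level
#'   across the cohort) used for the 100\%-level SNP criterion; defaults to
#'   each call's own level (single-sample behaviour).
#' @return \code{calls} with a \code{type} column added.
#' @export
classifySites <- function(calls, precursors, snp = NULL, maxLevel = NULL) {
  if (nrow(calls) == 0L) {
    calls$type <- character()
    return(calls)
  }
  mat <- as.data.frame(matureAnnotations(precursors))
  annotated <- unique(mat$precursor)
  if (!all(calls$precursor %in% annotated))
    warning("precursor(s) without mature annotation; ",
            "whole precursor treated as mature body")
  lv <- if (is.null(maxLevel)) calls$level
        else unname(maxLevel[calls$site])

  isSnp <- rep(FALSE, nrow(calls))
  if (!is.null(snp) && nrow(snp) > 0L) {
    proj <- .projectGenomic(precursors, calls$precursor, calls$position)
    gRef <- ifelse(proj$neg, .complement(calls$ref), calls$ref)
    gAlt <- ifelse(proj$neg, .complement(calls$alt), calls$alt)
    hit <- match(paste(proj$chrom, proj$gPos, gRef, gAlt),
                 paste(snp$chrom, snp$position, snp$ref, snp$alt))
    isSnp <- !is.na(hit) & !is.na(lv) & lv >= 1 - 1e-9
  }

  type <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (isSnp[i]) { type[i] <- "SNP"; next }
    if (!is.na(calls$meanWeight[i]) && calls$meanWeight[i] < 0.5) {
      type[i] <- "Pseudo"; next
    }
    arms <- mat[mat$precursor == calls$precursor[i], , drop = FALSE]
    pos <- calls$position[i]
    ref <- calls$ref[i]; alt <- calls$alt[i]
    inBody <- if (nrow(arms) == 0L) TRUE
      else any(pos >= arms$start & pos <= arms$end)
    if (inBody) {
      type[i] <- if (ref == "A" && alt == "G") "A-to-I"
        else if (ref == "C" && alt == "T") "C-to-U"
        else "Other"
    } else if (pos < min(arms$start)) {
      type[i] <- "5'-editing"
    } else {
      type[i] <- switch(alt, A = "3'-A", T = "3'-U", "3'-Other")
    }
  }
  calls$type <- type
  calls
}

#' Tags per ten million reads
#'
#' Depth-normalized abundance: \code{count / total * 1e7}.
#'
#' @param count (Weighted) read count of the entity.
#' @param total Total qualified reads in the sample.
#' @return TPTM abundance.
#' @export
tptm <- function(count, total) {
  if (any(total <= 0)) stop("total qualified reads must be positive")
  count / total * 1e7
}

#' Run the per-sample pipeline
#'
#' FASTQ to classified site calls for a single cell: quality filter
#' (Q >= \code{qMin} over the first \code{window} bases), collapse to unique
#' sequences (>= \code{minLen} nt), exact precursor alignment, cross-mapping
#' weighting, pileup construction and site calling/classification.
#'
#' @param fastq Path to a FASTQ(.gz) file, or a
#'   \link[Biostrings]{QualityScaledDNAStringSet}.
#' @param precursors A \linkS4class{PrecursorSet}.
#' @param sampleId Sample identifier (defaults to the file name).
#' @param cellType Optional cell-type label.
#' @param snp Optional SNP catalog ([readSnpCatalog()]).
#' @param qMin,window,minLen Preprocessing parameters (see
#'   [qualifyReads()], [collapseUnique()]).
#' @param maxMismatch,maxTail Aligner parameters (see [alignSample()]).
#' @param errorRate,minLevel,minSupport,alpha Caller parameters (see
#'   [callSites()]).
#' @return A \linkS4class{SampleProfile}.
#' @export
processSample <- function(fastq, precursors, sampleId = NULL,
                          cellType = NA_character_, snp = NULL,
                          qMin = 30L, window = 25L, minLen = 19L,
                          maxMismatch = 1L, maxTail = 3L,
                          errorRate = 1e-3, minLevel = 0.05,
                          minSupport = 10L, alpha = 0.05) {
  if (is.character(fastq)) {
    if (is.null(sampleId))
      sampleId <- sub("\\.f(ast)?q(\\.gz)?$", "", basename(fastq))
    fastq <- readFastqReads(fastq)
  }
  if (is.null(sampleId)) sampleId <- "sample"
  qualified <- qualifyReads(fastq, qMin = qMin, window = window)
  nq <- attr(qualified, "nReads")
  uniq <- suppressWarnings(collapseUnique(qualified, minLen = minLen))
  aln <- alignSample(uniq, precursors, maxMismatch = maxMismatch,
                     maxTail = maxTail)
  aln <- crossMappingWeights(aln)
  pile <- buildPileups(aln, precursors)
  calls <- callSites(pile, errorRate = errorRate, minLevel = minLevel,
                     minSupport = minSupport, alpha = alpha)
  calls <- classifySites(calls, precursors, snp = snp)
  posKey <- paste(pile$precursor, pile$position, sep = "\r")
  cov <- rowsum(cbind(n = pile$w, rawN = pile$raw), posKey)
  parts <- strsplit(rownames(cov), "\r", fixed = TRUE)
  coverage <- data.frame(
    precursor = vapply(parts, `[`, "", 1L),
    position = as.integer(vapply(parts, `[`, "", 2L)),
    n = cov[, "n"], rawN = as.integer(cov[, "rawN"]), row.names = NULL)
  new("SampleProfile",
      sampleId = sampleId, cellType = as.character(cellType),
      calls = calls, coverage = coverage,
      nReads = c(raw = unname(nq["raw"]),
                 qualified = unname(nq["qualified"]),
                 unique = nrow(uniq),
                 mapped = sum(uniq$count) - attr(aln, "nUnmapped"),
                 unmapped = attr(aln, "nUnmapped")))
}

#' @rdname scMirEdit-accessors
#' @param significantOnly For \code{siteCalls} on a
#'   \linkS4class{SampleProfile}: return only significant calls.
#' @param ... Passed between methods.
#' @export
setMethod("siteCalls", "SampleProfile",
  function(x, significantOnly = FALSE, ...) {
    if (significantOnly) x@calls[x@calls$significant, , drop = FALSE]
    else x@calls
  })

setMethod("show", "SampleProfile", function(object) {
  cat("SampleProfile", object@sampleId,
      if (!is.na(object@cellType)) paste0("(", object@cellType, ")"), "\n")
  nr <- object@nReads
  cat("  reads: ", nr["raw"], " raw, ", nr["qualified"], " qualified, ",
      nr["unique"], " unique, ", nr["unmapped"], " unmapped\n", sep = "")
  cat("  sites: ", nrow(object@calls), " candidates, ",
      sum(object@calls$significant), " significant\n", sep = "")
})

#' Write per-sample site calls as TSV
#'
#' Deterministic row order (precursor, position, alt), matching the caller
#' output.
#'
#' @param profile A \linkS4class{SampleProfile}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSiteCalls <- function(profile, path) {
  cl <- siteCalls(profile)
  cols <- c("site", "type", "level", "rawK", "rawN", "k", "n",
            "meanWeight", "p", "pAdj", "significant")
  utils::write.table(cl[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
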