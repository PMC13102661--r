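#' @include preprocess.R
#' @useDynLib scMirEdit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Align reads to pre-miRNA hairpins
#'
#' Exact short-read alignment against the precursor set. A read aligns at an
#' offset when it decomposes into a templated body with at most
#' \code{maxMismatch} substitutions followed by a 3' tail of at most
#' \code{maxTail} bases. The body is maximal at each offset (a templated
#' explanation beats a tail explanation), so a non-empty tail either
#' overhangs the precursor 3' end or starts with a base that disagrees with
#' the templated continuation. Every admissible (precursor, offset) is
#' reported; multi-mapping is resolved afterwards by
#' [crossMappingWeights()].
#'
#' This replaces the conventional genome-level BLASTN/Bowtie chain: at
#' precursor scale the hairpins are the only mapping targets, and what the
#' site caller needs is exactly this body/tail decomposition.
#'
#' @param unique A \code{data.frame} from [collapseUnique()] (columns
#'   \code{sequence}, \code{count}), or a character vector of sequences.
#' @param precursors A \linkS4class{PrecursorSet} or named
#'   \link[Biostrings]{DNAStringSet}.
#' @param maxMismatch Mismatch budget within the body (default 1).
#' @param maxTail Maximum 3' tail length (default 3).
#' @return \code{data.frame} with one row per alignment: \code{sequence},
#'   \code{count}, \code{precursor}, \code{start}, \code{bodyLen},
#'   \code{mmPos}, \code{mmRef}, \code{mmAlt}, \code{tail}, \code{weight}
#'   (initialized to NA until cross-mapping correction). Reads with no
#'   alignment are counted in attribute \code{"nUnmapped"}.
#' @export
alignSample <- function(unique, precursors, maxMismatch = 1L, maxTail = 3L) {
  if (is.character(unique))
    unique <- data.frame(sequence = unique,
                         count = rep(1L, length(unique)))
  seqs <- if (is(precursors, "PrecursorSet"))
    precursorSequences(precursors) else precursors
  precChar <- as.character(seqs)
  hits <- .alignReadsCpp(unique$sequence, unname(precChar),
                         maxMismatch = as.integer(maxMismatch),
                         maxTail = as.integer(maxTail))
  out <- data.frame(
    sequence = unique$sequence[hits$readIdx],
    count = unique$count[hits$readIdx],
    precursor = names(seqs)[hits$precIdx],
    start = hits$start,
    bodyLen = hits$bodyLen,
    mmPos = hits$mmPos,
    mmRef = hits$mmRef,
    mmAlt = hits$mmAlt,
    tail = hits$tail,
    weight = NA_real_,
    stringsAsFactors = FALSE)
  attr(out, "nUnmapped") <-
    sum(unique$count[!seq_len(nrow(unique)) %in% hits$readIdx])
  out
}

#' @rdname alignSample
#' @param read A single read sequence.
#' @param precursor A single precursor sequence (character or DNAString).
#' @return \code{alignRead}: alignments of one read against one precursor.
#' @export
alignRead <- function(read, precursor, maxMismatch = 1L, maxTail = 3L) {
  pr <- Biostrings::DNAStringSet(as.character(precursor))
  names(pr) <- "precursor"
  alignSample(data.frame(sequence = as.character(read), count = 1L),
              pr, maxMismatch, maxTail)
}

#' Cross-mapping correction weights
#'
#' Iterative expression-proportional reallocation of multi-mapping reads.
#' Each read's weight is initialized uniformly over its alignment loci;
#' then, repeatedly, the weighted expression of each precursor is
#' \eqn{E(p) = \sum_r count_r w_{rp}} and the new weight is
#' \eqn{w_{rp} = E(p) / \sum_{p' \in loci(r)} E(p')}, until the largest
#' absolute weight change drops below \code{tol} or \code{maxIter} is
#' reached. Single-locus reads keep weight 1. When all of a read's loci have
#' zero expression its weights revert to uniform (with a message).
#'
#' @param alignments \code{data.frame} from [alignSample()].
#' @param tol Convergence threshold on the max absolute weight change.
#' @param maxIter Iteration cap.
#' @return \code{alignments} with the \code{weight} column filled in;
#'   attribute \code{"iterations"} records the iteration count.
#' @export
crossMappingWeights <- function(alignments, tol = 1e-6, maxIter = 100L) {
  n <- nrow(alignments)
  if (n == 0L) {
    attr(alignments, "iterations") <- 0L
    return(alignments)
  }
  readId <- match(alignments$sequence, unique(alignments$sequence))
  precId <- match(alignments$precursor, unique(alignments$precursor))
  nLoci <- tabulate(readId)[readId]
  # warm-start from existing weights so re-running on a converged table is
  # a no-op (fixed-point property); otherwise initialize uniformly
  w <- if (!anyNA(alignments$weight)) alignments$weight else 1 / nLoci
  count <- alignments$count
  iter <- 0L
  repeat {
    iter <- iter + 1L
    expr <- rowsum(count * w, precId)          # E(p)
    eHere <- expr[precId, 1L]
    denom <- rowsum(eHere, readId)[readId, 1L] # sum over the read's loci
    wNew <- ifelse(denom > 0, eHere / denom, 1 / nLoci)
    if (any(denom == 0))
      message("crossMappingWeights: read(s) with all-zero locus expression",
              " reverted to uniform weights")
    delta <- max(abs(wNew - w))
    w <- wNew
    if (delta < tol || iter >= maxIter) break
  }
  alignments$weight <- w
  attr(alignments, "iterations") <- iter
  alignments
}
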