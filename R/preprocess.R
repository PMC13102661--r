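#' @include reference-io.R
NULL

#' Read a small-RNA FASTQ file
#'
#' Thin wrapper over Biostrings FASTQ input (Phred+33). Gzip input is
#' handled transparently.
#'
#' @param path Path to a FASTQ(.gz) file.
#' @return A \link[Biostrings]{QualityScaledDNAStringSet}.
#' @export
readFastqReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # Biostrings warns about dropping its own internal quality mcols here
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns on input", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Quality-filter raw reads
#'
#' A read is qualified when every base among its first
#' \code{min(window, length)} bases has a Phred score of at least
#' \code{qMin}. Reads shorter than the window are constrained over their
#' whole length; qualified reads are kept whole (no trimming).
#'
#' @param reads A \link[Biostrings]{QualityScaledDNAStringSet}
#'   (see [readFastqReads()]).
#' @param qMin Minimum Phred score (default 30).
#' @param window Number of 5' bases constrained (default 25).
#' @return The qualified subset, with attribute \code{"nReads"} carrying
#'   \code{c(raw = ..., qualified = ...)} counters ("valid reads").
#' @export
qualifyReads <- function(reads, qMin = 30L, window = 25L) {
  if (length(reads) == 0L) {
    out <- reads
    attr(out, "nReads") <- c(raw = 0L, qualified = 0L)
    return(out)
  }
  w <- Biostrings::width(reads)
  q <- Biostrings::quality(reads)
  if (any(Biostrings::width(q) != w)) {
    bad <- which(Biostrings::width(q) != w)[1L]
    stop("sequence/quality length mismatch for read ",
         names(reads)[bad] %||% bad)
  }
  head5 <- IRanges::narrow(q, start = 1L, end = pmin(w, window))
  minQ <- min(methods::as(head5, "IntegerList"))
  keep <- minQ >= qMin
  out <- reads[keep]
  attr(out, "nReads") <- c(raw = length(reads), qualified = sum(keep))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Collapse qualified reads to unique sequences
#'
#' Counts the multiplicity of each distinct sequence, dropping sequences
#' shorter than \code{minLen} (default 19 nt, i.e. "more than 18
#' nucleotides"). Output is sorted by descending count, then
#' lexicographically by sequence, so collapsed files are deterministic.
#'
#' @param reads A \link[Biostrings]{XStringSet} or character vector of
#'   qualified read sequences.
#' @param minLen Minimum retained read length (default 19).
#' @return \code{data.frame} with columns \code{sequence} and \code{count};
#'   attribute \code{"nDropped"} counts reads lost to the length filter.
#' @export
collapseUnique <- function(reads, minLen = 19L) {
  seqs <- as.character(reads)
  if (length(seqs) == 0L) {
    warning("collapseUnique: no input reads")
    out <- data.frame(sequence = character(), count = integer())
    attr(out, "nDropped") <- 0L
    return(out)
  }
  keep <- nchar(seqs) >= minLen
  nDropped <- sum(!keep)
  seqs <- seqs[keep]
  if (length(seqs) == 0L) {
    warning("collapseUnique: all reads shorter than ", minLen, " nt")
    out <- data.frame(sequence = character(), count = integer())
    attr(out, "nDropped") <- nDropped
    return(out)
  }
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nDropped") <- nDropped
  out
}

#' Collapsed-FASTA interchange
#'
#' Writes unique reads in the count-bearing header dialect
#' \code{>seq<i>_x<count>} used by small-RNA tools, and reads it back.
#'
#' @param unique A \code{data.frame} from [collapseUnique()].
#' @param path FASTA path.
#' @return \code{writeCollapsedFasta}: \code{path}, invisibly.
#' @export
writeCollapsedFasta <- function(unique, path) {
  x <- Biostrings::DNAStringSet(unique$sequence)
  names(x) <- sprintf("seq%d_x%d", seq_len(nrow(unique)), unique$count)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname writeCollapsedFasta
#' @export
readCollapsedFasta <- function(path) {
  x <- readPrecursorFasta(path)
  count <- suppressWarnings(as.integer(sub("^.*_x", "", names(x))))
  if (anyNA(count))
    stop("collapsed FASTA headers must end in _x<count>")
  data.frame(sequence = as.character(x), count = count, row.names = NULL)
}
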