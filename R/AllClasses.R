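#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet width
#' @importFrom GenomicRanges GRanges seqnames strand start end
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

#' Pre-miRNA reference set
#'
#' Container for pre-miRNA hairpin sequences together with their genomic loci
#' and mature-arm annotations. Sequences are stored in the DNA alphabet
#' (U is normalized to T on input); all coordinates are 1-based inclusive.
#' Mature coordinates are precursor-local, i.e. positions on the hairpin.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} of hairpin sequences,
#'   named by precursor.
#' @slot loci A \link[GenomicRanges]{GRanges} of genomic loci, parallel to
#'   \code{sequences} (same names, same order); width equals sequence length.
#' @slot matures A \link[S4Vectors]{DataFrame} with columns
#'   \code{precursor}, \code{name}, \code{start}, \code{end}, \code{arm}
#'   (\code{"5p"} or \code{"3p"}); \code{start}/\code{end} are precursor-local.
#'
#' @details Validity enforces the hairpin invariants: sequence lengths in
#' [40, 200], locus width equal to sequence length, one or two mature arms per
#' precursor, mature lengths in [18, 26] and mature intervals inside the
#' precursor. The seed region of a mature is positions
#' \code{start + 1 .. start + 7} (nucleotides 2-8 of the mature).
#'
#' @seealso [readMirnaGff3()], [simulateReference()]
#' @exportClass PrecursorSet
setClass("PrecursorSet",
  slots = c(
    sequences = "DNAStringSet",
    loci = "GRanges",
    matures = "DataFrame"
  )
)

setValidity("PrecursorSet", function(object) {
  msg <- character()
  nm <- names(object@sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "sequences must be named by precursor")
  if (anyDuplicated(nm))
    msg <- c(msg, paste("duplicate precursor names:",
                        paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  w <- Biostrings::width(object@sequences)
  if (any(w < 40L | w > 200L))
    msg <- c(msg, "precursor sequence lengths must be in [40, 200]")
  if (length(object@loci) != length(object@sequences))
    msg <- c(msg, "loci and sequences must be parallel")
  else if (any(GenomicRanges::width(object@loci) != w))
    msg <- c(msg, "locus width must equal sequence length")
  m <- object@matures
  need <- c("precursor", "name", "start", "end", "arm")
  if (!all(need %in% colnames(m))) {
    msg <- c(msg, paste("matures must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(m) > 0L) {
    if (!all(m$precursor %in% nm))
      msg <- c(msg, "mature rows refer to unknown precursors")
    per <- table(m$precursor)
    if (any(per > 2L))
      msg <- c(msg, "at most 2 mature arms per precursor")
    if (length(per) < length(nm))
      msg <- c(msg, "every precursor needs at least one mature arm")
    len <- m$end - m$start + 1L
    if (any(len < 18L | len > 26L))
      msg <- c(msg, "mature lengths must be in [18, 26]")
    plen <- stats::setNames(w, nm)[as.character(m$precursor)]
    if (any(m$start < 1L) || any(m$end > plen))
      msg <- c(msg, "mature intervals must lie within the precursor")
    if (!all(m$arm %in% c("5p", "3p")))
      msg <- c(msg, "arm must be '5p' or '3p'")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell M/E profile
#'
#' Result of running one cell's small-RNA reads through the per-sample
#' pipeline: all candidate mutation/editing sites with levels, support,
#' binomial p-values and nine-type classification, together with per-position
#' coverage and read-accounting statistics.
#'
#' @slot sampleId Single cell/sample identifier.
#' @slot cellType Cell-type label (may be \code{NA} until annotated).
#' @slot calls A \code{data.frame} of candidate sites: \code{precursor},
#'   \code{position}, \code{ref}, \code{alt} (DNA alphabet), \code{site}
#'   (codec name), \code{level}, \code{k} (weighted alt support), \code{n}
#'   (weighted coverage), \code{rawK}, \code{rawN} (integer read counts),
#'   \code{meanWeight}, \code{p}, \code{pAdj}, \code{significant},
#'   \code{type}.
#' @slot coverage A \code{data.frame} with \code{precursor}, \code{position},
#'   \code{n} (weighted) and \code{rawN} for every covered position, used to
#'   distinguish "covered but unedited" (level 0) from "no coverage" (NA)
#'   when profiles are combined.
#' @slot nReads Named numeric vector of read-accounting counters:
#'   \code{raw}, \code{qualified}, \code{unique}, \code{mapped},
#'   \code{unmapped}.
#'
#' @seealso [processSample()], [combineSamples()]
#' @exportClass SampleProfile
setClass("SampleProfile",
  slots = c(
    sampleId = "character",
    cellType = "character",
    calls = "data.frame",
    coverage = "data.frame",
    nReads = "numeric"
  )
)

setValidity("SampleProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  cl <- object@calls
  if (nrow(cl) > 0L) {
    key <- paste(cl$precursor, cl$position, cl$alt)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate site keys within a sample")
    if (any(cl$level < 0 | cl$level > 1, na.rm = TRUE))
      msg <- c(msg, "levels must be in [0, 1]")
    if (any(cl$k > cl$n + 1e-9))
      msg <- c(msg, "alt support k must not exceed coverage n")
  }
  if (length(msg)) msg else TRUE
})

#' Cohort editing-level matrix
#'
#' Sites-by-cells matrix of editing levels with cell-type annotation, stored
#' as a \link[SummarizedExperiment]{SummarizedExperiment} with a single
#' \code{"level"} assay. \code{NA} encodes absent coverage; 0 means the
#' position was covered but unedited in that cell. Row metadata carries the
#' site decomposition (\code{precursor}, \code{position}, \code{ref},
#' \code{alt}) and the consensus nine-type classification (\code{type});
#' column metadata carries \code{cellType} and optionally \code{subline}.
#'
#' @seealso [combineSamples()], [editingLevels()], [cellTypes()],
#'   [siteTypes()]
#' @exportClass EditingExperiment
setClass("EditingExperiment", contains = "SummarizedExperiment")

setValidity("EditingExperiment", function(object) {
  msg <- character()
  if (!"level" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "an assay named 'level' is required")
  else {
    lv <- SummarizedExperiment::assay(object, "level")
    if (any(lv < 0 | lv > 1, na.rm = TRUE))
      msg <- c(msg, "editing levels must be in [0, 1] or NA")
  }
  if (!"cellType" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'cellType' column")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate site names")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate cell ids")
  if (length(msg)) msg else TRUE
})
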