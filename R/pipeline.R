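#' @include simulate.R
NULL

#' Run the per-cell pipeline across a cohort and combine
#'
#' Processes every cell's reads with [processSample()] and combines the
#' resulting profiles into an \linkS4class{EditingExperiment} with
#' [combineSamples()].
#'
#' @param fastq Named list/vector: per-cell FASTQ paths or
#'   \link[Biostrings]{QualityScaledDNAStringSet} objects; names are cell
#'   ids.
#' @param precursors A \linkS4class{PrecursorSet}.
#' @param annotations Cell-annotation \code{data.frame} (\code{cellId},
#'   \code{cellType}).
#' @param snp Optional SNP catalog.
#' @param minPrevalence Cohort prevalence fraction (default 0.05).
#' @param verbose Print a progress line every 25 cells.
#' @param ... Further parameters passed to [processSample()].
#' @return List with \code{profiles} (list of \linkS4class{SampleProfile})
#'   and \code{editing} (\linkS4class{EditingExperiment}).
#' @export
runCohort <- function(fastq, precursors, annotations, snp = NULL,
                      minPrevalence = 0.05, verbose = FALSE, ...) {
  ids <- names(fastq)
  if (is.null(ids)) stop("fastq must be named by cell id")
  typeOf <- stats::setNames(annotations$cellType, annotations$cellId)
  profiles <- vector("list", length(fastq))
  for (i in seq_along(fastq)) {
    profiles[[i]] <- processSample(
      fastq[[i]], precursors, sampleId = ids[i],
      cellType = unname(typeOf[ids[i]]), snp = snp, ...)
    if (verbose && i %% 25L == 0L)
      message("processed ", i, "/", length(fastq), " cells")
  }
  names(profiles) <- ids
  editing <- combineSamples(profiles, annotations = annotations,
                            minPrevalence = minPrevalence,
                            precursors = precursors, snp = snp)
  list(profiles = profiles, editing = editing)
}
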