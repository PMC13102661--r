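#' @include AllGenerics.R
NULL

## Internal alphabet is DNA; RNA (U) appears only at I/O boundaries.
DNA_BASES <- c("A", "C", "G", "T")

.dnaToRna <- function(x) chartr("Tt", "Uu", x)
.rnaToDna <- function(x) chartr("Uu", "Tt", x)
.complement <- function(x) chartr("ACGT", "TGCA", x)

#' Construct a PrecursorSet
#'
#' @param sequences Named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of hairpin sequences.
#' @param loci \link[GenomicRanges]{GRanges} of genomic loci parallel to
#'   \code{sequences}. If missing, a toy locus on "chrU" is fabricated so that
#'   purely sequence-level workflows remain possible.
#' @param matures \code{data.frame} or \link[S4Vectors]{DataFrame} with
#'   columns \code{precursor}, \code{name}, \code{start}, \code{end},
#'   \code{arm} (precursor-local 1-based coordinates).
#' @return A \linkS4class{PrecursorSet}.
#' @export
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(p1 = paste(rep("ACGT", 15), collapse = "")))
#' mat <- data.frame(precursor = "p1", name = "p1-5p", start = 5, end = 26,
#'                   arm = "5p")
#' PrecursorSet(seqs, matures = mat)
PrecursorSet <- function(sequences, loci = NULL, matures) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(loci)) {
    w <- Biostrings::width(sequences)
    starts <- cumsum(c(1L, utils::head(w + 100L, -1L)))
    loci <- GenomicRanges::GRanges(
      "chrU", IRanges::IRanges(starts, width = w), strand = "+")
    names(loci) <- names(sequences)
  }
  if (is.data.frame(matures)) matures <- S4Vectors::DataFrame(matures)
  new("PrecursorSet", sequences = sequences, loci = loci, matures = matures)
}

#' @rdname scMirEdit-accessors
#' @export
setMethod("precursorNames", "PrecursorSet",
          function(x) names(x@sequences))

#' @rdname scMirEdit-accessors
#' @export
setMethod("precursorSequences", "PrecursorSet", function(x) x@sequences)

#' @rdname scMirEdit-accessors
#' @export
setMethod("precursorLoci", "PrecursorSet", function(x) x@loci)

#' @rdname scMirEdit-accessors
#' @export
setMethod("matureAnnotations", "PrecursorSet", function(x) x@matures)

setMethod("show", "PrecursorSet", function(object) {
  cat("PrecursorSet with", length(object@sequences), "pre-miRNA hairpins\n")
  w <- Biostrings::width(object@sequences)
  cat("  lengths:", min(w), "-", max(w), "nt;",
      nrow(object@matures), "mature arms\n")
})

setMethod("length", "PrecursorSet", function(x) length(x@sequences))

#' Read a pre-miRNA FASTA file
#'
#' Reads hairpin sequences, upper-casing and normalizing U to T (miRBase
#' distributes RNA-alphabet hairpins; the internal alphabet is DNA).
#' Record order is preserved; duplicate names are an error.
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
readPrecursorFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonEmpty[1L]]), ">"))
    stop("malformed FASTA: line ", nonEmpty[1L],
         " does not start a '>' header")
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file has no records: ", path)
  seqs <- toupper(.rnaToDna(as.character(raw)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("malformed FASTA: non-nucleotide characters in record(s) ",
         paste(names(raw)[bad], collapse = ", "))
  nm <- sub("\\s.*$", "", names(raw))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate precursor name(s) in FASTA: ",
         paste(dup, collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Read a miRBase-dialect GFF3 annotation
#'
#' Parses \code{miRNA_primary_transcript} and \code{miRNA} features
#' (attributes \code{ID}, \code{Name}, \code{Derives_from}) and converts
#' mature genomic coordinates to precursor-local 1-based coordinates,
#' strand-aware: on the minus strand the local start is
#' \code{precursor genomic end - mature genomic end + 1}.
#'
#' @param path Path to a GFF3 file.
#' @param precursors Named \link[Biostrings]{DNAStringSet} from
#'   [readPrecursorFasta()]; names must match the GFF3 \code{Name}
#'   attributes of the primary transcripts.
#' @return A \linkS4class{PrecursorSet}.
#' @export
readMirnaGff3 <- function(path, precursors) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  if (!all(c("type", "ID", "Name") %in% colnames(meta)))
    stop("GFF3 lacks miRBase attributes (type/ID/Name)")
  prim <- gr[meta$type == "miRNA_primary_transcript"]
  mats <- gr[meta$type == "miRNA"]
  pn <- as.character(S4Vectors::mcols(prim)$Name)
  missing <- setdiff(names(precursors), pn)
  if (length(missing))
    stop("precursors absent from GFF3: ", paste(missing, collapse = ", "))
  prim <- prim[match(names(precursors), pn)]
  names(prim) <- names(precursors)
  w <- Biostrings::width(precursors)
  if (any(GenomicRanges::width(prim) != w))
    stop("GFF3 locus width disagrees with precursor sequence length")

  primId <- as.character(S4Vectors::mcols(prim)$ID)
  df <- as.character(S4Vectors::mcols(mats)$Derives_from)
  idx <- match(df, primId)
  if (anyNA(idx))
    stop("mature feature(s) with unknown Derives_from: ",
         paste(unique(df[is.na(idx)]), collapse = ", "))
  precName <- names(precursors)[idx]
  pStart <- GenomicRanges::start(prim)[idx]
  pEnd <- GenomicRanges::end(prim)[idx]
  neg <- as.character(GenomicRanges::strand(prim))[idx] == "-"
  gS <- GenomicRanges::start(mats)
  gE <- GenomicRanges::end(mats)
  locStart <- ifelse(neg, pEnd - gE + 1L, gS - pStart + 1L)
  locEnd <- ifelse(neg, pEnd - gS + 1L, gE - pStart + 1L)
  if (any(locStart < 1L) || any(locEnd > w[idx]))
    stop("mature feature(s) outside their precursor span")

  # arm from the -5p/-3p suffix when present, else by hairpin midpoint
  mn <- as.character(S4Vectors::mcols(mats)$Name)
  arm <- ifelse(grepl("-5p$", mn), "5p",
         ifelse(grepl("-3p$", mn), "3p",
                ifelse((locStart + locEnd) / 2 <= w[idx] / 2, "5p", "3p")))
  matures <- S4Vectors::DataFrame(
    precursor = precName, name = mn,
    start = as.integer(locStart), end = as.integer(locEnd), arm = arm)
  o <- order(match(matures$precursor, names(precursors)), matures$start)
  PrecursorSet(precursors, loci = prim, matures = matures[o, ])
}

#' Site-name codec
#'
#' An M/E site is named \code{<precursor>_<position>_<REF>_<alt>} with the
#' templated nucleotide upper case and the edited/mutated nucleotide lower
#' case, both rendered in the RNA alphabet. The edited-miRNA display form is
#' \code{<precursor>_<position><alt>}. Nucleotides are supplied and returned
#' in the internal DNA alphabet.
#'
#' @param precursor Precursor name(s).
#' @param position 1-based position(s) on the precursor.
#' @param ref,alt Reference and alternative nucleotide(s), DNA alphabet.
#' @param edited If \code{TRUE}, produce the edited-miRNA display form.
#' @return \code{formatSiteName}: character vector of site names.
#' @export
#' @examples
#' formatSiteName("hsa-mir-376a-1", 49, "A", "G")  # "hsa-mir-376a-1_49_A_g"
#' parseSiteName("hsa-mir-376a-1_49_A_g")
formatSiteName <- function(precursor, position, ref, alt, edited = FALSE) {
  stopifnot(length(precursor) == length(position))
  ref <- toupper(.rnaToDna(ref)); alt <- toupper(.rnaToDna(alt))
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(position < 1L) || any(position != round(position)))
    stop("position must be a positive integer")
  refR <- toupper(.dnaToRna(ref))
  altR <- tolower(.dnaToRna(alt))
  if (edited) paste0(precursor, "_", position, altR)
  else paste0(precursor, "_", position, "_", refR, "_", altR)
}

#' @rdname formatSiteName
#' @param name Site name(s) in codec form.
#' @return \code{parseSiteName}: \code{data.frame} with columns
#'   \code{precursor}, \code{position}, \code{ref}, \code{alt}
#'   (DNA alphabet, both upper case).
#' @export
parseSiteName <- function(name) {
  m <- regmatches(name,
    regexec("^(.+)_([0-9]+)_([ACGU])_([acgu])$", name))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad))
    stop("malformed site name(s): ", paste(name[bad], collapse = ", "))
  precursor <- vapply(m, `[`, "", 2L)
  position <- as.integer(vapply(m, `[`, "", 3L))
  ref <- toupper(.rnaToDna(vapply(m, `[`, "", 4L)))
  alt <- toupper(.rnaToDna(vapply(m, `[`, "", 5L)))
  if (any(position < 1L)) stop("position must be a positive integer")
  if (any(ref == alt))
    stop("ref and alt must differ in: ",
         paste(name[ref == alt], collapse = ", "))
  data.frame(precursor = precursor, position = position,
             ref = ref, alt = alt)
}

#' Read a SNP catalog from a VCF subset
#'
#' Loads single-nucleotide variants from a VCF 4.x file. Multi-allelic rows
#' are split into one record per ALT allele; indels are skipped with a
#' message reporting the count. Positions are 1-based genomic.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @return \code{data.frame} with columns \code{chrom}, \code{position},
#'   \code{id}, \code{ref}, \code{alt}.
#' @export
readSnpCatalog <- function(path) {
  hdr <- readLines(path, n = 500L, warn = FALSE)
  if (!any(startsWith(hdr, "#CHROM")))
    stop("not a VCF file (missing #CHROM header line): ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & alt %in% DNA_BASES
  nIndel <- sum(!snv)
  if (nIndel > 0L)
    message("readSnpCatalog: skipped ", nIndel, " non-SNV record(s)")
  ids <- names(rr)
  if (is.null(ids)) ids <- rep(".", length(rr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[snv],
    position = GenomicRanges::start(rr)[snv],
    id = ids[snv],
    ref = ref[snv],
    alt = alt[snv],
    row.names = NULL)
}

#' Editing-matrix TSV round-trip
#'
#' Writes a sites-by-cells matrix of editing levels as TSV: header row of
#' cell ids, first column \code{site}, levels formatted with 6 decimals,
#' missing coverage encoded as \code{NA}. \code{readMatrixTsv(writeMatrixTsv(m))}
#' reproduces \code{m} within 1e-6.
#'
#' @param m Numeric matrix with unique row (site) and column (cell) names.
#' @param path Output/input TSV path.
#' @return \code{writeMatrixTsv}: \code{path}, invisibly.
#' @export
writeMatrixTsv <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have row and column names")
  if (anyDuplicated(rownames(m))) stop("duplicate site names")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  fmt <- matrix(sprintf("%.6f", m), nrow = nrow(m))
  fmt[is.na(m)] <- "NA"
  out <- cbind(site = rownames(m), fmt)
  colnames(out) <- c("site", colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @return \code{readMatrixTsv}: numeric matrix with \code{NA} for missing
#'   coverage.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "site") stop("first column must be 'site'")
  if (anyDuplicated(df$site)) stop("duplicate site names")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$site
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  m
}

#' Read a cell-annotation TSV
#'
#' @param path TSV with columns \code{cellId}, \code{cellType} and optionally
#'   \code{subline}.
#' @return \code{data.frame} with those columns.
#' @export
readCellAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cellId", "cellType") %in% colnames(df)))
    stop("cell annotation needs 'cellId' and 'cellType' columns")
  if (anyDuplicated(df$cellId)) stop("duplicate cell ids in annotation")
  df
}

# Project a precursor-local position to genomic coordinates. Returns a
# data.frame with chrom, gPos and strand; alleles must be complemented by the
# caller on the minus strand.
.projectGenomic <- function(precursors, precursor, position) {
  loci <- precursorLoci(precursors)
  i <- match(precursor, names(loci))
  if (anyNA(i)) stop("unknown precursor: ",
                     paste(unique(precursor[is.na(i)]), collapse = ", "))
  neg <- as.character(GenomicRanges::strand(loci))[i] == "-"
  gPos <- ifelse(neg,
                 GenomicRanges::end(loci)[i] - position + 1L,
                 GenomicRanges::start(loci)[i] + position - 1L)
  data.frame(chrom = as.character(GenomicRanges::seqnames(loci))[i],
             gPos = gPos, neg = neg)
}
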