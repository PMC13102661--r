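#' @include cohort.R
NULL

#' Default terminal nucleotidyltransferase (TENT) panel
#'
#' The TENT-family enzymes screened against 3' addition levels.
#' @return Character vector of gene symbols.
#' @export
tentEnzymes <- function() {
  c("TENT2", "TENT4A", "TENT4B", "TENT5A", "TENT5B", "TENT5C", "TENT5D",
    "TUT1", "TUT4", "TUT7")
}

#' Read a gene-expression TSV
#'
#' Genes-by-cells expression matrix (e.g. TPM scale), first column
#' \code{gene}, remaining columns cell ids.
#'
#' @param path TSV path.
#' @return Numeric matrix (genes x cells).
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  if (any(m < 0, na.rm = TRUE)) stop("expression must be non-negative")
  m
}

#' Correlate enzyme expression with 3' editing levels
#'
#' Pearson correlation between each enzyme's expression and each 3' addition
#' site's editing level across the cells shared by both matrices, with
#' two-sided p-values from the correlation t statistic (n - 2 degrees of
#' freedom). A pair is \code{positiveSignificant} when \code{r > 0} and
#' \code{p < alpha}. Pairs where either vector has zero variance get
#' \code{NA} correlations (flagged undefined). No multiple-testing
#' correction is applied by default, matching per-pair reporting practice;
#' \code{bhCorrect = TRUE} adds a BH-adjusted column and uses it for the
#' flag (with a logged caveat).
#'
#' @param expression Genes-by-cells matrix ([readExpressionMatrix()]).
#' @param editing An \linkS4class{EditingExperiment} or sites-by-cells
#'   matrix of editing levels (NA imputed as 0).
#' @param enzymes Enzyme gene symbols (default [tentEnzymes()]); unknown
#'   names are skipped with a warning.
#' @param siteTypes Named site-type vector; defaults to
#'   \code{siteTypes(editing)}. Only 3' types are correlated unless
#'   \code{includeCentral}.
#' @param includeCentral Also correlate central (substitution) sites.
#' @param alpha P-value threshold (default 0.05).
#' @param bhCorrect Apply BH across pairs (off by default).
#' @return \code{data.frame}: \code{enzyme}, \code{site}, \code{class}
#'   (added nucleotide: Adenine/Uracil/Cytosine/Guanine), \code{n},
#'   \code{r}, \code{p}, \code{positiveSignificant}.
#' @export
correlateEnzymeEditing <- function(expression, editing,
                                   enzymes = tentEnzymes(),
                                   siteTypes = NULL,
                                   includeCentral = FALSE,
                                   alpha = 0.05, bhCorrect = FALSE) {
  m <- .levelMatrix(editing)
  if (is.null(siteTypes)) {
    if (!is(editing, "EditingExperiment"))
      stop("siteTypes required for a plain matrix")
    siteTypes <- siteTypes(editing)
  }
  shared <- intersect(colnames(expression), colnames(m))
  if (length(shared) < 3L)
    stop("need at least 3 shared cells (got ", length(shared), ")")
  known <- enzymes %in% rownames(expression)
  if (!all(known)) {
    warning("enzyme(s) not in expression matrix, skipped: ",
            paste(enzymes[!known], collapse = ", "))
    enzymes <- enzymes[known]
  }
  keepTypes <- c("3'-A", "3'-U", "3'-Other")
  if (includeCentral) keepTypes <- c(keepTypes, "A-to-I", "C-to-U", "Other")
  sites <- rownames(m)[siteTypes[rownames(m)] %in% keepTypes]
  if (length(sites) == 0L || length(enzymes) == 0L)
    return(data.frame(enzyme = character(), site = character(),
                      class = character(), n = integer(), r = numeric(),
                      p = numeric(), positiveSignificant = logical()))
  nShared <- length(shared)
  altNt <- parseSiteName(sites)$alt
  class <- c(A = "Adenine", T = "Uracil", C = "Cytosine",
             G = "Guanine")[altNt]

  res <- do.call(rbind, lapply(enzymes, function(enz) {
    ex <- expression[enz, shared]
    r <- vapply(sites, function(s) {
      lvl <- m[s, shared]
      if (stats::sd(lvl) == 0 || stats::sd(ex) == 0) return(NA_real_)
      stats::cor(ex, lvl)
    }, numeric(1L))
    tstat <- r * sqrt((nShared - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = nShared - 2)
    p[!is.na(r) & abs(r) >= 1] <- 0
    data.frame(enzyme = enz, site = sites, class = unname(class),
               n = nShared, r = unname(r), p = unname(p),
               row.names = NULL)
  }))
  if (bhCorrect) {
    message("correlateEnzymeEditing: BH correction across ", nrow(res),
            " enzyme-site pairs; the conventional report is per-pair")
    ok <- !is.na(res$p)
    res$pAdj <- NA_real_
    res$pAdj[ok] <- bhAdjust(res$p[ok])
    res$positiveSignificant <- !is.na(res$r) & res$r > 0 &
      !is.na(res$pAdj) & res$pAdj < alpha
  } else {
    res$positiveSignificant <- !is.na(res$r) & res$r > 0 &
      !is.na(res$p) & res$p < alpha
  }
  rownames(res) <- NULL
  res
}

#' Enzyme-nucleotide mediation summary
#'
#' Collapses enzyme-site correlations into an enzymes-by-nucleotides grid:
#' a cell is supported (\code{"Y"}) when at least one positively significant
#' correlation links that enzyme to a 3' site adding that nucleotide, else
#' \code{"N"}. Counts of supporting sites are attached.
#'
#' @param correlations Output of [correlateEnzymeEditing()].
#' @param enzymes Row order of the grid (default [tentEnzymes()]).
#' @return List with \code{grid} (character matrix of Y/N) and
#'   \code{counts} (integer matrix of supporting-site counts).
#' @export
mediationTable <- function(correlations, enzymes = tentEnzymes()) {
  nts <- c("Adenine", "Uracil", "Cytosine", "Guanine")
  counts <- matrix(0L, nrow = length(enzymes), ncol = length(nts),
                   dimnames = list(enzymes, nts))
  sig <- correlations[correlations$positiveSignificant, , drop = FALSE]
  if (nrow(sig) > 0L) {
    tab <- table(factor(sig$enzyme, levels = enzymes),
                 factor(sig$class, levels = nts))
    counts[] <- as.integer(tab)
  }
  grid <- ifelse(counts > 0L, "Y", "N")
  list(grid = grid, counts = counts)
}

#' Write the mediation grid as TSV
#'
#' @param mediation Output of [mediationTable()].
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMediationTsv <- function(mediation, path) {
  out <- cbind(enzyme = rownames(mediation$grid),
               as.data.frame(mediation$grid))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
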