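#' @include site-calling.R
NULL

#' Prevalence threshold
#'
#' Minimum number of samples a site must be significant in to enter the
#' cohort matrix: \code{ceiling(fraction * nSamples)}.
#'
#' @param nSamples Number of samples in the cohort.
#' @param fraction Prevalence fraction (default 0.05).
#' @return Integer threshold.
#' @export
#' @examples
#' minSamples(448)       # 23
minSamples <- function(nSamples, fraction = 0.05) {
  if (length(nSamples) != 1L || is.na(nSamples) || nSamples < 1 ||
      nSamples != round(nSamples))
    stop("nSamples must be a positive integer")
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 ||
      fraction > 1)
    stop("fraction must lie in (0, 1]")
  # guard against upward float noise (0.05 * n is not exactly representable)
  as.integer(ceiling(fraction * nSamples - sqrt(.Machine$double.eps)))
}

#' Combine per-cell profiles into a cohort editing matrix
#'
#' Rows are the sites significant in at least
#' \code{minSamples(nCells, minPrevalence)} cells; each cell's entry is its
#' editing level for the site, 0 when the position was covered but unedited,
#' and \code{NA} when the cell had no coverage there. Site types are the
#' majority classification across significant calls; when a SNP catalog and
#' genomic loci are supplied, catalog-matching sites whose level reaches
#' 100\% in at least one cell are (re)classified as \code{SNP}.
#'
#' @param profiles List of \linkS4class{SampleProfile} objects.
#' @param annotations Optional cell-annotation \code{data.frame}
#'   (\code{cellId}, \code{cellType}, optional \code{subline}); otherwise the
#'   profiles' own \code{cellType} labels are used.
#' @param minPrevalence Prevalence fraction (default 0.05).
#' @param precursors Optional \linkS4class{PrecursorSet}, required for the
#'   SNP reclassification.
#' @param snp Optional SNP catalog from [readSnpCatalog()].
#' @return An \linkS4class{EditingExperiment}.
#' @export
combineSamples <- function(profiles, annotations = NULL,
                           minPrevalence = 0.05, precursors = NULL,
                           snp = NULL) {
  if (length(profiles) < 2L) stop("need at least 2 profiles to combine")
  ids <- vapply(profiles, function(p) p@sampleId, "")
  if (anyDuplicated(ids))
    stop("duplicate cell ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  thr <- minSamples(length(profiles), minPrevalence)

  sigTab <- lapply(profiles, function(p)
    p@calls[p@calls$significant, c("site", "type"), drop = FALSE])
  sigSites <- unlist(lapply(sigTab, `[[`, "site"), use.names = FALSE)
  prevalence <- table(sigSites)
  sites <- sort(names(prevalence[prevalence >= thr]))
  if (length(sites) == 0L)
    stop("no site passes the prevalence filter (threshold ", thr, ")")
  key <- parseSiteName(sites)

  lv <- matrix(NA_real_, nrow = length(sites), ncol = length(profiles),
               dimnames = list(sites, ids))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    covKey <- paste(p@coverage$precursor, p@coverage$position)
    covered <- paste(key$precursor, key$position) %in% covKey
    lv[covered, j] <- 0
    hit <- match(sites, p@calls$site)
    has <- !is.na(hit)
    lv[has, j] <- p@calls$level[hit[has]]
  }

  # consensus type: majority over significant calls, first label on ties
  allSig <- do.call(rbind, sigTab)
  type <- vapply(sites, function(s) {
    tt <- allSig$type[allSig$site == s]
    names(sort(table(tt), decreasing = TRUE))[1L]
  }, "")
  if (!is.null(snp) && !is.null(precursors)) {
    maxLv <- apply(lv, 1L, max, na.rm = TRUE)
    proj <- .projectGenomic(precursors, key$precursor, key$position)
    gRef <- ifelse(proj$neg, .complement(key$ref), key$ref)
    gAlt <- ifelse(proj$neg, .complement(key$alt), key$alt)
    hit <- match(paste(proj$chrom, proj$gPos, gRef, gAlt),
                 paste(snp$chrom, snp$position, snp$ref, snp$alt))
    type[!is.na(hit) & maxLv >= 1 - 1e-9] <- "SNP"
  }

  cellType <- vapply(profiles, function(p) p@cellType, "")
  subline <- rep(NA_character_, length(profiles))
  if (!is.null(annotations)) {
    i <- match(ids, annotations$cellId)
    if (anyNA(i))
      stop("cells missing from annotation: ",
           paste(ids[is.na(i)], collapse = ", "))
    cellType <- annotations$cellType[i]
    if ("subline" %in% colnames(annotations))
      subline <- annotations$subline[i]
  }
  totalReads <- vapply(profiles, function(p)
    unname(p@nReads["qualified"]), numeric(1L))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(level = lv),
    rowData = S4Vectors::DataFrame(
      precursor = key$precursor, position = key$position,
      ref = key$ref, alt = key$alt, type = type,
      prevalence = as.integer(prevalence[sites])),
    colData = S4Vectors::DataFrame(
      cellType = cellType, subline = subline,
      totalQualifiedReads = totalReads, row.names = ids))
  new("EditingExperiment", se)
}

#' @rdname scMirEdit-accessors
#' @export
setMethod("editingLevels", "EditingExperiment",
          function(x) SummarizedExperiment::assay(x, "level"))

#' @rdname scMirEdit-accessors
#' @export
setMethod("cellTypes", "EditingExperiment", function(x)
  stats::setNames(as.character(SummarizedExperiment::colData(x)$cellType),
                  colnames(x)))

#' @rdname scMirEdit-accessors
#' @export
setMethod("siteTypes", "EditingExperiment", function(x)
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$type),
                  rownames(x)))

# Accept an EditingExperiment or a plain sites-by-cells matrix; NA (no
# coverage) is imputed as 0 for pattern analyses: undetected editing at low
# coverage is closest to "no observed editing".
.levelMatrix <- function(x, impute = TRUE) {
  m <- if (is(x, "EditingExperiment")) editingLevels(x) else as.matrix(x)
  if (impute) m[is.na(m)] <- 0
  m
}

.typeLabels <- function(x, annotations) {
  if (!is.null(annotations)) {
    m <- if (is(x, "EditingExperiment")) editingLevels(x) else as.matrix(x)
    i <- match(colnames(m), annotations$cellId)
    if (anyNA(i)) stop("cells missing from annotation")
    return(stats::setNames(annotations$cellType[i], colnames(m)))
  }
  if (is(x, "EditingExperiment")) return(cellTypes(x))
  stop("cell-type annotations required for a plain matrix")
}

#' PCA of cohort editing levels
#'
#' Column-mean-centered (unscaled) principal component analysis of the
#' cells-by-sites editing-level matrix, via singular value decomposition.
#' Missing coverage is imputed as 0 first. The sign convention makes each
#' loading vector's largest-magnitude entry positive, so results are
#' reproducible across SVD implementations.
#'
#' @param x An \linkS4class{EditingExperiment} or sites-by-cells matrix.
#' @param nComponents Number of components to return (default
#'   \code{min(10, dims)}).
#' @return List with \code{scores} (cells x PCs), \code{loadings}
#'   (sites x PCs) and \code{varianceExplained} (fractions, non-increasing).
#' @export
pcaEditing <- function(x, nComponents = 10L) {
  m <- .levelMatrix(x)
  if (ncol(m) < 2L) stop("PCA needs at least 2 cells")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) {
    warning("constant editing matrix: zero variance explained")
    ve <- rep(0, length(pc$sdev))
  } else ve <- pc$sdev^2 / tot
  k <- min(nComponents, ncol(pc$x))
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  list(scores = sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`),
       loadings = sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L,
                        flip, `*`),
       varianceExplained = ve[seq_len(k)])
}

#' Hierarchical biclustering of the editing matrix
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of rows
#' (sites) and columns (cells) independently, with deterministic leaf order.
#' Missing coverage is imputed as 0.
#'
#' @param x An \linkS4class{EditingExperiment} or sites-by-cells matrix.
#' @return List with \code{rowDend} and \code{colDend}
#'   (\link[stats]{hclust} objects or NULL for a single row/column) and
#'   \code{matrix}, the input reordered by both dendrograms.
#' @export
hierBicluster <- function(x) {
  m <- .levelMatrix(x)
  cl <- function(mm) if (nrow(mm) < 2L) NULL else
    stats::hclust(stats::dist(mm, method = "euclidean"),
                  method = "complete")
  rowDend <- cl(m)
  colDend <- cl(t(m))
  ro <- if (is.null(rowDend)) seq_len(nrow(m)) else rowDend$order
  co <- if (is.null(colDend)) seq_len(ncol(m)) else colDend$order
  list(rowDend = rowDend, colDend = colDend,
       matrix = m[ro, co, drop = FALSE])
}

#' Export a dendrogram in Newick format
#'
#' @param hc An \link[stats]{hclust} object (e.g. from [hierBicluster()]).
#' @param path Optional output path; when NULL the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cell-type-specific M/E sites
#'
#' Correlates each site's editing-level vector with each cell type's 0/1
#' indicator vector across the cohort. Significance comes from the
#' correlation t statistic \eqn{r \sqrt{(n-2)/(1-r^2)}} with n-2 degrees of
#' freedom (two-sided). A site is specific to a type when \code{r > rMin}
#' and \code{p < alpha}. Zero-variance sites or degenerate indicators give
#' undefined r and are flagged, never specific.
#'
#' @param x An \linkS4class{EditingExperiment} or sites-by-cells matrix.
#' @param annotations Optional cell-annotation \code{data.frame} (needed for
#'   a plain matrix).
#' @param rMin Correlation threshold (default 0.3).
#' @param alpha P-value threshold (default 0.05).
#' @param method \code{"pearson"} (default, as in the study) or
#'   \code{"spearman"}.
#' @return \code{data.frame}: \code{site}, \code{cellType}, \code{r},
#'   \code{p}, \code{specific}.
#' @export
cellTypeSpecificSites <- function(x, annotations = NULL, rMin = 0.3,
                                  alpha = 0.05, method = "pearson") {
  m <- .levelMatrix(x)
  labels <- .typeLabels(x, annotations)
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need at least 2 distinct cell types")
  n <- ncol(m)
  if (method == "spearman") m <- t(apply(m, 1L, rank))
  res <- do.call(rbind, lapply(types, function(tp) {
    ind <- as.numeric(labels == tp)
    if (method == "spearman") ind <- rank(ind)
    sdInd <- stats::sd(ind)
    sdSite <- apply(m, 1L, stats::sd)
    r <- if (sdInd == 0) rep(NA_real_, nrow(m)) else {
      rr <- suppressWarnings(as.numeric(stats::cor(t(m), ind)))
      rr[sdSite == 0] <- NA_real_
      rr
    }
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[!is.na(r) & abs(r) >= 1] <- 0
    data.frame(site = rownames(m), cellType = tp, r = r, p = p,
               specific = !is.na(r) & r > rMin & !is.na(p) & p < alpha)
  }))
  rownames(res) <- NULL
  res
}

#' Editing-level variance tiers within cell types
#'
#' Population (n-denominator) standard deviation of each site's levels
#' within each cell type, grouped as \code{zero} (std = 0), \code{low}
#' (0 < std <= \code{tLow}), \code{medium} (\code{tLow} < std <=
#' \code{tHigh}) and \code{high} (std > \code{tHigh}). Boundary values fall
#' in the lower group. The conventional low-variance class is
#' \code{zero} plus \code{low} (std <= 0.2).
#'
#' @param x An \linkS4class{EditingExperiment} or sites-by-cells matrix.
#' @param annotations Optional cell-annotation \code{data.frame}.
#' @param tLow,tHigh Tier thresholds (defaults 0.2 and 0.3).
#' @return \code{data.frame}: \code{site}, \code{cellType}, \code{std},
#'   \code{group}.
#' @export
varianceGroups <- function(x, annotations = NULL, tLow = 0.2,
                           tHigh = 0.3) {
  m <- .levelMatrix(x)
  labels <- .typeLabels(x, annotations)
  types <- sort(unique(labels))
  res <- lapply(types, function(tp) {
    cols <- which(labels == tp)
    if (length(cols) < 2L) {
      warning("cell type '", tp, "' has fewer than 2 cells; skipped")
      return(NULL)
    }
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    std <- sqrt(rowMeans((sub - mu)^2))
    group <- cut(std, breaks = c(-Inf, 0, tLow, tHigh, Inf),
                 labels = c("zero", "low", "medium", "high"))
    data.frame(site = rownames(m), cellType = tp, std = std,
               group = as.character(group), row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(site = character(), cellType = character(),
                      std = numeric(), group = character())
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With \code{length(x) + length(y) <= exactMax}
#' and no ties the exact null distribution of U is used; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exactMax Size limit for the exact branch (default 16).
#' @return List with \code{U} (statistic for \code{x}) and \code{p}.
#' @export
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided: 0.1
mannWhitneyU <- function(x, y, exactMax = 16L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n + m <= exactMax) {
    pLow <- stats::pwilcox(U, n, m)
    pHigh <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    mu <- n * m / 2
    tieTab <- table(pooled)
    N <- n + m
    sigma2 <- n * m / 12 *
      (N + 1 - sum(tieTab^3 - tieTab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Differential editing between cell types
#'
#' Per-site two-sided Mann-Whitney tests of each cell type against the
#' reference type, BH-corrected across sites within each comparison.
#' Direction is the sign of the median-level difference (comparison minus
#' reference).
#'
#' @param x An \linkS4class{EditingExperiment} or sites-by-cells matrix.
#' @param annotations Optional cell-annotation \code{data.frame}.
#' @param referenceType Reference cell type (e.g. a naive ESC population).
#' @param alpha Significance threshold (default 0.05).
#' @param useAdjusted Use BH-adjusted p-values for the significance call
#'   (default); set \code{FALSE} to threshold raw p-values.
#' @return \code{data.frame}: \code{site}, \code{cellType},
#'   \code{referenceType}, \code{U}, \code{p}, \code{pAdj},
#'   \code{direction}, \code{significant}.
#' @export
differentialEditing <- function(x, annotations = NULL, referenceType,
                                alpha = 0.05, useAdjusted = TRUE) {
  m <- .levelMatrix(x)
  labels <- .typeLabels(x, annotations)
  if (!referenceType %in% labels)
    stop("reference type '", referenceType, "' not present")
  refCols <- which(labels == referenceType)
  types <- setdiff(sort(unique(labels)), referenceType)
  res <- lapply(types, function(tp) {
    cols <- which(labels == tp)
    if (length(cols) == 0L) return(NULL)
    tests <- lapply(seq_len(nrow(m)), function(i)
      mannWhitneyU(m[i, cols], m[i, refCols]))
    p <- vapply(tests, `[[`, numeric(1L), "p")
    pAdj <- bhAdjust(p)
    medDiff <- apply(m[, cols, drop = FALSE], 1L, stats::median) -
      apply(m[, refCols, drop = FALSE], 1L, stats::median)
    data.frame(
      site = rownames(m), cellType = tp, referenceType = referenceType,
      U = vapply(tests, `[[`, numeric(1L), "U"),
      p = p, pAdj = pAdj,
      direction = ifelse(medDiff > 0, "higher",
                         ifelse(medDiff < 0, "lower", "equal")),
      significant = (if (useAdjusted) pAdj else p) < alpha,
      row.names = NULL)
  })
  do.call(rbind, res)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions, corrected for chance; 1 means
#' identical clusterings, 0 is the expectation under independence. Used to
#' validate that editing-pattern clusters recover cell types.
#'
#' @param a,b Two cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  sumIj <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(length(a), 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIj - expected) / (maxIdx - expected)
}
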