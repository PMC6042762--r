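## Marker ranking: PCA summaries, discriminant (DAPC-style) loadings, and
## pairwise composite-genotype substitution distances.

## Impute missing dosages by the marker (column) mean; all-missing columns
## become 0.
.imputeByMean <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2L]]
  m
}

#' Principal component analysis of a genotype matrix
#'
#' Centred (unscaled) PCA of a samples x markers dosage matrix. Missing
#' entries are imputed by the marker mean beforehand. An all-constant
#' matrix is handled gracefully (zero scores, zero variance fractions).
#'
#' @param m Numeric matrix, samples x markers, entries 0/1/2 or `NA`.
#' @param nComponents Number of components to return (default:
#'   `min(dim(m)) - 1`, capped at the matrix rank).
#' @return A list with `scores` (samples x components), `explainedVariance`
#'   (fractions, non-increasing, summing to at most 1) and `rotation`.
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(2, 2), c = c(2, 0))
#' genoPCA(m)$explainedVariance
genoPCA <- function(m, nComponents = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 1L)
    stop("need at least 2 samples and 1 marker")
  m <- .imputeByMean(m)
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  ev <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  k <- if (is.null(nComponents)) length(p$sdev)
       else min(nComponents, length(p$sdev))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explainedVariance = ev[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' Discriminant (DAPC-style) marker loadings
#'
#' Performs PCA on the dosage matrix, retains the leading principal
#' components, fits a linear discriminant analysis of the group labels on
#' the retained PC scores, and back-projects the discriminant axes into
#' marker space. The loading of a marker is the sum over discriminant axes
#' of its squared back-projected coefficient — non-negative, larger for
#' markers whose diagnostic allele separates the groups more cleanly.
#'
#' @param m Numeric matrix, samples x markers, entries 0/1/2 or `NA`
#'   (imputed by marker mean).
#' @param groups Factor-like vector of group (species/site) labels, one per
#'   sample; at least 2 groups with at least 2 samples each.
#' @param nPcsRetained Number of PCs fed to the discriminant step; default
#'   the smallest number reaching 90% cumulative variance.
#' @return Named numeric vector of loadings, one per marker.
#' @export
dapcLoadings <- function(m, groups, nPcsRetained = NULL) {
  m <- as.matrix(m)
  groups <- factor(groups)
  if (length(groups) != nrow(m))
    stop("'groups' must have one label per sample (row)")
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  p <- genoPCA(m)
  ev <- p$explainedVariance
  if (sum(ev) == 0)  # all-constant matrix: nothing discriminates
    return(setNames(rep(0, ncol(m)), colnames(m)))
  if (is.null(nPcsRetained))
    nPcsRetained <- which(cumsum(ev) >= 0.9)[1L]
  keep <- seq_len(min(nPcsRetained, sum(ev > 1e-12)))
  scores <- p$scores[, keep, drop = FALSE]

  ## guard: lda() rejects predictors constant within groups, which happens
  ## for perfectly separated noise-free cohorts; drop such PCs
  withinSd <- vapply(seq_len(ncol(scores)), function(j) {
    sqrt(mean(unlist(tapply(scores[, j], groups, function(v)
      (v - mean(v))^2))))
  }, numeric(1))
  usable <- withinSd > 1e-8
  if (!any(usable)) {
    ## groups already separated exactly: rank markers by between-group
    ## projection alone
    B <- p$rotation[, keep, drop = FALSE]
    return(setNames(rowSums(B^2), colnames(m)))
  }
  scores <- scores[, usable, drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups)
  backProj <- p$rotation[, keep, drop = FALSE][, usable, drop = FALSE] %*%
    fit$scaling
  loadings <- rowSums(backProj^2)
  setNames(as.numeric(loadings), colnames(m))
}

#' Rank panel markers by discriminant loading
#'
#' Fills the `loading` and `coverage` columns of a [MarkerPanel-class] and
#' sorts it. The default ranking key weights the discriminant loading by
#' the fraction of samples genotyped at the marker, preferring
#' high-coverage loci that are less likely to be spurious; `key =
#' "loading"` ranks by the raw loading instead.
#'
#' @param panel A [MarkerPanel-class].
#' @param pg A [PanelGenotypes-class] of reference individuals typed at the
#'   panel's markers.
#' @param groups Group labels (normally species) per individual.
#' @param key `"coverage_weighted"` (default) or `"loading"`.
#' @param nPcsRetained Passed to [dapcLoadings()].
#' @return The panel, re-ordered by decreasing ranking key, with `loading`
#'   and `coverage` filled.
#' @export
rankMarkers <- function(panel, pg, groups,
                        key = c("coverage_weighted", "loading"),
                        nPcsRetained = NULL) {
  key <- match.arg(key)
  m <- dosageMatrix(pg)
  m <- m[, panel$marker_id, drop = FALSE]
  loadings <- dapcLoadings(m, groups, nPcsRetained = nPcsRetained)
  coverage <- colMeans(!is.na(m))
  panel$loading <- as.numeric(loadings[panel$marker_id])
  panel$coverage <- as.numeric(coverage[panel$marker_id])
  score <- if (key == "coverage_weighted") panel$loading * panel$coverage
           else panel$loading
  MarkerPanel(panel[order(score, decreasing = TRUE), ])
}

#' Substitution distance between two composite genotypes
#'
#' Counts allele differences (0, 1 or 2 per marker) between two diploid
#' genotypes over the markers non-missing in both. Symmetric; zero iff the
#' genotypes agree at every shared marker. When the two individuals share
#' no non-missing marker the distance is undefined and `NA` is returned
#' with a warning.
#'
#' @param a,b Either single-individual [PanelGenotypes-class] objects on
#'   the same panel, or indices/names of two individuals in `pg`.
#' @param pg Optional [PanelGenotypes-class] holding both individuals.
#' @return Integer substitution count (or `NA`).
#' @export
#' @examples
#' p <- mytilusPanel12()
#' compositeDistance(makeClassRepresentative("Me", p),
#'                   makeClassRepresentative("Mg", p))  # 14
compositeDistance <- function(a, b, pg = NULL) {
  getCalls <- function(x) {
    if (is(x, "PanelGenotypes")) {
      stopifnot(ncol(x) == 1L)
      list(a1 = assay(x, "a1")[, 1L], a2 = assay(x, "a2")[, 1L],
           ids = rowData(x)$marker_id)
    } else {
      stopifnot(!is.null(pg))
      list(a1 = assay(pg, "a1")[, x], a2 = assay(pg, "a2")[, x],
           ids = rowData(pg)$marker_id)
    }
  }
  ga <- getCalls(a); gb <- getCalls(b)
  if (!identical(ga$ids, gb$ids))
    stop("genotypes are not on the same marker set")
  .pairDistance(ga$a1, ga$a2, gb$a1, gb$a2)
}

## allele differences between two sorted-or-not diploid calls: per marker
## 2 - (largest multiset overlap of the two allele pairs)
.pairDistance <- function(xa1, xa2, ya1, ya2) {
  both <- !is.na(xa1) & !is.na(ya1)
  if (!any(both)) {
    warning("no marker genotyped in both individuals; distance undefined")
    return(NA_integer_)
  }
  m1 <- (xa1 == ya1) + (xa2 == ya2)
  m2 <- (xa1 == ya2) + (xa2 == ya1)
  overlap <- pmax(m1, m2)
  sum(2L - overlap[both])
}

#' Pairwise composite-distance matrix
#'
#' @param pg A [PanelGenotypes-class].
#' @return A symmetric numeric matrix of substitution counts with zero
#'   diagonal (`NA` where two individuals share no genotyped marker).
#' @export
distanceMatrix <- function(pg) {
  n <- ncol(pg)
  a1 <- assay(pg, "a1"); a2 <- assay(pg, "a2")
  d <- matrix(0, n, n, dimnames = list(colnames(pg), colnames(pg)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- suppressWarnings(
        .pairDistance(a1[, i], a2[, i], a1[, j], a2[, j]))
    }
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Square numeric distance matrix with row names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writePhylipDist <- function(d, path) {
  stopifnot(nrow(d) == ncol(d))
  nm <- rownames(d)
  if (is.null(nm)) nm <- paste0("taxon", seq_len(nrow(d)))
  ## PHYLIP names are 10 characters, padded
  nm <- formatC(substr(nm, 1L, 10L), width = 10L, flag = "-")
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste0(nm[i], paste(sprintf("%.6f", d[i, ]), collapse = "  ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
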