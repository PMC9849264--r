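## Accessibility layer: promoter/distal annotation, pairwise differential
## accessibility with TMM + exact NB testing, trajectory clustering with
## semantic cluster names, fold-change correlation with nearest genes, and
## validated-enhancer overlap contingency analysis.

#' Annotate elements with promoter/distal class and nearest gene
#'
#' An element is a `promoter` iff its interval intersects any TSS +/-
#' `promoter_halfwidth`; otherwise `distal`. The nearest gene is the gene
#' whose TSS is closest to the element midpoint (ties broken toward the
#' smaller gene id); the signed distance is TSS-to-midpoint, positive
#' downstream of the gene on its strand.
#'
#' @param elements data.frame `chrom`, `start`, `end`, `id` (0-based
#'   half-open).
#' @param genes data.frame `id`, `chrom`, `tss`, `strand`.
#' @param promoter_halfwidth window half-width in bp (default 2500).
#' @return elements with `class`, `nearest_gene`, `nearest_dist` added.
#' @export
annotate_elements <- function(elements, genes, promoter_halfwidth = 2500) {
  stopifnot(nrow(elements) > 0, nrow(genes) > 0)
  out <- elements
  out$class <- "distal"
  out$nearest_gene <- NA_character_
  out$nearest_dist <- NA_real_
  warn_chroms <- character(0)
  for (ch in unique(elements$chrom)) {
    ei <- which(elements$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) {
      warn_chroms <- c(warn_chroms, ch)
      next
    }
    g <- genes[gi, ]
    ord <- order(g$tss, g$id)
    g <- g[ord, ]
    mid <- floor((elements$start[ei] + elements$end[ei]) / 2)
    ## nearest TSS by midpoint, ties toward smaller gene id
    pos <- findInterval(mid, g$tss)
    lo <- pmax(pos, 1); hi <- pmin(pos + 1, nrow(g))
    dlo <- abs(mid - g$tss[lo]); dhi <- abs(mid - g$tss[hi])
    pick_hi <- dhi < dlo | (dhi == dlo & g$id[hi] < g$id[lo])
    near <- ifelse(pick_hi, hi, lo)
    out$nearest_gene[ei] <- g$id[near]
    sgn <- ifelse(g$strand[near] == "-", -1, 1)
    out$nearest_dist[ei] <- (mid - g$tss[near]) * sgn
    ## promoter iff any TSS falls in [start - hw, end - 1 + hw]
    n_le_hi <- findInterval(elements$end[ei] - 1 + promoter_halfwidth,
                            g$tss)
    n_lt_lo <- findInterval(elements$start[ei] - promoter_halfwidth - 1,
                            g$tss)
    out$class[ei] <- ifelse(n_le_hi > n_lt_lo, "promoter", "distal")
  }
  if (length(warn_chroms))
    warning("annotate_elements: no genes on chromosome(s): ",
            paste(warn_chroms, collapse = ", "))
  out
}

# Shared pairwise differential engine for counts (ATAC elements or genes):
# one TMM normalization over all samples, exact conditional NB test per
# feature per comparison, BH within comparison.
.diff_pairwise <- function(counts, samples, comparisons, fdr_cutoff,
                           lfc_cutoff) {
  counts <- as.matrix(counts)
  stopifnot(identical(colnames(counts), samples$sample))
  tps <- unique(samples$timepoint)
  if (is.null(comparisons))
    comparisons <- combn(tps, 2, simplify = FALSE)
  reps <- table(samples$timepoint)
  used <- unique(unlist(comparisons))
  if (any(reps[used] < 2))
    stop("differential testing needs >= 2 replicates per group")
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  sf <- eff / geometric_mean(eff)
  norm <- sweep(counts, 2, sf, "/")
  tests <- list()
  for (cmp in comparisons) {
    a <- which(samples$timepoint == cmp[1])
    b <- which(samples$timepoint == cmp[2])
    phi <- estimate_dispersions(counts[, c(a, b), drop = FALSE],
                                sf[c(a, b)],
                                samples$timepoint[c(a, b)])
    res <- lapply(seq_len(nrow(counts)), function(i) {
      nb_exact_test(counts[i, a], counts[i, b],
                    size_factors = sf[c(a, b)], dispersion = phi[i])
    })
    lfc <- vapply(res, `[[`, numeric(1), "log2FC")
    pv <- vapply(res, `[[`, numeric(1), "pvalue")
    fdr <- bh_adjust(pv)
    tests[[paste(cmp, collapse = "_vs_")]] <- data.frame(
      feature = rownames(counts), log2FC = lfc, pvalue = pv, fdr = fdr,
      signif = fdr < fdr_cutoff & abs(lfc) > lfc_cutoff,
      stringsAsFactors = FALSE)
  }
  dynamic <- sort(unique(unlist(
    lapply(tests, function(t) t$feature[t$signif]))))
  list(tests = tests, dynamic = dynamic, norm = norm, size_factors = sf,
       tmm = f, comparisons = comparisons,
       thresholds = c(fdr = fdr_cutoff, lfc = lfc_cutoff))
}

#' Differential accessibility across pairwise time-point comparisons
#'
#' TMM-normalizes once over all samples, applies the exact conditional NB
#' test per element for every comparison, adjusts p-values by
#' Benjamini-Hochberg within each comparison, and calls an element
#' dynamic iff any comparison reaches `fdr < 0.01` and `|log2FC| > 1`
#' (thresholds configurable). The dynamic set is the union over
#' comparisons.
#'
#' @param counts integer element x sample matrix.
#' @param samples data.frame with `sample` (matching `colnames(counts)`),
#'   `timepoint`, `replicate`.
#' @param comparisons list of time-point pairs `c(A, B)`; default all
#'   pairwise combinations in time order.
#' @param fdr_cutoff,lfc_cutoff significance gates (defaults 0.01, 1).
#' @return list of class `da_result`: per-comparison test tables,
#'   `dynamic` element ids, normalized matrix, size factors.
#' @export
differential_accessibility <- function(counts, samples, comparisons = NULL,
                                       fdr_cutoff = 0.01, lfc_cutoff = 1) {
  out <- .diff_pairwise(counts, samples, comparisons, fdr_cutoff,
                        lfc_cutoff)
  out$samples <- samples
  class(out) <- "da_result"
  out
}

#' @export
print.da_result <- function(x, ...) {
  cat("da_result:", nrow(x$norm), "features,", length(x$tests),
      "comparisons,", length(x$dynamic), "dynamic\n")
  invisible(x)
}

# Per-time-point replicate means of a normalized matrix.
timepoint_means <- function(norm, samples) {
  tps <- unique(samples$timepoint)
  m <- vapply(tps, function(tp) {
    rowMeans(norm[, samples$timepoint == tp, drop = FALSE])
  }, numeric(nrow(norm)))
  colnames(m) <- tps
  m
}

# Name a z-score centroid trajectory by shape.
.centroid_class <- function(ctr, tol = 1e-8) {
  d <- diff(ctr)
  if (all(d <= tol) && ctr[1] > ctr[length(ctr)]) return("down")
  if (all(d >= -tol) && ctr[length(ctr)] > ctr[1]) return("up")
  pk <- which.max(ctr)
  if (pk > 1 && pk < length(ctr)) return("transient")
  "other"
}

#' Cluster dynamic-element trajectories and name clusters by shape
#'
#' Z-scores the per-time-point replicate means of the dynamic elements and
#' partitions them by k-means. Each cluster is named by its centroid:
#' monotone decreasing = `down`, monotone increasing = `up`, interior peak
#' = `transient`, anything else = `other`.
#'
#' @param da `da_result` from [differential_accessibility()].
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the k-means++ restarts.
#' @return list with `calls` (data.frame `element`, `cluster`, `class`),
#'   `centroids`, `z` (the z-scored matrix).
#' @export
cluster_trajectories <- function(da, k = 4, seed = 1) {
  dyn <- da$dynamic
  if (length(dyn) < k)
    stop("cluster_trajectories: fewer dynamic elements than k")
  tm <- timepoint_means(da$norm[dyn, , drop = FALSE], da$samples)
  z <- zscore_rows(tm)
  km <- kmeans_rows(z, k = k, seed = seed)
  cls <- apply(km$centroids, 1, .centroid_class)
  list(calls = data.frame(element = dyn, cluster = km$labels,
                          class = cls[km$labels],
                          stringsAsFactors = FALSE),
       centroids = km$centroids, z = z)
}

#' Correlation of accessibility and expression fold-changes by distance
#'
#' Pairs each dynamic element with its nearest differential gene for a
#' shared comparison and reports the Pearson correlation of the two
#' log2 fold-changes within distance strata: `promoter` elements, distal
#' elements nearer than `distance_cut`, and distal elements at or beyond
#' it.
#'
#' @param da `da_result` for accessibility.
#' @param de `de_result` for expression (see
#'   [differential_expression()]).
#' @param elements annotated elements ([annotate_elements()]).
#' @param comparison name of a comparison present in both results.
#' @param distance_cut stratum boundary in bp (default 20 kb).
#' @return data.frame `stratum`, `n`, `r`, `pvalue`; strata with fewer
#'   than 3 pairs or undefined correlation are omitted and listed in the
#'   `notes` attribute.
#' @export
fc_correlation_nearest <- function(da, de, elements, comparison,
                                   distance_cut = 2e4) {
  at <- da$tests[[comparison]]
  ge <- de$tests[[comparison]]
  if (is.null(at) || is.null(ge))
    stop("fc_correlation_nearest: comparison not found in both results")
  dyn <- intersect(da$dynamic, elements$id)
  el <- elements[match(dyn, elements$id), ]
  gene <- el$nearest_gene
  deg <- ge$feature[ge$signif]
  keep <- !is.na(gene) & gene %in% deg
  el <- el[keep, , drop = FALSE]
  if (!nrow(el)) {
    out <- data.frame(stratum = character(0), n = integer(0),
                      r = numeric(0), pvalue = numeric(0))
    attr(out, "notes") <- "no dynamic element with a nearest DEG"
    return(out)
  }
  x <- at$log2FC[match(el$id, at$feature)]
  y <- ge$log2FC[match(el$nearest_gene, ge$feature)]
  stratum <- ifelse(el$class == "promoter", "promoter",
                    ifelse(abs(el$nearest_dist) < distance_cut,
                           "distal_near", "distal_far"))
  notes <- character(0)
  rows <- list()
  for (s in c("promoter", "distal_near", "distal_far")) {
    i <- which(stratum == s)
    if (length(i) < 3) {
      notes <- c(notes, paste0(s, ": fewer than 3 pairs, omitted"))
      next
    }
    if (sd(x[i]) == 0 || sd(y[i]) == 0) {
      notes <- c(notes, paste0(s, ": undefined correlation, omitted"))
      next
    }
    pr <- pearson_r(x[i], y[i])
    rows[[s]] <- data.frame(stratum = s, n = length(i), r = pr$r,
                            pvalue = pr$pvalue)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(0), n = integer(0), r = numeric(0),
               pvalue = numeric(0))
  rownames(out) <- NULL
  attr(out, "notes") <- notes
  out
}

#' Overlap of validated enhancer sets with accessible elements
#'
#' An enhancer is overlapped iff any accessible element intersects it by
#' at least 1 bp (counting on the enhancer side, so fragmenting an element
#' does not change the fraction). Reports per-set overlapped/total counts,
#' percentages to one decimal, and a chi-squared test on the 2x2 table.
#'
#' @param elements accessible element intervals (`chrom`, `start`, `end`).
#' @param positive_set,negative_set enhancer interval data.frames.
#' @return list with `table` (2x2), `fractions` (percent, 1 decimal),
#'   `statistic`, `pvalue`.
#' @export
enhancer_set_overlap <- function(elements, positive_set, negative_set) {
  if (!nrow(positive_set) || !nrow(negative_set))
    stop("enhancer_set_overlap: empty enhancer set")
  k_pos <- sum(overlaps_any(positive_set, elements))
  k_neg <- sum(overlaps_any(negative_set, elements))
  n_pos <- nrow(positive_set); n_neg <- nrow(negative_set)
  tab <- matrix(c(k_pos, n_pos - k_pos, k_neg, n_neg - k_neg),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("positive", "negative"),
                                c("overlapped", "not_overlapped")))
  chi <- if (any(colSums(tab) == 0))
    list(statistic = NA_real_, pvalue = NA_real_)   # degenerate table
  else chi2_2x2(tab)
  list(table = tab,
       fractions = c(positive = round(100 * k_pos / n_pos, 1),
                     negative = round(100 * k_neg / n_neg, 1)),
       statistic = chi$statistic, pvalue = chi$pvalue)
}
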