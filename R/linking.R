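## Linking layer: interaction classification (P-P / P-D / D-D), loop-based
## target-gene assignment, nearest-vs-interacting expression comparison,
## accessibility-expression correlation with a randomized-pair null, and
## loop-dynamics / expression coupling.

# Bin ids (1-based) covered by TSS +/- halfwidth windows.
promoter_bins <- function(genes, resolution, halfwidth, nbins) {
  lo <- pmax(0, genes$tss - halfwidth) %/% resolution + 1
  hi <- pmin(genes$tss + halfwidth, nbins * resolution - 1) %/%
    resolution + 1
  sort(unique(unlist(Map(seq, lo, hi))))
}

# Bin id of an interval midpoint.
midpoint_bin <- function(start, end, resolution) {
  floor((start + end) / 2) %/% resolution + 1
}

#' Classify passing loops as P-P, P-D or D-D
#'
#' An anchor is a promoter anchor if its bin carries any TSS +/-
#' `promoter_halfwidth` window (promoter status takes precedence over
#' element content); otherwise it is a distal anchor if the bin carries a
#' distal accessible element, else `other`. Fractions are reported to two
#' decimals.
#'
#' @param loops `loop_set`; only rows with `passes_filters` are
#'   classified.
#' @param genes gene table (`id`, `tss`).
#' @param elements annotated elements ([annotate_elements()]).
#' @param resolution bin width (bp).
#' @param nbins number of bins in the map.
#' @param promoter_halfwidth promoter window half-width (default 2500).
#' @return list with per-loop `type`, `counts`, `fractions` (percent, 2
#'   decimals) and `promoter_involving_pct`.
#' @export
classify_interactions <- function(loops, genes, elements, resolution,
                                  nbins, promoter_halfwidth = 2500) {
  lp <- loops[loops$passes_filters, , drop = FALSE]
  if (!nrow(lp)) stop("classify_interactions: no passing loops")
  pbins <- promoter_bins(genes, resolution, promoter_halfwidth, nbins)
  dist_el <- elements[elements$class == "distal", , drop = FALSE]
  dbins <- unique(midpoint_bin(dist_el$start, dist_el$end, resolution))
  rank1 <- ifelse(lp$bin1 %in% pbins, 1L,
                  ifelse(lp$bin1 %in% dbins, 2L, 3L))
  rank2 <- ifelse(lp$bin2 %in% pbins, 1L,
                  ifelse(lp$bin2 %in% dbins, 2L, 3L))
  lab <- c("P", "D", "o")
  type <- paste0(lab[pmin(rank1, rank2)], "-", lab[pmax(rank1, rank2)])
  a1 <- lab[rank1]; a2 <- lab[rank2]
  counts <- table(factor(type, levels = c("P-P", "P-D", "D-D",
                                          "P-o", "D-o", "o-o")))
  fr <- round(100 * as.vector(counts) / nrow(lp), 2)
  names(fr) <- names(counts)
  list(type = type, counts = counts, fractions = fr,
       promoter_involving = sum(a1 == "P" | a2 == "P"),
       promoter_involving_pct =
         round(100 * sum(a1 == "P" | a2 == "P") / nrow(lp), 2),
       n = nrow(lp))
}

#' Assign target genes to distal elements through loops
#'
#' For every distal element whose midpoint bin is an anchor of a passing
#' loop, emits an `interacting` link to each gene whose TSS bin is the
#' partner anchor, plus a paired `nearest` link (the element's nearest
#' gene) for comparison. Elements in no loop yield only nearest links when
#' `all_nearest` is set.
#'
#' @param loops `loop_set`.
#' @param elements annotated elements.
#' @param genes gene table.
#' @param resolution bin width (bp).
#' @param all_nearest also emit nearest links for loop-free distal
#'   elements (default FALSE).
#' @return data.frame `element`, `gene`, `mode`
#'   (`interacting`/`nearest`), `loop_id`.
#' @export
assign_targets <- function(loops, elements, genes, resolution,
                           all_nearest = FALSE) {
  lp <- loops[loops$passes_filters, , drop = FALSE]
  dist_el <- elements[elements$class == "distal", , drop = FALSE]
  ebin <- midpoint_bin(dist_el$start, dist_el$end, resolution)
  gbin <- genes$tss %/% resolution + 1
  out <- list()
  if (nrow(lp)) {
    for (i in seq_len(nrow(dist_el))) {
      hit1 <- which(lp$bin1 == ebin[i])
      hit2 <- which(lp$bin2 == ebin[i])
      partners <- c(lp$bin2[hit1], lp$bin1[hit2])
      lids <- c(lp$loop_id[hit1], lp$loop_id[hit2])
      if (!length(partners)) next
      gi <- which(gbin %in% partners)
      if (!length(gi)) next
      li <- lids[match(gbin[gi], partners)]
      out[[length(out) + 1]] <- data.frame(
        element = dist_el$id[i], gene = genes$id[gi],
        mode = "interacting", loop_id = li, stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- data.frame(
        element = dist_el$id[i], gene = dist_el$nearest_gene[i],
        mode = "nearest", loop_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (all_nearest) {
    have <- unique(unlist(lapply(out, `[[`, "element")))
    rest <- dist_el[!(dist_el$id %in% have), , drop = FALSE]
    if (nrow(rest))
      out[[length(out) + 1]] <- data.frame(
        element = rest$id, gene = rest$nearest_gene, mode = "nearest",
        loop_id = NA_character_, stringsAsFactors = FALSE)
  }
  links <- if (length(out)) do.call(rbind, out) else
    data.frame(element = character(0), gene = character(0),
               mode = character(0), loop_id = character(0))
  links <- unique(links)
  rownames(links) <- NULL
  links
}

#' Compare expression of nearest versus interacting genes per time point
#'
#' Wilcoxon rank-sum test between the per-link CPM values (replicate means
#' per time point) of the interacting-gene set and the nearest-gene set.
#'
#' @param links link table from [assign_targets()].
#' @param cpm gene CPM matrix.
#' @param samples RNA sample metadata.
#' @return data.frame `timepoint`, `median_nearest`,
#'   `median_interacting`, `pvalue`.
#' @export
nearest_vs_interacting <- function(links, cpm, samples) {
  gi <- links$gene[links$mode == "interacting"]
  gn <- links$gene[links$mode == "nearest"]
  gi <- gi[gi %in% rownames(cpm)]
  gn <- gn[gn %in% rownames(cpm)]
  if (!length(gi) || !length(gn))
    stop("nearest_vs_interacting: empty gene set")
  tm <- timepoint_means(cpm, samples)
  res <- lapply(colnames(tm), function(tp) {
    x <- tm[gi, tp]; y <- tm[gn, tp]
    w <- wilcoxon_rank_sum(x, y)
    data.frame(timepoint = tp, median_nearest = median(y),
               median_interacting = median(x), pvalue = w$pvalue)
  })
  do.call(rbind, res)
}

#' Accessibility-expression correlation per link with a randomized null
#'
#' For each interacting link, the Pearson correlation between the
#' element's normalized accessibility and the gene's CPM across the shared
#' time points (replicate means on both sides). The null is built by
#' randomly re-pairing elements and genes drawn from the link anchors
#' (`n_random` seeded draws). Reports counts of significantly positive and
#' negative links and a Wilcoxon comparison of |r| against the null.
#'
#' @param links link table (interacting rows are used).
#' @param atac_norm normalized element matrix; `atac_samples` its
#'   metadata.
#' @param cpm gene CPM matrix; `rna_samples` its metadata.
#' @param atac_samples,rna_samples sample metadata.
#' @param n_random number of randomized pairs (default 1000).
#' @param seed RNG seed for the null.
#' @param p_cutoff per-link significance level (default 0.05).
#' @return list with `links` (r/p per link), `null_r`, `summary`.
#' @export
link_correlation <- function(links, atac_norm, atac_samples, cpm,
                             rna_samples, n_random = 1000, seed = 1,
                             p_cutoff = 0.05) {
  lk <- links[links$mode == "interacting", , drop = FALSE]
  lk <- lk[lk$element %in% rownames(atac_norm) &
             lk$gene %in% rownames(cpm), , drop = FALSE]
  if (nrow(lk) < 2)
    stop("link_correlation: need at least 2 interacting links")
  tps <- intersect(unique(atac_samples$timepoint),
                   unique(rna_samples$timepoint))
  if (length(tps) < 3)
    stop("link_correlation: fewer than 3 shared time points")
  am <- timepoint_means(atac_norm, atac_samples)[, tps, drop = FALSE]
  gm <- timepoint_means(cpm, rna_samples)[, tps, drop = FALSE]
  corr_one <- function(e, g) {
    x <- am[e, ]; y <- gm[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    pr <- pearson_r(x, y)
    c(pr$r, pr$pvalue)
  }
  obs <- t(mapply(corr_one, lk$element, lk$gene))
  lk$r <- obs[, 1]; lk$pvalue <- obs[, 2]
  dropped <- sum(is.na(lk$r))
  null_r <- with_seed(seed, {
    ei <- sample(lk$element, n_random, replace = TRUE)
    gi <- sample(lk$gene, n_random, replace = TRUE)
    vapply(seq_len(n_random),
           function(b) corr_one(ei[b], gi[b])[1], numeric(1))
  })
  ok <- !is.na(lk$r)
  w <- wilcoxon_rank_sum(abs(lk$r[ok]), abs(null_r[!is.na(null_r)]))
  list(links = lk, null_r = null_r,
       summary = list(
         n_links = sum(ok), n_dropped = dropped,
         n_sig_pos = sum(ok & lk$pvalue < p_cutoff & lk$r > 0),
         n_sig_neg = sum(ok & lk$pvalue < p_cutoff & lk$r < 0),
         median_r = median(lk$r[ok]),
         median_null_r = median(null_r, na.rm = TRUE),
         wilcoxon_p = w$pvalue))
}

#' Couple loop dynamics with gene expression changes
#'
#' For each dynamic (weakened/enhanced) loop, lists the expression
#' log2 fold-changes of the genes linked through it and whether they are
#' DEGs; for each stable loop whose element is dynamic, groups the gene
#' fold-change by the element's accessibility direction.
#'
#' @param dyn_loops loop table from [differential_loops()].
#' @param links link table from [assign_targets()].
#' @param de `de_result`.
#' @param clusters trajectory calls from [cluster_trajectories()]
#'   (`calls` data.frame).
#' @param comparison expression comparison matching the HiChIP
#'   time points.
#' @return list with `dynamic` and `stable_dynamic_element`
#'   data.frames.
#' @export
couple_dynamics <- function(dyn_loops, links, de, clusters, comparison) {
  ge <- de$tests[[comparison]]
  if (is.null(ge)) stop("couple_dynamics: comparison not in de result")
  lk <- links[links$mode == "interacting", , drop = FALSE]
  lk$lfc <- ge$log2FC[match(lk$gene, ge$feature)]
  lk$deg <- lk$gene %in% de$dynamic
  lk$dynamics <- dyn_loops$dynamics[match(lk$loop_id,
                                          dyn_loops$loop_id)]
  ecls <- setNames(clusters$class, clusters$element)
  lk$element_class <- ecls[lk$element]
  dynamic <- lk[!is.na(lk$dynamics) &
                  lk$dynamics %in% c("weakened", "enhanced"),
                c("loop_id", "dynamics", "element", "gene", "lfc",
                  "deg", "element_class")]
  dynamic <- dynamic[!duplicated(dynamic[, c("loop_id", "gene")]), ]
  stable <- lk[!is.na(lk$dynamics) & lk$dynamics == "stable" &
                 lk$element_class %in% c("down", "up"),
               c("loop_id", "element", "element_class", "gene", "lfc",
                 "deg")]
  stable$direction <- ifelse(stable$element_class == "up",
                             "increased_accessibility",
                             "decreased_accessibility")
  rownames(dynamic) <- rownames(stable) <- NULL
  list(dynamic = dynamic, stable_dynamic_element = stable)
}

#' Census of loop dynamics
#'
#' Counts weakened/enhanced/stable loops and the dynamic percentage
#' (one decimal).
#'
#' @param dyn_loops loop table with a `dynamics` column (only rows passing
#'   filters are counted).
#' @return list with `counts`, `total`, `dynamic_pct`.
#' @export
dynamics_census <- function(dyn_loops) {
  lp <- if (!is.null(dyn_loops$passes_filters))
    dyn_loops[dyn_loops$passes_filters, , drop = FALSE] else dyn_loops
  counts <- table(factor(lp$dynamics,
                         levels = c("weakened", "enhanced", "stable")))
  n <- nrow(lp)
  ndyn <- sum(counts[c("weakened", "enhanced")])
  list(counts = counts, total = n,
       dynamic_pct = if (n > 0) round(100 * ndyn / n, 1) else 0)
}
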