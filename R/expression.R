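## Expression layer: CPM/FPKM normalization and pairwise differential
## expression sharing the accessibility module's TMM + exact-NB engine.

#' Counts-per-million (and FPKM) normalization
#'
#' CPM columns sum to exactly 1e6; when gene lengths are supplied, FPKM is
#' additionally returned as CPM divided by length in kilobases.
#'
#' @param counts integer gene x sample matrix with positive library sizes.
#' @param lengths optional positive gene lengths in bp (named or in row
#'   order).
#' @return CPM matrix, or list with `cpm` and `fpkm` when lengths given.
#' @export
normalize_cpm <- function(counts, lengths = NULL) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("normalize_cpm: non-positive library size")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  if (is.null(lengths)) return(cpm)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("normalize_cpm: zero or missing gene length")
  list(cpm = cpm, fpkm = cpm / (lengths / 1000))
}

#' Differential expression across pairwise time-point comparisons
#'
#' Same engine as [differential_accessibility()] (TMM + exact conditional
#' NB test + BH within comparison) with the expression gates: a gene is a
#' DEG iff some comparison reaches `fdr < 0.05` and `|log2FC| > 1`.
#'
#' @inheritParams differential_accessibility
#' @param fdr_cutoff,lfc_cutoff significance gates (defaults 0.05, 1).
#' @return list of class `de_result`: per-comparison tests, `dynamic`
#'   (DEG ids), normalized matrix, `cpm`.
#' @export
differential_expression <- function(counts, samples, comparisons = NULL,
                                    fdr_cutoff = 0.05, lfc_cutoff = 1) {
  out <- .diff_pairwise(counts, samples, comparisons, fdr_cutoff,
                        lfc_cutoff)
  out$samples <- samples
  out$cpm <- normalize_cpm(counts)
  class(out) <- "de_result"
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", nrow(x$norm), "genes,", length(x$tests),
      "comparisons,", length(x$dynamic), "DEGs\n")
  invisible(x)
}
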