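## Motif layer: PWM construction, log-odds scanning of element sequences,
## hypergeometric enrichment in directional element sets, and TF
## regulatome assembly.

new_pwm <- function(name, mat, background = rep(0.25, 4)) {
  stopifnot(nrow(mat) == 4)
  if (ncol(mat) < 4) stop("new_pwm: motif length must be >= 4")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-6))
    stop("new_pwm: columns must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = mat, background = background),
            class = "pwm")
}

#' Build a PWM from a consensus sequence
#'
#' Each column gives probability `majority` to the consensus base and
#' splits the remainder evenly.
#'
#' @param name motif name.
#' @param consensus A/C/G/T string of length >= 4.
#' @param majority consensus-base probability per column (default 0.85).
#' @return object of class `pwm`.
#' @export
pwm_from_consensus <- function(name, consensus, majority = 0.85) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("pwm_from_consensus: consensus must be over ACGT")
  L <- length(bases)
  mat <- matrix((1 - majority) / 3, nrow = 4, ncol = L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(bases, c("A", "C", "G", "T")), seq_len(L))] <- majority
  new_pwm(name, mat)
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", x$name, "length", ncol(x$matrix), "\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Default PWM library for the synthetic study
#'
#' The two planted motifs (MEF2-like and AP1-like) plus decoy motifs so
#' that enrichment rankings are non-trivial.
#'
#' @return named list of `pwm` objects.
#' @export
default_pwms <- function() {
  cons <- c(MEF2 = "CTAAAAATAG", AP1 = "TGACTCA",
            EBOX = "CACGTG", GATA = "AGATAAGA",
            NKX = "TNAAGTG", SP1 = "GGGGCGGGG",
            HOMEO = "TAATTA")
  cons["NKX"] <- "TCAAGTG"   # keep consensus strictly over ACGT
  lapply(setNames(names(cons), names(cons)), function(n)
    pwm_from_consensus(n, cons[[n]]))
}

# Reverse complement of a PWM: reverse columns, swap A<->T and C<->G.
.pwm_revcomp <- function(mat) {
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

# Per-base log2-odds matrix with worst-base row for N.
.lod_matrix <- function(pwm) {
  m <- pwm$matrix
  m[m == 0] <- 0.001
  lod <- log2(m / pwm$background)
  rbind(lod, N = apply(lod, 2, min))
}

# Scores at every offset of one encoded sequence (ints 1..5 for ACGTN).
.scan_scores <- function(code, lod) {
  L <- ncol(lod)
  n <- length(code) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (l in seq_len(L))
    s <- s + lod[cbind(code[l:(l + n - 1)], l)]
  s
}

#' Scan sequences with a PWM on both strands
#'
#' Log2-odds score against the background at every offset of each
#' sequence and of its reverse-complement reading; a hit is any offset
#' scoring at least `threshold_frac` of the maximum attainable score.
#' `N` bases score as the worst base of the column. Offsets are 0-based on
#' the forward sequence; minus-strand hits report the offset of the
#' leftmost matched base.
#'
#' @param sequences named character vector over A/C/G/T/N.
#' @param pwm a `pwm` object.
#' @param threshold_frac fraction of the maximum score in (0, 1\]
#'   (default 0.8).
#' @return data.frame `element`, `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold_frac = 0.8) {
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("scan_pwm: threshold_frac must lie in (0, 1]")
  lod_f <- .lod_matrix(pwm)
  pwm_rc <- pwm
  pwm_rc$matrix <- .pwm_revcomp(pwm$matrix)
  lod_r <- .lod_matrix(pwm_rc)
  max_score <- sum(apply(lod_f[1:4, , drop = FALSE], 2, max))
  thr <- threshold_frac * max_score
  L <- ncol(pwm$matrix)
  skipped <- character(0)
  out <- list()
  for (id in names(sequences)) {
    sq <- toupper(sequences[[id]])
    if (nchar(sq) < L) {
      skipped <- c(skipped, id)
      next
    }
    code <- match(strsplit(sq, "")[[1]], c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L
    for (str in c("+", "-")) {
      s <- .scan_scores(code, if (str == "+") lod_f else lod_r)
      hit <- which(s >= thr)
      if (length(hit))
        out[[length(out) + 1]] <- data.frame(
          element = id, offset = hit - 1L, strand = str,
          score = s[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("scan_pwm: sequences shorter than motif skipped: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) " ...")
  if (!length(out))
    return(data.frame(element = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  do.call(rbind, out)
}

#' Scan sequences with a PWM library
#'
#' @param sequences named character vector.
#' @param pwms named list of `pwm` objects.
#' @param threshold_frac hit threshold as in [scan_pwm()].
#' @return data.frame with a `pwm` column prepended to the hits.
#' @export
scan_pwms <- function(sequences, pwms, threshold_frac = 0.8) {
  res <- lapply(names(pwms), function(n) {
    h <- scan_pwm(sequences, pwms[[n]], threshold_frac)
    if (!nrow(h)) return(NULL)
    data.frame(pwm = n, h, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(pwm = character(0), element = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0)))
  do.call(rbind, res)
}

#' Hypergeometric motif enrichment in a target element set
#'
#' For each PWM, counts elements with at least one hit (multiplicity
#' ignored) in the target set versus the rest of the universe and computes
#' the one-sided hypergeometric upper-tail p-value, an odds ratio
#' (Haldane-corrected), and BH FDR across PWMs; results are ranked by
#' p-value.
#'
#' @param hits hit table from [scan_pwms()] (columns `pwm`, `element`).
#' @param target non-empty character vector of target element ids (subset
#'   of `universe`).
#' @param universe all element ids under consideration.
#' @return data.frame `pwm`, `target_hits`, `target_size`, `bg_hits`,
#'   `bg_size`, `odds_ratio`, `pvalue`, `fdr`, ordered by p.
#' @export
motif_enrichment <- function(hits, target, universe) {
  if (!length(target)) stop("motif_enrichment: empty target set")
  if (!all(target %in% universe))
    stop("motif_enrichment: target must be a subset of the universe")
  bg_size <- length(universe) - length(target)
  res <- lapply(unique(hits$pwm), function(p) {
    he <- unique(hits$element[hits$pwm == p])
    he <- he[he %in% universe]
    k <- sum(target %in% he)
    m <- length(he)
    pv <- phyper(k - 1, m, length(universe) - m, length(target),
                 lower.tail = FALSE)
    or <- ((k + 0.5) * (bg_size - (m - k) + 0.5)) /
      ((length(target) - k + 0.5) * (m - k + 0.5))
    data.frame(pwm = p, target_hits = k, target_size = length(target),
               bg_hits = m - k, bg_size = bg_size, odds_ratio = or,
               pvalue = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, -out$odds_ratio), ]
  rownames(out) <- NULL
  out
}

#' Build the TF regulatome from motifs, dynamics and links
#'
#' An edge (TF, gene) exists iff a dynamic element carries a hit for that
#' TF's PWM, the gene is differential, and the gene is the element's
#' promoter gene (proximal: the element is a promoter element and the gene
#' is its nearest gene) or an interacting gene (distal: linked through a
#' passing loop). Edges carry the element, mode and element direction.
#'
#' @param hits hit table from [scan_pwms()].
#' @param clusters trajectory calls (`calls` from
#'   [cluster_trajectories()]).
#' @param elements annotated elements.
#' @param links link table from [assign_targets()].
#' @param deg character vector of differential gene ids.
#' @return data.frame `tf`, `gene`, `element`, `mode`, `direction`.
#' @export
build_regulatome <- function(hits, clusters, elements, links, deg) {
  empty <- data.frame(tf = character(0), gene = character(0),
                      element = character(0), mode = character(0),
                      direction = character(0))
  if (!nrow(hits)) return(empty)
  dyn <- clusters$element
  dir <- setNames(clusters$class, clusters$element)
  hits <- hits[hits$element %in% dyn, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  el <- elements[match(hits$element, elements$id), ]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    e <- hits$element[i]
    if (el$class[i] == "promoter") {
      g <- el$nearest_gene[i]; mode <- "proximal"
    } else {
      g <- links$gene[links$mode == "interacting" & links$element == e]
      mode <- "distal"
    }
    g <- unique(g[!is.na(g) & g %in% deg])
    if (!length(g)) next
    out[[length(out) + 1]] <- data.frame(
      tf = hits$pwm[i], gene = g, element = e, mode = mode,
      direction = unname(dir[e]), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  edges <- unique(do.call(rbind, out))
  rownames(edges) <- NULL
  edges
}
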