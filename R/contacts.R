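## Contact-map layer: container, ICE balancing, distance-decay background,
## binomial loop calling on the combined map, differential looping, APA
## (P2LL) and virtual 4C.

#' Construct a binned sparse contact map
#'
#' Stores intra-chromosomal contacts as upper-triangle records
#' (`bin1 <= bin2`, 1-based bin ids into `bins`). Records below the
#' diagonal are transposed and duplicates aggregated.
#'
#' @param bins bin table (`chrom`, `start`, `end`, `bin`) tiling the genome
#'   at `resolution`.
#' @param counts data.frame with `bin1`, `bin2`, `count` (non-negative
#'   integers).
#' @param resolution bin width in bp.
#' @param sample optional sample label.
#' @param biases optional positive per-bin balancing biases (NA for masked
#'   bins).
#' @return object of class `contact_map`.
#' @export
contact_map <- function(bins, counts, resolution, sample = NA,
                        biases = NULL) {
  stopifnot(all(c("chrom", "start", "end", "bin") %in% names(bins)),
            all(c("bin1", "bin2", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("contact_map: negative counts")
  if (any(counts$bin1 < 1 | counts$bin2 < 1 |
          counts$bin1 > nrow(bins) | counts$bin2 > nrow(bins)))
    stop("contact_map: bin id outside bin table")
  flip <- counts$bin1 > counts$bin2
  if (any(flip)) {
    tmp <- counts$bin1[flip]
    counts$bin1[flip] <- counts$bin2[flip]
    counts$bin2[flip] <- tmp
  }
  key <- paste(counts$bin1, counts$bin2)
  if (anyDuplicated(key)) {
    agg <- rowsum(counts$count, key)
    parts <- do.call(rbind, strsplit(rownames(agg), " "))
    counts <- data.frame(bin1 = as.integer(parts[, 1]),
                         bin2 = as.integer(parts[, 2]),
                         count = as.vector(agg))
  }
  counts <- counts[counts$count > 0, , drop = FALSE]
  counts <- counts[order(counts$bin1, counts$bin2), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(bins = bins, counts = counts, resolution = resolution,
                 sample = sample, biases = biases),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$bins), "bins @", x$resolution, "bp,",
      nrow(x$counts), "nonzero pairs,", sum(x$counts$count), "contacts",
      if (!is.na(x$sample)) paste0("[", x$sample, "]"), "\n")
  invisible(x)
}

#' Combine several contact maps by summing counts
#' @param maps list of `contact_map` objects sharing one bin table.
#' @return combined `contact_map`.
#' @export
combine_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  all_counts <- do.call(rbind, lapply(maps, `[[`, "counts"))
  contact_map(maps[[1]]$bins, all_counts, maps[[1]]$resolution,
              sample = "combined")
}

# Full-matrix row sums of count/(b_i b_j) from upper-triangle storage
# (diagonal counted once).
.ice_rowsums <- function(cm, b) {
  v <- cm$counts$count / (b[cm$counts$bin1] * b[cm$counts$bin2])
  s <- numeric(nrow(cm$bins))
  s1 <- rowsum(v, cm$counts$bin1)
  s[as.integer(rownames(s1))] <- s[as.integer(rownames(s1))] + s1
  off <- cm$counts$bin1 != cm$counts$bin2
  if (any(off)) {
    s2 <- rowsum(v[off], cm$counts$bin2[off])
    s[as.integer(rownames(s2))] <- s[as.integer(rownames(s2))] + s2
  }
  s
}

#' Iterative correction (ICE) balancing of a contact map
#'
#' Finds positive per-bin biases b such that the balanced matrix
#' `count[i,j] / (b[i] b[j])` has equal row sums over unmasked bins
#' (Sinkhorn-style symmetric iteration). Bins with zero marginal are
#' masked (bias NA). Biases are normalized to mean 1 over unmasked bins;
#' they are invariant to a global rescaling of the counts.
#'
#' @param map a `contact_map`.
#' @param max_iter maximum iterations (default 200).
#' @param tol convergence tolerance on max relative row-sum deviation
#'   (default 1e-4).
#' @return the map with `biases` set.
#' @export
ice_balance <- function(map, max_iter = 200, tol = 1e-4) {
  if (!nrow(map$counts)) stop("ice_balance: empty map")
  n <- nrow(map$bins)
  b <- rep(1, n)
  marg <- .ice_rowsums(map, b)
  mask <- marg == 0
  if (all(mask)) stop("ice_balance: all bins empty")
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s <- .ice_rowsums(map, b)
    rel <- s[!mask] / mean(s[!mask])
    resid <- max(abs(rel - 1))
    if (resid < tol) break
    b[!mask] <- b[!mask] * sqrt(rel)
    if (it == max_iter)
      stop("ice_balance: no convergence in ", max_iter,
           " iterations (last residual ", signif(resid, 3), ")")
  }
  b[!mask] <- b[!mask] / mean(b[!mask])
  b[mask] <- NA_real_
  map$biases <- b
  map
}

#' Fit the distance-decay contact background by equal-occupancy strata
#'
#' Partitions pair distances within `[min_span, max_span]` into strata of
#' near-equal total contact mass and estimates, per stratum, the
#' probability that a single contact falls on one specific bin pair at that
#' distance: stratum counts / (total counts x possible pairs in stratum).
#' Estimates are made monotone non-increasing in distance by
#' pool-adjacent-violators.
#'
#' @param map a `contact_map` (typically the combined map).
#' @param n_bins number of distance strata (default 50).
#' @param min_span,max_span genomic span limits in bp (defaults 20 kb and
#'   2 Mb).
#' @return object of class `decay_table`: stratum table, total contact
#'   count, resolution.
#' @export
fit_distance_decay <- function(map, n_bins = 50, min_span = 2e4,
                               max_span = 2e6) {
  res <- map$resolution
  kmin <- ceiling(min_span / res); kmax <- floor(max_span / res)
  cc <- map$counts
  k <- cc$bin2 - cc$bin1
  keep <- k >= kmin & k <= kmax
  cc <- cc[keep, , drop = FALSE]
  if (sum(cc$count > 0) < n_bins)
    stop("fit_distance_decay: fewer nonzero pairs than strata")
  ## per-distance totals: observed counts and possible pairs per chromosome
  ks <- kmin:kmax
  obs <- numeric(length(ks))
  tab <- rowsum(cc$count, cc$bin2 - cc$bin1)
  obs[as.integer(rownames(tab)) - kmin + 1] <- tab
  npairs <- numeric(length(ks))
  for (ch in unique(map$bins$chrom)) {
    nb <- sum(map$bins$chrom == ch)
    npairs <- npairs + pmax(0, nb - ks)
  }
  total <- sum(obs)
  ## equal-occupancy stratum boundaries on cumulative observed mass
  cum <- cumsum(obs)
  stratum <- pmin(n_bins, floor(cum / (total / n_bins) - 1e-9) + 1)
  stratum <- cummax(stratum)   # all pairs at one distance share a stratum
  sc <- rowsum(obs, stratum)
  sp <- rowsum(npairs, stratum)
  phat <- as.vector(sc) / (total * as.vector(sp))
  phat <- .pava_decreasing(phat, as.vector(sp))
  dmin <- tapply(ks * res, stratum, min)
  dmax <- tapply(ks * res, stratum, max)
  structure(list(
    table = data.frame(stratum = as.integer(rownames(sc)),
                       d_min = as.vector(dmin), d_max = as.vector(dmax),
                       n_pairs = as.vector(sp), count = as.vector(sc),
                       phat = phat),
    total = total, resolution = res,
    min_span = min_span, max_span = max_span),
    class = "decay_table")
}

# Weighted pool-adjacent-violators for a non-increasing fit.
.pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; idx <- rep(1, n)
  m <- 0
  vals <- numeric(n); wts <- numeric(n); cnts <- integer(n)
  for (i in seq_len(n)) {
    m <- m + 1
    vals[m] <- y[i]; wts[m] <- w[i]; cnts[m] <- 1L
    while (m > 1 && vals[m - 1] < vals[m]) {
      vals[m - 1] <- (vals[m - 1] * wts[m - 1] + vals[m] * wts[m]) /
        (wts[m - 1] + wts[m])
      wts[m - 1] <- wts[m - 1] + wts[m]
      cnts[m - 1] <- cnts[m - 1] + cnts[m]
      m <- m - 1
    }
  }
  rep(vals[seq_len(m)], cnts[seq_len(m)])
}

# Expected single-contact probability for pair spans (bp) under a fitted
# decay table; spans outside the fitted range get the nearest stratum.
decay_lookup <- function(decay, span) {
  tb <- decay$table
  idx <- findInterval(span, tb$d_min)
  idx[idx < 1] <- 1
  tb$phat[idx]
}

#' Call loops on a contact map against the distance-decay background
#'
#' Candidate pairs are all nonzero pairs within the span limits. Each gets
#' an upper-tail binomial p-value with n = total contacts in the fitted
#' range and success probability `phat(d) * b_i * b_j` (bias-weighted when
#' balancing biases are present). A loop passes the filters iff
#' `p < p_cutoff`, its span lies within the limits, and its count strictly
#' exceeds `min_count`.
#'
#' @param map combined `contact_map`.
#' @param decay `decay_table` fitted on the same map.
#' @param biases optional per-bin biases (defaults to `map$biases`); any
#'   candidate touching a bin with a missing bias is an error.
#' @param p_cutoff,min_span,max_span,min_count filter thresholds
#'   (defaults 1e-4, 20 kb, 2 Mb, 8; the count gate is strict).
#' @return data.frame of class `loop_set`: `bin1`, `bin2`, `span`,
#'   `count`, `expected`, `pvalue`, `passes_filters`.
#' @export
call_loops <- function(map, decay, biases = NULL, p_cutoff = 1e-4,
                       min_span = 2e4, max_span = 2e6, min_count = 8) {
  biases <- biases %||% map$biases
  res <- map$resolution
  cc <- map$counts
  span <- (cc$bin2 - cc$bin1) * res
  keep <- span >= min_span & span <= max_span & cc$count > 0
  cc <- cc[keep, , drop = FALSE]
  span <- span[keep]
  q <- decay_lookup(decay, span)
  if (!is.null(biases)) {
    bb <- biases[cc$bin1] * biases[cc$bin2]
    if (any(!is.finite(bb)))
      stop("call_loops: missing balancing bias for a bin with counts")
    q <- q * bb
  }
  q <- pmin(q, 1)
  pv <- pbinom(cc$count - 1, decay$total, q, lower.tail = FALSE)
  out <- data.frame(bin1 = cc$bin1, bin2 = cc$bin2, span = span,
                    count = cc$count, expected = decay$total * q,
                    pvalue = pv,
                    passes_filters = pv < p_cutoff & cc$count > min_count)
  out$loop_id <- paste0("L", seq_len(nrow(out)))
  attr(out, "resolution") <- res
  class(out) <- c("loop_set", "data.frame")
  out
}

#' Differential looping between two groups of samples
#'
#' Extracts each loop's raw count from every per-sample map (absent pair =
#' 0), normalizes by per-sample total intra-chromosomal counts, and applies
#' the exact conditional NB test per loop. A loop is dynamic iff raw
#' `p < p_cutoff` and `|log2FC| > lfc_cutoff`; the later-time direction
#' names it `weakened` (negative) or `enhanced` (positive), else `stable`.
#'
#' @param loops `loop_set` (only rows passing filters are tested; others
#'   are kept and labeled `stable`).
#' @param maps list of per-sample `contact_map`s.
#' @param groups character/factor per map with exactly two levels ordered
#'   (earlier, later); >= 2 samples each.
#' @param p_cutoff,lfc_cutoff thresholds (defaults 0.05 and 1).
#' @return the loop table with per-sample counts, `dyn_log2FC`,
#'   `dyn_pvalue` and `dynamics`.
#' @export
differential_loops <- function(loops, maps, groups, p_cutoff = 0.05,
                               lfc_cutoff = 1) {
  groups <- factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("differential_loops: need two groups with >= 2 samples each")
  cnt <- vapply(maps, function(m) {
    key <- paste(m$counts$bin1, m$counts$bin2)
    v <- m$counts$count[match(paste(loops$bin1, loops$bin2), key)]
    ifelse(is.na(v), 0, v)
  }, numeric(nrow(loops)))
  cnt <- matrix(cnt, nrow = nrow(loops))
  totals <- vapply(maps, function(m) sum(m$counts$count), numeric(1))
  sf <- totals / geometric_mean(totals)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])
  phi <- estimate_dispersions(cnt, sf, groups)
  lfc <- pv <- rep(NA_real_, nrow(loops))
  test_rows <- which(loops$passes_filters)
  for (i in test_rows) {
    r <- nb_exact_test(cnt[i, ga], cnt[i, gb],
                       size_factors = sf[c(ga, gb)], dispersion = phi[i])
    lfc[i] <- r$log2FC; pv[i] <- r$pvalue
  }
  dyn <- rep("stable", nrow(loops))
  sig <- !is.na(pv) & pv < p_cutoff & abs(lfc) > lfc_cutoff
  dyn[sig & lfc < 0] <- "weakened"
  dyn[sig & lfc > 0] <- "enhanced"
  loops$dyn_log2FC <- lfc
  loops$dyn_pvalue <- pv
  loops$dynamics <- dyn
  smp <- vapply(seq_along(maps), function(j) {
    s <- maps[[j]]$sample
    if (is.na(s)) paste0("sample", j) else as.character(s)
  }, character(1))
  colnames(cnt) <- paste0("count_", smp)
  cbind(loops, as.data.frame(cnt))
}

#' Aggregate peak analysis with P2LL score
#'
#' For each eligible loop, extracts the `(2*radius+1)^2` window of
#' observed/expected values centred on its anchors, averages the windows
#' over loops, and reports P2LL: the centre value divided by the mean of
#' the `corner x corner` lower-left block (the short-distance corner,
#' where background is highest). Loops with span `<=
#' (radius + corner) * resolution`, or whose window leaves the map, are
#' skipped.
#'
#' @param map `contact_map`.
#' @param decay fitted `decay_table` providing expected counts.
#' @param loops data.frame with `bin1`, `bin2`.
#' @param radius_bins half-width of the window in bins (default 10).
#' @param corner_bins side of the lower-left block (default 6).
#' @return list with `matrix` (mean o/e window), `P2LL`, `n_loops`.
#' @export
apa <- function(map, decay, loops, radius_bins = 10, corner_bins = 6) {
  res <- map$resolution
  n <- nrow(map$bins)
  r <- radius_bins
  elig <- loops$span > (radius_bins + corner_bins) * res &
    loops$bin1 - r >= 1 & loops$bin2 + r <= n &
    loops$bin1 + r < loops$bin2 - r
  if (!any(elig)) stop("apa: no eligible loops")
  lp <- loops[elig, , drop = FALSE]
  M <- Matrix::sparseMatrix(i = map$counts$bin1, j = map$counts$bin2,
                            x = map$counts$count, dims = c(n, n))
  W <- matrix(0, 2 * r + 1, 2 * r + 1)
  off <- -r:r
  for (li in seq_len(nrow(lp))) {
    ii <- lp$bin1[li] + off
    jj <- lp$bin2[li] + off
    obs <- as.matrix(M[ii, jj])
    d <- outer(ii, jj, function(a, b) (b - a) * res)
    exp_ <- decay$total * decay_lookup(decay, d)
    W <- W + obs / exp_
  }
  A <- W / nrow(lp)
  ctr <- A[r + 1, r + 1]
  ll <- A[(2 * r + 2 - corner_bins):(2 * r + 1), 1:corner_bins]
  list(matrix = A, P2LL = ctr / mean(ll), n_loops = nrow(lp))
}

#' Virtual 4C profile at an anchor bin
#'
#' The row of the (optionally balanced) contact matrix at the anchor,
#' scaled to counts per million total contacts of the map.
#'
#' @param map `contact_map`.
#' @param anchor_bin 1-based bin id.
#' @param balanced divide counts by the bias product (requires biases).
#' @param per_million scale to contacts per million (default TRUE).
#' @return data.frame `bin`, `chrom`, `start`, `end`, `value`.
#' @export
virtual_4c <- function(map, anchor_bin, balanced = FALSE,
                       per_million = TRUE) {
  n <- nrow(map$bins)
  if (anchor_bin < 1 || anchor_bin > n)
    stop("virtual_4c: anchor outside map")
  v <- numeric(n)
  cc <- map$counts
  sel1 <- cc$bin1 == anchor_bin
  sel2 <- cc$bin2 == anchor_bin
  val <- cc$count
  if (balanced) {
    if (is.null(map$biases)) stop("virtual_4c: map has no biases")
    val <- val / (map$biases[cc$bin1] * map$biases[cc$bin2])
  }
  v[cc$bin2[sel1]] <- v[cc$bin2[sel1]] + val[sel1]
  off <- sel2 & cc$bin1 != anchor_bin
  v[cc$bin1[off]] <- v[cc$bin1[off]] + val[off]
  if (per_million) v <- v * 1e6 / sum(cc$count)
  data.frame(bin = seq_len(n), chrom = map$bins$chrom,
             start = map$bins$start, end = map$bins$end, value = v)
}

#' Write a loop set as BEDPE
#' @param loops `loop_set` data.frame.
#' @param bins bin table resolving bin ids to coordinates.
#' @param path output path.
#' @export
write_bedpe <- function(loops, bins, path) {
  b1 <- bins[loops$bin1, ]; b2 <- bins[loops$bin2, ]
  out <- data.frame(b1$chrom, b1$start, b1$end, b2$chrom, b2$start, b2$end,
                    loops$loop_id %||% seq_len(nrow(loops)), loops$count,
                    loops$pvalue,
                    if (!is.null(loops$dynamics)) loops$dynamics else ".")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}
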