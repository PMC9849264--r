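## Statistical kernel shared by all pipeline stages: TMM normalization, the
## exact conditional negative-binomial test, multiplicity correction,
## rank/correlation tests, k-means clustering and PCA.

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes composition-robust between-sample scaling factors for a count
#' matrix following the trimmed-mean-of-M-values definition: pairwise
#' log-ratios (M) and average log-intensities (A) against a reference sample
#' are double-trimmed and combined by inverse-variance weighting. The
#' reference sample is the one whose upper-quartile count fraction is
#' closest to the mean across samples. Factors are centred so their
#' geometric mean is exactly 1; effective library size is
#' `colSums(counts) * factors`.
#'
#' @param counts non-negative integer matrix, features x samples (>= 2
#'   samples).
#' @param trim_M two-sided trim fraction on M-values (default 0.30).
#' @param trim_A two-sided trim fraction on A-values (default 0.05).
#' @return named numeric vector of positive per-sample factors with
#'   geometric mean 1.
#' @examples
#' m <- cbind(s1 = c(10, 10, 10, 10, 100), s2 = c(10, 10, 10, 10, 10))
#' tmm_factors(m)
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("tmm_factors: need at least 2 samples")
  if (any(counts < 0)) stop("tmm_factors: counts must be non-negative")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    stop("tmm_factors: all-zero sample(s): ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  ## reference: upper-quartile count fraction closest to the mean
  uq <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / geometric_mean(f)
  names(f) <- colnames(counts)
  f
}

# One-vs-reference TMM factor (untrimmed samples with no finite M return 1).
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Exact conditional negative-binomial test for two groups of counts
#'
#' Tests for a difference in abundance between two small groups of counts
#' sharing a common dispersion. Conditional on the overall total, the group-A
#' sum follows (dispersion 0) a binomial law with success probability equal
#' to group A's share of the effective library size, or (dispersion > 0) the
#' normalized product of two negative-binomial mass functions. The two-sided
#' p-value doubles the smaller tail and caps at 1. The log2 fold-change is
#' computed from normalized group means with a pseudo-count of 0.5 (B over
#' A).
#'
#' @param group_a,group_b non-negative integer count vectors.
#' @param size_factors positive effective-library-size factors for the
#'   concatenated samples `c(group_a, group_b)`; default all 1.
#' @param dispersion common NB dispersion (0 = Poisson/binomial limit).
#' @return list with `log2FC`, `pvalue`.
#' @examples
#' nb_exact_test(c(0, 0), c(10, 10))        # strong difference
#' nb_exact_test(c(5, 5), c(5, 5))$pvalue   # 1
#' @export
nb_exact_test <- function(group_a, group_b, size_factors = NULL,
                          dispersion = 0) {
  if (any(group_a < 0) || any(group_b < 0))
    stop("nb_exact_test: negative counts")
  if (!length(group_a) || !length(group_b))
    stop("nb_exact_test: both groups must be non-empty")
  if (dispersion < 0) stop("nb_exact_test: dispersion must be >= 0")
  na <- length(group_a); nb <- length(group_b)
  sf <- size_factors %||% rep(1, na + nb)
  if (length(sf) != na + nb || any(sf <= 0))
    stop("nb_exact_test: bad size_factors")
  Na <- sum(sf[seq_len(na)]); Nb <- sum(sf[na + seq_len(nb)])
  Sa <- sum(group_a); Sb <- sum(group_b); Tt <- Sa + Sb
  lfc <- log2((Sb / Nb + 0.5) / (Sa / Na + 0.5))
  if (Tt == 0) return(list(log2FC = 0, pvalue = 1))
  pa <- Na / (Na + Nb)
  if (dispersion < 1e-10) {
    pl <- pbinom(Sa, Tt, pa)
    pu <- pbinom(Sa - 1, Tt, pa, lower.tail = FALSE)
  } else {
    s <- 0:Tt
    lw <- dnbinom(s, size = na / dispersion, mu = Tt * pa, log = TRUE) +
      dnbinom(Tt - s, size = nb / dispersion, mu = Tt * (1 - pa), log = TRUE)
    lw <- lw - max(lw)
    pr <- exp(lw); pr <- pr / sum(pr)
    pl <- sum(pr[s <= Sa])
    pu <- sum(pr[s >= Sa])
  }
  list(log2FC = lfc, pvalue = min(1, 2 * min(pl, pu)))
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values (same order as input), capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties are present; otherwise a normal approximation with tie correction
#' (no continuity correction, so identical samples give p = 1).
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `statistic` (rank-sum W of `x`) and `pvalue`
#'   (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("wilcoxon_rank_sum: empty input")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 10 && length(y) <= 10
  w <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  list(statistic = unname(w$statistic), pvalue = w$p.value)
}

#' Pearson correlation with two-sided t-distribution p-value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `pvalue`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearson_r: need two equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearson_r: undefined correlation (constant vector)")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value)
}

#' Pearson chi-squared test on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 non-negative matrix with all margins positive.
#' @return list with `statistic` and `pvalue` (df = 1).
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0))
    stop("chi2_2x2: need a non-negative 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi2_2x2: zero margin")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), pvalue = ct$p.value)
}

#' K-means with k-means++ seeding and restarts
#'
#' Runs `stats::kmeans` from `n_restarts` k-means++ initializations under a
#' private seeded RNG stream and keeps the solution with the lowest total
#' within-cluster sum of squares. Deterministic for a fixed seed.
#'
#' @param z_matrix numeric matrix, rows are observations.
#' @param k number of clusters (>= 2, <= number of distinct rows).
#' @param seed integer RNG seed.
#' @param n_restarts number of independent initializations (default 10).
#' @return list with `labels`, `centroids`, `inertia`.
#' @export
kmeans_rows <- function(z_matrix, k, seed = 1, n_restarts = 10) {
  z_matrix <- as.matrix(z_matrix)
  if (k < 2) stop("kmeans_rows: k must be >= 2")
  if (k > nrow(z_matrix)) stop("kmeans_rows: k exceeds number of rows")
  uniq <- unique(z_matrix)
  if (k > nrow(uniq)) stop("kmeans_rows: k exceeds number of distinct rows")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      centers <- .kmeanspp_centers(uniq, k)
      km <- suppressWarnings(
        kmeans(z_matrix, centers = centers, iter.max = 100)
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    list(labels = unname(best$cluster), centroids = best$centers,
         inertia = best$tot.withinss)
  })
}

# k-means++ seeding over distinct rows: each new center is drawn with
# probability proportional to squared distance from the nearest chosen one.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- colSums((t(x) - x[idx[1], ])^2)
  for (i in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    idx[i + 1] <- sample.int(n, 1, prob = probs)
    d2 <- pmin(d2, colSums((t(x) - x[idx[i + 1], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Row-wise z-scores (population standard deviation)
#'
#' @param matrix numeric matrix with no constant rows.
#' @return matrix of the same shape with each row at mean 0, sd 1.
#' @export
zscore_rows <- function(matrix) {
  m <- as.matrix(matrix)
  mu <- rowMeans(m)
  sdp <- sqrt(rowMeans((m - mu)^2))
  bad <- which(sdp == 0)
  if (length(bad))
    stop("zscore_rows: constant row(s): ",
         paste(rownames(m)[bad] %||% bad, collapse = ", "))
  (m - mu) / sdp
}

#' Sample-space principal component analysis
#'
#' Centred SVD projection of the samples (columns) of a normalized
#' feature-by-sample matrix. Axis signs are arbitrary.
#'
#' @param matrix numeric feature x sample matrix with >= 2 samples.
#' @return list with `coords` (samples x components) and `var_frac`
#'   (variance fractions summing to 1).
#' @export
pca_samples <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2) stop("pca_samples: need at least 2 samples")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  list(coords = pc$x, var_frac = v / sum(v))
}

# Per-feature NB dispersion: method-of-moments on within-group
# mean/variance of normalized counts. Raw per-feature estimates (negative
# values retained so the pooled mean stays unbiased) are averaged into a
# common dispersion and each feature is moderated toward it with a prior
# weight of `prior_df` residual degrees of freedom; with few replicates
# the common component dominates, which keeps the exact test calibrated.
estimate_dispersions <- function(counts, size_factors, groups,
                                 prior_df = 20) {
  norm <- sweep(as.matrix(counts), 2, size_factors, "/")
  groups <- as.factor(groups)
  num <- den <- rep(0, nrow(norm))
  for (g in levels(groups)) {
    j <- which(groups == g)
    if (length(j) < 2) next
    m <- rowMeans(norm[, j, drop = FALSE])
    v <- apply(norm[, j, drop = FALSE], 1, var)
    ok <- m > 0
    w <- length(j) - 1
    num[ok] <- num[ok] + w * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  raw <- ifelse(den > 0, num / den, NA_real_)
  phi_common <- max(0, mean(raw, na.rm = TRUE))
  if (!is.finite(phi_common)) phi_common <- 0
  raw[is.na(raw)] <- phi_common
  (den * pmax(0, raw) + prior_df * phi_common) / (den + prior_df)
}
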