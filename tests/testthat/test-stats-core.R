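# Statistical kernel: normalization, exact NB test, multiplicity, rank and
# correlation tests, clustering, z-scores, PCA.

test_that("tmm_factors handles library-size-only differences and errors", {
  m <- cbind(a = c(5L, 8L, 12L, 3L), b = c(5L, 8L, 12L, 3L))
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  # doubling a column is pure depth, not composition
  m2 <- cbind(a = c(5L, 8L, 12L, 3L), b = 2L * c(5L, 8L, 12L, 3L))
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
  expect_error(tmm_factors(cbind(a = c(1, 2))), "2 samples")
  expect_error(tmm_factors(cbind(a = c(1, 2), z = c(0, 0))), "z")
  expect_error(tmm_factors(cbind(a = c(-1, 2), b = c(1, 2))),
               "non-negative")
})

test_that("tmm_factors matches a hand-computed trimmed weighted mean", {
  # A carries one high-abundance feature; all M-values against A are equal
  # except feature 5, which the 30% M-trim removes.  The surviving
  # log-ratio is log2((10/50)/(10/140)) so the raw factor for B is 2.8;
  # centring to geometric mean 1 gives (1/sqrt(2.8), sqrt(2.8)).
  m <- cbind(A = c(10, 10, 10, 10, 100), B = c(10, 10, 10, 10, 10))
  f <- tmm_factors(m, trim_M = 0.30, trim_A = 0.05)
  expect_equal(unname(f), c(1 / sqrt(2.8), sqrt(2.8)), tolerance = 1e-10)
})

test_that("tmm_factors agrees with the edgeR reference implementation", {
  withr::local_seed(42)
  m <- matrix(rnbinom(400 * 6, mu = rlnorm(400, 4, 1), size = 10), 400, 6)
  colnames(m) <- paste0("s", 1:6)
  f_pkg <- tmm_factors(m)
  f_ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f_pkg), unname(f_ref), tolerance = 1e-6)
  expect_equal(exp(mean(log(f_pkg))), 1, tolerance = 1e-12)
})

test_that("nb_exact_test matches the conditional binomial oracle", {
  # oracle: enumerate the binomial pmf directly for all totals <= 30
  oracle <- function(sa, total, pa) {
    pmf <- vapply(0:total, function(s)
      choose(total, s) * pa^s * (1 - pa)^(total - s), numeric(1))
    min(1, 2 * min(sum(pmf[seq_len(sa + 1)]),
                   sum(pmf[(sa + 1):(total + 1)])))
  }
  for (sa in c(0, 3, 10, 15)) {
    for (tot in c(sa + 1, 20, 30)) {
      if (tot < sa) next
      got <- nb_exact_test(c(sa, 0), c(tot - sa, 0), dispersion = 0)
      expect_equal(got$pvalue, oracle(sa, tot, 0.5), tolerance = 1e-9)
    }
  }
  # the quoted extreme case: doubled binomial tail of 20/20 at rate 1/2
  r <- nb_exact_test(c(0, 0), c(10, 10), dispersion = 0)
  expect_equal(r$pvalue, 2 * 0.5^20, tolerance = 1e-12)
})

test_that("nb_exact_test is balanced at equality and monotone in effect", {
  r <- nb_exact_test(c(5, 5), c(5, 5))
  expect_equal(r$log2FC, 0)
  expect_equal(r$pvalue, 1)
  p_prev <- 1
  for (b in c(10, 20, 40, 80)) {
    p <- nb_exact_test(c(10, 10), c(b, b), dispersion = 0)$pvalue
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
  expect_error(nb_exact_test(c(-1, 2), c(1, 2)), "negative")
  expect_error(nb_exact_test(numeric(0), c(1)), "non-empty")
})

test_that("nb_exact_test with dispersion agrees with edgeR's exact test", {
  withr::local_seed(7)
  n <- 200
  mu <- rlnorm(n, log(80), 0.6)
  cnt <- matrix(rnbinom(n * 4, mu = rep(mu, 4), size = 20), n, 4)
  p_pkg <- vapply(seq_len(n), function(i)
    nb_exact_test(cnt[i, 1:2], cnt[i, 3:4], dispersion = 0.05)$pvalue,
    numeric(1))
  dge <- edgeR::DGEList(counts = cnt, group = c(1, 1, 2, 2))
  dge$samples$norm.factors <- rep(1, 4)
  p_ref <- edgeR::exactTest(dge, dispersion = 0.05)$table$PValue
  expect_gt(cor(p_pkg, p_ref), 0.995)
  expect_lt(max(abs(log10(p_pkg) - log10(p_ref))), 0.35)
})

test_that("null NB counts give a calibrated rejection fraction", {
  fx <- null_count_fixture(2000, seed = 11)
  sf <- rep(1, 4)
  phi <- perinet:::estimate_dispersions(fx$counts, sf,
                                        fx$samples$timepoint)
  pv <- vapply(seq_len(nrow(fx$counts)), function(i)
    nb_exact_test(fx$counts[i, 1:2], fx$counts[i, 3:4],
                  dispersion = phi[i])$pvalue, numeric(1))
  frac <- mean(pv < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("bh_adjust applies the step-up rule and validates input", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance: adjust, then restore order
  withr::local_seed(1)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("wilcoxon_rank_sum matches brute-force enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- wilcoxon_rank_sum(x, y)
  # enumerate all 20 rank assignments of 3-of-6
  ranks <- combn(6, 3)
  W <- colSums(ranks) - 6        # Mann-Whitney U of the first sample
  w_obs <- sum(rank(c(x, y))[1:3]) - 6
  p_oracle <- min(1, 2 * min(mean(W <= w_obs), mean(W >= w_obs)))
  expect_equal(got$pvalue, p_oracle, tolerance = 1e-12)
  # identical multisets: p = 1 under the tie-corrected normal path
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(2, 1, 2))$pvalue, 1)
  # rank tests are invariant under common monotone transforms
  a <- c(0.3, 1.2, 2.5, 4.1); b <- c(0.9, 3.3, 5.2, 6.4)
  expect_equal(wilcoxon_rank_sum(a, b)$pvalue,
               wilcoxon_rank_sum(exp(a), exp(b))$pvalue)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("pearson_r follows the closed-form covariance ratio", {
  x <- c(1, 2, 4, 7, 11); y <- c(0.5, 2.1, 3.2, 8.4, 13.0)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_r(x, y)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
})

test_that("chi2_2x2 matches the hand formula and handles margins", {
  t0 <- matrix(c(10, 10, 10, 10), 2)
  r0 <- chi2_2x2(t0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$pvalue, 1)
  t1 <- matrix(c(0, 10, 10, 0), 2)
  # n(ad - bc)^2 / (r1 r2 c1 c2) = 20 * 100^2 / 10^4
  expect_equal(chi2_2x2(t1)$statistic, 20)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("kmeans_rows separates clouds, is deterministic, inertia sane", {
  withr::local_seed(5)
  a <- matrix(rnorm(40, 0), 20, 2)
  b <- matrix(rnorm(40, 8), 20, 2)
  z <- rbind(a, b)
  km <- kmeans_rows(z, k = 2, seed = 9)
  expect_equal(length(unique(km$labels[1:20])), 1)
  expect_equal(length(unique(km$labels[21:40])), 1)
  expect_false(km$labels[1] == km$labels[21])
  km2 <- kmeans_rows(z, k = 2, seed = 9)
  expect_identical(km$labels, km2$labels)
  # duplicated rows always co-cluster
  z2 <- rbind(z, z[1, , drop = FALSE])
  km3 <- kmeans_rows(z2, k = 2, seed = 1)
  expect_equal(km3$labels[41], km3$labels[1])
  # inertia non-increasing in k
  inert <- vapply(2:5, function(k)
    kmeans_rows(z, k, seed = 3)$inertia, numeric(1))
  expect_true(all(diff(inert) <= 1e-8))
  expect_error(kmeans_rows(z[1:3, ], k = 4), "exceeds")
})

test_that("zscore_rows standardizes with population sd", {
  expect_equal(unname(zscore_rows(matrix(c(1, 2, 3), 1))[1, ]),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z <- zscore_rows(matrix(c(4, 0, 2, 7, 1, 1), 2))
  expect_equal(zscore_rows(z), z, tolerance = 1e-12)  # idempotent
  m <- matrix(c(1, 5, 9, 2, 2, 2), 2, byrow = TRUE,
              dimnames = list(c("ok", "flat"), NULL))
  expect_error(zscore_rows(m), "flat")
  # shift/scale invariance of the input
  x <- matrix(rnorm(12), 3)
  expect_equal(zscore_rows(x), zscore_rows(3 * x + 7), tolerance = 1e-10)
})

test_that("pca_samples reconstructs and separates duplicated groups", {
  withr::local_seed(2)
  m <- cbind(g1a = rnorm(30), g1b = 0, g2a = 0, g2b = 0)
  m[, "g1b"] <- m[, "g1a"] + rnorm(30, sd = 0.01)
  m[, "g2a"] <- rnorm(30, 5)
  m[, "g2b"] <- m[, "g2a"] + rnorm(30, sd = 0.01)
  pc <- pca_samples(m)
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-9)
  # PC1 separates the two duplicate-sample groups
  expect_gt(min(abs(pc$coords[1:2, 1] - pc$coords[3:4, 1])), 1)
  expect_lt(abs(diff(pc$coords[1:2, 1])), 0.5)
  # full reconstruction returns the centred input
  p <- prcomp(t(m), center = TRUE)
  rec <- p$x %*% t(p$rotation)
  expect_equal(rec, t(m) - rep(rowMeans(m), each = 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_samples(m[, 1, drop = FALSE]), "2 samples")
})
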