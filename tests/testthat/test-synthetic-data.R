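# Synthetic study generator: determinism, referential integrity, and the
# statistical structure of each planted signal.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(frac_down = 0.5, frac_transient = 0.4,
                          frac_up = 0.3), "sum")
  expect_error(sim_config(chrom_length = 1e6 + 1), "divide")
  expect_error(sim_config(atac_mean = 0), "positive")
  expect_error(sim_config(p_pos = 1.2), "\\[0, 1\\]")
})

test_that("simulate_genome is deterministic and respects geometry", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  # TSSs strictly increasing (non-overlapping gene models)
  expect_true(all(diff(g1$genes$tss) > 0))
  # at least the configured fraction of elements is >= 20 kb from any TSS
  mid <- floor((g1$elements$start + g1$elements$end) / 2)
  dist <- vapply(mid, function(m) min(abs(g1$genes$tss - m)), numeric(1))
  expect_gte(mean(dist >= 2e4), cfg$frac_distal)
  # empty element set remains valid
  g0 <- simulate_genome(small_cfg(n_elements = 0, n_loops = 0))
  expect_equal(nrow(g0$elements), 0)
  expect_equal(nrow(g0$genes), 60)
})

test_that("ground truth refers only to existing simulated entities", {
  st <- small_study()
  tr <- st$truth
  expect_true(all(names(tr$element_class) %in% st$elements$id))
  expect_true(all(tr$loops$bin1 %in% st$bins$bin))
  expect_true(all(tr$loops$bin2 %in% st$bins$bin))
  expect_true(all(tr$links$element %in% st$elements$id))
  expect_true(all(tr$links$gene %in% st$genes$id))
  expect_true(all(tr$motifs$element %in% st$elements$id))
  expect_true(all(tr$deg %in% st$genes$id))
  # loop spans stay inside the calling window
  spans <- (tr$loops$bin2 - tr$loops$bin1) * st$config$resolution
  expect_true(all(spans >= 2e4 & spans <= 2e6))
})

test_that("planted accessibility trajectories have the stated amplitude", {
  cfg <- sim_config(seed = 21, chrom_length = 8e6, n_genes = 100,
                    n_elements = 600, n_loops = 0, effect_log2fc = 2)
  gen <- simulate_genome(cfg)
  at <- simulate_accessibility(cfg, gen)
  cls <- gen$truth$element_class
  # library-normalize first so depth jitter does not enter the ratio
  tm <- perinet:::timepoint_means(normalize_cpm(at$counts), at$samples)
  dn <- names(cls)[cls == "down"]
  ratio <- mean(tm[dn, "E18.5"]) / mean(tm[dn, "P7"])
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
  up <- names(cls)[cls == "up"]
  expect_gt(mean(tm[up, "P7"]) / mean(tm[up, "E18.5"]), 4 * 0.8)
  # zero effect collapses the classes onto the static background
  cfg0 <- sim_config(seed = 21, chrom_length = 8e6, n_genes = 100,
                     n_elements = 600, n_loops = 0, effect_log2fc = 0)
  at0 <- simulate_accessibility(cfg0, simulate_genome(cfg0))
  tm0 <- perinet:::timepoint_means(normalize_cpm(at0$counts),
                                   at0$samples)
  r0 <- mean(tm0[dn, "E18.5"]) / mean(tm0[dn, "P7"])
  expect_gt(r0, 0.85)
  expect_lt(r0, 1.18)
})

test_that("contact backgrounds follow the configured distance decay", {
  cfg <- small_cfg(seed = 5, n_loops = 0)
  gen <- simulate_genome(cfg)
  maps <- simulate_contacts(cfg, gen)$maps
  cm <- combine_maps(maps)
  k <- cm$counts$bin2 - cm$counts$bin1
  mean_at <- function(kk) {
    nb <- nrow(cm$bins)
    sum(cm$counts$count[k >= kk & k < kk + 5]) / sum(nb - (kk:(kk + 4)))
  }
  # alpha = 1: doubling the distance halves the per-pair mean
  expect_equal(mean_at(20) / mean_at(10), 0.5, tolerance = 0.1)
  expect_equal(mean_at(80) / mean_at(40), 0.5, tolerance = 0.12)
  expect_error(simulate_contacts(small_cfg(decay_exponent = -1), gen),
               "positive")
})

test_that("planted loops are enriched by the configured multiplier", {
  st <- small_study()
  cm <- combine_maps(st$maps)
  lp <- st$truth$loops
  stable <- lp[lp$dynamics == "stable", ]
  key <- paste(cm$counts$bin1, cm$counts$bin2)
  obs <- cm$counts$count[match(paste(stable$bin1, stable$bin2), key)]
  # local background: same-distance mean per pair
  k <- cm$counts$bin2 - cm$counts$bin1
  nb <- nrow(cm$bins)
  bg <- vapply(stable$bin2 - stable$bin1, function(kk)
    sum(cm$counts$count[k == kk]) / (nb - kk), numeric(1))
  ratio <- mean(obs / bg)
  expect_gt(ratio, 0.6 * st$config$loop_multiplier)
  expect_lt(ratio, 1.6 * st$config$loop_multiplier)
})

test_that("expression is coupled to linked-element accessibility", {
  st <- small_study()
  tr <- st$truth
  cls <- tr$element_class
  tm <- perinet:::timepoint_means(normalize_cpm(st$rna$counts),
                                  st$rna$samples)
  g_dn <- tr$links$gene[cls[tr$links$element] == "down"]
  g_up <- tr$links$gene[cls[tr$links$element] == "up"]
  r_dn <- mean(tm[g_dn, "P7"] / tm[g_dn, "E18.5"])
  r_up <- mean(tm[g_up, "P7"] / tm[g_up, "E18.5"])
  expect_lt(r_dn, r_up)
  expect_lt(r_dn, 0.6)
  expect_gt(r_up, 1.6)
})

test_that("motif planting is verbatim at fraction 1 and absent at 0", {
  cfg <- small_cfg(seed = 8, plant_frac = 1)
  gen <- simulate_genome(cfg)
  sq <- simulate_sequences(cfg, gen)
  cls <- gen$truth$element_class
  dn <- names(cls)[cls == "down"]
  has_mef2 <- vapply(sq$sequences[dn], function(s)
    grepl("CTAAAAATAG", s) || grepl(perinet:::.revcomp("CTAAAAATAG"), s),
    logical(1))
  expect_true(all(has_mef2))
  # fraction 0: hit rate near the analytic background for a 7-mer
  cfg0 <- small_cfg(seed = 8, plant_frac = 0)
  sq0 <- simulate_sequences(cfg0, simulate_genome(cfg0))
  n_offsets <- sum(nchar(sq0$sequences) - 7 + 1) * 2
  expected_rate <- n_offsets * 0.25^7
  n_hits <- sum(vapply(sq0$sequences, function(s)
    grepl("TGACTCA", s) || grepl("TGAGTCA", s), logical(1)))
  expect_lt(n_hits, 3 * expected_rate + 10)
  expect_identical(sq$sequences,
                   simulate_sequences(cfg, gen)$sequences)
})

test_that("enhancer sets hit their configured overlap rates", {
  cfg <- small_cfg(seed = 13, p_pos = 0.822, p_neg = 0.365)
  gen <- simulate_genome(cfg)
  enh <- simulate_enhancer_sets(cfg, gen)
  ann <- gen$elements
  f_pos <- mean(perinet:::overlaps_any(enh$positive, ann))
  f_neg <- mean(perinet:::overlaps_any(enh$negative, ann))
  # within ~4 binomial standard errors of the planted rates
  expect_lt(abs(f_pos - 0.822), 4 * sqrt(0.822 * 0.178 / cfg$n_pos))
  expect_lt(abs(f_neg - 0.365), 4 * sqrt(0.365 * 0.635 / cfg$n_neg))
  # extremes are exact
  cfgx <- small_cfg(seed = 13, p_pos = 1, p_neg = 0)
  enhx <- simulate_enhancer_sets(cfgx, gen)
  expect_equal(mean(perinet:::overlaps_any(enhx$positive, ann)), 1)
  expect_equal(mean(perinet:::overlaps_any(enhx$negative, ann)), 0)
})

test_that("write_study output is byte-identical under a fixed seed", {
  st <- small_study()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(st, d1)
  write_study(simulate_study(small_cfg()), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # round-trip through the plain-text readers
  el <- read_bed(file.path(d1, "elements.bed"))
  expect_equal(el$start, st$elements$start)
  cnts <- read_counts(file.path(d1, "atac_counts.tsv"))
  expect_equal(unname(cnts), unname(st$atac$counts))
  fa <- read_fasta(file.path(d1, "elements.fa"))
  expect_identical(unname(fa), unname(st$sequences))
  bins <- read_bins(file.path(d1, "bins.bed"))
  m <- read_contact_matrix(
    file.path(d1, paste0("contacts_", st$maps[[1]]$sample, ".matrix")),
    bins, st$config$resolution)
  expect_equal(m$counts, st$maps[[1]]$counts)
})
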