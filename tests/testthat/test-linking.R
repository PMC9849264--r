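# Linking layer: interaction classification, target assignment,
# nearest-vs-interacting comparison, correlation null, dynamics coupling
# and census.

# Hand-built locus: two genes, one distal element looped to the far gene
# (its nearest gene is the close one), mirroring the canonical
# nearest != interacting configuration.
toy_locus <- function() {
  res <- 1e4
  genes <- data.frame(id = c("gNear", "gFar", "gOther"), chrom = "c",
                      tss = c(155000, 405000, 402000),
                      strand = c("+", "+", "-"))
  elements <- data.frame(chrom = "c", start = 120200, end = 120700,
                         id = "eD")
  elements <- annotate_elements(elements, genes)
  loops <- data.frame(bin1 = 13, bin2 = 41, span = 28 * res,
                      count = 50, expected = 2, pvalue = 1e-9,
                      passes_filters = TRUE, loop_id = "L1")
  list(res = res, genes = genes, elements = elements, loops = loops)
}

test_that("classify_interactions types anchors with promoter precedence", {
  tl <- toy_locus()
  # bin 13 holds only the distal element; bin 41 holds two promoters
  cls <- classify_interactions(tl$loops, tl$genes, tl$elements, tl$res,
                               nbins = 100)
  expect_equal(unname(cls$type), "P-D")
  expect_equal(cls$promoter_involving_pct, 100)
  # an anchor that carries both a promoter and an element counts as P
  el2 <- rbind(tl$elements,
               annotate_elements(
                 data.frame(chrom = "c", start = 404000, end = 404500,
                            id = "eP"), tl$genes))
  lp2 <- rbind(tl$loops,
               data.frame(bin1 = 41, bin2 = 60, span = 19e4, count = 20,
                          expected = 1, pvalue = 1e-8,
                          passes_filters = TRUE, loop_id = "L2"))
  cls2 <- classify_interactions(lp2, tl$genes, el2, tl$res, nbins = 100)
  expect_equal(unname(cls2$type), c("P-D", "P-o"))
  expect_error(classify_interactions(tl$loops[0, ], tl$genes,
                                     tl$elements, tl$res, 100),
               "no passing loops")
})

test_that("assign_targets links looped genes and emits nearest pairs", {
  tl <- toy_locus()
  lk <- assign_targets(tl$loops, tl$elements, tl$genes, tl$res)
  got <- lk[lk$element == "eD", ]
  # interacting links to both promoters in the partner bin
  inter <- got[got$mode == "interacting", ]
  expect_setequal(inter$gene, c("gFar", "gOther"))
  expect_equal(unique(inter$loop_id), "L1")
  # paired nearest link to the close gene
  expect_equal(got$gene[got$mode == "nearest"], "gNear")
  # an element in no loop yields only a nearest link when requested
  el2 <- rbind(tl$elements,
               annotate_elements(
                 data.frame(chrom = "c", start = 720100, end = 720600,
                            id = "eLone"), tl$genes))
  lk2 <- assign_targets(tl$loops, el2, tl$genes, tl$res,
                        all_nearest = TRUE)
  lone <- lk2[lk2$element == "eLone", ]
  expect_equal(lone$mode, "nearest")
  # every interacting link comes from a loop that passes filters
  run <- small_run()
  expect_true(all(!is.na(run$links$loop_id[
    run$links$mode == "interacting"])))
  passing <- run$loops$loop_id[run$loops$passes_filters]
  expect_true(all(run$links$loop_id[run$links$mode == "interacting"]
                  %in% passing))
})

test_that("nearest_vs_interacting compares per-time-point expression", {
  run <- small_run()
  st <- small_study()
  nv <- nearest_vs_interacting(run$links, run$de$cpm, st$rna$samples)
  expect_equal(nv$timepoint, unique(st$rna$samples$timepoint))
  # identical sets: p = 1 at every time point
  lk <- run$links
  lk2 <- lk[lk$mode == "interacting", ]
  lk2n <- lk2; lk2n$mode <- "nearest"
  nv2 <- nearest_vs_interacting(rbind(lk2, lk2n), run$de$cpm,
                                st$rna$samples)
  expect_true(all(nv2$pvalue == 1))
  # invariance under gene id relabeling
  cpm2 <- run$de$cpm
  rownames(cpm2) <- paste0("x_", rownames(cpm2))
  lk3 <- lk; lk3$gene <- paste0("x_", lk3$gene)
  nv3 <- nearest_vs_interacting(lk3, cpm2, st$rna$samples)
  expect_equal(nv3$pvalue, nv$pvalue)
  expect_error(nearest_vs_interacting(lk[lk$mode == "interacting", ],
                                      run$de$cpm, st$rna$samples),
               "empty")
})

test_that("planted coupling beats the randomized-pair null", {
  run <- small_run()
  st <- small_study()
  co <- run$correlation
  expect_gt(co$summary$median_r, co$summary$median_null_r)
  expect_gt(co$summary$n_sig_pos, co$summary$n_sig_neg)
  # links realizing planted couplings correlate strongly
  tr <- st$truth$links
  planted <- paste(co$links$element, co$links$gene) %in%
    paste(tr$element, tr$gene)
  expect_gt(median(co$links$r[planted]), 0.7)
  # same seed, same null
  co2 <- link_correlation(run$links, run$da$norm, run$study$atac$samples,
                          run$de$cpm, run$study$rna$samples,
                          n_random = run$thresholds$n_random,
                          seed = run$config$seed + 11)
  expect_equal(co2$null_r, co$null_r)
  expect_equal(co2$summary$wilcoxon_p, co$summary$wilcoxon_p)
  # single link: degenerate null is refused
  expect_error(link_correlation(run$links[
    which(run$links$mode == "interacting")[1], ],
    run$da$norm, run$study$atac$samples, run$de$cpm,
    run$study$rna$samples), "at least 2")
})

test_that("couple_dynamics routes loops by dynamics and direction", {
  run <- small_run()
  st <- small_study()
  cmp <- "E18.5_vs_P3"
  cd <- couple_dynamics(run$dyn_loops, run$links, run$de,
                        run$clusters$calls, cmp)
  dl <- run$dyn_loops[run$dyn_loops$passes_filters, ]
  dyn_ids <- dl$loop_id[dl$dynamics != "stable"]
  # every dynamic loop with a link appears exactly once per linked gene
  expect_true(all(cd$dynamic$loop_id %in% dyn_ids))
  expect_false(any(duplicated(cd$dynamic[, c("loop_id", "gene")])))
  # routing: a weakened loop whose element falls carries a falling DEG
  cls <- st$truth$element_class
  wk <- cd$dynamic[cd$dynamic$dynamics == "weakened" & cd$dynamic$deg &
                     cls[cd$dynamic$element] == "down", ]
  if (nrow(wk)) expect_lt(median(wk$lfc), 0)
  # stable loops with dynamic elements group by element direction
  sd <- cd$stable_dynamic_element
  expect_true(all(sd$direction[sd$element_class == "up"] ==
                    "increased_accessibility"))
  # all-static input: empty coupling table
  still <- run$dyn_loops
  still$dynamics <- "stable"
  calls0 <- run$clusters$calls[0, ]
  cd0 <- couple_dynamics(still, run$links, run$de, calls0, cmp)
  expect_equal(nrow(cd0$dynamic), 0)
  expect_equal(nrow(cd0$stable_dynamic_element), 0)
})

test_that("dynamics_census counts and percentage are conserved", {
  run <- small_run()
  cen <- run$census
  expect_equal(sum(cen$counts), cen$total)
  dl <- run$dyn_loops[run$dyn_loops$passes_filters, ]
  expect_equal(cen$total, nrow(dl))
  # zero dynamic loops -> 0.0%
  still <- data.frame(dynamics = rep("stable", 10))
  expect_equal(dynamics_census(still)$dynamic_pct, 0)
  # printed-count arithmetic: 145 dynamic of 2302 is 6.3%
  vec <- data.frame(dynamics = rep(c("weakened", "enhanced", "stable"),
                                   c(73, 72, 2302 - 145)))
  expect_equal(dynamics_census(vec)$dynamic_pct, 6.3)
})
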