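## End-to-end orchestration: default thresholds, the full pipeline runner,
## truth-recovery metrics, and the deterministic text report.

#' Default analysis thresholds
#'
#' The significance gates applied at each stage: differential
#' accessibility FDR < 0.01 with |log2FC| > 1; loop calling p < 1e-4,
#' spans 20 kb - 2 Mb, combined count > 8; differential loops raw
#' p < 0.05 with |log2FC| > 1; differential expression FDR < 0.05 with
#' |log2FC| > 1; link correlation p < 0.05.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(atac_fdr = 0.01, atac_lfc = 1,
       loop_p = 1e-4, loop_min_span = 2e4, loop_max_span = 2e6,
       loop_min_count = 8,
       diff_loop_p = 0.05, diff_loop_lfc = 1,
       deg_fdr = 0.05, deg_lfc = 1,
       corr_p = 0.05,
       promoter_halfwidth = 2500,
       cluster_k = 4, decay_bins = 50,
       apa_radius = 10, apa_corner = 6,
       motif_threshold = 0.8, n_random = 1000)
}

#' Run the full pipeline on a simulated study
#'
#' Executes every stage in dependency order on a synthetic study:
#' differential accessibility and trajectory clustering, differential
#' expression, combined-map ICE balancing, distance-decay fitting and loop
#' calling, differential looping, interaction classification and target
#' assignment, link correlation with randomized-pair null, motif scanning,
#' enrichment and regulatome construction, and truth-recovery metrics.
#'
#' @param config `sim_config` describing the study (also supplies all
#'   seeds).
#' @param thresholds list from [default_thresholds()] (any entry may be
#'   overridden).
#' @param study optional pre-simulated `sim_study` (must match `config`);
#'   simulated from `config` when NULL.
#' @return list of class `perinet_run` with all stage outputs, `recovery`
#'   metrics and a `manifest`.
#' @export
run_all <- function(config = sim_config(), thresholds = list(),
                    study = NULL) {
  thr <- utils::modifyList(default_thresholds(), thresholds)
  study <- study %||% simulate_study(config)
  cfg <- study$config

  elements <- annotate_elements(study$elements, study$genes,
                                thr$promoter_halfwidth)

  da <- differential_accessibility(study$atac$counts, study$atac$samples,
                                   fdr_cutoff = thr$atac_fdr,
                                   lfc_cutoff = thr$atac_lfc)
  clusters <- cluster_trajectories(da, k = thr$cluster_k,
                                   seed = cfg$seed + 10)

  de <- differential_expression(study$rna$counts, study$rna$samples,
                                fdr_cutoff = thr$deg_fdr,
                                lfc_cutoff = thr$deg_lfc)

  combined <- combine_maps(study$maps)
  combined <- ice_balance(combined)
  decay <- fit_distance_decay(combined, n_bins = thr$decay_bins,
                              min_span = thr$loop_min_span,
                              max_span = thr$loop_max_span)
  loops <- call_loops(combined, decay, p_cutoff = thr$loop_p,
                      min_span = thr$loop_min_span,
                      max_span = thr$loop_max_span,
                      min_count = thr$loop_min_count)
  dyn_loops <- differential_loops(loops, study$maps,
                                  study$hichip_samples$timepoint,
                                  p_cutoff = thr$diff_loop_p,
                                  lfc_cutoff = thr$diff_loop_lfc)

  classification <- classify_interactions(
    loops, study$genes, elements, cfg$resolution, nrow(study$bins),
    thr$promoter_halfwidth)
  links <- assign_targets(loops, elements, study$genes, cfg$resolution)
  census <- dynamics_census(dyn_loops)

  correlation <- if (sum(links$mode == "interacting") >= 2)
    link_correlation(links, da$norm, study$atac$samples, de$cpm,
                     study$rna$samples, n_random = thr$n_random,
                     seed = cfg$seed + 11, p_cutoff = thr$corr_p)
  else NULL

  pwms <- default_pwms()
  hits <- scan_pwms(study$sequences, pwms, thr$motif_threshold)
  down_el <- clusters$calls$element[clusters$calls$class == "down"]
  up_el <- clusters$calls$element[clusters$calls$class == "up"]
  universe <- study$elements$id
  enrich_down <- if (length(down_el))
    motif_enrichment(hits, down_el, universe) else NULL
  enrich_up <- if (length(up_el))
    motif_enrichment(hits, up_el, universe) else NULL
  regulatome <- build_regulatome(hits, clusters$calls, elements, links,
                                 de$dynamic)

  run <- list(config = cfg, thresholds = thr, study = study,
              elements = elements, da = da, clusters = clusters,
              de = de, combined = combined, decay = decay, loops = loops,
              dyn_loops = dyn_loops, classification = classification,
              links = links, census = census, correlation = correlation,
              hits = hits, enrich_down = enrich_down,
              enrich_up = enrich_up, regulatome = regulatome)
  run$recovery <- recovery_metrics(run)
  run$manifest <- list(
    package_version = as.character(utils::packageVersion("perinet")),
    seed = cfg$seed, thresholds = thr,
    n_elements = nrow(study$elements), n_genes = nrow(study$genes),
    n_bins = nrow(study$bins),
    n_dynamic_elements = length(da$dynamic),
    n_degs = length(de$dynamic),
    n_loops_passing = sum(loops$passes_filters),
    n_links = nrow(run$links),
    n_regulatome_edges = nrow(regulatome))
  class(run) <- "perinet_run"
  run
}

#' Truth-recovery metrics for a pipeline run
#'
#' Compares called results against the simulator's ground truth: dynamic
#' element sensitivity and empirical FDR, planted-loop sensitivity under
#' the calling filters, dynamics-label accuracy on planted dynamic loops,
#' APA P2LL on planted loops and on random off-loop anchors, enrichment
#' ranks of the planted motifs in the down/up clusters, and regulatome
#' edge sensitivity.
#'
#' @param run partial or complete `perinet_run` list.
#' @return named list of metrics.
#' @export
recovery_metrics <- function(run) {
  study <- run$study
  truth <- study$truth
  cfg <- study$config

  true_dyn <- names(truth$element_class)[
    truth$element_class %in% c("down", "transient", "up")]
  called_dyn <- run$da$dynamic
  el_sens <- if (length(true_dyn))
    sum(called_dyn %in% true_dyn) / length(true_dyn) else NA
  el_fdr <- if (length(called_dyn))
    sum(!(called_dyn %in% true_dyn)) / length(called_dyn) else 0

  lp <- run$loops[run$loops$passes_filters, ]
  key_called <- paste(lp$bin1, lp$bin2)
  key_true <- paste(truth$loops$bin1, truth$loops$bin2)
  loop_sens <- mean(key_true %in% key_called)

  dl <- run$dyn_loops[run$dyn_loops$passes_filters, ]
  ti <- match(paste(dl$bin1, dl$bin2), key_true)
  tested <- which(!is.na(ti) &
                    truth$loops$dynamics[ti] %in% c("weakened",
                                                    "enhanced"))
  label_acc <- if (length(tested))
    mean(dl$dynamics[tested] == truth$loops$dynamics[ti[tested]]) else NA

  ## APA on planted loops vs random anchors at matched spans
  res <- cfg$resolution
  tl <- data.frame(bin1 = truth$loops$bin1, bin2 = truth$loops$bin2,
                   span = (truth$loops$bin2 - truth$loops$bin1) * res)
  apa_loops <- apa(run$combined, run$decay, tl,
                   run$thresholds$apa_radius, run$thresholds$apa_corner)
  rand <- with_seed(cfg$seed + 12, {
    nbin <- nrow(study$bins)
    k <- sample(tl$bin2 - tl$bin1, 200, replace = TRUE)
    b1 <- vapply(k, function(kk) sample.int(nbin - kk, 1), integer(1))
    data.frame(bin1 = b1, bin2 = b1 + k, span = k * res)
  })
  rand <- rand[!(paste(rand$bin1, rand$bin2) %in% key_true), ]
  apa_rand <- apa(run$combined, run$decay, rand,
                  run$thresholds$apa_radius, run$thresholds$apa_corner)

  rank_of <- function(enr, motif) {
    if (is.null(enr)) return(NA_integer_)
    match(motif, enr$pwm)
  }
  planted <- names(cfg$motif_consensus)

  true_edges <- .true_regulatome(study)
  called_edges <- paste(run$regulatome$tf, run$regulatome$gene)
  reg_sens <- if (nrow(true_edges))
    mean(paste(true_edges$tf, true_edges$gene) %in% called_edges)
  else NA

  list(element_sensitivity = el_sens, element_fdr = el_fdr,
       loop_sensitivity = loop_sens, loop_label_accuracy = label_acc,
       apa_p2ll_loops = apa_loops$P2LL, apa_p2ll_random = apa_rand$P2LL,
       mef2_rank_down = rank_of(run$enrich_down, planted[1]),
       ap1_rank_up = rank_of(run$enrich_up, planted[2]),
       regulatome_sensitivity = reg_sens,
       n_true_edges = nrow(true_edges))
}

# Planted regulatome: TF -> gene edges implied by the truth channel
# (dynamic element with the TF's planted motif, linked to a planted DEG).
.true_regulatome <- function(study) {
  truth <- study$truth
  mot <- truth$motifs
  links <- truth$links
  cls <- truth$element_class
  rows <- list()
  for (i in seq_len(nrow(mot))) {
    e <- mot$element[i]
    g <- links$gene[links$element == e]
    g <- g[g %in% truth$deg]
    if (!length(g)) next
    rows[[length(rows) + 1]] <- data.frame(
      tf = mot$motif[i], gene = g, element = e,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(tf = character(0), gene = character(0),
                      element = character(0)))
  unique(do.call(rbind, rows))
}

#' Percentage table for published-style summary counts
#'
#' Recomputes fractions (to the stated precision) from a table of
#' numerators and denominators, as used for overlap and interaction-census
#' summaries.
#'
#' @param counts data.frame with columns `label`, `numerator`,
#'   `denominator`, `digits`.
#' @return the table with a `percent` column added.
#' @export
fraction_table <- function(counts) {
  counts$percent <- round(100 * counts$numerator / counts$denominator,
                          counts$digits)
  counts
}

#' Human-readable run report
#'
#' Deterministic text summary of a `perinet_run`: per-stage counts, the
#' interaction census, top motif enrichments and recovery metrics.
#' Sections whose inputs are absent are marked absent.
#'
#' @param run `perinet_run` (possibly partial).
#' @return character vector of report lines, invisibly printed.
#' @export
report <- function(run) {
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c("perinet run report", "==================")
  if (!is.null(run$manifest))
    lines <- c(lines, paste0("seed: ", run$manifest$seed))
  if (!is.null(run$da))
    lines <- c(lines, paste0("dynamic elements: ",
                             length(run$da$dynamic), " of ",
                             nrow(run$da$norm)))
  else lines <- c(lines, "accessibility: absent")
  if (!is.null(run$de))
    lines <- c(lines, paste0("differential genes: ",
                             length(run$de$dynamic), " of ",
                             nrow(run$de$norm)))
  else lines <- c(lines, "expression: absent")
  if (!is.null(run$loops)) {
    lines <- c(lines, paste0("loops passing filters: ",
                             sum(run$loops$passes_filters), " of ",
                             nrow(run$loops), " candidates"))
  } else lines <- c(lines, "loops: absent")
  if (!is.null(run$classification))
    lines <- c(lines, paste0(
      "promoter-involving interactions: ",
      run$classification$promoter_involving, " of ",
      run$classification$n, " (",
      fmt(run$classification$promoter_involving_pct), "%)"))
  if (!is.null(run$census))
    lines <- c(lines, paste0(
      "loop dynamics: ", run$census$counts["weakened"], " weakened / ",
      run$census$counts["enhanced"], " enhanced / ",
      run$census$counts["stable"], " stable (",
      fmt(run$census$dynamic_pct, 1), "% dynamic)"))
  else lines <- c(lines, "census: zeros")
  if (!is.null(run$correlation))
    lines <- c(lines, paste0(
      "link correlations: ", run$correlation$summary$n_sig_pos,
      " positive / ", run$correlation$summary$n_sig_neg,
      " negative at p < ", run$thresholds$corr_p))
  if (!is.null(run$enrich_down) && nrow(run$enrich_down))
    lines <- c(lines, paste0("top motif (down set): ",
                             run$enrich_down$pwm[1]))
  if (!is.null(run$enrich_up) && nrow(run$enrich_up))
    lines <- c(lines, paste0("top motif (up set): ",
                             run$enrich_up$pwm[1]))
  if (!is.null(run$regulatome))
    lines <- c(lines, paste0("regulatome edges: ",
                             nrow(run$regulatome)))
  if (!is.null(run$recovery)) {
    r <- run$recovery
    lines <- c(lines, "recovery vs ground truth:",
               paste0("  element sensitivity ", fmt(r$element_sensitivity),
                      ", empirical FDR ", fmt(r$element_fdr)),
               paste0("  loop sensitivity ", fmt(r$loop_sensitivity),
                      ", label accuracy ", fmt(r$loop_label_accuracy)),
               paste0("  APA P2LL loops ", fmt(r$apa_p2ll_loops),
                      ", random ", fmt(r$apa_p2ll_random)),
               paste0("  regulatome sensitivity ",
                      fmt(r$regulatome_sensitivity)))
  }
  lines
}

#' @export
print.perinet_run <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}
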