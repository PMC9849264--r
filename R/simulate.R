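## Synthetic multi-omics study generator. Emulates the assay design the
## pipeline expects -- four perinatal time points with two ATAC and two RNA
## replicates each, two HiChIP time points with three replicates at 10-kb
## resolution -- on a single synthetic chromosome, with every planted
## signal (element trajectories, loops and their dynamics, element-to-gene
## couplings, motif placements) recorded in a ground-truth channel.

#' Simulation configuration
#'
#' Defaults define the study conditions: a 20 Mb chromosome at 10 kb
#' resolution, 300 genes, 1000 elements of which 15%/10%/15% follow
#' decreasing/transient/increasing accessibility trajectories with a
#' 2-log2 effect, 80 planted loops (multiplier 4; 30% dynamic, i.e. 8x vs
#' 2x between the two HiChIP time points), expression of linked genes
#' driven by their element's trajectory with coupling strength `beta`,
#' ~2e6 contacts per HiChIP sample with +/-20% depth jitter, and MEF2-like
#' / AP1-like consensus motifs planted in 80% of down / up elements.
#'
#' @param seed integer master seed; per-stage seeds are derived as
#'   `seed + stage offset` (genome +0, accessibility +1, contacts +2,
#'   expression +3, sequences +4, enhancer sets +5).
#' @param chrom,chrom_length chromosome name and length (bp).
#' @param resolution contact-map bin width (bp); must divide
#'   `chrom_length`.
#' @param n_genes,n_elements feature counts.
#' @param timepoints ordered time-point labels.
#' @param atac_reps,rna_reps replicates per time point.
#' @param hichip_timepoints,hichip_reps HiChIP design (two time points,
#'   three replicates).
#' @param decay_exponent contact distance-decay exponent alpha > 0.
#' @param loop_multiplier contact enrichment of planted loops over
#'   background.
#' @param frac_down,frac_transient,frac_up element trajectory fractions
#'   (sum <= 1; remainder static).
#' @param effect_log2fc trajectory amplitude in log2 units.
#' @param nb_dispersion NB dispersion of ATAC/RNA counts.
#' @param frac_dynamic_loops fraction of planted loops that change between
#'   the HiChIP time points (split evenly weakened/enhanced).
#' @param n_loops number of planted loops.
#' @param frac_distal fraction of elements placed >= 20 kb from every TSS;
#'   the rest overlap a TSS window.
#' @param beta coupling strength from element accessibility z-score to
#'   linked-gene log2 expression.
#' @param promoter_drive_frac fraction of dynamic promoter elements that
#'   drive their own gene (proximal links).
#' @param atac_mean,rna_mean mean counts per feature per sample.
#' @param hichip_depth expected contacts per HiChIP sample.
#' @param depth_jitter relative per-sample depth jitter (default 0.2).
#' @param element_width element width in bp.
#' @param promoter_halfwidth promoter window half-width (bp).
#' @param motif_consensus named character vector of planted consensus
#'   motifs.
#' @param plant_frac fraction of down/up elements receiving their motif.
#' @param n_pos,n_neg,p_pos,p_neg validated-enhancer set sizes and
#'   element-overlap rates.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom = "chrS", chrom_length = 2e7,
                       resolution = 1e4,
                       n_genes = 300, n_elements = 1000,
                       timepoints = c("E18.5", "P1", "P3", "P7"),
                       atac_reps = 2, rna_reps = 2,
                       hichip_timepoints = c("E18.5", "P3"),
                       hichip_reps = 3,
                       decay_exponent = 1, loop_multiplier = 4,
                       frac_down = 0.15, frac_transient = 0.10,
                       frac_up = 0.15,
                       effect_log2fc = 2, nb_dispersion = 0.05,
                       frac_dynamic_loops = 0.3, n_loops = 80,
                       frac_distal = 0.5, beta = 1,
                       promoter_drive_frac = 0.5,
                       atac_mean = 100, rna_mean = 100,
                       hichip_depth = 2e6, depth_jitter = 0.2,
                       element_width = 500, promoter_halfwidth = 2500,
                       motif_consensus = c(MEF2 = "CTAAAAATAG",
                                           AP1 = "TGACTCA"),
                       plant_frac = 0.8,
                       n_pos = 292, n_neg = 1305,
                       p_pos = 0.822, p_neg = 0.365) {
  cfg <- as.list(environment())
  if (frac_down + frac_transient + frac_up > 1)
    stop("sim_config: trajectory fractions must sum to <= 1")
  if (chrom_length %% resolution != 0)
    stop("sim_config: resolution must divide chrom_length")
  if (atac_mean <= 0 || rna_mean <= 0 || hichip_depth <= 0)
    stop("sim_config: sequencing depths must be positive")
  if (length(hichip_timepoints) != 2)
    stop("sim_config: exactly two HiChIP time points")
  if (p_pos < 0 || p_pos > 1 || p_neg < 0 || p_neg > 1)
    stop("sim_config: overlap rates must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate gene models, element intervals, bin table and planted topology
#'
#' Places non-overlapping gene TSSs on a regular jittered grid, elements
#' either overlapping a TSS window (promoter-like) or at least 20 kb from
#' every TSS (distal, a `frac_distal` share), assigns planted trajectory
#' classes, and plants loops between distal-element bins and gene-TSS bins
#' (spans within 20 kb - 2 Mb) together with the element-to-gene links they
#' realize. Deterministic for a fixed seed.
#'
#' @param config `sim_config`.
#' @return list with `genes`, `elements`, `bins` and `truth` (element
#'   classes, loops with per-time-point multipliers and dynamics labels,
#'   links, linked-gene table).
#' @export
simulate_genome <- function(config) {
  cfg <- config
  with_seed(cfg$seed + 0, {
    spacing <- cfg$chrom_length / (cfg$n_genes + 1)
    if (spacing < 2 * (2e4 + cfg$element_width))
      stop("simulate_genome: too many genes for chrom_length")
    tss <- round(spacing * seq_len(cfg$n_genes) +
                   runif(cfg$n_genes, -spacing / 8, spacing / 8))
    genes <- data.frame(
      id = sprintf("g%04d", seq_len(cfg$n_genes)),
      chrom = cfg$chrom, tss = as.integer(tss),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      stringsAsFactors = FALSE)

    n_distal <- round(cfg$n_elements * cfg$frac_distal)
    n_prom <- cfg$n_elements - n_distal
    w <- cfg$element_width
    ## promoter-like elements: centred near a TSS (inside the window)
    host <- sample.int(cfg$n_genes, n_prom, replace = TRUE)
    pstart <- tss[host] - w %/% 2 +
      round(runif(n_prom, -cfg$promoter_halfwidth / 2,
                  cfg$promoter_halfwidth / 2))
    ## distal elements: uniform over regions >= 20 kb + width from any TSS
    gaps <- cbind(c(0, tss + 2e4), c(tss - 2e4 - w, cfg$chrom_length - w))
    gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
    glen <- gaps[, 2] - gaps[, 1]
    gi <- sample.int(nrow(gaps), n_distal, replace = TRUE,
                     prob = glen / sum(glen))
    dstart <- round(gaps[gi, 1] + runif(n_distal) * glen[gi])
    starts <- as.integer(c(pstart, dstart))
    elements <- data.frame(
      chrom = rep(cfg$chrom, cfg$n_elements),
      start = starts, end = starts + as.integer(w),
      id = sprintf("e%04d", seq_len(cfg$n_elements)),
      stringsAsFactors = FALSE)
    elements <- elements[order(elements$start), ]
    elements$id <- sprintf("e%04d", seq_len(cfg$n_elements))
    rownames(elements) <- NULL

    nbin <- cfg$chrom_length / cfg$resolution
    bins <- data.frame(chrom = cfg$chrom,
                       start = as.integer((seq_len(nbin) - 1) *
                                            cfg$resolution),
                       end = as.integer(seq_len(nbin) * cfg$resolution),
                       bin = seq_len(nbin))

    ## planted trajectory classes
    n_dn <- round(cfg$n_elements * cfg$frac_down)
    n_tr <- round(cfg$n_elements * cfg$frac_transient)
    n_up <- round(cfg$n_elements * cfg$frac_up)
    cls <- rep("static", cfg$n_elements)
    dynidx <- sample.int(cfg$n_elements, n_dn + n_tr + n_up)
    cls[dynidx] <- rep(c("down", "transient", "up"),
                       c(n_dn, n_tr, n_up))
    element_class <- setNames(cls, elements$id)

    truth <- list(element_class = element_class)
    truth <- c(truth, .plant_loops(cfg, genes, elements, element_class))
    list(genes = genes, elements = elements, bins = bins, truth = truth)
  })
}

# Plant loops joining distal-element bins to gene-TSS bins, and the
# element-to-gene links (distal via loops, proximal via promoter windows).
.plant_loops <- function(cfg, genes, elements, element_class) {
  res <- cfg$resolution
  mid <- floor((elements$start + elements$end) / 2)
  ebin <- mid %/% res + 1
  gbin <- genes$tss %/% res + 1
  ## nearest gene (by TSS-to-midpoint) for the nearest!=linked flag
  near <- vapply(mid, function(m) which.min(abs(genes$tss - m)),
                 integer(1))
  is_distal <- !vapply(seq_len(nrow(elements)), function(i) {
    any(abs(genes$tss - mid[i]) <= 2e4)
  }, logical(1))
  cand <- which(is_distal)
  ## favour dynamic elements so loops probe the coupled stages
  ord <- if (length(cand)) {
    dynw <- ifelse(element_class[cand] %in% c("down", "up", "transient"),
                   3, 1)
    sample(cand, length(cand), prob = dynw / sum(dynw))
  } else integer(0)
  used_pairs <- character(0)
  used_genes <- integer(0)
  rows <- list()
  for (ei in ord) {
    if (length(rows) >= cfg$n_loops) break
    d <- abs(genes$tss - mid[ei])
    ok <- which(d >= 4e4 & d <= 1.5e6 & gbin != ebin[ei] &
                  !(seq_len(nrow(genes)) %in% used_genes))
    if (!length(ok)) next
    gi <- sample(ok, 1)
    b1 <- min(ebin[ei], gbin[gi]); b2 <- max(ebin[ei], gbin[gi])
    key <- paste(b1, b2)
    if (key %in% used_pairs || (b2 - b1) * res < 2e4) next
    used_pairs <- c(used_pairs, key)
    used_genes <- c(used_genes, gi)
    rows[[length(rows) + 1]] <- data.frame(
      bin1 = b1, bin2 = b2, element = elements$id[ei],
      gene = genes$id[gi], nearest_gene = genes$id[near[ei]],
      stringsAsFactors = FALSE)
  }
  loops <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin1 = integer(0), bin2 = integer(0),
               element = character(0), gene = character(0),
               nearest_gene = character(0))
  n <- nrow(loops)
  n_dyn <- if (n) round(n * cfg$frac_dynamic_loops) else 0L
  dyn <- sample.int(n, n_dyn)
  lab <- rep("stable", n)
  lab[dyn] <- rep(c("weakened", "enhanced"), length.out = n_dyn)
  m <- cfg$loop_multiplier
  loops$mult_t1 <- ifelse(lab == "weakened", 2 * m,
                          ifelse(lab == "enhanced", m / 2, m))
  loops$mult_t2 <- ifelse(lab == "weakened", m / 2,
                          ifelse(lab == "enhanced", 2 * m, m))
  loops$dynamics <- lab
  ## proximal links: dynamic promoter-like elements driving their own gene
  emid <- floor((elements$start + elements$end) / 2)
  prom <- which(!is_distal &
                  element_class %in% c("down", "transient", "up"))
  prom <- prom[!(genes$id[near[prom]] %in% loops$gene)]
  prom <- prom[!duplicated(genes$id[near[prom]])]
  prom <- prom[runif(length(prom)) < cfg$promoter_drive_frac]
  links <- rbind(
    if (nrow(loops))
      data.frame(element = loops$element, gene = loops$gene,
                 mode = "distal", stringsAsFactors = FALSE),
    if (length(prom))
      data.frame(element = elements$id[prom], gene = genes$id[near[prom]],
                 mode = "proximal", stringsAsFactors = FALSE))
  links <- links %||% data.frame(element = character(0),
                                 gene = character(0),
                                 mode = character(0))
  links <- links[!duplicated(links$gene), ]
  rownames(links) <- NULL
  list(loops = loops, links = links)
}

# Per-class log2 offsets across the time course (amplitude = effect).
.trajectory_offsets <- function(class, timepoints, effect) {
  Tn <- length(timepoints)
  switch(class,
         down = effect * (Tn - seq_len(Tn)) / (Tn - 1),
         up = effect * (seq_len(Tn) - 1) / (Tn - 1),
         transient = effect * c(0, rep(1, Tn - 2), 0),
         rep(0, Tn))
}

#' Simulate the element-by-sample accessibility count matrix
#'
#' NB counts with mean `baseline * 2^offset(class, t) * depth jitter`;
#' `down` elements fall monotonically by `effect_log2fc` log2 units over
#' the time course, `up` elements rise, `transient` elements peak at the
#' interior time points.
#'
#' @param config `sim_config`.
#' @param truth genome truth from [simulate_genome()] (full genome list).
#' @return list with `counts` (elements x samples) and `samples` metadata.
#' @export
simulate_accessibility <- function(config, truth) {
  cfg <- config
  el <- truth$elements
  cls <- truth$truth$element_class
  with_seed(cfg$seed + 1, {
    tps <- cfg$timepoints
    samples <- data.frame(
      sample = paste0("atac_", rep(tps, each = cfg$atac_reps), "_r",
                      rep(seq_len(cfg$atac_reps), length(tps))),
      timepoint = rep(tps, each = cfg$atac_reps),
      replicate = rep(seq_len(cfg$atac_reps), length(tps)),
      assay = "ATAC", stringsAsFactors = FALSE)
    base <- rlnorm(nrow(el), meanlog = log(cfg$atac_mean), sdlog = 0.5)
    offs <- t(vapply(cls[el$id], .trajectory_offsets,
                     numeric(length(tps)),
                     timepoints = tps, effect = cfg$effect_log2fc))
    depth <- runif(nrow(samples), 1 - cfg$depth_jitter,
                   1 + cfg$depth_jitter)
    counts <- matrix(0L, nrow(el), nrow(samples),
                     dimnames = list(el$id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      tj <- match(samples$timepoint[j], tps)
      mu <- base * 2^offs[, tj] * depth[j]
      counts[, j] <- rnbinom(nrow(el), mu = mu,
                             size = 1 / cfg$nb_dispersion)
    }
    list(counts = counts, samples = samples)
  })
}

#' Simulate per-sample HiChIP contact maps with planted loops
#'
#' Background counts for pair (i, j) are Poisson with mean proportional to
#' `distance^-alpha`, scaled so each sample totals about `hichip_depth`
#' contacts (with per-sample depth jitter). Planted loop pairs have their
#' mean multiplied by the loop's time-point-specific multiplier.
#'
#' @param config `sim_config`.
#' @param truth genome list from [simulate_genome()].
#' @return list with `maps` (list of `contact_map`) and `samples`
#'   metadata.
#' @export
simulate_contacts <- function(config, truth) {
  cfg <- config
  if (cfg$decay_exponent <= 0)
    stop("simulate_contacts: decay exponent must be positive")
  bins <- truth$bins
  loops <- truth$truth$loops
  nbin <- nrow(bins)
  res <- cfg$resolution
  ks <- seq_len(nbin - 1)
  base_k <- (ks * res)^(-cfg$decay_exponent)
  norm <- sum((nbin - ks) * base_k)
  rate_k <- cfg$hichip_depth * base_k / norm
  tps <- cfg$hichip_timepoints
  samples <- data.frame(
    sample = paste0("hichip_", rep(tps, each = cfg$hichip_reps), "_r",
                    rep(seq_len(cfg$hichip_reps), length(tps))),
    timepoint = rep(tps, each = cfg$hichip_reps),
    replicate = rep(seq_len(cfg$hichip_reps), length(tps)),
    assay = "HiChIP", stringsAsFactors = FALSE)
  loop_k <- if (!is.null(loops)) loops$bin2 - loops$bin1 else integer(0)
  maps <- with_seed(cfg$seed + 2, {
    depth <- runif(nrow(samples), 1 - cfg$depth_jitter,
                   1 + cfg$depth_jitter)
    lapply(seq_len(nrow(samples)), function(si) {
      mult <- if (samples$timepoint[si] == tps[1]) loops$mult_t1
              else loops$mult_t2
      parts <- vector("list", nbin - 1)
      for (k in ks) {
        n <- nbin - k
        x <- rpois(n, rate_k[k] * depth[si])
        lk <- which(loop_k == k)
        if (length(lk))
          x[loops$bin1[lk]] <- rpois(length(lk),
                                     rate_k[k] * depth[si] * mult[lk])
        nz <- which(x > 0L)
        if (length(nz))
          parts[[k]] <- data.frame(bin1 = nz, bin2 = nz + k,
                                   count = x[nz])
      }
      contact_map(bins, do.call(rbind, parts), res,
                  sample = samples$sample[si])
    })
  })
  list(maps = maps, samples = samples)
}

#' Simulate the gene-by-sample expression count matrix
#'
#' Linked genes follow their element: log2 mean expression is
#' `baseline + beta * z(accessibility trajectory of the linked element at
#' that time point)`; unlinked genes are static. NB noise and depth jitter
#' as for accessibility.
#'
#' @param config `sim_config`.
#' @param truth genome list from [simulate_genome()].
#' @return list with `counts`, `samples`, and `deg` (ids of genes planted
#'   to change, i.e. genes linked to a dynamic element when `beta != 0`).
#' @export
simulate_expression <- function(config, truth) {
  cfg <- config
  genes <- truth$genes
  links <- truth$truth$links
  cls <- truth$truth$element_class
  tps <- cfg$timepoints
  with_seed(cfg$seed + 3, {
    samples <- data.frame(
      sample = paste0("rna_", rep(tps, each = cfg$rna_reps), "_r",
                      rep(seq_len(cfg$rna_reps), length(tps))),
      timepoint = rep(tps, each = cfg$rna_reps),
      replicate = rep(seq_len(cfg$rna_reps), length(tps)),
      assay = "RNA", stringsAsFactors = FALSE)
    base <- rlnorm(nrow(genes), meanlog = log(cfg$rna_mean), sdlog = 0.7)
    offs <- matrix(0, nrow(genes), length(tps))
    li <- match(genes$id, links$gene)
    linked <- which(!is.na(li))
    for (g in linked) {
      ecl <- cls[links$element[li[g]]]
      tr <- .trajectory_offsets(ecl, tps, cfg$effect_log2fc)
      if (sd(tr) > 0) {
        z <- (tr - mean(tr)) / sqrt(mean((tr - mean(tr))^2))
        offs[g, ] <- cfg$beta * z
      }
    }
    depth <- runif(nrow(samples), 1 - cfg$depth_jitter,
                   1 + cfg$depth_jitter)
    counts <- matrix(0L, nrow(genes), nrow(samples),
                     dimnames = list(genes$id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      tj <- match(samples$timepoint[j], tps)
      mu <- base * 2^offs[, tj] * depth[j]
      counts[, j] <- rnbinom(nrow(genes), mu = mu,
                             size = 1 / cfg$nb_dispersion)
    }
    deg <- if (cfg$beta != 0)
      links$gene[cls[links$element] %in% c("down", "transient", "up")]
    else character(0)
    list(counts = counts, samples = samples, deg = deg)
  })
}

#' Simulate element sequences with planted motifs
#'
#' Uniform i.i.d. A/C/G/T backgrounds; the first configured consensus
#' (MEF2-like) is planted verbatim in a `plant_frac` share of `down`
#' elements and the second (AP1-like) in `up` elements, on a random
#' strand at a random offset; placements are recorded.
#'
#' @param config `sim_config`.
#' @param truth genome list from [simulate_genome()].
#' @return list with `sequences` (named character vector) and `motifs`
#'   (data.frame element, motif, offset, strand).
#' @export
simulate_sequences <- function(config, truth) {
  cfg <- config
  el <- truth$elements
  cls <- truth$truth$element_class
  cons <- cfg$motif_consensus
  widths <- el$end - el$start
  if (any(widths < max(nchar(cons))))
    stop("simulate_sequences: element shorter than motif")
  with_seed(cfg$seed + 4, {
    seqs <- vapply(widths, function(w) {
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- el$id
    plant <- list()
    for (tf in names(cons)[1:2]) {
      target_cls <- if (tf == names(cons)[1]) "down" else "up"
      idx <- which(cls[el$id] == target_cls)
      idx <- idx[runif(length(idx)) < cfg$plant_frac]
      for (i in idx) {
        motif <- cons[[tf]]
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") motif else .revcomp(motif)
        L <- nchar(ins)
        off <- sample.int(widths[i] - L + 1, 1) - 1L
        substr(seqs[i], off + 1, off + L) <- ins
        plant[[length(plant) + 1]] <- data.frame(
          element = el$id[i], motif = tf, offset = off, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    motifs <- if (length(plant)) do.call(rbind, plant) else
      data.frame(element = character(0), motif = character(0),
                 offset = integer(0), strand = character(0))
    list(sequences = seqs, motifs = motifs)
  })
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate labeled validated-enhancer sets
#'
#' Draws a positive set that overlaps accessible elements at per-interval
#' rate `p_pos` and a negative set at rate `p_neg` (Bernoulli per
#' enhancer); non-overlapping enhancers are placed clear of all elements.
#'
#' @param config `sim_config`.
#' @param truth genome list from [simulate_genome()].
#' @return list with `positive` and `negative` interval data.frames.
#' @export
simulate_enhancer_sets <- function(config, truth) {
  cfg <- config
  el <- truth$elements
  with_seed(cfg$seed + 5, {
    list(positive = .enhancer_set(el, cfg, cfg$n_pos, cfg$p_pos, "pos"),
         negative = .enhancer_set(el, cfg, cfg$n_neg, cfg$p_neg, "neg"))
  })
}

.enhancer_set <- function(el, cfg, n, p, tag) {
  w <- 1000L
  hit <- runif(n) < p
  start <- integer(n)
  ## overlapping: centred on a random element
  hi <- which(hit)
  if (length(hi)) {
    ei <- sample.int(nrow(el), length(hi), replace = TRUE)
    start[hi] <- as.integer(floor((el$start[ei] + el$end[ei]) / 2) -
                              w %/% 2)
  }
  ## non-overlapping: drawn from gaps between inflated elements
  lo <- which(!hit)
  if (length(lo)) {
    infl_s <- pmax(0, el$start - w)
    gaps <- cbind(c(0, el$end), c(infl_s - 1, cfg$chrom_length - w))
    gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
    glen <- gaps[, 2] - gaps[, 1]
    gi <- sample.int(nrow(gaps), length(lo), replace = TRUE,
                     prob = glen / sum(glen))
    start[lo] <- as.integer(round(gaps[gi, 1] + runif(length(lo)) *
                                    glen[gi]))
  }
  data.frame(chrom = cfg$chrom, start = start, end = start + w,
             id = sprintf("%s%04d", tag, seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator stage and bundles the outputs with the ground
#' truth.
#'
#' @param config `sim_config`.
#' @return list of class `sim_study` with `genes`, `elements`, `bins`,
#'   `atac`, `maps`, `hichip_samples`, `rna`, `sequences`, `enhancers`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  atac <- simulate_accessibility(config, gen)
  hic <- simulate_contacts(config, gen)
  rna <- simulate_expression(config, gen)
  seqs <- simulate_sequences(config, gen)
  enh <- simulate_enhancer_sets(config, gen)
  truth <- gen$truth
  truth$deg <- rna$deg
  truth$motifs <- seqs$motifs
  structure(list(genes = gen$genes, elements = gen$elements,
                 bins = gen$bins,
                 atac = atac, maps = hic$maps,
                 hichip_samples = hic$samples, rna = rna,
                 sequences = seqs$sequences, enhancers = enh,
                 truth = truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", nrow(x$elements), "elements,", nrow(x$genes),
      "genes,", length(x$maps), "HiChIP maps,",
      nrow(x$truth$loops), "planted loops\n")
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Emits `elements.bed`, `genes.tsv`, `bins.bed`,
#' `contacts_<sample>.matrix`, `atac_counts.tsv`, `atac_samples.tsv`,
#' `rna_counts.tsv`, `rna_samples.tsv`, `elements.fa`,
#' `enhancers_pos.bed`, `enhancers_neg.bed` and `truth.json` under `dir`.
#'
#' @param study `sim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_bed(study$elements, p("elements.bed"))
  write_genes(study$genes, p("genes.tsv"))
  write_bins(study$bins, p("bins.bed"))
  for (m in study$maps)
    write_contact_matrix(m, p(paste0("contacts_", m$sample, ".matrix")))
  write_counts(study$atac$counts, p("atac_counts.tsv"))
  write.table(study$atac$samples, p("atac_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_counts(study$rna$counts, p("rna_counts.tsv"))
  write.table(study$rna$samples, p("rna_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(study$sequences, p("elements.fa"))
  write_bed(study$enhancers$positive, p("enhancers_pos.bed"))
  write_bed(study$enhancers$negative, p("enhancers_neg.bed"))
  tr <- study$truth
  tr$element_class <- as.list(tr$element_class)
  jsonlite::write_json(tr, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
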