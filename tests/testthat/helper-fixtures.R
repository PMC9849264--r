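# Shared fixtures: a desk-scale simulated study (4 Mb chromosome) cached
# across test files, sample-sheet builders and interval constructors.

.fixture_cache <- new.env(parent = emptyenv())

small_cfg <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(seed = seed, chrom_length = 4e6, n_genes = 60,
         n_elements = 200, n_loops = 20, hichip_depth = 4e5),
    list(...))
  do.call(sim_config, args)
}

small_study <- function() {
  if (is.null(.fixture_cache$study))
    .fixture_cache$study <- simulate_study(small_cfg())
  .fixture_cache$study
}

small_run <- function() {
  if (is.null(.fixture_cache$run))
    .fixture_cache$run <- run_all(small_cfg(), study = small_study())
  .fixture_cache$run
}

make_samples <- function(timepoints, reps, assay = "ATAC") {
  data.frame(
    sample = paste0("s_", rep(timepoints, each = reps), "_r",
                    rep(seq_len(reps), length(timepoints))),
    timepoint = rep(timepoints, each = reps),
    replicate = rep(seq_len(reps), length(timepoints)),
    assay = assay, stringsAsFactors = FALSE)
}

# Null two-group count matrix (no true difference) with its sample sheet.
null_count_fixture <- function(n, seed, mean_count = 100,
                               dispersion = 0.05, reps = 2) {
  withr::local_seed(seed)
  mu <- rlnorm(n, log(mean_count), 0.5)
  cnt <- matrix(rnbinom(n * 2 * reps, mu = rep(mu, 2 * reps),
                        size = 1 / dispersion), n, 2 * reps)
  samp <- make_samples(c("A", "B"), reps)
  colnames(cnt) <- samp$sample
  rownames(cnt) <- paste0("f", seq_len(n))
  list(counts = cnt, samples = samp)
}

# Interval sets realizing given overlap counts: `k` of `n` enhancers get a
# private overlapping element; the rest sit in element-free territory.
overlap_fixture <- function(k_pos, n_pos, k_neg, n_neg, width = 1000) {
  gap <- 10 * width
  mk <- function(n, offset) {
    s <- offset + gap * seq_len(n)
    data.frame(chrom = "chrF", start = s, end = s + width,
               id = paste0("iv", offset + seq_len(n)))
  }
  pos <- mk(n_pos, 0)
  neg <- mk(n_neg, gap * (n_pos + 2))
  hit <- rbind(head(pos, k_pos), head(neg, k_neg))
  elements <- data.frame(chrom = "chrF",
                         start = hit$start + width %/% 4,
                         end = hit$start + width %/% 2,
                         id = paste0("e", seq_len(nrow(hit))))
  list(elements = elements, positive = pos, negative = neg)
}

# Uniform toy contact map: every pair at bin distance 1..kmax has `count`.
uniform_map <- function(nbins, resolution = 1e4, count = 2,
                        kmax = nbins - 1) {
  pairs <- do.call(rbind, lapply(seq_len(kmax), function(k) {
    data.frame(bin1 = seq_len(nbins - k), bin2 = seq_len(nbins - k) + k,
               count = count)
  }))
  bins <- data.frame(chrom = "chrT",
                     start = (seq_len(nbins) - 1) * resolution,
                     end = seq_len(nbins) * resolution,
                     bin = seq_len(nbins))
  contact_map(bins, pairs, resolution)
}

# Flat decay table: expected count exactly `expected` for every pair.
flat_decay <- function(total, resolution, expected = 1,
                       max_span = 2e6) {
  structure(list(
    table = data.frame(stratum = 1L, d_min = resolution,
                       d_max = max_span, n_pairs = NA, count = NA,
                       phat = expected / total),
    total = total, resolution = resolution,
    min_span = resolution, max_span = max_span),
    class = "decay_table")
}
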