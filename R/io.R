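## Plain-text readers/writers for the pipeline's interchange formats:
## BED3+id intervals, gene tables, bin tables, HiC-Pro-style sparse contact
## matrices, count TSVs, FASTA and JASPAR-style PWM text.

#' Read a BED3+name file of intervals
#'
#' @param path BED file (chrom, start, end, optional name; 0-based
#'   half-open).
#' @return data.frame with columns `chrom`, `start`, `end`, `id`.
#' @export
read_bed <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "id", "V5", "V6")[
                    seq_len(min(6, ncol(read.table(path, sep = "\t",
                                                   nrows = 1))))],
                  stringsAsFactors = FALSE)
  if (is.null(b$id)) b$id <- paste0("iv", seq_len(nrow(b)))
  b[, c("chrom", "start", "end", "id")]
}

#' Write intervals as BED3+name
#' @param x data.frame with `chrom`, `start`, `end` and optionally `id`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "id"), names(x))
  write.table(x[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read/write a feature-by-sample count matrix TSV
#'
#' First column holds feature ids; remaining columns are samples.
#' @param path TSV path.
#' @return integer matrix with feature rownames and sample colnames.
#' @export
read_counts <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts matrix to write.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene table (id, chrom, tss, strand)
#' @param path TSV with header.
#' @return data.frame.
#' @export
read_genes <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_genes
#' @param genes data.frame to write.
#' @export
write_genes <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read element sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(s)), names(s))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 80L)
}

#' Read a JASPAR-style PWM text file
#'
#' Accepts a `>name` header followed by four rows (A, C, G, T) of counts or
#' probabilities, with or without base labels and brackets. Columns are
#' normalized to probabilities; multiple records per file are supported.
#'
#' @param path PWM text file.
#' @return list of PWM objects (see [pwm_from_consensus()]).
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("read_pwms: no '>' headers found")
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    name <- trimws(sub("^>\\s*", "", lines[i]))
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lines[(i + 1):j]
    if (length(rows) != 4)
      stop("read_pwms: expected 4 base rows for ", name)
    parsed <- lapply(rows, function(r) {
      r <- sub("^[ACGTacgt][ :]*", "", trimws(r))
      r <- gsub("\\[|\\]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1)
      stop("read_pwms: ragged rows for ", name)
    mat <- do.call(rbind, parsed)
    rownames(mat) <- c("A", "C", "G", "T")
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[name]] <- new_pwm(name, mat)
  }
  out
}

#' Read a HiC-Pro-style bin table (BED of fixed-width bins with bin ids)
#' @param path bins.bed path (chrom, start, end, 1-based bin id).
#' @return data.frame with `chrom`, `start`, `end`, `bin`.
#' @export
read_bins <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "bin"),
                  stringsAsFactors = FALSE)
  b
}

#' @rdname read_bins
#' @param bins data.frame to write.
#' @export
write_bins <- function(bins, path) {
  write.table(bins[, c("chrom", "start", "end", "bin")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a sparse upper-triangle contact matrix (HiC-Pro dialect)
#'
#' Three whitespace-separated columns: 1-based bin ids i <= j and an
#' integer count.
#'
#' @param path matrix file path.
#' @param bins bin table from [read_bins()].
#' @param resolution bin width in bp.
#' @param sample optional sample label.
#' @return a `contact_map` object.
#' @export
read_contact_matrix <- function(path, bins, resolution, sample = NA) {
  d <- read.table(path, header = FALSE,
                  col.names = c("bin1", "bin2", "count"))
  contact_map(bins, d, resolution, sample = sample)
}

#' @rdname read_contact_matrix
#' @param map contact_map to write.
#' @export
write_contact_matrix <- function(map, path) {
  write.table(map$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

## ---- interval overlap helpers (IRanges-backed, BED half-open) ----

# TRUE for each query interval that shares >= 1 bp with any subject
# interval on the same chromosome.
overlaps_any <- function(query, subject) {
  hit <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = subject$start[si] + 1L,
                          end = subject$end[si])
    ov <- IRanges::findOverlaps(q, s)
    hit[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}
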