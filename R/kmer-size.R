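# k-mer depth-distribution genome-size estimation.
#
# The estimator is the classical ratio method: count canonical k-mers in
# the reads, treat the low-depth tail of the depth histogram (below the
# first valley) as sequencing errors, and divide the total number of
# error-free k-mer occurrences by the modal ("peak") depth of the
# error-free part. For unique-sequence genomes the peak depth is the
# effective k-mer coverage, so the ratio recovers the genome length.

#' Construct a k-mer depth histogram
#'
#' @param depth positive integer depths
#' @param count number of distinct canonical k-mers observed at each depth
#' @param k the k-mer size the histogram was computed at (odd, <= 31)
#' @return a `kmer_histogram` (data.frame with columns depth, count)
#' @export
kmer_histogram <- function(depth, count, k = NA_integer_) {
  depth <- as.numeric(depth)
  count <- as.numeric(count)
  stopifnot(length(depth) == length(count), all(depth >= 1), all(count >= 0),
            !anyDuplicated(depth))
  o <- order(depth)
  structure(data.frame(depth = depth[o], count = count[o]),
            class = c("kmer_histogram", "data.frame"), k = as.integer(k))
}

#' Count canonical k-mers in reads
#'
#' Every window of length `k` containing no N contributes the
#' lexicographically smaller of itself and its reverse complement. Counting
#' is exact (C++ backend, 2-bit packed codes).
#'
#' @param reads a `read_set`, an `assembly`, or a character vector of
#'   sequences over A,C,G,T,N
#' @param k odd k-mer size, 1..31
#' @return a `kmer_histogram`
#' @export
count_kmers <- function(reads, k) {
  seqs <- if (inherits(reads, c("read_set", "assembly"))) reads$seq else as.character(reads)
  k <- as.integer(k)
  if (k < 1L || k > 31L) stop("k must be in 1..31")
  if (k %% 2L == 0L) stop("k must be odd: canonical form is ill-defined for even k")
  df <- count_kmers_cpp(seqs, k)
  kmer_histogram(df$depth, df$count, k = k)
}

#' Read / write a k-mer histogram TSV (depth, count)
#'
#' Two-column TSV with header `depth<TAB>count`, compatible with common
#' k-mer-counter histogram output.
#'
#' @param path TSV file
#' @param k k-mer size to attach (not stored in the file)
#' @return a `kmer_histogram`
#' @export
read_kmer_hist <- function(path, k = NA_integer_) {
  df <- read_table_schema(path, "kmer_hist")
  kmer_histogram(df$depth, df$count, k = k)
}

#' @rdname read_kmer_hist
#' @param hist a `kmer_histogram`
#' @export
write_kmer_hist <- function(hist, path) {
  write_table_tsv(data.frame(depth = hist$depth, count = hist$count), path)
}

# Dense count vector n(1..max_depth), missing depths filled with 0.
dense_counts <- function(hist) {
  maxd <- max(hist$depth)
  n <- numeric(maxd)
  n[hist$depth] <- hist$count
  n
}

#' Find the error cutoff depth of a k-mer histogram
#'
#' Returns the smallest depth d >= 2 on the dense histogram (missing depths
#' count as 0) that is a local minimum (n(d) <= n(d-1) and n(d) <= n(d+1))
#' and has positive k-mer mass below it (an error tail to cut away). K-mers
#' below this valley are treated as sequencing errors. If no such valley
#' exists (e.g. a pure single-peak histogram without an error tail),
#' returns 1 with a warning and attribute `warned = TRUE`.
#'
#' @param hist a `kmer_histogram`
#' @return integer cutoff depth (attribute `warned` set if the fallback fired)
#' @export
find_error_cutoff <- function(hist) {
  if (nrow(hist) == 0L) stop("empty histogram")
  n <- dense_counts(hist)
  np1 <- c(n[-1], 0)               # n(d+1), zero past the end
  nm1 <- c(Inf, n[-length(n)])     # n(d-1), d=1 never eligible
  d <- seq_along(n)
  # a valley must separate an actual error tail from the coverage peak:
  # require positive mass strictly below the candidate depth
  below <- c(0, cumsum(n)[-length(n)])
  ok <- d >= 2 & n <= nm1 & n <= np1 & below > 0
  if (any(ok)) {
    structure(which(ok)[1], warned = FALSE)
  } else {
    warning("no valley found in k-mer histogram; treating all depths as error-free")
    structure(1L, warned = TRUE)
  }
}

#' Find the peak (modal) depth of the error-free histogram
#'
#' Argmax of n(d) over d >= cutoff; ties break toward the smaller depth.
#'
#' @param hist a `kmer_histogram`
#' @param cutoff smallest depth treated as error-free
#' @return integer peak depth
#' @export
find_peak_depth <- function(hist, cutoff) {
  stopifnot(cutoff >= 1)
  sel <- hist$depth >= cutoff & hist$count > 0
  if (!any(sel)) stop("no k-mer mass at or above the error cutoff")
  d <- hist$depth[sel]
  n <- hist$count[sel]
  as.integer(d[which.max(n)])   # which.max takes the first (smallest depth) tie
}

#' Estimate genome size from a k-mer depth histogram
#'
#' Genome size = (total error-free k-mer occurrences) / (their modal
#' depth): size = round(sum_{d >= cutoff} d * n(d) / peak).
#'
#' @param hist a `kmer_histogram`
#' @param cutoff error cutoff depth; found with [find_error_cutoff()] when NULL
#' @return a `genome_size_estimate` with fields k, error_cutoff_depth,
#'   peak_depth, error_free_total, size_bp
#' @export
estimate_genome_size <- function(hist, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- find_error_cutoff(hist)
  peak <- find_peak_depth(hist, cutoff)
  stopifnot(cutoff <= peak)
  sel <- hist$depth >= cutoff
  total <- sum(hist$depth[sel] * hist$count[sel])
  est <- structure(list(k = attr(hist, "k"),
                        error_cutoff_depth = as.integer(cutoff),
                        peak_depth = peak,
                        error_free_total = total,
                        size_bp = round_half_up(total / peak)),
                   class = "genome_size_estimate")
  if (est$error_free_total > 0) stopifnot(est$size_bp > 0)
  est
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(paste0("Genome size estimate (k=%s)\n",
                     "  error cutoff depth : %d\n",
                     "  peak depth         : %d\n",
                     "  error-free k-mers  : %s\n",
                     "  estimated size     : %s bp\n"),
              ifelse(is.na(x$k), "?", x$k), x$error_cutoff_depth, x$peak_depth,
              format(x$error_free_total, big.mark = ",", scientific = FALSE),
              format(x$size_bp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Genome coverage of an assembly relative to a size estimate
#'
#' @param assembly_total_bp total assembled bases
#' @param estimate_bp estimated genome size in bp
#' @return percentage, rounded half-up to one decimal (82.9 means 82.9%)
#' @export
#' @examples
#' genome_coverage(2222062302, 2.68e9)  # 82.9
genome_coverage <- function(assembly_total_bp, estimate_bp) {
  stopifnot(assembly_total_bp > 0)
  if (estimate_bp <= 0) stop("genome size estimate must be positive")
  round_half_up(100 * assembly_total_bp / estimate_bp, 1)
}
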