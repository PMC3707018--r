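# Assembly summary statistics as reported in draft-genome resource tables:
# sequence counts, total/max/mean lengths, N50, undefined-base (N) content
# and, given a genome-size estimate, genome coverage.

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together contain
#' at least half of the total bases. Computed by exact rational comparison
#' (2 * running sum >= total), so odd totals carry no float ambiguity.
#'
#' @param lengths positive sequence lengths
#' @return the N50 length
#' @export
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # 5
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("n50 of an empty length set is undefined")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(2 * cumsum(s) >= sum(s))[1]]
}

#' Compute assembly summary statistics
#'
#' Undefined bases are 'N' characters (lowercase is normalized on read).
#' Mean length is rounded half-up to 2 decimals, percentages to 1 decimal.
#'
#' @param asm an `assembly`
#' @param genome_size_estimate optional estimated genome size in bp; enables
#'   the coverage percentage
#' @return an `assembly_stats` list: num_sequences, total_bp, max_bp,
#'   mean_bp, n50_bp, undefined_bases, undefined_pct, non_gapped_pct,
#'   coverage_pct (NA without an estimate)
#' @export
compute_stats <- function(asm, genome_size_estimate = NULL) {
  stopifnot(inherits(asm, "assembly"), length(asm$id) > 0L)
  lens <- nchar(asm$seq)
  total <- sum(lens)
  undef <- sum(vapply(gregexpr("[Nn]", asm$seq, perl = TRUE),
                      function(m) if (m[1] == -1L) 0L else length(m), 0L))
  est <- genome_size_estimate
  if (inherits(est, "genome_size_estimate")) est <- est$size_bp
  structure(list(
    num_sequences = length(lens),
    total_bp = total,
    max_bp = max(lens),
    mean_bp = round_half_up(total / length(lens), 2),
    n50_bp = n50(lens),
    undefined_bases = undef,
    undefined_pct = round_half_up(100 * undef / total, 1),
    non_gapped_pct = round_half_up(100 * (total - undef) / total, 1),
    coverage_pct = if (is.null(est)) NA_real_ else genome_coverage(total, est)
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat("Assembly statistics\n")
  cat(sprintf("  Sequences        %s\n", fmt(x$num_sequences)))
  cat(sprintf("  Average length   %s bp\n", format(x$mean_bp, nsmall = 2, big.mark = ",")))
  cat(sprintf("  Maximum length   %s bp\n", fmt(x$max_bp)))
  cat(sprintf("  N50 length       %s bp\n", fmt(x$n50_bp)))
  cat(sprintf("  Total length     %s bp\n", fmt(x$total_bp)))
  cat(sprintf("  Undefined bases  %s (%.1f%%)\n", fmt(x$undefined_bases), x$undefined_pct))
  if (!is.na(x$coverage_pct)) cat(sprintf("  Genome coverage  %.1f%%\n", x$coverage_pct))
  invisible(x)
}

#' Drop sequences below a minimum length
#'
#' @param asm an `assembly`
#' @param min_bp minimum retained length (inclusive)
#' @return list with `assembly` (order preserved) and `removed` (count)
#' @export
min_length_filter <- function(asm, min_bp) {
  stopifnot(inherits(asm, "assembly"), min_bp >= 0)
  keep <- nchar(asm$seq) >= min_bp
  list(assembly = new_assembly(asm$id[keep], asm$seq[keep], asm$name),
       removed = sum(!keep))
}
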