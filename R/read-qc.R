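# Read preprocessing: 3' quality trimming followed by a length rule and a
# quality-fraction rule. Two presets mirror the DNA and RNA policies used
# for short-read draft-genome work: DNA reads are 3'-trimmed at Q30 and
# kept only if >= 50 bases long with >= 90% of bases at Q30+; RNA reads are
# kept at >= 50 bases with >= 75% of bases at Q20+.

#' Define a read filtering policy
#'
#' @param trim_quality Phred threshold for 3' trimming: trailing bases with
#'   quality below this are removed
#' @param min_length minimum post-trim read length in bases
#' @param min_fraction minimum fraction of post-trim bases that must reach
#'   `fraction_quality`
#' @param fraction_quality Phred threshold used by the fraction rule
#' @return a `filter_policy`
#' @export
filter_policy <- function(trim_quality, min_length, min_fraction, fraction_quality) {
  stopifnot(trim_quality >= 0, min_length >= 0, fraction_quality >= 0,
            min_fraction >= 0, min_fraction <= 1)
  structure(list(trim_quality = as.integer(trim_quality),
                 min_length = as.integer(min_length),
                 min_fraction = as.numeric(min_fraction),
                 fraction_quality = as.integer(fraction_quality)),
            class = "filter_policy")
}

#' @rdname filter_policy
#' @export
dna_policy <- function() filter_policy(30, 50, 0.90, 30)

#' @rdname filter_policy
#' @export
rna_policy <- function() filter_policy(20, 50, 0.75, 20)

#' Trim low-quality 3' bases from a read
#'
#' Removes the maximal 3' run of bases with quality below `threshold`: the
#' result is the prefix ending at the last base with quality >= threshold
#' (possibly empty).
#'
#' @param read list with `id`, `seq` and integer `qual` (decoded Phred)
#' @param threshold Phred threshold
#' @return the read with `seq`/`qual` truncated
#' @export
trim_3prime <- function(read, threshold) {
  if (is.null(read$qual)) stop(sprintf("read '%s' has no qualities", read$id %||% "?"))
  q <- as.integer(read$qual)
  keep <- which(q >= threshold)
  n <- if (length(keep) == 0L) 0L else keep[length(keep)]
  read$seq <- substr(read$seq, 1L, n)
  read$qual <- q[seq_len(n)]
  read
}

#' Apply a filter policy to a single read
#'
#' Trims first, then tests the length rule and the quality-fraction rule on
#' the post-trim read.
#'
#' @param read list with `id`, `seq`, integer `qual`
#' @param policy a [filter_policy()]
#' @return list with `keep` (logical), `reason` ("kept", "short" or
#'   "fraction") and `read` (the trimmed read)
#' @export
apply_policy <- function(read, policy) {
  r <- trim_3prime(read, policy$trim_quality)
  n <- length(r$qual)
  if (n < policy$min_length) {
    return(list(keep = FALSE, reason = "short", read = r))
  }
  frac <- sum(r$qual >= policy$fraction_quality) / n
  if (frac < policy$min_fraction) {
    return(list(keep = FALSE, reason = "fraction", read = r))
  }
  list(keep = TRUE, reason = "kept", read = r)
}

#' Run quality trimming and filtering over a read set
#'
#' @param reads a `read_set`
#' @param policy a [filter_policy()]
#' @return list with `kept` (a trimmed `read_set`, input order preserved)
#'   and `summary` (reads_in, reads_kept, reads_discarded_short,
#'   reads_discarded_fraction, bases_trimmed)
#' @export
run_qc <- function(reads, policy) {
  stopifnot(inherits(reads, "read_set"), inherits(policy, "filter_policy"))
  quals <- qual_scores(reads)
  n <- length(reads$id)
  keep <- logical(n)
  reason <- character(n)
  trimmed_seq <- character(n)
  trimmed_qual <- vector("list", n)
  bases_trimmed <- 0L
  for (i in seq_len(n)) {
    res <- apply_policy(list(id = reads$id[i], seq = reads$seq[i], qual = quals[[i]]),
                        policy)
    keep[i] <- res$keep
    reason[i] <- res$reason
    trimmed_seq[i] <- res$read$seq
    trimmed_qual[[i]] <- res$read$qual
    bases_trimmed <- bases_trimmed + (length(quals[[i]]) - length(res$read$qual))
  }
  kept <- new_read_set(reads$id[keep], trimmed_seq[keep],
                       encode_quals(trimmed_qual[keep]))
  summary <- list(reads_in = n, reads_kept = sum(keep),
                  reads_discarded_short = sum(reason == "short"),
                  reads_discarded_fraction = sum(reason == "fraction"),
                  bases_trimmed = bases_trimmed)
  stopifnot(summary$reads_in == summary$reads_kept + summary$reads_discarded_short +
              summary$reads_discarded_fraction)
  list(kept = kept, summary = summary, reason = reason)
}
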