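# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (enumeration, all-pairs scans) so they never share
# code with the implementation paths they check.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Canonical k-mer depth histogram by direct window enumeration and string
# comparison.
bf_kmer_hist <- function(seqs, k) {
  kmers <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, 1:(n - k + 1), k:n)
    w <- w[!grepl("N", w, fixed = TRUE)]
    if (length(w) == 0L) next
    kmers <- c(kmers, pmin(w, revcomp(w)))
  }
  if (length(kmers) == 0L) {
    return(data.frame(depth = numeric(0), count = numeric(0)))
  }
  depth_per_kmer <- table(kmers)
  h <- table(as.integer(depth_per_kmer))
  data.frame(depth = as.numeric(names(h)), count = as.numeric(h))
}

# N50 by testing every candidate length L.
bf_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) * 2 >= total) return(L)
  }
  stop("unreachable")
}

# All full-length ungapped primer placements on both strands by a sliding
# Hamming scan (vectorized over start positions).
bf_primer_sites <- function(primer, seqs, min_identity = 0.95) {
  len <- nchar(primer)
  out <- list()
  for (sid in names(seqs)) {
    chars <- strsplit(seqs[[sid]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < len) next
    for (strand in c("+", "-")) {
      pat <- strsplit(if (strand == "+") primer else revcomp(primer), "",
                      fixed = TRUE)[[1]]
      mm <- integer(n - len + 1L)
      for (j in seq_len(len)) {
        mm <- mm + (chars[j:(n - len + j)] != pat[j])
      }
      hit <- which((len - mm) / len >= min_identity - 1e-12)
      if (length(hit) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid, start = hit - 1L, end = hit - 1L + len, strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$seq_id, res$start, res$strand), , drop = FALSE]
}

# Region FPKM sums by an all-pairs overlap scan.
bf_region_fpkm <- function(regions, transcripts) {
  sums <- numeric(nrow(regions))
  ns <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(transcripts))) {
      if (regions$seq_id[i] == transcripts$seq_id[j] &&
          regions$start[i] < transcripts$end[j] &&
          transcripts$start[j] < regions$end[i]) {
        sums[i] <- sums[i] + transcripts$fpkm[j]
        ns[i] <- ns[i] + 1L
      }
    }
  }
  data.frame(region_id = regions$region_id, fpkm_sum = sums, n_transcripts = ns,
             stringsAsFactors = FALSE)
}

# 3' trimming by scanning from the end, one base at a time.
bf_trim_3prime <- function(qual, threshold) {
  n <- length(qual)
  while (n > 0L && qual[n] < threshold) n <- n - 1L
  n
}

# A read with explicit integer qualities.
make_read <- function(id, len, qual) {
  stopifnot(length(qual) == len)
  list(id = id, seq = random_dna(len), qual = as.integer(qual))
}

make_read_set <- function(n, len, qmin = 30, qmax = 40) {
  ids <- sprintf("r%04d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i) random_dna(len), "")
  quals <- encode_quals(lapply(seq_len(n), function(i)
    sample(qmin:qmax, len, replace = TRUE)))
  read_set(ids, seqs, quals)
}
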