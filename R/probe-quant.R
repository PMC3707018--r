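# Exon-array probe placement and FPKM region quantification.
#
# Probes are retained only when they match the assembly perfectly and at
# exactly one locus (searching both strands; a probe hitting one locus
# forward and another reverse-complemented has two matches and is
# rejected). Expression of a genome region is the sum of FPKM values of
# transcripts overlapping it by at least one base.

#' Place probes on an assembly (perfect, unique matches only)
#'
#' @param probes named character vector of probe sequences (A,C,G,T), or an
#'   `assembly`/`read_set` of probes
#' @param asm an `assembly`
#' @param regions optional data.frame (region_id, seq_id, start, end;
#'   0-based half-open); retained probes fully contained in a region are
#'   annotated with its region_id, partial overlaps are flagged
#' @return list with `placements` (probe_id, seq_id, start, strand,
#'   region_id, partial_overlap) and `rejected` (probe_id, reason in
#'   none/multiple)
#' @export
place_probes <- function(probes, asm, regions = NULL) {
  if (inherits(probes, c("assembly", "read_set"))) {
    probe_seq <- probes$seq; names(probe_seq) <- probes$id
  } else {
    probe_seq <- stats::setNames(toupper(as.character(probes)), names(probes))
    if (is.null(names(probe_seq))) stop("probes must be named")
  }
  subject <- as_dss(asm)
  placements <- list()
  rejected <- list()
  for (i in seq_along(probe_seq)) {
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") probe_seq[[i]] else revcomp(probe_seq[[i]])
      m <- as.data.frame(Biostrings::vmatchPattern(pat, subject, max.mismatch = 0,
                                                   fixed = TRUE))
      if (nrow(m) > 0L) {
        hits[[strand]] <- data.frame(seq_id = asm$id[m$group], start = m$start - 1L,
                                     end = m$end, strand = strand,
                                     stringsAsFactors = FALSE)
      }
    }
    h <- if (length(hits) > 0L) do.call(rbind, c(hits, list(make.row.names = FALSE)))
         else NULL
    # a palindromic probe hits the same interval on both strands: one placement
    if (!is.null(h)) h <- h[!duplicated(h[, c("seq_id", "start", "end")]), , drop = FALSE]
    n_hits <- if (is.null(h)) 0L else nrow(h)
    if (n_hits == 1L) {
      placements[[length(placements) + 1L]] <-
        cbind(probe_id = names(probe_seq)[i], h)
    } else {
      rejected[[length(rejected) + 1L]] <-
        data.frame(probe_id = names(probe_seq)[i],
                   reason = if (n_hits == 0L) "none" else "multiple",
                   stringsAsFactors = FALSE)
    }
  }
  pl <- if (length(placements) > 0L)
    do.call(rbind, c(placements, list(make.row.names = FALSE)))
  else data.frame(probe_id = character(0), seq_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0), stringsAsFactors = FALSE)
  pl$region_id <- rep(NA_character_, nrow(pl))
  pl$partial_overlap <- rep(FALSE, nrow(pl))
  if (!is.null(regions) && nrow(pl) > 0L) {
    for (j in seq_len(nrow(pl))) {
      r <- regions[regions$seq_id == pl$seq_id[j], , drop = FALSE]
      contained <- r$start <= pl$start[j] & r$end >= pl$end[j]
      partial <- r$start < pl$end[j] & r$end > pl$start[j] & !contained
      if (any(contained)) {
        pl$region_id[j] <- r$region_id[which(contained)[1]]
      } else if (any(partial)) {
        pl$partial_overlap[j] <- TRUE
      }
    }
  }
  list(placements = pl,
       rejected = if (length(rejected) > 0L)
         do.call(rbind, c(rejected, list(make.row.names = FALSE)))
       else data.frame(probe_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE))
}

#' Sum transcript FPKM over genome regions
#'
#' A transcript contributes to a region when it overlaps it by at least one
#' base on the same sequence (strand is ignored). Coordinates are 0-based
#' half-open.
#'
#' @param regions data.frame (region_id, seq_id, start, end)
#' @param transcripts data.frame (transcript_id, seq_id, start, end, fpkm)
#' @return data.frame (region_id, fpkm_sum, n_transcripts), one row per
#'   region in input order
#' @export
sum_region_fpkm <- function(regions, transcripts) {
  stopifnot(all(c("region_id", "seq_id", "start", "end") %in% names(regions)),
            all(c("seq_id", "start", "end", "fpkm") %in% names(transcripts)),
            all(regions$start < regions$end))
  if (any(transcripts$fpkm < 0)) {
    stop(sprintf("negative FPKM for transcript '%s'",
                 transcripts$transcript_id[which(transcripts$fpkm < 0)[1]]),
         call. = FALSE)
  }
  fpkm_sum <- numeric(nrow(regions))
  n_tx <- integer(nrow(regions))
  for (sid in unique(regions$seq_id)) {
    ri <- which(regions$seq_id == sid)
    ti <- which(transcripts$seq_id == sid)
    if (length(ti) == 0L) next
    # 0-based half-open -> 1-based inclusive
    rr <- IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri])
    tr <- IRanges::IRanges(transcripts$start[ti] + 1L, transcripts$end[ti])
    ov <- IRanges::findOverlaps(rr, tr, minoverlap = 1L)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    agg <- tapply(transcripts$fpkm[ti][sh], qh, sum)
    cnt <- tapply(sh, qh, length)
    idx <- as.integer(names(agg))
    fpkm_sum[ri[idx]] <- as.numeric(agg)
    n_tx[ri[idx]] <- as.integer(cnt)
  }
  data.frame(region_id = regions$region_id, fpkm_sum = fpkm_sum,
             n_transcripts = n_tx, stringsAsFactors = FALSE)
}
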