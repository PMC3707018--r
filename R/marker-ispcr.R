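# In-silico PCR for SSR/COSII marker primer pairs.
#
# Primer matching is ungapped, full-length and substitution-only; a primer
# site is retained when identity (matches / primer length) reaches the
# threshold (default 95%, i.e. at most 1 mismatch on a 20-mer). An
# amplicon is a convergent pairing of a plus-strand site and a downstream
# minus-strand site on the same sequence, with outer span at most
# `max_product_bp`. A marker maps "unique" when it yields exactly one
# amplicon genome-wide; only unique markers are retained.

#' Find primer binding sites
#'
#' Reports every ungapped full-length placement of the primer (forward
#' strand) or its reverse complement (minus strand) with identity at least
#' `min_identity`.
#'
#' @param primer primer sequence, 5'->3', over A,C,G,T
#' @param asm an `assembly`
#' @param min_identity minimum matches/length (default 0.95)
#' @return data.frame (seq_id, start, end, strand, mismatches, identity);
#'   start/end 0-based half-open on the forward coordinate system
#' @export
find_primer_sites <- function(primer, asm, min_identity = 0.95) {
  primer <- toupper(primer)
  stopifnot(!grepl("[^ACGT]", primer))
  len <- nchar(primer)
  max_mm <- floor(len * (1 - min_identity) + 1e-9)
  subject <- as_dss(asm)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max_mm,
                                   with.indels = FALSE, fixed = TRUE)
    hits <- as.data.frame(m)
    if (nrow(hits) == 0L) next
    mm <- vapply(seq_len(nrow(hits)), function(j) {
      s <- substr(asm$seq[hits$group[j]], hits$start[j], hits$end[j])
      sum(utf8ToInt(s) != utf8ToInt(pat))
    }, 0L)
    out[[strand]] <- data.frame(seq_id = asm$id[hits$group],
                                start = hits$start - 1L, end = hits$end,
                                strand = strand, mismatches = mm,
                                identity = (len - mm) / len,
                                stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0L) do.call(rbind, c(out, list(make.row.names = FALSE))) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  res[res$identity >= min_identity - 1e-12, , drop = FALSE]
}

#' Predict PCR amplicons for a primer pair
#'
#' Every pairing of a plus-strand site of one primer with a downstream
#' minus-strand site of the other primer (convergent orientation) on the
#' same sequence yields an amplicon, provided the outer span is at least
#' the two primer lengths (no overlapping sites) and at most
#' `max_product_bp`. The pair is unordered: both primers are tried in both
#' roles, and duplicate intervals are reported once.
#'
#' @param forward_seq,reverse_seq primer sequences, 5'->3'
#' @param asm an `assembly`
#' @param min_identity per-primer identity threshold
#' @param max_product_bp maximum product length (default 2000)
#' @return data.frame (seq_id, start, end, product_bp, fwd_identity,
#'   rev_identity); start/end 0-based half-open outer primer boundaries
#' @export
predict_amplicons <- function(forward_seq, reverse_seq, asm, min_identity = 0.95,
                              max_product_bp = 2000L) {
  sites_f <- find_primer_sites(forward_seq, asm, min_identity)
  sites_r <- find_primer_sites(reverse_seq, asm, min_identity)
  min_len <- nchar(forward_seq) + nchar(reverse_seq)
  pair_up <- function(plus, minus, id_plus, id_minus) {
    out <- list()
    for (sid in intersect(unique(plus$seq_id), unique(minus$seq_id))) {
      p <- plus[plus$seq_id == sid, , drop = FALSE]
      q <- minus[minus$seq_id == sid, , drop = FALSE]
      for (i in seq_len(nrow(p))) for (j in seq_len(nrow(q))) {
        prod <- q$end[j] - p$start[i]
        if (prod >= min_len && prod <= max_product_bp) {
          out[[length(out) + 1L]] <- data.frame(
            seq_id = sid, start = p$start[i], end = q$end[j], product_bp = prod,
            fwd_identity = if (id_plus == "f") p$identity[i] else q$identity[j],
            rev_identity = if (id_plus == "f") q$identity[j] else p$identity[i],
            stringsAsFactors = FALSE)
        }
      }
    }
    out
  }
  amps <- c(pair_up(sites_f[sites_f$strand == "+", , drop = FALSE],
                    sites_r[sites_r$strand == "-", , drop = FALSE], "f", "r"),
            pair_up(sites_r[sites_r$strand == "+", , drop = FALSE],
                    sites_f[sites_f$strand == "-", , drop = FALSE], "r", "f"))
  if (length(amps) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      product_bp = integer(0), fwd_identity = numeric(0),
                      rev_identity = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, c(amps, list(make.row.names = FALSE)))
  res <- res[!duplicated(res[, c("seq_id", "start", "end")]), , drop = FALSE]
  res <- res[order(res$seq_id, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a marker's mapping status in one genome
#'
#' `unique` = exactly one amplicon genome-wide, `multiple` = two or more,
#' `none` = zero. Only unique markers are retained for anchoring.
#'
#' @inheritParams predict_amplicons
#' @return list with `status` and the `amplicons` data.frame
#' @export
classify_marker <- function(forward_seq, reverse_seq, asm, min_identity = 0.95,
                            max_product_bp = 2000L) {
  amps <- predict_amplicons(forward_seq, reverse_seq, asm, min_identity, max_product_bp)
  status <- if (nrow(amps) == 1L) "unique" else if (nrow(amps) >= 2L) "multiple" else "none"
  list(status = status, amplicons = amps)
}

#' Run in-silico PCR for a table of primer pairs
#'
#' @param pairs data.frame with columns marker_id, forward_seq, reverse_seq
#' @param asm an `assembly`
#' @inheritParams predict_amplicons
#' @return list with `status` (marker_id, status, n_amplicons) and `hits`
#'   (per-amplicon rows with marker_id)
#' @export
run_ispcr <- function(pairs, asm, min_identity = 0.95, max_product_bp = 2000L) {
  stopifnot(all(c("marker_id", "forward_seq", "reverse_seq") %in% names(pairs)))
  status <- character(nrow(pairs))
  n_amp <- integer(nrow(pairs))
  hits <- list()
  for (i in seq_len(nrow(pairs))) {
    cl <- classify_marker(pairs$forward_seq[i], pairs$reverse_seq[i], asm,
                          min_identity, max_product_bp)
    status[i] <- cl$status
    n_amp[i] <- nrow(cl$amplicons)
    if (n_amp[i] > 0L) {
      hits[[length(hits) + 1L]] <- cbind(marker_id = pairs$marker_id[i], cl$amplicons)
    }
  }
  list(status = data.frame(marker_id = pairs$marker_id, status = status,
                           n_amplicons = n_amp, stringsAsFactors = FALSE),
       hits = if (length(hits) > 0L) do.call(rbind, c(hits, list(make.row.names = FALSE)))
              else data.frame(marker_id = character(0), seq_id = character(0),
                              start = integer(0), end = integer(0),
                              product_bp = integer(0), fwd_identity = numeric(0),
                              rev_identity = numeric(0), stringsAsFactors = FALSE))
}

#' Cross-tabulate marker mapping against external evidence
#'
#' Combines per-genome mapping statuses (genome A and genome B) into a
#' joint category (`A_only`, `B_only`, `both`, `neither`; a marker counts
#' as mapped in a genome only when its status there is `unique`) and
#' cross-tabulates it against an external evidence panel (amplification
#' tests, genetic-map membership). Markers absent from the panel are
#' counted under evidence class `unknown` with a warning.
#'
#' @param results_a,results_b data.frames (marker_id, status) from
#'   [run_ispcr()] against the two genomes
#' @param panel data.frame (marker_id, evidence_class)
#' @return a `concordance_table`: list with `details` (per-marker rows) and
#'   `table` (joint_category x evidence_class counts)
#' @export
aggregate_concordance <- function(results_a, results_b, panel) {
  ids <- union(results_a$marker_id, results_b$marker_id)
  sa <- results_a$status[match(ids, results_a$marker_id)]
  sb <- results_b$status[match(ids, results_b$marker_id)]
  sa[is.na(sa)] <- "none"
  sb[is.na(sb)] <- "none"
  ma <- sa == "unique"
  mb <- sb == "unique"
  joint <- ifelse(ma & mb, "both", ifelse(ma, "A_only", ifelse(mb, "B_only", "neither")))
  ev <- panel$evidence_class[match(ids, panel$marker_id)]
  if (anyNA(ev)) {
    warning(sprintf("%d marker(s) missing from the evidence panel; counted as 'unknown'",
                    sum(is.na(ev))))
    ev[is.na(ev)] <- "unknown"
  }
  details <- data.frame(marker_id = ids, status_a = sa, status_b = sb,
                        joint_category = factor(joint, levels = c("A_only", "B_only",
                                                                  "both", "neither")),
                        evidence_class = ev, stringsAsFactors = FALSE)
  structure(list(details = details,
                 table = table(joint = details$joint_category, evidence = ev)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Marker concordance (joint mapping category x evidence class)\n")
  print(x$table)
  invisible(x)
}

#' Summarize markers mapped to one genome within evidence classes
#'
#' Counts, within the given evidence classes, the markers mapped to genome
#' A (joint category `A_only` or `both`) or genome B (`B_only` or `both`),
#' with the percentage rounded half-up to a whole number.
#'
#' @param ct a `concordance_table`
#' @param evidence_classes evidence classes defining the denominator
#' @param genome "A" or "B"
#' @return list with n_markers, n_mapped, pct
#' @export
concordance_summary <- function(ct, evidence_classes, genome = c("A", "B")) {
  genome <- match.arg(genome)
  d <- ct$details[ct$details$evidence_class %in% evidence_classes, , drop = FALSE]
  mapped_cats <- if (genome == "A") c("A_only", "both") else c("B_only", "both")
  n_mapped <- sum(d$joint_category %in% mapped_cats)
  list(n_markers = nrow(d), n_mapped = n_mapped,
       pct = round_half_up(100 * n_mapped / max(nrow(d), 1L)))
}
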