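# Physical-map guided superscaffolding.
#
# A sequence-tag physical map (WGP-style) provides map contigs, each an
# ordered list of short tags. Tags are located on the assembly; scaffolds
# carrying >= 2 concordantly ordered tags of a single map contig are
# anchored and oriented; anchored, oriented scaffolds are chained in map
# order with estimated N gaps. Scaffolds of unknown orientation and
# scaffolds whose tags span several map contigs are discarded, mirroring
# the conservative published procedure.

#' Construct a physical map
#'
#' @param tags data.frame with columns tag_id, map_contig_id, rank (ranks
#'   consecutive integers from 0 within each contig; tag_ids globally unique)
#' @param template_pos optional data.frame (tag_id, template_pos) giving
#'   each tag's coordinate on a template genome in bp, used for gap
#'   estimation
#' @return a `physical_map`
#' @export
physical_map <- function(tags, template_pos = NULL) {
  stopifnot(all(c("tag_id", "map_contig_id", "rank") %in% names(tags)))
  if (anyDuplicated(tags$tag_id)) {
    stop(sprintf("tag id '%s' appears in the map more than once",
                 tags$tag_id[duplicated(tags$tag_id)][1]), call. = FALSE)
  }
  for (cid in unique(tags$map_contig_id)) {
    r <- sort(tags$rank[tags$map_contig_id == cid])
    if (!identical(as.integer(r), seq(0L, length(r) - 1L))) {
      stop(sprintf("map contig '%s': ranks must be consecutive integers from 0", cid),
           call. = FALSE)
    }
  }
  tags <- tags[order(tags$map_contig_id, tags$rank), , drop = FALSE]
  rownames(tags) <- NULL
  if (!is.null(template_pos)) {
    stopifnot(all(c("tag_id", "template_pos") %in% names(template_pos)))
    tags$template_pos <- template_pos$template_pos[match(tags$tag_id, template_pos$tag_id)]
  }
  structure(list(tags = tags), class = "physical_map")
}

#' @export
print.physical_map <- function(x, ...) {
  cat(sprintf("<physical_map: %d tag(s) on %d map contig(s)%s>\n",
              nrow(x$tags), length(unique(x$tags$map_contig_id)),
              if ("template_pos" %in% names(x$tags)) ", with template positions" else ""))
  invisible(x)
}

#' Place map tags on an assembly
#'
#' Reports every occurrence (forward or reverse-complement) of each tag
#' with at most `max_mismatches` substitutions; offsets are 0-based on the
#' forward scaffold coordinate system. Tags occurring more than once in the
#' whole assembly are flagged non-unique and excluded from anchoring.
#'
#' @param tags named character vector of tag sequences, or an
#'   `assembly`/`read_set` of tags
#' @param asm an `assembly`
#' @param max_mismatches maximum substitutions per placement (default 0:
#'   tags derive from the same species)
#' @return a `tag_placements` data.frame (tag_id, scaffold_id, offset,
#'   strand, mismatches, tag_length) of all placements, with attributes
#'   `non_unique` and `unplaced` (tag id vectors)
#' @export
place_tags <- function(tags, asm, max_mismatches = 0L) {
  if (inherits(tags, c("assembly", "read_set"))) {
    tag_seq <- tags$seq; names(tag_seq) <- tags$id
  } else {
    tag_seq <- stats::setNames(toupper(as.character(tags)), names(tags))
    if (is.null(names(tag_seq))) stop("tags must be named")
  }
  subject <- as_dss(asm)
  out <- vector("list", 2L * length(tag_seq))
  k <- 0L
  for (i in seq_along(tag_seq)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag_seq[[i]] else revcomp(tag_seq[[i]])
      m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max_mismatches,
                                     with.indels = FALSE, fixed = TRUE)
      hits <- as.data.frame(m)   # group, start, end per hit
      if (nrow(hits) == 0L) next
      mm <- vapply(seq_len(nrow(hits)), function(j) {
        s <- substr(asm$seq[hits$group[j]], hits$start[j], hits$end[j])
        sum(utf8ToInt(s) != utf8ToInt(pat))
      }, 0L)
      k <- k + 1L
      out[[k]] <- data.frame(tag_id = names(tag_seq)[i],
                             scaffold_id = asm$id[hits$group],
                             offset = hits$start - 1L,
                             strand = strand,
                             mismatches = mm,
                             tag_length = nchar(tag_seq[[i]]),
                             stringsAsFactors = FALSE)
    }
  }
  pl <- if (k > 0L) do.call(rbind, out[seq_len(k)]) else
    data.frame(tag_id = character(0), scaffold_id = character(0), offset = integer(0),
               strand = character(0), mismatches = integer(0), tag_length = integer(0),
               stringsAsFactors = FALSE)
  counts <- table(pl$tag_id)
  non_unique <- names(counts)[counts > 1L]
  unplaced <- setdiff(names(tag_seq), pl$tag_id)
  structure(pl, class = c("tag_placements", "data.frame"),
            non_unique = non_unique, unplaced = unplaced)
}

# Placements from uniquely placed tags only.
unique_placements <- function(placements) {
  placements[!(placements$tag_id %in% attr(placements, "non_unique")), , drop = FALSE]
}

#' Anchor scaffolds to map contigs
#'
#' Per scaffold, uniquely placed tags are grouped by map contig. Tags on
#' more than one map contig give status `multi_contig`. Otherwise the
#' orientation is inferred from the joint order of (scaffold offset, map
#' rank): all pairs concordant ascending gives `+`, all descending `-`;
#' any discordance, tied offsets, or fewer than 2 tags gives
#' `unknown_orientation`. The anchor rank is the mean map rank of the
#' scaffold's tags.
#'
#' @param placements result of [place_tags()] (non-unique tags are dropped
#'   automatically)
#' @param map a [physical_map()]
#' @return a `scaffold_anchors` data.frame (scaffold_id, map_contig_id,
#'   orientation, anchor_rank, n_tags, status), with per-tag detail in
#'   attribute `tag_detail`
#' @export
anchor_scaffolds <- function(placements, map) {
  pl <- unique_placements(placements)
  mt <- map$tags
  unknown <- setdiff(pl$tag_id, mt$tag_id)
  if (length(unknown) > 0L) {
    stop(sprintf("placement references tag '%s' absent from the physical map",
                 unknown[1]), call. = FALSE)
  }
  idx <- match(pl$tag_id, mt$tag_id)
  pl$map_contig_id <- mt$map_contig_id[idx]
  pl$rank <- mt$rank[idx]
  if ("template_pos" %in% names(mt)) pl$template_pos <- mt$template_pos[idx]
  rows <- lapply(split(pl, pl$scaffold_id), function(g) {
    contigs <- unique(g$map_contig_id)
    if (length(contigs) > 1L) {
      return(data.frame(scaffold_id = g$scaffold_id[1], map_contig_id = NA_character_,
                        orientation = "unknown", anchor_rank = NA_real_,
                        n_tags = nrow(g), status = "multi_contig",
                        stringsAsFactors = FALSE))
    }
    orientation <- "unknown"
    status <- "unknown_orientation"
    if (nrow(g) >= 2L && !anyDuplicated(g$offset) && !anyDuplicated(g$rank)) {
      r <- g$rank[order(g$offset)]
      if (all(diff(r) > 0)) { orientation <- "+"; status <- "ok" }
      else if (all(diff(r) < 0)) { orientation <- "-"; status <- "ok" }
    }
    data.frame(scaffold_id = g$scaffold_id[1], map_contig_id = contigs,
               orientation = orientation, anchor_rank = mean(g$rank),
               n_tags = nrow(g), status = status, stringsAsFactors = FALSE)
  })
  anchors <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(anchors)) {
    anchors <- data.frame(scaffold_id = character(0), map_contig_id = character(0),
                          orientation = character(0), anchor_rank = numeric(0),
                          n_tags = integer(0), status = character(0),
                          stringsAsFactors = FALSE)
  }
  structure(anchors, class = c("scaffold_anchors", "data.frame"), tag_detail = pl)
}

#' Gap policies for superscaffold construction
#'
#' `gap_policy_fixed` inserts a constant gap. `gap_policy_template`
#' estimates each gap from the tags' template-genome coordinates: the
#' template distance between consecutive components' tag spans minus the
#' component bases outside those spans, clamped to `[min_gap, max_gap]`.
#'
#' @param gap fixed gap length in bp
#' @return a `gap_policy`
#' @export
gap_policy_fixed <- function(gap = 100L) {
  structure(list(type = "fixed", gap = as.integer(gap)), class = "gap_policy")
}

#' @rdname gap_policy_fixed
#' @param min_gap,max_gap clamp bounds in bp
#' @export
gap_policy_template <- function(min_gap = 10L, max_gap = 50000L) {
  structure(list(type = "template", min_gap = as.integer(min_gap),
                 max_gap = as.integer(max_gap)), class = "gap_policy")
}

# Template-coordinate extent of one anchored component: the tag span
# extended by the scaffold bases that extend past the outermost tags.
component_template_extent <- function(detail, orientation, scaffold_len) {
  i_lo <- which.min(detail$template_pos)
  i_hi <- which.max(detail$template_pos)
  t_lo <- detail$template_pos[i_lo]
  t_hi <- detail$template_pos[i_hi] + detail$tag_length[i_hi]
  if (orientation == "+") {
    head <- detail$offset[i_lo]
    tail <- scaffold_len - (detail$offset[i_hi] + detail$tag_length[i_hi])
  } else {
    head <- scaffold_len - (detail$offset[i_lo] + detail$tag_length[i_lo])
    tail <- detail$offset[i_hi]
  }
  c(start = t_lo - head, end = t_hi + tail)
}

#' Build superscaffolds from anchored scaffolds
#'
#' Each map contig with at least two `ok` anchors yields one superscaffold:
#' components sorted by anchor rank (ties broken by scaffold id and
#' flagged), joined with gaps from the gap policy. Map contigs with fewer
#' than two `ok` anchors yield nothing.
#'
#' @param anchors result of [anchor_scaffolds()]
#' @param map the [physical_map()]
#' @param asm the `assembly` the anchors refer to
#' @param gap_policy a [gap_policy_fixed()] or [gap_policy_template()]
#' @return list with `superscaffolds` (list of `superscaffold`: id,
#'   map_contig_id, components, total_span_bp) and `report` (placement and
#'   discard counters)
#' @export
build_superscaffolds <- function(anchors, map, asm, gap_policy = gap_policy_fixed()) {
  stopifnot(inherits(anchors, "scaffold_anchors"), inherits(map, "physical_map"),
            inherits(asm, "assembly"), inherits(gap_policy, "gap_policy"))
  ok <- anchors[anchors$status == "ok", , drop = FALSE]
  if (anyDuplicated(ok$scaffold_id)) {
    stop("internal error: scaffold anchored ok to more than one map contig",
         call. = FALSE)
  }
  detail <- attr(anchors, "tag_detail")
  lens <- stats::setNames(nchar(asm$seq), asm$id)
  ties_broken <- character(0)
  superscaffolds <- list()
  for (cid in unique(map$tags$map_contig_id)) {
    grp <- ok[ok$map_contig_id == cid, , drop = FALSE]
    if (nrow(grp) < 2L) next
    if (anyDuplicated(grp$anchor_rank)) {
      ties_broken <- c(ties_broken,
                       grp$scaffold_id[grp$anchor_rank %in%
                                         grp$anchor_rank[duplicated(grp$anchor_rank)]])
    }
    grp <- grp[order(grp$anchor_rank, grp$scaffold_id), , drop = FALSE]
    n <- nrow(grp)
    gaps <- rep(NA_integer_, n)
    if (gap_policy$type == "fixed") {
      if (n > 1L) gaps[seq_len(n - 1L)] <- gap_policy$gap
    } else {
      if (!("template_pos" %in% names(detail))) {
        stop("template gap policy requires a map with template positions", call. = FALSE)
      }
      ext <- t(vapply(seq_len(n), function(i) {
        d <- detail[detail$scaffold_id == grp$scaffold_id[i], , drop = FALSE]
        component_template_extent(d, grp$orientation[i], lens[[grp$scaffold_id[i]]])
      }, c(start = 0, end = 0)))
      for (i in seq_len(n - 1L)) {
        raw <- ext[i + 1L, "start"] - ext[i, "end"]
        gaps[i] <- as.integer(min(max(raw, gap_policy$min_gap), gap_policy$max_gap))
      }
    }
    comp <- data.frame(scaffold_id = grp$scaffold_id, orientation = grp$orientation,
                       length = unname(lens[grp$scaffold_id]), gap_after = gaps,
                       stringsAsFactors = FALSE)
    ss <- structure(list(id = paste0("ss_", cid), map_contig_id = cid,
                         components = comp,
                         total_span_bp = sum(comp$length) + sum(gaps, na.rm = TRUE)),
                    class = "superscaffold")
    superscaffolds[[ss$id]] <- ss
  }
  consumed <- unlist(lapply(superscaffolds, function(s) s$components$scaffold_id))
  n_unknown <- sum(anchors$status == "unknown_orientation")
  n_multi <- sum(anchors$status == "multi_contig")
  report <- list(
    n_superscaffolds = length(superscaffolds),
    sequences_in_superscaffolds = length(consumed),
    discarded_unknown_orientation = n_unknown,
    discarded_multi_contig = n_multi,
    anchored_ok_but_alone = nrow(ok) - length(consumed),
    unplaced = length(asm$id) - length(consumed) - n_unknown - n_multi -
      (nrow(ok) - length(consumed)),
    ties_broken = unique(ties_broken)
  )
  list(superscaffolds = superscaffolds, report = report)
}

#' @export
print.superscaffold <- function(x, ...) {
  cat(sprintf("<superscaffold '%s' on map contig '%s': %d components, %s bp span>\n",
              x$id, x$map_contig_id, nrow(x$components),
              format(x$total_span_bp, big.mark = ",")))
  invisible(x)
}

#' Render superscaffolds as gapped sequences
#'
#' Components are oriented (reverse-complemented where anchored `-`) and
#' joined with runs of N of the estimated gap lengths; sequences not
#' consumed by any superscaffold pass through untouched.
#'
#' @param superscaffolds list of `superscaffold`
#' @param asm the source `assembly`
#' @param keep_unplaced include non-superscaffolded sequences in the output
#' @return an `assembly` of superscaffold (and optionally pass-through)
#'   sequences
#' @export
superscaffold_fasta <- function(superscaffolds, asm, keep_unplaced = TRUE) {
  seqs <- character(0)
  ids <- character(0)
  for (ss in superscaffolds) {
    comp <- ss$components
    pieces <- character(0)
    for (i in seq_len(nrow(comp))) {
      s <- asm$seq[match(comp$scaffold_id[i], asm$id)]
      if (comp$orientation[i] == "-") s <- revcomp(s)
      pieces <- c(pieces, s)
      if (!is.na(comp$gap_after[i])) {
        pieces <- c(pieces, strrep("N", comp$gap_after[i]))
      }
    }
    ids <- c(ids, ss$id)
    seqs <- c(seqs, paste0(pieces, collapse = ""))
  }
  if (keep_unplaced) {
    consumed <- unlist(lapply(superscaffolds, function(s) s$components$scaffold_id))
    rest <- !(asm$id %in% consumed)
    ids <- c(ids, asm$id[rest])
    seqs <- c(seqs, asm$seq[rest])
  }
  new_assembly(ids, seqs, paste0(asm$name, "_superscaffolded"))
}

#' N50 before and after superscaffolding
#'
#' The after-set consists of the superscaffold spans plus the lengths of
#' all sequences not consumed by any superscaffold.
#'
#' @param asm the `assembly`
#' @param superscaffolds list of `superscaffold`
#' @return named numeric vector `c(n50_before, n50_after)`
#' @export
superscaffold_n50_gain <- function(asm, superscaffolds) {
  before <- n50(nchar(asm$seq))
  consumed <- unlist(lapply(superscaffolds, function(s) s$components$scaffold_id))
  spans <- vapply(superscaffolds, function(s) s$total_span_bp, 0)
  after <- n50(c(spans, nchar(asm$seq)[!(asm$id %in% consumed)]))
  c(n50_before = before, n50_after = after)
}
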