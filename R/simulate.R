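# Deterministic synthetic-fixture generator.
#
# Produces random genomes, shotgun read sets, fragmented assemblies,
# sequence-tag physical maps, planted marker panels and planted
# region/transcript expression tables, each with recorded ground truth, so
# every pipeline stage can be scored against planted truth without any
# external data. Each operation draws from its own RNG stream derived from
# (seed, operation name), so adding an operation never perturbs existing
# fixtures. Genomes are i.i.d. (no repeat families): k-mer depth histograms
# stay unimodal, which is the regime the ratio size-estimator assumes.

#' Simulation configuration
#'
#' Defaults emulate, at desk scale, a short-read draft-genome study:
#' 100 bp reads at 40x coverage with 0.5% substitution error from a 100 kb
#' genome at GC 0.4, fragmented into 40 scaffolds carrying 3 tags of 50 bp
#' each on a 4-contig physical map, and a 50-marker primer panel.
#'
#' @param genome_bp genome length in bp
#' @param gc_fraction genome GC content (0..1)
#' @param n_scaffolds number of assembly fragments
#' @param read_length read length in bp
#' @param coverage_x sequencing depth (genome equivalents)
#' @param error_rate per-base substitution error rate (0 <= e < 0.1)
#' @param tag_length physical-map tag length in bp
#' @param tags_per_scaffold tags planted per scaffold
#' @param n_map_contigs number of physical-map contigs
#' @param n_markers number of planted marker primer pairs
#' @param seed RNG seed (mandatory)
#' @return a `sim_config`
#' @export
sim_config <- function(genome_bp = 100000L, gc_fraction = 0.4, n_scaffolds = 40L,
                       read_length = 100L, coverage_x = 40, error_rate = 0.005,
                       tag_length = 50L, tags_per_scaffold = 3L, n_map_contigs = 4L,
                       n_markers = 50L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(genome_bp > 0, gc_fraction >= 0, gc_fraction <= 1, n_scaffolds >= 2,
            read_length > 0, coverage_x > 0, error_rate >= 0, error_rate < 0.1,
            tag_length > 0, tags_per_scaffold >= 1, n_map_contigs >= 1, n_markers >= 0)
  structure(list(genome_bp = as.integer(genome_bp), gc_fraction = gc_fraction,
                 n_scaffolds = as.integer(n_scaffolds),
                 read_length = as.integer(read_length), coverage_x = coverage_x,
                 error_rate = error_rate, tag_length = as.integer(tag_length),
                 tags_per_scaffold = as.integer(tags_per_scaffold),
                 n_map_contigs = as.integer(n_map_contigs),
                 n_markers = as.integer(n_markers), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genome
#'
#' I.i.d. bases at the configured GC fraction; deterministic given the seed.
#'
#' @param config a [sim_config()]
#' @return character scalar genome sequence
#' @export
simulate_genome <- function(config) {
  with_stream_seed(config$seed, "genome", {
    gc <- config$gc_fraction
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste0(sample(names(p), config$genome_bp, replace = TRUE, prob = p),
           collapse = "")
  })
}

mutate_bases <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste0(ch, collapse = "")
}

#' Simulate shotgun reads with errors and planted QC failures
#'
#' Reads are uniformly positioned on both strands to total
#' `coverage_x * genome_bp` bases; substitution errors are i.i.d. at
#' `error_rate`. Qualities are drawn internally consistent (Q34-40 for
#' correct bases, Q30-35 for erroneous ones, so unplanted reads pass the
#' DNA policy); planted QC failures override the draws deterministically:
#' "short" reads get a low-quality 3' tail that trims them below 50 bases,
#' "fraction" reads keep full length but have 15% of interior bases set to
#' Q20.
#'
#' @param genome genome sequence (character scalar)
#' @param config a [sim_config()]
#' @param plant_short,plant_fraction number of reads planted to fail QC
#' @return list with `reads` (a `read_set`) and `truth` (positions,
#'   strands, error counts, planted failure ids)
#' @export
simulate_reads <- function(genome, config, plant_short = 0L, plant_fraction = 0L) {
  G <- nchar(genome)
  L <- config$read_length
  stopifnot(L <= G)
  n_reads <- ceiling(config$coverage_x * G / L)
  stopifnot(plant_short + plant_fraction <= n_reads)
  with_stream_seed(config$seed, "reads", {
    starts <- sample.int(G - L + 1L, n_reads, replace = TRUE)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(genome, starts, starts + L - 1L)
    minus <- strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    n_err <- stats::rbinom(n_reads, L, config$error_rate)
    err_pos <- vector("list", n_reads)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(L, n_err[i])
      err_pos[[i]] <- pos
      seqs[i] <- mutate_bases(seqs[i], pos)
    }
    qual <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      q <- sample(34:40, L, replace = TRUE)
      if (n_err[i] > 0L) q[err_pos[[i]]] <- sample(30:35, n_err[i], replace = TRUE)
      qual[[i]] <- q
    }
    planted <- sample.int(n_reads, plant_short + plant_fraction)
    short_ids <- planted[seq_len(plant_short)]
    frac_ids <- setdiff(planted, short_ids)
    for (i in short_ids) {
      keep_len <- sample(0:49, 1L)   # post-trim length, below the 50-base rule
      if (keep_len < L) qual[[i]][(keep_len + 1L):L] <- sample(2:29, L - keep_len,
                                                               replace = TRUE)
    }
    for (i in frac_ids) {
      # 15% of bases below Q30 (fraction 0.85 < 0.90), but never the final
      # base, so no 3' trimming is triggered and the read stays full length
      n_low <- ceiling(0.15 * L)
      pos <- sample.int(L - 1L, n_low)
      qual[[i]][pos] <- 20L
      qual[[i]][L] <- max(qual[[i]][L], 34L)
    }
    ids <- sprintf("r%06d", seq_len(n_reads))
    list(reads = read_set(ids, seqs, encode_quals(qual)),
         truth = list(start = starts, strand = strand, n_errors = n_err,
                      planted_short = ids[short_ids],
                      planted_fraction = ids[frac_ids]))
  })
}

#' Fragment a genome into a shuffled, randomly oriented assembly
#'
#' The genome is cut at random positions into `n_scaffolds` pieces; each
#' piece is independently reverse-complemented with probability 0.5 and
#' the pieces are shuffled and relabelled. The truth records the original
#' order and orientation.
#'
#' @param genome genome sequence
#' @param config a [sim_config()]
#' @param min_piece_bp minimum fragment length (cut sets violating it are
#'   redrawn; guarantees room for the configured tags)
#' @return list with `assembly` and `truth` (data.frame: scaffold_id,
#'   genome_start, genome_end (0-based half-open), order, orientation)
#' @export
fragment_assembly <- function(genome, config,
                              min_piece_bp = 2L * config$tags_per_scaffold *
                                config$tag_length) {
  G <- nchar(genome)
  n <- config$n_scaffolds
  stopifnot(n >= 2L, n * min_piece_bp <= G)
  with_stream_seed(config$seed, "fragment", {
    for (try in seq_len(1000L)) {
      cuts <- sort(sample.int(G - 1L, n - 1L))
      bounds <- c(0L, cuts, G)
      if (min(diff(bounds)) >= min_piece_bp) break
      if (try == 1000L) stop("could not draw fragment cuts respecting min_piece_bp")
    }
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    pieces <- substring(genome, starts + 1L, ends)
    orient <- sample(c("+", "-"), n, replace = TRUE)
    pieces[orient == "-"] <- revcomp(pieces[orient == "-"])
    perm <- sample.int(n)
    ids <- sprintf("scf_%03d", seq_len(n))
    truth <- data.frame(scaffold_id = ids[order(perm)],
                        genome_start = starts, genome_end = ends,
                        order = seq_len(n), orientation = orient,
                        stringsAsFactors = FALSE)
    asm <- new_assembly(ids, pieces[perm], "sim")
    list(assembly = asm, truth = truth[order(match(truth$scaffold_id, ids)), ])
  })
}

#' Generate a sequence-tag physical map over a fragmented genome
#'
#' Tags are exact genome substrings sampled at spaced positions
#' (`tags_per_scaffold` per scaffold, one per equal-width bin), ranked by
#' genome order, and grouped into `n_map_contigs` contiguous map contigs.
#' Template positions are the tags' genome coordinates.
#'
#' @param genome genome sequence
#' @param truth fragmentation truth from [fragment_assembly()]
#' @param config a [sim_config()]
#' @param tags_per_scaffold override of `config$tags_per_scaffold`
#' @return list with `map` (a [physical_map()] with template positions),
#'   `tag_seqs` (named character vector) and `truth` (tag_id, genome_pos,
#'   scaffold_id)
#' @export
generate_wgp_map <- function(genome, truth, config,
                             tags_per_scaffold = config$tags_per_scaffold) {
  tl <- config$tag_length
  with_stream_seed(config$seed, "wgpmap", {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      lo <- truth$genome_start[i]
      hi <- truth$genome_end[i]
      n <- tags_per_scaffold
      bin <- (hi - lo) / n
      if (bin < tl) stop(sprintf("scaffold '%s' too short for %d tag(s) of %d bp",
                                 truth$scaffold_id[i], n, tl), call. = FALSE)
      for (b in seq_len(n)) {
        b_lo <- lo + floor((b - 1) * bin)
        b_hi <- lo + floor(b * bin)
        pos <- b_lo + sample.int(b_hi - b_lo - tl + 1L, 1L) - 1L  # 0-based start
        rows[[length(rows) + 1L]] <- data.frame(
          genome_pos = pos, scaffold_id = truth$scaffold_id[i],
          stringsAsFactors = FALSE)
      }
    }
    tg <- do.call(rbind, rows)
    tg <- tg[order(tg$genome_pos), , drop = FALSE]
    tg$tag_id <- sprintf("tag_%04d", seq_len(nrow(tg)))
    tg$seq <- substring(genome, tg$genome_pos + 1L, tg$genome_pos + tl)
    block <- nchar(genome) / config$n_map_contigs
    contig_idx <- pmin(floor(tg$genome_pos / block) + 1L, config$n_map_contigs)
    tg$map_contig_id <- sprintf("wgp_%02d", contig_idx)
    rank <- unlist(lapply(split(seq_len(nrow(tg)), tg$map_contig_id),
                          function(ix) seq_along(ix) - 1L))
    tg$rank <- NA_integer_
    tg$rank[unlist(split(seq_len(nrow(tg)), tg$map_contig_id))] <- rank
    map <- physical_map(tg[, c("tag_id", "map_contig_id", "rank")],
                        template_pos = data.frame(tag_id = tg$tag_id,
                                                  template_pos = tg$genome_pos))
    tag_seqs <- stats::setNames(tg$seq, tg$tag_id)
    list(map = map, tag_seqs = tag_seqs,
         truth = tg[, c("tag_id", "genome_pos", "scaffold_id")])
  })
}

random_dna_local <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                       collapse = "")

#' Plant marker primer pairs into a genome
#'
#' Each marker is a convergent 20-mer primer pair flanking a 100-1,000 bp
#' insert, overwritten into its own spaced slot of the genome. A
#' configurable subset is planted twice (expected status `multiple`),
#' planted with 2 substitutions in each primer copy (`none` at the 95%
#' identity threshold), or with 1 substitution in one primer (still
#' `unique`). The remaining markers are planted exactly once, exactly.
#'
#' @param genome genome sequence (will be edited)
#' @param config a [sim_config()]
#' @param n_multiple,n_none,n_one_mismatch planted deviations (counted
#'   within `config$n_markers`)
#' @return list with `genome` (edited sequence), `primer_pairs`
#'   (marker_id, forward_seq, reverse_seq) and `truth` (marker_id,
#'   expected_status, product_bp)
#' @export
plant_markers <- function(genome, config, n_multiple = 5L, n_none = 5L,
                          n_one_mismatch = 5L) {
  n <- config$n_markers
  if (n == 0L) {
    return(list(genome = genome,
                primer_pairs = data.frame(marker_id = character(0),
                                          forward_seq = character(0),
                                          reverse_seq = character(0),
                                          stringsAsFactors = FALSE),
                truth = data.frame(marker_id = character(0),
                                   expected_status = character(0),
                                   product_bp = integer(0), stringsAsFactors = FALSE)))
  }
  stopifnot(n_multiple + n_none + n_one_mismatch <= n)
  n_slots <- n + n_multiple
  G <- nchar(genome)
  slot_w <- floor(G / n_slots)
  stopifnot(slot_w >= 1100L)   # room for the largest product plus margin
  with_stream_seed(config$seed, "markers", {
    status <- c(rep("multiple", n_multiple), rep("none", n_none),
                rep("unique", n_one_mismatch), rep("unique", n - n_multiple -
                                                     n_none - n_one_mismatch))
    flavor <- c(rep("dup", n_multiple), rep("mut2", n_none),
                rep("mut1", n_one_mismatch), rep("exact", n - n_multiple -
                                                   n_none - n_one_mismatch))
    ids <- sprintf("mk_%03d", seq_len(n))
    fwd <- vapply(seq_len(n), function(i) random_dna_local(20L), "")
    rev <- vapply(seq_len(n), function(i) random_dna_local(20L), "")
    product <- sample(140:1040, n, replace = TRUE)
    insert <- vapply(product - 40L, random_dna_local, "")
    slot <- 0L
    for (i in seq_len(n)) {
      f_g <- fwd[i]
      r_g <- rev[i]
      if (flavor[i] == "mut2") {
        f_g <- mutate_bases(f_g, sample.int(20L, 2L))
        r_g <- mutate_bases(r_g, sample.int(20L, 2L))
      } else if (flavor[i] == "mut1") {
        f_g <- mutate_bases(f_g, sample.int(20L, 1L))
      }
      amp <- paste0(f_g, insert[i], revcomp(r_g))
      copies <- if (flavor[i] == "dup") 2L else 1L
      for (cp in seq_len(copies)) {
        slot <- slot + 1L
        at <- (slot - 1L) * slot_w + 30L   # 0-based slot offset with margin
        substr(genome, at + 1L, at + nchar(amp)) <- amp
      }
    }
    list(genome = genome,
         primer_pairs = data.frame(marker_id = ids, forward_seq = fwd,
                                   reverse_seq = rev, stringsAsFactors = FALSE),
         truth = data.frame(marker_id = ids, expected_status = status,
                            product_bp = product, stringsAsFactors = FALSE))
  })
}

#' Plant expression regions, transcripts and probes
#'
#' Carves `n_regions` spaced regions on a single reference sequence,
#' plants transcripts with exponential-tailed FPKM values either inside a
#' region, spanning a region boundary, or in the background, and samples
#' one perfect unique probe per region from the genome. Truth records each
#' region's FPKM sum by construction.
#'
#' @param genome genome sequence (used as sequence "chr1")
#' @param config a [sim_config()]
#' @param n_regions number of regions
#' @param tx_per_region transcripts planted fully inside each region
#' @param n_background transcripts planted outside every region
#' @return list with `regions`, `transcripts`, `probes` (named character),
#'   and `truth` (region_id, fpkm_sum, n_transcripts)
#' @export
simulate_expression <- function(genome, config, n_regions = 20L, tx_per_region = 3L,
                                n_background = 30L) {
  G <- nchar(genome)
  slot_w <- floor(G / n_regions)
  region_w <- floor(slot_w / 2L)
  stopifnot(region_w >= 400L)
  with_stream_seed(config$seed, "expression", {
    regions <- data.frame(region_id = sprintf("rg_%03d", seq_len(n_regions)),
                          seq_id = "chr1",
                          start = (seq_len(n_regions) - 1L) * slot_w,
                          end = (seq_len(n_regions) - 1L) * slot_w + region_w,
                          stringsAsFactors = FALSE)
    tx <- list()
    truth_sum <- numeric(n_regions)
    truth_n <- integer(n_regions)
    for (i in seq_len(n_regions)) {
      for (j in seq_len(tx_per_region)) {
        w <- sample(100:300, 1L)
        s <- regions$start[i] + sample.int(region_w - w, 1L) - 1L
        f <- round(stats::rexp(1L, 1 / 10), 3)
        tx[[length(tx) + 1L]] <- data.frame(
          transcript_id = sprintf("tx_%03d_%d", i, j), seq_id = "chr1",
          start = s, end = s + w, fpkm = f, stringsAsFactors = FALSE)
        truth_sum[i] <- truth_sum[i] + f
        truth_n[i] <- truth_n[i] + 1L
      }
    }
    # background transcripts sit in the second half of each slot, clear of
    # every region
    for (b in seq_len(n_background)) {
      i <- sample.int(n_regions, 1L)
      w <- sample(100:300, 1L)
      gap_lo <- regions$end[i] + 10L
      gap_hi <- (regions$start[i] + slot_w) - w - 10L
      if (gap_hi <= gap_lo) next
      s <- gap_lo + sample.int(gap_hi - gap_lo, 1L) - 1L
      tx[[length(tx) + 1L]] <- data.frame(
        transcript_id = sprintf("bg_%03d", b), seq_id = "chr1",
        start = s, end = s + w, fpkm = round(stats::rexp(1L, 1 / 10), 3),
        stringsAsFactors = FALSE)
    }
    transcripts <- do.call(rbind, c(tx, list(make.row.names = FALSE)))
    probes <- stats::setNames(
      substring(genome, regions$start + 1L + 50L, regions$start + 50L + 35L),
      sprintf("pb_%03d", seq_len(n_regions)))
    list(regions = regions, transcripts = transcripts, probes = probes,
         truth = data.frame(region_id = regions$region_id, fpkm_sum = truth_sum,
                            n_transcripts = truth_n, stringsAsFactors = FALSE))
  })
}
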