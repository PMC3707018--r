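test_that("place_tags reports planted occurrences with the strand convention", {
  set.seed(41)
  s1 <- random_dna(500)
  tag <- substr(s1, 38, 87)        # planted at 0-based offset 37
  asm <- assembly(c(S1 = s1, S2 = random_dna(300)))
  pl <- place_tags(c(t1 = tag), asm)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$scaffold_id, "S1")
  expect_equal(pl$offset, 37L)
  expect_equal(pl$strand, "+")
  expect_equal(pl$mismatches, 0L)

  pl_rc <- place_tags(c(t1 = revcomp(tag)), asm)
  expect_equal(pl_rc$offset, 37L)
  expect_equal(pl_rc$strand, "-")
})

test_that("tags placed more than once are flagged non-unique and excluded", {
  set.seed(42)
  core <- random_dna(2000)
  dup <- substr(core, 101, 150)
  s2 <- paste0(random_dna(400), dup, random_dna(100))   # second copy
  asm <- assembly(c(A = core, B = s2))
  uniq_tag <- substr(core, 501, 550)
  pl <- place_tags(c(d = dup, u = uniq_tag), asm)
  expect_setequal(attr(pl, "non_unique"), "d")
  expect_equal(unique(draftanchor:::unique_placements(pl)$tag_id), "u")
})

test_that("anchor_scaffolds infers orientation from offset/rank concordance", {
  map <- physical_map(data.frame(tag_id = paste0("t", 0:5), map_contig_id = "C1",
                                 rank = 0:5))
  mk_pl <- function(df) {
    df$mismatches <- 0L
    df$tag_length <- 50L
    structure(df, class = c("tag_placements", "data.frame"),
              non_unique = character(0), unplaced = character(0))
  }
  pl <- mk_pl(data.frame(tag_id = c("t4", "t5"), scaffold_id = "S1",
                         offset = c(10L, 500L), strand = "+",
                         stringsAsFactors = FALSE))
  an <- anchor_scaffolds(pl, map)
  expect_equal(an$orientation, "+")
  expect_equal(an$anchor_rank, 4.5)
  expect_equal(an$status, "ok")

  # descending ranks along the scaffold -> "-"
  pl <- mk_pl(data.frame(tag_id = c("t5", "t4"), scaffold_id = "S1",
                         offset = c(10L, 500L), strand = "+",
                         stringsAsFactors = FALSE))
  expect_equal(anchor_scaffolds(pl, map)$orientation, "-")

  # single tag -> unknown orientation
  pl <- mk_pl(data.frame(tag_id = "t1", scaffold_id = "S1", offset = 10L,
                         strand = "+", stringsAsFactors = FALSE))
  expect_equal(anchor_scaffolds(pl, map)$status, "unknown_orientation")

  # discordant ranks -> unknown orientation
  pl <- mk_pl(data.frame(tag_id = c("t1", "t3", "t2"), scaffold_id = "S1",
                         offset = c(10L, 200L, 400L), strand = "+",
                         stringsAsFactors = FALSE))
  expect_equal(anchor_scaffolds(pl, map)$status, "unknown_orientation")

  # tags on two map contigs -> multi_contig
  map2 <- physical_map(data.frame(tag_id = paste0("t", 0:3),
                                  map_contig_id = c("C1", "C1", "C2", "C2"),
                                  rank = c(0, 1, 0, 1)))
  pl <- mk_pl(data.frame(tag_id = c("t1", "t2"), scaffold_id = "S1",
                         offset = c(10L, 400L), strand = "+",
                         stringsAsFactors = FALSE))
  expect_equal(anchor_scaffolds(pl, map2)$status, "multi_contig")

  # unknown tag id -> error
  pl <- mk_pl(data.frame(tag_id = "nope", scaffold_id = "S1", offset = 0L,
                         strand = "+", stringsAsFactors = FALSE))
  expect_error(anchor_scaffolds(pl, map), "nope")
})

sim_ss_fixture <- function(seed, genome_bp = 200000L, n_scaffolds = 10L,
                           tags_per_scaffold = 3L) {
  cfg <- sim_config(genome_bp = genome_bp, n_scaffolds = n_scaffolds,
                    tags_per_scaffold = tags_per_scaffold, n_map_contigs = 4L,
                    seed = seed)
  g <- simulate_genome(cfg)
  fr <- fragment_assembly(g, cfg)
  wgp <- generate_wgp_map(g, fr$truth, cfg)
  list(cfg = cfg, genome = g, fr = fr, wgp = wgp)
}

test_that("two or more unambiguous anchors are required for a superscaffold", {
  fx <- sim_ss_fixture(7)
  pl <- place_tags(fx$wgp$tag_seqs, fx$fr$assembly)
  an <- anchor_scaffolds(pl, fx$wgp$map)
  ok <- an[an$status == "ok", ]
  # keep only one ok anchor on the first map contig: no superscaffold there
  first_contig <- ok$map_contig_id[1]
  drop <- ok$scaffold_id[ok$map_contig_id == first_contig][-1]
  an2 <- an[!(an$scaffold_id %in% drop), , drop = FALSE]
  attr(an2, "tag_detail") <- attr(an, "tag_detail")
  class(an2) <- class(an)
  built <- build_superscaffolds(an2, fx$wgp$map, fx$fr$assembly)
  expect_false(first_contig %in% vapply(built$superscaffolds,
                                        function(s) s$map_contig_id, ""))
  expect_gte(built$report$anchored_ok_but_alone, 1L)
})

test_that("the pipeline recovers planted order and orientation exactly", {
  fx <- sim_ss_fixture(11)
  pl <- place_tags(fx$wgp$tag_seqs, fx$fr$assembly)
  an <- anchor_scaffolds(pl, fx$wgp$map)
  built <- build_superscaffolds(an, fx$wgp$map, fx$fr$assembly,
                                gap_policy_template())
  ok <- an[an$status == "ok", ]
  expect_gt(nrow(ok), 0L)
  tr <- fx$fr$truth
  expect_equal(ok$orientation, tr$orientation[match(ok$scaffold_id, tr$scaffold_id)])
  for (ss in built$superscaffolds) {
    gs <- tr$genome_start[match(ss$components$scaffold_id, tr$scaffold_id)]
    expect_true(all(diff(gs) > 0))
  }
  # partition: every scaffold is in exactly one bucket
  rep <- built$report
  expect_equal(rep$sequences_in_superscaffolds + rep$discarded_unknown_orientation +
                 rep$discarded_multi_contig + rep$anchored_ok_but_alone +
                 rep$unplaced, length(fx$fr$assembly$id))
})

test_that("reversing a map contig's tag order reverses components and flips strands", {
  fx <- sim_ss_fixture(13)
  pl <- place_tags(fx$wgp$tag_seqs, fx$fr$assembly)
  an <- anchor_scaffolds(pl, fx$wgp$map)
  built <- build_superscaffolds(an, fx$wgp$map, fx$fr$assembly)

  tags_rev <- fx$wgp$map$tags
  for (cid in unique(tags_rev$map_contig_id)) {
    sel <- tags_rev$map_contig_id == cid
    tags_rev$rank[sel] <- max(tags_rev$rank[sel]) - tags_rev$rank[sel]
  }
  map_rev <- physical_map(tags_rev[, c("tag_id", "map_contig_id", "rank")])
  an_rev <- anchor_scaffolds(pl, map_rev)
  built_rev <- build_superscaffolds(an_rev, map_rev, fx$fr$assembly)

  for (id in names(built$superscaffolds)) {
    fwd <- built$superscaffolds[[id]]$components
    bwd <- built_rev$superscaffolds[[id]]$components
    expect_equal(bwd$scaffold_id, rev(fwd$scaffold_id))
    expect_equal(bwd$orientation, rev(ifelse(fwd$orientation == "+", "-", "+")))
  }
})

test_that("gapped sequences add exactly the emitted gap lengths in N", {
  fx <- sim_ss_fixture(15)
  pl <- place_tags(fx$wgp$tag_seqs, fx$fr$assembly)
  an <- anchor_scaffolds(pl, fx$wgp$map)
  built <- build_superscaffolds(an, fx$wgp$map, fx$fr$assembly,
                                gap_policy_fixed(100L))
  out <- superscaffold_fasta(built$superscaffolds, fx$fr$assembly)
  n_before <- sum(vapply(gregexpr("N", fx$fr$assembly$seq, fixed = TRUE),
                         function(m) if (m[1] == -1L) 0L else length(m), 0L))
  n_after <- sum(vapply(gregexpr("N", out$seq, fixed = TRUE),
                        function(m) if (m[1] == -1L) 0L else length(m), 0L))
  total_gaps <- sum(vapply(built$superscaffolds, function(s)
    sum(s$components$gap_after, na.rm = TRUE), 0))
  expect_equal(n_after - n_before, total_gaps)
  # spans match the rendered sequences
  for (ss in built$superscaffolds) {
    expect_equal(nchar(out$seq[match(ss$id, out$id)]), ss$total_span_bp)
  }
})

test_that("superscaffold N50 gain is monotone and bookkeeping is exact", {
  fx <- sim_ss_fixture(19)
  expect_equal(superscaffold_n50_gain(fx$fr$assembly, list()),
               c(n50_before = n50(nchar(fx$fr$assembly$seq)),
                 n50_after = n50(nchar(fx$fr$assembly$seq))))

  pl <- place_tags(fx$wgp$tag_seqs, fx$fr$assembly)
  an <- anchor_scaffolds(pl, fx$wgp$map)
  built <- build_superscaffolds(an, fx$wgp$map, fx$fr$assembly)
  gain <- superscaffold_n50_gain(fx$fr$assembly, built$superscaffolds)
  expect_gte(gain[["n50_after"]], gain[["n50_before"]])
})

test_that("a single tag per scaffold forces zero superscaffolds", {
  fx <- sim_ss_fixture(23, tags_per_scaffold = 1L)
  pl <- place_tags(fx$wgp$tag_seqs, fx$fr$assembly)
  an <- anchor_scaffolds(pl, fx$wgp$map)
  built <- build_superscaffolds(an, fx$wgp$map, fx$fr$assembly)
  expect_equal(built$report$n_superscaffolds, 0L)
})
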