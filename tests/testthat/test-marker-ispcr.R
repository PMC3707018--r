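test_that("find_primer_sites applies the identity threshold per primer", {
  set.seed(51)
  primer <- random_dna(20)
  g <- paste0(random_dna(200), primer, random_dna(200))
  asm <- assembly(c(chr = g))
  sites <- find_primer_sites(primer, asm)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$start, 200L)
  expect_equal(sites$identity, 1.0)

  # 1 substitution on a 20-mer: 19/20 = 0.95, retained
  mut1 <- primer
  substr(mut1, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(primer, 10, 10))[1]
  g1 <- paste0(random_dna(100), mut1, random_dna(100))
  s1 <- find_primer_sites(primer, assembly(c(chr = g1)))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$mismatches, 1L)

  # 2 substitutions: 18/20 = 0.90, rejected
  mut2 <- mut1
  substr(mut2, 15, 15) <- setdiff(c("A", "C", "G", "T"), substr(primer, 15, 15))[1]
  g2 <- paste0(random_dna(100), mut2, random_dna(100))
  expect_equal(nrow(find_primer_sites(primer, assembly(c(chr = g2)))), 0L)
})

test_that("find_primer_sites equals a brute-force Hamming scan on both strands", {
  set.seed(3)
  seqs <- c(g1 = random_dna(20000), g2 = random_dna(5000))
  asm <- assembly(seqs)
  for (i in 1:5) {
    # seed a couple of planted near-matches so hits actually occur
    primer <- substr(seqs[["g1"]], i * 1000, i * 1000 + 19)
    sites <- find_primer_sites(primer, asm, min_identity = 0.9)
    bf <- bf_primer_sites(primer, as.list(seqs), min_identity = 0.9)
    sites <- sites[order(sites$seq_id, sites$start, sites$strand), ]
    expect_equal(sites[, c("seq_id", "start", "end", "strand", "mismatches")],
                 bf, ignore_attr = TRUE)
  }
})

test_that("amplicons require convergent orientation within the size limit", {
  set.seed(53)
  fwd <- random_dna(20)
  rev <- random_dna(20)
  insert <- random_dna(300 - 40)
  g <- paste0(random_dna(150), fwd, insert, revcomp(rev), random_dna(150))
  asm <- assembly(c(chr = g))
  amp <- predict_amplicons(fwd, rev, asm)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_bp, 300L)
  expect_equal(amp$start, 150L)

  # divergent orientation (primers pointing away): no amplicon
  g_div <- paste0(random_dna(150), revcomp(fwd), insert, rev, random_dna(150))
  expect_equal(nrow(predict_amplicons(fwd, rev, assembly(c(chr = g_div)))), 0L)

  # product above the cap: rejected
  g_far <- paste0(random_dna(100), fwd, random_dna(3000), revcomp(rev))
  expect_equal(nrow(predict_amplicons(fwd, rev, assembly(c(chr = g_far)))), 0L)

  # swapping the primer roles leaves the amplicon set unchanged
  amp_sw <- predict_amplicons(rev, fwd, asm)
  expect_equal(amp_sw[, c("seq_id", "start", "end", "product_bp")],
               amp[, c("seq_id", "start", "end", "product_bp")])
})

test_that("classify_marker partitions into unique / multiple / none", {
  set.seed(54)
  fwd <- random_dna(20); rev <- random_dna(20)
  amp <- paste0(fwd, random_dna(200), revcomp(rev))
  one <- assembly(c(chr = paste0(random_dna(100), amp, random_dna(100))))
  expect_equal(classify_marker(fwd, rev, one)$status, "unique")

  two <- assembly(c(c1 = paste0(random_dna(50), amp, random_dna(50)),
                    c2 = paste0(random_dna(80), amp, random_dna(20))))
  expect_equal(classify_marker(fwd, rev, two)$status, "multiple")

  none <- assembly(c(chr = random_dna(500)))
  expect_equal(classify_marker(fwd, rev, none)$status, "none")
})

test_that("planted marker panel statuses are recovered exactly", {
  cfg <- sim_config(genome_bp = 100000L, n_markers = 50L, seed = 3)
  pm <- plant_markers(simulate_genome(cfg), cfg)
  asm <- assembly(c(chr1 = pm$genome))
  res <- run_ispcr(pm$primer_pairs, asm)
  cmp <- merge(res$status, pm$truth, by = "marker_id")
  expect_equal(cmp$status, cmp$expected_status)
  # status partition
  expect_equal(sum(table(res$status$status)), nrow(pm$primer_pairs))
  # unique products match planted sizes
  uni <- merge(res$hits, pm$truth[pm$truth$expected_status == "unique", ],
               by = "marker_id", suffixes = c("_found", "_planted"))
  expect_gt(nrow(uni), 0L)
  expect_equal(uni$product_bp_found, uni$product_bp_planted)
})

test_that("aggregate_concordance reproduces the printed map-A arithmetic", {
  ids <- sprintf("m%03d", 1:173)
  # 75 on map A found in A only, 50 found in both, 1 map-A+map-B marker in A
  # only, 2 map-A+map-B in both, 45 not found in A at all
  status_a <- c(rep("unique", 128), rep("none", 45))
  status_b <- c(rep("none", 75), rep("unique", 50), rep("none", 1),
                rep("unique", 2), rep("none", 45))
  evidence <- c(rep("map_A", 125), rep("map_A+map_B", 3), rep("map_A", 45))
  ct <- aggregate_concordance(data.frame(marker_id = ids, status = status_a),
                              data.frame(marker_id = ids, status = status_b),
                              data.frame(marker_id = ids, evidence_class = evidence))
  s <- concordance_summary(ct, c("map_A", "map_A+map_B"), genome = "A")
  expect_equal(s$n_markers, 173L)
  expect_equal(s$n_mapped, 128L)
  expect_equal(s$pct, 74)

  # empty inputs give an all-zero table
  empty <- data.frame(marker_id = character(0), status = character(0))
  ct0 <- aggregate_concordance(empty, empty,
                               data.frame(marker_id = character(0),
                                          evidence_class = character(0)))
  expect_equal(sum(ct0$table), 0L)

  # markers missing from the panel land in 'unknown' with a warning
  expect_warning(
    ctw <- aggregate_concordance(
      data.frame(marker_id = "x", status = "unique"),
      data.frame(marker_id = "x", status = "none"),
      data.frame(marker_id = character(0), evidence_class = character(0))),
    "unknown")
  expect_equal(ctw$details$evidence_class, "unknown")
})

test_that("planted evidence panel cross-tabulates to the generator truth", {
  set.seed(59)
  n <- 60L
  ids <- sprintf("p%03d", seq_len(n))
  truth_a <- sample(c("unique", "multiple", "none"), n, TRUE)
  truth_b <- sample(c("unique", "multiple", "none"), n, TRUE)
  ev <- sample(c("amp_A", "amp_B"), n, TRUE)
  ct <- aggregate_concordance(data.frame(marker_id = ids, status = truth_a),
                              data.frame(marker_id = ids, status = truth_b),
                              data.frame(marker_id = ids, evidence_class = ev))
  joint <- ifelse(truth_a == "unique" & truth_b == "unique", "both",
                  ifelse(truth_a == "unique", "A_only",
                         ifelse(truth_b == "unique", "B_only", "neither")))
  for (jc in c("A_only", "B_only", "both", "neither")) {
    for (e in c("amp_A", "amp_B")) {
      expect_equal(unname(ct$table[jc, e]), sum(joint == jc & ev == e))
    }
  }
})
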