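test_that("read_fasta parses minimal and wrapped records", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT"), p)
  asm <- read_fasta(p)
  expect_equal(asm$id, "s1")
  expect_equal(nchar(asm$seq), 4L)

  writeLines(c(">s1", "AC", "GT", ">s2", "NNN"), p)
  asm <- read_fasta(p)
  expect_equal(nchar(asm$seq), c(4L, 3L))
  expect_equal(asm$seq[1], "ACGT")
})

test_that("read_fasta rejects malformed input with located errors", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">s1", "ACGT"), p)
  expect_error(read_fasta(p), "line 1")
  writeLines(c(">dup", "AC", ">dup", "GT"), p)
  expect_error(read_fasta(p), "dup")
  writeLines(c(">s1", "ACXT"), p)
  expect_error(read_fasta(p), "invalid character")
})

test_that("fasta round-trips to a byte-identical normalized form", {
  set.seed(101)
  n <- 1000L
  asm <- assembly(vapply(seq_len(n), function(i) random_dna(sample(50:250, 1)), ""),
                  ids = sprintf("seq_%04d", seq_len(n)))
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(asm, p1)
  back <- read_fasta(p1)
  expect_identical(back$id, asm$id)
  expect_identical(back$seq, asm$seq)
  write_fasta(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("read_fastq decodes Phred+33 and enforces length equality", {
  p <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), p)
  reads <- read_fastq(p)
  expect_equal(qual_scores(reads)[[1]], rep(40L, 4L))

  writeLines(c("@r1", "ACGT", "+", "II"), p)
  expect_error(read_fastq(p), "r1")

  writeLines(c("@r1", "ACGT", "+"), p)
  expect_error(read_fastq(p), "truncated")
})

test_that("fastq round-trips losslessly", {
  set.seed(202)
  reads <- make_read_set(10000L, 100L, qmin = 2, qmax = 41)
  p <- withr::local_tempfile(fileext = ".fq")
  write_fastq(reads, p)
  back <- read_fastq(p)
  expect_identical(back$id, reads$id)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
})

make_ss <- function(id, comps) {
  structure(list(id = id, map_contig_id = id, components = comps,
                 total_span_bp = sum(comps$length) + sum(comps$gap_after, na.rm = TRUE)),
            class = "superscaffold")
}

test_that("write_agp emits coordinate-consistent AGP v2.1 rows", {
  ss <- make_ss("obj1", data.frame(
    scaffold_id = c("S1", "S2"), orientation = c("+", "-"),
    length = c(100L, 80L), gap_after = c(50L, NA), stringsAsFactors = FALSE))
  p <- withr::local_tempfile(fileext = ".agp")
  expect_equal(write_agp(list(ss), p), 3L)
  agp <- read_agp(p)
  expect_equal(nrow(agp), 3L)
  expect_equal(agp$object_end[3], 230L)
  expect_equal(agp$component_type, c("W", "N", "W"))

  expect_equal(write_agp(list(), p), 0L)
  expect_equal(nrow(read_agp(p)), 0L)
})

test_that("AGP rows tile the object exactly with no overlap or hole", {
  set.seed(33)
  lens <- sample(100:5000, 20L)
  gaps <- c(sample(10:500, 19L), NA)
  ss <- make_ss("big", data.frame(
    scaffold_id = sprintf("S%02d", 1:20), orientation = sample(c("+", "-"), 20, TRUE),
    length = lens, gap_after = gaps, stringsAsFactors = FALSE))
  p <- withr::local_tempfile(fileext = ".agp")
  write_agp(list(ss), p)
  agp <- read_agp(p)
  expect_equal(agp$object_start[1], 1L)
  expect_equal(agp$object_start[-1], agp$object_end[-nrow(agp)] + 1L)
  expect_equal(agp$object_end[nrow(agp)], ss$total_span_bp)
  expect_equal(sum(agp$object_end - agp$object_start + 1L), ss$total_span_bp)
  w <- agp$component_type == "W"
  expect_equal(agp$object_end[w] - agp$object_start[w] + 1L,
               as.integer(agp$col8[w]) - as.integer(agp$col7[w]) + 1L)
})

test_that("read_table_schema types columns and names schema violations", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("depth\tcount", "10\t100"), p)
  df <- read_table_schema(p, "kmer_hist")
  expect_equal(df$depth, 10)
  expect_equal(df$count, 100)

  writeLines(c("marker_id\tforward_seq", "m1\tACGT"), p)
  expect_error(read_table_schema(p, "primer_pairs"), "reverse_seq")

  writeLines(c("depth\tcount", "10\tabc"), p)
  expect_error(read_table_schema(p, "kmer_hist"), "row 1")
})

test_that("fpkm tables parse with totals preserved", {
  set.seed(404)
  n <- 500L
  starts <- sample.int(1e6, n)
  df <- data.frame(transcript_id = sprintf("t%03d", 1:n), seq_id = "chr1",
                   start = starts, end = starts + sample(100:1000, n, TRUE),
                   fpkm = round(rexp(n, 1 / 5), 4))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(df, p)
  back <- read_table_schema(p, "fpkm")
  expect_equal(nrow(back), n)
  expect_equal(sum(back$fpkm), sum(df$fpkm))
})
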