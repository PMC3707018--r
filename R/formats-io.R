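# On-disk formats: FASTA, FASTQ (Phred+33), AGP v2.1, fixed-schema TSV
# tables. Internal coordinates are 0-based half-open everywhere; AGP and
# report output convert to 1-based inclusive on write.

VALID_BASES <- c("A", "C", "G", "T", "N")

check_alphabet <- function(seqs, ids, where) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop(sprintf("%s: record '%s' contains invalid character '%s' (allowed: A,C,G,T,N)",
                 where, ids[i], ch), call. = FALSE)
  }
}

new_assembly <- function(id, seq, name = "assembly") {
  structure(list(id = as.character(id), seq = as.character(seq), name = name),
            class = "assembly")
}

#' Construct an assembly from sequences
#'
#' An assembly is an ordered set of named DNA sequences (scaffolds/contigs)
#' with unique ids, restricted to the alphabet A,C,G,T,N.
#'
#' @param seqs named character vector, or unnamed with `ids` given
#' @param ids sequence ids (defaults to names of `seqs`)
#' @param name assembly label, e.g. "Nsyl"
#' @return an `assembly` object
#' @export
assembly <- function(seqs, ids = names(seqs), name = "assembly") {
  if (is.null(ids)) stop("sequence ids are required")
  seqs <- toupper(as.character(seqs))
  ids <- as.character(ids)
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1]), call. = FALSE)
  }
  if (any(!nzchar(ids)) || any(grepl("\\s", ids))) {
    stop("sequence ids must be non-empty and contain no whitespace")
  }
  check_alphabet(seqs, ids, "assembly")
  new_assembly(ids, unname(seqs), name)
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s': %d sequence(s), %s bp>\n", x$name,
              length(x$id), format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

#' @export
length.assembly <- function(x) length(x$id)

# DNAStringSet view of an assembly (for Biostrings matching).
as_dss <- function(asm) {
  x <- Biostrings::DNAStringSet(asm$seq)
  names(x) <- asm$id
  x
}

#' Read a FASTA file
#'
#' Multi-line records are concatenated, lowercase is uppercased, and ids are
#' the first whitespace-delimited token of the header. Duplicate ids and
#' characters outside A,C,G,T,N are errors.
#'
#' @param path FASTA file (plain or gzip)
#' @param name assembly label
#' @return an `assembly`
#' @export
read_fasta <- function(path, name = sub("\\.(fa|fasta)(\\.gz)?$", "", basename(path))) {
  lines <- read_all_lines(path)
  keep <- !grepl("^\\s*$", lines)
  first <- which(keep)[1]
  if (is.na(first)) stop(sprintf("'%s' is empty", path), call. = FALSE)
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("'%s' line %d: expected FASTA header starting with '>'", path, first),
         call. = FALSE)
  }
  lines <- lines[keep]
  hdr <- startsWith(lines, ">")
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  rec <- cumsum(hdr)
  body <- vapply(split(lines[!hdr], factor(rec[!hdr], levels = seq_len(sum(hdr)))),
                 paste0, "", collapse = "")
  assembly(toupper(gsub("\\s", "", body)), ids = ids, name = name)
}

#' Write an assembly as normalized FASTA
#'
#' @param asm an `assembly` (or read set; qualities are dropped)
#' @param path output path
#' @param width line-wrap width in bases
#' @return invisibly, the number of records written
#' @export
write_fasta <- function(asm, path, width = 60L) {
  out <- file(path, "wt")
  on.exit(close(out))
  for (i in seq_along(asm$id)) {
    writeLines(paste0(">", asm$id[i]), out)
    s <- asm$seq[i]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), out)
  }
  invisible(length(asm$id))
}

new_read_set <- function(id, seq, qual) {
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = as.character(qual)), class = "read_set")
}

#' Construct a read set
#'
#' A read set stores sequences plus per-base Phred qualities (kept in their
#' Phred+33 string encoding; see [qual_scores()] to decode).
#'
#' @param id,seq,qual parallel character vectors; `qual` is Phred+33 encoded
#' @return a `read_set`
#' @export
read_set <- function(id, seq, qual) {
  seq <- toupper(as.character(seq))
  id <- as.character(id)
  qual <- as.character(qual)
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- nchar(seq) != nchar(qual)
  if (any(bad)) {
    stop(sprintf("read '%s': sequence and quality lengths differ (%d vs %d)",
                 id[which(bad)[1]], nchar(seq[which(bad)[1]]),
                 nchar(qual[which(bad)[1]])), call. = FALSE)
  }
  check_alphabet(seq, id, "read_set")
  if (any(grepl("[^\\x21-\\x7e]", qual, perl = TRUE))) {
    i <- which(grepl("[^\\x21-\\x7e]", qual, perl = TRUE))[1]
    stop(sprintf("read '%s': quality string contains characters outside Phred+33 range",
                 id[i]), call. = FALSE)
  }
  new_read_set(id, seq, qual)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set: %d read(s), %s bases>\n", length(x$id),
              format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$id)

#' Decode Phred+33 quality strings to integer scores
#'
#' @param x a `read_set` or character vector of Phred+33 strings
#' @return list of integer vectors, one per read
#' @export
qual_scores <- function(x) {
  q <- if (inherits(x, "read_set")) x$qual else as.character(x)
  lapply(q, function(s) if (nchar(s) == 0L) integer(0) else utf8ToInt(s) - 33L)
}

#' Encode integer Phred scores as Phred+33 strings
#'
#' @param scores list of integer vectors (each score in 0..93)
#' @return character vector
#' @export
encode_quals <- function(scores) {
  vapply(scores, function(q) {
    if (length(q) == 0L) return("")
    stopifnot(all(q >= 0L), all(q <= 93L))
    intToUtf8(as.integer(q) + 33L)
  }, "")
}

#' Read a FASTQ file (Phred+33)
#'
#' Strict four-line records; sequence/quality length equality is enforced
#' per record.
#'
#' @param path FASTQ file (plain or gzip)
#' @return a `read_set`
#' @export
read_fastq <- function(path) {
  lines <- read_all_lines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("'%s': truncated FASTQ (line count %d not a multiple of 4)", path, n),
         call. = FALSE)
  }
  if (n == 0L) return(new_read_set(character(0), character(0), character(0)))
  h <- lines[seq(1L, n, 4L)]
  if (any(!startsWith(h, "@"))) {
    bad <- which(!startsWith(h, "@"))[1]
    stop(sprintf("'%s' line %d: expected '@' header", path, (bad - 1L) * 4L + 1L),
         call. = FALSE)
  }
  plus <- lines[seq(3L, n, 4L)]
  if (any(!startsWith(plus, "+"))) {
    bad <- which(!startsWith(plus, "+"))[1]
    stop(sprintf("'%s' line %d: expected '+' separator", path, (bad - 1L) * 4L + 3L),
         call. = FALSE)
  }
  ids <- sub("^@\\s*(\\S+).*$", "\\1", h)
  read_set(ids, lines[seq(2L, n, 4L)], lines[seq(4L, n, 4L)])
}

#' Write a read set as FASTQ (Phred+33)
#'
#' @param reads a `read_set`
#' @param path output path
#' @return invisibly, the number of reads written
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  out <- file(path, "wt")
  on.exit(close(out))
  if (length(reads$id) > 0L) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)), out)
  }
  invisible(length(reads$id))
}

# Fixed TSV schemas: name -> list(cols, numeric cols)
TABLE_SCHEMAS <- list(
  primer_pairs = list(cols = c("marker_id", "forward_seq", "reverse_seq"), num = character(0)),
  map_tags     = list(cols = c("tag_id", "map_contig_id", "rank"), num = "rank"),
  fpkm         = list(cols = c("transcript_id", "seq_id", "start", "end", "fpkm"),
                      num = c("start", "end", "fpkm")),
  kmer_hist    = list(cols = c("depth", "count"), num = c("depth", "count")),
  regions      = list(cols = c("region_id", "seq_id", "start", "end"),
                      num = c("start", "end")),
  template_pos = list(cols = c("tag_id", "template_pos"), num = "template_pos")
)

#' Read a fixed-schema TSV table
#'
#' Supported schemas: `primer_pairs`, `map_tags`, `fpkm`, `kmer_hist`,
#' `regions`, `template_pos`. The header must contain the schema's columns;
#' extra columns are carried through untyped.
#'
#' @param path TSV file with a header row
#' @param schema schema name
#' @return data.frame with typed columns, row order preserved
#' @export
read_table_schema <- function(path, schema) {
  sc <- TABLE_SCHEMAS[[schema]]
  if (is.null(sc)) stop(sprintf("unknown schema '%s'", schema), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  missing <- setdiff(sc$cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("'%s': schema '%s' requires column '%s'", path, schema, missing[1]),
         call. = FALSE)
  }
  for (col in sc$num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0L || anyNA(v)) {
      row <- if (length(bad) > 0L) bad[1] else which(is.na(v))[1]
      stop(sprintf("'%s' row %d: non-numeric value '%s' in column '%s'",
                   path, row, df[[col]][row], col), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write a table as TSV
#'
#' @param df data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write superscaffolds as AGP v2.1
#'
#' Emits 9-column AGP rows (1-based inclusive coordinates): W rows for
#' components, N rows (gap_type "scaffold", evidence "map") for estimated
#' gaps.
#'
#' @param superscaffolds list of `superscaffold` objects (see
#'   [build_superscaffolds()])
#' @param path output path
#' @param lengths named vector of component lengths; required only if the
#'   superscaffolds lack recorded lengths
#' @return number of rows written (excluding the header comment)
#' @export
write_agp <- function(superscaffolds, path, lengths = NULL) {
  rows <- list()
  for (ss in superscaffolds) {
    pos <- 0L   # 0-based cursor
    part <- 0L
    comp <- ss$components
    for (i in seq_len(nrow(comp))) {
      len <- comp$length[i]
      if (is.na(len) && !is.null(lengths)) len <- lengths[[comp$scaffold_id[i]]]
      if (is.na(len)) stop("component length unknown for ", comp$scaffold_id[i])
      if (comp$orientation[i] %in% c("unknown", "?")) {
        stop(sprintf("internal error: unoriented component '%s' in superscaffold '%s'",
                     comp$scaffold_id[i], ss$id), call. = FALSE)
      }
      part <- part + 1L
      rows[[length(rows) + 1L]] <- c(ss$id, pos + 1L, pos + len, part, "W",
                                     comp$scaffold_id[i], 1L, len, comp$orientation[i])
      pos <- pos + len
      gap <- comp$gap_after[i]
      if (!is.na(gap)) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- c(ss$id, pos + 1L, pos + gap, part, "N",
                                       gap, "scaffold", "yes", "map")
        pos <- pos + gap
      }
    }
  }
  out <- file(path, "wt")
  on.exit(close(out))
  writeLines("##agp-version\t2.1", out)
  for (r in rows) writeLines(paste(r, collapse = "\t"), out)
  length(rows)
}

#' Read an AGP file back into row form
#'
#' @param path AGP file
#' @return data.frame of AGP columns (coordinates 1-based inclusive as on disk)
#' @export
read_agp <- function(path) {
  lines <- read_all_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(object_id = character(0), object_start = integer(0),
                      object_end = integer(0), part_number = integer(0),
                      component_type = character(0), col6 = character(0),
                      col7 = character(0), col8 = character(0), col9 = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(parts) == 9L))
  m <- do.call(rbind, parts)
  data.frame(object_id = m[, 1], object_start = as.integer(m[, 2]),
             object_end = as.integer(m[, 3]), part_number = as.integer(m[, 4]),
             component_type = m[, 5], col6 = m[, 6], col7 = m[, 7], col8 = m[, 8],
             col9 = m[, 9], stringsAsFactors = FALSE)
}
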