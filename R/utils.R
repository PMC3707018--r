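#' @useDynLib draftanchor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
NULL

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; assembly reports conventionally
#' round half up (8748.835 -> 8748.84), so all printed-precision fields go
#' through this helper.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
#' @examples
#' round_half_up(0.5)      # 1
#' round_half_up(2.675, 2) # 2.68
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny nudge guards against decimal values just below .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over A,C,G,T,N (case-insensitive)
#' @return character vector of reverse complements (uppercase)
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Open a file for reading text, transparently handling gzip by magic bytes.
open_text <- function(path) {
  stopifnot(file.exists(path))
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}

read_all_lines <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Evaluate expr under a temporary RNG state seeded deterministically from
# (seed, stream), so each simulator operation has its own stream and adding
# one never perturbs the others.
with_stream_seed <- function(seed, stream, expr) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  derived <- (as.numeric(seed) * 48271 + h) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
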