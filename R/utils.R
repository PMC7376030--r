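#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper used throughout the package for
#' strings that are not worth round-tripping through a DNAString.
#' Handles the alphabet {A,C,G,T,N} (uppercase).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Complement (without reversal) of a nucleotide string
#' @param x character vector of nucleotide strings.
#' @return character vector of complements.
#' @export
complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse (without complementation) of a nucleotide string
#' @param x character vector of nucleotide strings.
#' @return character vector of reversed strings.
#' @export
reverse_seq <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# split a string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# extract a subsequence in 0-based half-open coordinates, wrapping the
# origin when end > nchar(s) (circular records)
.subseq0 <- function(s, start, end) {
  n <- nchar(s)
  stopifnot(start >= 0L, end > start, end - start <= n)
  if (end <= n) {
    substr(s, start + 1L, end)
  } else {
    paste0(substr(s, start + 1L, n), substr(s, 1L, end - n))
  }
}

# rotate a circular sequence so that 0-based position `offset` becomes 0
.rotate0 <- function(s, offset) {
  n <- nchar(s)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(s)
  paste0(substr(s, offset + 1L, n), substr(s, 1L, offset))
}

# uniform random DNA string
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a data frame as TSV with a coordinate-convention header comment
#'
#' All tabular outputs of the package use 0-based half-open coordinates;
#' the header comment states this so downstream consumers need not guess.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param comment optional extra comment lines (without leading "# ").
#' @export
write_tsv_report <- function(df, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# coordinates: 0-based half-open [start, end)",
               paste0("# ", comment)[seq_along(comment)]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
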