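# Shared low-level helpers: sequence handling, small IO, validation.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "-")

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that works on plain
#' character scalars and preserves IUPAC ambiguity codes.
#'
#' @param x single nucleotide string.
#' @return reverse-complemented string, upper case.
#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# complement of a character vector of single bases (no reversal)
comp_chars <- function(x) {
  chartr("ACGTRYKMBDHVN", "TGCAYRMKVHDBN", x)
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1L]]

chars_to_seq <- function(x) paste(x, collapse = "")

assert_nucleotides <- function(x, what = "sequence") {
  ch <- unique(seq_chars(x))
  bad <- setdiff(ch, IUPAC_CHARS)
  if (nchar(x) == 0L) stop(what, " is empty", call. = FALSE)
  if (length(bad) > 0L) {
    stop(what, " contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# GC fraction of a character vector of bases; ambiguity codes are excluded
# from numerator and denominator.  Returns NA_real_ if no unambiguous base.
gc_fraction <- function(ch) {
  n_gc <- sum(ch == "G" | ch == "C")
  n_at <- sum(ch == "A" | ch == "T")
  tot <- n_gc + n_at
  if (tot == 0L) return(NA_real_)
  n_gc / tot
}

# circular substring: 0-based start, length len, on a string of length n
circ_substr <- function(s, start0, len) {
  n <- nchar(s)
  start0 <- start0 %% n
  if (start0 + len <= n) {
    substr(s, start0 + 1L, start0 + len)
  } else {
    paste0(substr(s, start0 + 1L, n), substr(s, 1L, start0 + len - n))
  }
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# deterministic JSON writer used for all machine-readable reports
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record).
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# adjusted Rand index between two label vectors (small-n exact formula)
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
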