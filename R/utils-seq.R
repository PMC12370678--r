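# Low-level nucleotide and quality helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Plain-character implementation (A/C/G/T/N); the k-mer index stores the
#' forward orientation of the reference only, so strand handling always
#' goes through reverse-complementing the read.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

# All k-mer start positions of a single sequence; returns character(0) when
# the sequence is shorter than k.
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# Phred+33 quality string -> integer scores.
qual_to_int <- function(qual) {
  utf8ToInt(qual) - 33L
}

int_to_qual <- function(q) {
  intToUtf8(q + 33L)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute positions `pos` of `s` with a uniformly chosen *different* base.
mutate_bases <- function(s, pos) {
  if (length(pos) == 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

assert_seq_alphabet <- function(seq, name = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T,N}: %s",
      name, paste(head(which(bad), 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}
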