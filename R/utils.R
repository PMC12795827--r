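DNA_BASES <- c("A", "C", "G", "T")

# complement index: A<->T, C<->G
COMP_IDX <- c(4L, 3L, 2L, 1L)

#' Reverse complement of a DNA string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out. Ambiguity codes are preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode a DNA string as integer codes 1..4 (A,C,G,T); anything else -> NA.
dna_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(chars, DNA_BASES)
}

# Nucleotide composition of a character vector of sequences, optionally
# symmetrized over complementary bases (so that one PWM cutoff is valid on
# both strands). Ambiguity codes are ignored.
#' Nucleotide background composition of a sequence set
#'
#' @param seqs character vector of DNA sequences.
#' @param symmetrize average complementary bases (A with T, C with G) so the
#'   background is strand-symmetric. Default `TRUE`.
#' @return named numeric vector of frequencies over A, C, G, T summing to 1.
#' @export
background_composition <- function(seqs, symmetrize = TRUE) {
  codes <- unlist(lapply(seqs, dna_codes), use.names = FALSE)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) stop("no unambiguous bases in sequence set")
  counts <- tabulate(codes, nbins = 4L)
  freq <- counts / sum(counts)
  if (symmetrize) {
    freq <- (freq + freq[COMP_IDX]) / 2
  }
  stats::setNames(freq, DNA_BASES)
}

# stop() with a sprintf-style message, no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic TSV writer used for all output tables
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
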