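# Genome sequences and interval sequence extraction.
#
# All coordinates in this package are 0-based half-open ([start, end)) on the
# plus strand of the contig; 1-based formats (GTF, CIRI2, SAM) are converted
# at the I/O boundary.

#' Read a genome FASTA file
#'
#' Loads a (multi-)FASTA file into a `DNAStringSet` keyed by contig name.
#' Sequence names are truncated at the first whitespace, matching common
#' aligner behaviour.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique contig names.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) abort("duplicate contig names in FASTA")
  if (any(Biostrings::width(genome) == 0)) abort("zero-length contig in FASTA")
  genome
}

#' Write a genome FASTA file
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Fetch the sequence of a genomic interval
#'
#' Extracts the plus-strand sequence of `[start, end)` from `genome` and
#' reverse-complements it when `strand` is `"-"`. Strand `"."` is treated as
#' `"+"` with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] as returned by [read_genome()].
#' @param chrom Contig name.
#' @param start,end 0-based half-open coordinates (`end > start`).
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A character scalar DNA sequence.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(paste0("unknown contig: ", chrom))
  }
  if (end <= start) abort("interval must satisfy end > start")
  len <- length(genome[[chrom]])
  if (start < 0 || end > len) {
    abort(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                  start, end, chrom, len))
  }
  if (strand == ".") {
    warn("strand '.' treated as '+' for sequence extraction")
    strand <- "+"
  }
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse-complement a DNA string
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", seq),
         function(s) intToUtf8(rev(utf8ToInt(s))),
         character(1), USE.NAMES = FALSE)
}

gc_fraction <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  acgt <- rowSums(f)
  ifelse(acgt == 0, NA_real_, (f[, "C"] + f[, "G"]) / acgt)
}
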