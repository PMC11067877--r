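# Sequence-computable intron features: splice-site PWMs, GC, lengths,
# relative transcript position.

DONOR_EXONIC <- 3L    # donor window: 3 exonic + 6 intronic nt around the GT
DONOR_INTRONIC <- 6L
ACC_INTRONIC <- 20L   # acceptor window: 20 intronic + 3 exonic nt around the AG
ACC_EXONIC <- 3L

# strand-aware splice-site window sequences for one intron (transcript
# orientation: donor at the intron 5' end, acceptor at the 3' end)
splice_windows <- function(intron, genome) {
  if (intron$strand == "-") {
    donor <- fetch_sequence(genome, intron$chrom,
                            intron$end - DONOR_INTRONIC,
                            intron$end + DONOR_EXONIC, "-")
    acceptor <- fetch_sequence(genome, intron$chrom,
                               intron$start - ACC_EXONIC,
                               intron$start + ACC_INTRONIC, "-")
  } else {
    donor <- fetch_sequence(genome, intron$chrom,
                            intron$start - DONOR_EXONIC,
                            intron$start + DONOR_INTRONIC, "+")
    acceptor <- fetch_sequence(genome, intron$chrom,
                               intron$end - ACC_INTRONIC,
                               intron$end + ACC_EXONIC, "+")
  }
  list(donor = donor, acceptor = acceptor)
}

#' Estimate splice-site position weight matrices from a catalog
#'
#' Builds donor (3 exonic + 6 intronic nt around the GT) and acceptor
#' (20 intronic + 3 exonic nt around the AG) log-odds PWMs from all
#' annotated introns of the catalog, with a pseudocount of 1 per base and
#' position against a uniform background.
#'
#' @param catalog A [transcript_catalog()].
#' @param genome Genome `DNAStringSet`.
#' @return List of class `splice_pwm` with log2-odds matrices `donor`
#'   (4 x 9) and `acceptor` (4 x 23).
#' @export
build_splice_pwm <- function(catalog, genome) {
  introns <- distinct(catalog$introns, .data$intron_id, .keep_all = TRUE)
  if (nrow(introns) == 0) abort("catalog has no introns to train PWMs on")
  wins <- map(seq_len(nrow(introns)),
              function(i) splice_windows(introns[i, ], genome))
  pwm_from <- function(seqs) {
    mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    prob <- sweep(mat + 1, 2, colSums(mat + 1), "/")  # pseudocount 1
    log2(prob / 0.25)
  }
  structure(list(donor = pwm_from(map_chr(wins, "donor")),
                 acceptor = pwm_from(map_chr(wins, "acceptor"))),
            class = "splice_pwm")
}

#' Score a sequence against a PWM
#'
#' Sum of per-position log2-odds (bits); `N` bases score 0 at their
#' position.
#'
#' @param seq DNA string whose length equals `ncol(pwm)`.
#' @param pwm Log-odds matrix from [build_splice_pwm()].
#' @return Numeric score in bits.
#' @export
score_pwm <- function(seq, pwm) {
  bases <- strsplit(seq, "")[[1]]
  if (length(bases) != ncol(pwm)) {
    abort(sprintf("sequence length %d does not match PWM width %d",
                  length(bases), ncol(pwm)))
  }
  idx <- match(bases, rownames(pwm))
  sum(pwm[cbind(idx, seq_along(bases))], na.rm = TRUE)
}

#' Extract sequence-computable features for introns
#'
#' Per intron: log10 length, GC fraction, relative transcript position
#' (ordinal / intron count, in (0, 1]), 5' and 3' splice-site PWM log-odds
#' scores, and log10 length plus GC of the flanking (transcript-orientation
#' upstream and downstream) exons. Conservation, structure, motif and
#' nucleosome features require external resources and can be supplied as
#' extra columns downstream.
#'
#' @param introns Tibble of introns with `intron_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, `ordinal`, `n_introns` (as in
#'   `catalog$introns`).
#' @param catalog A [transcript_catalog()] (for flanking exons).
#' @param genome Genome `DNAStringSet`.
#' @param pwm Optional [build_splice_pwm()] result; built from `catalog`
#'   when `NULL`.
#' @return Tibble: `intron_id`, `transcript_id` and the numeric features
#'   `intron_length_log10`, `intron_gc`, `rel_position`, `ss5_score`,
#'   `ss3_score`, `up_exon_length_log10`, `down_exon_length_log10`,
#'   `up_exon_gc`, `down_exon_gc`.
#' @export
extract_features <- function(introns, catalog, genome, pwm = NULL) {
  if (is.null(pwm)) pwm <- build_splice_pwm(catalog, genome)
  rows <- map(seq_len(nrow(introns)), function(i) {
    intr <- introns[i, ]
    ex <- filter(catalog$exons, .data$transcript_id == intr$transcript_id)
    left <- filter(ex, .data$end == intr$start)   # genomic-left exon
    right <- filter(ex, .data$start == intr$end)  # genomic-right exon
    if (nrow(left) == 0 || nrow(right) == 0) {
      abort(sprintf("intron %s lacks a flanking exon in transcript %s",
                    intr$intron_id, intr$transcript_id))
    }
    if (intr$strand == "-") { up <- right[1, ]; down <- left[1, ] }
    else { up <- left[1, ]; down <- right[1, ] }
    wins <- splice_windows(intr, genome)
    iseq <- fetch_sequence(genome, intr$chrom, intr$start, intr$end, "+")
    tibble(
      intron_id = intr$intron_id,
      transcript_id = intr$transcript_id,
      intron_length_log10 = log10(intr$end - intr$start),
      intron_gc = gc_fraction(iseq),
      rel_position = intr$ordinal / intr$n_introns,
      ss5_score = score_pwm(wins$donor, pwm$donor),
      ss3_score = score_pwm(wins$acceptor, pwm$acceptor),
      up_exon_length_log10 = log10(up$end - up$start),
      down_exon_length_log10 = log10(down$end - down$start),
      up_exon_gc = gc_fraction(fetch_sequence(genome, up$chrom, up$start,
                                              up$end, "+")),
      down_exon_gc = gc_fraction(fetch_sequence(genome, down$chrom,
                                                down$start, down$end, "+"))
    )
  })
  bind_rows(rows)
}
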