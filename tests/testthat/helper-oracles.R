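# Independent brute-force oracles and tiny fixture builders used across the
# suite. The oracles deliberately share no code with the package internals:
# CIGARs are walked with a hand-rolled parser and metrics counted per read,
# per base.

aln_row <- function(read_id, start, cigar, chrom = "chrT", mate = 1L,
                    strand = "+", mapq = 60L) {
  tibble::tibble(read_id = read_id, mate = mate, chrom = chrom,
                 start = as.integer(start),
                 end = as.integer(start + naive_ref_width(cigar)),
                 strand = strand, mapq = as.integer(mapq), cigar = cigar)
}

# parse "10M5N20M" into a data.frame of (op, len)
naive_cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  data.frame(op = ops, len = lens)
}

naive_ref_width <- function(cigar) {
  ops <- naive_cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

# reference blocks of one alignment: contiguous runs of M/D/=/X split at N
naive_blocks <- function(start, cigar) {
  ops <- naive_cigar_ops(cigar)
  pos <- start
  blocks <- list()
  cur_start <- NA
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (is.na(cur_start)) cur_start <- pos
      pos <- pos + len
    } else if (op == "N") {
      if (!is.na(cur_start)) blocks[[length(blocks) + 1]] <- c(cur_start, pos)
      cur_start <- NA
      pos <- pos + len
    }
    # I, S, H consume no reference
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1]] <- c(cur_start, pos)
  do.call(rbind, blocks)
}

# per-read, per-base re-scan of the retention metrics for one intron
naive_intron_metrics <- function(aln, intron, overhang = 5L, window = 200L,
                                 min_mapq = 1L) {
  aln <- aln[aln$mapq >= min_mapq & aln$chrom == intron$chrom, ]
  EE <- 0L; EI <- 0L; IE <- 0L; I <- 0L
  ilen <- intron$end - intron$start
  wlen <- min(window, ilen)
  wstart <- intron$start + (ilen - wlen) %/% 2
  wend <- wstart + wlen
  covered <- rep(FALSE, ilen)
  for (r in seq_len(nrow(aln))) {
    blocks <- naive_blocks(aln$start[r], aln$cigar[r])
    # coverage
    for (b in seq_len(nrow(blocks))) {
      lo <- max(blocks[b, 1], intron$start); hi <- min(blocks[b, 2], intron$end)
      if (hi > lo) covered[(lo - intron$start + 1):(hi - intron$start)] <- TRUE
    }
    # EE: a gap between consecutive blocks matching the intron exactly
    is_ee <- FALSE
    if (nrow(blocks) > 1) {
      for (b in seq_len(nrow(blocks) - 1)) {
        if (blocks[b, 2] == intron$start && blocks[b + 1, 1] == intron$end &&
            (blocks[b, 2] - blocks[b, 1]) >= overhang &&
            (blocks[b + 1, 2] - blocks[b + 1, 1]) >= overhang) {
          is_ee <- TRUE
        }
      }
    }
    if (is_ee) { EE <- EE + 1L; next }
    # EI / IE: one contiguous block straddling a boundary
    hit_ei <- FALSE; hit_ie <- FALSE
    for (b in seq_len(nrow(blocks))) {
      if (blocks[b, 1] <= intron$start - overhang &&
          blocks[b, 2] >= intron$start + overhang) hit_ei <- TRUE
      if (blocks[b, 1] <= intron$end - overhang &&
          blocks[b, 2] >= intron$end + overhang) hit_ie <- TRUE
    }
    if (hit_ei) EI <- EI + 1L
    if (hit_ie) IE <- IE + 1L
    # I: inside-intron read touching the middle window
    touching <- blocks[blocks[, 1] < intron$end & blocks[, 2] > intron$start, ,
                       drop = FALSE]
    if (nrow(touching) > 0 &&
        all(touching[, 1] >= intron$start & touching[, 2] <= intron$end) &&
        any(touching[, 1] < wend & touching[, 2] > wstart)) {
      I <- I + 1L
    }
  }
  list(EE = EE, EI = EI, IE = IE, I = I, IC = mean(covered))
}

# brute-force host scoring: score every transcript, keep all maxima
naive_assign <- function(circ, catalog) {
  scores <- sapply(catalog$transcripts$transcript_id, function(tid) {
    ex <- catalog$exons[catalog$exons$transcript_id == tid, ]
    if (ex$chrom[1] != circ$chrom) return(NA_integer_)
    if (!(min(ex$start) < circ$end && max(ex$end) > circ$start)) {
      return(NA_integer_)
    }
    if (circ$strand %in% c("+", "-") && ex$strand[1] != circ$strand) {
      return(NA_integer_)
    }
    as.integer(circ$start %in% ex$start) + as.integer(circ$end %in% ex$end)
  })
  if (all(is.na(scores))) return(list(score = NA, hosts = character()))
  best <- max(scores, na.rm = TRUE)
  list(score = best,
       hosts = sort(names(scores)[!is.na(scores) & scores == best]))
}

# random toy catalog for property tests
random_catalog <- function(n_tx = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_tx), function(t) {
    n_ex <- sample(2:5, 1)
    start <- sample(0:2000, 1)
    exl <- sample(50:200, n_ex, replace = TRUE)
    inl <- sample(30:300, n_ex - 1, replace = TRUE)
    starts <- start + cumsum(c(0, head(exl, -1) + inl))
    tibble::tibble(
      transcript_id = sprintf("tx%02d", t), gene_id = sprintf("g%02d", t),
      chrom = "chrT", start = as.integer(starts),
      end = as.integer(starts + exl),
      strand = sample(c("+", "-"), 1)
    )
  })
  eicir::transcript_catalog(dplyr::bind_rows(rows))
}

default_templates <- function(depth = 50) {
  tibble::tribble(
    ~template_id, ~type, ~transcript_id, ~retained_intron, ~depth,
    "eici1", "eici", "gene1.t1", 2L, depth,
    "lin1", "linear", "gene1.t1", NA_integer_, depth,
    "ecirc1", "ecirc", "gene2.t1", NA_integer_, depth,
    "lin3", "linear", "gene3.t1", NA_integer_, depth
  )
}

run_planted <- function(seed, depth = 50, ...) {
  toy <- make_toy_genome(seed = seed)
  sim <- simulate_reads(toy$genome, toy$catalog, default_templates(depth),
                        seed = seed)
  res <- detect_eicirnas(toy$genome, toy$catalog, sim$bsj_calls,
                         sim$alignments, sim$reads1, sim$reads2, ...)
  truth_intron <- toy$catalog$introns$intron_id[
    toy$catalog$introns$transcript_id == "gene1.t1" &
      toy$catalog$introns$ordinal == 2]
  list(toy = toy, sim = sim, res = res, truth_intron = truth_intron)
}
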