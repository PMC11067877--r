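# Synthetic fixtures: toy genomes with exon/intron structure, paired-end
# reads from linear, EcircRNA and EIciRNA templates (with truth tables and
# splice-aware SAM), and labelled feature sets.

#' Generate a toy genome with annotated gene structures
#'
#' Builds one contig of uniform-random sequence, plants the requested genes
#' (non-overlapping, separated by `spacing` nt) and gives every intron
#' canonical boundaries: `GTAAGT` at the donor, a pyrimidine tract ending in
#' `AG` at the acceptor. Deterministic under `seed`.
#'
#' @param genes List of gene specs, each a list with `gene_id`,
#'   `exon_lengths` (integer vector) and `intron_lengths` (length
#'   `n_exons - 1`); or `NULL` to build `n_genes` identical genes.
#' @param n_genes,n_exons,exon_length,intron_length Defaults used when
#'   `genes` is `NULL`.
#' @param spacing Intergenic spacing in nt (default 500).
#' @param contig Contig name.
#' @param seed RNG seed.
#' @return List with `genome` (`DNAStringSet`) and `catalog`
#'   ([transcript_catalog()]).
#' @export
make_toy_genome <- function(genes = NULL, n_genes = 3L, n_exons = 5L,
                            exon_length = 150L, intron_length = 400L,
                            spacing = 500L, contig = "chrS", seed = 1L) {
  if (is.null(genes)) {
    genes <- map(seq_len(n_genes), function(g) {
      list(gene_id = sprintf("gene%d", g),
           exon_lengths = rep(exon_length, n_exons),
           intron_lengths = rep(intron_length, n_exons - 1L))
    })
  }
  for (g in genes) {
    if (length(g$intron_lengths) != length(g$exon_lengths) - 1L) {
      abort(sprintf("gene %s: need one intron length per exon gap", g$gene_id))
    }
    if (any(g$intron_lengths < 30L)) {
      abort(sprintf("gene %s: intron lengths must be >= 30 nt", g$gene_id))
    }
    if (any(g$exon_lengths < 1L)) {
      abort(sprintf("gene %s: exon lengths must be >= 1 nt", g$gene_id))
    }
  }
  if (anyDuplicated(map_chr(genes, "gene_id"))) {
    abort("duplicate (overlapping) gene ids requested")
  }
  set.seed(seed)
  exon_rows <- list()
  cursor <- spacing
  for (g in genes) {
    n <- length(g$exon_lengths)
    starts <- integer(n)
    for (i in seq_len(n)) {
      starts[i] <- cursor
      cursor <- cursor + g$exon_lengths[i]
      if (i < n) cursor <- cursor + g$intron_lengths[i]
    }
    exon_rows[[g$gene_id]] <- tibble(
      transcript_id = paste0(g$gene_id, ".t1"), gene_id = g$gene_id,
      chrom = contig, start = starts, end = starts + g$exon_lengths,
      strand = "+"
    )
  }
  total <- cursor + spacing
  seq <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  catalog <- transcript_catalog(bind_rows(exon_rows))
  for (i in seq_len(nrow(catalog$introns))) {
    intr <- catalog$introns[i, ]
    seq[(intr$start + 1):(intr$start + 6)] <- c("G", "T", "A", "A", "G", "T")
    tract <- sample(c("C", "T"), 10, replace = TRUE)
    seq[(intr$end - 11):(intr$end - 2)] <- tract
    seq[(intr$end - 1):intr$end] <- c("A", "G")
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- contig
  list(genome = genome, catalog = catalog)
}

# genomic segments (ascending) making up a template
template_segments <- function(catalog, type, transcript_id,
                              circ_exons = NULL, retained_intron = NA) {
  ex <- filter(catalog$exons, .data$transcript_id == !!transcript_id)
  if (nrow(ex) == 0) abort(paste0("unknown transcript: ", transcript_id))
  if (ex$strand[1] != "+") {
    abort("the read simulator supports plus-strand transcripts only")
  }
  if (type == "linear") {
    return(select(ex, "chrom", "start", "end") |> mutate(kind = "exon"))
  }
  circ_exons <- circ_exons %||% c(2L, nrow(ex) - 1L)
  keep <- filter(ex, .data$exon_rank >= circ_exons[1],
                 .data$exon_rank <= circ_exons[2])
  if (nrow(keep) < 1) abort("circularised exon range is empty")
  segs <- select(keep, "chrom", "start", "end") |> mutate(kind = "exon")
  if (type == "eici") {
    intr <- filter(catalog$introns, .data$transcript_id == !!transcript_id,
                   .data$ordinal == retained_intron)
    if (nrow(intr) == 0) {
      abort(sprintf("retained intron ordinal %s not found in %s",
                    retained_intron, transcript_id))
    }
    if (intr$start < min(segs$start) || intr$end > max(segs$end)) {
      abort("retained intron lies outside the circularised exons")
    }
    segs <- bind_rows(segs,
                      select(intr, "chrom", "start", "end") |>
                        mutate(kind = "intron"))
  }
  arrange(segs, .data$start)
}

# map a template-coordinate interval [a, b) (no wrap) to genomic blocks
segs_to_blocks <- function(segs, a, b) {
  offs <- cumsum(c(0L, segs$end - segs$start))
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s0 <- offs[i]; s1 <- offs[i + 1]
    lo <- max(a, s0); hi <- min(b, s1)
    if (hi > lo) {
      out[[length(out) + 1]] <- c(segs$start[i] + (lo - s0),
                                  segs$start[i] + (hi - s0))
    }
  }
  do.call(rbind, out)
}

blocks_to_cigar <- function(blocks, lead_clip = 0L, tail_clip = 0L) {
  parts <- character(0)
  if (lead_clip > 0) parts <- c(parts, paste0(lead_clip, "S"))
  for (i in seq_len(nrow(blocks))) {
    if (i > 1) {
      parts <- c(parts, paste0(blocks[i, 1] - blocks[i - 1, 2], "N"))
    }
    parts <- c(parts, paste0(blocks[i, 2] - blocks[i, 1], "M"))
  }
  if (tail_clip > 0) parts <- c(parts, paste0(tail_clip, "S"))
  paste(parts, collapse = "")
}

# alignment record for one mate given its template interval (may wrap on
# circular templates); BSJ-crossing mates keep their longer arm aligned and
# the rest soft-clipped, emulating a local aligner at the junction
mate_alignment <- function(segs, tlen, a, len, circular) {
  b <- a + len
  if (!circular || b <= tlen) {
    blocks <- segs_to_blocks(segs, a, b)
    return(list(blocks = blocks, cigar = blocks_to_cigar(blocks),
                wraps = FALSE))
  }
  arm1 <- tlen - a
  arm2 <- b - tlen
  if (arm1 >= arm2) {
    blocks <- segs_to_blocks(segs, a, tlen)
    cigar <- blocks_to_cigar(blocks, tail_clip = arm2)
  } else {
    blocks <- segs_to_blocks(segs, 0L, arm2)
    cigar <- blocks_to_cigar(blocks, lead_clip = arm1)
  }
  list(blocks = blocks, cigar = cigar, wraps = TRUE)
}

circ_substr <- function(seq, tlen, a, len) {
  b <- a + len
  if (b <= tlen) {
    substr(seq, a + 1, b)
  } else {
    paste0(substr(seq, a + 1, tlen), substr(seq, 1, b - tlen))
  }
}

add_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

#' Simulate paired-end reads from linear, EcircRNA and EIciRNA templates
#'
#' Samples fragments (Gaussian length, truncated to
#' `[read_length, template length]`) from each template: spliced mRNA for
#' `linear`, circularised spliced exons for `ecirc` (fragments wrap the
#' back-splice junction), circularised exons plus one retained intron for
#' `eici`. Substitution errors are applied per base. Besides FASTQ-ready
#' read sets, the simulator emits genome alignments equivalent to a
#' splice-aware aligner's output (exact, since true origins are known; BSJ
#' -crossing mates are soft-clipped at the junction), a per-read truth
#' table, and a CIRI2-format truth BSJ table for the circular templates.
#'
#' @param genome,catalog From [make_toy_genome()].
#' @param templates Tibble with `template_id`, `type` (`linear`, `ecirc`,
#'   `eici`), `transcript_id`, `depth`, and for circular types optionally
#'   `circ_first_exon`, `circ_last_exon` (default second to second-last
#'   exon) and `retained_intron` (transcript-orientation intron ordinal,
#'   `eici` only).
#' @param read_length Read length in nt (default 150).
#' @param fragment_mean,fragment_sd Fragment length distribution (defaults
#'   300/30; the mean must be at least `read_length`; libraries with
#'   fragments well above 250 nt give the intron-side mate room to land in
#'   retained introns).
#' @param error_rate Per-base substitution rate (default 0.005).
#' @param seed RNG seed; identical seeds give identical output.
#' @return List: `reads1`/`reads2` (named character vectors, as sequenced),
#'   `truth` (read pair -> template, type, `crosses_bsj`,
#'   `covers_retained_intron`), `bsj_calls` (CIRI2-schema tibble as from
#'   [read_ciri2()]), `alignments` (tibble consumable by
#'   [intron_metrics()], with `seq`/`flag` columns for SAM export).
#' @export
simulate_reads <- function(genome, catalog, templates, read_length = 150L,
                           fragment_mean = 300, fragment_sd = 30,
                           error_rate = 0.005, seed = 1L) {
  if (fragment_mean < read_length) {
    abort("fragment_mean must be >= read_length")
  }
  set.seed(seed)
  reads1 <- character(); reads2 <- character()
  truth <- list(); aln <- list(); bsj <- list()
  for (ti in seq_len(nrow(templates))) {
    tmpl <- templates[ti, ]
    circular <- tmpl$type %in% c("ecirc", "eici")
    segs <- template_segments(
      catalog, tmpl$type, tmpl$transcript_id,
      circ_exons = if (circular && all(c("circ_first_exon", "circ_last_exon")
                                       %in% names(tmpl)))
        c(tmpl$circ_first_exon, tmpl$circ_last_exon) else NULL,
      retained_intron = if ("retained_intron" %in% names(tmpl))
        tmpl$retained_intron else NA
    )
    tseq <- paste0(map_chr(seq_len(nrow(segs)), function(i) {
      fetch_sequence(genome, segs$chrom[i], segs$start[i], segs$end[i], "+")
    }), collapse = "")
    tlen <- nchar(tseq)
    n_pairs <- max(0L, as.integer(round(tmpl$depth * tlen /
                                          (2 * read_length))))
    if (n_pairs == 0) next
    flen <- as.integer(round(rnorm(n_pairs, fragment_mean, fragment_sd)))
    flen <- pmin(pmax(flen, read_length), tlen)
    starts <- if (circular) {
      as.integer(floor(runif(n_pairs, 0, tlen)))
    } else {
      as.integer(floor(runif(n_pairs, 0, tlen - flen + 1)))
    }
    offs <- cumsum(c(0L, segs$end - segs$start))
    intr_rng <- if (tmpl$type == "eici") {
      i <- which(segs$kind == "intron")
      c(offs[i], offs[i + 1])
    } else NULL
    ids <- sprintf("%s_r%05d", tmpl$template_id, seq_len(n_pairs))
    crosses <- logical(n_pairs); covers <- logical(n_pairs)
    m1 <- vector("list", n_pairs); m2 <- vector("list", n_pairs)
    e1s <- character(n_pairs); e2s <- character(n_pairs)
    for (j in seq_len(n_pairs)) {
      a1 <- starts[j]
      a2 <- starts[j] + flen[j] - read_length
      if (circular) a2 <- a2 %% tlen
      r1 <- circ_substr(tseq, tlen, a1, read_length)
      r2 <- circ_substr(tseq, tlen, a2, read_length)
      e1s[j] <- add_errors(r1, error_rate)
      e2s[j] <- add_errors(revcomp(r2), error_rate)
      m1[[j]] <- mate_alignment(segs, tlen, a1, read_length, circular)
      m2[[j]] <- mate_alignment(segs, tlen, a2, read_length, circular)
      crosses[j] <- m1[[j]]$wraps || m2[[j]]$wraps
      if (!is.null(intr_rng)) {
        ov <- function(a) {
          b <- a + read_length
          pos <- c(a, if (b > tlen) 0 else NULL)
          end <- c(min(b, tlen), if (b > tlen) b - tlen else NULL)
          any(pos < intr_rng[2] & end > intr_rng[1])
        }
        covers[j] <- ov(a1) || ov(a2)
      }
    }
    reads1[ids] <- e1s
    reads2[ids] <- e2s
    aln_of <- function(mates, mate_no, strand, flag, seqs) {
      tibble(
        read_id = ids, mate = mate_no, chrom = segs$chrom[1],
        start = map_int(mates, ~ as.integer(.x$blocks[1, 1])),
        end = map_int(mates, ~ as.integer(.x$blocks[nrow(.x$blocks), 2])),
        strand = strand, mapq = 60L,
        cigar = map_chr(mates, "cigar"), flag = flag, seq = seqs
      )
    }
    aln[[tmpl$template_id]] <- bind_rows(
      aln_of(m1, 1L, "+", 99L, e1s),
      # SEQ stored on the reference strand for the reverse mate
      aln_of(m2, 2L, "-", 147L, revcomp(e2s))
    ) |> arrange(.data$read_id, .data$mate)
    truth[[tmpl$template_id]] <- tibble(
      read_id = ids, template_id = tmpl$template_id,
      template_type = tmpl$type, crosses_bsj = crosses,
      covers_retained_intron = covers
    )
    if (circular) {
      cs <- min(segs$start); ce <- max(segs$end)
      bsj[[tmpl$template_id]] <- tibble(
        circ_id = sprintf("%s:%d|%d", segs$chrom[1], cs + 1L, ce),
        chrom = segs$chrom[1], start = cs, end = ce, strand = "+",
        bsj_count = sum(crosses), circ_type = "exon",
        read_ids = list(ids[crosses])
      )
    }
  }
  list(reads1 = reads1, reads2 = reads2,
       truth = bind_rows(truth),
       bsj_calls = bind_rows(bsj),
       alignments = bind_rows(aln))
}

#' Write simulated reads as FASTQ
#'
#' Constant quality (Phred 30) strings; quality modelling is out of scope.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path (gzip-compressed when it ends in `.gz`).
#' @param suffix Read-name suffix, e.g. `"/1"`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, suffix = "") {
  lines <- as.vector(rbind(paste0("@", names(reads), suffix),
                           unname(reads),
                           "+",
                           strrep("?", nchar(reads))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' Write simulator alignments as SAM
#'
#' @param aln Alignment tibble from [simulate_reads()] (`$alignments`).
#' @param genome Genome `DNAStringSet` (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  aln <- arrange(aln, .data$read_id, .data$mate)
  pnext <- aln |>
    group_by(.data$read_id) |>
    mutate(pnext = rev(.data$start) + 1L) |>
    ungroup()
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s",
                  aln$read_id, aln$flag, aln$chrom, aln$start + 1L,
                  aln$mapq, aln$cigar, pnext$pnext, aln$seq,
                  strrep("?", nchar(aln$seq)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a labelled intron feature set
#'
#' Draws class-conditional Gaussian feature vectors whose mean shifts
#' follow the observed direction of effects: versus NCI, both CIR and LIR
#' introns are shorter, have weaker splice sites and higher GC; versus LIR,
#' CIR introns are longer, lower-GC and sit closer to the transcript
#' 5' end.
#'
#' @param n_per_class Rows per class (>= 10).
#' @param effect_size Shift magnitude in within-class standard deviations
#'   applied to the planted features (default 2; 0 makes classes
#'   indistinguishable).
#' @param seed RNG seed.
#' @return Tibble with `intron_id`, `label` and the feature columns of
#'   [extract_features()].
#' @export
make_feature_dataset <- function(n_per_class = 600L, effect_size = 2,
                                 seed = 1L) {
  if (n_per_class < 10) abort("need at least 10 rows per class")
  if (effect_size < 0) abort("effect_size must be non-negative")
  set.seed(seed)
  base <- tribble(
    ~feature, ~mean, ~sd,
    "intron_length_log10", 3.2, 0.4,
    "intron_gc", 0.45, 0.06,
    "rel_position", 0.5, 0.15,
    "ss5_score", 8, 2,
    "ss3_score", 8, 2,
    "up_exon_length_log10", 2.2, 0.25,
    "down_exon_length_log10", 2.2, 0.25,
    "up_exon_gc", 0.5, 0.05,
    "down_exon_gc", 0.5, 0.05
  )
  # per-class shifts in sd units (scaled by effect_size)
  shifts <- list(
    NCI = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    CIR = c(-1, 1, -0.5, -1, -1, 0, 0, 0, 0),
    LIR = c(-2, 2, 0.5, -1, -1, 0, 0, 0, 0)
  )
  rows <- imap(shifts, function(sh, cl) {
    m <- matrix(rnorm(n_per_class * nrow(base)), n_per_class)
    m <- sweep(m, 2, base$sd, "*")
    m <- sweep(m, 2, base$mean + sh * effect_size * base$sd, "+")
    colnames(m) <- base$feature
    out <- as_tibble(m)
    out$intron_gc <- pmin(pmax(out$intron_gc, 0.02), 0.98)
    out$up_exon_gc <- pmin(pmax(out$up_exon_gc, 0.02), 0.98)
    out$down_exon_gc <- pmin(pmax(out$down_exon_gc, 0.02), 0.98)
    out$rel_position <- pmin(pmax(out$rel_position, 0.01), 1)
    mutate(out, label = cl, .before = 1)
  })
  bind_rows(rows) |>
    mutate(intron_id = sprintf("synthetic_intron_%04d", row_number()),
           .before = 1)
}
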