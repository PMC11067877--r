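# Circular pseudo-references: rotation pad, read placement, back-projection
# and classification of BSJ read pairs for intronic evidence.

#' Build a rotated circular pseudo-reference for a circRNA
#'
#' Linearises the circle as the genomic span `[start, end)` followed by its
#' first `readlen - 1` bases again (the rotation pad, truncated to the circle
#' length), so any single read from the circle aligns contiguously and a read
#' crossing the back-splice junction does so exactly once. The junction sits
#' at pseudo-reference offset `end - start`.
#'
#' @param circ One-row tibble with `circ_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome [Biostrings::DNAStringSet] genome.
#' @param readlen Read length in nt (default 150).
#' @return Object of class `pseudo_ref`: list with `circ_id`, `chrom`,
#'   `start`, `end`, `circ_len`, `pad`, `junction_offset` and the pseudo
#'   sequence `seq` (plus strand).
#' @export
build_pseudo_reference <- function(circ, genome, readlen = 150L) {
  L <- circ$end - circ$start
  if (L < 20L) {
    abort(sprintf("circRNA span %d nt is too short to place reads (< 20 nt)", L))
  }
  if (readlen < 1L) abort("readlen must be >= 1")
  pad <- min(readlen - 1L, L)
  body <- fetch_sequence(genome, circ$chrom, circ$start, circ$end, "+")
  seq <- paste0(body, substr(body, 1L, pad))
  structure(
    list(circ_id = circ$circ_id, chrom = circ$chrom, start = circ$start,
         end = circ$end, circ_len = L, pad = pad, junction_offset = L,
         seq = seq),
    class = "pseudo_ref"
  )
}

#' Project pseudo-reference positions back to the genome
#'
#' Every pseudo-reference position maps to exactly one genomic position:
#' positions in the rotation pad wrap back to the circle start.
#'
#' @param pseudo A [build_pseudo_reference()] object.
#' @param pos Integer vector of 0-based pseudo-reference positions.
#' @return Integer vector of 0-based genomic positions on `pseudo$chrom`.
#' @export
project_to_genome <- function(pseudo, pos) {
  if (any(pos < 0 | pos >= pseudo$circ_len + pseudo$pad)) {
    abort("pseudo-reference position out of range")
  }
  as.integer(pseudo$start + ifelse(pos >= pseudo$circ_len,
                                   pos - pseudo$circ_len, pos))
}

# Exact k-mer seeded, ungapped placement of one read on the pseudo-reference.
# Seeds are non-overlapping k-mers along the read; each seed hit proposes an
# offset, candidates are scored by full-length Hamming distance. Returns the
# unique best placement or marks the read ambiguous/unplaced.
place_read <- function(seq, pseudo, k = 20L, max_mismatch_rate = 0.05) {
  n <- nchar(seq)
  ref_len <- nchar(pseudo$seq)
  unplaced <- tibble(offset = NA_integer_, strand = NA_character_,
                     mismatches = NA_integer_, status = "unplaced")
  if (n > ref_len) return(unplaced)
  # seeds tried in order; scanning stops at the first seed producing any
  # candidate (later seeds only rescue reads whose earlier seeds hold errors)
  candidates <- function(query) {
    seeds <- unique(c(seq(1L, max(1L, n - k + 1L), by = k), n - k + 1L))
    seeds <- seeds[seeds >= 1L & seeds + k - 1L <= n]
    for (s in seeds) {
      kmer <- substr(query, s, s + k - 1L)
      hits <- gregexpr(kmer, pseudo$seq, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      offs <- unique(as.integer(hits) - s)  # 0-based read start offset
      offs <- offs[offs >= 0L & offs + n <= ref_len]
      if (length(offs)) return(offs)
    }
    integer(0)
  }
  score <- function(query, off) {
    window <- substr(pseudo$seq, off + 1L, off + n)
    sum(charToRaw(query) != charToRaw(window))
  }
  offs <- list("+" = candidates(seq), "-" = candidates(revcomp(seq)))
  best <- bind_rows(imap(offs, function(o, str) {
    if (length(o) == 0) return(NULL)
    query <- if (str == "+") seq else revcomp(seq)
    tibble(offset = o, strand = str,
           mismatches = map_int(o, ~ score(query, .x)))
  }))
  max_mm <- floor(max_mismatch_rate * n)
  if (nrow(best) == 0) return(unplaced)
  best <- filter(best, .data$mismatches <= max_mm)
  if (nrow(best) == 0) return(unplaced)
  top <- filter(best, .data$mismatches == min(.data$mismatches))
  if (nrow(top) > 1) {
    return(mutate(unplaced, status = "ambiguous"))
  }
  mutate(top, status = "placed")
}

#' Place a read pair on a circular pseudo-reference
#'
#' Built-in ungapped placement: exact k-mer seeding plus full-length
#' mismatch scoring of each mate in both orientations, requiring the mates
#' to land on opposite strands (consistent with a circular template).
#' Reads with multiple equally good placements are reported `ambiguous`.
#'
#' @param mate1,mate2 DNA strings of the two mates (as sequenced).
#' @param pseudo A [build_pseudo_reference()] object.
#' @param k Seed length (default 20).
#' @param max_mismatch_rate Maximum tolerated mismatch fraction per mate
#'   (default 0.05).
#' @return Tibble with one row per mate: `mate`, `offset` (0-based start on
#'   the pseudo-reference), `strand`, `mismatches`, `status` in
#'   `{placed, ambiguous, unplaced}`, `len`.
#' @export
place_pair <- function(mate1, mate2, pseudo, k = 20L,
                       max_mismatch_rate = 0.05) {
  p1 <- place_read(mate1, pseudo, k, max_mismatch_rate)
  p2 <- place_read(mate2, pseudo, k, max_mismatch_rate)
  out <- bind_rows(mutate(p1, mate = 1L, len = nchar(mate1)),
                   mutate(p2, mate = 2L, len = nchar(mate2)))
  both <- all(out$status == "placed")
  if (both && out$strand[1] == out$strand[2]) {
    # orientation inconsistent with a paired-end fragment on the circle
    out$status <- "unplaced"
    out$offset <- NA_integer_
  }
  relocate(out, "mate")
}

# Project a placed mate (contiguous on the pseudo-reference) to genomic
# segments: at most two, when the mate wraps across the junction offset.
mate_segments <- function(offset, len, pseudo) {
  L <- pseudo$circ_len
  s <- offset
  e <- offset + len
  if (e <= L) {
    tibble(gstart = pseudo$start + s, gend = pseudo$start + e)
  } else if (s >= L) {
    tibble(gstart = pseudo$start + s - L, gend = pseudo$start + e - L)
  } else {
    tibble(gstart = c(pseudo$start + s, pseudo$start),
           gend = c(pseudo$start + L, pseudo$start + e - L))
  }
}

#' Classify a placed BSJ read pair against a circRNA's internal introns
#'
#' Projects each placed mate's aligned bases back to genomic coordinates and
#' assigns the pair one category: `intronic` if some mate lies entirely
#' within one internal intron; `exon_intron_junction` if some mate spans an
#' exon/intron boundary with at least `overhang` aligned bases on both
#' sides; `exonic_only` otherwise; `unplaced` when no mate placed.
#' `crosses_bsj` records whether any mate wraps the back-splice junction.
#'
#' @param placement Tibble from [place_pair()].
#' @param pseudo The pseudo-reference the pair was placed on.
#' @param introns Tibble of the circRNA's internal introns (genomic
#'   coordinates, from [assign_hosts()]).
#' @param overhang Minimum aligned bases on each side of an exon/intron
#'   boundary (default 5).
#' @return One-row tibble: `circ_id`, `category`, `supporting_introns`
#'   (list of intron ids), `crosses_bsj`.
#' @export
classify_pair <- function(placement, pseudo, introns, overhang = 5L) {
  placed <- filter(placement, .data$status == "placed")
  if (nrow(placed) == 0) {
    return(tibble(circ_id = pseudo$circ_id, category = "unplaced",
                  supporting_introns = list(character()),
                  crosses_bsj = FALSE))
  }
  crosses <- any(placed$offset < pseudo$junction_offset &
                   placed$offset + placed$len > pseudo$junction_offset)
  intronic_ids <- character(0)
  junction_ids <- character(0)
  for (j in seq_len(nrow(placed))) {
    segs <- mate_segments(placed$offset[j], placed$len[j], pseudo)
    if (nrow(introns) == 0) next
    if (nrow(segs) == 1) {
      inside <- introns$start <= segs$gstart & introns$end >= segs$gend
      intronic_ids <- c(intronic_ids, introns$intron_id[inside])
    }
    for (b in seq_len(nrow(segs))) {
      gs <- segs$gstart[b]; ge <- segs$gend[b]
      hit5 <- gs <= introns$start - overhang & ge >= introns$start + overhang
      hit3 <- gs <= introns$end - overhang & ge >= introns$end + overhang
      junction_ids <- c(junction_ids, introns$intron_id[hit5 | hit3])
    }
  }
  if (length(intronic_ids)) {
    category <- "intronic"; support <- unique(intronic_ids)
  } else if (length(junction_ids)) {
    category <- "exon_intron_junction"; support <- unique(junction_ids)
  } else {
    category <- "exonic_only"; support <- character(0)
  }
  tibble(circ_id = pseudo$circ_id, category = category,
         supporting_introns = list(support), crosses_bsj = crosses)
}

#' Extract BSJ-supporting read pairs for circRNA calls
#'
#' Pulls both mates of every read pair named in a call's BSJ read-id list
#' from name-indexed read sets. Listed ids missing from the input are
#' skipped with a warning.
#'
#' @param calls Tibble of calls with list column `read_ids`.
#' @param reads1,reads2 Named character vectors or `DNAStringSet`s of mate 1
#'   and mate 2 sequences, names = read ids.
#' @return Tibble: `circ_id`, `read_id`, `seq1`, `seq2`.
#' @export
extract_bsj_read_pairs <- function(calls, reads1, reads2) {
  to_named <- function(r) {
    out <- as.character(r)
    if (is.null(names(out))) names(out) <- names(r)
    out
  }
  reads1 <- to_named(reads1); reads2 <- to_named(reads2)
  rows <- map(seq_len(nrow(calls)), function(i) {
    ids <- calls$read_ids[[i]]
    if (length(ids) == 0) {
      warn(sprintf("call %s lists no BSJ read ids; dropped", calls$circ_id[i]))
      return(NULL)
    }
    present <- ids %in% names(reads1) & ids %in% names(reads2)
    if (any(!present)) {
      warn(sprintf("%d BSJ read id(s) of %s absent from input; skipped",
                   sum(!present), calls$circ_id[i]))
    }
    ids <- ids[present]
    tibble(circ_id = calls$circ_id[i], read_id = ids,
           seq1 = unname(reads1[ids]), seq2 = unname(reads2[ids]))
  })
  bind_rows(rows)
}

#' Collect pair evidence for the calls of one sample
#'
#' Convenience wrapper running [build_pseudo_reference()], [place_pair()]
#' and [classify_pair()] over every call and its extracted BSJ pairs.
#'
#' @param calls Calls tibble (already filtered to `circ_type == "exon"`).
#' @param assignments Host assignments from [assign_hosts()].
#' @param pairs Tibble from [extract_bsj_read_pairs()].
#' @param genome Genome `DNAStringSet`.
#' @param readlen Read length used for the rotation pad.
#' @param overhang Junction overhang (default 5).
#' @param max_mismatch_rate Placement mismatch tolerance.
#' @return Tibble of pair evidence: `circ_id`, `read_id`, `category`,
#'   `supporting_introns`, `crosses_bsj`.
#' @export
collect_pair_evidence <- function(calls, assignments, pairs, genome,
                                  readlen = 150L, overhang = 5L,
                                  max_mismatch_rate = 0.05) {
  rows <- map(seq_len(nrow(calls)), function(i) {
    circ <- calls[i, ]
    asn <- filter(assignments, .data$circ_id == circ$circ_id)
    if (nrow(asn) == 0 || asn$unannotated[1]) return(NULL)
    my_pairs <- filter(pairs, .data$circ_id == circ$circ_id)
    if (nrow(my_pairs) == 0) return(NULL)
    pseudo <- build_pseudo_reference(circ, genome, readlen)
    introns <- asn$internal_introns[[1]]
    bind_rows(map(seq_len(nrow(my_pairs)), function(j) {
      pl <- place_pair(my_pairs$seq1[j], my_pairs$seq2[j], pseudo,
                       max_mismatch_rate = max_mismatch_rate)
      classify_pair(pl, pseudo, introns, overhang) |>
        mutate(read_id = my_pairs$read_id[j], .after = "circ_id")
    }))
  })
  bind_rows(rows)
}

#' Enumerate candidate EIciRNAs from pair evidence
#'
#' A (circRNA, intron) candidate exists when at least `min_support` BSJ read
#' pairs carry `intronic` or `exon_intron_junction` evidence naming that
#' intron.
#'
#' @param evidence Tibble from [collect_pair_evidence()].
#' @param min_support Minimum qualifying pairs (default 1).
#' @return Tibble: `circ_id`, `intron_id`, `support` (qualifying pair
#'   count).
#' @export
candidate_eicirnas <- function(evidence, min_support = 1L) {
  if (nrow(evidence) == 0) {
    return(tibble(circ_id = character(), intron_id = character(),
                  support = integer()))
  }
  evidence |>
    filter(.data$category %in% c("intronic", "exon_intron_junction")) |>
    select("circ_id", "read_id", "supporting_introns") |>
    tidyr::unnest_longer("supporting_introns", values_to = "intron_id") |>
    distinct(.data$circ_id, .data$read_id, .data$intron_id) |>
    count(.data$circ_id, .data$intron_id, name = "support") |>
    filter(.data$support >= min_support)
}
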