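# Host-transcript assignment for circRNA BSJ calls.

#' Score a transcript against a circRNA call
#'
#' Boundary-match score used to pick host transcripts: 2 if both the circRNA
#' start and end coincide exactly with exon boundaries of the transcript
#' (start with an exon start, end with an exon end), 1 if exactly one
#' boundary matches, 0 otherwise. Matching is exact (no tolerance): BSJ
#' coordinates from splice-site-anchored callers are expected to be precise.
#'
#' @param circ One-row tibble (or list) with `chrom`, `start`, `end`.
#' @param exons Tibble of the transcript's exons (`chrom`, `start`, `end`).
#' @return Integer score in `{0, 1, 2}`.
#' @export
score_transcript <- function(circ, exons) {
  if (nrow(exons) == 0) return(0L)
  if (any(exons$chrom != circ$chrom)) {
    abort("circRNA and transcript are on different contigs")
  }
  start_hit <- circ$start %in% exons$start
  end_hit <- circ$end %in% exons$end
  as.integer(start_hit) + as.integer(end_hit)
}

#' Assign host transcripts to circRNA calls
#'
#' For every call, scores all overlapping transcripts with
#' [score_transcript()] and keeps every transcript achieving the maximal
#' score (ties are all retained and their internal introns unioned;
#' `tie_rule = "intersect"` intersects them instead). Internal introns are
#' the host introns fully contained in the circRNA span, deduplicated by
#' coordinates. Calls overlapping no transcript are flagged `unannotated`
#' and carry no hosts.
#'
#' @param calls Tibble of calls as from [read_ciri2()].
#' @param catalog A [transcript_catalog()].
#' @param stranded If `TRUE` (default), hosts must match the call strand
#'   unless the call strand is `"."`, which matches either.
#' @param tie_rule `"union"` (default) or `"intersect"`: how internal-intron
#'   sets of equally scored hosts are combined.
#' @return Tibble with one row per call: `circ_id`, `score`,
#'   `host_transcripts` (list of transcript ids), `unannotated`, and a list
#'   column `internal_introns` of intron tibbles.
#' @export
assign_hosts <- function(calls, catalog, stranded = TRUE,
                         tie_rule = c("union", "intersect")) {
  tie_rule <- match.arg(tie_rule)
  tx <- catalog$transcripts
  rows <- map(seq_len(nrow(calls)), function(i) {
    circ <- calls[i, ]
    cand <- filter(tx, .data$chrom == circ$chrom,
                   .data$start < circ$end, .data$end > circ$start)
    if (stranded && circ$strand %in% c("+", "-")) {
      cand <- filter(cand, .data$strand == circ$strand)
    }
    if (nrow(cand) == 0) {
      return(tibble(circ_id = circ$circ_id, score = NA_integer_,
                    host_transcripts = list(character()),
                    unannotated = TRUE,
                    internal_introns = list(empty_introns())))
    }
    scores <- map_int(cand$transcript_id, function(tid) {
      score_transcript(circ, filter(catalog$exons, .data$transcript_id == tid))
    })
    best <- max(scores)
    hosts <- cand$transcript_id[scores == best]
    intr_sets <- map(hosts, function(tid) {
      filter(catalog$introns, .data$transcript_id == tid,
             .data$start >= circ$start, .data$end <= circ$end)
    })
    introns <- bind_rows(intr_sets)
    if (tie_rule == "intersect" && length(intr_sets) > 1) {
      keys <- map(intr_sets, ~ .x$intron_id)
      shared <- Reduce(intersect, keys)
      introns <- filter(introns, .data$intron_id %in% shared)
    }
    introns <- distinct(introns, .data$intron_id, .keep_all = TRUE)
    tibble(circ_id = circ$circ_id, score = best,
           host_transcripts = list(hosts), unannotated = FALSE,
           internal_introns = list(select(introns, -"transcript_id")))
  })
  bind_rows(rows)
}

empty_introns <- function() {
  tibble(intron_id = character(), chrom = character(), start = integer(),
         end = integer(), strand = character(), ordinal = integer(),
         n_introns = integer())
}

#' Write a host-assignment report
#'
#' @param assignments Tibble from [assign_hosts()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_host_report <- function(assignments, path) {
  tab <- tibble(
    circ_id = assignments$circ_id,
    score = assignments$score,
    host_transcripts = map_chr(assignments$host_transcripts, paste,
                               collapse = ","),
    n_internal_introns = map_int(assignments$internal_introns, nrow)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
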