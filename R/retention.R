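# Per-intron retention metrics from genome alignments (#EE, #EI, #IE, #I,
# #IC), percent intron retention, validation and CIR/NCI/LIR class labels.

#' Compute per-intron retention metrics
#'
#' For each intron, counts from genome alignments:
#' * `EE` — spliced reads whose `N` gap spans the intron exactly, with at
#'   least `overhang` aligned bases flanking both ends;
#' * `EI` / `IE` — unspliced reads with a contiguous aligned block crossing
#'   the exon-to-intron (resp. intron-to-exon) boundary with at least
#'   `overhang` aligned bases on each side;
#' * `I` — reads with at least one aligned base in the middle `window` nt of
#'   the intron (whole intron when shorter) whose blocks overlapping the
#'   intron lie entirely within it;
#' * `IC` — fraction of intron positions covered by at least one aligned
#'   block, using all primary alignments.
#' A read with an exactly matching gap counts toward `EE` only.
#'
#' All alignments passing the `min_mapq` filter contribute, regardless of
#' BSJ status: linear reads legitimately add to the metrics.
#'
#' @param aln Alignment tibble from [read_alignments()] or the simulator.
#' @param introns Tibble of introns (`intron_id`, `chrom`, `start`, `end`).
#' @param overhang Minimum junction overhang in nt (default 5).
#' @param window Middle-window size in nt (default 200).
#' @param min_mapq Alignments below this mapping quality are ignored
#'   (default 1, excluding typical multi-mappers).
#' @return Tibble: `intron_id`, `chrom`, `start`, `end`, `EE`, `EI`, `IE`,
#'   `I`, `IC`, `PIR`.
#' @export
intron_metrics <- function(aln, introns, overhang = 5L, window = 200L,
                           min_mapq = 1L) {
  aln <- filter(aln, .data$mapq >= min_mapq)
  blocks <- alignment_blocks(aln)
  # per-alignment N gaps = spaces between consecutive blocks
  gaps <- blocks |>
    group_by(.data$aln_idx) |>
    filter(n() > 1) |>
    summarise(
      read_id = .data$read_id[1], chrom = .data$chrom[1],
      gap_start = list(head(.data$block_end, -1)),
      gap_end = list(.data$block_start[-1]),
      left_w = list(head(.data$block_end - .data$block_start, -1)),
      right_w = list((.data$block_end - .data$block_start)[-1]),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("gap_start", "gap_end", "left_w", "right_w"))

  out <- map(seq_len(nrow(introns)), function(i) {
    intr <- introns[i, ]
    ilen <- intr$end - intr$start
    g <- filter(gaps, .data$chrom == intr$chrom,
                .data$gap_start == intr$start, .data$gap_end == intr$end,
                .data$left_w >= overhang, .data$right_w >= overhang)
    ee_alns <- unique(g$aln_idx)

    b <- filter(blocks, .data$chrom == intr$chrom,
                .data$block_start < intr$end, .data$block_end > intr$start)
    ei <- b |>
      filter(.data$block_start <= intr$start - overhang,
             .data$block_end >= intr$start + overhang,
             !.data$aln_idx %in% ee_alns)
    ie <- b |>
      filter(.data$block_start <= intr$end - overhang,
             .data$block_end >= intr$end + overhang,
             !.data$aln_idx %in% ee_alns)

    # middle window
    wlen <- min(window, ilen)
    wstart <- intr$start + (ilen - wlen) %/% 2L
    wend <- wstart + wlen
    imid <- b |>
      group_by(.data$aln_idx) |>
      summarise(
        contained = all(.data$block_start >= intr$start &
                          .data$block_end <= intr$end),
        in_window = any(.data$block_start < wend & .data$block_end > wstart),
        .groups = "drop"
      ) |>
      filter(.data$contained, .data$in_window)

    covered <- 0L
    if (nrow(b) > 0) {
      clipped <- IRanges::IRanges(pmax(b$block_start, intr$start) + 1L,
                                  pmin(b$block_end, intr$end))
      covered <- sum(IRanges::width(IRanges::reduce(clipped)))
    }

    tibble(intron_id = intr$intron_id, chrom = intr$chrom,
           start = intr$start, end = intr$end,
           EE = length(ee_alns),
           EI = length(unique(ei$aln_idx)),
           IE = length(unique(ie$aln_idx)),
           I = nrow(imid),
           IC = covered / ilen)
  })
  bind_rows(out) |>
    mutate(PIR = compute_pir(.data$EI, .data$IE, .data$EE))
}

#' Percent intron retention from junction counts
#'
#' Junction-based retention ratio `PIR = m / (m + EE)` with
#' `m = (EI + IE) / 2`; defined as 0 when no junction read of either kind is
#' observed.
#'
#' @param EI,IE,EE Non-negative junction read counts (vectorised).
#' @return Numeric vector of PIR values in `[0, 1]`.
#' @export
compute_pir <- function(EI, IE, EE) {
  m <- (EI + IE) / 2
  ifelse(m == 0 & EE == 0, 0, m / (m + EE))
}

#' Default retention validation thresholds
#'
#' `EE >= 1`, `EI >= 1`, `IE >= 1`, `I >= 1`, `IC >= 0.9`.
#'
#' @return Named list of thresholds.
#' @export
retention_thresholds <- function() {
  list(EE = 1L, EI = 1L, IE = 1L, I = 1L, IC = 0.9)
}

#' Validate intron retention
#'
#' An intron is considered retained when all five metric thresholds hold.
#'
#' @param metrics Tibble from [intron_metrics()].
#' @param thresholds Named list as [retention_thresholds()].
#' @return `metrics` with a logical `valid` column.
#' @export
validate_retention <- function(metrics, thresholds = retention_thresholds()) {
  mutate(metrics,
         valid = .data$EE >= thresholds$EE & .data$EI >= thresholds$EI &
           .data$IE >= thresholds$IE & .data$I >= thresholds$I &
           .data$IC >= thresholds$IC)
}

#' Call EIciRNAs from candidates and retention metrics
#'
#' Joins step-2 candidates with per-intron retention metrics and emits one
#' record per (circRNA, validated intron). The BSJ count of a record is the
#' number of BSJ read pairs that qualified in step 2 (the candidate's
#' support).
#'
#' @param candidates Tibble from [candidate_eicirnas()].
#' @param metrics Tibble from [intron_metrics()] covering the candidate
#'   introns.
#' @param calls Calls tibble (for coordinates/strand).
#' @param assignments Host assignments from [assign_hosts()].
#' @param thresholds Validation thresholds ([retention_thresholds()]).
#' @return Tibble of EIciRNA records: circRNA coordinates, host
#'   transcripts, retained intron coordinates, the five metrics, `PIR` and
#'   `bsj_count`.
#' @export
call_eicirnas <- function(candidates, metrics, calls, assignments,
                          thresholds = retention_thresholds()) {
  empty <- tibble(circ_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  host_transcripts = list(), intron_id = character(),
                  intron_start = integer(), intron_end = integer(),
                  EE = integer(), EI = integer(), IE = integer(),
                  I = integer(), IC = double(), PIR = double(),
                  bsj_count = integer())
  if (nrow(candidates) == 0) return(empty)
  validated <- validate_retention(metrics, thresholds) |>
    filter(.data$valid) |>
    select("intron_id", intron_start = "start", intron_end = "end",
           "EE", "EI", "IE", "I", "IC", "PIR")
  recs <- candidates |>
    inner_join(validated, by = "intron_id") |>
    inner_join(select(calls, "circ_id", "chrom", "start", "end", "strand"),
               by = "circ_id") |>
    left_join(select(assignments, "circ_id", "host_transcripts"),
              by = "circ_id")
  if (nrow(recs) == 0) return(empty)
  recs |>
    transmute(.data$circ_id, .data$chrom, .data$start, .data$end,
              .data$strand, host_transcripts = .data$host_transcripts,
              .data$intron_id, .data$intron_start, .data$intron_end,
              .data$EE, .data$EI, .data$IE, .data$I, .data$IC, .data$PIR,
              bsj_count = .data$support)
}

#' Label introns as CIR, NCI or LIR
#'
#' Applies the class cutoffs: `CIR` for introns retained in circRNAs
#' (validated, circ-context `PIR >= 0.1`), `NCI` for introns internal to an
#' EcircRNA with circ-context `PIR <= 0.02`, `LIR` for introns with linear
#' `IRratio >= 0.1` (computed with the same junction-based ratio on the
#' linear library). An intron meeting several definitions receives all
#' matching labels; one meeting none is `unclassified`.
#'
#' @param circ_metrics Validated circ-context metrics
#'   ([validate_retention()] output) for candidate CIR introns.
#' @param ecirc_introns Character vector of intron ids internal to
#'   EcircRNAs.
#' @param linear_metrics Linear-library metrics ([intron_metrics()]) for the
#'   same introns (may be empty).
#' @param cir_cutoff,nci_cutoff,lir_cutoff Class cutoffs (defaults 0.1,
#'   0.02, 0.1).
#' @return Tibble: `intron_id`, `label`, `value` (the supporting PIR or
#'   IRratio).
#' @export
label_intron_classes <- function(circ_metrics, ecirc_introns = character(),
                                 linear_metrics = NULL,
                                 cir_cutoff = 0.1, nci_cutoff = 0.02,
                                 lir_cutoff = 0.1) {
  labels <- list()
  if (nrow(circ_metrics) > 0) {
    if (!"valid" %in% names(circ_metrics)) {
      circ_metrics <- validate_retention(circ_metrics)
    }
    labels$cir <- circ_metrics |>
      filter(.data$valid, .data$PIR >= cir_cutoff) |>
      transmute(.data$intron_id, label = "CIR", value = .data$PIR)
    labels$nci <- circ_metrics |>
      filter(.data$intron_id %in% ecirc_introns, .data$PIR <= nci_cutoff) |>
      transmute(.data$intron_id, label = "NCI", value = .data$PIR)
  }
  if (!is.null(linear_metrics) && nrow(linear_metrics) > 0) {
    labels$lir <- linear_metrics |>
      filter(.data$PIR >= lir_cutoff) |>
      transmute(.data$intron_id, label = "LIR", value = .data$PIR)
  }
  out <- bind_rows(labels)
  seen <- unique(c(circ_metrics$intron_id,
                   if (!is.null(linear_metrics)) linear_metrics$intron_id))
  rest <- setdiff(seen, out$intron_id)
  bind_rows(out, tibble(intron_id = rest, label = "unclassified",
                        value = NA_real_))
}
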