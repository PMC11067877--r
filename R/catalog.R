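# Transcript catalog: exon/intron structure derived from a GTF.

#' Build a transcript catalog from an exon table
#'
#' Constructs the package's annotation container from a tibble of exons in
#' internal coordinates (0-based half-open). Introns are derived per
#' transcript as the gaps between consecutive exons; their ordinal follows
#' transcript orientation (reverse-numbered on the minus strand).
#'
#' @param exons Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (one row per exon, 0-based half-open).
#' @return An object of class `transcript_catalog`: a list with tibbles
#'   `exons` (sorted, with `exon_rank` in genomic order), `introns`
#'   (with `intron_id` and `ordinal`) and `transcripts` (spans).
#' @export
transcript_catalog <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(exons))
  if (length(missing)) {
    abort(paste0("exon table lacks columns: ", paste(missing, collapse = ", ")))
  }
  exons <- as_tibble(exons) |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = seq_len(n())) |>
    ungroup()
  if (any(exons$end <= exons$start)) abort("exon with end <= start")
  ov <- exons |>
    group_by(.data$transcript_id) |>
    summarise(bad = any(.data$start[-1] < head(.data$end, -1)), .groups = "drop")
  if (any(ov$bad)) {
    abort(paste0("overlapping exons in transcript(s): ",
                 paste(ov$transcript_id[ov$bad], collapse = ", ")))
  }
  transcripts <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = suppressWarnings(min(.data$start)),
              end = suppressWarnings(max(.data$end)),
              n_exons = n(), .groups = "drop")
  introns <- exons |>
    group_by(.data$transcript_id) |>
    group_modify(~ derive_introns(.x)) |>
    ungroup() |>
    relocate("transcript_id")
  structure(
    list(exons = exons, introns = introns, transcripts = transcripts),
    class = "transcript_catalog"
  )
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("<transcript_catalog> %d transcripts, %d exons, %d introns\n",
              nrow(x$transcripts), nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Derive introns from the exons of one transcript
#'
#' Given the exons of a single transcript, returns the n - 1 gaps between
#' consecutive exons. The ordinal is 1-based 5' to 3' in transcript
#' orientation, so it counts from the rightmost intron on the minus strand.
#' Zero-length gaps (abutting exons) are dropped with a warning.
#'
#' @param exons Tibble of one transcript's exons (`chrom`, `start`, `end`,
#'   `strand`, optionally `gene_id`).
#' @return Tibble with `intron_id`, `chrom`, `start`, `end`, `strand`,
#'   `ordinal`, `n_introns` (introns of the transcript after dropping
#'   zero-length gaps).
#' @export
derive_introns <- function(exons) {
  empty <- tibble(intron_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  ordinal = integer(), n_introns = integer())
  if (nrow(exons) < 2) return(empty)
  exons <- arrange(exons, .data$start)
  gap_start <- head(exons$end, -1)
  gap_end <- exons$start[-1]
  keep <- gap_end > gap_start
  if (any(!keep)) {
    warn(sprintf("%d abutting exon pair(s) produced no intron", sum(!keep)))
  }
  if (!any(keep)) return(empty)
  strand <- exons$strand[1]
  out <- tibble(
    chrom = exons$chrom[1],
    start = as.integer(gap_start[keep]),
    end = as.integer(gap_end[keep]),
    strand = strand
  )
  n <- nrow(out)
  out$ordinal <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
  out$n_introns <- n
  out$intron_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  relocate(out, "intron_id")
}

#' Read a GTF annotation into a transcript catalog
#'
#' Parses exon records of a GENCODE-style GTF (1-based closed coordinates)
#' and converts them to the internal 0-based half-open convention.
#' Single-exon transcripts are retained (they simply contribute no introns).
#'
#' @param path Path to a GTF file.
#' @return A [transcript_catalog()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(body)[which(nf != 9)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                  bad, nf[which(nf != 9)[1]]))
  }
  if (!any(body)) {
    return(transcript_catalog(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    return(transcript_catalog(tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()
    )))
  }
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    abort("GTF exon record without transcript_id attribute")
  }
  gid <- gr$gene_id %||% tid
  tibble(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    mutate(strand = ifelse(.data$strand == "*", ".", .data$strand)) |>
    transcript_catalog()
}

#' Write a transcript catalog as GTF
#'
#' Emits one `exon` feature per exon, converting back to 1-based closed
#' coordinates. Round-trips with [read_gtf()].
#'
#' @param catalog A [transcript_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path) {
  ex <- catalog$exons
  lines <- sprintf(
    '%s\teicir\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number "%d";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    ex$exon_rank
  )
  writeLines(lines, path)
  invisible(path)
}
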