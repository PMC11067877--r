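# Genome alignments (SAM/BAM) as a tidy per-record table.

#' Read genome alignments from SAM or BAM
#'
#' Loads primary mapped records into a tibble, one row per aligned segment.
#' Unmapped, secondary and supplementary records are excluded by default.
#' SAM input is converted through [Rsamtools::asBam()] (which also sorts and
#' indexes), so region queries work on SAM files too; BAM input queried by
#' region must be coordinate-sorted and indexed.
#'
#' @param path Path to a SAM or BAM file.
#' @param region Optional list/tibble with `chrom`, `start`, `end` (0-based
#'   half-open) restricting the query.
#' @param include_secondary Keep secondary/supplementary records (default
#'   `FALSE`).
#' @param min_mapq Minimum mapping quality to keep (default 0; retention
#'   metrics apply their own stricter default).
#' @return Tibble with `read_id`, `mate` (1/2), `chrom`, `start`, `end`
#'   (0-based half-open span on the reference), `strand`, `mapq`, `cigar`.
#'   Aligned blocks are derived from the CIGAR with [alignment_blocks()].
#' @export
read_alignments <- function(path, region = NULL, include_secondary = FALSE,
                            min_mapq = 0L) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (include_secondary) NA else FALSE,
    isSupplementaryAlignment = if (include_secondary) NA else FALSE
  )
  param_args <- list(what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
                     flag = flags)
  if (!is.null(region)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      abort(paste0("region queries need a BAM index; run samtools index on ",
                   bam))
    }
    param_args$which <- GenomicRanges::GRanges(
      region$chrom, IRanges::IRanges(region$start + 1L, region$end))
  }
  param <- do.call(Rsamtools::ScanBamParam, param_args)
  recs <- Rsamtools::scanBam(bam, param = param)
  recs <- purrr::list_transpose(map(recs, ~ map(.x, identity)))
  recs <- map(recs, ~ unlist(.x, use.names = FALSE))
  flag <- recs$flag
  if (length(flag) == 0) {
    return(tibble(read_id = character(), mate = integer(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  mapq = integer(), cigar = character()))
  }
  refwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(recs$cigar)
  out <- tibble(
    read_id = recs$qname,
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    chrom = as.character(recs$rname),
    start = recs$pos - 1L,
    end = recs$pos - 1L + refwidth,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(recs$mapq),
    cigar = recs$cigar
  )
  filter(out, .data$mapq >= min_mapq) |> distinct()
}

#' Derive aligned reference blocks from CIGAR strings
#'
#' Splits each alignment into contiguous reference blocks at `N` (splice)
#' operations; `D` consumes reference within a block, and `I`/`S`/`H` consume
#' none. Returns a flat table for vectorised downstream counting.
#'
#' @param aln Alignment tibble from [read_alignments()].
#' @return Tibble with one row per block: `aln_idx` (row of `aln`),
#'   `read_id`, `mate`, `chrom`, `mapq`, `block_start`, `block_end`
#'   (0-based half-open), `block_i`, `n_blocks`.
#' @export
alignment_blocks <- function(aln) {
  if (nrow(aln) == 0) {
    return(tibble(aln_idx = integer(), read_id = character(), mate = integer(),
                  chrom = character(), mapq = integer(),
                  block_start = integer(), block_end = integer(),
                  block_i = integer(), n_blocks = integer()))
  }
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$start + 1L, ops = c("M", "D", "=", "X"),
    reduce.ranges = TRUE)
  n <- S4Vectors::elementNROWS(rl)
  flat <- as.data.frame(rl)
  idx <- rep(seq_len(nrow(aln)), n)
  tibble(
    aln_idx = idx,
    read_id = aln$read_id[idx],
    mate = aln$mate[idx],
    chrom = aln$chrom[idx],
    mapq = aln$mapq[idx],
    block_start = flat$start - 1L,
    block_end = flat$end,
    block_i = sequence(n),
    n_blocks = rep(n, n)
  )
}
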