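# CIRI2-format BSJ call tables and BED export.

ciri2_required <- c("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                    "#junction_reads", "circRNA_type", "strand",
                    "junction_reads_ID")

#' Read a CIRI2 output table of circRNA BSJ calls
#'
#' Parses the tab-separated CIRI2 result table. Input coordinates are 1-based
#' inclusive and converted to 0-based half-open. Rows are preserved in input
#' order; no type filtering is applied here (selecting `circRNA_type ==
#' "exon"` is a downstream step).
#'
#' @param path Path to a CIRI2 output table (tab-separated, with header).
#' @return Tibble with one row per call: `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `bsj_count`, `circ_type` and a list column `read_ids` of
#'   BSJ-supporting read names (may be empty).
#' @export
read_ciri2 <- function(path) {
  if (!file.exists(path)) abort(paste0("CIRI2 table not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(ciri2_required, names(tab))
  if (length(missing)) {
    abort(paste0("CIRI2 table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  counts <- suppressWarnings(as.integer(tab$`#junction_reads`))
  starts <- suppressWarnings(as.integer(tab$circRNA_start))
  ends <- suppressWarnings(as.integer(tab$circRNA_end))
  bad <- which(is.na(counts) | is.na(starts) | is.na(ends))
  if (length(bad)) {
    abort(sprintf("non-integer coordinate or count in CIRI2 table, line %d",
                  bad[1] + 1L))
  }
  read_ids <- strsplit(dplyr::coalesce(tab$junction_reads_ID, ""), ",",
                       fixed = TRUE)
  read_ids <- map(read_ids, function(x) x[nzchar(x)])
  tibble(
    circ_id = tab$circRNA_ID,
    chrom = tab$chr,
    start = starts - 1L,   # 1-based inclusive -> 0-based half-open
    end = ends,
    strand = tab$strand,
    bsj_count = counts,
    circ_type = tab$circRNA_type,
    read_ids = read_ids
  )
}

#' Write circRNA calls as a CIRI2-format table
#'
#' Inverse of [read_ciri2()] on the columns this package uses; the remaining
#' CIRI2 columns are emitted as placeholders so the file parses as a valid
#' CIRI2 table.
#'
#' @param calls Tibble as returned by [read_ciri2()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ciri2 <- function(calls, path) {
  tab <- tibble(
    circRNA_ID = calls$circ_id,
    chr = calls$chrom,
    circRNA_start = calls$start + 1L,
    circRNA_end = calls$end,
    `#junction_reads` = calls$bsj_count,
    SM_MS_SMS = "0_0_0",
    `#non_junction_reads` = 0L,
    junction_reads_ratio = 1,
    gene_id = "n/a",
    strand = calls$strand,
    circRNA_type = calls$circ_type,
    junction_reads_ID = map_chr(calls$read_ids, paste, collapse = ",")
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Export circRNA calls as BED6
#'
#' @param calls Tibble as returned by [read_ciri2()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   calls$chrom, calls$start, calls$end, calls$circ_id,
                   calls$bsj_count, calls$strand)
  writeLines(lines, path)
  invisible(path)
}
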