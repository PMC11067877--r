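# Cross-sample quantification: BRPM, expression matrices, tau.

#' Back-spliced reads per million mapped reads
#'
#' `BRPM = bsj_count / total_mapped_reads * 1e6`. The denominator is the
#' library's total primary mapped read count, depth-normalising across
#' libraries.
#'
#' @param bsj_count Non-negative integer vector of BSJ read counts.
#' @param total_mapped_reads Positive total mapped reads of the library.
#' @return Numeric vector of BRPM values.
#' @export
brpm <- function(bsj_count, total_mapped_reads) {
  if (any(total_mapped_reads <= 0)) {
    abort("total_mapped_reads must be positive")
  }
  if (any(bsj_count < 0)) abort("bsj_count must be non-negative")
  bsj_count / total_mapped_reads * 1e6
}

#' Build a feature-by-sample expression matrix from EIciRNA records
#'
#' Features are EIciRNAs keyed by BSJ plus retained-intron coordinates; the
#' union over samples is taken and absent features get 0.
#'
#' @param records Named list of per-sample record tibbles
#'   ([call_eicirnas()] output with a `brpm` or `bsj_count` column).
#' @param value Column to tabulate (default `"brpm"`, falling back to
#'   `"bsj_count"` when absent).
#' @return Wide tibble: `feature_id` then one numeric column per sample.
#' @export
build_matrix <- function(records, value = "brpm") {
  if (anyDuplicated(names(records))) abort("duplicate sample id")
  if (is.null(names(records)) && length(records) > 0) {
    abort("records must be a named list (names = sample ids)")
  }
  long <- imap(records, function(recs, sample_id) {
    if (nrow(recs) == 0) return(NULL)
    col <- if (value %in% names(recs)) value else "bsj_count"
    tibble(feature_id = paste0(recs$chrom, ":", recs$start, "-", recs$end,
                               "|", recs$intron_id),
           sample_id = sample_id,
           value = as.numeric(recs[[col]]))
  }) |> bind_rows()
  if (is.null(long) || nrow(long) == 0) {
    out <- tibble(feature_id = character())
    for (s in names(records)) out[[s]] <- numeric(0)
    return(out)
  }
  long |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                       values_fill = 0) |>
    # samples with zero records still get a column
    (\(w) {for (s in setdiff(names(records), names(w))) w[[s]] <- 0; w})() |>
    arrange(.data$feature_id)
}

#' Tissue-specificity index tau for one expression vector
#'
#' `tau = sum_i(1 - x_i / max(x)) / (n - 1)` over per-tissue values
#' (optionally `log2(x + 1)`-transformed first). 0 for uniform expression,
#' 1 for single-tissue expression; undefined for all-zero vectors.
#'
#' @param x Non-negative per-tissue expression values (`n >= 2`).
#' @param log2_transform Apply `log2(x + 1)` before the formula (default
#'   `TRUE`).
#' @return Scalar tau in `[0, 1]`, or `NA` when undefined.
#' @export
tau_index <- function(x, log2_transform = TRUE) {
  if (length(x) < 2) abort("tau needs at least 2 tissues")
  if (any(x < 0)) abort("negative expression value")
  if (log2_transform) x <- log2(x + 1)
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Tissue-specificity index tau across an expression matrix
#'
#' Averages replicate samples per tissue (arithmetic mean), then applies
#' [tau_index()] per feature.
#'
#' @param mat Wide tibble from [build_matrix()] (`feature_id` + one column
#'   per sample).
#' @param sample_info Tibble with `sample_id`, `tissue`.
#' @param log2_transform Passed to [tau_index()].
#' @return Tibble: `feature_id`, `tau`, `n_tissues`, `max_tissue`,
#'   `undefined`.
#' @export
tau <- function(mat, sample_info, log2_transform = TRUE) {
  samples <- setdiff(names(mat), "feature_id")
  missing <- setdiff(samples, sample_info$sample_id)
  if (length(missing)) {
    abort(paste0("samples without tissue label: ",
                 paste(missing, collapse = ", ")))
  }
  long <- mat |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "value") |>
    left_join(sample_info, by = "sample_id") |>
    group_by(.data$feature_id, .data$tissue) |>
    summarise(value = mean(.data$value), .groups = "drop")
  long |>
    group_by(.data$feature_id) |>
    summarise(
      tau = tau_index(.data$value, log2_transform),
      n_tissues = n(),
      max_tissue = .data$tissue[which.max(.data$value)],
      .groups = "drop"
    ) |>
    mutate(undefined = is.na(.data$tau))
}

#' Write an expression matrix or tau table with a provenance header
#'
#' @param tab Tibble to write.
#' @param path Output path (TSV).
#' @param header Named character vector written as `# key: value` comment
#'   lines.
#' @return `path`, invisibly.
#' @export
write_tsv_with_header <- function(tab, path, header = character()) {
  writeLines(sprintf("# %s: %s", names(header), unlist(header)), path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
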