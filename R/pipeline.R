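# End-to-end orchestration of the three detection steps, plus config-file
# subcommand wrappers.

#' Detect EIciRNAs from in-memory inputs
#'
#' Runs the full detection chain: keep `exon`-type calls, assign host
#' transcripts, place BSJ read pairs on circular pseudo-references and
#' classify them for intronic evidence, compute per-intron retention
#' metrics on the genome alignments, validate, and quantify records as
#' BRPM.
#'
#' @param genome Genome `DNAStringSet`.
#' @param catalog A [transcript_catalog()].
#' @param calls Calls tibble ([read_ciri2()] schema).
#' @param alignments Genome alignments ([read_alignments()] schema).
#' @param reads1,reads2 Named mate sequence vectors (ids matching the
#'   calls' BSJ read ids).
#' @param read_length Read length for the rotation pad (default 150).
#' @param overhang Junction overhang in nt (default 5).
#' @param min_support Minimum qualifying BSJ pairs per candidate
#'   (default 1).
#' @param thresholds Retention validation thresholds
#'   ([retention_thresholds()]).
#' @param max_mismatch_rate Pseudo-reference placement tolerance.
#' @param min_mapq Mapping-quality filter for retention metrics
#'   (default 1).
#' @param total_mapped Library size for BRPM; defaults to the number of
#'   primary alignment records.
#' @return List with tibbles `records` (EIciRNAs with BRPM), `evidence`,
#'   `candidates`, `assignments`, `metrics` and per-stage `counts`.
#' @export
detect_eicirnas <- function(genome, catalog, calls, alignments, reads1,
                            reads2, read_length = 150L, overhang = 5L,
                            min_support = 1L,
                            thresholds = retention_thresholds(),
                            max_mismatch_rate = 0.05, min_mapq = 1L,
                            total_mapped = NULL) {
  bad <- setdiff(unique(c(calls$chrom, alignments$chrom)), names(genome))
  if (length(bad)) {
    abort(paste0("contig name(s) absent from the genome FASTA: ",
                 paste(bad, collapse = ", ")))
  }
  exonic <- filter(calls, .data$circ_type == "exon")
  assignments <- assign_hosts(exonic, catalog)
  pairs <- extract_bsj_read_pairs(exonic, reads1, reads2)
  evidence <- collect_pair_evidence(exonic, assignments, pairs, genome,
                                    readlen = read_length,
                                    overhang = overhang,
                                    max_mismatch_rate = max_mismatch_rate)
  candidates <- candidate_eicirnas(evidence, min_support = min_support)
  cand_introns <- assignments |>
    select("internal_introns") |>
    tidyr::unnest("internal_introns") |>
    distinct(.data$intron_id, .keep_all = TRUE) |>
    filter(.data$intron_id %in% candidates$intron_id)
  metrics <- intron_metrics(alignments, cand_introns, overhang = overhang,
                            min_mapq = min_mapq)
  records <- call_eicirnas(candidates, metrics, exonic, assignments,
                           thresholds)
  total_mapped <- total_mapped %||% nrow(alignments)
  if (nrow(records) > 0) {
    records <- mutate(records, brpm = brpm(.data$bsj_count, total_mapped))
  } else {
    records$brpm <- numeric(0)
  }
  counts <- tibble(
    stage = c("calls", "exon_type_calls", "annotated", "pairs_extracted",
              "candidates", "eicirnas"),
    n = c(nrow(calls), nrow(exonic), sum(!assignments$unannotated),
          nrow(pairs), nrow(candidates), nrow(records))
  )
  list(records = records, evidence = evidence, candidates = candidates,
       assignments = assignments, metrics = metrics, counts = counts)
}

#' Export EIciRNA records as BED12
#'
#' One line per record spanning the BSJ; the thick interval marks the
#' retained intron.
#'
#' @param records Records tibble from [detect_eicirnas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eicirna_bed12 <- function(records, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t1\t%d\t0",
    records$chrom, records$start, records$end,
    paste0(records$circ_id, "|", records$intron_id),
    records$bsj_count, records$strand,
    records$intron_start, records$intron_end,
    records$end - records$start)
  writeLines(lines, path)
  invisible(path)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

strip_mate_suffix <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))

read_fastq_named <- function(path) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(reads)
  names(out) <- strip_mate_suffix(names(reads))
  out
}

manifest_for <- function(config, seed) {
  m <- list(package = "eicir",
            version = as.character(utils::packageVersion("eicir")),
            seed = seed, config = config)
  # the hash covers everything that determines the results; the output
  # location does not, so reruns into different directories stay identical
  m$hash <- rlang::hash(m[c("package", "version", "seed",
                            "config")] |>
                          (\(x) {x$config$outdir <- NULL; x})())
  m
}

#' Run EIciRNA detection from a config
#'
#' Config keys (list or YAML path): `genome_fasta`, `gtf`, `ciri2`,
#' `alignments` (SAM/BAM), `fastq1`, `fastq2`, `outdir`, and optional
#' `read_length`, `overhang`, `min_support`, `min_mapq`, `ic_cutoff`,
#' `seed`. Writes `eicirnas.tsv`, `eicirnas.bed12`, `diagnostics.tsv`,
#' `stage_counts.tsv` and `manifest.json` into `outdir`.
#'
#' @param config List or YAML file path.
#' @return The [detect_eicirnas()] result list, invisibly.
#' @export
run_detect <- function(config) {
  config <- read_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_genome(config$genome_fasta)
  catalog <- read_gtf(config$gtf)
  calls <- read_ciri2(config$ciri2)
  aln <- read_alignments(config$alignments)
  thresholds <- retention_thresholds()
  if (!is.null(config$ic_cutoff)) thresholds$IC <- config$ic_cutoff
  res <- detect_eicirnas(
    genome, catalog, calls, aln,
    read_fastq_named(config$fastq1), read_fastq_named(config$fastq2),
    read_length = config$read_length %||% 150L,
    overhang = config$overhang %||% 5L,
    min_support = config$min_support %||% 1L,
    thresholds = thresholds,
    min_mapq = config$min_mapq %||% 1L
  )
  manifest <- manifest_for(config, config$seed %||% NA)
  out <- res$records |>
    mutate(host_transcripts = map_chr(.data$host_transcripts, paste,
                                      collapse = ","))
  write_tsv_with_header(out, file.path(config$outdir, "eicirnas.tsv"),
                        c(manifest = manifest$hash))
  write_eicirna_bed12(res$records,
                      file.path(config$outdir, "eicirnas.bed12"))
  diag <- res$evidence |>
    count(.data$circ_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  write_tsv_with_header(diag, file.path(config$outdir, "diagnostics.tsv"),
                        c(manifest = manifest$hash))
  write_tsv_with_header(res$counts,
                        file.path(config$outdir, "stage_counts.tsv"),
                        c(manifest = manifest$hash))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Run the read simulator from a config
#'
#' Config keys: `outdir`, `seed`, optional `genes`, `templates` (tibble or
#' list of lists), `read_length`, `fragment_mean`, `fragment_sd`,
#' `error_rate`, `depth`. Writes FASTA, GTF, FASTQ pair, SAM, truth table
#' and CIRI2-format truth BSJ table.
#'
#' @param config List or YAML file path.
#' @return List of written paths plus the simulation objects, invisibly.
#' @export
run_simulate <- function(config) {
  config <- read_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  toy <- make_toy_genome(genes = config$genes, seed = seed)
  templates <- config$templates
  if (is.null(templates)) {
    depth <- config$depth %||% 50
    templates <- tribble(
      ~template_id, ~type, ~transcript_id, ~retained_intron, ~depth,
      "eici1", "eici", "gene1.t1", 2L, depth,
      "lin1", "linear", "gene1.t1", NA_integer_, depth,
      "ecirc1", "ecirc", "gene2.t1", NA_integer_, depth,
      "lin3", "linear", "gene3.t1", NA_integer_, depth
    )
  } else if (!is.data.frame(templates)) {
    templates <- bind_rows(map(templates, as_tibble))
  }
  sim <- simulate_reads(toy$genome, toy$catalog, templates,
                        read_length = config$read_length %||% 150L,
                        fragment_mean = config$fragment_mean %||% 300,
                        fragment_sd = config$fragment_sd %||% 30,
                        error_rate = config$error_rate %||% 0.005,
                        seed = seed)
  paths <- list(
    genome_fasta = file.path(config$outdir, "genome.fa"),
    gtf = file.path(config$outdir, "annotation.gtf"),
    fastq1 = file.path(config$outdir, "reads_1.fastq"),
    fastq2 = file.path(config$outdir, "reads_2.fastq"),
    alignments = file.path(config$outdir, "alignments.sam"),
    truth = file.path(config$outdir, "truth.tsv"),
    ciri2 = file.path(config$outdir, "bsj_truth.tsv")
  )
  write_genome(toy$genome, paths$genome_fasta)
  write_gtf(toy$catalog, paths$gtf)
  write_fastq(sim$reads1, paths$fastq1)
  write_fastq(sim$reads2, paths$fastq2)
  write_sam(sim$alignments, toy$genome, paths$alignments)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  write_ciri2(sim$bsj_calls, paths$ciri2)
  invisible(c(paths, list(toy = toy, sim = sim, templates = templates)))
}

#' Train and evaluate the intron classifier from a config
#'
#' Config keys: `outdir`, `seed`, and either `features` (TSV with a label
#' column) or `n_per_class`/`effect_size` for a simulated set; optional
#' `hidden`, `epochs`.
#'
#' @param config List or YAML file path.
#' @return List with the model and evaluation, invisibly.
#' @export
run_classify <- function(config) {
  config <- read_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  feats <- if (!is.null(config$features)) {
    readr::read_tsv(config$features, show_col_types = FALSE, progress = FALSE)
  } else {
    make_feature_dataset(config$n_per_class %||% 600L,
                         config$effect_size %||% 2, seed = seed)
  }
  model <- train_classifier(feats,
                            hidden = unlist(config$hidden %||%
                                              c(64L, 32L, 16L)),
                            epochs = config$epochs %||% 150L, seed = seed)
  ev <- evaluate(model, seed = seed)
  write_classifier(model, file.path(config$outdir, "model.json"))
  readr::write_tsv(ev$pairwise, file.path(config$outdir, "pairwise.tsv"),
                   progress = FALSE)
  readr::write_tsv(ev$importance, file.path(config$outdir, "importance.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(pairwise = ev$pairwise,
                            importance = ev$importance),
                       file.path(config$outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(model = model, evaluation = ev))
}

#' Compute tau tissue specificity from a config
#'
#' Config keys: `matrix` (TSV, `feature_id` + sample columns; `#` comment
#' lines allowed), `samples` (TSV with `sample_id`, `tissue`), `outdir`,
#' optional `log2_transform`.
#'
#' @param config List or YAML file path.
#' @return The tau tibble, invisibly.
#' @export
run_tau <- function(config) {
  config <- read_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  mat <- readr::read_tsv(config$matrix, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(config$samples, comment = "#",
                             show_col_types = FALSE, progress = FALSE)
  lt <- config$log2_transform %||% TRUE
  res <- tau(mat, samples, log2_transform = lt)
  write_tsv_with_header(res, file.path(config$outdir, "tau.tsv"),
                        c(transform = if (lt) "log2(x+1)" else "none",
                          denominator = "per-million-mapped"))
  invisible(res)
}
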