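test_that("toy genomes have the requested structure and planted splice sites", {
  toy <- make_toy_genome(n_genes = 3, n_exons = 5, seed = 1)
  expect_equal(nrow(toy$catalog$transcripts), 3)
  expect_equal(nrow(toy$catalog$exons), 15)
  expect_equal(nrow(toy$catalog$introns), 12)
  for (i in seq_len(nrow(toy$catalog$introns))) {
    intr <- toy$catalog$introns[i, ]
    iseq <- fetch_sequence(toy$genome, intr$chrom, intr$start, intr$end, "+")
    expect_equal(substr(iseq, 1, 2), "GT")
    expect_equal(substr(iseq, nchar(iseq) - 1, nchar(iseq)), "AG")
  }
})

test_that("toy genome generation is deterministic and validates inputs", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome(make_toy_genome(seed = 42)$genome, f1)
  write_genome(make_toy_genome(seed = 42)$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    as.character(make_toy_genome(seed = 1)$genome),
    as.character(make_toy_genome(seed = 2)$genome)))

  expect_error(make_toy_genome(genes = list(list(
    gene_id = "g", exon_lengths = c(100L, 100L), intron_lengths = 0L))),
    ">= 30")
  expect_error(make_toy_genome(genes = list(list(
    gene_id = "g", exon_lengths = c(100L, 100L),
    intron_lengths = c(50L, 50L)))), "one intron length")
})

test_that("simulate_reads honours depth 0 and fragment constraints", {
  toy <- make_toy_genome(seed = 2)
  templates <- tibble::tibble(template_id = "lin", type = "linear",
                              transcript_id = "gene1.t1",
                              retained_intron = NA_integer_, depth = 0)
  sim <- simulate_reads(toy$genome, toy$catalog, templates, seed = 2)
  expect_equal(length(sim$reads1), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_error(simulate_reads(toy$genome, toy$catalog,
                              dplyr::mutate(templates, depth = 10),
                              read_length = 150L, fragment_mean = 100,
                              seed = 2),
               "fragment_mean")
})

test_that("error-free reads re-align exactly to their source blocks", {
  toy <- make_toy_genome(seed = 3)
  sim <- simulate_reads(toy$genome, toy$catalog, default_templates(15),
                        error_rate = 0, seed = 3)
  # reconstruct every non-clipped alignment's sequence from the genome
  aln <- dplyr::filter(sim$alignments, !grepl("S", cigar))
  expect_gt(nrow(aln), 100)
  for (r in sample(nrow(aln), 50)) {
    blocks <- naive_blocks(aln$start[r], aln$cigar[r])
    ref <- paste(vapply(seq_len(nrow(blocks)), function(b)
      fetch_sequence(toy$genome, aln$chrom[r], blocks[b, 1], blocks[b, 2],
                     "+"), character(1)), collapse = "")
    expect_equal(ref, aln$seq[r])
  }
  # FASTQ mates match the SAM SEQ orientation convention
  one <- dplyr::filter(sim$alignments, mate == 2, !grepl("S", cigar))[1, ]
  expect_equal(one$seq, revcomp(sim$reads2[[one$read_id]]))
})

test_that("every simulated pair appears exactly once in the truth table", {
  toy <- make_toy_genome(seed = 4)
  sim <- simulate_reads(toy$genome, toy$catalog, default_templates(20),
                        seed = 4)
  expect_equal(anyDuplicated(sim$truth$read_id), 0L)
  expect_setequal(names(sim$reads1), sim$truth$read_id)
  expect_setequal(names(sim$reads2), sim$truth$read_id)
  # BSJ truth ids are exactly the crossing pairs of circular templates
  for (i in seq_len(nrow(sim$bsj_calls))) {
    call <- sim$bsj_calls[i, ]
    tmpl <- sub("_r[0-9]+$", "", call$read_ids[[1]][1])
    tt <- dplyr::filter(sim$truth, template_id == tmpl)
    expect_setequal(call$read_ids[[1]], tt$read_id[tt$crosses_bsj])
    expect_equal(call$bsj_count, sum(tt$crosses_bsj))
    expect_equal(call$circ_type, "exon")
  }
})

test_that("empirical fragment lengths match the configured distribution", {
  toy <- make_toy_genome(genes = list(list(
    gene_id = "g1", exon_lengths = rep(400L, 5),
    intron_lengths = rep(100L, 4))), seed = 5)
  templates <- tibble::tibble(template_id = "lin", type = "linear",
                              transcript_id = "g1.t1",
                              retained_intron = NA_integer_, depth = 200)
  sim <- simulate_reads(toy$genome, toy$catalog, templates,
                        fragment_mean = 300, fragment_sd = 30, seed = 5)
  # fragment span in template coordinates via the mate alignments
  frag <- sim$alignments |>
    dplyr::group_by(read_id) |>
    dplyr::summarise(span = max(end) - min(start), n_gap = sum(grepl("N", cigar)))
  lin_frag <- dplyr::filter(frag, n_gap == 0)$span
  expect_gt(length(lin_frag), 300)
  expect_lt(abs(mean(lin_frag) - 300), 3 * 30 / sqrt(length(lin_frag)) + 2)
})

test_that("retained introns are deeply covered at 20x and above", {
  for (seed in c(31, 32, 33)) {
    res <- run_planted(seed, depth = 20)
    intr <- dplyr::filter(res$toy$catalog$introns,
                          intron_id == res$truth_intron)
    m <- intron_metrics(res$sim$alignments, intr)
    expect_gte(m$IC, 0.9)
    expect_gte(m$I, 1)
  }
})

test_that("feature datasets are deterministic with direction-true effects", {
  d1 <- make_feature_dataset(50, effect_size = 2, seed = 9)
  d2 <- make_feature_dataset(50, effect_size = 2, seed = 9)
  expect_identical(d1, d2)
  expect_setequal(unique(d1$label), c("NCI", "CIR", "LIR"))
  agg <- d1 |>
    dplyr::group_by(label) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean))
  mean_of <- function(lbl, col) agg[[col]][agg$label == lbl]
  # CIR vs NCI: shorter, higher GC, weaker splice sites
  expect_lt(mean_of("CIR", "intron_length_log10"),
            mean_of("NCI", "intron_length_log10"))
  expect_gt(mean_of("CIR", "intron_gc"), mean_of("NCI", "intron_gc"))
  expect_lt(mean_of("CIR", "ss5_score"), mean_of("NCI", "ss5_score"))
  # CIR vs LIR: longer, lower GC, closer to the 5' end
  expect_gt(mean_of("CIR", "intron_length_log10"),
            mean_of("LIR", "intron_length_log10"))
  expect_lt(mean_of("CIR", "intron_gc"), mean_of("LIR", "intron_gc"))
  expect_lt(mean_of("CIR", "rel_position"), mean_of("LIR", "rel_position"))
  expect_error(make_feature_dataset(50, effect_size = -1), "non-negative")
  expect_error(make_feature_dataset(5), "at least 10")
})
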