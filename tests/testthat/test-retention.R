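# fixture intron on chrT
fix_intron <- tibble::tibble(intron_id = "i1", chrom = "chrT",
                             start = 1000L, end = 1100L, strand = "+",
                             ordinal = 1L, n_introns = 1L)

test_that("EE counts exact-gap spliced reads with enough overhang", {
  # gap [1000,1100) exactly: 10M100N10M starting at 990
  aln <- dplyr::bind_rows(
    aln_row("ee_ok", 990, "10M100N10M"),
    aln_row("ee_near_miss", 991, "10M100N10M"),   # gap [1001,1101)
    aln_row("ee_short_flank", 996, "4M100N30M"))  # 4 nt left overhang
  m <- intron_metrics(aln, fix_intron)
  expect_equal(m$EE, 1L)
})

test_that("EI and IE need 5 aligned bases on both boundary sides", {
  aln <- dplyr::bind_rows(
    aln_row("ei_6", 980, "26M"),    # [980,1006): 6 intronic bases
    aln_row("ei_5", 980, "25M"),    # exactly 5: counts
    aln_row("ei_4", 980, "24M"),    # 4: does not count
    aln_row("ie_ok", 1090, "30M"),  # [1090,1120): crosses end with 10/20
    aln_row("ie_4", 1090, "14M"))   # 4 exonic bases after 1100
  m <- intron_metrics(aln, fix_intron)
  expect_equal(m$EI, 2L)
  expect_equal(m$IE, 1L)
})

test_that("a read can serve EI at one boundary and IE at the other", {
  aln <- aln_row("spans_all", 990, "120M")  # covers the whole intron + exons
  m <- intron_metrics(aln, fix_intron)
  expect_equal(m$EI, 1L)
  expect_equal(m$IE, 1L)
  expect_equal(m$EE, 0L)
})

test_that("exact-gap reads count as EE only, never EI/IE", {
  aln <- aln_row("ee", 990, "10M100N10M")
  m <- intron_metrics(aln, fix_intron)
  expect_equal(unlist(m[c("EE", "EI", "IE")]), c(EE = 1L, EI = 0L, IE = 0L))
})

test_that("middle window counts intron-contained reads only", {
  # intron length 100 < 200: window is the whole intron
  aln <- dplyr::bind_rows(
    aln_row("inside", 1020, "50M"),          # fully inside
    aln_row("bleed", 980, "60M"),            # crosses into the intron
    aln_row("spliced", 990, "10M100N10M"))   # skips the intron
  m <- intron_metrics(aln, fix_intron)
  expect_equal(m$I, 1L)

  # long intron: the window is its centered 200 nt
  long_intron <- dplyr::mutate(fix_intron, end = 2000L)  # length 1000
  # window = [1400, 1600); a read at [1100,1150) misses it
  aln2 <- dplyr::bind_rows(
    aln_row("off_window", 1100, "50M"),
    aln_row("in_window", 1450, "50M"))
  m2 <- intron_metrics(aln2, long_intron)
  expect_equal(m2$I, 1L)
})

test_that("IC is the fraction of covered intron bases", {
  expect_equal(intron_metrics(aln_row("r", 0, "10M")[0, ], fix_intron)$IC, 0)
  tiling <- dplyr::bind_rows(lapply(0:9, function(i)
    aln_row(paste0("t", i), 1000 + i * 10, "10M")))
  expect_equal(intron_metrics(tiling, fix_intron)$IC, 1)
  expect_equal(intron_metrics(tiling[1:9, ], fix_intron)$IC, 0.9)
})

test_that("PIR follows the junction-based formula", {
  expect_equal(compute_pir(2, 2, 2), 0.5)
  expect_equal(compute_pir(0, 0, 10), 0)
  expect_equal(compute_pir(4, 2, 0), 1)
  expect_equal(compute_pir(0, 0, 0), 0)
  set.seed(1)
  ei <- rpois(50, 3); ie <- rpois(50, 3); ee <- rpois(50, 3)
  pir <- compute_pir(ei, ie, ee)
  expect_true(all(pir >= 0 & pir <= 1))
})

test_that("validation requires all five thresholds", {
  base <- tibble::tibble(intron_id = "i", chrom = "c", start = 0L, end = 1L,
                         EE = 3L, EI = 2L, IE = 2L, I = 5L, IC = 0.95,
                         PIR = 0.4)
  expect_true(validate_retention(base)$valid)
  expect_false(validate_retention(dplyr::mutate(base, IC = 0.85))$valid)
  expect_false(validate_retention(dplyr::mutate(base, EE = 0L))$valid)
  expect_false(validate_retention(dplyr::mutate(base, EI = 0L))$valid)
  expect_false(validate_retention(dplyr::mutate(base, IE = 0L))$valid)
  expect_false(validate_retention(dplyr::mutate(base, I = 0L))$valid)
  # boundary: IC exactly 0.9 passes
  expect_true(validate_retention(dplyr::mutate(base, IC = 0.9))$valid)
})

test_that("metrics equal the per-read brute-force oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:12) {
    n_reads <- sample(20:120, 1)
    cigars <- character(n_reads)
    starts <- integer(n_reads)
    for (r in seq_len(n_reads)) {
      kind <- sample(c("plain", "spliced", "clipped"), 1,
                     prob = c(0.6, 0.3, 0.1))
      starts[r] <- sample(900:1150, 1)
      cigars[r] <- switch(kind,
        plain = paste0(sample(20:80, 1), "M"),
        spliced = {
          left <- sample(3:30, 1); right <- sample(3:30, 1)
          gap <- sample(c(100L, sample(40:160, 1)), 1)  # sometimes exact
          if (runif(1) < 0.5) starts[r] <- 1000L - left  # anchor on boundary
          paste0(left, "M", gap, "N", right, "M")
        },
        clipped = paste0(sample(5:20, 1), "S", sample(20:60, 1), "M"))
    }
    aln <- dplyr::bind_rows(purrr::map(seq_len(n_reads), function(r)
      aln_row(paste0("r", r), starts[r], cigars[r],
              mapq = sample(c(0L, 60L), 1, prob = c(0.1, 0.9)))))
    fast <- intron_metrics(aln, fix_intron)
    slow <- naive_intron_metrics(aln, fix_intron)
    expect_equal(fast$EE, slow$EE)
    expect_equal(fast$EI, slow$EI)
    expect_equal(fast$IE, slow$IE)
    expect_equal(fast$I, slow$I)
    expect_equal(fast$IC, slow$IC)
  }
})

test_that("IC is monotone non-decreasing as reads are added", {
  set.seed(7)
  reads <- dplyr::bind_rows(lapply(1:30, function(i)
    aln_row(paste0("r", i), sample(950:1080, 1),
            paste0(sample(10:40, 1), "M"))))
  ics <- vapply(seq(5, 30, by = 5), function(n)
    intron_metrics(reads[1:n, ], fix_intron)$IC, numeric(1))
  expect_true(all(diff(ics) >= 0))
})

test_that("low mapping quality reads are excluded from the metrics", {
  aln <- dplyr::bind_rows(
    aln_row("good", 990, "10M100N10M", mapq = 60L),
    aln_row("multi", 990, "10M100N10M", mapq = 0L))
  expect_equal(intron_metrics(aln, fix_intron)$EE, 1L)
  expect_equal(intron_metrics(aln, fix_intron, min_mapq = 0L)$EE, 2L)
})

test_that("call_eicirnas keeps only circRNAs with a validated intron", {
  candidates <- tibble::tibble(circ_id = c("c1", "c2"),
                               intron_id = c("i1", "i2"),
                               support = c(4L, 2L))
  metrics <- tibble::tibble(
    intron_id = c("i1", "i2"), chrom = "chrT",
    start = c(1000L, 2000L), end = c(1100L, 2100L),
    EE = c(5L, 5L), EI = c(3L, 3L), IE = c(2L, 2L), I = c(4L, 4L),
    IC = c(0.95, 0.80), PIR = compute_pir(c(3, 3), c(2, 2), c(5, 5)))
  calls <- tibble::tibble(circ_id = c("c1", "c2"), chrom = "chrT",
                          start = c(900L, 1900L), end = c(1500L, 2500L),
                          strand = "+", bsj_count = c(9L, 9L),
                          circ_type = "exon",
                          read_ids = list(character(0), character(0)))
  asn <- tibble::tibble(circ_id = c("c1", "c2"), score = 2L,
                        host_transcripts = list("tA", "tB"),
                        unannotated = FALSE,
                        internal_introns = list(tibble::tibble(),
                                                tibble::tibble()))
  recs <- call_eicirnas(candidates, metrics, calls, asn)
  expect_equal(recs$circ_id, "c1")      # c2 fails IC
  expect_equal(recs$bsj_count, 4L)      # step-2 qualifying pair count
  expect_equal(recs$intron_id, "i1")
})

test_that("intron class labels follow the PIR and IRratio cutoffs", {
  circ_m <- tibble::tibble(
    intron_id = c("cir_hi", "between", "ecirc_low"), chrom = "chrT",
    start = 0L, end = 100L,
    EE = c(2L, 9L, 50L), EI = c(4L, 1L, 1L), IE = c(4L, 0L, 1L),
    I = c(5L, 5L, 0L), IC = c(0.95, 0.95, 0.2),
    PIR = compute_pir(c(4, 1, 1), c(4, 0, 1), c(2, 9, 50)))
  lin_m <- tibble::tibble(
    intron_id = "lir1", chrom = "chrT", start = 0L, end = 100L,
    EE = 8L, EI = 2L, IE = 2L, I = 3L, IC = 0.5,
    PIR = compute_pir(2, 2, 8))
  labels <- label_intron_classes(circ_m, ecirc_introns = "ecirc_low",
                                 linear_metrics = lin_m)
  expect_equal(labels$label[labels$intron_id == "cir_hi"], "CIR")
  expect_equal(labels$label[labels$intron_id == "ecirc_low"], "NCI")
  expect_equal(labels$label[labels$intron_id == "lir1"], "LIR")
  expect_equal(labels$label[labels$intron_id == "between"], "unclassified")
})
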