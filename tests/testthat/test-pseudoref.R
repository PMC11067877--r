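random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

pseudo_fixture <- function(circ_len = 800L, readlen = 150L, seed = 1) {
  set.seed(seed)
  genome <- Biostrings::DNAStringSet(setNames(random_dna(circ_len + 200L),
                                              "chrT"))
  circ <- tibble::tibble(circ_id = "c1", chrom = "chrT", start = 100L,
                         end = 100L + circ_len, strand = "+")
  list(genome = genome, circ = circ,
       pseudo = build_pseudo_reference(circ, genome, readlen))
}

test_that("pseudo-reference has rotation pad readlen - 1, truncated", {
  fx <- pseudo_fixture(800L, 150L)
  expect_equal(nchar(fx$pseudo$seq), 949L)
  expect_equal(fx$pseudo$junction_offset, 800L)

  short <- pseudo_fixture(100L, 150L)
  expect_equal(nchar(short$pseudo$seq), 200L)
  expect_equal(short$pseudo$pad, 100L)

  tiny <- pseudo_fixture(100L, 150L)
  tiny$circ$end <- tiny$circ$start + 15L
  expect_error(build_pseudo_reference(tiny$circ, tiny$genome, 150L),
               "too short")
})

test_that("back-projection is the rotation identity", {
  fx <- pseudo_fixture(800L, 150L)
  p <- fx$pseudo
  expect_equal(project_to_genome(p, p$junction_offset), p$start)
  # non-pad region is the identity shifted by start
  pos <- 0:(p$circ_len - 1)
  expect_equal(project_to_genome(p, pos), p$start + pos)
  # pad wraps to the circle start
  pad_pos <- p$circ_len:(p$circ_len + p$pad - 1)
  expect_equal(project_to_genome(p, pad_pos), p$start + pad_pos - p$circ_len)
  expect_error(project_to_genome(p, nchar(p$seq)), "out of range")
})

test_that("verbatim and mutated reads place, unrelated reads do not", {
  fx <- pseudo_fixture(800L, 150L, seed = 2)
  p <- fx$pseudo
  read <- substr(p$seq, 301, 450)
  hit <- place_read(read, p)
  expect_equal(hit$status, "placed")
  expect_equal(hit$offset, 300L)
  expect_equal(hit$mismatches, 0L)

  # 4% mismatches (6 of 150) still places at the 5% threshold
  set.seed(9)
  bases <- strsplit(read, "")[[1]]
  flip <- sample(150, 6)
  bases[flip] <- vapply(bases[flip],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
  hit_mm <- place_read(paste(bases, collapse = ""), p)
  expect_equal(hit_mm$status, "placed")
  expect_equal(hit_mm$offset, 300L)
  expect_equal(hit_mm$mismatches, 6L)

  set.seed(10)
  expect_equal(place_read(random_dna(150), p)$status, "unplaced")
})

test_that("reverse-strand mates place and pairs need opposite strands", {
  fx <- pseudo_fixture(800L, 150L, seed = 3)
  p <- fx$pseudo
  m1 <- substr(p$seq, 101, 250)
  m2 <- revcomp(substr(p$seq, 301, 450))
  pl <- place_pair(m1, m2, p)
  expect_equal(pl$status, c("placed", "placed"))
  expect_equal(pl$strand, c("+", "-"))
  expect_equal(pl$offset, c(100L, 300L))

  # same-strand "pairs" are rejected as inconsistent
  bad <- place_pair(m1, substr(p$seq, 301, 450), p)
  expect_true(all(bad$status == "unplaced"))
})

test_that("rotation-uniform circular reads place with high probability", {
  fx <- pseudo_fixture(600L, 100L, seed = 4)
  p <- fx$pseudo
  circle <- substr(p$seq, 1, p$circ_len)
  set.seed(11)
  n <- 500
  placed <- 0L
  for (i in seq_len(n)) {
    a <- sample(0:(p$circ_len - 1), 1)
    read <- substr(paste0(circle, circle), a + 1, a + 100)
    bases <- strsplit(read, "")[[1]]
    err <- runif(100) < 0.01
    bases[err] <- vapply(bases[err],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         character(1))
    hit <- place_read(paste(bases, collapse = ""), p)
    if (hit$status == "placed" &&
        (hit$offset == a || hit$offset == a + p$circ_len)) {
      placed <- placed + 1L
    }
  }
  expect_gte(placed / n, 0.99)
})

test_that("classify_pair distinguishes intronic, junction and exonic pairs", {
  fx <- pseudo_fixture(800L, 150L, seed = 5)
  p <- fx$pseudo
  # one internal intron at genomic [300, 500)
  introns <- tibble::tibble(intron_id = "i1", chrom = "chrT", start = 300L,
                            end = 500L, strand = "+", ordinal = 1L,
                            n_introns = 1L)
  place_at <- function(off1, off2, len = 100L) {
    tibble::tibble(mate = 1:2, offset = c(off1, off2), strand = c("+", "-"),
                   mismatches = 0L, status = "placed", len = len)
  }
  # mate fully inside the intron (pseudo offset 250 -> genomic 350)
  ev <- classify_pair(place_at(250L, 600L), p, introns)
  expect_equal(ev$category, "intronic")
  expect_equal(ev$supporting_introns[[1]], "i1")

  # mate crossing the exon|intron boundary at genomic 300 (pseudo 200),
  # 5 intronic bases aligned
  ev5 <- classify_pair(place_at(105L, 600L), p, introns)
  expect_equal(ev5$category, "exon_intron_junction")
  # 4 intronic bases: below the overhang
  ev4 <- classify_pair(place_at(104L, 600L), p, introns)
  expect_equal(ev4$category, "exonic_only")

  # unplaced pair
  unp <- tibble::tibble(mate = 1:2, offset = NA_integer_,
                        strand = NA_character_, mismatches = NA_integer_,
                        status = "unplaced", len = 100L)
  expect_equal(classify_pair(unp, p, introns)$category, "unplaced")
})

test_that("classify_pair is invariant to mate swap and flags BSJ wrap", {
  fx <- pseudo_fixture(800L, 150L, seed = 6)
  p <- fx$pseudo
  introns <- tibble::tibble(intron_id = "i1", chrom = "chrT", start = 300L,
                            end = 500L, strand = "+", ordinal = 1L,
                            n_introns = 1L)
  pl <- tibble::tibble(mate = 1:2, offset = c(250L, 750L),
                       strand = c("+", "-"), mismatches = 0L,
                       status = "placed", len = 100L)
  swapped <- dplyr::mutate(pl[2:1, ], mate = 1:2)
  a <- classify_pair(pl, p, introns)
  b <- classify_pair(swapped, p, introns)
  expect_equal(a$category, b$category)
  expect_equal(a$supporting_introns, b$supporting_introns)
  expect_true(a$crosses_bsj)   # offset 750 + 100 wraps junction at 800
})

test_that("extract_bsj_read_pairs recovers listed pairs and warns on gaps", {
  reads1 <- c(r1 = "ACGT", r2 = "GGGG", r3 = "TTTT")
  reads2 <- c(r1 = "CCCC", r2 = "AAAA", r3 = "ACAC")
  calls <- tibble::tibble(circ_id = "c1", chrom = "chrT", start = 0L,
                          end = 100L, strand = "+", bsj_count = 3L,
                          circ_type = "exon",
                          read_ids = list(c("r1", "r2", "r3")))
  pairs <- extract_bsj_read_pairs(calls, reads1, reads2)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$seq1[pairs$read_id == "r2"], "GGGG")

  gappy <- dplyr::mutate(calls, read_ids = list(c("r1", "missing")))
  expect_warning(p2 <- extract_bsj_read_pairs(gappy, reads1, reads2),
                 "absent")
  expect_equal(p2$read_id, "r1")

  none <- dplyr::mutate(calls, read_ids = list(character(0)))
  expect_warning(p3 <- extract_bsj_read_pairs(none, reads1, reads2),
                 "no BSJ read ids")
  expect_equal(nrow(p3), 0)
})

test_that("candidates require intron-supporting evidence", {
  ev <- tibble::tibble(
    circ_id = c("cA", "cA", "cA", "cB"),
    read_id = c("r1", "r2", "r3", "r4"),
    category = c("intronic", "intronic", "exonic_only", "exonic_only"),
    supporting_introns = list("i1", "i1", character(0), character(0)),
    crosses_bsj = c(TRUE, FALSE, TRUE, TRUE))
  cand <- candidate_eicirnas(ev)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$circ_id, "cA")
  expect_equal(cand$intron_id, "i1")
  expect_equal(cand$support, 2L)
  expect_equal(nrow(candidate_eicirnas(ev, min_support = 3L)), 0)
})

test_that("simulated EcircRNAs never yield intronic candidates", {
  toy <- make_toy_genome(seed = 21)
  templates <- tibble::tribble(
    ~template_id, ~type, ~transcript_id, ~retained_intron, ~depth,
    "ecirc1", "ecirc", "gene2.t1", NA_integer_, 40)
  sim <- simulate_reads(toy$genome, toy$catalog, templates, seed = 21)
  asn <- assign_hosts(sim$bsj_calls, toy$catalog)
  pairs <- extract_bsj_read_pairs(sim$bsj_calls, sim$reads1, sim$reads2)
  ev <- collect_pair_evidence(sim$bsj_calls, asn, pairs, toy$genome)
  cand <- candidate_eicirnas(ev)
  expect_equal(nrow(dplyr::filter(ev, category == "intronic")), 0)
  # junction-category artifacts may appear at exon edges, but no intronic
  # evidence is possible from a fully spliced circle
  expect_true(all(cand$support <= nrow(dplyr::filter(
    ev, category == "exon_intron_junction"))))
})
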