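caller_setup <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      g <- fixture_caller_genome()
      tr <- simulate_transposition(g, "ISAm1", n_events = 1, seed = 91)
      mg <- tr$genomes[[1]]
      rd <- simulate_reads(list(list(genome = g, weight = 0.55),
                                list(genome = mg, weight = 0.45)),
                          depth = 80, read_length = 120,
                          insert_size = 260, error_rate = 0.002,
                          seed = 92)
      el <- c(ISAm1 = g$elements$ISAm1$consensus)
      jx <- find_junctions(rd$reads, g, el)
      env <<- list(g = g, tr = tr, rd = rd, el = el, jx = jx)
    }
    env
  }
})

test_that("reads wholly within the reference produce no junction evidence", {
  g <- fixture_caller_genome()
  rd <- simulate_reads(list(list(genome = g, weight = 1)), depth = 5,
                       read_length = 120, insert_size = 260,
                       error_rate = 0, seed = 93)
  jx <- find_junctions(rd$reads, g, c(ISAm1 = g$elements$ISAm1$consensus))
  expect_equal(nrow(jx$evidence), 0)
  expect_gt(nrow(jx$spanning), 0)
})

test_that("a planted insertion yields left and right junction groups at truth", {
  e <- caller_setup()
  ev <- e$jx$evidence
  expect_gt(nrow(ev), 0)
  grp <- unique(ev[c("contig", "boundary", "side")])
  expect_equal(nrow(grp), 2)
  expect_setequal(grp$side, c("left", "right"))
  s <- e$tr$truth$site[1]
  k <- nchar(e$tr$truth$tsd_seq[1])
  expect_equal(grp$boundary[grp$side == "left"], s + k - 1)
  expect_equal(grp$boundary[grp$side == "right"], s)
  # every supporting read satisfies the minimum overhang on both sides
  expect_true(all(ev$overhang_ref >= 12 & ev$overhang_elem >= 12))
})

test_that("short element overhangs below m are not counted", {
  e <- caller_setup()
  g <- e$g
  s <- e$tr$truth$site[1]
  mut <- e$tr$genomes[[1]]$contigs[[1]]
  # a chimeric read with only a 6-base element overhang
  chim <- substr(mut, s - 114 + 8, s + 8 - 1 + 6)  # 114 ref+tsd, 6 elem
  expect_equal(nchar(chim), 120)
  jx <- find_junctions(data.frame(id = "c1", seq = chim, qual = strrep("I", 120)),
                       g, e$el)
  expect_equal(nrow(jx$evidence), 0)
})

test_that("calls recover site, TSD, orientation and frequency", {
  e <- caller_setup()
  calls <- call_insertions(e$jx, e$g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$site, e$tr$truth$site[1])
  expect_identical(calls$tsd_seq, e$tr$truth$tsd_seq[1])
  expect_identical(calls$orientation, e$tr$truth$orientation[1])
  expect_equal(calls$k, 8L)
  expect_equal(calls$status, "PASS")
  expect_lt(abs(calls$frequency - 0.45), 0.06)
  # f equals the declared estimator
  f <- mean(c(calls$J_left / (calls$J_left + calls$S_left),
              calls$J_right / (calls$J_right + calls$S_right)))
  expect_equal(calls$frequency, f)
})

test_that("the frequency estimator is pure arithmetic over J and S", {
  ref <- c(chr = isburst:::random_dna(400, 0.5))
  ev <- rbind(
    data.frame(contig = "chr", boundary = 207L, side = "left",
               family = "ISX", orientation = "+",
               read_id = sprintf("l%d", 1:8),
               read_strand = rep(c("+", "-"), 4),
               overhang_ref = 50L, overhang_elem = 50L,
               elem_quals = strrep("I", 50), stringsAsFactors = FALSE),
    data.frame(contig = "chr", boundary = 200L, side = "right",
               family = "ISX", orientation = "+",
               read_id = sprintf("r%d", 1:8),
               read_strand = rep(c("+", "-"), 4),
               overhang_ref = 50L, overhang_elem = 50L,
               elem_quals = strrep("I", 50), stringsAsFactors = FALSE))
  mk_span <- function(n) data.frame(
    contig = "chr", start = 150L, end = 280L,
    read_strand = rep(c("+", "-"), length.out = n),
    read_id = sprintf("s%d", 1:n), qual = strrep("I", 131),
    stringsAsFactors = FALSE)
  jx <- structure(list(evidence = ev, spanning = mk_span(12)),
                  class = "junction_evidence")
  calls <- call_insertions(jx, ref)
  expect_equal(calls$frequency, 0.40)      # 8/(8+12) on both sides
  expect_equal(calls$site, 200L)
  expect_equal(calls$k, 8L)
  expect_identical(calls$tsd_seq, substr(ref[["chr"]], 200, 207))
  expect_equal(calls$status, "PASS")
  # J=1 vs S=99: below the 2% detection cutoff
  jx2 <- structure(list(evidence = ev[1, ], spanning = mk_span(99)),
                   class = "junction_evidence")
  calls2 <- call_insertions(jx2, ref)
  expect_equal(calls2$frequency, 0.01)
  expect_match(calls2$status, "LOW_FREQ")
  expect_match(calls2$status, "ONE_SIDED")
})

test_that("TSD inference follows the boundary arithmetic", {
  ref <- isburst:::random_dna(100, 0.5)
  t1 <- infer_tsd(a = 57, b = 54, reference = ref)
  expect_equal(t1$k, 4L)
  expect_identical(t1$tsd_seq, substr(ref, 54, 57))
  t0 <- infer_tsd(a = 53, b = 54, reference = ref)
  expect_equal(t0$k, 0L)
  expect_identical(t0$tsd_seq, "")
  td <- infer_tsd(a = 50, b = 54, reference = ref)
  expect_identical(td$flag, "TARGET_DELETION")
  expect_identical(td$tsd_seq, "")
})

test_that("Fisher strand test matches exhaustive enumeration", {
  expect_equal(strand_bias_test(matrix(c(5, 5, 50, 50), 2,
                                       byrow = TRUE))$p, 1.0)
  expect_identical(strand_bias_test(matrix(c(0, 0, 10, 10), 2,
                                           byrow = TRUE))$p, 1)
  # one-strand junction support versus balanced reference
  biased <- strand_bias_test(matrix(c(30, 0, 50, 50), 2, byrow = TRUE))
  expect_lt(biased$p, 0.01)
  expect_true(biased$flag)
  # oracle equivalence over random small tables
  set.seed(101)
  for (i in 1:50) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(strand_bias_test(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("KS quality test is one-sided and matches enumeration", {
  same <- quality_bias_test(rep(c(10, 20, 30), 5), rep(c(10, 20, 30), 5))
  expect_equal(same$p, 1)
  low <- quality_bias_test(rep(10, 20), rep(35, 20))
  expect_lt(low$p, 1e-6)
  expect_true(low$flag)
  high <- quality_bias_test(rep(35, 20), rep(10, 20))
  expect_gte(high$p, 0.5)
  expect_identical(quality_bias_test(c(1, 2), c(1, 2, 3))$note,
                   "INSUFFICIENT_DATA")
  # oracle equivalence on small untied samples
  set.seed(102)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- sample(seq(1, 100), n1); y <- sample(seq(101, 200), n2) - 100.5
    expect_equal(quality_bias_test(x, y)$p, oracle_ks_p(x, y),
                 tolerance = 1e-9, info = paste(i))
  }
})

test_that("terminal inverted repeats are found and bounded", {
  set.seed(103)
  core <- isburst:::random_dna(472, 0.5)
  itr <- "ACGGTTCAGGCAAT"
  elem <- paste0(itr, core, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(itr))))
  got <- find_inverted_repeats(elem)
  expect_equal(got$itr_length, oracle_itr(elem))
  expect_equal(got$itr_length, 14)
  expect_identical(got$left_seq, itr)
  # random sequence: agree with the exhaustive scan (usually 0)
  for (i in 1:10) {
    s <- isburst:::random_dna(200, 0.5)
    expect_equal(find_inverted_repeats(s)$itr_length, oracle_itr(s))
  }
  # palindrome is capped at half the element length
  pal <- paste0(core, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core))))
  expect_equal(find_inverted_repeats(pal)$itr_length, nchar(core))
})

test_that("TSD GC summarizes calls against the genomic background", {
  g <- fixture_caller_genome()
  calls <- data.frame(tsd_seq = c("ATAT", "GCGC"))
  got <- target_site_gc(calls, g)
  expect_equal(got$mean_tsd_gc, 0.5)
  expect_equal(got$n_tsd, 2)
  none <- target_site_gc(data.frame(tsd_seq = character(0)), g)
  expect_true(is.na(none$mean_tsd_gc))
})

test_that("calls round-trip through TSV", {
  e <- caller_setup()
  calls <- call_insertions(e$jx, e$g)
  p <- tempfile(fileext = ".tsv")
  write_calls(calls, p)
  back <- read_calls(p)
  expect_equal(back$site, calls$site)
  expect_equal(back$frequency, calls$frequency)
  expect_identical(back$tsd_seq, calls$tsd_seq)
  unlink(p)
})

test_that("frequency is invariant to read order", {
  e <- caller_setup()
  rd2 <- e$rd$reads[rev(seq_len(nrow(e$rd$reads))), ]
  jx2 <- find_junctions(rd2, e$g, e$el)
  c1 <- call_insertions(e$jx, e$g)
  c2 <- call_insertions(jx2, e$g)
  expect_equal(c1$frequency, c2$frequency)
  expect_equal(c1$site, c2$site)
})
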