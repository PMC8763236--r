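make_cluster_genes <- function(n = 2, len = 600, gc = 0.5, seed = 81) {
  set.seed(seed)
  base <- isburst:::random_dna(len, gc)
  out <- c(base)
  for (i in seq_len(n - 1)) {
    s <- base
    pos <- 50 * i
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, pos, pos))[1]
    out <- c(out, s)
  }
  setNames(out, paste0("g", seq_len(n)))
}

test_that("recruitment honors the mismatch threshold and cluster ties", {
  genes <- make_cluster_genes(2)
  clusters <- list(clA = genes)
  read <- substr(genes[["g1"]], 101, 175)
  r <- recruit_reads(setNames(read, "r1"), clusters)
  expect_equal(r$cluster_id, "clA")
  # four mismatches exceed the threshold
  bad <- read
  for (p in c(10, 20, 30, 40))
    substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, p, p))[1]
  expect_equal(nrow(recruit_reads(setNames(bad, "r2"), clusters)), 0)
  # a read matching two clusters equally is dropped and logged
  other <- list(clB = c(g3 = genes[["g1"]]))
  tie <- recruit_reads(setNames(read, "r3"), c(clusters, other))
  expect_equal(nrow(tie), 0)
  expect_equal(attr(tie, "n_tie_dropped"), 1L)
})

test_that("ambiguity classification keys on perfect unique substrings", {
  genes <- make_cluster_genes(2)  # members differ at position 50 only
  ident <- list(cl = c(a = genes[["g1"]], b = genes[["g1"]]))
  anyread <- substr(genes[["g1"]], 1, 75)
  expect_equal(classify_ambiguity(anyread, ident$cl)$status, "ambiguous")
  # read covering the single diagnostic site of g2 is unambiguous
  diag <- substr(genes[["g2"]], 21, 95)
  cl <- classify_ambiguity(diag, genes)
  expect_equal(cl$status, "unambiguous")
  expect_equal(cl$gene, "g2")
})

test_that("reads from one member never classify to the other", {
  genes <- make_cluster_genes(2, seed = 82)
  sim <- simulate_rnaseq(data.frame(gene_id = "g1", seq = genes[["g1"]],
                                    weight = 1), n_reads = 400, seed = 83)
  rec <- recruit_reads(sim$reads, list(cl = genes))
  expect_equal(nrow(rec), 400)
  u <- rec[!is.na(rec$unambiguous_gene), ]
  expect_gt(nrow(u), 0)
  expect_true(all(u$unambiguous_gene == "g1"))
  # reads overlapping the diagnostic site are exactly the unambiguous ones
  pos <- with(sim$reads, regexpr(substr(genes[["g1"]], 1, 1), "A"))
  expect_true(all(is.na(rec$unambiguous_gene) |
                    rec$n_perfect_members == 1))
})

test_that("counting separates sense/antisense and ambiguity", {
  ev <- data.frame(read_id = sprintf("r%d", 1:10),
                   cluster_id = "cl",
                   mismatches = 0L,
                   orientation = "-",  # RF protocol: '-' match = sense
                   n_perfect_members = 2L,
                   unambiguous_gene = NA_character_,
                   stringsAsFactors = FALSE)
  ce <- count_expression(ev, protocol = "RF-stranded")
  expect_equal(ce$clusters$total_sense, 10L)
  expect_equal(ce$clusters$total_antisense, 0L)
  expect_equal(nrow(ce$genes), 0)
  expect_error(count_expression(ev, protocol = "bogus"), "protocol")
})

test_that("simulated antisense fraction is recovered through the pipeline", {
  genes <- make_cluster_genes(2, seed = 84)
  gdf <- data.frame(gene_id = names(genes), seq = unname(genes),
                    weight = c(3, 1), stringsAsFactors = FALSE)
  sim <- simulate_rnaseq(gdf, n_reads = 10000, antisense_fraction = 0.2,
                         seed = 85)
  rec <- recruit_reads(sim$reads, list(cl = genes))
  # simulator emits sense reads on the transcript strand -> FR protocol
  ce <- count_expression(rec, protocol = "FR-stranded")
  anti <- ce$clusters$total_antisense /
    (ce$clusters$total_sense + ce$clusters$total_antisense)
  expect_lt(abs(anti - 0.2), 0.01)
  # 3:1 weights -> unambiguous split 0.75/0.25
  gg <- ce$genes
  tot <- gg$unambiguous_sense + gg$unambiguous_antisense
  expect_lt(abs(tot[gg$gene_id == "g1"] / sum(tot) - 0.75), 0.03)
})

test_that("per-gene unambiguous counts match a unique-mapping oracle", {
  genes <- make_cluster_genes(3, len = 400, seed = 86)
  # make members mutually distinguishable in every 60 bp window
  set.seed(87)
  for (i in 2:3) {
    s <- genes[[i]]
    for (pos in seq(25, 390, by = 40))
      substr(s, pos + i, pos + i) <-
        setdiff(c("A", "C", "G", "T"), substr(s, pos + i, pos + i))[i - 1]
    genes[[i]] <- s
  }
  sim <- simulate_rnaseq(data.frame(gene_id = names(genes),
                                    seq = unname(genes), weight = 1),
                         n_reads = 300, read_length = 60, seed = 88)
  rec <- recruit_reads(sim$reads, list(cl = genes))
  ce <- count_expression(rec, protocol = "FR-stranded")
  oracle <- oracle_unique_counts(sim$reads$seq, genes)
  got <- ce$genes$unambiguous_sense[match(names(genes),
                                          ce$genes$gene_id)]
  got[is.na(got)] <- 0L
  expect_equal(got, unname(oracle))
})

test_that("TPM normalizes to one million with length weighting", {
  tpm <- compute_tpm(c(100, 100), c(1000, 2000))
  expect_equal(tpm, c(2, 1) / 3 * 1e6, tolerance = 1e-9)
  expect_equal(compute_tpm(5, 777), 1e6)
  expect_equal(compute_tpm(c(0, 0), c(100, 200)), c(0, 0))
  expect_error(compute_tpm(c(-1, 2), c(10, 10)), "negative")
  # property: sums to 1e6 for random inputs with any positive count
  set.seed(89)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    counts <- rpois(n, 50) * rbinom(n, 1, 0.8)
    if (all(counts == 0)) counts[1] <- 1
    expect_equal(sum(compute_tpm(counts, sample(200:3000, n))), 1e6,
                 tolerance = 1e-6)
  }
})

test_that("IS share of sense transcription is computed per replicate", {
  expr <- data.frame(feature = rep(c("g1", "g2", "tnp"), 2),
                     sense_count = c(490, 490, 20, 980, 980, 40),
                     is_flag = rep(c(FALSE, FALSE, TRUE), 2),
                     replicate = rep(1:2, each = 3))
  fr <- is_transcriptome_fraction(expr)
  expect_equal(fr$per_replicate$percent, c(2, 2))
  expect_equal(fr$mean, 2)
  # degenerate cases
  none <- is_transcriptome_fraction(
    data.frame(feature = "g", sense_count = 10, is_flag = FALSE))
  expect_equal(none$mean, 0)
  all_is <- is_transcriptome_fraction(
    data.frame(feature = "t", sense_count = 10, is_flag = TRUE))
  expect_equal(all_is$mean, 100)
  zero <- is_transcriptome_fraction(
    data.frame(feature = "g", sense_count = 0, is_flag = TRUE))
  expect_true(is.na(zero$per_replicate$percent))
})
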