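test_that("N50 follows the cumulative-length rule", {
  contigs <- setNames(
    vapply(c(5, 4, 3, 2, 1) * 10, isburst:::random_dna, "", gc = 0.5),
    paste0("c", 1:5))
  st <- assembly_stats(contigs)
  expect_equal(st$n_contigs, 5)
  expect_equal(st$total_length, 150)
  expect_equal(st$n50, 40)
  one <- assembly_stats(c(x = isburst:::random_dna(777, 0.5)))
  expect_equal(one$n50, 777)
  expect_error(assembly_stats(character(0)))
  expect_true(is.na(st$gc_coding))  # no annotation supplied
})

make_protein <- function(n) paste(
  sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
  collapse = "")

mutate_protein <- function(p, positions) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(p, "")[[1]]
  for (i in positions) chars[i] <- sample(setdiff(aa, chars[i]), 1)
  paste(chars, collapse = "")
}

test_that("paralog clustering applies identity/coverage single linkage", {
  set.seed(61)
  a <- make_protein(100)
  # identical pair -> one cluster of two
  cl <- cluster_paralogs(c(p1 = a, p2 = a))
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(cl$n_members, c(2L, 2L))
  # ~40% identity, full coverage -> two singletons
  b40 <- mutate_protein(a, 1:60)
  cl2 <- cluster_paralogs(c(p1 = a, p2 = b40))
  expect_equal(length(unique(cl2$cluster_id)), 2)
  # A~B 60%, B~C 60%, A~C ~30% -> one cluster by transitivity
  b <- mutate_protein(a, 1:40)
  cc <- mutate_protein(b, 31:70)
  cl3 <- cluster_paralogs(c(A = a, B = b, C = cc))
  expect_equal(length(unique(cl3$cluster_id)), 1)
  expect_equal(sort(cl3$gene_id), c("A", "B", "C"))
})

test_that("clustering is invariant to input order and rejects bad residues", {
  set.seed(62)
  prots <- c(x1 = make_protein(80), x2 = make_protein(120),
             x3 = make_protein(60))
  prots["x4"] <- mutate_protein(prots[["x1"]], 1:20)  # 75% id to x1
  c1 <- cluster_paralogs(prots)
  c2 <- cluster_paralogs(rev(prots))
  expect_identical(c1, c2)
  expect_message(cbad <- cluster_paralogs(c(prots, bad = "MKL123")),
                 "invalid residues")
  expect_identical(attr(cbad, "rejected"), "bad")
  expect_false("bad" %in% cbad$gene_id)
})

test_that("family annotation classifies by E-value against a reference", {
  set.seed(63)
  ref <- c(tnpA_IS630 = make_protein(300), tnpB_IS4 = make_protein(280))
  fams <- c("IS630", "IS4")
  # identical to the IS630 reference -> labelled IS630
  ann <- annotate_is_families(c(q = ref[[1]]), ref, fams)
  expect_equal(ann$family, "IS630")
  expect_lt(ann$evalue, 1e-9)
  # a random sequence finds no significant hit
  ann2 <- annotate_is_families(c(q = make_protein(300)), ref, fams)
  expect_equal(ann2$family, "unclassified")
  # a family absent from the reference stays unclassified
  novel <- make_protein(350)
  ann3 <- annotate_is_families(c(ISAm1_like = novel), ref, fams)
  expect_equal(ann3$family, "unclassified")
  expect_warning(annotate_is_families(c(q = novel), character(0)),
                 "empty reference")
})

test_that("pseudogene flagging detects frameshifts and premature stops", {
  set.seed(64)
  intact <- isburst:::random_orf(99, 0.5)
  expect_true(flag_pseudogenes(c(g = intact))$intact)
  # single-base deletion at codon 10: frameshift
  fs <- paste0(substr(intact, 1, 29), substr(intact, 31, nchar(intact)))
  ffs <- flag_pseudogenes(c(g = fs))
  expect_false(ffs$intact)
  expect_match(ffs$reasons, "frameshift")
  # frameshift-induced premature stop is confirmed by translation
  aa <- isburst:::translate_cds(substr(fs, 1, nchar(fs) - nchar(fs) %% 3))
  expect_identical(grepl("\\*", substr(aa, 1, nchar(aa) - 1)),
                   grepl("premature_stop", ffs$reasons))
  # internal TGA at codon 5
  ps <- paste0(substr(intact, 1, 12), "TGA", substr(intact, 16,
                                                    nchar(intact)))
  fps <- flag_pseudogenes(c(g = ps))
  expect_false(fps$intact)
  expect_match(fps$reasons, "premature_stop")
})

test_that("element scanning recovers planted copies and nothing else", {
  g <- fixture_nine_copy_genome()
  el <- g$elements$ISAm1$consensus
  hits <- scan_element_copies(g, el)
  expect_equal(nrow(hits), 9)
  # every planted copy is recovered at its planted coordinates
  truth <- g$copies[order(g$copies$start), ]
  expect_true(all(abs(hits$start - truth$start) <= 2))
  expect_true(all(abs(hits$end - truth$end) <= 2))
  expect_identical(hits$strand, truth$strand)
  # an unrelated element is not found
  absent <- isburst:::random_dna(1200, 0.45)
  expect_equal(nrow(scan_element_copies(g, absent)), 0)
})

test_that("family divergence report aggregates and sorts by recency", {
  # a recently expanded family: four intact copies at 0.5% divergence
  fam <- is_family("ISNew", element_length = 900, copy_number = 4,
                   intact_copies = 4, divergence = 0.005)
  g <- generate_genome(contig_lengths = 2e4, family_specs = list(fam),
                       gene_density = 0.2, seed = 65)
  tnp <- g$copies$gene_id
  cds <- get_cds(g, tnp)
  members <- data.frame(gene_id = tnp, family = "ISNew")
  pairs <- pairwise_dnds_table(cds, members)
  fl <- flag_pseudogenes(cds)
  rep <- family_divergence_report(members, pairs, fl)
  expect_equal(rep$copy_number, 4)
  expect_equal(rep$n_pairs, 6)
  expect_equal(rep$fraction_pseudogenized, 0)
  # planted per-copy divergence 0.005 -> mean pairwise dS near 2x
  expect_gt(rep$mean_dS, 0)
  expect_lt(rep$mean_dS, 0.05)
  # ordering: the recent-burst family sorts before a diverged one
  pairs2 <- rbind(pairs, data.frame(gene_a = "o1", gene_b = "o2", S = 100,
                                    N = 200, Sd = 25, Nd = 10, pS = 0.25,
                                    pN = 0.05, dS = 0.3, dN = 0.05,
                                    saturated_s = FALSE,
                                    saturated_n = FALSE))
  members2 <- rbind(members,
                    data.frame(gene_id = c("o1", "o2"), family = "ISOld"))
  rep2 <- family_divergence_report(members2, pairs2, fl)
  expect_identical(rep2$family, c("ISNew", "ISOld"))
  # the nine-copy ancestral configuration: 8/9 pseudogenized
  g9 <- fixture_nine_copy_genome()
  fl9 <- flag_pseudogenes(get_cds(g9, g9$copies$gene_id))
  rep9 <- family_divergence_report(
    data.frame(gene_id = g9$copies$gene_id, family = "ISAm1"),
    pairs[0, ], fl9)
  expect_equal(rep9$fraction_pseudogenized, 8 / 9)
})
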