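# Transposase census: assembly statistics, identity/coverage paralog
# clustering, IS family annotation by local similarity, pseudogene
# flagging, and genome-wide scanning for element copies.

#' Assembly statistics (contig count, N50, GC, coding/noncoding GC)
#'
#' N50 is the length of the shortest contig in the smallest set of longest
#' contigs whose summed length reaches half the assembly total. GC is
#' computed over unambiguous bases. Coding/noncoding GC requires an
#' annotation (gene intervals are merged before splitting the genome).
#'
#' @param contigs Named character vector (or `DNAStringSet`) of contig
#'   sequences, or an `is_genome`.
#' @param annotation Optional gene table with columns `contig`, `start`,
#'   `end` (1-based inclusive); taken from the genome when `contigs` is an
#'   `is_genome`.
#' @return List of class `assembly_stats`: n_contigs, total_length, n50,
#'   gc_overall, gc_coding, gc_noncoding (the last two `NA` without
#'   annotation).
#' @export
assembly_stats <- function(contigs, annotation = NULL) {
  if (inherits(contigs, "is_genome")) {
    annotation <- annotation %||% contigs$genes
    contigs <- contigs$contigs
  }
  nm <- names(contigs)
  contigs <- as.character(contigs)
  names(contigs) <- nm %||% sprintf("contig_%d", seq_along(contigs))
  if (!length(contigs) || any(!nzchar(contigs)))
    stop("need at least one non-empty contig")
  lens <- nchar(contigs)
  sl <- sort(unname(lens), decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1]]
  gc_coding <- gc_noncoding <- NA_real_
  if (!is.null(annotation) && nrow(annotation)) {
    cod <- character(0); noncod <- character(0)
    for (ct in names(contigs)) {
      a <- annotation[annotation$contig == ct, , drop = FALSE]
      if (nrow(a)) {
        ir <- IRanges::reduce(IRanges::IRanges(a$start, a$end))
        cod <- c(cod, substring(contigs[[ct]], IRanges::start(ir),
                                IRanges::end(ir)))
        gap <- IRanges::setdiff(IRanges::IRanges(1, nchar(contigs[[ct]])), ir)
        if (length(gap))
          noncod <- c(noncod, substring(contigs[[ct]], IRanges::start(gap),
                                        IRanges::end(gap)))
      } else noncod <- c(noncod, contigs[[ct]])
    }
    if (length(cod)) gc_coding <- gc_fraction_pooled(cod)
    if (length(noncod)) gc_noncoding <- gc_fraction_pooled(noncod)
  }
  structure(list(n_contigs = length(contigs), total_length = sum(lens),
                 n50 = n50, gc_overall = gc_fraction_pooled(contigs),
                 gc_coding = gc_coding, gc_noncoding = gc_noncoding),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("Assembly: %d contigs, %s bp, N50 = %s\n", x$n_contigs,
              format(x$total_length, big.mark = ","),
              format(x$n50, big.mark = ",")))
  cat(sprintf("  GC overall %.3f | coding %s | noncoding %s\n",
              x$gc_overall,
              ifelse(is.na(x$gc_coding), "-", sprintf("%.3f", x$gc_coding)),
              ifelse(is.na(x$gc_noncoding), "-",
                     sprintf("%.3f", x$gc_noncoding))))
  invisible(x)
}

VALID_AA <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"

# Pairwise overlap (ends-free) alignment of two proteins; returns identity
# over the shorter sequence and coverage of each sequence by the aligned
# region.
protein_pair_stats <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "overlap",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  nm <- Biostrings::nmatch(aln)
  list(identity = nm / min(nchar(a), nchar(b)),
       cov_a = Biostrings::width(Biostrings::pattern(aln)) / nchar(a),
       cov_b = Biostrings::width(Biostrings::subject(aln)) / nchar(b))
}

#' Cluster paralogous proteins by identity/coverage single linkage
#'
#' Two proteins are linked when a pairwise alignment reaches at least
#' `min_identity` amino-acid identity over the length of the shorter
#' sequence and covers at least `min_coverage` of the target sequence
#' (the criterion is tested with either sequence as target). Clusters are
#' the connected components (single linkage), so homology is transitive
#' across linked pairs. Deterministic: cluster membership is independent
#' of input order, cluster ids are assigned by the lexicographically
#' smallest member, and the representative is the longest member (ties
#' broken by id).
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param min_identity,min_coverage Linking thresholds in [0, 1].
#' @return Data frame (gene_id, cluster_id, representative, n_members),
#'   one row per retained protein; records with invalid residues are
#'   rejected and listed in `attr(, "rejected")`.
#' @export
cluster_paralogs <- function(proteins, min_identity = 0.5,
                             min_coverage = 0.5) {
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  bad <- !grepl(VALID_AA, proteins)
  # a single terminal stop is tolerated (translated CDS convention)
  proteins <- sub("\\*$", "", proteins)
  bad <- bad & !grepl(VALID_AA, proteins)
  rejected <- names(proteins)[bad]
  if (length(rejected))
    message("rejecting ", length(rejected),
            " record(s) with invalid residues: ",
            paste(rejected, collapse = ", "))
  proteins <- proteins[!bad]
  ids <- sort(names(proteins))
  proteins <- proteins[ids]
  n <- length(proteins)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      st <- protein_pair_stats(proteins[[i]], proteins[[j]])
      if (st$identity >= min_identity &&
          max(st$cov_a, st$cov_b) >= min_coverage) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  cluster_id <- paste0("cl_", ids[root])
  rep_of <- vapply(unique(root), function(r) {
    mem <- which(root == r)
    lens <- nchar(proteins[mem])
    ids[mem[order(-lens, ids[mem])[1]]]
  }, "")
  names(rep_of) <- as.character(unique(root))
  out <- data.frame(gene_id = ids, cluster_id = cluster_id,
                    representative = rep_of[as.character(root)],
                    n_members = as.integer(table(root)[as.character(root)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1);
# declared so the E-value model is explicit and fixed.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Annotate transposase proteins with IS family labels
#'
#' Each query is aligned locally (Smith-Waterman, BLOSUM62, gap 11/1)
#' against a reference transposase set; the family of the best hit with
#' Karlin-Altschul E-value `K*m*n*exp(-lambda*S)` at or below `max_evalue`
#' is assigned, otherwise `"unclassified"`.
#'
#' @param proteins Named character vector of query proteins.
#' @param reference_transposases Named character vector of reference
#'   proteins; `reference_families` gives a family label per reference
#'   (defaults to the reference names).
#' @param reference_families Character vector parallel to the reference.
#' @param max_evalue E-value cutoff.
#' @return Data frame (gene_id, family, best_hit, score, evalue).
#' @export
annotate_is_families <- function(proteins, reference_transposases,
                                 reference_families =
                                   names(reference_transposases),
                                 max_evalue = 1e-9) {
  if (!length(reference_transposases)) {
    warning("empty reference set; all queries unclassified")
    return(data.frame(gene_id = names(proteins), family = "unclassified",
                      best_hit = NA_character_, score = NA_real_,
                      evalue = NA_real_, stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(proteins), function(i) {
    q <- proteins[[i]]
    sc <- vapply(reference_transposases, function(ref)
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(ref), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE), 0)
    ev <- KA_K * nchar(q) * nchar(reference_transposases) *
      exp(-KA_LAMBDA * sc)
    best <- which.min(ev)
    data.frame(gene_id = names(proteins)[i],
               family = if (ev[best] <= max_evalue)
                 reference_families[best] else "unclassified",
               best_hit = names(reference_transposases)[best],
               score = sc[best], evalue = unname(ev[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag transposase coding sequences as intact or pseudogenized
#'
#' A CDS is intact iff its length is divisible by 3, it begins with a
#' bacterial start codon (ATG/GTG/TTG), ends with a stop codon, and has no
#' internal stop codon. Otherwise the reasons are reported (frameshift,
#' i.e. length not divisible by 3; no_start; premature_stop; no_stop).
#'
#' @param cds Named character vector of nucleotide sequences.
#' @return Data frame (gene_id, intact, reasons).
#' @export
flag_pseudogenes <- function(cds) {
  out <- lapply(seq_along(cds), function(i) {
    s <- toupper(cds[[i]])
    reasons <- character(0)
    if (nchar(s) %% 3 != 0) {
      reasons <- c(reasons, "frameshift")
      # inspect the longest in-frame prefix for the induced premature stop
      s3 <- substr(s, 1, nchar(s) - nchar(s) %% 3)
    } else s3 <- s
    cods <- if (nchar(s3) >= 3) split_codons(s3) else character(0)
    if (!length(cods) || !cods[1] %in% START_CODONS)
      reasons <- c(reasons, "no_start")
    if (length(cods) > 1 && any(cods[-length(cods)] %in% STOP_CODONS))
      reasons <- c(reasons, "premature_stop")
    if (!length(cods) || !cods[length(cods)] %in% STOP_CODONS)
      if (!"premature_stop" %in% reasons)
        reasons <- c(reasons, "no_stop")
    data.frame(gene_id = names(cds)[i] %||% as.character(i),
               intact = length(reasons) == 0,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scan a genome for copies of an IS element
#'
#' Seed-and-extend search: exact 18-mers sampled every 5 bp along the
#' element (and its reverse complement) anchor candidate loci; each
#' candidate region is then aligned globally against the element and
#' retained when identity over the element length reaches `min_identity`
#' and the aligned element span covers at least `min_length_fraction` of
#' the element. Overlapping candidates are resolved by highest identity,
#' then leftmost position.
#'
#' @param genome An `is_genome` or named character vector of contigs.
#' @param element_seq The query element sequence (>= 50 bp).
#' @param min_identity Minimum identity over the element length.
#' @param min_length_fraction Minimum aligned fraction of the element.
#' @return Data frame (contig, start, end, strand, identity,
#'   length_fraction) sorted by position.
#' @export
scan_element_copies <- function(genome, element_seq, min_identity = 0.95,
                                min_length_fraction = 0.90) {
  contigs <- if (inherits(genome, "is_genome")) genome$contigs else
    as.character(genome)
  L <- nchar(element_seq)
  stopifnot(L >= 50)
  seed_w <- 18L
  offs <- unique(c(seq(1L, L - seed_w + 1L, by = 5L), L - seed_w + 1L))
  queries <- c(`+` = element_seq, `-` = revcomp(element_seq))
  cand <- list()
  for (strand in names(queries)) {
    q <- queries[[strand]]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(
      substring(q, offs, offs + seed_w - 1L)))
    for (ct in names(contigs)) {
      hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(contigs[[ct]]))
      starts <- unlist(lapply(seq_along(offs), function(i)
        Biostrings::start(hits[[i]]) - offs[i] + 1L))
      if (!length(starts)) next
      tab <- table(starts)
      cand[[length(cand) + 1L]] <- data.frame(
        contig = ct, strand = strand, start = as.integer(names(tab)),
        n_seeds = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), length_fraction = numeric(0))
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # merge candidate anchors within 30 bp (same contig/strand) and align
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  rows <- list()
  for (key in unique(paste(cand$contig, cand$strand))) {
    cc <- cand[paste(cand$contig, cand$strand) == key, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(cc$start) > 30))
    for (g in unique(grp)) {
      anchor <- cc$start[grp == g][which.max(cc$n_seeds[grp == g])]
      ct <- cc$contig[1]; strand <- cc$strand[1]
      clen <- nchar(contigs[[ct]])
      ws <- max(1L, anchor - 20L)
      we <- min(clen, anchor + L + 19L)
      win <- substring(contigs[[ct]], ws, we)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(queries[[strand]]),
        Biostrings::DNAString(win), type = "global-local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      nm <- Biostrings::nmatch(aln)
      span <- Biostrings::width(Biostrings::subject(aln))
      identity <- nm / L
      length_fraction <- min(1, span / L)
      if (identity >= min_identity &&
          length_fraction >= min_length_fraction) {
        st <- ws + Biostrings::start(Biostrings::subject(aln)) - 1L
        en <- ws + Biostrings::end(Biostrings::subject(aln)) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ct, start = st, end = en,
          strand = strand, identity = identity,
          length_fraction = length_fraction, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # resolve overlaps: highest identity wins, then leftmost
  out <- out[order(out$contig, -out$identity, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i & out$contig == out$contig[i] &
                 out$start <= out$end[i] & out$end >= out$start[i])
    keep[j] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-family divergence and pseudogenization summary
#'
#' Aggregates pairwise divergence estimates and pseudogene flags by IS
#' family: copy number, mean and minimum pairwise dS (saturated pairs
#' excluded from the mean and counted separately), and the fraction of
#' copies flagged as pseudogenes. Families are ordered by ascending mean
#' dS, so the most recent burst sorts first.
#'
#' @param members Data frame (gene_id, family) assigning genes to
#'   families.
#' @param pairs Data frame of [pairwise_dnds()] results with columns
#'   gene_a, gene_b, dS, saturated_s (within-family pairs are selected by
#'   membership of both genes).
#' @param flags Optional [flag_pseudogenes()] output for the same genes.
#' @return Data frame (family, copy_number, mean_dS, min_dS,
#'   n_pairs, n_saturated, fraction_pseudogenized).
#' @export
family_divergence_report <- function(members, pairs, flags = NULL) {
  fam_of <- stats::setNames(members$family, members$gene_id)
  out <- lapply(sort(unique(members$family)), function(fam) {
    ids <- members$gene_id[members$family == fam]
    pp <- pairs[!is.na(fam_of[pairs$gene_a]) & !is.na(fam_of[pairs$gene_b]) &
                  fam_of[pairs$gene_a] == fam & fam_of[pairs$gene_b] == fam,
                , drop = FALSE]
    sat <- if (nrow(pp)) pp$saturated_s else logical(0)
    ds <- if (nrow(pp)) pp$dS[!sat] else numeric(0)
    frac_pseudo <- if (!is.null(flags)) {
      fl <- flags[flags$gene_id %in% ids, , drop = FALSE]
      if (nrow(fl)) mean(!fl$intact) else NA_real_
    } else NA_real_
    data.frame(family = fam, copy_number = length(ids),
               mean_dS = if (length(ds)) mean(ds) else NA_real_,
               min_dS = if (length(ds)) min(ds) else NA_real_,
               n_pairs = nrow(pp), n_saturated = sum(sat),
               fraction_pseudogenized = frac_pseudo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$mean_dS, out$family), , drop = FALSE]
}
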