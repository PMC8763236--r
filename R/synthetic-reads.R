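# Paired-end DNA-seq and stranded RNA-seq read simulators with truth.

phred_char <- function(q) intToUtf8(pmin(q, 93) + 33L, multiple = FALSE)

# iid substitution errors over a character vector of reads; returns the
# mutated reads. Error positions are uniform over read bases.
apply_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) <= 1)
  rl <- rl[1]
  chars <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                  nrow = rl)
  hit <- which(stats::runif(length(chars)) < error_rate)
  if (length(hit)) {
    orig <- chars[hit]
    repl <- vapply(orig, function(b) sample(setdiff(BASES, b), 1), "")
    chars[hit] <- repl
  }
  apply(chars, 2, paste, collapse = "")
}

#' Simulate paired-end sequencing reads from a genome mixture
#'
#' Fragments are sampled from each genome with probability proportional to
#' weight x genome length, with uniform start positions within contigs
#' (chosen proportional to contig length) and a random sequencing strand.
#' Base-calling errors are i.i.d. substitutions; the quality string encodes
#' the per-base error rate on the Sanger Phred+33 scale.
#'
#' @param genome_mixture List of `list(genome = <is_genome>, weight = w)`
#'   entries; weights must sum to 1.
#' @param depth Target mean coverage (fold).
#' @param read_length Read length in bp.
#' @param insert_size Outer fragment length; must be >= `read_length`.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return A list with `reads` (data.frame: id, mate, seq, qual, and truth
#'   columns genome, contig, start, end, strand) where both mates of a
#'   fragment share an id.
#' @export
simulate_reads <- function(genome_mixture, depth = 50, read_length = 150,
                           insert_size = 300, error_rate = 0.005,
                           seed = NULL) {
  w <- vapply(genome_mixture, function(x) x$weight, 0)
  stopifnot(abs(sum(w) - 1) < 1e-9, depth > 0)
  if (insert_size < read_length)
    stop("insert_size must be >= read_length")
  lens <- vapply(genome_mixture, function(x) sum(nchar(x$genome$contigs)), 0)
  n_frag <- max(1L, round(depth * max(lens) / (2 * read_length)))
  with_seed(seed, {
    gsel <- sample.int(length(w), n_frag, replace = TRUE, prob = w * lens)
    rows <- vector("list", length(genome_mixture))
    for (gi in seq_along(genome_mixture)) {
      nf <- sum(gsel == gi)
      if (!nf) next
      contigs <- genome_mixture[[gi]]$genome$contigs
      cl <- nchar(contigs)
      ok <- cl >= insert_size
      stopifnot(any(ok))
      csel <- sample(names(contigs)[ok], nf, replace = TRUE,
                     prob = cl[ok])
      start <- floor(stats::runif(nf) * (cl[csel] - insert_size)) + 1L
      frag <- substring(contigs[csel], start, start + insert_size - 1L)
      strand <- sample(c("+", "-"), nf, replace = TRUE)
      frag[strand == "-"] <- revcomp(frag[strand == "-"])
      r1 <- substr(frag, 1, read_length)
      r2 <- revcomp(substr(frag, insert_size - read_length + 1L,
                           insert_size))
      rows[[gi]] <- data.frame(genome = gi, contig = csel, start = start,
                               end = start + insert_size - 1L,
                               strand = strand, r1 = r1, r2 = r2,
                               stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    tr <- tr[sample.int(nrow(tr)), , drop = FALSE]
    tr$id <- sprintf("frag_%06d", seq_len(nrow(tr)))
    q <- phred_char(rep(round(-10 * log10(max(error_rate, 1e-4))),
                        read_length))
    reads <- data.frame(
      id = rep(tr$id, 2L),
      mate = rep(1:2, each = nrow(tr)),
      seq = apply_errors(c(tr$r1, tr$r2), error_rate),
      qual = q,
      genome = rep(tr$genome, 2L), contig = rep(tr$contig, 2L),
      start = rep(tr$start, 2L), end = rep(tr$end, 2L),
      strand = rep(tr$strand, 2L), stringsAsFactors = FALSE)
    rownames(reads) <- NULL
    list(reads = reads, n_fragments = nrow(tr))
  })
}

#' Write reads to FASTQ
#'
#' @param reads The `reads` data frame from [simulate_reads()] or
#'   [simulate_rnaseq()].
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  ids <- if (!is.null(reads$mate)) paste0(reads$id, "/", reads$mate) else
    reads$id
  writeLines(paste0("@", ids, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Simulate stranded RNA-seq reads from a set of genes
#'
#' Reads are sampled from genes with probability proportional to
#' weight x gene length, uniformly positioned within the gene. A fraction
#' of reads is emitted antisense (reverse-complement of the transcript).
#' Truth records per-gene sense and antisense counts.
#'
#' @param genes Data frame with columns `gene_id`, `seq`
#'   (transcript-oriented sequence) and `weight` (expression level per
#'   transcript, >= 0, not all zero).
#' @param n_reads Number of reads to draw.
#' @param antisense_fraction Fraction of reads emitted antisense.
#' @param read_length Read length (genes shorter than this are rejected).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return List with `reads` (data.frame: id, seq, qual, plus truth
#'   columns gene and sense) and `truth` (per-gene sense/antisense
#'   counts).
#' @export
simulate_rnaseq <- function(genes, n_reads = 1e4, antisense_fraction = 0,
                            read_length = 75, error_rate = 0,
                            seed = NULL) {
  stopifnot(all(genes$weight >= 0), any(genes$weight > 0),
            antisense_fraction >= 0, antisense_fraction <= 1)
  len <- nchar(genes$seq)
  if (any(len < read_length & genes$weight > 0))
    stop("genes shorter than read_length cannot be simulated")
  with_seed(seed, {
    pr <- genes$weight * len
    gi <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = pr)
    pos <- floor(stats::runif(n_reads) * (len[gi] - read_length + 1L)) + 1L
    seqs <- substring(genes$seq[gi], pos, pos + read_length - 1L)
    sense <- stats::runif(n_reads) >= antisense_fraction
    if (any(!sense)) seqs[!sense] <- revcomp(seqs[!sense])
    seqs <- apply_errors(seqs, error_rate)
    q <- phred_char(rep(round(-10 * log10(max(error_rate, 1e-4))),
                        read_length))
    reads <- data.frame(id = sprintf("rna_%06d", seq_len(n_reads)),
                        seq = seqs, qual = q,
                        gene = genes$gene_id[gi], sense = sense,
                        stringsAsFactors = FALSE)
    truth <- data.frame(
      gene_id = genes$gene_id,
      sense_count = tabulate(gi[sense], nbins = nrow(genes)),
      antisense_count = tabulate(gi[!sense], nbins = nrow(genes)))
    list(reads = reads, truth = truth)
  })
}
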