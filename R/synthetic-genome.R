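#' Specification of a synthetic IS element family
#'
#' Describes one insertion-sequence family to plant in a synthetic genome:
#' a transposase ORF flanked by terminal inverted repeats (ITRs), present in
#' `copy_number` copies of which `intact_copies` carry an undisrupted ORF.
#' The remaining copies receive a single-base deletion inside the ORF
#' (a frameshift), emulating pseudogenized element copies.
#'
#' @param family_id Family label, e.g. `"ISAm1"`.
#' @param element_length Total element length in bp (ITRs included).
#' @param copy_number Number of copies to plant.
#' @param intact_copies Number of copies whose transposase ORF is intact.
#' @param divergence Expected substitutions/site of each copy from the
#'   family consensus (per-site Bernoulli mutation draws).
#' @param itr_length Length of the terminal inverted repeat in bp.
#' @param tsd_length Target-site duplication length `k` generated on
#'   transposition of this family.
#' @return An object of class `is_family` (a validated list).
#' @export
is_family <- function(family_id, element_length = 1500, copy_number = 1,
                      intact_copies = 1, divergence = 0,
                      itr_length = 14, tsd_length = 8) {
  stopifnot(intact_copies <= copy_number,
            itr_length >= 0, tsd_length >= 0,
            element_length > 2 * itr_length,
            divergence >= 0, divergence < 1)
  structure(list(family_id = as.character(family_id),
                 element_length = as.integer(element_length),
                 copy_number = as.integer(copy_number),
                 intact_copies = as.integer(intact_copies),
                 divergence = divergence,
                 itr_length = as.integer(itr_length),
                 tsd_length = as.integer(tsd_length)),
            class = "is_family")
}

# Consensus element: left ITR + spacer/ORF + right ITR (= revcomp of left).
build_element_consensus <- function(fam, gc = 0.45) {
  itr <- fam$itr_length
  interior <- fam$element_length - 2L * itr
  # transposase ORF fills as much of the interior as codon structure allows
  n_codons <- interior %/% 3L
  orf <- random_orf(n_codons, gc)
  pad <- interior - 3L * n_codons
  left <- if (itr > 0) random_dna(itr, gc) else ""
  right <- if (itr > 0) revcomp(left) else ""
  pad_seq <- if (pad > 0) random_dna(pad, gc) else ""
  # keep the realized inverted repeat at exactly itr bp: the base just
  # inside the right ITR must not complement the base just inside the
  # left ITR (which is the A of the ORF's ATG)
  if (itr > 0 && pad > 0 && substr(pad_seq, pad, pad) == "T")
    substr(pad_seq, pad, pad) <- "A"
  seq <- paste0(left, orf, pad_seq, right)
  stopifnot(nchar(seq) == fam$element_length)
  list(seq = seq, orf_start = itr + 1L, orf_end = itr + 3L * n_codons)
}

# Mutate a copy away from consensus; for intact copies the ORF must stay
# intact (start codon, no internal stop, terminal stop), so draws are
# retried a bounded number of times.
mutate_copy <- function(consensus, divergence, keep_orf_intact,
                        orf_start, orf_end, max_tries = 50) {
  if (divergence <= 0) return(consensus)
  n <- nchar(consensus)
  for (try in seq_len(max_tries)) {
    idx <- which(stats::runif(n) < divergence)
    if (!length(idx)) return(consensus)
    chars <- strsplit(consensus, "")[[1]]
    for (i in idx) chars[i] <- sample(setdiff(BASES, chars[i]), 1)
    out <- paste(chars, collapse = "")
    if (!keep_orf_intact) return(out)
    orf <- substr(out, orf_start, orf_end)
    cods <- split_codons(orf)
    if (cods[1] %in% START_CODONS &&
        cods[length(cods)] %in% STOP_CODONS &&
        !any(cods[-length(cods)] %in% STOP_CODONS)) return(out)
  }
  consensus  # give up mutating rather than break the ORF
}

#' Generate a synthetic annotated genome with planted IS element copies
#'
#' Builds one or more contigs of random sequence with a coding/noncoding GC
#' split, ordinary protein-coding genes at the requested density, and IS
#' element copies planted according to `family_specs` (see [is_family()]).
#' Non-intact copies carry a 1-bp deletion in the transposase ORF
#' (frameshift), so they are detectable by [flag_pseudogenes()].
#'
#' @param contig_lengths Integer vector of target contig lengths (bp).
#'   Realized lengths may differ by up to one gene/element length.
#' @param gc_coding,gc_noncoding GC fraction used when drawing coding and
#'   noncoding sequence.
#' @param gene_density Approximate fraction of each contig covered by
#'   ordinary genes.
#' @param family_specs List of [is_family()] objects.
#' @param mean_gene_length Mean ordinary-gene length in bp.
#' @param seed Integer seed; the result is deterministic given all
#'   arguments and the seed.
#' @return An object of class `is_genome`: a list with `contigs` (named
#'   character vector), `genes` (annotation data frame: gene_id, contig,
#'   start, end, strand, product, family, is_transposase, intact),
#'   `elements` (per-family consensus sequences) and `copies` (truth table
#'   of planted element copies with coordinates and intact status).
#' @export
generate_genome <- function(contig_lengths = 5e4, gc_coding = 0.475,
                            gc_noncoding = 0.415, gene_density = 0.6,
                            family_specs = list(), mean_gene_length = 900,
                            seed = NULL) {
  stopifnot(all(contig_lengths > 0), gc_coding > 0, gc_coding < 1,
            gc_noncoding > 0, gc_noncoding < 1,
            gene_density >= 0, gene_density < 1)
  for (f in family_specs)
    if (!inherits(f, "is_family")) stop("family_specs must be is_family objects")
  with_seed(seed, {
    elements <- list()
    copy_items <- list()  # one entry per planted copy
    for (f in family_specs) {
      cons <- build_element_consensus(f, gc = gc_coding)
      elements[[f$family_id]] <- list(spec = f, consensus = cons$seq,
                                      orf_start = cons$orf_start,
                                      orf_end = cons$orf_end)
      if (f$copy_number == 0) next
      intact <- rep(c(TRUE, FALSE), c(f$intact_copies,
                                      f$copy_number - f$intact_copies))
      for (ci in seq_len(f$copy_number)) {
        s <- mutate_copy(cons$seq, f$divergence, intact[ci],
                         cons$orf_start, cons$orf_end)
        orf_end <- cons$orf_end
        if (!intact[ci]) {  # frameshift: delete one base mid-ORF
          del <- sample(seq(cons$orf_start + 30L, cons$orf_end - 30L), 1)
          s <- paste0(substr(s, 1, del - 1), substr(s, del + 1, nchar(s)))
          orf_end <- orf_end - 1L
        }
        copy_items[[length(copy_items) + 1L]] <- list(
          family = f$family_id, copy_index = ci, seq = s, intact = intact[ci],
          orf_start = cons$orf_start, orf_end = orf_end)
      }
    }
    # distribute planted copies across contigs proportional to length
    n_contig <- length(contig_lengths)
    copy_contig <- if (length(copy_items))
      sort(sample.int(n_contig, length(copy_items), replace = TRUE,
                      prob = contig_lengths)) else integer(0)
    genes <- list(); copies <- list(); contigs <- character(n_contig)
    gene_n <- 0L
    for (ct in seq_len(n_contig)) {
      len <- contig_lengths[ct]
      items <- list()
      # ordinary genes
      n_genes <- max(0L, round(gene_density * len / mean_gene_length))
      for (g in seq_len(n_genes)) {
        nc <- max(60L, round(stats::rnorm(1, mean_gene_length, mean_gene_length / 5))) %/% 3L
        items[[length(items) + 1L]] <- list(kind = "gene",
                                            seq = random_orf(nc, gc_coding),
                                            strand = sample(c("+", "-"), 1))
      }
      for (k in which(copy_contig == ct)) {
        it <- copy_items[[k]]
        it$kind <- "is_copy"
        it$strand <- sample(c("+", "-"), 1)
        items[[length(items) + 1L]] <- it
      }
      item_len <- sum(vapply(items, function(i) nchar(i$seq), 0))
      spacer_total <- len - item_len
      if (spacer_total < length(items) + 1L)
        stop("contig ", ct, " too short to host the requested genes/copies")
      if (length(items)) items <- items[sample.int(length(items))]
      cuts <- sort(sample.int(spacer_total - 1L, length(items)))
      spac <- diff(c(0L, cuts, spacer_total))
      pos <- 1L; parts <- character(0)
      parts <- c(parts, random_dna(spac[1], gc_noncoding))
      pos <- pos + spac[1]
      for (i in seq_along(items)) {
        it <- items[[i]]
        w <- nchar(it$seq)
        seq_out <- if (it$strand == "-") revcomp(it$seq) else it$seq
        start <- pos; end <- pos + w - 1L
        if (it$kind == "gene") {
          gene_n <- gene_n + 1L
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = sprintf("gene_%04d", gene_n), contig = ct,
            start = start, end = end, strand = it$strand,
            product = "hypothetical protein", family = NA_character_,
            is_transposase = FALSE, intact = TRUE,
            stringsAsFactors = FALSE)
        } else {
          gene_n <- gene_n + 1L
          # transposase CDS coordinates inside the planted element
          if (it$strand == "+") {
            gs <- start + it$orf_start - 1L; ge <- start + it$orf_end - 1L
          } else {
            gs <- end - it$orf_end + 1L; ge <- end - it$orf_start + 1L
          }
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = sprintf("gene_%04d", gene_n), contig = ct,
            start = gs, end = ge, strand = it$strand,
            product = "transposase", family = it$family,
            is_transposase = TRUE, intact = it$intact,
            stringsAsFactors = FALSE)
          copies[[length(copies) + 1L]] <- data.frame(
            family = it$family, copy_index = it$copy_index, contig = ct,
            start = start, end = end, strand = it$strand,
            intact = it$intact, gene_id = sprintf("gene_%04d", gene_n),
            stringsAsFactors = FALSE)
        }
        parts <- c(parts, seq_out)
        pos <- end + 1L
        parts <- c(parts, random_dna(spac[i + 1L], gc_noncoding))
        pos <- pos + spac[i + 1L]
      }
      contigs[ct] <- paste(parts, collapse = "")
    }
    names(contigs) <- sprintf("contig_%d", seq_len(n_contig))
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), contig = integer(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 product = character(0), family = character(0),
                 is_transposase = logical(0), intact = logical(0))
    copies <- if (length(copies)) do.call(rbind, copies) else
      data.frame(family = character(0), copy_index = integer(0),
                 contig = integer(0), start = integer(0), end = integer(0),
                 strand = character(0), intact = logical(0),
                 gene_id = character(0))
    genes$contig <- names(contigs)[genes$contig]
    if (nrow(copies)) copies$contig <- names(contigs)[copies$contig]
    structure(list(contigs = contigs, genes = genes,
                   elements = elements, copies = copies),
              class = "is_genome")
  })
}

#' @export
print.is_genome <- function(x, ...) {
  cat("Synthetic annotated genome\n")
  cat(sprintf("  contigs: %d (%s bp total)\n", length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  cat(sprintf("  genes: %d (%d transposase)\n", nrow(x$genes),
              sum(x$genes$is_transposase)))
  if (nrow(x$copies))
    cat(sprintf("  planted IS copies: %d in %d families\n",
                nrow(x$copies), length(unique(x$copies$family))))
  invisible(x)
}

#' Extract a gene's coding sequence from an annotated genome
#'
#' @param genome An `is_genome` (or any list with `contigs` and `genes`).
#' @param gene_id Gene identifier(s) from the annotation table.
#' @return Named character vector of CDS sequences, transcript-oriented.
#' @export
get_cds <- function(genome, gene_id) {
  g <- genome$genes[match(gene_id, genome$genes$gene_id), , drop = FALSE]
  if (anyNA(g$start)) stop("unknown gene id(s)")
  out <- substring(genome$contigs[g$contig], g$start, g$end)
  neg <- g$strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  names(out) <- gene_id
  out
}

#' Write a genome as FASTA plus a GFF3 annotation
#'
#' Coordinates in the GFF3 are 1-based inclusive.
#'
#' @param genome An `is_genome`.
#' @param fasta_path,gff_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, fasta_path)
  g <- genome$genes
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ct in names(genome$contigs))
    writeLines(sprintf("##sequence-region %s 1 %d", ct,
                       nchar(genome$contigs[[ct]])), con)
  if (nrow(g)) {
    attrs <- sprintf("ID=%s;product=%s%s", g$gene_id, g$product,
                     ifelse(is.na(g$family), "",
                            paste0(";is_family=", g$family)))
    writeLines(sprintf("%s\tisburst\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       g$contig, g$start, g$end, g$strand, attrs), con)
  }
  invisible(c(fasta_path, gff_path))
}

#' Read a FASTA + GFF3 pair back into the genome container
#'
#' Understands the subset of GFF3 written by [write_genome()] (CDS rows
#' with ID/product/is_family attributes).
#'
#' @param fasta_path,gff_path Input file paths.
#' @return An `is_genome` (without element consensus or truth tables).
#' @export
read_genome <- function(fasta_path, gff_path = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- as.character(ss)
  names(contigs) <- sub("\\s.*$", "", names(ss))
  genes <- data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), product = character(0),
                      family = character(0), is_transposase = logical(0),
                      intact = logical(0))
  if (!is.null(gff_path)) {
    ln <- readLines(gff_path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    if (length(ln)) {
      f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
      attr_get <- function(a, key) {
        m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
        vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
      }
      fam <- attr_get(f[, 9], "is_family")
      genes <- data.frame(
        gene_id = attr_get(f[, 9], "ID"), contig = f[, 1],
        start = as.integer(f[, 4]), end = as.integer(f[, 5]),
        strand = f[, 7], product = attr_get(f[, 9], "product"),
        family = fam, is_transposase = !is.na(fam),
        intact = NA, stringsAsFactors = FALSE)
    }
  }
  structure(list(contigs = contigs, genes = genes,
                 elements = list(), copies = NULL),
            class = "is_genome")
}
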