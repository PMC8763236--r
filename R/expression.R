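# Ambiguity-aware expression quantification for clusters of
# near-identical paralogs: read recruitment (end-to-end, substitution
# only), exact-match disambiguation, strand-aware counting, and TPM.

# All end-to-end substitution-only matches of equal-width reads against a
# set of member sequences. Returns a data.frame (read, member, mm,
# orientation). Exact matches are found in bulk with PDict; reads without
# an exact hit are rescanned per member allowing up to max_mm
# substitutions.
match_reads_to_members <- function(reads, members, max_mm) {
  stopifnot(length(unique(nchar(reads))) <= 1)
  n <- length(reads)
  if (!n) return(data.frame(read = integer(0), member = character(0),
                            mm = integer(0), orientation = character(0)))
  hits <- list()
  for (ori in c("+", "-")) {
    seqs <- if (ori == "+") reads else revcomp(reads)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
    for (mb in names(members)) {
      cnt <- Biostrings::countPDict(pd, Biostrings::DNAString(members[[mb]]))
      idx <- which(cnt > 0)
      if (length(idx))
        hits[[length(hits) + 1L]] <- data.frame(
          read = idx, member = mb, mm = 0L, orientation = ori,
          stringsAsFactors = FALSE)
    }
  }
  exact <- if (length(hits)) do.call(rbind, hits) else
    data.frame(read = integer(0), member = character(0), mm = integer(0),
               orientation = character(0))
  if (max_mm > 0) {
    unmatched <- setdiff(seq_len(n), unique(exact$read))
    extra <- list()
    for (i in unmatched) {
      for (ori in c("+", "-")) {
        s <- if (ori == "+") reads[i] else revcomp(reads[i])
        for (mb in names(members)) {
          m <- Biostrings::matchPattern(s, members[[mb]],
                                        max.mismatch = max_mm,
                                        with.indels = FALSE)
          if (length(m)) {
            mm <- min(vapply(as.character(m), function(w)
              hamming(w, s), 0L))
            extra[[length(extra) + 1L]] <- data.frame(
              read = i, member = mb, mm = mm, orientation = ori,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(extra)) exact <- rbind(exact, do.call(rbind, extra))
  }
  exact
}

#' Recruit reads to clusters of paralogous genes
#'
#' A read is recruited to a cluster when it aligns end-to-end to at least
#' one member with at most `max_mismatches` substitutions (no indels), in
#' either orientation. A read matching members of several clusters is
#' assigned to the cluster with the fewest mismatches; cross-cluster ties
#' are dropped and counted.
#'
#' @param reads Character vector (or the `reads` data frame from
#'   [simulate_rnaseq()]) of equal-length reads.
#' @param clusters Named list: cluster id -> named character vector of
#'   member gene sequences.
#' @param max_mismatches Maximum substitutions for recruitment.
#' @return Data frame (read_id, cluster_id, mismatches, orientation,
#'   n_perfect_members, unambiguous_gene). `unambiguous_gene` is the
#'   single member the read matches perfectly end-to-end, or `NA` when
#'   the read is ambiguous within its cluster. `attr(, "n_tie_dropped")`
#'   counts reads dropped for cross-cluster ties.
#' @export
recruit_reads <- function(reads, clusters, max_mismatches = 3) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    reads <- reads$seq
  } else ids <- names(reads) %||% as.character(seq_along(reads))
  stopifnot(length(reads) > 0, length(clusters) > 0)
  member_cluster <- rep(names(clusters),
                        vapply(clusters, length, 0L))
  members <- unlist(unname(lapply(clusters, identity)))
  names(members) <- unlist(lapply(clusters, names))
  stopifnot(!anyDuplicated(names(members)))
  hits <- match_reads_to_members(reads, members, max_mismatches)
  if (!nrow(hits)) {
    out <- data.frame(read_id = character(0), cluster_id = character(0),
                      mismatches = integer(0), orientation = character(0),
                      n_perfect_members = integer(0),
                      unambiguous_gene = character(0))
    attr(out, "n_tie_dropped") <- 0L
    return(out)
  }
  hits$cluster <- member_cluster[match(hits$member, names(members))]
  # best hit per (read, cluster), then winning cluster per read
  h <- hits[order(hits$read, hits$mm), , drop = FALSE]
  bk <- h[!duplicated(paste(h$read, h$cluster)), , drop = FALSE]
  bk <- bk[order(bk$read, bk$mm), , drop = FALSE]
  best <- bk[!duplicated(bk$read), , drop = FALSE]
  min_mm <- best$mm[match(bk$read, best$read)]
  n_best <- tapply(bk$mm <= min_mm, bk$read, sum)
  tied <- names(n_best)[n_best > 1]
  n_tie <- length(tied)
  best <- best[!as.character(best$read) %in% tied, , drop = FALSE]
  # perfect full-length members within the winning cluster
  ph <- hits[hits$mm == 0, , drop = FALSE]
  ph <- ph[paste(ph$read, ph$cluster) %in%
             paste(best$read, best$cluster), , drop = FALSE]
  ph <- ph[!duplicated(paste(ph$read, ph$member)), , drop = FALSE]
  n_perfect <- tapply(ph$member, ph$read, length)
  single <- tapply(ph$member, ph$read, function(m)
    if (length(m) == 1) m else NA_character_)
  np <- as.integer(n_perfect[as.character(best$read)])
  np[is.na(np)] <- 0L
  out <- data.frame(
    read_id = ids[best$read], cluster_id = best$cluster,
    mismatches = best$mm, orientation = best$orientation,
    n_perfect_members = np,
    unambiguous_gene = unname(single[as.character(best$read)]),
    stringsAsFactors = FALSE)
  out <- out[order(best$read), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tie_dropped") <- n_tie
  out
}

#' Classify one recruited read as unambiguous or ambiguous
#'
#' A read is unambiguous iff it is a perfect full-length substring (either
#' orientation) of exactly one cluster member.
#'
#' @param read A single read sequence.
#' @param members Named character vector of cluster member sequences.
#' @return `list(status = "unambiguous", gene = <id>)` or
#'   `list(status = "ambiguous", gene = NA)`.
#' @export
classify_ambiguity <- function(read, members) {
  hit <- vapply(members, function(m)
    length(Biostrings::matchPattern(read, m)) > 0 ||
      length(Biostrings::matchPattern(revcomp(read), m)) > 0, TRUE)
  if (sum(hit) == 1)
    list(status = "unambiguous", gene = names(members)[hit])
  else list(status = "ambiguous", gene = NA_character_)
}

#' Strand-aware cluster and per-gene expression counts
#'
#' Each recruited read increments exactly one cluster total (sense or
#' antisense, according to the match orientation and the library
#' protocol) and, when unambiguous, the counter of its single perfectly
#' matching member gene. Member sequences are transcript-oriented, so a
#' `+` orientation match means the read was sequenced from the transcript
#' strand.
#'
#' @param recruitment Output of [recruit_reads()].
#' @param protocol `"FR-stranded"` (read 1 on the transcript strand),
#'   `"RF-stranded"` (dUTP; read 1 opposite the transcript strand) or
#'   `"unstranded"` (all reads counted as sense).
#' @return List with `clusters` (cluster_id, total_sense,
#'   total_antisense) and `genes` (cluster_id, gene_id,
#'   unambiguous_sense, unambiguous_antisense).
#' @export
count_expression <- function(recruitment, protocol = "RF-stranded") {
  if (!protocol %in% c("FR-stranded", "RF-stranded", "unstranded"))
    stop("unknown protocol: ", protocol)
  r <- recruitment
  sense <- switch(protocol,
                  "FR-stranded" = r$orientation == "+",
                  "RF-stranded" = r$orientation == "-",
                  "unstranded" = rep(TRUE, nrow(r)))
  cl <- sort(unique(r$cluster_id))
  clusters <- data.frame(
    cluster_id = cl,
    total_sense = vapply(cl, function(c)
      sum(r$cluster_id == c & sense), 0L),
    total_antisense = vapply(cl, function(c)
      sum(r$cluster_id == c & !sense), 0L),
    stringsAsFactors = FALSE)
  u <- r[!is.na(r$unambiguous_gene), , drop = FALSE]
  us <- sense[!is.na(r$unambiguous_gene)]
  key <- paste(u$cluster_id, u$unambiguous_gene)
  uk <- unique(key)
  genes <- data.frame(
    cluster_id = sub(" .*$", "", uk),
    gene_id = sub("^[^ ]* ", "", uk),
    unambiguous_sense = vapply(uk, function(k) sum(key == k & us), 0L),
    unambiguous_antisense = vapply(uk, function(k) sum(key == k & !us), 0L),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  list(clusters = clusters, genes = genes)
}

#' Transcripts-per-million normalization
#'
#' `rate_i = count_i / (length_i/1000)`; `TPM_i = 1e6 * rate_i / sum(rate)`.
#' All-zero counts yield all-zero TPM.
#'
#' @param counts Non-negative read counts (one per feature).
#' @param lengths Feature lengths in bp (> 0).
#' @return Numeric TPM vector (sums to 1e6 when any count is positive).
#' @export
compute_tpm <- function(counts, lengths) {
  if (any(counts < 0)) stop("negative counts")
  stopifnot(all(lengths > 0), length(counts) == length(lengths))
  rate <- counts / (lengths / 1000)
  if (sum(rate) == 0) return(rate)
  1e6 * rate / sum(rate)
}

#' Percent of sense transcription derived from IS features
#'
#' @param expression Data frame with columns `feature`, `sense_count`,
#'   `is_flag` (logical) and optionally `replicate`.
#' @return List with `per_replicate` (replicate, percent), `mean` and
#'   `sd` (NA with a single replicate). Replicates with zero total counts
#'   yield `NA` percent.
#' @export
is_transcriptome_fraction <- function(expression) {
  stopifnot(all(c("feature", "sense_count", "is_flag") %in%
                  names(expression)))
  if (is.null(expression$replicate)) expression$replicate <- 1L
  reps <- sort(unique(expression$replicate))
  pct <- vapply(reps, function(rp) {
    e <- expression[expression$replicate == rp, , drop = FALSE]
    tot <- sum(e$sense_count)
    if (tot == 0) return(NA_real_)
    100 * sum(e$sense_count[e$is_flag]) / tot
  }, 0)
  list(per_replicate = data.frame(replicate = reps, percent = pct),
       mean = mean(pct, na.rm = TRUE),
       sd = if (length(pct) > 1) stats::sd(pct, na.rm = TRUE) else NA_real_)
}
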