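# Junction-evidence insertion caller for mixed-population short reads.
#
# A read supports a junction when it splits into a reference-matching
# segment and an element-terminus-matching segment, each of at least m
# bases with at most one mismatch. Reference-spanning reads at the same
# coordinate provide the denominator for the allele-frequency estimate
# f = mean over sides of J/(J+S).

# Maximal prefix length of `seg` matching `ref_window` (equal length)
# under the rule: at most one mismatch, and a mismatch is only accepted
# when followed by >= 4 further matching bases (an internal sequencing
# error, not a junction breakpoint).
max_prefix_match <- function(seg, ref_window) {
  mm <- mismatch_positions(seg, ref_window)
  n <- nchar(seg)
  if (!length(mm)) return(n)
  m1 <- mm[1]
  nxt <- if (length(mm) > 1) mm[2] else n + 1L
  if (nxt - m1 > 4L) nxt - 1L else m1 - 1L
}

# Matches of `seg` against the start of `term` allowing <= 1 mismatch.
matches_prefix <- function(seg, term) {
  h <- nchar(seg)
  h <= nchar(term) && hamming(seg, substr(term, 1, h)) <= 1
}
matches_suffix <- function(seg, term) {
  h <- nchar(seg)
  h <= nchar(term) &&
    hamming(seg, substr(term, nchar(term) - h + 1, nchar(term))) <= 1
}

#' Find IS junction evidence in reads by split matching
#'
#' Reads are anchored to the reference with exact 16-mers at either end
#' and extended; reads matching the reference end-to-end are recorded as
#' reference alignments, while reads with an overhang of at least `m`
#' bases matching an element terminus (either element orientation, at
#' most one mismatch per segment) become junction evidence. A `left`
#' junction has reference sequence to the left of the element in forward
#' reference coordinates; its boundary is the last reference-matching
#' base. A `right` junction's boundary is the first reference-matching
#' base after the element.
#'
#' @param reads Data frame with `seq` and `qual` columns (e.g. from
#'   [simulate_reads()]) or a character vector.
#' @param reference Named character vector of contigs or an `is_genome`.
#' @param element_library Named character vector of full element
#'   sequences (names = family labels).
#' @param m Minimum segment length on each side of the junction.
#' @return List of class `junction_evidence`: `evidence` (one row per
#'   supporting read: contig, boundary, side, family, orientation,
#'   read_id, read_strand, overhang_ref, overhang_elem, elem_quals) and
#'   `spanning` (full-length reference alignments: contig, start, end,
#'   read_strand).
#' @export
find_junctions <- function(reads, reference, element_library, m = 12) {
  if (inherits(reference, "is_genome")) reference <- reference$contigs
  if (is.data.frame(reads)) {
    ids <- if (!is.null(reads$mate)) paste0(reads$id, "/", reads$mate) else
      reads$id %||% as.character(seq_len(nrow(reads)))
    quals <- reads$qual
    reads <- reads$seq
  } else {
    ids <- names(reads) %||% as.character(seq_along(reads))
    quals <- NULL
  }
  stopifnot(all(nchar(element_library) >= m))
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) == 1)
  rl <- rl[1]
  # exact anchor no longer than the minimum overhang, so junction reads
  # with an m-base flank segment are still anchorable
  anchor_w <- max(10L, min(16L, as.integer(m)))
  termini <- list()  # per family/orientation: element start/end sequences
  for (fam in names(element_library)) {
    el <- element_library[[fam]]
    t <- min(nchar(el), rl + 16L)
    termini[[fam]] <- list(
      `+` = list(start = substr(el, 1, t),
                 end = substr(el, nchar(el) - t + 1, nchar(el))),
      `-` = list(start = substr(revcomp(el), 1, t),
                 end = substr(revcomp(el), nchar(el) - t + 1, nchar(el))))
  }
  oriented <- c(reads, revcomp(reads))
  strand <- rep(c("+", "-"), each = length(reads))
  read_ix <- rep(seq_along(reads), 2)
  # exact 16-mer anchors at both read ends, found in bulk per contig
  pre <- Biostrings::PDict(Biostrings::DNAStringSet(
    substr(oriented, 1, anchor_w)))
  suf <- Biostrings::PDict(Biostrings::DNAStringSet(
    substr(oriented, rl - anchor_w + 1, rl)))
  ev <- list(); sp <- list()
  seen_full <- rep(FALSE, length(oriented))
  # bulk fast path: reads matching the reference exactly end-to-end
  full_pd <- Biostrings::PDict(Biostrings::DNAStringSet(oriented))
  for (ct in names(reference)) {
    fh <- Biostrings::matchPDict(full_pd,
                                 Biostrings::DNAString(reference[[ct]]))
    nfh <- IRanges::elementNROWS(fh)
    idx <- which(nfh > 0 & !seen_full)
    if (length(idx)) {
      st <- vapply(idx, function(i) Biostrings::start(fh[[i]])[1], 0L)
      sp[[length(sp) + 1L]] <- data.frame(
        contig = ct, start = st, end = st + rl - 1L,
        read_strand = strand[idx], read_id = ids[read_ix[idx]],
        qual = if (!is.null(quals)) quals[read_ix[idx]] else "",
        stringsAsFactors = FALSE)
      seen_full[idx] <- TRUE
      # one spanning record per read: mark the opposite orientation too
      nr <- length(reads)
      seen_full[ifelse(idx <= nr, idx + nr, idx - nr)] <- TRUE
    }
  }
  for (ct in names(reference)) {
    refseq <- reference[[ct]]
    subj <- Biostrings::DNAString(refseq)
    clen <- nchar(refseq)
    pre_hits <- Biostrings::matchPDict(pre, subj)
    suf_hits <- Biostrings::matchPDict(suf, subj)
    pre_n <- IRanges::elementNROWS(pre_hits)
    suf_n <- IRanges::elementNROWS(suf_hits)
    for (oi in which((pre_n > 0 | suf_n > 0) & !seen_full)) {
      s <- oriented[oi]
      q <- if (!is.null(quals)) quals[read_ix[oi]] else NULL
      handled_full <- FALSE
      # --- prefix-anchored: reference flank then (maybe) element tail
      for (p in Biostrings::start(pre_hits[[oi]])) {
        if (p + rl - 1L <= clen) {
          win <- substr(refseq, p, p + rl - 1L)
          if (hamming(s, win) <= 2) {  # reference-spanning read
            if (!seen_full[oi]) {
              sp[[length(sp) + 1L]] <- data.frame(
                contig = ct, start = p, end = p + rl - 1L,
                read_strand = strand[oi], read_id = ids[read_ix[oi]],
                qual = q %||% "", stringsAsFactors = FALSE)
              seen_full[oi] <- TRUE
            }
            handled_full <- TRUE
            next
          }
          plen <- max_prefix_match(s, win)
        } else {
          win <- substr(refseq, p, clen)
          plen <- max_prefix_match(substr(s, 1, nchar(win)), win)
        }
        h <- rl - plen
        if (plen < m || h < m) next
        tail_seg <- substr(s, plen + 1L, rl)
        # the maximal reference extension may absorb up to `ov` bases of
        # element-start microhomology; scan offsets and correct the
        # boundary back to the true junction coordinate
        found <- FALSE
        for (ov in 0:min(16L, plen - m)) {
          if (found) break
          for (fam in names(termini)) {
            if (found) break
            for (ori in c("+", "-")) {
              term <- termini[[fam]][[ori]]$start
              if (ov + nchar(tail_seg) > nchar(term)) next
              if (hamming(tail_seg, substr(term, ov + 1L,
                                           ov + nchar(tail_seg))) <= 1) {
                qs <- if (!is.null(q)) substr(q, plen + 1L, rl) else ""
                ev[[length(ev) + 1L]] <- data.frame(
                  contig = ct, boundary = p + plen - 1L - ov,
                  side = "left", family = fam, orientation = ori,
                  read_id = ids[read_ix[oi]], read_strand = strand[oi],
                  overhang_ref = plen - ov, overhang_elem = h + ov,
                  elem_quals = qs, stringsAsFactors = FALSE)
                found <- TRUE
                break
              }
            }
          }
        }
      }
      if (handled_full) next
      # --- suffix-anchored: element head then reference flank
      for (pend in Biostrings::end(suf_hits[[oi]])) {
        pstart <- pend - rl + 1L
        ws <- max(1L, pstart)
        win <- substr(refseq, ws, pend)
        seg <- substr(s, rl - nchar(win) + 1L, rl)
        if (pstart >= 1L && hamming(s, win) <= 2) {
          # reference-spanning read whose leading bases carry an error
          # (prefix anchor missed it)
          if (!seen_full[oi]) {
            sp[[length(sp) + 1L]] <- data.frame(
              contig = ct, start = pstart, end = pend,
              read_strand = strand[oi], read_id = ids[read_ix[oi]],
              qual = q %||% "", stringsAsFactors = FALSE)
            seen_full[oi] <- TRUE
          }
          next
        }
        # maximal suffix match via reversed prefix rule
        rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = "")
        slen <- max_prefix_match(rev_str(seg), rev_str(win))
        if (slen == rl) next  # full match under the extension rule
        h <- rl - slen
        if (slen < m || h < m) next
        head_seg <- substr(s, 1, h)
        found <- FALSE
        for (ov in 0:min(16L, slen - m)) {
          if (found) break
          for (fam in names(termini)) {
            if (found) break
            for (ori in c("+", "-")) {
              term <- termini[[fam]][[ori]]$end
              w <- nchar(term)
              if (ov + nchar(head_seg) > w) next
              if (hamming(head_seg, substr(term, w - ov - nchar(head_seg)
                                           + 1L, w - ov)) <= 1) {
                qs <- if (!is.null(q)) substr(q, 1, h) else ""
                ev[[length(ev) + 1L]] <- data.frame(
                  contig = ct, boundary = pend - slen + 1L + ov,
                  side = "right", family = fam, orientation = ori,
                  read_id = ids[read_ix[oi]], read_strand = strand[oi],
                  overhang_ref = slen - ov, overhang_elem = h + ov,
                  elem_quals = qs, stringsAsFactors = FALSE)
                found <- TRUE
                break
              }
            }
          }
        }
      }
    }
  }
  empty_ev <- data.frame(contig = character(0), boundary = integer(0),
                         side = character(0), family = character(0),
                         orientation = character(0), read_id = character(0),
                         read_strand = character(0),
                         overhang_ref = integer(0),
                         overhang_elem = integer(0),
                         elem_quals = character(0))
  empty_sp <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0), read_strand = character(0),
                         read_id = character(0), qual = character(0))
  evidence <- if (length(ev)) do.call(rbind, ev) else empty_ev
  # a read pair can touch a junction with both mates; each read counts once
  if (nrow(evidence))
    evidence <- evidence[!duplicated(evidence[c("read_id", "contig",
                                                "boundary", "side")]), ,
                         drop = FALSE]
  structure(list(evidence = evidence,
                 spanning = if (length(sp)) do.call(rbind, sp) else
                   empty_sp),
            class = "junction_evidence")
}

#' @export
print.junction_evidence <- function(x, ...) {
  cat(sprintf("Junction evidence: %d supporting reads at %d junction group(s); %d spanning alignments\n",
              nrow(x$evidence),
              nrow(unique(x$evidence[c("contig", "boundary", "side")])),
              nrow(x$spanning)))
  invisible(x)
}

phred_values <- function(qual_strings) {
  qs <- paste(qual_strings, collapse = "")
  if (!nchar(qs)) return(numeric(0))
  utf8ToInt(qs) - 33
}

#' Call IS insertions from junction evidence
#'
#' Left and right junction groups at nearby coordinates are paired when
#' the implied target-site duplication length `k = a - b + 1` (a = left
#' boundary, b = right boundary) lies within `[-max_tsd, max_tsd]`; the
#' allele frequency is the mean of per-side `J/(J+S)` where S counts
#' reference-spanning reads covering the boundary with at least `m` bases
#' on each side. Calls failing the frequency cutoff, the support minimum,
#' or missing one side are emitted with a non-PASS status rather than
#' dropped. Fisher strand-bias and Kolmogorov-Smirnov base-quality tests
#' annotate each two-sided call.
#'
#' @param junctions A `junction_evidence` object from [find_junctions()].
#' @param reference Named character vector of contigs or `is_genome`
#'   (used for TSD sequence extraction).
#' @param min_freq Frequency cutoff below which calls are flagged
#'   `LOW_FREQ`.
#' @param min_support Minimum total junction reads for PASS.
#' @param max_tsd Maximum |k| for pairing left and right junctions.
#' @param m Spanning-read margin (same as in [find_junctions()]).
#' @param min_group Junction groups with fewer reads than this are
#'   discarded as noise before pairing.
#' @return Data frame of class `insertion_calls`: family, contig, site
#'   (first TSD base, 1-based), orientation, tsd_seq, k, J_left, J_right,
#'   S_left, S_right, frequency, p_strand, p_qual, status.
#' @export
call_insertions <- function(junctions, reference, min_freq = 0.02,
                            min_support = 2, max_tsd = 20, m = 12,
                            min_group = 1, strict = FALSE) {
  if (inherits(reference, "is_genome")) reference <- reference$contigs
  ev <- junctions$evidence
  sp <- junctions$spanning
  empty <- data.frame(family = character(0), contig = character(0),
                      site = integer(0), orientation = character(0),
                      tsd_seq = character(0), k = integer(0),
                      J_left = integer(0), J_right = integer(0),
                      S_left = integer(0), S_right = integer(0),
                      frequency = numeric(0), p_strand = numeric(0),
                      p_qual = numeric(0), flag_strand = logical(0),
                      flag_qual = logical(0), status = character(0))
  if (!nrow(ev)) return(structure(empty, class = c("insertion_calls",
                                                   "data.frame")))
  key <- paste(ev$contig, ev$boundary, ev$side, ev$family)
  groups <- lapply(split(seq_len(nrow(ev)), key), function(ix)
    ev[ix, , drop = FALSE])
  gmeta <- do.call(rbind, lapply(groups, function(g) data.frame(
    contig = g$contig[1], boundary = g$boundary[1], side = g$side[1],
    family = g$family[1],
    orientation = names(sort(table(g$orientation),
                             decreasing = TRUE))[1],
    n = nrow(g), stringsAsFactors = FALSE)))
  keep <- gmeta$n >= min_group
  groups <- groups[keep]; gmeta <- gmeta[keep, , drop = FALSE]
  # --- fragment (read-pair) bookkeeping --------------------------------
  # With paired reads (ids of the form <fragment>/<mate>), J and S are
  # counted in fragment units: a concordant all-reference pair spanning a
  # boundary supports the reference allele over its whole outer span
  # (including the unsequenced inner gap), and a discordant pair whose
  # near mate points at the boundary supports the insertion even when
  # neither read crosses the junction (the far mate multi-maps back to a
  # resident element copy). Single-end input falls back to read units.
  paired <- nrow(sp) > 0 && any(grepl("/[12]$", sp$read_id))
  if (paired) {
    frag_of <- function(id) sub("/[12]$", "", id)
    sp$frag <- frag_of(sp$read_id)
    ev$frag <- frag_of(ev$read_id)
    # outer span per all-reference fragment on one contig
    two_r <- sp[order(sp$frag), , drop = FALSE]
    spl <- split(seq_len(nrow(two_r)), two_r$frag)
    pair_rows <- vapply(spl, length, 0L) == 2L
    pr <- t(vapply(spl[pair_rows], function(ix) {
      c(min(two_r$start[ix]), max(two_r$end[ix]),
        length(unique(two_r$contig[ix])))
    }, numeric(3)))
    pr_contig <- vapply(spl[pair_rows], function(ix) two_r$contig[ix[1]],
                        "")
    span <- pr[, 2] - pr[, 1] + 1
    ins_est <- stats::median(span[pr[, 3] == 1 & span < 5000])
    conc <- pr[, 3] == 1 & abs(span - ins_est) <= 0.25 * ins_est
    conc_df <- data.frame(frag = names(spl[pair_rows])[conc],
                          contig = pr_contig[conc],
                          start = pr[conc, 1], end = pr[conc, 2],
                          stringsAsFactors = FALSE)
    # near-mate candidates for discordant support: reference reads whose
    # fragment is not concordant and not already junction evidence
    junction_frags <- unique(ev$frag)
    disc <- sp[!(sp$frag %in% conc_df$frag) &
                 !(sp$frag %in% junction_frags), , drop = FALSE]
    reach <- max(0, round(ins_est)) # how far a near mate can sit from
                                    # the boundary and still span it
  }
  span_count <- function(contig, pos) {
    sum(sp$contig == contig & sp$start <= pos - m + 1L &
          sp$end >= pos + m - 1L)
  }
  frag_counts <- function(contig, pos, side, group) {
    # fragment-unit J and S for one boundary
    j_frags <- unique(sub("/[12]$", "", group$read_id))
    if (side == "left") {
      d <- disc[disc$contig == contig & disc$read_strand == "+" &
                  disc$end <= pos & disc$end >= pos - (reach - 1L) &
                  !(disc$frag %in% j_frags), , drop = FALSE]
    } else {
      d <- disc[disc$contig == contig & disc$read_strand == "-" &
                  disc$start >= pos & disc$start <= pos + (reach - 1L) &
                  !(disc$frag %in% j_frags), , drop = FALSE]
    }
    J <- length(j_frags) + length(unique(d$frag))
    S <- sum(conc_df$contig == contig & conc_df$start <= pos - m + 1L &
               conc_df$end >= pos + m - 1L)
    c(J = J, S = S)
  }
  span_strands <- function(contig, pos) {
    s <- sp$read_strand[sp$contig == contig & sp$start <= pos - m + 1L &
                          sp$end >= pos + m - 1L]
    c(fwd = sum(s == "+"), rev = sum(s == "-"))
  }
  used <- rep(FALSE, nrow(gmeta))
  calls <- list()
  add_call <- function(left, right, lg, rg) {
    # left/right: gmeta rows (or NULL); lg/rg: evidence data frames
    contig <- (left %||% right)$contig
    family <- (left %||% right)$family
    a <- if (!is.null(left)) left$boundary else NA_integer_
    b <- if (!is.null(right)) right$boundary else NA_integer_
    k <- if (!is.na(a) && !is.na(b)) a - b + 1L else NA_integer_
    status <- character(0)
    tsd <- ""
    if (!is.na(k)) {
      if (k > 0) tsd <- substr(reference[[contig]], b, a)
      if (k < 0) { status <- c(status, "TARGET_DELETION"); k <- k }
    } else status <- c(status, "ONE_SIDED")
    site <- if (!is.na(b)) b else a + 1L
    if (paired) {
      cl <- if (!is.na(a)) frag_counts(contig, a, "left", lg)
      cr <- if (!is.na(b)) frag_counts(contig, b, "right", rg)
      Jl <- if (!is.na(a)) cl[["J"]] else 0L
      Jr <- if (!is.na(b)) cr[["J"]] else 0L
      Sl <- if (!is.na(a)) cl[["S"]] else NA_integer_
      Sr <- if (!is.na(b)) cr[["S"]] else NA_integer_
    } else {
      Jl <- if (!is.null(lg)) nrow(lg) else 0L
      Jr <- if (!is.null(rg)) nrow(rg) else 0L
      Sl <- if (!is.na(a)) span_count(contig, a) else NA_integer_
      Sr <- if (!is.na(b)) span_count(contig, b) else NA_integer_
    }
    fsides <- c(if (Jl > 0 || (!is.na(Sl) && Sl > 0)) Jl / (Jl + Sl),
                if (Jr > 0 || (!is.na(Sr) && Sr > 0)) Jr / (Jr + Sr))
    f <- if (length(fsides)) mean(fsides) else NA_real_
    jstr <- c(if (!is.null(lg)) lg$read_strand,
              if (!is.null(rg)) rg$read_strand)
    rstr <- span_strands(contig, site)
    tab <- matrix(c(sum(jstr == "+"), sum(jstr == "-"),
                    rstr["fwd"], rstr["rev"]), nrow = 2, byrow = TRUE)
    ps <- strand_bias_test(tab)
    # base qualities at junction-supporting element-side bases vs the
    # base quality of reference-spanning reads at the site itself
    jq <- phred_values(c(if (!is.null(lg)) lg$elem_quals,
                         if (!is.null(rg)) rg$elem_quals))
    spr <- sp[sp$contig == contig & sp$start <= site & sp$end >= site, ,
              drop = FALSE]
    rq <- if (nrow(spr) && all(nzchar(spr$qual)))
      utf8ToInt(paste(substr(spr$qual, site - spr$start + 1L,
                             site - spr$start + 1L), collapse = "")) - 33
    else numeric(0)
    pq <- quality_bias_test(jq, rq)
    if (!is.na(f) && f < min_freq) status <- c(status, "LOW_FREQ")
    if (Jl + Jr < min_support) status <- c(status, "LOW_SUPPORT")
    if (strict) {
      if (isTRUE(ps$flag)) status <- c(status, "STRAND_BIAS")
      if (isTRUE(pq$flag)) status <- c(status, "QUAL_BIAS")
    }
    calls[[length(calls) + 1L]] <<- data.frame(
      family = family, contig = contig, site = site,
      orientation = (left %||% right)$orientation,
      tsd_seq = tsd, k = if (is.na(k)) NA_integer_ else as.integer(k),
      J_left = Jl, J_right = Jr, S_left = Sl, S_right = Sr,
      frequency = f, p_strand = ps$p, p_qual = pq$p,
      flag_strand = ps$flag, flag_qual = pq$flag,
      status = if (length(status)) paste(status, collapse = ";") else
        "PASS", stringsAsFactors = FALSE)
  }
  lefts <- which(gmeta$side == "left")
  rights <- which(gmeta$side == "right")
  for (li in lefts) {
    cand <- rights[!used[rights] & gmeta$contig[rights] == gmeta$contig[li] &
                     gmeta$family[rights] == gmeta$family[li]]
    if (length(cand)) {
      kk <- gmeta$boundary[li] - gmeta$boundary[cand] + 1L
      ok <- abs(kk) <= max_tsd
      cand <- cand[ok]; kk <- kk[ok]
    }
    if (length(cand)) {
      ri <- cand[which.min(abs(kk))]
      used[li] <- used[ri] <- TRUE
      add_call(gmeta[li, ], gmeta[ri, ], groups[[li]], groups[[ri]])
    }
  }
  for (li in lefts[!used[lefts]])
    add_call(gmeta[li, ], NULL, groups[[li]], NULL)
  for (ri in rights[!used[rights]])
    add_call(NULL, gmeta[ri, ], NULL, groups[[ri]])
  out <- if (length(calls)) do.call(rbind, calls) else empty
  out <- out[order(out$contig, out$site), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("insertion_calls", "data.frame"))
}

#' Infer the target-site duplication from paired junction boundaries
#'
#' With `a` the left-flank boundary and `b` the right-flank resumption
#' coordinate (both 1-based), `k = a - b + 1`: `k > 0` yields the
#' duplicated sequence `reference[b..a]`, `k = 0` a blunt insertion, and
#' `k < 0` an implied target deletion (no TSD, flagged).
#'
#' @param a,b Left and right boundary coordinates.
#' @param reference Contig sequence (character) containing the site.
#' @return List (k, tsd_seq, flag).
#' @export
infer_tsd <- function(a, b, reference) {
  k <- a - b + 1L
  if (k > 0) list(k = k, tsd_seq = substr(reference, b, a), flag = NA)
  else if (k == 0) list(k = 0L, tsd_seq = "", flag = NA)
  else list(k = k, tsd_seq = "", flag = "TARGET_DELETION")
}

#' Fisher exact test for strand bias at a candidate insertion
#'
#' Two-sided exact test on the 2x2 table of forward/reverse read counts
#' among junction-supporting vs reference-supporting reads.
#'
#' @param tab 2x2 matrix: rows = junction, reference; columns = forward,
#'   reverse.
#' @return List (p, flag): `flag` is `TRUE` when p < 0.01. Empty margins
#'   give p = 1 with `flag = NA`.
#' @export
strand_bias_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, flag = NA))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(p = p, flag = p < 0.01)
}

#' Kolmogorov-Smirnov test for low base quality at a candidate insertion
#'
#' One-sided two-sample KS test of the alternative that
#' junction-supporting base qualities are stochastically lower than
#' reference-supporting ones. Exact small-sample p when both samples have
#' at most 25 observations, asymptotic otherwise.
#'
#' @param junction_quals,ref_quals Numeric Phred quality samples.
#' @return List (p, flag, note). Fewer than 3 observations in either
#'   class yields p = NA with `note = "INSUFFICIENT_DATA"`.
#' @export
quality_bias_test <- function(junction_quals, ref_quals) {
  if (length(junction_quals) < 3 || length(ref_quals) < 3)
    return(list(p = NA_real_, flag = NA, note = "INSUFFICIENT_DATA"))
  exact <- length(junction_quals) <= 25 && length(ref_quals) <= 25
  p <- suppressWarnings(stats::ks.test(junction_quals, ref_quals,
                                       alternative = "greater",
                                       exact = exact)$p.value)
  list(p = p, flag = p < 0.01, note = NA)
}

#' Terminal inverted repeat of an IS element
#'
#' Longest prefix (at least `min_len`) whose reverse complement equals
#' the element suffix with at most `max_mismatch` mismatches, capped at
#' half the element length.
#'
#' @param element_seq Element sequence.
#' @param min_len Minimum reportable repeat length.
#' @param max_mismatch Allowed mismatches between prefix and
#'   reverse-complemented suffix.
#' @return List (itr_length, left_seq, right_seq); `itr_length = 0` when
#'   no repeat of at least `min_len` exists.
#' @export
find_inverted_repeats <- function(element_seq, min_len = 5,
                                  max_mismatch = 0) {
  n <- nchar(element_seq)
  stopifnot(n >= 2 * min_len)
  best <- 0L
  for (L in seq(min_len, n %/% 2)) {
    pre <- substr(element_seq, 1, L)
    suf <- substr(element_seq, n - L + 1, n)
    if (hamming(revcomp(pre), suf) <= max_mismatch) best <- L
  }
  if (best == 0)
    return(list(itr_length = 0L, left_seq = "", right_seq = ""))
  list(itr_length = best, left_seq = substr(element_seq, 1, best),
       right_seq = substr(element_seq, n - best + 1, n))
}

#' Mean GC of target-site duplications vs genomic background
#'
#' @param calls `insertion_calls` (or any data frame with `tsd_seq`).
#' @param reference Contigs or `is_genome` for the background.
#' @param annotation Optional gene table for the coding/noncoding split.
#' @return List (mean_tsd_gc, n_tsd, gc_coding, gc_noncoding,
#'   gc_overall); `mean_tsd_gc` is the unweighted mean over non-empty
#'   TSDs (`NA` when none).
#' @export
target_site_gc <- function(calls, reference, annotation = NULL) {
  tsd <- calls$tsd_seq[!is.na(calls$tsd_seq) & nzchar(calls$tsd_seq)]
  st <- assembly_stats(reference, annotation)
  list(mean_tsd_gc = if (length(tsd)) mean(gc_fraction(tsd)) else NA_real_,
       n_tsd = length(tsd), gc_coding = st$gc_coding,
       gc_noncoding = st$gc_noncoding, gc_overall = st$gc_overall)
}
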